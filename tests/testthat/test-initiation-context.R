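# TE-weighted PSSM construction and WRENT scoring.

test_that("context extraction yields 23-nt windows and drops truncated AUGs", {
  set.seed(2)
  tx <- random_transcript(40, 120)
  ctx <- extract_contexts(tx, data.frame(transcript_id = "T1",
                                         start = tx$cds_start))
  expect_equal(nchar(ctx$context), 23L)
  expect_equal(substr(ctx$context, 11, 13), "ATG")
  # an AUG 5 nt from the transcript start cannot host a full context
  tx2 <- tx_fixture(paste0("CCCCC", "ATGTAA", strrep("C", 20),
                           "ATG", strrep("GCA", 39), "TAA"), 31, 151)
  ctx2 <- extract_contexts(tx2, data.frame(transcript_id = "T1", start = 5L))
  expect_equal(nrow(ctx2), 0L)
  expect_equal(attr(ctx2, "n_truncated"), 1L)
})

test_that("weighted column frequencies match hand computation", {
  # two contexts, both TE = e - 1 so each weight is exactly 1
  ctxs <- c("CA", "GA")
  m <- build_wrent(ctxs, tes = c(exp(1) - 1, exp(1) - 1), pseudocount = 0,
                   aug_at = NA)
  expect_equal(unname(m$columns[, 1]), c(0, 0.5, 0.5, 0))  # {C,G} equal split
  expect_equal(unname(m$columns[, 2]), c(1, 0, 0, 0))
  # all training contexts identical -> point-mass columns
  m2 <- build_wrent(rep("TGA", 5), tes = rep(2, 5), pseudocount = 0, aug_at = NA)
  expect_equal(unname(m2$columns[4, 1]), 1)
  # scaling all weights equally leaves the model unchanged
  tes1 <- c(0.5, 3, 9); tes10 <- expm1(10 * log1p(tes1))
  ma <- build_wrent(c("AC", "CG", "GT"), tes1, pseudocount = 0.01, aug_at = NA)
  mb <- build_wrent(c("AC", "CG", "GT"), tes10, pseudocount = 0.1, aug_at = NA)
  # weights scale x10 and the pseudocount follows -> identical frequencies
  expect_equal(ma$columns, mb$columns, tolerance = 1e-12)
})

test_that("equal-TE weighting reproduces a classical unweighted PSSM", {
  set.seed(31)
  ctxs <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = ""), character(1))
  ctxs <- paste0(substr(ctxs, 1, 10), "ATG", substr(ctxs, 14, 23))
  m <- build_wrent(ctxs, tes = rep(exp(1) - 1, 60), pseudocount = 0)
  want <- oracle_unweighted_pssm(ctxs, pseudocount = 0)
  expect_equal(unname(m$columns), unname(want), tolerance = 1e-9)
})

test_that("the toy 2-position model scores 'AC' at 2 bits and background-equal models at 0", {
  cols <- cbind(c(1, 0, 0, 0), c(0, 0.5, 0.5, 0))
  bg <- c(0.5, 0.25, 0.25, 0)
  toy <- wrent_model(cols, background = bg)
  expect_equal(wrent_score(toy, "AC"), 2)     # 1 bit + 1 bit, hand-derived
  expect_equal(wrent_score(toy, "AG"), 2)
  # a base rarer in the column than in the background contributes negatively
  toy2 <- wrent_model(cbind(c(0.1, 0.3, 0.3, 0.3)), background = c(0.25, 0.25, 0.25, 0.25))
  expect_lt(wrent_score(toy2, "A"), 0)
  # every column equal to background -> score 0 for any context
  flat <- wrent_model(matrix(0.25, 4, 23), background = rep(0.25, 4),
                      scored = setdiff(1:23, 11:13))
  set.seed(4)
  rnd <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = ""), character(1))
  expect_equal(wrent_score(flat, rnd), rep(0, 20))
})

test_that("scores decompose into per-position terms (additivity)", {
  set.seed(12)
  ctxs <- vapply(1:40, function(i)
    paste0(paste(sample(c("A","C","G","T"), 10, TRUE), collapse = ""), "ATG",
           paste(sample(c("A","C","G","T"), 10, TRUE), collapse = "")),
    character(1))
  m <- build_wrent(ctxs, tes = runif(40, 0, 5))
  sc <- wrent_score(m, ctxs[1])
  terms <- vapply(m$scored, function(p) {
    b <- uorfrepress:::seq_to_int(substr(ctxs[1], p, p)) + 1L
    log2(m$columns[b, p] / m$background[b])
  }, numeric(1))
  expect_equal(sc, sum(terms), tolerance = 1e-12)
})

test_that("relative entropy is 0 at background, 2 bits at a point mass over uniform", {
  flat <- wrent_model(matrix(0.25, 4, 3), background = rep(0.25, 4))
  expect_equal(relative_entropy_profile(flat), rep(0, 3))
  pm <- wrent_model(cbind(c(1, 0, 0, 0)), background = rep(0.25, 4))
  expect_equal(relative_entropy_profile(pm), 2)
  toy <- wrent_model(cbind(c(1, 0, 0, 0), c(0, 0.5, 0.5, 0)),
                     background = c(0.5, 0.25, 0.25, 0))
  expect_equal(relative_entropy_profile(toy, 2), 1)  # 0.5*1 + 0.5*1
})

test_that("WRENT rank-correlates with TE when TE is coupled to a planted motif", {
  set.seed(77)
  n <- 500
  ref <- kozak_reference_model(0.45)
  # draw contexts from a mixture of consensus and background, TE tied to the
  # mixture weight
  q <- runif(n)
  bg <- c(0.275, 0.225, 0.225, 0.275)
  ctxs <- vapply(seq_len(n), function(i) {
    s <- vapply(1:23, function(p) {
      pr <- (1 - q[i]) * bg + q[i] * ref$columns[, p]
      sample(c("A", "C", "G", "T"), 1, prob = pr)
    }, character(1))
    paste(c(s[1:10], "ATG", s[14:23]), collapse = "")
  }, character(1))
  te <- exp(2 * q + rnorm(n, 0, 0.3))
  m <- build_wrent(ctxs, te)
  sc <- wrent_score(m, ctxs)
  ct <- cor.test(sc, te, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("a WRENT model survives TSV/JSON serialization", {
  set.seed(8)
  ctxs <- vapply(1:30, function(i)
    paste0(paste(sample(c("A","C","G","T"), 10, TRUE), collapse = ""), "ATG",
           paste(sample(c("A","C","G","T"), 10, TRUE), collapse = "")),
    character(1))
  m <- build_wrent(ctxs, runif(30, 0, 3))
  dir <- withr::local_tempdir()
  write_wrent(m, file.path(dir, "m.tsv"), file.path(dir, "m.json"))
  m2 <- read_wrent(file.path(dir, "m.tsv"), file.path(dir, "m.json"))
  expect_equal(m2$columns, m$columns, tolerance = 1e-12)
  expect_equal(m2$background, m$background, tolerance = 1e-12)
  expect_equal(m2$scored, m$scored)
  set.seed(9)
  probe <- vapply(1:10, function(i)
    paste0(paste(sample(c("A","C","G","T"), 10, TRUE), collapse = ""), "ATG",
           paste(sample(c("A","C","G","T"), 10, TRUE), collapse = "")),
    character(1))
  expect_equal(wrent_score(m2, probe), wrent_score(m, probe), tolerance = 1e-12)
})

test_that("degenerate training sets are rejected", {
  expect_error(build_wrent(character(0), numeric(0)), "empty")
  expect_error(build_wrent(c("ACA", "AGA"), c(0, 0), aug_at = NA), "weight")
})
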