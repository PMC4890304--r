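# Ridge regression, PRESS, fold change and the feature-table assembly.

test_that("zscore uses the sample SD and is affine-invariant and idempotent", {
  z <- zscore(data.frame(a = c(1, 2, 3)))
  expect_equal(unname(z$z[, 1]), c(-1, 0, 1))
  set.seed(61)
  x <- data.frame(f1 = rnorm(50, 10, 3), f2 = runif(50))
  z1 <- zscore(x)
  # idempotence on already-standardized input
  z2 <- zscore(as.data.frame(z1$z))
  expect_equal(z2$z, z1$z, tolerance = 1e-12)
  # affine invariance
  x2 <- data.frame(f1 = 5 * x$f1 - 2, f2 = 0.1 * x$f2 + 7)
  expect_equal(zscore(x2)$z, z1$z, tolerance = 1e-12)
  expect_error(zscore(data.frame(ok = rnorm(5), flat = rep(1, 5))), "flat")
})

test_that("ridge at alpha -> 0 recovers the least-squares slope exactly", {
  set.seed(62)
  x <- matrix(rnorm(100), dimnames = list(NULL, "f"))
  y <- 2.5 * x[, 1] + 1
  fit <- fit_ridge(x, y, alpha = 1e-10)
  ls <- unname(coef(lm(y ~ x))[2])
  expect_equal(unname(fit$coefficients), ls, tolerance = 1e-6)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_error(fit_ridge(cbind(f1 = x[, 1], f2 = x[, 1]), y, alpha = 0),
               "alpha")
})

test_that("coefficients match the augmented-least-squares ridge oracle", {
  set.seed(63)
  for (rep in 1:10) {
    n <- sample(40:120, 1); p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    alpha <- sample(c(0.01, 0.5, 1, 10), 1)
    fit <- fit_ridge(x, y, alpha)
    want <- oracle_ridge(x, y, alpha)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), want,
                 tolerance = 1e-8)
  }
})

test_that("null responses give small correlations at the expected rate", {
  n <- 750
  hits <- 0L
  for (s in 1:40) {
    d <- simulate_feature_response(n, c(a = 0, b = 0, c = 0), noise_sd = 1,
                                   seed = 700 + s)
    fit <- fit_ridge(d$x, d$y, alpha = 1)
    if (abs(fit$pearson_r) < 3 / sqrt(n)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})

test_that("hat-matrix LOO equals explicit refits and PRESS >= RESS", {
  set.seed(65)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rnorm(50)
    for (alpha in c(0.1, 1, 10)) {
      fit <- fit_ridge(x, y, alpha)
      expect_equal(fit$press, press_explicit(x, y, alpha), tolerance = 1e-8)
      expect_gt(fit$press, fit$ress)
    }
  }
})

test_that("duplicating every row decreases PRESS (information check)", {
  set.seed(66)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x %*% c(1, -1, 0.5) + rnorm(40, 0, 1)
  f1 <- fit_ridge(x, as.vector(y), 1)
  f2 <- fit_ridge(rbind(x, x), c(y, y), 1)
  expect_lt(f2$press / 2, f1$press)   # per-copy prediction error shrinks
})

test_that("an irrelevant noise feature does not materially improve PRESS", {
  worse <- 0L
  for (s in 1:20) {
    d <- simulate_feature_response(300, c(a = 0.5, b = -0.5), noise_sd = 0.7,
                                   seed = 900 + s)
    base <- fit_ridge(d$x, d$y, 1)$press
    set.seed(9000 + s)
    xx <- cbind(d$x, junk = rnorm(300))
    with_junk <- fit_ridge(xx, d$y, 1)$press
    if (with_junk < base * 0.98) worse <- worse + 1L
  }
  expect_lte(worse, 2L)   # soft check over seeds
})

test_that("combined scores are order-invariant", {
  d <- simulate_feature_response(200, c(a = 0.4, b = -0.2, c = 0.1),
                                 noise_sd = 0.5, seed = 67)
  f1 <- fit_ridge(d$x, d$y, 1)
  perm <- c("c", "a", "b")
  f2 <- fit_ridge(d$x[, perm], d$y, 1)
  expect_equal(f2$combined_score, f1$combined_score, tolerance = 1e-10)
  expect_equal(f2$coefficients[perm], f1$coefficients[perm], tolerance = 1e-10)
  rp <- sample(200)
  f3 <- fit_ridge(d$x[rp, ], d$y[rp], 1)
  expect_equal(sort(f3$coefficients), sort(f1$coefficients), tolerance = 1e-10)
})

test_that("fold_change_95 equals direct evaluation of the fitted line", {
  d <- simulate_feature_response(400, c(f = 0.6), noise_sd = 0.4, seed = 68)
  fit <- fit_ridge(d$x, d$y, 1)
  qs <- quantile(fit$combined_score, c(0.025, 0.975), type = 7, names = FALSE)
  line <- function(s) fit$slope * s    # fitted line up to intercept
  expect_equal(fit$fold_change_95, exp(line(qs[2]) - line(qs[1])),
               tolerance = 1e-9)
  # slope 0 -> fold 1
  flat <- fit; flat$slope <- 0
  expect_equal(fold_change_95(flat), 1)
  # degenerate scores -> fold 1
  deg <- fit; deg$combined_score <- rep(0.3, 400)
  expect_equal(fold_change_95(deg), 1)
})

test_that("planted coefficient signs are recovered at study scale", {
  beta <- c(uorf_density = -0.3, uorf_wrent = -0.3, cds_wrent = 0.3,
            leader_mean_efe = 0.3, cds_mean_efe = 0.3)
  ok <- 0L
  for (s in 1:25) {
    d <- simulate_feature_response(750, beta, noise_sd = 0.5, seed = 100 + s)
    fit <- fit_ridge(d$x, d$y, alpha = 1)
    if (all(sign(fit$coefficients[names(beta)]) == sign(beta))) ok <- ok + 1L
  }
  expect_gte(ok / 25, 0.95)
})

test_that("the feature table honors subset filters and the density pseudocount", {
  set.seed(70)
  cfg <- sim_config(n_transcripts = 60, seed = 12, depth = 3,
                    uorf_rate = 0.5)
  ds <- simulate_dataset(cfg)
  tx <- ds$transcripts
  orfs <- find_orfs_all(tx)
  tet <- te_table(tx, orfs, ds$tracks)
  wrent <- kozak_reference_model()
  profiles <- efe_profiles_all(tx, gc_engine(), orfs = orfs)

  ft <- build_feature_table(tx, orfs, tet, wrent, profiles,
                            subset = "one_nonoverlapping_uorf",
                            response = "repressiveness")
  nu <- n_uorfs_per_transcript(tx, orfs)
  # every retained transcript has exactly one uORF and it is non-overlapping
  expect_true(all(nu[match(ft$transcript_id, tx$transcript_id)] == 1L))
  expect_true(all(c("uorf_wrent", "uorf_length", "uorf_end_pos_rel_cds")
                  %in% names(ft)))
  expect_true(all(is.finite(ft$response)))

  fta <- build_feature_table(tx, orfs, tet, wrent, profiles,
                             subset = "all", response = "cds_te")
  # transcripts lacking uORFs use the 0.1 pseudocount in the log density
  no_u <- fta$transcript_id[fta$transcript_id %in%
                              tx$transcript_id[nu == 0L]]
  i <- match(no_u, fta$transcript_id)
  j <- match(no_u, tx$transcript_id)
  expect_equal(fta$uorf_density[i], log(0.1 / tx$cds_start[j]))

  ftw <- build_feature_table(tx, orfs, tet, wrent, profiles,
                             subset = "without_uorfs", response = "cds_te")
  expect_true(all(nu[match(ftw$transcript_id, tx$transcript_id)] == 0L))
  expect_error(build_feature_table(tx[nu >= 1, ], orfs, tet, wrent, profiles,
                                   subset = "without_uorfs",
                                   response = "cds_te"),
               "empty subset")
})

test_that("model_report returns one row per feature-set combination", {
  d <- simulate_feature_response(300, c(a = 0.3, b = -0.3, c = 0.2),
                                 noise_sd = 0.5, seed = 71)
  tbl <- as.data.frame(d$x)
  tbl$response <- d$y
  mr <- model_report(tbl, list(one = "a", two = c("a", "b"),
                               three = c("a", "b", "c")), alpha = 1)
  expect_equal(mr$report$feature_set, c("one", "two", "three"))
  expect_true(all(mr$report$press >= mr$report$ress))
  expect_true(all(diff(mr$report$pearson_r) > 0))  # nested sets improve fit here
})
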