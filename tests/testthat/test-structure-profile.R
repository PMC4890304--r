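# Sliding-window EFE profiles, anchors, region means and meta-profiles.

test_that("profile length arithmetic is exact for all supported windows", {
  set.seed(21)
  tx <- random_transcript(60, 150, 40)
  for (w in c(25L, 30L, 35L, 40L)) {
    pr <- efe_profile(tx[1, ], gc_engine(), window = w)
    expect_length(pr$values, nchar(tx$sequence) - w + 1L)
  }
  # transcript shorter than the window -> empty profile
  short <- tx_fixture(paste0("A", "ATG", strrep("GCA", 9), "TAA"), 1, 34)  # 34 nt
  expect_length(efe_profile(short[1, ], gc_engine(), 35)$values, 0L)
  # transcripts containing N are skipped
  n_tx <- tx_fixture(paste0("AANAA", strrep("C", 20), "ATG", strrep("GCA", 39),
                            "TAA"), 25, 145)
  prn <- efe_profile(n_tx[1, ], gc_engine(), 35)
  expect_true(prn$skipped)
  expect_length(prn$values, 0L)
})

test_that("a constant engine yields constant profiles and means", {
  set.seed(22)
  tx <- random_transcript(80, 150, 40)
  pr <- efe_profile(tx[1, ], constant_engine(0), 35, orf_starts = tx$cds_start)
  expect_true(all(pr$values == 0))
  rm <- region_mean_efe(pr, tx[1, ])
  expect_equal(rm$leader_mean_efe, 0)
  expect_equal(rm$cds_mean_efe, 0)
})

test_that("the GC toy engine fast path equals the generic substring path", {
  set.seed(25)
  tx <- random_transcript(70, 150, 30)
  eng <- gc_engine()
  fast <- efe_profile(tx[1, ], eng, 35)$values
  slow_eng <- list(name = "gc_slow", fold = eng$fold)   # no profile shortcut
  slow <- efe_profile(tx[1, ], slow_eng, 35)$values
  expect_equal(fast, slow)
})

test_that("anchor windows start at orf_start - 25 and orf_start + 1", {
  set.seed(26)
  tx <- random_transcript(80, 150, 30)
  eng <- gc_engine()
  pr <- efe_profile(tx[1, ], eng, 35, orf_starts = tx$cds_start)
  a <- pr$anchors
  expect_equal(a$efe_minus25, pr$values[tx$cds_start - 25 + 1])
  expect_equal(a$efe_plus1, pr$values[tx$cds_start + 1 + 1])
  # an ORF start too close to the 5' end has no -25 anchor
  pr2 <- efe_profile(tx[1, ], eng, 35, orf_starts = 10L)
  expect_true(is.na(pr2$anchors$efe_minus25))
})

test_that("region means use strictly contained windows only", {
  # leader of 40 with window 35: window starts 0..5 are fully inside
  set.seed(27)
  tx <- random_transcript(40, 150, 30)
  eng <- gc_engine()
  pr <- efe_profile(tx[1, ], eng, 35)
  rm <- region_mean_efe(pr, tx[1, ])
  expect_equal(rm$leader_mean_efe, mean(pr$values[1:6]))
  ks <- (tx$cds_start):(tx$cds_end - 35)
  expect_equal(rm$cds_mean_efe, mean(pr$values[ks + 1]))
  # region shorter than the window -> absent
  tx2 <- random_transcript(20, 150, 30)
  rm2 <- region_mean_efe(efe_profile(tx2[1, ], eng, 35), tx2[1, ])
  expect_true(is.na(rm2$leader_mean_efe))
})

test_that("meta-profiles average per offset and recover a planted hairpin dip", {
  set.seed(28)
  # two constant-profile transcripts -> meta-profile is the average
  tx2 <- transcriptome(rbind(random_transcript(60, 120, 30, id = "m1"),
                             random_transcript(60, 120, 30, id = "m2")))
  profs <- list(m1 = efe_profile(tx2[1, ], constant_engine(0), 35,
                                 tx2$cds_start[1]),
                m2 = efe_profile(tx2[2, ], constant_engine(-2), 35,
                                 tx2$cds_start[2]))
  orfs <- data.frame(transcript_id = c("m1", "m2"), start = tx2$cds_start)
  mp <- meta_profile(profs, orfs, span = 20L)
  expect_true(all(abs(mp$mean_efe - (-1)) < 1e-12))
  expect_true(all(mp$n == 2L))
  # single ORF -> its own profile slice
  mp1 <- meta_profile(profs["m1"], orfs[1, ], span = 10L)
  expect_equal(mp1$mean_efe, rep(0, 21))

  # a GC-rich hairpin planted just downstream of CDS starts produces a dip
  # there under the GC engine, absent at uORF starts
  n <- 30
  mk <- function(i) {
    lead <- paste0(strrep("A", 30), "ATGTAA", strrep("A", 60))  # uORF at 30
    hair <- paste0(strrep("GC", 8), strrep("A", 105 - 16))
    tx_fixture(paste0(lead, "ATG", hair, strrep("A", 12), "TAA",
                      strrep("A", 30)),
               96, 96 + 123, id = sprintf("h%02d", i))
  }
  txh <- transcriptome(do.call(rbind, lapply(1:n, mk)))
  orfsh <- find_orfs_all(txh)
  profh <- efe_profiles_all(txh, gc_engine(), orfs = orfsh)
  cds_meta <- meta_profile(profh, orfsh[orfsh$klass == "CDS", ], span = 30L)
  uorf_meta <- meta_profile(profh, orfsh[orfsh$klass == "uORF_nonoverlapping", ],
                            span = 20L)
  expect_lt(min(cds_meta$mean_efe[cds_meta$offset > 0]),
            min(uorf_meta$mean_efe, na.rm = TRUE) - 1)
})

test_that("swapping engines changes values but not shape or indexing", {
  set.seed(29)
  tx <- random_transcript(60, 150, 30)
  p1 <- efe_profile(tx[1, ], constant_engine(-1), 35, tx$cds_start)
  p2 <- efe_profile(tx[1, ], gc_engine(), 35, tx$cds_start)
  expect_length(p2$values, length(p1$values))
  expect_equal(p2$anchors$orf_start, p1$anchors$orf_start)
  expect_false(isTRUE(all.equal(p1$values, p2$values)))
})

test_that("anchor_scan is null on independent TE and peaks at a planted offset", {
  set.seed(30)
  n <- 120
  txs <- transcriptome(do.call(rbind, lapply(seq_len(n), function(i)
    random_transcript(80, 150, 30, id = sprintf("s%03d", i)))))
  profs <- efe_profiles_all(txs, gc_engine())
  # independent TE -> correlations small at every offset
  st <- data.frame(transcript_id = txs$transcript_id, start = txs$cds_start,
                   log_te = rnorm(n))
  sc <- anchor_scan(profs, st, offsets = seq(-30L, 10L, by = 5L))
  expect_true(all(abs(sc$pearson) < 4 / sqrt(n), na.rm = TRUE))
  # TE a monotone function of the EFE at offset +1 -> |r| maximal there
  efe_p1 <- vapply(seq_len(n), function(i)
    profs[[i]]$values[txs$cds_start[i] + 2], numeric(1))
  st2 <- st; st2$log_te <- 0.8 * scale(efe_p1)[, 1] + rnorm(n, 0, 0.2)
  sc2 <- anchor_scan(profs, st2, offsets = c(-25L, -10L, 1L, 8L))
  expect_equal(sc2$offset[which.max(abs(sc2$pearson))], 1L)
  # constant EFE -> correlation absent
  profc <- efe_profiles_all(txs, constant_engine(0))
  scc <- anchor_scan(profc, st, offsets = 1L)
  expect_true(is.na(scc$pearson))
})

test_that("the ViennaRNA engine reports near-zero EFE for unstructured poly-A", {
  eng <- vienna_engine()
  tx <- tx_fixture(paste0(strrep("A", 40), "ATG", strrep("AAA", 18), "TAA",
                          strrep("A", 3)), 40, 100)
  pr <- efe_profile(tx[1, ], eng, 35)
  expect_length(pr$values, nchar(tx$sequence) - 34)
  expect_true(all(pr$values >= -0.5))
  # and a strong hairpin folds stably
  hp <- "GGGGCCCCAAAAGGGGCCCCGGGGCCCCAAAAGGG"
  expect_lt(eng$fold(hp), -5)
})
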