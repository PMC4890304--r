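# Cross-species ortholog comparisons: z-normalization, divergence,
# correlations and divergence models.

# small paired summaries built directly (no read simulation needed)
summary_fixture <- function(n, rho, seed, sd_b = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n) * sd_b
  mk <- function(v, tag) data.frame(
    transcript_id = sprintf("%s%04d", tag, seq_len(n)),
    level = exp(v + rnorm(n, 3, 0.1)), cds_density = exp(v),
    cds_te = exp(v / 2), leader_te = exp(v / 3),
    leader_repressiveness = exp(v / 4),
    n_uorfs = rpois(n, 1), leader_length = 100 + seq_len(n) %% 50,
    leader_mean_efe = -5 + v / 10, cds_wrent = v, cds_mean_efe = -8 + v / 5,
    stringsAsFactors = FALSE)
  list(a = mk(a, "m"), b = mk(b, "h"),
       pairs = data.frame(id_a = sprintf("m%04d", seq_len(n)),
                          id_b = sprintf("h%04d", seq_len(n))))
}

test_that("divergences are z-differences, antisymmetric, and z has mean 0 sd 1", {
  fx <- summary_fixture(200, 0.6, 81)
  ot <- ortholog_table(fx$a, fx$b, fx$pairs)
  for (q in c("log_cds_density", "log_cds_te", "n_uorfs")) {
    za <- ot[[paste0("z_", q, "_a")]]; zb <- ot[[paste0("z_", q, "_b")]]
    expect_equal(mean(za), 0, tolerance = 1e-9)
    expect_equal(sd(za), 1, tolerance = 1e-9)
    expect_equal(ot[[paste0("d_", q)]], za - zb, tolerance = 1e-12)
  }
  # swapped species order negates every divergence
  ot_sw <- ortholog_table(fx$b, fx$a,
                          data.frame(id_a = fx$pairs$id_b, id_b = fx$pairs$id_a))
  expect_equal(ot_sw$d_log_cds_te, -ot$d_log_cds_te, tolerance = 1e-12)
  # identical species inputs -> zero divergence, perfect correlation
  ot_id <- ortholog_table(fx$a, fx$a,
                          data.frame(id_a = fx$a$transcript_id,
                                     id_b = fx$a$transcript_id))
  expect_true(all(abs(ot_id$d_log_cds_density) < 1e-12))
  cc <- conservation_correlations(ot_id, "log_cds_density")
  expect_equal(cc$pearson, 1)
})

test_that("simple z-divergence arithmetic matches the worked example", {
  # a pair with z_a = 1.0 and z_b = -0.5 diverges by 1.5
  a <- data.frame(transcript_id = c("x1", "x2", "x3"),
                  level = NA, cds_density = exp(c(1, 0, -1)), cds_te = NA,
                  leader_te = NA, leader_repressiveness = NA, n_uorfs = 0,
                  leader_length = 1, leader_mean_efe = NA, cds_wrent = NA,
                  cds_mean_efe = NA)
  b <- a; b$transcript_id <- c("y1", "y2", "y3")
  b$cds_density <- exp(c(-0.5, 0, 0.5))
  ot <- ortholog_table(a, b, data.frame(id_a = a$transcript_id,
                                        id_b = b$transcript_id))
  expect_equal(ot$z_log_cds_density_a[1], 1)
  expect_equal(ot$z_log_cds_density_b[1], -1)
  expect_equal(ot$d_log_cds_density[1], 2)
})

test_that("a planted cross-species correlation is estimated consistently", {
  fx <- summary_fixture(2000, 0.7, 82)
  ot <- ortholog_table(fx$a, fx$b, fx$pairs)
  cc <- conservation_correlations(ot, "log_cds_density")
  expect_equal(cc$n, 2000L)
  expect_lt(abs(cc$pearson - 0.7), 0.05)
  # independent species -> near-zero correlation
  fx0 <- summary_fixture(800, 0, 83)
  cc0 <- conservation_correlations(ortholog_table(fx0$a, fx0$b, fx0$pairs),
                                   "log_cds_density")
  expect_lt(abs(cc0$pearson), 3 / sqrt(800))
  # pair order never matters
  perm <- sample(nrow(fx$pairs))
  cc_p <- conservation_correlations(ortholog_table(fx$a, fx$b, fx$pairs[perm, ]),
                                    "log_cds_density")
  expect_equal(cc_p$pearson, cc$pearson, tolerance = 1e-12)
  # insufficient pairs -> absent with a reason
  few <- conservation_correlations(ortholog_table(fx$a, fx$b, fx$pairs[1:5, ]),
                                   "log_cds_density")
  expect_true(is.na(few$pearson))
})

test_that("stratification by uORF count returns per-stratum correlations", {
  fx <- summary_fixture(900, 0.5, 84)
  ot <- ortholog_table(fx$a, fx$b, fx$pairs)
  cc <- conservation_correlations(ot, "log_cds_te", by_n_uorfs = TRUE)
  expect_true(nrow(cc$strata) >= 2)
  expect_true(all(cc$strata$n >= 10))
})

test_that("an exactly composed divergence response is fit with r = 1 and equal coefficients", {
  set.seed(85)
  n <- 300
  rec <- data.frame(d_log_level = rnorm(n), d_log_cds_te = rnorm(n),
                    d_log_leader_te = rnorm(n))
  rec$d_log_cds_density <- rec$d_log_level + rec$d_log_cds_te
  fit <- divergence_model(rec, alpha = 1e-8)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-6)
  cf <- fit$coefficients
  expect_gt(cf[["d_log_cds_te"]], 0)
  expect_gt(cf[["d_log_level"]], 0)
  # equal planted contributions -> unit slopes on the original scale
  expect_equal(cf[["d_log_cds_te"]] / sd(rec$d_log_cds_te), 1, tolerance = 1e-6)
  expect_equal(cf[["d_log_level"]] / sd(rec$d_log_level), 1, tolerance = 1e-6)
  expect_equal(cf[["d_log_leader_te"]], 0, tolerance = 1e-6)
})

test_that("a TE contribution planted at half the level contribution is recovered", {
  rec <- simulate_divergence_records(2000, beta_level = 1, beta_te = 0.5,
                                     noise_sd = 0.1, seed = 86)
  fit <- divergence_model(rec, alpha = 0.01)
  ratio <- fit$coefficients[["d_log_cds_te"]] / fit$coefficients[["d_log_level"]]
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("a null divergence response keeps PRESS near the intercept-only error", {
  set.seed(87)
  n <- 400
  rec <- data.frame(d_log_level = rnorm(n), d_log_cds_te = rnorm(n),
                    d_log_leader_te = rnorm(n),
                    d_log_cds_density = rnorm(n))
  fit <- divergence_model(rec, alpha = 1)
  # intercept-only LOO error: sum((y - mean_{-i})^2) = ress * (n/(n-1))^2
  y <- rec$d_log_cds_density
  press0 <- sum(((y - mean(y)) / (1 - 1 / n))^2)
  expect_gt(fit$press, 0.95 * press0 - 5)
  expect_gt(fit$press, fit$ress)
})

test_that("full simulated ortholog pairs flow through the pipeline summaries", {
  cfg <- sim_config(n_transcripts = 80, seed = 31, depth = 3)
  op <- simulate_ortholog_pair(cfg, rho = 1)
  # rho = 1: identical latent translation states
  expect_equal(op$a$ground_truth$latent$log_te, op$b$ground_truth$latent$log_te)
  sum_of <- function(side) {
    orfs <- find_orfs_all(side$transcripts)
    tet <- te_table(side$transcripts, orfs, side$tracks)
    transcript_summary(side$transcripts, orfs, tet)
  }
  sa <- sum_of(op$a); sb <- sum_of(op$b)
  ot <- ortholog_table(sa, sb, op$pairs)
  cc <- conservation_correlations(ot, "log_cds_density")
  expect_gt(cc$pearson, 0.9)    # measurement noise only
  # rho = 0 decorrelates the latent states
  op0 <- simulate_ortholog_pair(cfg, rho = 0)
  ot0 <- ortholog_table(sum_of(op0$a), sum_of(op0$b), op0$pairs)
  cc0 <- conservation_correlations(ot0, "log_cds_density")
  expect_lt(abs(cc0$pearson), 4 / sqrt(cc0$n))
})
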