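# Cross-species comparison of translation and sequence features over
# one-to-one orthologs.
#
# Quantities measured on reads (transcript level, CDS read density, CDS TE,
# leader TE, leader repressiveness) enter on the natural-log scale; each
# quantity is Z-normalized within the paired subset (pairs where both species
# have the value), and divergence is the signed difference z_a - z_b.

# per-quantity transform: TRUE -> natural log of positive values
.CONS_QUANTITIES <- c(
  log_level = TRUE, log_cds_density = TRUE, log_cds_te = TRUE,
  log_leader_te = TRUE, log_leader_repressiveness = TRUE,
  n_uorfs = FALSE, leader_length = FALSE, leader_mean_efe = FALSE,
  cds_wrent = FALSE, cds_mean_efe = FALSE)

#' Per-transcript summary used for ortholog comparisons
#'
#' Collapses pipeline outputs to one row per transcript: abundance, CDS read
#' density and TE, leader TE and repressiveness, uORF count, leader length,
#' mean EFEs and CDS WRENT score.
#'
#' @param tx a `"transcriptome"`.
#' @param orfs ORF table.
#' @param tet TE table from [te_table()].
#' @param wrent reference `"wrent_model"`.
#' @param profiles named list of `"efe_profile"` objects (may be `NULL`;
#'   structure columns are then `NA`).
#' @return data.frame keyed by `transcript_id`.
#' @export
transcript_summary <- function(tx, orfs, tet, wrent = NULL, profiles = NULL) {
  cds_rows <- tet[tet$klass == "CDS", ]
  idx <- match(tx$transcript_id, cds_rows$transcript_id)
  n_uorfs <- n_uorfs_per_transcript(tx, orfs)
  cds_wrent <- rep(NA_real_, nrow(tx))
  if (!is.null(wrent)) {
    ctx <- extract_contexts(tx, data.frame(transcript_id = tx$transcript_id,
                                           start = tx$cds_start))
    cds_wrent[match(ctx$transcript_id, tx$transcript_id)] <-
      wrent_score(wrent, ctx$context)
  }
  lme <- cme <- rep(NA_real_, nrow(tx))
  if (!is.null(profiles)) {
    for (i in seq_len(nrow(tx))) {
      pr <- profiles[[tx$transcript_id[i]]]
      if (is.null(pr)) next
      rm <- region_mean_efe(pr, tx[i, ])
      lme[i] <- rm$leader_mean_efe; cme[i] <- rm$cds_mean_efe
    }
  }
  data.frame(
    transcript_id = tx$transcript_id,
    level = tx$fpkm,
    cds_density = cds_rows$density[idx],
    cds_te = cds_rows$te[idx],
    leader_te = cds_rows$leader_te[idx],
    leader_repressiveness = cds_rows$leader_repressiveness[idx],
    n_uorfs = n_uorfs,
    leader_length = tx$cds_start,
    leader_mean_efe = lme,
    cds_wrent = cds_wrent,
    cds_mean_efe = cme,
    stringsAsFactors = FALSE)
}

.safe_log <- function(x) ifelse(!is.na(x) & x > 0, log(x), NA_real_)

# z within the pairs where both species have the quantity
.pairwise_z <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  za <- zb <- rep(NA_real_, length(a))
  if (sum(ok) >= 3L) {
    mu_a <- mean(a[ok]); s_a <- stats::sd(a[ok])
    mu_b <- mean(b[ok]); s_b <- stats::sd(b[ok])
    if (s_a > 0 && s_b > 0) {
      za[ok] <- (a[ok] - mu_a) / s_a
      zb[ok] <- (b[ok] - mu_b) / s_b
    }
  }
  list(za = za, zb = zb)
}

#' Build the ortholog comparison table
#'
#' Joins two species' per-transcript summaries over a one-to-one pair table,
#' log-transforms the read-based quantities, Z-normalizes each quantity
#' within the paired subset and fills signed divergences `z_a - z_b`.
#'
#' @param summary_a,summary_b outputs of [transcript_summary()] for the two
#'   species.
#' @param pairs data.frame `id_a`, `id_b` (see [load_orthologs()]).
#' @return data.frame with, per quantity `q`, columns `q_a`, `q_b`, `z_q_a`,
#'   `z_q_b` and `d_q` (divergence); class `"ortholog_table"`.
#' @export
ortholog_table <- function(summary_a, summary_b, pairs) {
  ia <- match(pairs$id_a, summary_a$transcript_id)
  ib <- match(pairs$id_b, summary_b$transcript_id)
  ok <- !is.na(ia) & !is.na(ib)
  pairs <- pairs[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  out <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                    stringsAsFactors = FALSE)
  src <- c(log_level = "level", log_cds_density = "cds_density",
           log_cds_te = "cds_te", log_leader_te = "leader_te",
           log_leader_repressiveness = "leader_repressiveness",
           n_uorfs = "n_uorfs", leader_length = "leader_length",
           leader_mean_efe = "leader_mean_efe", cds_wrent = "cds_wrent",
           cds_mean_efe = "cds_mean_efe")
  for (q in names(src)) {
    a <- summary_a[[src[[q]]]][ia]
    b <- summary_b[[src[[q]]]][ib]
    if (.CONS_QUANTITIES[[q]]) { a <- .safe_log(a); b <- .safe_log(b) }
    zz <- .pairwise_z(a, b)
    out[[paste0(q, "_a")]] <- a
    out[[paste0(q, "_b")]] <- b
    out[[paste0("z_", q, "_a")]] <- zz$za
    out[[paste0("z_", q, "_b")]] <- zz$zb
    out[[paste0("d_", q)]] <- zz$za - zz$zb
  }
  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Cross-species correlation of a quantity over ortholog pairs
#'
#' @param records an `"ortholog_table"`.
#' @param quantity quantity name (e.g. `"log_cds_density"`).
#' @param by_n_uorfs also report correlations stratified by the (species A)
#'   uORF count.
#' @param min_n below this pair count the correlation is absent.
#' @return list `pearson`, `spearman`, `n`, and optionally `strata`
#'   (data.frame `n_uorfs`, `pearson`, `spearman`, `n`).
#' @export
conservation_correlations <- function(records, quantity = "log_cds_density",
                                      by_n_uorfs = FALSE, min_n = 10L) {
  a <- records[[paste0(quantity, "_a")]]
  b <- records[[paste0(quantity, "_b")]]
  if (is.null(a) || is.null(b))
    stop("conservation_correlations: unknown quantity ", quantity)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_n)
    return(list(pearson = NA_real_, spearman = NA_real_, n = n,
                reason = "insufficient pairs"))
  out <- list(pearson = stats::cor(a[ok], b[ok]),
              spearman = stats::cor(a[ok], b[ok], method = "spearman"),
              n = n)
  if (by_n_uorfs) {
    nu <- records$n_uorfs_a
    strata <- lapply(sort(unique(nu[ok])), function(k) {
      sel <- ok & nu == k
      if (sum(sel) < min_n) return(NULL)
      data.frame(n_uorfs = k, pearson = stats::cor(a[sel], b[sel]),
                 spearman = stats::cor(a[sel], b[sel], method = "spearman"),
                 n = sum(sel))
    })
    out$strata <- do.call(rbind, strata)
  }
  out
}

#' Ridge model of cross-species divergence
#'
#' Fits the divergence of one quantity (default: CDS read density) on the
#' divergences of others (default: CDS TE, leader TE, transcript level),
#' using the same ridge/PRESS machinery as the within-species models.
#' Predictor divergences are Z-scored before fitting.
#'
#' @param records an `"ortholog_table"` (or any data.frame with `d_*`
#'   columns).
#' @param response divergence column name.
#' @param predictors divergence column names.
#' @param alpha ridge penalty.
#' @return a `"ridge_fit"` (attribute `n_dropped`: incomplete pairs removed).
#' @export
divergence_model <- function(records, response = "d_log_cds_density",
                             predictors = c("d_log_cds_te", "d_log_leader_te",
                                            "d_log_level"),
                             alpha = 1) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("divergence_model: missing columns: ",
                         paste(miss, collapse = ", "))
  df <- records[, cols, drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  zs <- zscore(df[, predictors, drop = FALSE])
  fit <- fit_ridge(zs$z, df[[response]], alpha = alpha,
                   feature_set_name = paste(predictors, collapse = "+"))
  attr(fit, "n_dropped") <- sum(!cc)
  fit
}
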