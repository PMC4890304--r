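# Ridge-regression models of uORF repressiveness and CDS TE.
#
# Features are Z-scored against their endogenous variation (sample SD), the
# intercept is unpenalized, and models report the Pearson correlation of the
# response with the combined score (sum of Z features weighted by their
# coefficients), in-sample RESS, leave-one-out PRESS (hat-matrix identity,
# exact for ridge with a fixed penalty), and the fold change in the response
# across the 2.5th-97.5th percentile range of the combined score.

#' Z-score feature columns
#'
#' `z = (x - mean) / sd` with the sample SD (`n - 1` denominator).
#'
#' @param x data.frame or matrix of numeric features.
#' @param scaler optional previously fitted scaler (data.frame `feature`,
#'   `mean`, `sd`) to apply instead of refitting.
#' @return list `z` (matrix of Z-scores) and `scaler`.
#' @export
zscore <- function(x, scaler = NULL) {
  m <- as.matrix(x)
  if (is.null(scaler)) {
    mu <- colMeans(m)
    sd <- apply(m, 2L, stats::sd)
    if (any(sd == 0 | is.na(sd)))
      stop("zscore: zero-variance feature(s): ",
           paste(colnames(m)[sd == 0 | is.na(sd)], collapse = ", "))
    scaler <- data.frame(feature = colnames(m), mean = mu, sd = sd,
                         row.names = NULL)
  }
  z <- sweep(sweep(m, 2L, scaler$mean[match(colnames(m), scaler$feature)]),
             2L, scaler$sd[match(colnames(m), scaler$feature)], "/")
  list(z = z, scaler = scaler)
}

# Penalized normal equations on the augmented design [1, X] with penalty
# diag(0, alpha, ..., alpha); shared by the fit and the explicit LOO.
.ridge_solve <- function(A, y, alpha) {
  p <- ncol(A) - 1L
  D <- diag(c(0, rep(alpha, p)), nrow = p + 1L)
  solve(crossprod(A) + D, crossprod(A, y))
}

#' Fit a ridge regression of a response on Z-scored features
#'
#' @param z matrix of Z-scored features (n x p, named columns).
#' @param y numeric response (log scale for repressiveness / TE models).
#' @param alpha ridge penalty on the Z-scored features (default 1; the
#'   intercept is never penalized).
#' @param feature_set_name label carried into reports.
#' @return object of class `"ridge_fit"`: `coefficients` (standardized),
#'   `intercept`, `alpha`, `combined_score` (`z %*% coefficients`), `slope`
#'   (least-squares slope of `y` on the combined score), `pearson_r`,
#'   `p_value` (two-sided t), `ress`, `press`, `fold_change_95`, `n`.
#' @export
fit_ridge <- function(z, y, alpha = 1, feature_set_name = "features") {
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  stopifnot(length(y) == n)
  if (n <= p) stop("fit_ridge: need n > number of features")
  if (alpha <= 0) {
    qx <- qr(cbind(1, z))
    if (qx$rank < p + 1L)
      stop("fit_ridge: singular design with alpha = 0; use alpha > 0")
  }
  A <- cbind(`(intercept)` = 1, z)
  b <- .ridge_solve(A, y, alpha)
  coef <- stats::setNames(as.vector(b)[-1L], colnames(z))
  intercept <- as.vector(b)[1L]
  score <- as.vector(z %*% coef)
  fitted <- intercept + score
  e <- y - fitted
  ress <- sum(e^2)
  # hat diagonal of the penalized smoother
  D <- diag(c(0, rep(alpha, p)), nrow = p + 1L)
  M <- solve(crossprod(A) + D)
  h <- rowSums((A %*% M) * A)
  press <- sum((e / (1 - h))^2)
  sv <- stats::sd(score)
  if (sv > 0) {
    slope <- stats::cov(y, score) / stats::var(score)
    r <- stats::cor(y, score)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    pval <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    slope <- 0; r <- NA_real_; pval <- NA_real_
  }
  fit <- structure(list(
    feature_set_name = feature_set_name, coefficients = coef,
    intercept = intercept, alpha = alpha, combined_score = score,
    slope = slope, pearson_r = r, p_value = pval,
    ress = ress, press = press, n = n), class = "ridge_fit")
  fit$fold_change_95 <- fold_change_95(fit)
  fit
}

#' Leave-one-out PRESS by explicit refits
#'
#' Refits the penalized normal equations `n` times, leaving out one row each
#' time, and accumulates the squared prediction errors. Serves as the slow
#' oracle for the hat-matrix shortcut in [fit_ridge()]; the two agree to
#' numerical precision.
#'
#' @param z,y,alpha as in [fit_ridge()].
#' @return the PRESS statistic.
#' @export
press_explicit <- function(z, y, alpha = 1) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n <= ncol(z) + 1L) stop("press_explicit: need n > p + 1")
  A <- cbind(1, z)
  sum(vapply(seq_len(n), function(i) {
    b <- .ridge_solve(A[-i, , drop = FALSE], y[-i], alpha)
    (y[i] - as.vector(A[i, ] %*% b))^2
  }, numeric(1)))
}

#' Fold change in the response over the 95% range of the combined score
#'
#' `exp(slope * (q97.5 - q2.5))` where the quantiles (type 7) are of the
#' combined score and the slope is that of the response on the score; the
#' response is modelled in natural log, so the result is a plain fold change.
#' A degenerate score distribution gives fold 1.
#'
#' @param fit a `"ridge_fit"`.
#' @return fold change (>= 0).
#' @export
fold_change_95 <- function(fit) {
  s <- fit$combined_score
  if (stats::sd(s) == 0) return(1)
  qs <- stats::quantile(s, c(0.025, 0.975), type = 7, names = FALSE)
  exp(fit$slope * (qs[2] - qs[1]))
}

# ---- feature-table assembly ------------------------------------------------

#' Assemble a per-transcript feature table for linear modelling
#'
#' Joins the outputs of the upstream stages into one row per transcript, for
#' one of the analysis subsets:
#' \describe{
#'   \item{one_nonoverlapping_uorf}{exactly one uORF on the transcript, lying
#'     entirely upstream of the CDS and passing the uORF length filter; uORF
#'     features are populated.}
#'   \item{all / with_uorfs / without_uorfs}{expanded analyses over uORF
#'     counts; the uORF-density feature is populated (log density with
#'     pseudocount 0.1 uORFs for transcripts lacking them).}
#' }
#' Responses are natural-log transformed; rows with a nonpositive response
#' input or any absent feature are dropped and counted in attribute
#' `n_dropped`.
#'
#' @param tx a `"transcriptome"`.
#' @param orfs ORF table from [find_orfs_all()].
#' @param tet TE table from [te_table()].
#' @param wrent reference `"wrent_model"` (CDS-trained).
#' @param profiles named list of `"efe_profile"` objects with anchors for the
#'   relevant ORF starts.
#' @param subset one of the subset labels above.
#' @param response `"repressiveness"` (`log(uORF TE / CDS TE)`) or
#'   `"cds_te"` (`log(CDS TE)`).
#' @param density_pseudocount pseudocount in uORFs for transcripts lacking
#'   uORFs (default 0.1).
#' @return data.frame with `transcript_id`, `response` and feature columns;
#'   attribute `subset`.
#' @export
build_feature_table <- function(tx, orfs, tet, wrent, profiles,
                                subset = c("one_nonoverlapping_uorf", "all",
                                           "with_uorfs", "without_uorfs"),
                                response = c("repressiveness", "cds_te"),
                                density_pseudocount = 0.1) {
  subset <- match.arg(subset)
  response <- match.arg(response)
  if (subset != "one_nonoverlapping_uorf" && response == "repressiveness")
    stop("build_feature_table: repressiveness response requires the one-uORF subset")

  n_uorfs <- n_uorfs_per_transcript(tx, orfs)
  cds_rows <- tet[tet$klass == "CDS", ]
  cidx <- match(tx$transcript_id, cds_rows$transcript_id)
  nn <- orfs[orfs$klass == "uORF_nonoverlapping", , drop = FALSE]
  nn_idx <- split(seq_len(nrow(nn)), nn$transcript_id)
  ut <- tet[tet$klass == "uORF_nonoverlapping", , drop = FALSE]
  ut_idx <- split(seq_len(nrow(ut)), ut$transcript_id)

  anchor_of <- function(id, start) {
    pr <- profiles[[id]]
    if (is.null(pr)) return(c(NA_real_, NA_real_))
    a <- pr$anchors[match(start, pr$anchors$orf_start), ]
    c(a$efe_minus25, a$efe_plus1)
  }

  rows <- vector("list", nrow(tx))
  n_dropped <- 0L
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    cr <- cds_rows[cidx[i], ]
    keep <- switch(subset,
      one_nonoverlapping_uorf = n_uorfs[i] == 1L,
      all = TRUE,
      with_uorfs = n_uorfs[i] >= 1L,
      without_uorfs = n_uorfs[i] == 0L)
    if (!isTRUE(keep) || is.na(cidx[i])) next
    txr <- tx[i, ]
    pr <- profiles[[id]]
    rme <- if (!is.null(pr)) region_mean_efe(pr, txr)
           else list(leader_mean_efe = NA_real_, cds_mean_efe = NA_real_)
    cds_anch <- anchor_of(id, txr$cds_start)
    cds_ctx <- extract_contexts(txr, data.frame(transcript_id = id,
                                                start = txr$cds_start))
    cds_wrent <- if (nrow(cds_ctx)) wrent_score(wrent, cds_ctx$context) else NA_real_

    feat <- data.frame(
      transcript_id = id,
      leader_length = txr$cds_start,
      leader_mean_efe = rme$leader_mean_efe,
      cds_wrent = cds_wrent,
      cds_efe_minus25 = cds_anch[1], cds_efe_plus1 = cds_anch[2],
      cds_mean_efe = rme$cds_mean_efe,
      stringsAsFactors = FALSE)

    if (subset == "one_nonoverlapping_uorf") {
      if (is.null(nn_idx[[id]]) || is.null(ut_idx[[id]])) {
        n_dropped <- n_dropped + 1L; next
      }
      u <- nn[nn_idx[[id]], , drop = FALSE]
      if (nrow(u) != 1L) { n_dropped <- n_dropped + 1L; next }
      urows <- ut[ut_idx[[id]], , drop = FALSE]
      ur <- urows[urows$start == u$start, , drop = FALSE]
      if (!nrow(ur) || !ur$passes_length_filter[1]) { n_dropped <- n_dropped + 1L; next }
      u_anch <- anchor_of(id, u$start)
      u_ctx <- extract_contexts(txr, data.frame(transcript_id = id, start = u$start))
      feat$uorf_wrent <- if (nrow(u_ctx)) wrent_score(wrent, u_ctx$context) else NA_real_
      feat$uorf_efe_minus25 <- u_anch[1]
      feat$uorf_efe_plus1 <- u_anch[2]
      feat$uorf_length <- u$length_nt
      feat$uorf_end_pos_rel_cds <- u$end - txr$cds_start
      resp_val <- if (response == "repressiveness") ur$uorf_repressiveness[1]
                  else cr$te
    } else {
      ne <- if (n_uorfs[i] == 0L) density_pseudocount else n_uorfs[i]
      feat$uorf_density <- if (txr$cds_start > 0) log(ne / txr$cds_start) else NA_real_
      resp_val <- cr$te
    }
    if (is.na(resp_val) || resp_val <= 0) { n_dropped <- n_dropped + 1L; next }
    feat$response <- log(resp_val)
    rows[[i]] <- feat
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("build_feature_table: empty subset after filters (subset = ", subset,
         ", response = ", response, ")")
  cc <- stats::complete.cases(out)
  n_dropped <- n_dropped + sum(!cc)
  out <- out[cc, , drop = FALSE]
  if (!nrow(out))
    stop("build_feature_table: empty subset after filters (subset = ", subset,
         ", response = ", response, ")")
  rownames(out) <- NULL
  attr(out, "subset") <- subset
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Named feature sets mirroring the modelling feature groups
#'
#' @param expanded include `uorf_density` (expanded analyses) instead of the
#'   single-uORF features.
#' @return named list of character vectors.
#' @export
feature_sets <- function(expanded = FALSE) {
  if (expanded) {
    list(uORF = c("uorf_density"),
         leader = c("leader_length", "leader_mean_efe"),
         CDS = c("cds_wrent", "cds_efe_minus25", "cds_efe_plus1", "cds_mean_efe"))
  } else {
    list(uORF = c("uorf_wrent", "uorf_efe_minus25", "uorf_efe_plus1",
                  "uorf_length", "uorf_end_pos_rel_cds"),
         leader = c("leader_length", "leader_mean_efe"),
         CDS = c("cds_wrent", "cds_efe_minus25", "cds_efe_plus1", "cds_mean_efe"))
  }
}

#' Fit ridge models for several feature-set combinations
#'
#' Produces the summary table of the modelling stage: one row per feature-set
#' combination with Pearson r, p-value, fold change over the 95% score range,
#' PRESS, RESS and n.
#'
#' @param table feature table from [build_feature_table()].
#' @param sets named list: combination label -> character vector of feature
#'   columns.
#' @param alpha ridge penalty.
#' @param skip_infeasible drop (with a warning) combinations whose feature
#'   count reaches the row count instead of failing; skipped names are kept
#'   in attribute `skipped`.
#' @return list `report` (data.frame), `fits` (list of `"ridge_fit"`) and
#'   `skipped` (character).
#' @export
model_report <- function(table, sets, alpha = 1, skip_infeasible = FALSE) {
  feasible <- vapply(sets, function(cols) nrow(table) > length(cols) + 1L,
                     logical(1))
  skipped <- names(sets)[!feasible]
  if (length(skipped)) {
    if (!skip_infeasible)
      stop("model_report: too few rows (", nrow(table), ") for set(s): ",
           paste(skipped, collapse = ", "))
    warning("model_report: skipping underdetermined set(s): ",
            paste(skipped, collapse = ", "))
    sets <- sets[feasible]
  }
  fits <- lapply(names(sets), function(nm) {
    cols <- sets[[nm]]
    zs <- zscore(table[, cols, drop = FALSE])
    fit_ridge(zs$z, table$response, alpha = alpha, feature_set_name = nm)
  })
  names(fits) <- names(sets)
  report <- do.call(rbind, lapply(fits, function(f)
    data.frame(feature_set = f$feature_set_name, pearson_r = f$pearson_r,
               p_value = f$p_value, fold_change = f$fold_change_95,
               press = f$press, ress = f$ress, n = f$n, alpha = f$alpha)))
  if (is.null(report)) report <- data.frame()
  rownames(report) <- NULL
  list(report = report, fits = fits, skipped = skipped)
}
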