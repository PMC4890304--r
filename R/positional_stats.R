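# Positional trinucleotide bias in 5' leaders and shuffle-null depletion of
# uORF ends near the CDS.
#
# Position axes are relative to the CDS start: a trinucleotide starting p nt
# upstream sits at position -p; a uORF end (exclusive) at the CDS boundary
# sits at position 0. The shuffle null permutes each leader's nucleotides
# (mononucleotide shuffle, exact multiset preserved), re-detects uORF ends on
# every shuffled copy and compares observed to expected end counts.

#' Positional trinucleotide bias in 5' leaders
#'
#' For each leader position `p` (trinucleotide start relative to the CDS
#' start; only positions where the trinucleotide fits inside the leader),
#' the observed frequency of the trinucleotide set across transcripts is
#' normalized by the expected frequency from the per-position marginal
#' nucleotide frequencies: `expected(p) = sum_t prod_o marg(t[o], p + o)`.
#'
#' @param tx a `"transcriptome"`.
#' @param trinucs character vector of trinucleotides, e.g. `"ATG"` or
#'   `c("TAA","TAG","TGA")`.
#' @param frame `"all"` or 0/1/2: restrict positions to one frame relative to
#'   the CDS (`p %% 3 == frame`).
#' @param require_preceding_atg count a stop trinucleotide only where it
#'   terminates a uORF (an in-frame ATG upstream in the leader with no
#'   intervening in-frame stop).
#' @param min_n positions covered by fewer transcripts are omitted.
#' @param smoothing_window width of the reported moving average (nt).
#' @return data.frame `position`, `n`, `observed`, `expected`, `bias`
#'   (`NA` where expected is 0), `bias_smoothed`, `bias_se` (delta-method
#'   Monte-Carlo SE of the smoothed bias under the positional null, treating
#'   positions as independent).
#' @export
trinucleotide_bias <- function(tx, trinucs = "ATG",
                               frame = "all",
                               require_preceding_atg = FALSE,
                               min_n = 50L, smoothing_window = 24L) {
  n_tx <- nrow(tx)
  llen <- tx$cds_start
  maxL <- max(llen)
  if (maxL < 3L) stop("trinucleotide_bias: no leader is >= 3 nt")
  # matrix of leader bases right-aligned at the CDS start:
  # column j holds position p = j - maxL - 1 (p in -maxL .. -1), NA where the
  # leader does not reach.
  bases <- matrix(NA_integer_, nrow = n_tx, ncol = maxL)
  ends_at <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    if (llen[i] == 0L) next
    s <- seq_to_int(substr(tx$sequence[i], 1L, llen[i]))
    bases[i, (maxL - llen[i] + 1L):maxL] <- s
    if (require_preceding_atg) {
      e <- leader_orf_ends_int(s)             # exclusive ends, 0-based in leader
      ends_at[[i]] <- e - llen[i]             # rel. CDS start
    }
  }
  tri_int <- lapply(trinucs, seq_to_int)
  positions <- seq.int(-maxL, -3L)
  if (!identical(frame, "all"))
    positions <- positions[positions %% 3L == as.integer(frame)]

  res <- lapply(positions, function(p) {
    j <- p + maxL + 1L                        # column of position p
    b1 <- bases[, j]; b2 <- bases[, j + 1L]; b3 <- bases[, j + 2L]
    cover <- !is.na(b1) & !is.na(b2) & !is.na(b3)
    n <- sum(cover)
    if (n < min_n) return(NULL)
    hit <- rep(FALSE, n_tx)
    for (t in tri_int)
      hit <- hit | (b1 == t[1] & b2 == t[2] & b3 == t[3])
    hit <- hit & cover
    if (require_preceding_atg) {
      is_end <- vapply(seq_len(n_tx), function(i) (p + 3L) %in% ends_at[[i]],
                       logical(1))
      hit <- hit & is_end
    }
    marg <- function(b) tabulate(b[cover] + 1L, nbins = 4L) / n
    m1 <- marg(b1); m2 <- marg(b2); m3 <- marg(b3)
    expected <- sum(vapply(tri_int, function(t)
      m1[t[1] + 1L] * m2[t[2] + 1L] * m3[t[3] + 1L], numeric(1)))
    data.frame(position = p, n = n, observed = sum(hit) / n, expected = expected)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("trinucleotide_bias: no position reaches min_n transcripts")
  out$bias <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out$bias_smoothed <- moving_average(out$bias, smoothing_window, na.rm = TRUE)
  # delta-method SE of bias at each position, then propagated through the
  # moving average assuming independent positions
  se2 <- ifelse(out$expected > 0,
                out$expected * (1 - out$expected) / out$n / out$expected^2,
                NA_real_)
  out$bias_se <- sqrt(moving_average(se2, smoothing_window, na.rm = TRUE) /
                        smoothing_window)
  rownames(out) <- NULL
  out
}

#' Shuffle-null depletion profile of uORF ends
#'
#' Detects uORF ends (exclusive, relative to the CDS start) on each original
#' leader and on `n_shuffles` mononucleotide-shuffled copies, aggregates end
#' counts per position across transcripts and reports the observed/expected
#' ratio with a moving average.
#'
#' @param tx a `"transcriptome"` (leaders >= 3 nt contribute).
#' @param n_shuffles number of shuffles per leader (default 1000).
#' @param seed RNG seed for the shuffle null (default 1663).
#' @param smoothing_window moving-average width (nt).
#' @return data.frame `position`, `observed`, `expected`, `ratio`,
#'   `observed_smoothed`, `expected_smoothed`, `ratio_smoothed`, `ratio_se`
#'   (SD of the smoothed per-shuffle counts across shuffles, scaled to the
#'   ratio, inflated by `sqrt(1 + 1/n_shuffles)` for the expected-side noise).
#'   The per-shuffle position-count matrix is kept in attribute
#'   `shuffle_counts` for zone tests; `n_shuffles` and `seed` are attributes.
#' @export
uorf_end_depletion <- function(tx, n_shuffles = 1000L, seed = 1663L,
                               smoothing_window = 24L) {
  llen <- tx$cds_start
  use <- which(llen >= 3L)
  if (!length(use)) stop("uorf_end_depletion: no leaders >= 3 nt")
  maxL <- max(llen[use])
  positions <- seq.int(-maxL, 0L)
  np <- length(positions)
  obs <- integer(np)
  shuf <- matrix(0L, nrow = np, ncol = n_shuffles)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in use) {
    s <- seq_to_int(substr(tx$sequence[i], 1L, llen[i]))
    e <- leader_orf_ends_int(s) - llen[i]          # rel. CDS start
    if (length(e)) obs <- obs + tabulate(e + maxL + 1L, nbins = np)
    for (k in seq_len(n_shuffles)) {
      es <- leader_orf_ends_int(sample(s)) - llen[i]
      if (length(es)) {
        tb <- tabulate(es + maxL + 1L, nbins = np)
        shuf[, k] <- shuf[, k] + tb
      }
    }
  }
  expected <- rowMeans(shuf)
  obs_s <- moving_average(obs, smoothing_window)
  exp_s <- moving_average(expected, smoothing_window)
  shuf_s <- .moving_average_mat(shuf, smoothing_window)
  sd_s <- apply(shuf_s, 1L, stats::sd)
  out <- data.frame(
    position = positions, observed = obs, expected = expected,
    ratio = ifelse(expected > 0, obs / expected, NA_real_),
    observed_smoothed = obs_s, expected_smoothed = exp_s,
    ratio_smoothed = ifelse(exp_s > 0, obs_s / exp_s, NA_real_),
    ratio_se = ifelse(exp_s > 0,
                      sd_s / exp_s * sqrt(1 + 1 / n_shuffles), NA_real_))
  attr(out, "shuffle_counts") <- shuf
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "seed") <- seed
  class(out) <- c("depletion_profile", "data.frame")
  out
}

#' Shuffle-based depletion test over a positional zone
#'
#' Compares the observed number of uORF ends in `zone` with its distribution
#' over the shuffle replicates; the one-sided p-value for depletion is
#' `(1 + #\{shuffles <= observed\}) / (n_shuffles + 1)`.
#'
#' @param profile a `"depletion_profile"` from [uorf_end_depletion()].
#' @param zone half-open position interval `c(lo, hi)` relative to the CDS
#'   start (default `c(-50, 0)`).
#' @return list `observed`, `expected`, `ratio`, `p_value`.
#' @export
depletion_zone_test <- function(profile, zone = c(-50L, 0L)) {
  sel <- profile$position >= zone[1] & profile$position < zone[2]
  obs <- sum(profile$observed[sel])
  shuf <- colSums(attr(profile, "shuffle_counts")[sel, , drop = FALSE])
  list(observed = obs, expected = mean(shuf),
       ratio = if (mean(shuf) > 0) obs / mean(shuf) else NA_real_,
       p_value = (1 + sum(shuf <= obs)) / (length(shuf) + 1))
}
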