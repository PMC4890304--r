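# AUG-initiated ORF discovery and classification on transcript models.
#
# An ORF runs from the A of an ATG to the last nucleotide of the first
# in-frame stop codon (end index exclusive, stop included in the length).
# No minimum length is imposed at discovery: every ATG opens an ORF, and two
# in-frame ATGs sharing a stop are two distinct ORFs. ATGs with no in-frame
# stop anywhere on the transcript are excluded (counted in an attribute).

# Core scan on an integer-encoded sequence. Returns 0-based starts and
# exclusive ends (NA end where no in-frame stop exists downstream).
orf_scan_int <- function(s) {
  cc <- codon_codes(s)
  atg <- which(cc == .ATG_CODE)           # 1-based codon-start index
  if (!length(atg)) {
    return(list(start = integer(0), end = integer(0)))
  }
  is_stop <- !is.na(cc) & (cc == 48L | cc == 50L | cc == 56L)
  stop_idx <- which(is_stop)
  start0 <- atg - 1L
  end0 <- rep(NA_integer_, length(atg))
  for (f in 0:2) {
    in_f <- (start0 %% 3L) == f
    if (!any(in_f)) next
    sf <- stop_idx[(stop_idx - 1L) %% 3L == f]   # stops in frame f, sorted
    if (!length(sf)) next
    pos <- findInterval(atg[in_f], sf) + 1L       # first stop index > atg
    hit <- pos <= length(sf)
    e <- rep(NA_integer_, sum(in_f))
    e[hit] <- sf[pos[hit]] - 1L + 3L              # 0-based exclusive end
    end0[in_f] <- e
  }
  list(start = start0, end = end0)
}

# uORF ends (exclusive, 0-based) strictly within a leader sequence given as an
# integer vector; used by the shuffle-null machinery where only the leader
# sequence is shuffled. Each ATG with an in-frame stop inside the leader
# contributes one end (shared stops count once per ATG).
leader_orf_ends_int <- function(s) {
  sc <- orf_scan_int(s)
  sc$end[!is.na(sc$end)]
}

#' Find AUG-initiated ORFs on a transcript
#'
#' Scans a transcript for ORFs whose ATG lies in the requested region and
#' classifies them relative to the annotated CDS:
#' \describe{
#'   \item{uORF_nonoverlapping}{ATG upstream of the CDS, stop entirely within
#'     the leader (`end <= cds_start`).}
#'   \item{uORF_overlapping_cds}{ATG upstream of the CDS, first in-frame stop
#'     at or beyond the CDS start.}
#'   \item{CDS}{the ORF opened by the annotated start codon itself.}
#'   \item{cds_internal}{ATG inside the CDS (excluding the annotated start).}
#'   \item{utr3_orf}{ATG in the 3' UTR.}
#' }
#'
#' @param tx_row one row of a `"transcriptome"` (or any list with `sequence`,
#'   `cds_start`, `cds_end`, `transcript_id`).
#' @param region one of `"leader"`, `"cds"`, `"utr3"`, `"all"` — the region
#'   the ATG must lie in.
#' @return data.frame with columns `transcript_id`, `start`, `end`,
#'   `frame_rel_cds`, `klass`, `length_nt` (0-based half-open coordinates,
#'   stop codon included in the length). ATGs with no downstream in-frame stop
#'   are excluded; their number is in attribute `n_no_stop`.
#' @export
find_orfs <- function(tx_row, region = c("all", "leader", "cds", "utr3")) {
  region <- match.arg(region)
  s <- seq_to_int(tx_row$sequence)
  cds_start <- tx_row$cds_start
  cds_end <- tx_row$cds_end
  sc <- orf_scan_int(s)
  start <- sc$start; end <- sc$end

  keep <- switch(region,
    all    = rep(TRUE, length(start)),
    leader = start < cds_start,
    cds    = start >= cds_start & start < cds_end,
    utr3   = start >= cds_end)
  start <- start[keep]; end <- end[keep]

  no_stop <- is.na(end)
  n_no_stop <- sum(no_stop)
  start <- start[!no_stop]; end <- end[!no_stop]

  klass <- character(length(start))
  up <- start < cds_start
  klass[up & end <= cds_start] <- "uORF_nonoverlapping"
  klass[up & end > cds_start] <- "uORF_overlapping_cds"
  klass[start == cds_start] <- "CDS"
  klass[start > cds_start & start < cds_end] <- "cds_internal"
  klass[start >= cds_end] <- "utr3_orf"

  out <- data.frame(
    transcript_id = rep(tx_row$transcript_id, length(start)),
    start = start, end = end,
    frame_rel_cds = ((start - cds_start) %% 3L),
    klass = klass,
    length_nt = end - start,
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_stop") <- n_no_stop
  out
}

#' Find ORFs across a whole transcriptome
#'
#' @param tx a `"transcriptome"`.
#' @param region as in [find_orfs()].
#' @return row-bound ORF table over all transcripts; attribute `n_no_stop`
#'   totals ATGs lacking an in-frame stop.
#' @export
find_orfs_all <- function(tx, region = "all") {
  parts <- lapply(seq_len(nrow(tx)), function(i) find_orfs(tx[i, ], region))
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- find_orfs(tx[1, ], region)[0, ]
  rownames(out) <- NULL
  attr(out, "n_no_stop") <- sum(vapply(parts, attr, integer(1), "n_no_stop"))
  out
}

#' Per-transcript uORF summary
#'
#' Counts uORFs (both classes), computes uORF density per leader nucleotide
#' and reports uORF end positions relative to the CDS start (exclusive end
#' minus `cds_start`; a uORF abutting the CDS has end position 0, ends further
#' upstream are negative).
#'
#' @param tx_row one transcript row.
#' @param orfs ORF table for this transcript (from [find_orfs()]).
#' @return list with `transcript_id`, `n_uorfs`, `uorf_density` (`NA` when the
#'   leader has length 0) and `uorf_end_positions_rel_cds` (non-overlapping
#'   uORFs only, since overlapping uORFs end beyond the CDS start).
#' @export
uorf_summary <- function(tx_row, orfs) {
  u <- orfs[orfs$transcript_id == tx_row$transcript_id &
              orfs$klass %in% c("uORF_nonoverlapping", "uORF_overlapping_cds"), ]
  llen <- tx_row$cds_start
  nn <- u[u$klass == "uORF_nonoverlapping", ]
  list(transcript_id = tx_row$transcript_id,
       n_uorfs = nrow(u),
       uorf_density = if (llen > 0) nrow(u) / llen else NA_real_,
       uorf_end_positions_rel_cds = nn$end - tx_row$cds_start)
}

#' Count uORFs per transcript
#'
#' @param tx a `"transcriptome"`.
#' @param orfs ORF table from [find_orfs_all()].
#' @param klasses uORF classes to count.
#' @return integer vector aligned with the rows of `tx`.
#' @export
n_uorfs_per_transcript <- function(tx, orfs,
                                   klasses = c("uORF_nonoverlapping",
                                               "uORF_overlapping_cds")) {
  u <- orfs[orfs$klass %in% klasses, ]
  cnt <- table(factor(u$transcript_id, levels = tx$transcript_id))
  as.integer(cnt)
}
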