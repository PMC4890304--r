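# ORF-level read densities, translational efficiencies and repressiveness.
#
# TE of an ORF = P-site read density over [start, end - 10) divided by the
# transcript's FPKM. The last 10 nt are omitted because of the read peak at
# stop codons. Minimum lengths of 21 nt (uORFs, stop included) and 100 nt
# (CDSes) apply only when translation is quantified, never at discovery.

#' Translational efficiency of one ORF
#'
#' @param orf one ORF row (from [find_orfs()]).
#' @param track integer P-site count vector for the ORF's transcript.
#' @param fpkm transcript abundance (`NA` or 0 leaves `te` absent).
#' @param min_uorf_len,min_cds_len length filters in nt (stop codon included);
#'   uORF classes are checked against `min_uorf_len`, the CDS against
#'   `min_cds_len`. The filter is recorded, not applied.
#' @param omit_tail nucleotides dropped from the ORF 3' end (default 10).
#' @return list: `reads_in_window`, `density` (reads/nt over the window, `NA`
#'   when the window is empty), `te` (`density / fpkm`), `passes_length_filter`.
#' @export
orf_te <- function(orf, track, fpkm, min_uorf_len = 21L, min_cds_len = 100L,
                   omit_tail = 10L) {
  wlen <- orf$length_nt - omit_tail
  if (wlen <= 0L) {
    return(list(reads_in_window = NA_integer_, density = NA_real_,
                te = NA_real_, passes_length_filter = FALSE, window_len = wlen))
  }
  idx <- (orf$start + 1L):(orf$end - omit_tail)   # 1-based window indices
  reads <- sum(track[idx])
  density <- reads / wlen
  te <- if (!is.na(fpkm) && fpkm > 0) density / fpkm else NA_real_
  min_len <- if (orf$klass %in% c("uORF_nonoverlapping", "uORF_overlapping_cds"))
    min_uorf_len else min_cds_len
  list(reads_in_window = reads, density = density, te = te,
       passes_length_filter = orf$length_nt >= min_len, window_len = wlen)
}

#' uORF and 5' leader repressiveness for one transcript
#'
#' uORF repressiveness is the ratio of the uORF's TE to the cognate CDS's TE;
#' 5' leader repressiveness is the ratio of the read density over the leader
#' to that over the CDS (CDS window omitting its last 10 nt). Ratios are
#' absent when the denominator is 0 or absent.
#'
#' @param tx_row transcript row.
#' @param uorf_te,cds_te results of [orf_te()] for the uORF and the CDS
#'   (`uorf_te` may be `NULL` when the transcript has no quantified uORF).
#' @param track P-site count vector.
#' @return list with `uorf_te`, `cds_te`, `uorf_repressiveness`,
#'   `leader_density`, `leader_te`, `leader_repressiveness`.
#' @export
repressiveness <- function(tx_row, uorf_te, cds_te, track) {
  llen <- tx_row$cds_start
  leader_density <- if (llen > 0) sum(track[seq_len(llen)]) / llen else NA_real_
  fpkm <- tx_row$fpkm
  leader_te <- if (!is.na(fpkm) && fpkm > 0 && !is.na(leader_density))
    leader_density / fpkm else NA_real_
  cds_ok <- !is.na(cds_te$density) && cds_te$density > 0
  list(
    uorf_te = if (is.null(uorf_te)) NA_real_ else uorf_te$te,
    cds_te = cds_te$te,
    uorf_repressiveness =
      if (!is.null(uorf_te) && !is.na(uorf_te$te) && !is.na(cds_te$te) &&
          cds_te$te > 0) uorf_te$te / cds_te$te else NA_real_,
    leader_density = leader_density,
    leader_te = leader_te,
    leader_repressiveness =
      if (cds_ok && !is.na(leader_density)) leader_density / cds_te$density
      else NA_real_)
}

#' ORF-level TE table for a transcriptome
#'
#' One row per ORF with a positive quantification window, carrying the ORF's
#' read statistics, its TE, the cognate CDS TE and per-transcript leader
#' statistics. Exclusion counts (empty window, zero/absent FPKM, zero CDS
#' density) are recorded in the `exclusions` attribute; length filters are
#' recorded per row in `passes_length_filter`, applied by downstream callers.
#'
#' @param tx a `"transcriptome"`.
#' @param orfs ORF table from [find_orfs_all()].
#' @param tracks `"psite_tracks"` list.
#' @param min_uorf_len,min_cds_len,omit_tail see [orf_te()].
#' @return data.frame, one row per surviving ORF.
#' @export
te_table <- function(tx, orfs, tracks, min_uorf_len = 21L, min_cds_len = 100L,
                     omit_tail = 10L) {
  rows <- vector("list", nrow(tx))
  n_empty_window <- 0L; n_no_fpkm <- 0L; n_zero_cds <- 0L
  orf_idx <- split(seq_len(nrow(orfs)), orfs$transcript_id)
  for (i in seq_len(nrow(tx))) {
    txr <- tx[i, ]
    id <- txr$transcript_id
    ii <- orf_idx[[id]]
    if (is.null(ii)) next
    o <- orfs[ii, , drop = FALSE]
    track <- tracks[[id]]
    cds_row <- o[o$klass == "CDS", , drop = FALSE]
    cds_q <- if (nrow(cds_row)) orf_te(cds_row[1, ], track, txr$fpkm,
                                       min_uorf_len, min_cds_len, omit_tail)
             else list(density = NA_real_, te = NA_real_)
    if (is.na(txr$fpkm) || txr$fpkm <= 0) n_no_fpkm <- n_no_fpkm + 1L
    if (!is.na(cds_q$density) && cds_q$density == 0) n_zero_cds <- n_zero_cds + 1L
    llen <- txr$cds_start
    leader_density <- if (llen > 0) sum(track[seq_len(llen)]) / llen else NA_real_
    res <- lapply(seq_len(nrow(o)), function(j) {
      q <- orf_te(o[j, ], track, txr$fpkm, min_uorf_len, min_cds_len, omit_tail)
      if (!is.na(q$window_len) && q$window_len <= 0) return(NULL)
      data.frame(
        o[j, c("transcript_id", "start", "end", "frame_rel_cds", "klass", "length_nt")],
        reads_in_window = q$reads_in_window,
        density = q$density,
        te = q$te,
        passes_length_filter = q$passes_length_filter,
        cds_te = cds_q$te,
        cds_density = cds_q$density,
        uorf_repressiveness =
          if (o$klass[j] %in% c("uORF_nonoverlapping", "uORF_overlapping_cds") &&
              !is.na(q$te) && !is.na(cds_q$te) && cds_q$te > 0)
            q$te / cds_q$te else NA_real_,
        leader_density = leader_density,
        leader_te = if (!is.na(txr$fpkm) && txr$fpkm > 0 && !is.na(leader_density))
          leader_density / txr$fpkm else NA_real_,
        leader_repressiveness =
          if (!is.na(cds_q$density) && cds_q$density > 0 && !is.na(leader_density))
            leader_density / cds_q$density else NA_real_,
        fpkm = txr$fpkm,
        stringsAsFactors = FALSE)
    })
    null_rows <- vapply(res, is.null, logical(1))
    n_empty_window <- n_empty_window + sum(null_rows)
    rows[[i]] <- do.call(rbind, res[!null_rows])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("te_table: no quantifiable ORFs")
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(empty_window = n_empty_window,
                               no_fpkm = n_no_fpkm, zero_cds_density = n_zero_cds)
  .log_msg("te_table: ", nrow(out), " ORF rows; excluded ", n_empty_window,
           " with empty windows")
  out
}
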