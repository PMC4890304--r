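# Loading transcript models, P-site tracks, abundances and ortholog tables.
#
# A "transcriptome" is a data.frame with one row per retained transcript:
#   transcript_id, gene_id, sequence, cds_start, cds_end, fpkm
# Coordinates are 0-based half-open on the transcript; the 5' leader is
# [0, cds_start), the CDS [cds_start, cds_end) and the 3' UTR [cds_end, length).

#' Construct and validate a transcriptome table
#'
#' @param df data.frame with columns `transcript_id`, `gene_id`, `sequence`,
#'   `cds_start`, `cds_end` and optionally `fpkm` (absent values as `NA`).
#' @return the validated data.frame with class `"transcriptome"`, sequences
#'   uppercased and rows ordered by `transcript_id`.
#' @export
transcriptome <- function(df) {
  need <- c("transcript_id", "gene_id", "sequence", "cds_start", "cds_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("transcriptome: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("transcriptome: duplicate transcript_id")
  if (!"fpkm" %in% names(df)) df$fpkm <- NA_real_
  df$sequence <- toupper(df$sequence)
  len <- nchar(df$sequence)
  bad <- df$cds_start < 0 | df$cds_end > len | (df$cds_end - df$cds_start) < 3
  if (any(bad))
    stop("transcriptome: CDS span out of range or shorter than one codon for: ",
         paste(utils::head(df$transcript_id[bad], 5), collapse = ", "))
  df <- df[order(df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("transcriptome", "data.frame")
  df
}

leader_length <- function(tx) tx$cds_start
cds_length <- function(tx) tx$cds_end - tx$cds_start

#' Select one transcript per gene
#'
#' Applies the transcript-per-gene rule: among a gene's isoforms keep the one
#' with the longest CDS, then the longest 5' leader, then (for determinism)
#' the lexicographically smallest `transcript_id`.
#'
#' @param df annotation data.frame with `transcript_id`, `gene_id`,
#'   `cds_start`, `cds_end` and either a `sequence` column or a `length` column.
#' @return the rows of `df` for selected transcripts, one per gene.
#' @export
select_one_per_gene <- function(df) {
  cdslen <- df$cds_end - df$cds_start
  ldrlen <- df$cds_start
  ord <- order(df$gene_id, -cdslen, -ldrlen, df$transcript_id)
  df <- df[ord, , drop = FALSE]
  df[!duplicated(df$gene_id), , drop = FALSE]
}

#' Load a transcriptome from FASTA + annotation + FPKM tables
#'
#' Reads transcript sequences (FASTA, mRNA-sense orientation), a transcript-
#' relative annotation table (`transcript_id gene_id cds_start cds_end`,
#' 0-based half-open, TSV with header) and an FPKM table
#' (`transcript_id fpkm`). Applies [select_one_per_gene()], then excludes
#' transcripts whose CDS does not start with ATG or whose CDS length is not a
#' multiple of 3 (counts recorded in attributes `n_bad_cds`).
#'
#' @param fasta_path path to the transcript FASTA.
#' @param annotation_path path to the annotation TSV.
#' @param fpkm_path optional path to the FPKM TSV (`NULL` to skip).
#' @return a `"transcriptome"` data.frame (see [transcriptome()]).
#' @export
load_transcriptome <- function(fasta_path, annotation_path, fpkm_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seqv <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  ann <- read_tsv(annotation_path)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$transcript_id)) stop("annotation: duplicate transcript_id")
  unknown <- !(ann$transcript_id %in% names(seqv))
  if (any(unknown))
    stop("annotation references sequences absent from FASTA: ",
         paste(utils::head(ann$transcript_id[unknown], 5), collapse = ", "))
  ann <- select_one_per_gene(ann)
  ann$sequence <- toupper(unname(seqv[ann$transcript_id]))

  # malformed CDS: length not a codon multiple, or not starting ATG
  cdslen <- ann$cds_end - ann$cds_start
  start_codon <- substr(ann$sequence, ann$cds_start + 1L, ann$cds_start + 3L)
  bad <- cdslen %% 3L != 0L | start_codon != "ATG" |
    ann$cds_start < 0L | ann$cds_end > nchar(ann$sequence)
  n_bad <- sum(bad)
  if (n_bad) .log_msg("load_transcriptome: excluded ", n_bad, " transcripts with malformed CDS")
  ann <- ann[!bad, , drop = FALSE]

  if (!nrow(ann))
    stop("load_transcriptome: no transcripts left after CDS validation")
  ann$fpkm <- NA_real_
  if (!is.null(fpkm_path)) {
    fp <- read_tsv(fpkm_path)
    if (!all(c("transcript_id", "fpkm") %in% names(fp)))
      stop("fpkm table: need columns transcript_id, fpkm")
    idx <- match(ann$transcript_id, fp$transcript_id)
    ann$fpkm <- fp$fpkm[idx]
  }
  tx <- transcriptome(ann[, c("transcript_id", "gene_id", "sequence",
                              "cds_start", "cds_end", "fpkm")])
  attr(tx, "n_bad_cds") <- n_bad
  tx
}

#' Write a transcriptome back to FASTA + annotation + FPKM files
#'
#' Inverse of [load_transcriptome()]; writing then re-loading yields
#' field-identical records.
#'
#' @param tx a `"transcriptome"`.
#' @param fasta_path,annotation_path,fpkm_path output paths.
#' @export
write_transcriptome <- function(tx, fasta_path, annotation_path, fpkm_path) {
  ss <- Biostrings::DNAStringSet(tx$sequence)
  names(ss) <- tx$transcript_id
  Biostrings::writeXStringSet(ss, fasta_path)
  write_tsv(tx[, c("transcript_id", "gene_id", "cds_start", "cds_end")],
            annotation_path)
  fp <- tx[!is.na(tx$fpkm), c("transcript_id", "fpkm")]
  write_tsv(fp, fpkm_path)
  invisible(tx)
}

#' Load single-nucleotide P-site counts
#'
#' Reads a 3-column TSV `transcript_id position count` (0-based transcript
#' positions) into per-transcript integer count tracks, zero-filled where no
#' record exists. Out-of-bounds records are rejected and counted; records for
#' transcripts not in `tx` are skipped with a warning (or are fatal with
#' `strict = TRUE`).
#'
#' @param path P-site TSV path.
#' @param tx a `"transcriptome"`.
#' @param strict unknown transcript ids are fatal when `TRUE`.
#' @return named list of integer vectors (class `"psite_tracks"`), one per
#'   transcript in `tx`; attributes `n_out_of_bounds`, `n_unknown`.
#' @export
load_psites <- function(path, tx, strict = FALSE) {
  rec <- read_tsv(path)
  if (nrow(rec) && !all(c("transcript_id", "position", "count") %in% names(rec)))
    stop("psites: need columns transcript_id, position, count")
  tracks <- lapply(nchar(tx$sequence), function(L) integer(L))
  names(tracks) <- tx$transcript_id
  n_oob <- 0L; n_unknown <- 0L
  if (nrow(rec)) {
    known <- rec$transcript_id %in% tx$transcript_id
    n_unknown <- sum(!known)
    if (n_unknown) {
      if (strict) stop("psites: unknown transcript ids: ",
                       paste(utils::head(unique(rec$transcript_id[!known]), 5), collapse = ", "))
      warning("psites: skipped ", n_unknown, " records for unknown transcripts")
      rec <- rec[known, , drop = FALSE]
    }
    L <- nchar(tx$sequence)[match(rec$transcript_id, tx$transcript_id)]
    oob <- rec$position < 0L | rec$position >= L
    n_oob <- sum(oob)
    if (n_oob) .log_msg("load_psites: rejected ", n_oob, " out-of-bounds records")
    rec <- rec[!oob, , drop = FALSE]
    for (id in unique(rec$transcript_id)) {
      r <- rec[rec$transcript_id == id, ]
      v <- tracks[[id]]
      agg <- tapply(r$count, r$position, sum)
      v[as.integer(names(agg)) + 1L] <- v[as.integer(names(agg)) + 1L] + as.integer(agg)
      tracks[[id]] <- v
    }
  }
  structure(tracks, class = "psite_tracks",
            n_out_of_bounds = n_oob, n_unknown = n_unknown)
}

#' Write P-site tracks as a sparse TSV
#' @param tracks a `"psite_tracks"` list.
#' @param path output TSV path.
#' @export
write_psites <- function(tracks, path) {
  rows <- lapply(names(tracks), function(id) {
    v <- tracks[[id]]
    nz <- which(v != 0L)
    if (!length(nz)) return(NULL)
    data.frame(transcript_id = id, position = nz - 1L, count = v[nz])
  })
  df <- do.call(rbind, c(rows, list(data.frame(transcript_id = character(0),
                                               position = integer(0),
                                               count = integer(0)))))
  write_tsv(df, path)
}

#' Load a one-to-one ortholog table
#'
#' Reads a two-column TSV `id_a id_b`. Pairs referencing transcripts absent
#' from either transcriptome are dropped (count in attribute `n_dropped`);
#' an id appearing in more than one pair violates the one-to-one contract and
#' is fatal.
#'
#' @param path TSV path.
#' @param tx_a,tx_b the two species' transcriptomes (optional; `NULL` skips
#'   the presence filter).
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
load_orthologs <- function(path, tx_a = NULL, tx_b = NULL) {
  df <- read_tsv(path)
  if (!all(c("id_a", "id_b") %in% names(df)))
    stop("orthologs: need columns id_a, id_b")
  if (anyDuplicated(df$id_a) || anyDuplicated(df$id_b))
    stop("orthologs: an id appears in more than one pair (one-to-one violated)")
  n0 <- nrow(df)
  if (!is.null(tx_a)) df <- df[df$id_a %in% tx_a$transcript_id, , drop = FALSE]
  if (!is.null(tx_b)) df <- df[df$id_b %in% tx_b$transcript_id, , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped) .log_msg("load_orthologs: dropped ", n_dropped, " pairs with unloaded transcripts")
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}
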