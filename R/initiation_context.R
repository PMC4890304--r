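# TE-weighted initiation-context PSSMs and WRENT scores.
#
# The initiation context of an AUG is the 23-nt window from 10 nt upstream of
# the A to 10 nt downstream of the G (AUG included at offsets 10..12). The
# weighted PSSM is built from CDS contexts of transcripts lacking uORFs, each
# context contributing with weight ln(1 + TE). Scores (WRENT, in bits) are the
# log2 likelihood ratio of the 20 flanking positions against the pooled
# background of those same positions; the invariant AUG columns are excluded
# from both scoring and background since they shift every score by the same
# constant.

#' Extract initiation contexts around AUG starts
#'
#' @param tx a `"transcriptome"`.
#' @param starts data.frame with `transcript_id` and `start` (0-based position
#'   of the A of ATG).
#' @param up,down flanking widths in nt (defaults 10/10, giving 23-nt
#'   contexts including the ATG).
#' @return data.frame `transcript_id`, `start`, `context`; AUGs whose window
#'   would extend past either transcript end are excluded (attribute
#'   `n_truncated`), as padding would fabricate sequence.
#' @export
extract_contexts <- function(tx, starts, up = 10L, down = 10L) {
  idx <- match(starts$transcript_id, tx$transcript_id)
  if (anyNA(idx)) stop("extract_contexts: unknown transcript ids")
  L <- nchar(tx$sequence)[idx]
  lo <- starts$start - up          # 0-based inclusive
  hi <- starts$start + 2L + down   # 0-based inclusive
  ok <- lo >= 0L & hi <= L - 1L
  ctx <- substr(tx$sequence[idx[ok]], lo[ok] + 1L, hi[ok] + 1L)
  bad_aug <- substr(ctx, up + 1L, up + 3L) != "ATG"
  if (any(bad_aug)) stop("extract_contexts: a supplied start is not an ATG")
  out <- data.frame(transcript_id = starts$transcript_id[ok],
                    start = starts$start[ok],
                    context = ctx, stringsAsFactors = FALSE)
  attr(out, "n_truncated") <- sum(!ok)
  out
}

#' Construct a WRENT model directly from matrices
#'
#' Low-level constructor, mainly for toy models in tests and for
#' deserialization. `columns` is a 4 x W matrix of per-position nucleotide
#' frequencies (rows A, C, G, T, each column summing to 1).
#'
#' @param columns 4 x W frequency matrix.
#' @param background length-4 frequency vector; defaults to the row means of
#'   the scored columns.
#' @param scored integer positions (1-based) entering scores and the pooled
#'   background; defaults to all positions.
#' @param pseudocount,total_weight metadata carried along.
#' @return object of class `"wrent_model"`.
#' @export
wrent_model <- function(columns, background = NULL, scored = NULL,
                        pseudocount = NA_real_, total_weight = NA_real_) {
  stopifnot(nrow(columns) == 4L)
  rownames(columns) <- .BASES
  if (is.null(scored)) scored <- seq_len(ncol(columns))
  if (is.null(background)) background <- rowMeans(columns[, scored, drop = FALSE])
  names(background) <- .BASES
  csum <- colSums(columns)
  if (any(abs(csum - 1) > 1e-9)) stop("wrent_model: columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("wrent_model: background must sum to 1")
  structure(list(columns = columns, background = background, scored = scored,
                 pseudocount = pseudocount, total_weight = total_weight,
                 width = ncol(columns)),
            class = "wrent_model")
}

#' Build a TE-weighted PSSM (WRENT model) from initiation contexts
#'
#' Each context contributes with weight `log(1 + te)` (natural log). Column
#' frequencies use a per-base pseudocount:
#' `freq(b, p) = (pc + sum_i w_i [base_i,p == b]) / (4 pc + sum_i w_i)`.
#' The background is the weight-pooled frequency over the scored (non-AUG)
#' positions, i.e. the mean of those columns.
#'
#' @param contexts character vector of equal-length contexts (ATG at offsets
#'   `aug_at .. aug_at + 2`, 0-based).
#' @param tes matching TE values (>= 0); the training set of the reference
#'   model is CDS contexts of transcripts lacking uORFs.
#' @param pseudocount per-base per-column pseudocount (default 0.01).
#' @param aug_at 0-based offset of the A of ATG within the context
#'   (default 10); `NA` scores all positions (no AUG exclusion).
#' @return a `"wrent_model"`.
#' @export
build_wrent <- function(contexts, tes, pseudocount = 0.01, aug_at = 10L) {
  if (!length(contexts)) stop("build_wrent: empty training set")
  stopifnot(length(contexts) == length(tes), all(tes >= 0, na.rm = TRUE))
  keep <- !is.na(tes)
  contexts <- contexts[keep]; tes <- tes[keep]
  W <- unique(nchar(contexts))
  if (length(W) != 1L) stop("build_wrent: contexts differ in length")
  w <- log1p(tes)
  tw <- sum(w)
  if (tw <= 0) stop("build_wrent: total weight is 0 (all TE = 0)")
  m <- matrix(unlist(lapply(contexts, seq_to_int), use.names = FALSE),
              nrow = W)                       # positions x contexts
  counts <- matrix(0, nrow = 4L, ncol = W, dimnames = list(.BASES, NULL))
  for (b in 0:3) counts[b + 1L, ] <- as.vector((m == b) %*% w)
  cols <- (counts + pseudocount) / (4 * pseudocount + tw)
  scored <- if (is.na(aug_at)) seq_len(W) else setdiff(seq_len(W), aug_at + (1:3))
  wrent_model(cols, scored = scored, pseudocount = pseudocount, total_weight = tw)
}

#' WRENT score of initiation contexts (bits)
#'
#' Sum over the scored positions of `log2(column_freq(base, p) /
#' background(base))`. Contexts containing an undefined base at a scored
#' position score `NA`.
#'
#' @param model a `"wrent_model"`.
#' @param contexts character vector, same width as the model.
#' @return numeric score per context.
#' @export
wrent_score <- function(model, contexts) {
  if (!length(contexts)) return(numeric(0))
  W <- model$width
  if (any(nchar(contexts) != W)) stop("wrent_score: context width mismatch")
  lodds <- log2(model$columns / model$background)   # 4 x W
  m <- matrix(unlist(lapply(contexts, seq_to_int), use.names = FALSE), nrow = W)
  vapply(seq_along(contexts), function(i) {
    b <- m[model$scored, i]
    if (anyNA(b)) return(NA_real_)
    sum(lodds[cbind(b + 1L, model$scored)])
  }, numeric(1))
}

#' Per-position relative entropy of a WRENT model (bits)
#'
#' The per-position Kullback-Leibler term
#' `sum_b freq(b,p) log2(freq(b,p)/background(b))`, the quantity displayed as
#' letter-stack heights in initiation-context motifs.
#'
#' @param model a `"wrent_model"`.
#' @param positions positions to evaluate (default: all model positions).
#' @return numeric vector of relative entropies.
#' @export
relative_entropy_profile <- function(model, positions = seq_len(model$width)) {
  vapply(positions, function(p) {
    col <- model$columns[, p]
    ok <- col > 0
    sum(col[ok] * log2(col[ok] / model$background[ok]))
  }, numeric(1))
}

#' Serialize / deserialize a WRENT model as TSV + JSON metadata
#' @param model a `"wrent_model"`.
#' @param matrix_path TSV path for the frequency matrix (W rows x 4 columns).
#' @param meta_path JSON path for background/scored/pseudocount metadata.
#' @export
write_wrent <- function(model, matrix_path, meta_path) {
  df <- as.data.frame(t(model$columns))
  df <- cbind(position = seq_len(model$width) - 1L, df)
  write_tsv(df, matrix_path)
  jsonlite::write_json(
    list(background = as.list(model$background), scored = model$scored - 1L,
         pseudocount = model$pseudocount, total_weight = model$total_weight),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_wrent
#' @export
read_wrent <- function(matrix_path, meta_path) {
  df <- read_tsv(matrix_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  wrent_model(t(as.matrix(df[, .BASES])),
              background = unlist(meta$background),
              scored = meta$scored + 1L,
              pseudocount = meta$pseudocount,
              total_weight = meta$total_weight)
}
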