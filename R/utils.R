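# Internal sequence encoding and small shared helpers.
#
# Sequences are handled as uppercase character strings externally and as
# integer vectors internally (A=0, C=1, G=2, T=3, anything else NA).
# All user-facing coordinates are 0-based, half-open, transcript-relative.

.BASES <- c("A", "C", "G", "T")

# lookup table from UTF-8 code point to base code
.base_lookup <- local({
  lk <- rep(NA_integer_, 256L)
  lk[utf8ToInt("A")] <- 0L; lk[utf8ToInt("a")] <- 0L
  lk[utf8ToInt("C")] <- 1L; lk[utf8ToInt("c")] <- 1L
  lk[utf8ToInt("G")] <- 2L; lk[utf8ToInt("g")] <- 2L
  lk[utf8ToInt("T")] <- 3L; lk[utf8ToInt("t")] <- 3L
  lk
})

seq_to_int <- function(seq) {
  .base_lookup[utf8ToInt(seq)]
}

int_to_seq <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[ok] <- .BASES[x[ok] + 1L]
  out[!ok] <- "N"
  paste(out, collapse = "")
}

# codon code at 0-based position i (1-based index i+1): 16*s[i] + 4*s[i+1] + s[i+2]
# NA where any base undefined or out of range.
codon_codes <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  16L * s[1:(n - 2L)] + 4L * s[2:(n - 1L)] + s[3:n]
}

.ATG_CODE <- 14L                 # A,T,G -> 0*16 + 3*4 + 2
.STOP_CODES <- c(48L, 50L, 56L)  # TAA, TAG, TGA

#' Centered moving average with shrinking edges
#'
#' Smooths a positional series with a centered window of `window` positions.
#' Near the series ends the window shrinks to the available positions, so no
#' positions are lost. For an even `window` the extra position is taken on the
#' right (window of 24 spans 11 positions left, 12 right of the center).
#'
#' @param x numeric series (may contain `NA`).
#' @param window integer window width in positions (>= 1).
#' @param na.rm drop `NA` values within each window.
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window, na.rm = FALSE) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - left)
    hi <- min(n, i + right)
    mean(x[lo:hi], na.rm = na.rm)
  }, numeric(1))
}

# moving average applied to the columns of a matrix (used for shuffle replicates)
.moving_average_mat <- function(m, window) {
  apply(m, 2L, moving_average, window = window)
}

# gated progress/exclusion logging
.log_msg <- function(...) {
  if (isTRUE(getOption("uorfrepress.verbose", FALSE))) message(...)
  invisible(NULL)
}

# deterministic TSV writer used across the pipeline
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}
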