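# Sliding-window ensemble free energy (EFE) profiles with pluggable folding
# engines.
#
# A profile holds one EFE value per window start position (0-based, step 1 nt;
# default window 35 nt). The anchor windows used downstream start 25 nt
# upstream (-25) and 1 nt downstream (+1) of an ORF's A-of-AUG — i.e. window
# start index orf_start - 25 and orf_start + 1. That convention is an
# off-by-one hazard: "+1" is the window *starting* one nucleotide after the A.

#' Folding engine constructors
#'
#' A folding engine is a list with a `name`, a vectorized
#' `fold(seqs) -> numeric` returning ensemble free energies in kcal/mol
#' (<= 0; closer to 0 means less structure), and optionally a fast
#' `profile(seq, window)` path. Engines must be deterministic and pure.
#'
#' `constant_engine` returns a fixed value for every window;
#' `gc_engine` is a deterministic toy proxy scoring `per_gc` kcal/mol per G or
#' C in the window; `vienna_engine` delegates to the external ViennaRNA
#' `RNAfold` program (partition function, ensemble free energy, default
#' parameters at 37 C), substituting T with U.
#'
#' @param value constant EFE for `constant_engine`.
#' @param per_gc kcal/mol per G/C nucleotide (negative) for `gc_engine`.
#' @param rnafold path to the RNAfold executable.
#' @return a folding engine list.
#' @name folding_engines
NULL

#' @rdname folding_engines
#' @export
constant_engine <- function(value = 0) {
  stopifnot(value <= 0)
  list(name = "constant", params = list(value = value),
       fold = function(seqs) rep(value, length(seqs)),
       profile = function(seq, window) {
         n <- nchar(seq) - window + 1L
         if (n < 1L) numeric(0) else rep(value, n)
       })
}

#' @rdname folding_engines
#' @export
gc_engine <- function(per_gc = -0.35) {
  stopifnot(per_gc < 0)
  list(name = "gc", params = list(per_gc = per_gc),
       fold = function(seqs) {
         gc <- nchar(gsub("[^GCgc]", "", seqs))
         per_gc * gc
       },
       profile = function(seq, window) {
         s <- seq_to_int(seq)
         n <- length(s) - window + 1L
         if (n < 1L) return(numeric(0))
         is_gc <- as.integer(!is.na(s) & (s == 1L | s == 2L))
         cs <- cumsum(c(0L, is_gc))
         per_gc * (cs[(window + 1):(length(s) + 1L)] - cs[1:n])
       })
}

#' @rdname folding_engines
#' @export
vienna_engine <- function(rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) stop("vienna_engine: RNAfold executable not found")
  list(name = "vienna", params = list(rnafold = rnafold, temperature = 37),
       fold = function(seqs) {
         if (!length(seqs)) return(numeric(0))
         rna <- chartr("Tt", "Uu", seqs)
         inp <- tempfile(fileext = ".fa"); on.exit(unlink(inp))
         writeLines(rna, inp)
         out <- system2(rnafold, c("-p", "--noPS", "--noDP"),
                        stdin = inp, stdout = TRUE, stderr = FALSE)
         # ensemble free energy lines look like: "....... [ -3.41]"
         efe_lines <- grep("\\[", out, value = TRUE)
         if (length(efe_lines) != length(seqs))
           stop("vienna_engine: unexpected RNAfold output")
         as.numeric(sub(".*\\[\\s*(-?[0-9.]+)\\s*\\].*", "\\1", efe_lines))
       })
}

#' Sliding-window EFE profile of a transcript
#'
#' @param tx_row transcript row; transcripts containing `N` are skipped
#'   (empty profile, `skipped = TRUE`) since folding is undefined there.
#' @param engine a folding engine (see [folding_engines]).
#' @param window window width in nt (default 35; 25/30/40 are the supported
#'   alternatives, any >= 1 works).
#' @param orf_starts optional integer vector of ORF start positions for which
#'   the -25/+1 anchor EFEs are extracted.
#' @return object of class `"efe_profile"`: list with `transcript_id`,
#'   `window`, `values` (EFE per window start, length `L - window + 1`),
#'   `anchors` (data.frame `orf_start`, `efe_minus25`, `efe_plus1`, `NA` when
#'   a window is out of range) and `skipped`.
#' @export
efe_profile <- function(tx_row, engine, window = 35L, orf_starts = integer(0)) {
  L <- nchar(tx_row$sequence)
  skipped <- grepl("N", tx_row$sequence, fixed = TRUE)
  n_win <- L - window + 1L
  values <- if (skipped || n_win < 1L) {
    numeric(0)
  } else if (!is.null(engine$profile)) {
    engine$profile(tx_row$sequence, window)
  } else {
    starts <- seq_len(n_win)
    engine$fold(substring(tx_row$sequence, starts, starts + window - 1L))
  }
  at <- function(k) {           # EFE of window with 0-based start k
    ifelse(k >= 0L & k < length(values), values[pmax(k, 0L) + 1L], NA_real_)
  }
  anchors <- data.frame(orf_start = orf_starts,
                        efe_minus25 = at(orf_starts - 25L),
                        efe_plus1 = at(orf_starts + 1L))
  structure(list(transcript_id = tx_row$transcript_id, window = window,
                 values = values, anchors = anchors, skipped = skipped),
            class = "efe_profile")
}

#' EFE profiles for a whole transcriptome
#'
#' @param tx a `"transcriptome"`.
#' @param engine folding engine.
#' @param window window width.
#' @param orfs optional ORF table; each transcript's ORF starts feed the
#'   anchor extraction.
#' @return named list of `"efe_profile"` objects.
#' @export
efe_profiles_all <- function(tx, engine, window = 35L, orfs = NULL) {
  out <- lapply(seq_len(nrow(tx)), function(i) {
    starts <- if (is.null(orfs)) integer(0)
      else orfs$start[orfs$transcript_id == tx$transcript_id[i]]
    efe_profile(tx[i, ], engine, window, starts)
  })
  names(out) <- tx$transcript_id
  out
}

#' Mean EFE over the 5' leader and the CDS
#'
#' Means are taken over windows lying fully inside the region (strict
#' containment: window start `k` with `k >= region_start` and
#' `k + window <= region_end`); a region shorter than the window, or a
#' transcript skipped for undefined nucleotides, yields `NA`.
#'
#' @param profile an `"efe_profile"`.
#' @param tx_row the matching transcript row.
#' @return list `leader_mean_efe`, `cds_mean_efe`.
#' @export
region_mean_efe <- function(profile, tx_row) {
  w <- profile$window
  v <- profile$values
  mean_in <- function(lo, hi) {     # region [lo, hi), 0-based
    if (hi - lo < w || !length(v)) return(NA_real_)
    ks <- seq.int(lo, hi - w)       # window starts fully inside
    ks <- ks[ks >= 0L & ks < length(v)]
    if (!length(ks)) return(NA_real_)
    mean(v[ks + 1L])
  }
  list(leader_mean_efe = if (tx_row$cds_start >= w) mean_in(0L, tx_row$cds_start) else NA_real_,
       cds_mean_efe = mean_in(tx_row$cds_start, tx_row$cds_end))
}

#' Meta-profile of EFE around ORF starts
#'
#' For each offset `o` in `-span..span`, the mean over the supplied ORFs of
#' the EFE value at window start `orf_start + o`, with the per-offset number
#' of contributing ORFs.
#'
#' @param profiles named list of `"efe_profile"` objects.
#' @param orfs ORF table (uses `transcript_id` and `start`).
#' @param span half-width of the offset range in nt.
#' @return data.frame `offset`, `mean_efe`, `n`.
#' @export
meta_profile <- function(profiles, orfs, span = 50L) {
  offsets <- seq.int(-span, span)
  acc <- numeric(length(offsets)); n <- integer(length(offsets))
  for (i in seq_len(nrow(orfs))) {
    pr <- profiles[[orfs$transcript_id[i]]]
    if (is.null(pr) || !length(pr$values)) next
    k <- orfs$start[i] + offsets
    ok <- k >= 0L & k < length(pr$values)
    acc[ok] <- acc[ok] + pr$values[k[ok] + 1L]
    n <- n + ok
  }
  data.frame(offset = offsets,
             mean_efe = ifelse(n > 0, acc / pmax(n, 1L), NA_real_),
             n = n)
}

#' Correlation of window EFE with log CDS TE across start offsets
#'
#' Scans window-start offsets around ORF starts and correlates the EFE at
#' each offset with log CDS TE across transcripts, the analysis used to pick
#' the -25/+1 anchors (run on transcripts lacking uORFs).
#'
#' @param profiles named list of `"efe_profile"` objects.
#' @param starts data.frame `transcript_id`, `start`, `log_te`.
#' @param offsets integer offsets of the window start relative to the ORF
#'   start.
#' @param min_n offsets with fewer contributing transcripts yield `NA`.
#' @return data.frame `offset`, `pearson`, `spearman`, `n`.
#' @export
anchor_scan <- function(profiles, starts, offsets = -45:20, min_n = 10L) {
  res <- lapply(offsets, function(o) {
    efe <- vapply(seq_len(nrow(starts)), function(i) {
      pr <- profiles[[starts$transcript_id[i]]]
      if (is.null(pr) || !length(pr$values)) return(NA_real_)
      k <- starts$start[i] + o
      if (k < 0L || k >= length(pr$values)) NA_real_ else pr$values[k + 1L]
    }, numeric(1))
    ok <- !is.na(efe) & !is.na(starts$log_te)
    n <- sum(ok)
    if (n < min_n || stats::sd(efe[ok]) == 0 || stats::sd(starts$log_te[ok]) == 0) {
      data.frame(offset = o, pearson = NA_real_, spearman = NA_real_, n = n)
    } else {
      data.frame(offset = o,
                 pearson = stats::cor(efe[ok], starts$log_te[ok]),
                 spearman = stats::cor(efe[ok], starts$log_te[ok], method = "spearman"),
                 n = n)
    }
  })
  do.call(rbind, res)
}
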