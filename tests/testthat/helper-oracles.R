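# Independent brute-force oracles, deliberately written with different
# machinery (substr walks, table counts, augmented least squares) than the
# implementation they check.

# For every ATG in [0, region_end) walk codons via substring until the first
# in-frame stop anywhere on the sequence; returns 0-based start/end pairs.
oracle_orfs <- function(seq, region_start = 0L, region_end = nchar(seq)) {
  starts <- integer(0); ends <- integer(0)
  L <- nchar(seq)
  for (p0 in region_start:(max(region_start, region_end - 1L))) {
    if (p0 + 3L > L) break
    if (substr(seq, p0 + 1L, p0 + 3L) != "ATG") next
    q <- p0 + 3L
    end <- NA_integer_
    while (q + 3L <= L) {
      cod <- substr(seq, q + 1L, q + 3L)
      if (cod %in% c("TAA", "TAG", "TGA")) { end <- q + 3L; break }
      q <- q + 3L
    }
    if (!is.na(end)) { starts <- c(starts, p0); ends <- c(ends, end) }
  }
  data.frame(start = starts, end = ends)
}

# classical unweighted PSSM frequencies from a table() count
oracle_unweighted_pssm <- function(contexts, pseudocount = 0) {
  W <- nchar(contexts[1])
  bases <- c("A", "C", "G", "T")
  cols <- sapply(seq_len(W), function(p) {
    cnt <- table(factor(substr(contexts, p, p), levels = bases))
    (as.numeric(cnt) + pseudocount) / (length(contexts) + 4 * pseudocount)
  })
  rownames(cols) <- bases
  cols
}

# closed-form ridge with unpenalized intercept via augmented least squares:
# append sqrt(alpha) pseudo-rows, solve with lm.fit (QR), a code path
# disjoint from the package's normal-equations solve.
oracle_ridge <- function(x, y, alpha) {
  p <- ncol(x)
  aug_x <- rbind(cbind(1, x), cbind(0, sqrt(alpha) * diag(p)))
  aug_y <- c(y, rep(0, p))
  unname(stats::lm.fit(aug_x, aug_y)$coefficients)
}

# random transcript sequence with a valid CDS (ATG start, stop-free body,
# terminal stop), for fixtures
random_transcript <- function(leader_len, cds_len, utr3_len = 30L,
                              id = "T1", gc = 0.5) {
  stopifnot(cds_len %% 3 == 0)
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(n) paste(sample(bases, n, TRUE, prob = pr), collapse = "")
  body <- character(0)
  ncod <- cds_len / 3 - 2L
  while (length(body) < ncod) {
    cod <- draw(3)
    if (!cod %in% c("TAA", "TAG", "TGA")) body <- c(body, cod)
  }
  seqs <- paste0(draw(leader_len), "ATG", paste(body, collapse = ""), "TAA",
                 draw(utr3_len))
  transcriptome(data.frame(
    transcript_id = id, gene_id = paste0("g_", id), sequence = seqs,
    cds_start = leader_len, cds_end = leader_len + cds_len, fpkm = NA_real_))
}

# transcript with a fully specified sequence
tx_fixture <- function(seq, cds_start, cds_end, id = "T1", fpkm = NA_real_) {
  transcriptome(data.frame(
    transcript_id = id, gene_id = paste0("g_", id), sequence = seq,
    cds_start = cds_start, cds_end = cds_end, fpkm = fpkm))
}
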