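# Synthetic transcriptomes, P-site tracks, FPKM tables and ortholog pairs
# with the statistical structure the analysis assumes, plus ground truth for
# every planted effect.
#
# The generator re-measures its own output with the pipeline's feature
# extractors (reference initiation-context PSSM, toy GC folding engine), so
# GroundTruth stores realized, not merely intended, feature values and the
# feature conventions are guaranteed consistent with the analysis stages.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: mammalian-like leader and
#' CDS length distributions (log-normal; leaders median ~160 nt, CDSes median
#' ~480 nt floored at 120 nt and rounded to codons), GC 60%, a planted
#' Kozak-like CDS initiation motif, uORF ATGs injected at ~0.7 per leader on
#' top of chance AUGs, and a log-linear TE model over Z-scored realized
#' features whose signs mirror the fitted within-species models: uORF density
#' and uORF WRENT repress CDS TE, CDS WRENT and the mean EFEs (less stable
#' structure) increase it.
#'
#' @param n_transcripts number of transcripts.
#' @param seed base RNG seed; every stage derives its stream from it.
#' @param leader_meanlog,leader_sdlog,leader_min leader length distribution.
#' @param cds_meanlog,cds_sdlog,cds_min CDS length distribution (floored,
#'   rounded to codons).
#' @param utr3_meanlog,utr3_sdlog 3' UTR length distribution.
#' @param gc_content genome-wide GC fraction.
#' @param motif_strength sharpness of the planted CDS initiation motif in
#'   [0, 1].
#' @param uorf_rate mean planted uORF ATGs per leader (Poisson).
#' @param uorf_depletion_zone interval of uORF-end positions relative to the
#'   CDS start where the placement multiplier applies.
#' @param uorf_depletion_multiplier survival probability for uORF ends in the
#'   zone (1 = no depletion, 0 = none end there). Applied twice, emulating
#'   selection: planted uORFs whose end would fall in the zone are dropped
#'   (thinned placement), and realized in-zone ends — planted or arising by
#'   chance — have their stop codon disrupted with probability
#'   `1 - multiplier`, extending the ORF to its next in-frame stop.
#' @param te_beta named standardized coefficients of the CDS TE model (names
#'   must be feature columns of the ground truth).
#' @param te_mu,te_noise_sd intercept (natural log TE) and residual SD.
#' @param uorf_te_beta,uorf_te_mu,uorf_te_noise_sd same for uORF TEs (features
#'   `uorf_wrent`, `uorf_efe_plus1`).
#' @param shared_activity_sd SD of a per-transcript log-scale translational
#'   activity shared by the CDS and its uORFs, inducing the positive
#'   correlation between leader/uORF and CDS translation seen in ribosome
#'   profiling data (0 disables the coupling).
#' @param depth expected P-site reads per nucleotide at TE = 1, FPKM = 1.
#' @param background_rate untranslated background read rate relative to TE=1.
#' @param fpkm_meanlog,fpkm_sdlog FPKM distribution (log-normal).
#' @param ortholog_rho latent cross-species correlation used by
#'   [simulate_ortholog_pair()].
#' @return classed list `"sim_config"`.
#' @export
sim_config <- function(n_transcripts = 500L, seed = 1L,
                       leader_meanlog = log(160), leader_sdlog = 0.55,
                       leader_min = 30L,
                       cds_meanlog = log(480), cds_sdlog = 0.45,
                       cds_min = 120L,
                       utr3_meanlog = log(180), utr3_sdlog = 0.5,
                       gc_content = 0.6,
                       motif_strength = 0.8,
                       uorf_rate = 0.7,
                       uorf_depletion_zone = c(-100L, 0L),
                       uorf_depletion_multiplier = 0.4,
                       te_beta = c(uorf_density = -0.3, uorf_wrent = -0.3,
                                   cds_wrent = 0.3, leader_mean_efe = 0.3,
                                   cds_mean_efe = 0.3),
                       te_mu = 0, te_noise_sd = 0.5,
                       uorf_te_beta = c(uorf_wrent = 0.4, uorf_efe_plus1 = 0.3),
                       uorf_te_mu = log(0.08), uorf_te_noise_sd = 0.5,
                       shared_activity_sd = 0.6,
                       depth = 1, background_rate = 0.05,
                       fpkm_meanlog = log(20), fpkm_sdlog = 1,
                       ortholog_rho = 0.7) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_transcripts >= 1, cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$motif_strength >= 0, cfg$motif_strength <= 1,
            cfg$uorf_rate >= 0, cfg$uorf_depletion_multiplier >= 0,
            cfg$uorf_depletion_multiplier <= 1, cfg$depth > 0,
            cfg$background_rate >= 0, cfg$ortholog_rho >= 0,
            cfg$ortholog_rho <= 1)
  structure(cfg, class = "sim_config")
}

# Kozak-like consensus probabilities for the 20 flanking positions of a
# 23-nt context (ATG at offsets 11..13, 1-based). A sharpened parameterized
# consensus around published initiation-context preferences, not a claim
# about any measured PSSM.
.kozak_cols <- function(gc = 0.6) {
  bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cols <- matrix(bg, nrow = 4L, ncol = 23L, dimnames = list(.BASES, NULL))
  mix <- function(p, base, w) (1 - w) * p + w * (.BASES == base)
  # offsets relative to the A of ATG (0-based): -3 purine (A), -6..-1 GCCACC,
  # +3 G (first base after the G of ATG), weak C preference elsewhere upstream
  setcol <- function(off, base, w) cols[, off + 11L] <<- mix(cols[, off + 11L], base, w)
  for (off in -10:-7) setcol(off, "C", 0.12)
  setcol(-6L, "G", 0.35); setcol(-5L, "C", 0.35); setcol(-4L, "C", 0.35)
  setcol(-3L, "A", 0.75); setcol(-2L, "C", 0.4); setcol(-1L, "C", 0.4)
  setcol(3L, "G", 0.55)
  for (off in 4:12) setcol(off, "C", 0.08)
  cols[, 11L] <- as.numeric(.BASES == "A")
  cols[, 12L] <- as.numeric(.BASES == "T")
  cols[, 13L] <- as.numeric(.BASES == "G")
  cols
}

#' Reference initiation-context scoring model of the simulator
#'
#' The WRENT model whose columns are the planted consensus probabilities;
#' used by the generator to measure realized initiation-context features.
#'
#' @param gc_content background GC fraction.
#' @return a `"wrent_model"`.
#' @export
kozak_reference_model <- function(gc_content = 0.6) {
  wrent_model(.kozak_cols(gc_content), scored = setdiff(1:23, 11:13))
}

.sample_bases <- function(n, gc) {
  sample(0:3, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# mutate in-frame stop codons inside the CDS body to leave the annotated ORF
# intact (first base T -> C)
.fix_cds_stops <- function(s, cds_start, cds_end) {
  repeat {
    body <- seq.int(cds_start + 3L, cds_end - 3L - 1L)
    if (length(body) < 3L) return(s)
    starts <- body[seq.int(1L, length(body), by = 3L)]
    cc <- 16L * s[starts + 1L] + 4L * s[starts + 2L] + s[starts + 3L]
    bad <- starts[!is.na(cc) & cc %in% .STOP_CODES]
    if (!length(bad)) return(s)
    s[bad + 1L] <- 1L   # T -> C
  }
}

#' Simulate a transcriptome with planted motifs and uORFs
#'
#' Draws leader/CDS/UTR lengths and iid bases at the configured GC, writes a
#' valid CDS (ATG start, stop-free body, terminal stop), plants a Kozak-like
#' initiation context around the CDS start with per-transcript strength
#' `motif_strength * U(0,1)`, and injects `Poisson(uorf_rate)` uORF ATGs per
#' leader, re-drawing placements whose realized uORF end falls in the
#' depletion zone with probability `1 - uorf_depletion_multiplier`. Chance
#' AUGs arising from the background composition are kept and tracked: the
#' ground truth records realized uORF counts from a re-scan, not planted
#' counts.
#'
#' @param config a `"sim_config"`.
#' @return list `transcripts` (a `"transcriptome"`, FPKM unset),
#'   `ground_truth` (list: per-transcript realized `features` data.frame,
#'   `orfs`, `n_planted_uorfs`, the reference scoring model and engine).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_transcripts
    gc <- config$gc_content
    kz <- .kozak_cols(gc)
    bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    llen <- pmax(config$leader_min, round(stats::rlnorm(n, config$leader_meanlog,
                                                        config$leader_sdlog)))
    clen <- pmax(config$cds_min, round(stats::rlnorm(n, config$cds_meanlog,
                                                     config$cds_sdlog)))
    clen <- as.integer(3L * round(clen / 3))
    ulen <- pmax(20L, round(stats::rlnorm(n, config$utr3_meanlog,
                                          config$utr3_sdlog)))
    seqs <- character(n)
    n_planted <- integer(n)
    placements <- vector("list", n)
    stops_int <- list(c(3L, 0L, 0L), c(3L, 0L, 2L), c(3L, 2L, 0L))
    for (i in seq_len(n)) {
      L <- llen[i] + clen[i] + ulen[i]
      s <- .sample_bases(L, gc)
      cs <- llen[i]                      # 0-based cds_start
      ce <- cs + clen[i]
      s[cs + (1:3)] <- c(0L, 3L, 2L)     # ATG
      s[(ce - 3L) + (1:3)] <- stops_int[[sample.int(3L, 1L)]]
      # planted initiation motif with per-transcript quality
      es <- config$motif_strength * stats::runif(1)
      for (off in setdiff(-10:12, 0:2)) {
        p <- cs + off
        col <- (1 - es) * bg + es * kz[, off + 11L]
        s[p + 1L] <- sample(0:3, 1L, prob = col)
      }
      s <- .fix_cds_stops(s, cs, ce)
      # uORF injection: complete ATG..stop ORFs inside the leader, with the
      # end-zone placement multiplier
      k <- stats::rpois(1L, config$uorf_rate)
      zone <- config$uorf_depletion_zone
      planted <- 0L
      placed <- list()
      for (u in seq_len(k)) {
        for (attempt in 1:30) {
          len <- 3L * sample(7:25, 1L)           # 21..75 nt body incl. ATG
          if (cs < len + 3L) next                # leader too short for this draw
          p <- sample.int(cs - len - 2L, 1L) - 1L  # start in [0, cs - len - 3]
          e <- p + len + 3L                      # exclusive end (stop included)
          # thinned placement: a draw ending in the depletion zone is dropped
          # (not re-placed) with probability 1 - multiplier
          in_zone <- (e - cs) >= zone[1] && (e - cs) < zone[2]
          if (in_zone && stats::runif(1) >= config$uorf_depletion_multiplier)
            break
          s[p + (1:3)] <- c(0L, 3L, 2L)
          # clear in-frame stops in the body so the ORF ends where planted
          body <- seq.int(p + 3L, e - 6L, by = 3L)
          if (length(body)) {
            cc <- 16L * s[body + 1L] + 4L * s[body + 2L] + s[body + 3L]
            s[body[!is.na(cc) & cc %in% .STOP_CODES] + 1L] <- 1L
          }
          s[(e - 3L) + (1:3)] <- stops_int[[sample.int(3L, 1L)]]
          planted <- planted + 1L
          placed[[planted]] <- c(p, e)
          break
        }
      }
      n_planted[i] <- planted
      placements[[i]] <- placed
      # selection against uORF ends in the zone also acts on chance AUG-stop
      # pairs: realized in-zone ends are disrupted (stop T -> C, extending the
      # ORF to its next in-frame stop) with probability 1 - multiplier
      if (config$uorf_depletion_multiplier < 1 && cs >= 9L) {
        kept <- integer(0)
        for (pass in 1:10) {
          ends <- unique(leader_orf_ends_int(s[seq_len(cs)]))
          cand <- setdiff(ends[(ends - cs) >= zone[1] & (ends - cs) < zone[2]],
                          kept)
          if (!length(cand)) break
          keep <- stats::runif(length(cand)) < config$uorf_depletion_multiplier
          kept <- c(kept, cand[keep])
          if (all(keep)) break
          s[(cand[!keep] - 3L) + 1L] <- 1L
        }
      }
      seqs[i] <- int_to_seq(s)
    }
    ids <- sprintf("TX%05d", seq_len(n))
    tx <- transcriptome(data.frame(
      transcript_id = ids, gene_id = sprintf("G%05d", seq_len(n)),
      sequence = seqs, cds_start = llen, cds_end = llen + clen,
      fpkm = NA_real_, stringsAsFactors = FALSE))
    orfs <- find_orfs_all(tx)
    engine <- gc_engine()
    wrent_ref <- kozak_reference_model(gc)
    profiles <- efe_profiles_all(tx, engine, orfs = orfs)
    features <- .ground_truth_features(tx, orfs, wrent_ref, profiles)
    planted_df <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (!length(placements[[i]])) return(NULL)
      m <- do.call(rbind, placements[[i]])
      data.frame(transcript_id = ids[i], start = m[, 1], end = m[, 2])
    }))
    if (is.null(planted_df))
      planted_df <- data.frame(transcript_id = character(0),
                               start = integer(0), end = integer(0))
    list(transcripts = tx,
         ground_truth = list(
           config = config, features = features, orfs = orfs,
           n_planted_uorfs = n_planted, planted_uorfs = planted_df,
           reference_model = wrent_ref,
           engine = engine, profiles = profiles))
  })
}

# realized per-transcript features measured with the pipeline's extractors
.ground_truth_features <- function(tx, orfs, wrent_ref, profiles) {
  n <- nrow(tx)
  nu <- n_uorfs_per_transcript(tx, orfs)
  ctx <- extract_contexts(tx, data.frame(transcript_id = tx$transcript_id,
                                         start = tx$cds_start))
  cds_wrent <- rep(NA_real_, n)
  cds_wrent[match(ctx$transcript_id, tx$transcript_id)] <-
    wrent_score(wrent_ref, ctx$context)
  lme <- cme <- cm25 <- cp1 <- rep(NA_real_, n)
  uw <- u25 <- up1 <- ulen <- uend <- rep(NA_real_, n)
  nn <- orfs[orfs$klass == "uORF_nonoverlapping", , drop = FALSE]
  nn_idx <- split(seq_len(nrow(nn)), nn$transcript_id)
  for (i in seq_len(n)) {
    pr <- profiles[[tx$transcript_id[i]]]
    rm <- region_mean_efe(pr, tx[i, ])
    lme[i] <- rm$leader_mean_efe; cme[i] <- rm$cds_mean_efe
    a <- pr$anchors[match(tx$cds_start[i], pr$anchors$orf_start), ]
    cm25[i] <- a$efe_minus25; cp1[i] <- a$efe_plus1
    ii <- nn_idx[[tx$transcript_id[i]]]
    u <- if (is.null(ii)) nn[0, , drop = FALSE] else nn[ii, , drop = FALSE]
    if (nrow(u) == 1L) {
      ua <- pr$anchors[match(u$start, pr$anchors$orf_start), ]
      u25[i] <- ua$efe_minus25; up1[i] <- ua$efe_plus1
      ulen[i] <- u$length_nt; uend[i] <- u$end - tx$cds_start[i]
      uctx <- extract_contexts(tx[i, ], data.frame(transcript_id = tx$transcript_id[i],
                                                   start = u$start))
      if (nrow(uctx)) uw[i] <- wrent_score(wrent_ref, uctx$context)
    }
  }
  ne <- ifelse(nu == 0L, 0.1, nu)
  data.frame(
    transcript_id = tx$transcript_id, n_uorfs = nu,
    uorf_density = ifelse(tx$cds_start > 0, log(ne / tx$cds_start), NA_real_),
    leader_length = tx$cds_start, leader_mean_efe = lme,
    cds_wrent = cds_wrent, cds_efe_minus25 = cm25, cds_efe_plus1 = cp1,
    cds_mean_efe = cme,
    uorf_wrent = uw, uorf_efe_minus25 = u25, uorf_efe_plus1 = up1,
    uorf_length = ulen, uorf_end_pos_rel_cds = uend,
    stringsAsFactors = FALSE)
}

# z-score with NA -> 0 (mean) imputation, for building planted responses
.z0 <- function(x) {
  mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  z <- (x - mu) / s
  z[is.na(z)] <- 0
  z
}

#' Simulate P-site tracks and FPKM values for a simulated transcriptome
#'
#' Draws FPKM log-normally, sets each transcript's log CDS TE from the
#' planted log-linear model over Z-scored realized features plus Gaussian
#' noise, sets uORF TEs from their own feature model, and draws P-site counts
#' per position as independent Poissons: rate `te * fpkm * depth` inside each
#' translated ORF (uniform within the ORF) plus
#' `background_rate * fpkm * depth` everywhere.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param config the same `"sim_config"`.
#' @param latent optional list with `log_te`, `log_fpkm`, `uorf_activity`
#'   vectors overriding the feature-model draws (used for correlated
#'   ortholog simulations).
#' @return list `transcripts` (FPKM filled in), `tracks`
#'   (`"psite_tracks"`), `fpkm` (data.frame), `ground_truth` extended with
#'   `te_cds`, `uorf_te` and `depth`.
#' @export
simulate_ribo <- function(sim, config, latent = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    tx <- sim$transcripts
    gt <- sim$ground_truth
    n <- nrow(tx)
    feats <- gt$features
    log_fpkm <- if (!is.null(latent$log_fpkm)) latent$log_fpkm
      else stats::rnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
    fpkm <- exp(log_fpkm)
    activity <- rep(0, n)
    if (!is.null(latent$log_te)) {
      log_te <- latent$log_te
    } else {
      if (config$shared_activity_sd > 0)
        activity <- stats::rnorm(n, 0, config$shared_activity_sd)
      eta <- rep(config$te_mu, n)
      for (j in names(config$te_beta))
        eta <- eta + config$te_beta[[j]] * .z0(feats[[j]])
      log_te <- eta + activity + stats::rnorm(n, 0, config$te_noise_sd)
    }
    te_cds <- exp(log_te)

    uorfs <- gt$orfs[gt$orfs$klass %in% c("uORF_nonoverlapping",
                                          "uORF_overlapping_cds"), , drop = FALSE]
    u_te <- numeric(nrow(uorfs))
    if (nrow(uorfs)) {
      uctx <- extract_contexts(tx, data.frame(transcript_id = uorfs$transcript_id,
                                              start = uorfs$start))
      uw <- rep(NA_real_, nrow(uorfs))
      key_all <- paste(uorfs$transcript_id, uorfs$start)
      uw[match(paste(uctx$transcript_id, uctx$start), key_all)] <-
        wrent_score(gt$reference_model, uctx$context)
      up1 <- vapply(seq_len(nrow(uorfs)), function(k) {
        pr <- gt$profiles[[uorfs$transcript_id[k]]]
        a <- pr$anchors[match(uorfs$start[k], pr$anchors$orf_start), ]
        a$efe_plus1
      }, numeric(1))
      eta_u <- rep(config$uorf_te_mu, nrow(uorfs)) +
        config$uorf_te_beta[["uorf_wrent"]] * .z0(uw) +
        config$uorf_te_beta[["uorf_efe_plus1"]] * .z0(up1) +
        activity[match(uorfs$transcript_id, tx$transcript_id)]
      u_te <- exp(eta_u + stats::rnorm(nrow(uorfs), 0, config$uorf_te_noise_sd))
      if (!is.null(latent$uorf_activity))
        u_te <- u_te * latent$uorf_activity[match(uorfs$transcript_id,
                                                  tx$transcript_id)]
    }

    tracks <- vector("list", n)
    for (i in seq_len(n)) {
      L <- nchar(tx$sequence[i])
      lam <- rep(config$background_rate * fpkm[i] * config$depth, L)
      cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
      lam[(cs + 1L):ce] <- lam[(cs + 1L):ce] + te_cds[i] * fpkm[i] * config$depth
      ui <- which(uorfs$transcript_id == tx$transcript_id[i])
      for (k in ui) {
        span <- (uorfs$start[k] + 1L):uorfs$end[k]
        lam[span] <- lam[span] + u_te[k] * fpkm[i] * config$depth
      }
      tracks[[i]] <- stats::rpois(L, lam)
    }
    names(tracks) <- tx$transcript_id
    class(tracks) <- "psite_tracks"
    tx$fpkm <- fpkm
    gt$te_cds <- te_cds
    gt$uorf_te <- cbind(uorfs[, c("transcript_id", "start", "end")],
                        te = u_te)
    gt$depth <- config$depth
    list(transcripts = tx, tracks = tracks,
         fpkm = data.frame(transcript_id = tx$transcript_id, fpkm = fpkm),
         ground_truth = gt)
  })
}

#' Simulate a complete dataset (transcriptome + reads)
#'
#' @param config a `"sim_config"`.
#' @return as [simulate_ribo()].
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_transcriptome(config)
  simulate_ribo(sim, config)
}

#' Simulate iid leaders with optional planted positional effects
#'
#' Lightweight generator for positional-statistics calibration: transcripts
#' with iid uniform-ish leaders and a minimal valid CDS. Optionally thins ATG
#' occurrences in a positional zone (multiplicative suppression of the start
#' trinucleotide) or rejects uORF ends from a zone (stop-codon disruption
#' until no leader-contained uORF ends there).
#'
#' @param n number of transcripts.
#' @param leader_len leader length in nt (single value or range `c(lo, hi)`).
#' @param gc_content GC fraction.
#' @param seed RNG seed.
#' @param atg_zone,atg_multiplier keep an ATG starting in the zone (positions
#'   relative to the CDS start) with this probability, else disrupt it.
#' @param reject_end_zone disallow leader uORF ends in this zone.
#' @return a `"transcriptome"` (FPKM unset).
#' @export
simulate_leaders <- function(n, leader_len = 240L, gc_content = 0.5, seed = 1L,
                             atg_zone = NULL, atg_multiplier = 1,
                             reject_end_zone = NULL) {
  .with_seed(seed, {
    lens <- if (length(leader_len) == 2L)
      sample(leader_len[1]:leader_len[2], n, replace = TRUE)
    else rep(as.integer(leader_len), n)
    cds_len <- 120L
    seqs <- character(n)
    for (i in seq_len(n)) {
      L <- lens[i]
      s <- .sample_bases(L + cds_len, gc_content)
      s[L + (1:3)] <- c(0L, 3L, 2L)
      s <- .fix_cds_stops(s, L, L + cds_len)
      s[(L + cds_len - 3L) + (1:3)] <- c(3L, 0L, 0L)
      if (!is.null(atg_zone) && atg_multiplier < 1) {
        for (pass in 1:3) {
          cc <- codon_codes(s[seq_len(L)])
          atg <- which(cc == .ATG_CODE) - 1L        # 0-based leader positions
          atg <- atg[(atg - L) >= atg_zone[1] & (atg - L) < atg_zone[2]]
          drop <- atg[stats::runif(length(atg)) > atg_multiplier]
          if (!length(drop)) break
          s[drop + 2L] <- 1L                        # middle base -> C
        }
      }
      if (!is.null(reject_end_zone)) {
        for (pass in 1:60) {
          ends <- leader_orf_ends_int(s[seq_len(L)]) - L
          bad <- ends[ends >= reject_end_zone[1] & ends < reject_end_zone[2]]
          if (!length(bad)) break
          s[(bad + L) - 3L + 1L] <- 1L              # stop's T -> C
        }
      }
      seqs[i] <- int_to_seq(s)
    }
    transcriptome(data.frame(
      transcript_id = sprintf("L%05d", seq_len(n)),
      gene_id = sprintf("LG%05d", seq_len(n)),
      sequence = seqs, cds_start = lens, cds_end = lens + cds_len,
      fpkm = NA_real_, stringsAsFactors = FALSE))
  })
}

#' Simulate a Z-scored feature matrix with a planted linear response
#'
#' Features are independent standard normals; the response is
#' `X beta + N(0, noise_sd)`. Used for regression-recovery calibration.
#'
#' @param n rows.
#' @param beta named coefficient vector.
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return list `x` (matrix), `y`, `beta`.
#' @export
simulate_feature_response <- function(n, beta, noise_sd = 0.5, seed = 1L) {
  .with_seed(seed, {
    p <- length(beta)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, names(beta)))
    y <- as.vector(x %*% beta) + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = y, beta = beta)
  })
}

#' Simulate an orthologous pair of datasets with correlated translation
#'
#' Species A is a full [simulate_dataset()] draw. Species B shares A's
#' transcript architecture (leader/CDS/UTR lengths) but redraws its bases
#' independently; its latent log CDS TE, log FPKM and per-leader uORF
#' activity are bivariate-normal copies of A's at correlation `rho`, and
#' P-site counts are generated through the same read model. Ground truth
#' stores both latent vectors and `rho`.
#'
#' @param config a `"sim_config"`.
#' @param rho latent cross-species correlation (default `config$ortholog_rho`).
#' @return list `a`, `b` (each as [simulate_ribo()]), `pairs`
#'   (data.frame `id_a`, `id_b`) and `rho`.
#' @export
simulate_ortholog_pair <- function(config, rho = config$ortholog_rho) {
  stopifnot(rho >= 0, rho <= 1)
  n <- config$n_transcripts
  sim_a <- simulate_transcriptome(config)
  cfg_b <- config
  cfg_b$seed <- config$seed + 100003L
  sim_b <- simulate_transcriptome(cfg_b)
  # latent translation/abundance states are the correlated layer; sequences
  # of the two species are independent draws from the same configuration
  lat <- .with_seed(config$seed + 7L, {
    z_te_a <- stats::rnorm(n); z_lv_a <- stats::rnorm(n); z_ac_a <- stats::rnorm(n)
    mix <- function(z) rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    list(a = list(log_te = config$te_mu + 0.8 * z_te_a,
                  log_fpkm = config$fpkm_meanlog + config$fpkm_sdlog * z_lv_a,
                  uorf_activity = exp(0.6 * z_ac_a)),
         b = list(log_te = config$te_mu + 0.8 * mix(z_te_a),
                  log_fpkm = config$fpkm_meanlog + config$fpkm_sdlog * mix(z_lv_a),
                  uorf_activity = exp(0.6 * mix(z_ac_a))))
  })
  a <- simulate_ribo(sim_a, config, latent = lat$a)
  b <- simulate_ribo(sim_b, cfg_b, latent = lat$b)
  a$ground_truth$latent <- lat$a
  b$ground_truth$latent <- lat$b
  list(a = a, b = b,
       pairs = data.frame(id_a = a$transcripts$transcript_id,
                          id_b = b$transcripts$transcript_id,
                          stringsAsFactors = FALSE),
       rho = rho)
}

#' Simulate ortholog divergence records with planted contributions
#'
#' Draws independent standard-normal divergences of transcript level, CDS TE
#' and leader TE, and composes the divergence of CDS read density as
#' `beta_level * d_level + beta_te * d_te + beta_leader_te * d_leader_te +
#' N(0, noise_sd)`. Mirrors the structure of the cross-species divergence
#' model with a controllable contribution ratio.
#'
#' @param n pairs.
#' @param beta_level,beta_te,beta_leader_te planted contributions.
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return data.frame with `d_log_level`, `d_log_cds_te`, `d_log_leader_te`,
#'   `d_log_cds_density`.
#' @export
simulate_divergence_records <- function(n, beta_level = 1, beta_te = 0.5,
                                        beta_leader_te = 0, noise_sd = 0.1,
                                        seed = 1L) {
  .with_seed(seed, {
    d_level <- stats::rnorm(n); d_te <- stats::rnorm(n); d_lte <- stats::rnorm(n)
    data.frame(
      d_log_level = d_level, d_log_cds_te = d_te, d_log_leader_te = d_lte,
      d_log_cds_density = beta_level * d_level + beta_te * d_te +
        beta_leader_te * d_lte + stats::rnorm(n, 0, noise_sd))
  })
}
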