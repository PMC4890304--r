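# End-to-end orchestration: load or simulate inputs, run every analysis
# stage, write TSV outputs and a manifest of all thresholds and seeds.

.default_params <- function() {
  list(
    min_uorf_len = 21L, min_cds_len = 100L, omit_tail = 10L,
    efe_window = 35L, anchor_offsets = c(-25L, 1L),
    smoothing_window = 24L, n_shuffles = 1000L, shuffle_seed = 1663L,
    wrent_pseudocount = 0.01, density_pseudocount = 0.1,
    alpha = 1, engine = "gc", meta_span = 50L)
}

.known_keys <- c("fasta", "annotation", "fpkm", "psites", "simulate", "out_dir",
                 "fasta_b", "annotation_b", "fpkm_b", "psites_b", "orthologs",
                 names(.default_params()))

#' Validate and complete a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with either input paths
#' (`fasta`, `annotation`, `fpkm`, `psites`) or a `simulate` block of
#' [sim_config()] arguments, an optional `out_dir`, and any of the named
#' analysis parameters (`min_uorf_len` 21, `min_cds_len` 100, `omit_tail` 10,
#' `efe_window` 35, `anchor_offsets` -25/+1, `smoothing_window` 24,
#' `n_shuffles` 1000, `shuffle_seed` 1663, `wrent_pseudocount` 0.01,
#' `density_pseudocount` 0.1, `alpha` 1, `engine` one of
#' `"gc"`/`"constant"`/`"vienna"`). Unknown keys are fatal.
#'
#' @param config named list or path to a YAML file.
#' @return completed configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_keys)
  if (length(unknown))
    stop("pipeline_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(.default_params(),
                              config[intersect(names(config),
                                               names(.default_params()))])
  config[names(params)] <- params
  has_paths <- all(c("fasta", "annotation") %in% names(config))
  if (!has_paths && is.null(config$simulate))
    stop("pipeline_config: need either fasta+annotation inputs or a simulate block")
  config
}

.make_engine <- function(name) {
  switch(name,
         gc = gc_engine(),
         constant = constant_engine(0),
         vienna = vienna_engine(),
         stop("unknown folding engine: ", name))
}

#' Run the full uORF analysis pipeline
#'
#' Executes load (or simulate) -> ORF discovery -> TE quantification ->
#' WRENT -> structure profiling -> positional bias/depletion -> linear
#' modelling (-> conservation when a second species and an ortholog table
#' are configured via `fasta_b`/`annotation_b`/`fpkm_b`/`psites_b`/
#' `orthologs`), writing deterministic TSV outputs and a `manifest.json`
#' (configuration snapshot, seeds, thresholds, per-stage row and exclusion
#' counts) into `out_dir`. Reruns with the same configuration and seeds give
#' byte-identical outputs.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("run_all: no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), c("simulate", "out_dir"))],
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    res
  }

  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, cfg$simulate)
    ds <- stage("simulate", simulate_dataset(sim_cfg))
    tx <- ds$transcripts; tracks <- ds$tracks
    manifest$config$simulate <- unclass(sim_cfg)
  } else {
    tx <- stage("load", load_transcriptome(cfg$fasta, cfg$annotation, cfg$fpkm))
    tracks <- stage("load",
      if (!is.null(cfg$psites)) load_psites(cfg$psites, tx)
      else stop("run_all: psites input required"))
  }
  write_tsv(data.frame(tx)[, c("transcript_id", "gene_id", "cds_start",
                               "cds_end", "fpkm")],
            file.path(out_dir, "transcripts.tsv"))
  manifest$stages$load <- list(n_transcripts = nrow(tx))

  orfs <- stage("find-orfs", find_orfs_all(tx))
  write_tsv(orfs, file.path(out_dir, "orfs.tsv"))
  manifest$stages$find_orfs <- list(n_orfs = nrow(orfs),
                                    n_no_stop = attr(orfs, "n_no_stop"))

  tet <- stage("quantify", te_table(tx, orfs, tracks,
                                    min_uorf_len = cfg$min_uorf_len,
                                    min_cds_len = cfg$min_cds_len,
                                    omit_tail = cfg$omit_tail))
  write_tsv(tet, file.path(out_dir, "te_table.tsv"))
  manifest$stages$quantify <- list(n_rows = nrow(tet),
                                   exclusions = as.list(attr(tet, "exclusions")))

  # WRENT trained on CDS contexts of transcripts lacking uORFs
  wrent <- stage("wrent", {
    nu <- n_uorfs_per_transcript(tx, orfs)
    train_tx <- tx[nu == 0L, , drop = FALSE]
    cds_rows <- tet[tet$klass == "CDS", ]
    ctx <- extract_contexts(train_tx,
                            data.frame(transcript_id = train_tx$transcript_id,
                                       start = train_tx$cds_start))
    tes <- cds_rows$te[match(ctx$transcript_id, cds_rows$transcript_id)]
    keep <- !is.na(tes)
    build_wrent(ctx$context[keep], tes[keep],
                pseudocount = cfg$wrent_pseudocount)
  })
  write_wrent(wrent, file.path(out_dir, "wrent_matrix.tsv"),
              file.path(out_dir, "wrent_meta.json"))
  manifest$stages$wrent <- list(total_weight = wrent$total_weight,
                                pseudocount = cfg$wrent_pseudocount)

  engine <- .make_engine(cfg$engine)
  profiles <- stage("structure", efe_profiles_all(tx, engine,
                                                  window = cfg$efe_window,
                                                  orfs = orfs))
  region_means <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    rm <- region_mean_efe(profiles[[i]], tx[i, ])
    data.frame(transcript_id = tx$transcript_id[i],
               leader_mean_efe = rm$leader_mean_efe,
               cds_mean_efe = rm$cds_mean_efe)
  }))
  write_tsv(region_means, file.path(out_dir, "efe_region_means.tsv"))
  manifest$stages$structure <- list(engine = engine$name,
                                    window = cfg$efe_window,
                                    n_skipped = sum(vapply(profiles, `[[`,
                                                           logical(1), "skipped")))

  bias <- stage("bias", trinucleotide_bias(tx, "ATG",
                                           smoothing_window = cfg$smoothing_window))
  write_tsv(bias, file.path(out_dir, "bias_atg.tsv"))
  depl <- stage("depletion", uorf_end_depletion(tx,
                                                n_shuffles = cfg$n_shuffles,
                                                seed = cfg$shuffle_seed,
                                                smoothing_window = cfg$smoothing_window))
  write_tsv(data.frame(depl), file.path(out_dir, "depletion.tsv"))
  manifest$stages$positional <- list(n_shuffles = cfg$n_shuffles,
                                     shuffle_seed = cfg$shuffle_seed)

  models <- stage("model", {
    ft <- build_feature_table(tx, orfs, tet, wrent, profiles,
                              subset = "one_nonoverlapping_uorf",
                              response = "repressiveness",
                              density_pseudocount = cfg$density_pseudocount)
    fs <- feature_sets()
    sets <- list(uORF = fs$uORF,
                 `uORF+leader` = c(fs$uORF, fs$leader),
                 `uORF+CDS` = c(fs$uORF, fs$CDS),
                 `uORF+CDS+leader` = c(fs$uORF, fs$CDS, fs$leader))
    suppressWarnings(model_report(ft, sets, alpha = cfg$alpha,
                                  skip_infeasible = TRUE))
  })
  if (!nrow(models$report))
    stop("stage 'model' failed: too few complete single-uORF transcripts (",
         "rows do not support any feature set)")
  write_tsv(models$report, file.path(out_dir, "model_report.tsv"))
  manifest$stages$model <- list(alpha = cfg$alpha,
                                n = models$report$n[1],
                                skipped_sets = models$skipped)

  conserve <- NULL
  if (!is.null(cfg$orthologs)) {
    conserve <- stage("conserve", {
      if (is.null(cfg$fasta_b) || is.null(cfg$annotation_b) ||
          is.null(cfg$psites_b))
        stop("two-species run needs fasta_b, annotation_b and psites_b")
      tx_b <- load_transcriptome(cfg$fasta_b, cfg$annotation_b, cfg$fpkm_b)
      tracks_b <- load_psites(cfg$psites_b, tx_b)
      orfs_b <- find_orfs_all(tx_b)
      tet_b <- te_table(tx_b, orfs_b, tracks_b,
                        min_uorf_len = cfg$min_uorf_len,
                        min_cds_len = cfg$min_cds_len,
                        omit_tail = cfg$omit_tail)
      pairs <- load_orthologs(cfg$orthologs, tx, tx_b)
      ot <- ortholog_table(transcript_summary(tx, orfs, tet, wrent, profiles),
                           transcript_summary(tx_b, orfs_b, tet_b),
                           pairs)
      cors <- do.call(rbind, lapply(
        c("log_cds_density", "log_cds_te", "log_leader_te",
          "log_leader_repressiveness"),
        function(q) {
          cc <- conservation_correlations(ot, q)
          data.frame(quantity = q, pearson = cc$pearson,
                     spearman = cc$spearman, n = cc$n)
        }))
      dm <- tryCatch(divergence_model(ot, alpha = cfg$alpha),
                     error = function(e) NULL)
      list(table = ot, correlations = cors, divergence = dm)
    })
    write_tsv(data.frame(conserve$table), file.path(out_dir, "orthologs.tsv"))
    write_tsv(conserve$correlations,
              file.path(out_dir, "conservation_correlations.tsv"))
    manifest$stages$conserve <- list(n_pairs = nrow(conserve$table))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(transcripts = tx, tracks = tracks, orfs = orfs, te = tet,
                 wrent = wrent, profiles = profiles, bias = bias,
                 depletion = depl, models = models, conserve = conserve,
                 manifest = manifest, out_dir = out_dir))
}
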