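#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed for the simulation stage.
#' @return nested list understood by [run_pipeline()]: stage toggles
#'   (`stages`), simulator overrides (`simulate`), input paths used when
#'   the simulate stage is off (`inputs`), and stage parameters
#'   (`params`).
#' @export
pipeline_config <- function(out_dir = "hmrkit_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = list(simulate = TRUE, call_hmrs = TRUE, compare = TRUE,
                  profile = TRUE, enrich = TRUE, annotate_peaks = TRUE),
    simulate = list(),
    inputs = list(methylome_a = NULL, methylome_b = NULL,
                  chrom_sizes = NULL, genes = NULL, cgis = NULL,
                  peaks = NULL, motif_hits = list()),
    params = list(min_cpgs = 4L, maxgap = 1000L, tau = 20L, phi = 0.5,
                  min_cov = 1L, body_bins = 30L, flank_bp = 2000L,
                  flank_bins = 10L, cor_max_dist = 1000L,
                  cor_bin_width = 10L)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the two-tissue methylome comparison pipeline
#'
#' Executes, as enabled by the config's stage toggles: synthetic data
#' generation, HMR calling per tissue, overlap classification,
#' methylation profiling (four-level summary, level composition,
#' feature means, neighbour correlation, HMR-scaled matrix), motif
#' enrichment over the taxonomy classes, and peak annotation. Every
#' output file is listed in a manifest with its md5 digest; given the
#' same config and seed the digests are identical across runs.
#'
#' @param config a config list (see [pipeline_config()]), or the path of
#'   a YAML file holding one; partial configs are completed with
#'   defaults.
#' @param verbose log stage progress to standard error.
#' @return list with `manifest` (data.frame of file, md5) and the main
#'   in-memory results per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(pipeline_config(), config)
  p <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[hmrkit] ", ...)
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  results <- list()

  sizes <- NULL
  ma <- mb <- NULL
  genes <- NULL
  cgis <- NULL
  peaks <- NULL
  hit_sets <- list()
  truth <- NULL

  if (isTRUE(config$stages$simulate)) {
    log_msg("simulate: planting two-tissue truth")
    scfg <- do.call(sim_config, c(config$simulate,
                                  list(seed = config$seed)))
    truth <- build_truth(scfg)
    ma <- simulate_methylome(truth, "A")
    mb <- simulate_methylome(truth, "B")
    sizes <- scfg$chrom_sizes
    genes <- simulate_genes(truth)
    peaks <- simulate_peaks(truth)
    hit_sets <- list(
      uniform_motif = simulate_motif_hits(truth, n_hits = 10000L, fold = 1,
                                          motif_id = "uniform_motif"),
      planted_motif = simulate_motif_hits(truth, n_hits = 10000L, fold = 5,
                                          target_class = "SPEC_A",
                                          motif_id = "planted_motif"))
    emit(write_methylome(ma, file.path(out_dir, "methylome_A.tsv")))
    emit(write_methylome(mb, file.path(out_dir, "methylome_B.tsv")))
    emit(write_chrom_sizes(sizes, file.path(out_dir, "chrom.sizes")))
    emit(write_genes(genes, file.path(out_dir, "genes.bed")))
    emit(write_intervals(peaks[, c("chrom", "start", "end", "name")],
                         file.path(out_dir, "peaks.bed")))
    for (nm in names(hit_sets)) {
      emit(write_intervals(hit_sets[[nm]],
                           file.path(out_dir, paste0(nm, ".bed"))))
    }
    for (tis in c("A", "B")) {
      segs <- truth$segments[truth$segments$tissue == tis, , drop = FALSE]
      for (cls in unique(segs$class)) {
        df <- segs[segs$class == cls, c("chrom", "start", "end")]
        df$name <- cls
        emit(write_intervals(
          df, file.path(out_dir, sprintf("truth_%s_%s.bed", tis, cls))))
      }
    }
    results$truth <- truth
  } else {
    inp <- config$inputs
    if (!is.null(inp$methylome_a)) {
      ma <- read_methylome(inp$methylome_a, min_cov = 0L)
    }
    if (!is.null(inp$methylome_b)) {
      mb <- read_methylome(inp$methylome_b, min_cov = 0L)
    }
    if (!is.null(inp$chrom_sizes)) sizes <- read_chrom_sizes(inp$chrom_sizes)
    if (!is.null(inp$genes)) genes <- read_genes(inp$genes)
    if (!is.null(inp$cgis)) cgis <- read_intervals(inp$cgis)
    if (!is.null(inp$peaks)) peaks <- read_intervals(inp$peaks)
    for (nm in names(inp$motif_hits)) {
      hit_sets[[nm]] <- read_intervals(inp$motif_hits[[nm]])
    }
  }

  hmr_a <- hmr_b <- NULL
  if (isTRUE(config$stages$call_hmrs)) {
    if (is.null(ma) || is.null(mb)) stop("call_hmrs: no methylomes")
    log_msg("call_hmrs: tissue A (", nrow(ma), " sites)")
    hmr_a <- call_hmrs(ma, min_cpgs = p$min_cpgs, maxgap = p$maxgap)
    log_msg("call_hmrs: tissue B (", nrow(mb), " sites)")
    hmr_b <- call_hmrs(mb, min_cpgs = p$min_cpgs, maxgap = p$maxgap)
    emit(write_hmrs(hmr_a, file.path(out_dir, "hmrs_A.bed")))
    emit(write_hmrs(hmr_b, file.path(out_dir, "hmrs_B.bed")))
    for (tis in c("A", "B")) {
      prm <- attr(if (tis == "A") hmr_a else hmr_b, "params")
      f <- file.path(out_dir, sprintf("hmm_params_%s.yaml", tis))
      yaml::write_yaml(list(
        init = prm$init, trans = as.vector(prm$trans),
        alpha_hypo = prm$alpha_hypo, beta_hypo = prm$beta_hypo,
        alpha_hyper = prm$alpha_hyper, beta_hyper = prm$beta_hyper), f)
      emit(f)
    }
    results$hmr_a <- hmr_a
    results$hmr_b <- hmr_b
  }

  comparison <- NULL
  if (isTRUE(config$stages$compare)) {
    if (is.null(hmr_a) || is.null(sizes)) stop("compare: missing inputs")
    log_msg("compare: classifying overlap components")
    comparison <- compare_sets(hmr_a, hmr_b, sizes, tau = p$tau)
    tsv <- file.path(out_dir, "comparison_report.tsv")
    utils::write.table(comparison$class_table, tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(tsv)
    ext <- extension_segments(comparison, ma, mb, min_cov = p$min_cov)
    etsv <- file.path(out_dir, "extensions.tsv")
    utils::write.table(ext, etsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(etsv)
    results$comparison <- comparison
    results$extensions <- ext
  }

  if (isTRUE(config$stages$profile)) {
    if (is.null(comparison)) stop("profile: needs the compare stage")
    log_msg("profile: methylation summaries")
    fl <- four_level_summary(comparison, ma, mb, min_cov = p$min_cov)
    emit_tsv <- function(df, name) {
      f <- file.path(out_dir, name)
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(f)
      f
    }
    emit_tsv(fl, "four_level_summary.tsv")
    emit_tsv(rbind(cbind(tissue = "A", composition(ma, min_cov = p$min_cov)),
                   cbind(tissue = "B", composition(mb, min_cov = p$min_cov))),
             "level_composition.tsv")
    if (!is.null(genes)) {
      emit_tsv(rbind(cbind(tissue = "A",
                           feature_summary(ma, genes, min_cov = p$min_cov)),
                     cbind(tissue = "B",
                           feature_summary(mb, genes, min_cov = p$min_cov))),
               "feature_summary.tsv")
    }
    nc <- neighbor_correlation(ma, max_dist = p$cor_max_dist,
                               bin_width = p$cor_bin_width,
                               min_cov = p$min_cov)
    emit_tsv(nc, "neighbor_correlation_A.tsv")
    s1a_rows <- unlist(lapply(which(comparison$labels == "S1_A"),
                              function(i)
                                comparison$component_members[[i]]$a))
    if (length(s1a_rows) > 0L) {
      sm <- scaled_matrix(comparison$setA[s1a_rows, , drop = FALSE], mb,
                          body_bins = p$body_bins, flank_bp = p$flank_bp,
                          flank_bins = p$flank_bins, min_cov = p$min_cov)
      emit_tsv(as.data.frame(sm), "s1a_matrix_in_B.tsv")
    }
    results$four_level <- fl
    results$neighbor_correlation <- nc
  }

  if (isTRUE(config$stages$enrich)) {
    if (is.null(comparison) || length(hit_sets) == 0L) {
      stop("enrich: needs the compare stage and motif hit sets")
    }
    log_msg("enrich: scoring motif sets over taxonomy classes")
    members <- comparison$component_members
    class_regions <- function(lab, side) {
      rows <- unlist(lapply(which(comparison$labels == lab),
                            function(i) members[[i]][[side]]))
      set <- if (side == "a") comparison$setA else comparison$setB
      set[rows, c("chrom", "start", "end"), drop = FALSE]
    }
    region_sets <- list(
      S1_A = class_regions("S1_A", "a"),
      S1_B = class_regions("S1_B", "b"),
      common = class_regions("C1", "a"))
    ext <- comparison$extensions
    for (tis in c("A", "B")) {
      e <- ext[ext$tissue == tis, c("chrom", "start", "end"), drop = FALSE]
      region_sets[[paste0("ext_", tis)]] <- e
    }
    region_sets <- Filter(function(df) nrow(df) > 0L, region_sets)
    et <- enrich_table(hit_sets, region_sets, sizes)
    f <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(et, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
    results$enrichment <- et
  }

  if (isTRUE(config$stages$annotate_peaks)) {
    if (is.null(peaks) || is.null(hmr_a)) {
      stop("annotate_peaks: needs peaks and called HMRs")
    }
    log_msg("annotate_peaks: ", nrow(peaks), " peaks")
    ann <- annotate_peaks(peaks, hmr_a, hmr_b, ma, mb, genes = genes,
                          cgis = cgis, phi = p$phi, min_cov = p$min_cov)
    f <- file.path(out_dir, "peak_annotation.tsv")
    utils::write.table(ann$peaks, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(f)
    f2 <- file.path(out_dir, "peak_state_by_feature.tsv")
    utils::write.table(as.data.frame(ann$state_feature), f2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(f2)
    results$peak_annotation <- ann
  }

  digests <- if (length(manifest) > 0L) {
    as.character(tools::md5sum(manifest))
  } else {
    character(0)
  }
  results$manifest <- data.frame(file = manifest, md5 = digests,
                                 stringsAsFactors = FALSE)
  mf <- file.path(out_dir, "manifest.tsv")
  utils::write.table(results$manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_msg("done: ", length(manifest), " output file(s)")
  results
}
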