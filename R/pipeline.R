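#' Assemble a pipeline configuration
#'
#' Collects the per-stage parameter blocks for a full synthetic run:
#' simulate, call-dmc, call-dmr, classify-dose, annotate, overlap.  A YAML
#' file with the same block names may be supplied instead.
#'
#' @param seed master seed; every stage derives its RNG stream from it.
#' @param sim a [simulation_config()] (its seed is overridden by `seed`).
#' @param dmc a [dmc_params()].
#' @param smooth a [smooth_params()].
#' @param alpha dose-classification significance level.
#' @param window annotation window in bp.
#' @param n_genes,n_tes synthetic annotation sizes.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, sim = simulation_config(seed = seed),
                            dmc = dmc_params(), smooth = smooth_params(),
                            alpha = 0.05, window = 2000,
                            n_genes = 40L, n_tes = 20L) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, dmc = dmc,
                 smooth = smooth, alpha = as.numeric(alpha),
                 window = as.numeric(window), n_genes = as.integer(n_genes),
                 n_tes = as.integer(n_tes)),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised blocks: `seed`, `sim`, `dmc`, `smooth`, `alpha`, `window`,
#' `n_genes`, `n_tes`; each block holds arguments for the matching
#' constructor.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  pipeline_config(
    seed = seed,
    sim = do.call(simulation_config, c(list(seed = seed), y$sim)),
    dmc = do.call(dmc_params, y$dmc %||% list()),
    smooth = do.call(smooth_params, y$smooth %||% list()),
    alpha = y$alpha %||% 0.05, window = y$window %||% 2000,
    n_genes = y$n_genes %||% 40L, n_tes = y$n_tes %||% 20L)
}

#' Run the full synthetic pipeline
#'
#' Executes the six stages in order on simulated data — simulate counts,
#' call DmCs (both treated doses vs control), call DMRs with both callers
#' and reconcile, classify dose response, annotate against a synthetic
#' gene/TE annotation, and compute cross-stress-style overlap statistics on
#' the associated gene sets — writing each stage's tabular output under
#' `outdir` with a provenance header (package version, seed, config hash)
#' and an md5 manifest.  Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param outdir output directory (created if absent).
#' @return List with `manifest` (data frame `stage`, `file`, `md5`) and the
#'   in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::serializeJSON(unclass(config))
  tf <- tempfile(); writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)
  seed <- config$seed
  stamp <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_stamped(df, path, seed = seed, config_hash = config_hash)
    path
  }
  manifest <- list()
  log_stage <- function(stage, files, n_out) {
    message(sprintf("[%s] wrote %d record(s) to %s", stage, n_out,
                    paste(basename(files), collapse = ", ")))
    for (f in files)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = stage, file = basename(f), md5 = unname(tools::md5sum(f)),
        stringsAsFactors = FALSE)
  }

  # stage 1: simulate
  ref <- generate_reference(config$sim)
  if (is.null(config$sim$dmr_spec))
    config$sim$dmr_spec <- plant_dmrs(ref$sites, seed = seed)
  sim <- simulate_counts(ref, config$sim)
  f_truth <- stamp(sim$truth, "truth.tsv")
  log_stage("simulate", f_truth, nrow(sim$truth))
  doses <- vapply(sim$samples, `[[`, numeric(1), "dose")
  g0 <- sim$samples[doses == 0]
  g5 <- sim$samples[doses == 5]
  g10 <- sim$samples[doses == 10]

  # stage 2: call-dmc
  dmcs5 <- call_dmcs(g0, g5, config$dmc)
  dmcs10 <- call_dmcs(g0, g10, config$dmc)
  f_dmc <- c(stamp(dmcs5, "dmcs_dose5.tsv"), stamp(dmcs10, "dmcs_dose10.tsv"))
  log_stage("call-dmc", f_dmc, nrow(dmcs5) + nrow(dmcs10))

  # stage 3: call-dmr (both callers, per dose, reconciled)
  sm0 <- smooth_methylation(g0, config$smooth)
  sm5 <- smooth_methylation(g5, config$smooth)
  sm10 <- smooth_methylation(g10, config$smooth)
  smooth5 <- tstat_regions(sm0, sm5, config$smooth)
  smooth10 <- tstat_regions(sm0, sm10, config$smooth)
  merged5 <- merge_dmrs(dmcs5)
  merged10 <- merge_dmrs(dmcs10)
  high5 <- intersect_callers(merged5, smooth5)
  high10 <- intersect_callers(merged10, smooth10)
  rec <- reconcile_doses(smooth5, smooth10)
  # same row order as classify_all(): unique_10, unique_5, shared
  all_dmrs <- rbind(rec$unique_10, rec$unique_5, rec$shared)
  f_dmr <- c(stamp(all_dmrs, "dmrs_reconciled.tsv"),
             stamp(rbind(high5, high10), "dmrs_high_confidence.tsv"))
  log_stage("call-dmr", f_dmr, nrow(all_dmrs))

  # stage 4: classify-dose
  cls <- classify_all(rec, sim$samples, alpha = config$alpha)
  f_cls <- stamp(cls$classifications, "dose_classes.tsv")
  log_stage("classify-dose", f_cls, nrow(cls$classifications))

  # stage 5: annotate
  features <- simulate_features(ref, config$n_genes, config$n_tes,
                                seed = seed)
  dmrs_id <- cbind(dmr_id = cls$classifications$dmr_id,
                   all_dmrs)
  assoc <- associate_dmrs(dmrs_id, features, config$window)
  tally <- tally_by_context(dmrs_id, assoc)
  f_ann <- c(stamp(assoc, "associations.tsv"),
             stamp(tally, "context_tally.tsv"))
  log_stage("annotate", f_ann, nrow(assoc))

  # stage 6: overlap (per-dose associated gene sets + all genes universe)
  genes5 <- associated_genes(
    associate_dmrs(rec$unique_5, features, config$window))
  genes10 <- associated_genes(
    associate_dmrs(rec$unique_10, features, config$window))
  genes_shared <- associated_genes(
    associate_dmrs(rec$shared, features, config$window))
  sets <- list(dose5 = union(genes5, genes_shared),
               dose10 = union(genes10, genes_shared),
               shared = genes_shared)
  universe_n <- sum(features$feature_type == "gene")
  report <- overlap_report(sets, max(universe_n, 1L))
  f_ov <- file.path(outdir, "overlap.json")
  jsonlite::write_json(report, f_ov, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("overlap", f_ov, length(report$chisq))

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, truth = sim$truth,
                 dmcs = list(dose5 = dmcs5, dose10 = dmcs10),
                 dmrs = rec, high_confidence = rbind(high5, high10),
                 classes = cls, associations = assoc, overlap = report))
}
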