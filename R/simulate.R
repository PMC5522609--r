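#' Configuration for the synthetic bisulfite methylome
#'
#' The generator emulates the design of a dose-structured herbicide-stress
#' methylome experiment: three treatment groups (0, 5 and 10 percent of the
#' field application rate) sequenced in quadruplicate, per-replicate genome
#' coverage in the tens, plant-typical context-specific baseline methylation
#' (CG highest, then CHG, then CHH), an unmethylated control contig standing
#' in for the chloroplast, and planted differentially methylated regions in
#' dose-independent, positive dose-dependent and inverse dose-dependent
#' classes.
#'
#' @param seed integer RNG seed; every operation derives its stream from it.
#' @param n_contigs number of nuclear contigs.
#' @param contig_length length of each contig in bp (>= 1000).
#' @param gc_content GC fraction of the random reference.
#' @param include_control_contig add an unmethylated control contig.
#' @param control_length length of the control contig.
#' @param doses treatment doses in percent of field rate.
#' @param n_replicates replicates per dose (>= 2).
#' @param mean_coverage mean per-site read depth (negative binomial mean).
#' @param coverage_dispersion negative binomial size parameter; larger is
#'   closer to Poisson.
#' @param baseline_beta_params named list of `c(alpha, beta)` per context for
#'   the across-site latent methylation-level distribution.
#' @param replicate_dispersion beta-binomial precision for per-replicate
#'   level noise; 0 (default) disables it and counts are binomial given the
#'   site's latent level.
#' @param non_conversion_rate bisulfite non-conversion probability.
#' @param dmr_spec data frame of planted DMRs, usually from [plant_dmrs()].
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 2L,
                              contig_length = 20000L,
                              gc_content = 0.5,
                              include_control_contig = TRUE,
                              control_length = 4000L,
                              doses = c(0, 5, 10),
                              n_replicates = 4L,
                              mean_coverage = 60,
                              coverage_dispersion = 10,
                              baseline_beta_params = list(
                                CG = c(0.6, 1.4),
                                CHG = c(0.3, 2.7),
                                CHH = c(0.2, 3.8)),
                              replicate_dispersion = 0,
                              non_conversion_rate = 0.005,
                              dmr_spec = NULL) {
  stopifnot(contig_length >= 1000, n_replicates >= 2,
            non_conversion_rate >= 0, non_conversion_rate <= 1,
            gc_content > 0, gc_content < 1, mean_coverage > 0)
  if (!all(c("CG", "CHG", "CHH") %in% names(baseline_beta_params)))
    stop("baseline_beta_params must name CG, CHG and CHH")
  structure(
    list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
         contig_length = as.integer(contig_length),
         gc_content = as.numeric(gc_content),
         include_control_contig = include_control_contig,
         control_length = as.integer(control_length),
         doses = as.numeric(doses), n_replicates = as.integer(n_replicates),
         mean_coverage = as.numeric(mean_coverage),
         coverage_dispersion = as.numeric(coverage_dispersion),
         baseline_beta_params = lapply(baseline_beta_params, as.numeric),
         replicate_dispersion = as.numeric(replicate_dispersion),
         non_conversion_rate = as.numeric(non_conversion_rate),
         dmr_spec = dmr_spec),
    class = "SimulationConfig"
  )
}

# Catalogue every cytosine (both strands) of a character vector sequence.
scan_cytosines <- function(seq_chars, chrom) {
  L <- length(seq_chars)
  out <- list()
  for (str in c("+", "-")) {
    if (str == "+") {
      pos <- which(seq_chars == "C")
      b1 <- ifelse(pos + 1 <= L, seq_chars[pmin(pos + 1, L)], NA)
      b2 <- ifelse(pos + 2 <= L, seq_chars[pmin(pos + 2, L)], NA)
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      pos <- which(seq_chars == "G")
      b1 <- ifelse(pos - 1 >= 1, unname(comp[seq_chars[pmax(pos - 1, 1)]]), NA)
      b2 <- ifelse(pos - 2 >= 1, unname(comp[seq_chars[pmax(pos - 2, 1)]]), NA)
    }
    ctx <- ifelse(!is.na(b1) & b1 == "G", "CG",
           ifelse(is.na(b1) | is.na(b2), NA,
           ifelse(b2 == "G", "CHG", "CHH")))
    keep <- !is.na(ctx)
    out[[str]] <- data.frame(chrom = chrom, pos = pos[keep], strand = str,
                             context = ctx[keep], stringsAsFactors = FALSE)
  }
  res <- rbind(out[["+"]], out[["-"]])
  res[order(res$pos, res$strand), , drop = FALSE]
}

#' Generate a random reference genome and its cytosine catalogue
#'
#' @param config a [simulation_config()].
#' @return List with `reference` (a [Biostrings::DNAStringSet]), `sites`
#'   (data frame `chrom`, `pos`, `strand`, `context`), and `control_contig`
#'   (id or `NA`). Identical seeds give byte-identical output.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, 1L))
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  n_ctg <- config$n_contigs + as.integer(config$include_control_contig)
  lens <- c(rep(config$contig_length, config$n_contigs),
            if (config$include_control_contig) config$control_length)
  ids <- c(sprintf("contig%02d", seq_len(config$n_contigs)),
           if (config$include_control_contig) "ctrl")
  seqs <- character(n_ctg)
  sites <- vector("list", n_ctg)
  for (i in seq_len(n_ctg)) {
    chars <- sample(names(p), lens[i], replace = TRUE, prob = p)
    seqs[i] <- paste(chars, collapse = "")
    sites[[i]] <- scan_cytosines(chars, ids[i])
  }
  reference <- Biostrings::DNAStringSet(seqs)
  names(reference) <- ids
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  list(reference = reference, sites = sites,
       control_contig = if (config$include_control_contig) "ctrl" else NA)
}

#' Plant ground-truth DMRs into a site catalogue
#'
#' Chooses non-overlapping intervals on the nuclear contigs, each holding at
#' least `min_sites` cytosines of the chosen context, and assigns every
#' interval a direction (hyper/hypo), a dose class and the corresponding
#' signed methylation-ratio shifts at the two treated doses.  Default
#' effects: dose-independent regions shift by the same amount at both doses;
#' positive dose-dependent regions shift twice as much at dose 10 as at dose
#' 5; inverse dose-dependent regions the reverse.
#'
#' @param sites site catalogue from [generate_reference()].
#' @param n_per_class planted DMRs per dose class.
#' @param width_range interval width range in bp.
#' @param min_sites minimum cytosines of the planted context per interval.
#' @param effect_size magnitude of the larger dose shift.
#' @param contexts contexts to draw planted regions from.
#' @param seed RNG seed.
#' @return Data frame of class `PlantedDMR` columns: `dmr_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `context`, `direction`,
#'   `dose_class`, `effect_5`, `effect_10`, `n_sites`.
#' @export
plant_dmrs <- function(sites, n_per_class = 4L,
                       width_range = c(200L, 1000L), min_sites = 5L,
                       effect_size = 0.5,
                       contexts = c("CG", "CHG", "CHH"), seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  nuclear <- sites[sites$chrom != "ctrl", , drop = FALSE]
  classes <- rep(c("independent", "positive", "inverse"), each = n_per_class)
  n_total <- length(classes)
  out <- vector("list", n_total)
  taken <- list()  # per-chrom list of claimed intervals
  tries <- 0L
  i <- 1L
  while (i <= n_total && tries < 2000L) {
    tries <- tries + 1L
    chrom <- sample(unique(nuclear$chrom), 1L)
    ctx <- sample(contexts, 1L)
    w <- sample(seq(width_range[1], width_range[2]), 1L)
    cs <- nuclear[nuclear$chrom == chrom & nuclear$context == ctx, "pos"]
    if (length(cs) < min_sites) next
    anchor <- sample(cs, 1L)
    start0 <- max(0L, anchor - 1L - sample.int(w, 1L) + 1L)
    end0 <- start0 + w
    if (end0 > max(nuclear$pos[nuclear$chrom == chrom])) next
    n_in <- sum(cs > start0 & cs <= end0)
    if (n_in < min_sites) next
    clash <- FALSE
    for (iv in taken[[chrom]] %||% list())
      if (start0 < iv[2] && iv[1] < end0) { clash <- TRUE; break }
    if (clash) next
    taken[[chrom]] <- c(taken[[chrom]] %||% list(), list(c(start0, end0)))
    cls <- classes[i]
    dir <- sample(c("hyper", "hypo"), 1L)
    sgn <- if (dir == "hyper") 1 else -1
    eff <- switch(cls,
      independent = c(effect_size, effect_size),
      positive = c(effect_size / 2, effect_size),
      inverse = c(effect_size, effect_size / 2))
    out[[i]] <- data.frame(
      dmr_id = sprintf("planted_%02d", i), chrom = chrom,
      start = start0, end = end0, context = ctx, direction = dir,
      dose_class = cls, effect_5 = sgn * eff[1], effect_10 = sgn * eff[2],
      n_sites = n_in, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  if (i <= n_total)
    warning("placed only ", i - 1L, " of ", n_total, " planted DMRs")
  res <- if (i > 1L) do.call(rbind, out[seq_len(i - 1L)]) else
    data.frame(dmr_id = character(), chrom = character(), start = integer(),
               end = integer(), context = character(),
               direction = character(), dose_class = character(),
               effect_5 = numeric(), effect_10 = numeric(),
               n_sites = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("PlantedDMR", "data.frame")
  res
}

#' Simulate replicate count tables with a planted ground truth
#'
#' Per site a latent methylation level is drawn once from the context's beta
#' baseline (zero on the control contig), shifted inside planted DMRs of the
#' matching context by the dose-specific effect and clamped to \[0, 1\].
#' Coverage is negative binomial per site and replicate; the methylated
#' count is binomial at the latent level adjusted for bisulfite
#' non-conversion (`level + (1 - level) * non_conversion_rate`).
#'
#' @param ref output of [generate_reference()].
#' @param config a [simulation_config()]; its `dmr_spec` (if any) must lie
#'   within contig bounds and be non-overlapping.
#' @return List with `samples` (list of [sample_set()], one per
#'   dose x replicate, named `d<dose>_r<rep>`) and `truth` (the planted-DMR
#'   table, possibly empty).
#' @export
simulate_counts <- function(ref, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  sites <- ref$sites
  spec <- config$dmr_spec
  if (!is.null(spec) && nrow(spec)) {
    lens <- Biostrings::width(ref$reference)
    names(lens) <- names(ref$reference)
    if (any(spec$start < 0 | spec$end > lens[spec$chrom]))
      stop("planted DMR outside contig bounds")
    for (chr in unique(spec$chrom)) {
      iv <- spec[spec$chrom == chr, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
        stop("planted DMRs overlap on ", chr)
    }
  }
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(sites)
  is_ctrl <- sites$chrom == "ctrl"
  bb <- config$baseline_beta_params
  base <- numeric(n)
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(sites$context == ctx & !is_ctrl)
    base[idx] <- stats::rbeta(length(idx), bb[[ctx]][1], bb[[ctx]][2])
  }
  base[is_ctrl] <- 0
  # per-dose latent level after planted shifts
  level_at_dose <- function(dose) {
    lv <- base
    if (is.null(spec) || !nrow(spec) || dose == 0) return(lv)
    eff_col <- if (dose == 5) "effect_5" else if (dose == 10) "effect_10"
      else return(lv)
    for (j in seq_len(nrow(spec))) {
      idx <- which(sites$chrom == spec$chrom[j] &
                   sites$context == spec$context[j] &
                   sites$pos > spec$start[j] & sites$pos <= spec$end[j])
      lv[idx] <- pmin(1, pmax(0, lv[idx] + spec[[eff_col]][j]))
    }
    lv
  }
  samples <- list()
  for (dose in config$doses) {
    lv <- level_at_dose(dose)
    p_obs <- lv + (1 - lv) * config$non_conversion_rate
    for (rep_i in seq_len(config$n_replicates)) {
      cov <- stats::rnbinom(n, mu = config$mean_coverage,
                            size = config$coverage_dispersion)
      p_rep <- if (config$replicate_dispersion > 0) {
        nu <- config$replicate_dispersion
        a <- pmax(p_obs * nu, 1e-8); b <- pmax((1 - p_obs) * nu, 1e-8)
        stats::rbeta(n, a, b)
      } else p_obs
      m <- stats::rbinom(n, cov, p_rep)
      rec <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        strand = sites$strand, context = sites$context,
                        n_meth = m, n_unmeth = cov - m,
                        stringsAsFactors = FALSE)
      id <- sprintf("d%g_r%d", dose, rep_i)
      samples[[id]] <- sample_set(rec, id, dose = dose, replicate = rep_i)
    }
  }
  list(samples = samples,
       truth = spec %||% plant_dmrs(sites, n_per_class = 0L))
}

#' Write / read the planted-DMR truth table
#'
#' @param truth planted-DMR data frame ([plant_dmrs()]).
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("PlantedDMR", "data.frame")
  res
}

#' Simulate a gene / transposable-element annotation for the synthetic genome
#'
#' Places non-overlapping gene and TE features uniformly on the nuclear
#' contigs so that the annotation and enrichment stages can run end to end
#' on simulated data.  This is synthetic plumbing, not a model of real
#' genome architecture.
#'
#' @param ref output of [generate_reference()].
#' @param n_genes,n_tes feature counts.
#' @param width_range feature width range in bp.
#' @param seed RNG seed.
#' @return Feature data frame in the [read_features_gff()] layout.
#' @export
simulate_features <- function(ref, n_genes = 40L, n_tes = 20L,
                              width_range = c(500L, 2000L), seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  ids <- names(ref$reference)
  ids <- ids[ids != "ctrl"]
  lens <- Biostrings::width(ref$reference)[match(ids, names(ref$reference))]
  n <- n_genes + n_tes
  type <- c(rep("gene", n_genes), rep("transposable_element", n_tes))
  out <- vector("list", n)
  taken <- list()
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 5000L) {
    tries <- tries + 1L
    ci <- sample(length(ids), 1L)
    w <- sample(seq(width_range[1], width_range[2]), 1L)
    if (lens[ci] <= w) next
    start0 <- sample.int(lens[ci] - w, 1L) - 1L
    end0 <- start0 + w
    clash <- FALSE
    for (iv in taken[[ids[ci]]] %||% list())
      if (start0 < iv[2] && iv[1] < end0) { clash <- TRUE; break }
    if (clash) next
    taken[[ids[ci]]] <- c(taken[[ids[ci]]] %||% list(),
                          list(c(start0, end0)))
    placed <- placed + 1L
    out[[placed]] <- data.frame(
      id = sprintf("%s%03d", if (type[placed] == "gene") "GENE" else "TE",
                   placed),
      chrom = ids[ci], start = start0, end = end0,
      feature_type = type[placed], stringsAsFactors = FALSE)
  }
  if (placed < n)
    warning("placed only ", placed, " of ", n, " requested features")
  res <- do.call(rbind, out[seq_len(placed)])
  res[order(res$chrom, res$start), , drop = FALSE]
}
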