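# Shared fixture builders; everything is generated in code.

# Quick site-record frame.
rec_frame <- function(chrom, pos, strand = "+", context = "CG",
                      n_meth = 0L, n_unmeth = 0L) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_unmeth = as.integer(n_unmeth), stringsAsFactors = FALSE)
}

# A sample with constant coverage and given per-site methylated counts.
toy_sample <- function(id, m, cov = 10L, pos = seq_along(m) * 50L,
                       chrom = "chr1", context = "CG", dose = NA,
                       replicate = NA) {
  sample_set(rec_frame(chrom, pos, "+", context, m, cov - m),
             id, dose, replicate)
}

# Small simulated experiment shared across tests (memoised per seed/spec).
.sim_cache <- new.env(parent = emptyenv())
small_experiment <- function(seed = 1L, planted = TRUE,
                             n_contigs = 1L, contig_length = 6000L,
                             mean_coverage = 40, n_per_class = 2L) {
  key <- paste(seed, planted, n_contigs, contig_length, mean_coverage,
               n_per_class)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- simulation_config(seed = seed, n_contigs = n_contigs,
                           contig_length = contig_length,
                           mean_coverage = mean_coverage,
                           control_length = 2000L)
  ref <- generate_reference(cfg)
  if (planted)
    cfg$dmr_spec <- plant_dmrs(ref$sites, n_per_class = n_per_class,
                               seed = seed)
  sim <- simulate_counts(ref, cfg)
  doses <- vapply(sim$samples, `[[`, numeric(1), "dose")
  out <- list(cfg = cfg, ref = ref, sim = sim,
              g0 = sim$samples[doses == 0], g5 = sim$samples[doses == 5],
              g10 = sim$samples[doses == 10])
  .sim_cache[[key]] <- out
  out
}

# Planted-vs-called interval recall and FDR.
interval_recovery <- function(truth, called) {
  gr_t <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start + 1, truth$end))
  if (!nrow(called))
    return(c(recall = 0, fdr = 0))
  gr_c <- GenomicRanges::GRanges(called$chrom,
                                 IRanges::IRanges(called$start + 1,
                                                  called$end))
  c(recall = mean(GenomicRanges::countOverlaps(gr_t, gr_c) > 0),
    fdr = 1 - mean(GenomicRanges::countOverlaps(gr_c, gr_t) > 0))
}

# Full per-dose smoothing calls + reconciliation for one seed.
call_reconciled <- function(seed, params = smooth_params()) {
  ex <- small_experiment(seed, planted = TRUE, n_contigs = 2L,
                         contig_length = 20000L, mean_coverage = 60,
                         n_per_class = 4L)
  d5 <- call_dmrs_smooth(ex$g0, ex$g5, params)
  d10 <- call_dmrs_smooth(ex$g0, ex$g10, params)
  list(ex = ex, rec = reconcile_doses(d5, d10), d5 = d5, d10 = d10)
}
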