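dmc_row <- function(pos, direction = "hyper", diff = 40, chrom = "chr1",
                    context = "CG") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             context = context, ratio_control = 0.2, ratio_treated = 0.6,
             diff = ifelse(direction == "hyper", abs(diff), -abs(diff)),
             p = 1e-6, q = 1e-5, direction = direction,
             stringsAsFactors = FALSE)
}

test_that("distance merging joins same-direction runs and applies filters", {
  d <- do.call(rbind, lapply(c(100, 150, 200), dmc_row))
  out <- merge_dmrs(d, max_gap = 100, min_dmcs = 3)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(99, 200))
  expect_equal(out$n_sites, 3)
  expect_equal(out$context_label, "CG")

  far <- rbind(dmc_row(100), dmc_row(5000))
  expect_equal(nrow(merge_dmrs(far, 100, 3)), 0)

  alt <- rbind(dmc_row(100, "hyper"), dmc_row(110, "hypo"),
               dmc_row(120, "hyper"))
  expect_equal(nrow(merge_dmrs(alt, 100, 3)), 0)

  weak <- do.call(rbind, lapply(c(100, 150, 200), dmc_row, diff = 5))
  expect_equal(nrow(merge_dmrs(weak, 100, 3, min_mean_diff = 10)), 0)

  # modal context labelling
  mix <- rbind(dmc_row(100), dmc_row(150, context = "CHH"),
               dmc_row(200, context = "CHH"))
  expect_equal(merge_dmrs(mix, 100, 3)$context_label, "CHH")
})

test_that("auto gap finds the antimode of bimodal spacings or falls back", {
  set.seed(8)
  # clusters of DmCs ~15 bp apart separated by ~3000 bp
  starts <- seq(1000, by = 3000, length.out = 12)
  pos <- sort(unlist(lapply(starts, function(s)
    s + cumsum(sample(10:25, 5, replace = TRUE)))))
  d <- do.call(rbind, lapply(pos, dmc_row))
  out <- merge_dmrs(d, max_gap = "auto", min_dmcs = 3)
  expect_equal(nrow(out), 12)  # one region per cluster

  expect_warning(merge_dmrs(dmc_row(100), max_gap = "auto", min_dmcs = 1),
                 "gap 100")
})

test_that("smoothing preserves constants and respects monotone steps", {
  s <- toy_sample("c", m = rep(8L, 30), cov = 10L, pos = 1:30 * 20L)
  sm <- smooth_methylation(list(s), smooth_params())[[1]]
  expect_equal(sm$smoothed, rep(0.8, 30), tolerance = 1e-12)

  # step 0 -> 1: smoothed values are monotone over the step
  step <- toy_sample("st", m = c(rep(0L, 10), rep(10L, 10)), cov = 10L,
                     pos = 1:20 * 30L)
  sm2 <- smooth_methylation(list(step),
                            smooth_params(bandwidth_bp = 100))[[1]]
  expect_true(all(diff(sm2$smoothed) >= -1e-9))
  expect_lt(sm2$smoothed[1], 0.2)
  expect_gt(sm2$smoothed[20], 0.8)

  # window widening reaches the configured minimum site count
  sparse <- toy_sample("sp", m = c(0L, 10L, 0L, 10L, 0L, 10L), cov = 10L,
                       pos = c(10L, 2000L, 4000L, 6000L, 8000L, 10000L))
  sm3 <- smooth_methylation(list(sparse),
                            smooth_params(bandwidth_bp = 50,
                                          min_sites_in_window = 3))[[1]]
  expect_false(any(is.na(sm3$smoothed)))
  expect_false(all(sm3$smoothed %in% c(0, 1)))  # neighbours were pulled in
})

test_that("t-statistic regions require consistent sign, size and areaStat", {
  ex <- small_experiment(1, planted = TRUE, n_contigs = 2L,
                         contig_length = 20000L, mean_coverage = 60,
                         n_per_class = 4L)
  p <- smooth_params()
  sm0 <- smooth_methylation(ex$g0, p)
  # identical groups: all t = 0, no regions
  expect_equal(nrow(tstat_regions(sm0[1:2], sm0[1:2], p)), 0)

  sm10 <- smooth_methylation(ex$g10, p)
  out <- tstat_regions(sm0, sm10, p)
  expect_true(all(out$n_sites >= p$min_sites_per_dmr))
  expect_true(all(abs(out$area_stat) >= p$area_stat_min))
  expect_equal(out$direction, ifelse(out$area_stat > 0, "hyper", "hypo"))
  expect_true(all(out$end > out$start))

  # label swap negates areaStat and flips direction
  swapped <- tstat_regions(sm10, sm0, p)
  expect_equal(nrow(swapped), nrow(out))
  m <- match(paste(out$chrom, out$start), paste(swapped$chrom, swapped$start))
  expect_equal(swapped$area_stat[m], -out$area_stat, tolerance = 1e-9)
  expect_equal(swapped$direction[m],
               ifelse(out$direction == "hyper", "hypo", "hyper"))

  # intervals from one call never overlap each other
  gr <- GenomicRanges::GRanges(paste(out$chrom, out$context_label),
                               IRanges::IRanges(out$start + 1, out$end))
  expect_equal(max(GenomicRanges::countOverlaps(gr, gr)), 1)
})

test_that("dose reconciliation unions, separates and excludes conflicts", {
  mk <- function(start, end, dir, chrom = "chr1") {
    data.frame(chrom = chrom, start = start, end = end, n_sites = 5L,
               context_label = "CG", direction = dir, mean_diff = 30,
               area_stat = 15, source = "smooth", dose_group = NA,
               stringsAsFactors = FALSE)
  }
  # conflicting overlap: both excluded
  rec <- reconcile_doses(mk(100, 200, "hyper"), mk(150, 250, "hypo"))
  expect_equal(nrow(rec$shared), 0)
  expect_equal(nrow(rec$unique_5), 0)
  expect_equal(nrow(rec$unique_10), 0)
  expect_equal(nrow(rec$excluded_conflicts), 2)

  # same-direction overlap: interval union
  rec2 <- reconcile_doses(mk(100, 200, "hyper"), mk(150, 250, "hyper"))
  expect_equal(nrow(rec2$shared), 1)
  expect_equal(c(rec2$shared$start, rec2$shared$end), c(100, 250))
  expect_equal(rec2$shared$dose_group, "both")

  # disjoint: unique to each dose
  rec3 <- reconcile_doses(mk(100, 200, "hyper"), mk(1000, 1100, "hyper"))
  expect_equal(nrow(rec3$unique_5), 1)
  expect_equal(nrow(rec3$unique_10), 1)
  expect_equal(rec3$unique_5$dose_group, "5")
  expect_equal(rec3$unique_10$dose_group, "10")
})

test_that("caller intersection keeps same-direction overlapping regions", {
  mk <- function(start, end, dir, src) {
    data.frame(chrom = "chr1", start = start, end = end, n_sites = 4L,
               context_label = "CG", direction = dir, mean_diff = 30,
               area_stat = if (src == "smooth") 12 else NA, source = src,
               dose_group = NA, stringsAsFactors = FALSE)
  }
  m <- mk(100, 200, "hyper", "merge")
  s <- mk(150, 260, "hyper", "smooth")
  out <- intersect_callers(m, s)
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "both")

  expect_equal(nrow(intersect_callers(m, mk(1000, 1100, "hyper", "smooth"))),
               0)
  expect_equal(nrow(intersect_callers(m, mk(150, 260, "hypo", "smooth"))), 0)
})

test_that("replicate subsampling enumerates combinations and orders cutoffs", {
  ex <- small_experiment(2, planted = TRUE, n_contigs = 1L,
                         contig_length = 10000L, mean_coverage = 40,
                         n_per_class = 2L)
  lenient <- replicate_stability(ex$g0, ex$g10,
                                 smooth_params(t_cutoff_quantile = 0.1),
                                 k_values = c(2, 4))
  expect_equal(lenient$summary$n_combos[lenient$summary$k == 2], 36)
  expect_equal(lenient$summary$n_combos[lenient$summary$k == 4], 1)

  stringent <- replicate_stability(ex$g0, ex$g10,
                                   smooth_params(t_cutoff_quantile = 0.01),
                                   k_values = 2)
  expect_gte(lenient$summary$mean_dmrs[lenient$summary$k == 2],
             stringent$summary$mean_dmrs[stringent$summary$k == 2])

  expect_error(replicate_stability(ex$g0, ex$g10, k_values = 5), "exceeds")
})
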