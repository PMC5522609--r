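test_that("reference generation is seed-deterministic and scan-consistent", {
  cfg <- simulation_config(seed = 5, n_contigs = 1, contig_length = 5000)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  expect_identical(r1$sites, r2$sites)

  # site catalogue equals an oracle character scan
  chars <- strsplit(as.character(r1$reference[["contig01"]]), "")[[1]]
  n_c <- sum(chars[-length(chars)] == "C")  # last-base C has no context
  n_g <- sum(chars[-1] == "G")
  got <- r1$sites[r1$sites$chrom == "contig01", ]
  # plus-strand catalogued sites are the Cs with a defined context
  expect_lte(abs(sum(got$strand == "+") - n_c), 1)
  expect_lte(abs(sum(got$strand == "-") - n_g), 1)
  ctx_oracle <- vapply(got$pos[got$strand == "+"], function(p) {
    if (chars[p + 1] == "G") "CG"
    else if (chars[p + 2] == "G") "CHG" else "CHH"
  }, character(1))
  expect_equal(got$context[got$strand == "+"], ctx_oracle)

  cfg2 <- simulation_config(seed = 5, n_contigs = 1, contig_length = 5000,
                            include_control_contig = FALSE)
  r3 <- generate_reference(cfg2)
  expect_false("ctrl" %in% r3$sites$chrom)
})

test_that("simulated counts track the latent levels", {
  ex <- small_experiment(3, planted = TRUE, n_contigs = 2L,
                         contig_length = 20000L, mean_coverage = 60,
                         n_per_class = 4L)
  truth <- ex$sim$truth
  sites <- ex$ref$sites

  # control contig is unmethylated up to non-conversion
  ctrl_rec <- ex$g0[[1]]$records
  ctrl_rec <- ctrl_rec[ctrl_rec$chrom == "ctrl", ]
  rate <- sum(ctrl_rec$n_meth) / sum(ctrl_rec$n_meth + ctrl_rec$n_unmeth)
  expect_lt(abs(rate - ex$cfg$non_conversion_rate), 0.002)

  # per-context mean methylation matches the beta-baseline mean at dose 0
  for (ctx in c("CG", "CHG", "CHH")) {
    ab <- ex$cfg$baseline_beta_params[[ctx]]
    expected <- ab[1] / sum(ab)
    r <- do.call(rbind, lapply(ex$g0, function(s) {
      rr <- s$records[s$records$context == ctx & s$records$chrom != "ctrl", ]
      c(sum(rr$n_meth), sum(rr$n_meth + rr$n_unmeth))
    }))
    got <- sum(r[, 1]) / sum(r[, 2])
    expect_lt(abs(got - expected -
                    (1 - expected) * ex$cfg$non_conversion_rate), 0.02)
  }

  # inside every planted region the realised dose-10 shift has the planted
  # sign and is bounded by the nominal effect (clamping only shrinks it)
  region_mean <- function(samples, pd) {
    r <- do.call(rbind, lapply(samples, function(s) {
      rr <- s$records
      rr <- rr[rr$chrom == pd$chrom & rr$context == pd$context &
                 rr$pos > pd$start & rr$pos <= pd$end, ]
      c(sum(rr$n_meth), sum(rr$n_meth + rr$n_unmeth))
    }))
    sum(r[, 1]) / sum(r[, 2])
  }
  for (i in seq_len(nrow(truth))) {
    pd <- truth[i, ]
    shift <- region_mean(ex$g10, pd) - region_mean(ex$g0, pd)
    expect_equal(sign(shift), sign(pd$effect_10))
    expect_lt(abs(shift), abs(pd$effect_10) + 0.1)
  }
})

test_that("a planted shift on a concentrated baseline matches the binomial mean", {
  # baseline beta(20, 80): mean 0.2, sd 0.04, so a +0.5 hyper effect is
  # essentially unclamped and the dose-10 region mean must be ~0.7
  cfg <- simulation_config(seed = 12, n_contigs = 1L, contig_length = 4000L,
                           include_control_contig = FALSE,
                           baseline_beta_params = list(CG = c(20, 80),
                                                       CHG = c(20, 80),
                                                       CHH = c(20, 80)),
                           non_conversion_rate = 0)
  ref <- generate_reference(cfg)
  cfg$dmr_spec <- data.frame(
    dmr_id = "p1", chrom = "contig01", start = 500L, end = 1500L,
    context = "CHH", direction = "hyper", dose_class = "independent",
    effect_5 = 0.5, effect_10 = 0.5, n_sites = 10L, stringsAsFactors = FALSE)
  sim <- simulate_counts(ref, cfg)
  doses <- vapply(sim$samples, `[[`, numeric(1), "dose")
  pooled <- function(samples) {
    r <- do.call(rbind, lapply(samples, function(s) {
      rr <- s$records
      rr <- rr[rr$context == "CHH" & rr$pos > 500 & rr$pos <= 1500, ]
      c(sum(rr$n_meth), sum(rr$n_meth + rr$n_unmeth))
    }))
    sum(r[, 1]) / sum(r[, 2])
  }
  expect_equal(pooled(sim$samples[doses == 0]), 0.2, tolerance = 0.05)
  expect_equal(pooled(sim$samples[doses == 10]), 0.7, tolerance = 0.05)
})

test_that("planted truth obeys its class constraints and round-trips", {
  ex <- small_experiment(2, planted = TRUE, n_per_class = 3L)
  truth <- ex$sim$truth
  expect_equal(as.integer(table(truth$dose_class)[c("independent", "inverse",
                                                    "positive")]),
               rep(3L, 3))
  pos <- truth[truth$dose_class == "positive", ]
  expect_true(all(abs(pos$effect_10) > abs(pos$effect_5)))
  inv <- truth[truth$dose_class == "inverse", ]
  expect_true(all(abs(inv$effect_5) > abs(inv$effect_10)))
  ind <- truth[truth$dose_class == "independent", ]
  expect_true(all(ind$effect_5 == ind$effect_10 & ind$effect_5 != 0))
  expect_true(all(truth$n_sites >= 5))

  f <- tempfile(fileext = ".tsv")
  write_truth_table(truth, f)
  back <- read_truth_table(f)
  expect_equal(as.data.frame(back), as.data.frame(truth))
})

test_that("whole-module output is byte-identical under one seed", {
  a <- small_experiment(7, planted = TRUE)
  .sim_cache <- new.env()  # bypass helper memoisation
  cfg <- simulation_config(seed = 7, n_contigs = 1L, contig_length = 6000L,
                           mean_coverage = 40, control_length = 2000L)
  ref <- generate_reference(cfg)
  cfg$dmr_spec <- plant_dmrs(ref$sites, n_per_class = 2L, seed = 7)
  sim <- simulate_counts(ref, cfg)
  expect_identical(sim$truth, a$sim$truth)
  expect_identical(lapply(sim$samples, `[[`, "records"),
                   lapply(a$sim$samples, `[[`, "records"))
})

test_that("overlapping planted regions are rejected", {
  ex <- small_experiment(1, planted = FALSE)
  cfg <- ex$cfg
  cfg$dmr_spec <- data.frame(
    dmr_id = c("a", "b"), chrom = "contig01", start = c(100L, 300L),
    end = c(400L, 600L), context = "CHH", direction = "hyper",
    dose_class = "independent", effect_5 = 0.3, effect_10 = 0.3,
    n_sites = 5L, stringsAsFactors = FALSE)
  expect_error(simulate_counts(ex$ref, cfg), "overlap")
})

test_that("synthetic features are placed without overlap on nuclear contigs", {
  ex <- small_experiment(1, planted = FALSE)
  feats <- simulate_features(ex$ref, n_genes = 6, n_tes = 3, seed = 3,
                             width_range = c(200L, 500L))
  expect_equal(sum(feats$feature_type == "gene"), 6)
  expect_false("ctrl" %in% feats$chrom)
  for (chr in unique(feats$chrom)) {
    f <- feats[feats$chrom == chr, ]
    f <- f[order(f$start), ]
    if (nrow(f) > 1) expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  }
})
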