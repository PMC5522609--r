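#' Parameters for the smoothing-based DMR caller
#'
#' @param bandwidth_bp half-width of the smoothing window in bp.
#' @param min_sites_in_window minimum sites per smoothing window; windows are
#'   widened symmetrically until this is met.
#' @param t_cutoff_quantile q: per-site t-statistic cutoffs are the empirical
#'   q and 1-q quantiles of all smoothed t values (0 < q < 0.5).
#' @param area_stat_min minimum `|sum of member t|` for a region to be kept.
#' @param min_sites_per_dmr minimum member sites per region.
#' @return A list of class `SmoothParams`.
#' @export
smooth_params <- function(bandwidth_bp = 100, min_sites_in_window = 5,
                          t_cutoff_quantile = 0.015, area_stat_min = 10,
                          min_sites_per_dmr = 3) {
  stopifnot(bandwidth_bp > 0, t_cutoff_quantile > 0, t_cutoff_quantile < 0.5)
  structure(list(bandwidth_bp = as.numeric(bandwidth_bp),
                 min_sites_in_window = as.integer(min_sites_in_window),
                 t_cutoff_quantile = as.numeric(t_cutoff_quantile),
                 area_stat_min = as.numeric(area_stat_min),
                 min_sites_per_dmr = as.integer(min_sites_per_dmr)),
            class = "SmoothParams")
}

#' Merge consecutive same-direction DmCs into regions
#'
#' The merging caller joins consecutive DmCs of the same direction whose
#' inter-site distance is at most `max_gap` into one region, then drops
#' regions with fewer than `min_dmcs` sites or mean absolute difference
#' below `min_mean_diff` percent.  With `max_gap = "auto"` the gap is the
#' antimode of a two-component Gaussian mixture fitted to the log10
#' inter-DmC distances (within-region vs between-region spacings); with
#' fewer than two distances this falls back to 100 bp with a warning.
#'
#' @param dmcs DmC table from [call_dmcs()].
#' @param max_gap maximum inter-site distance in bp, or `"auto"`.
#' @param min_dmcs minimum member DmCs per region.
#' @param min_mean_diff minimum `|mean diff|` in percent.
#' @return DMR data frame (0-based half-open intervals, `source = "merge"`).
#' @export
merge_dmrs <- function(dmcs, max_gap = 100, min_dmcs = 3,
                       min_mean_diff = 10) {
  if (identical(max_gap, "auto")) max_gap <- auto_gap(dmcs)
  stopifnot(is.numeric(max_gap), max_gap > 0)
  if (!nrow(dmcs)) return(empty_dmr_frame())
  dmcs <- dmcs[order(dmcs$chrom, dmcs$pos), , drop = FALSE]
  out <- list()
  for (chr in unique(dmcs$chrom)) {
    d <- dmcs[dmcs$chrom == chr, , drop = FALSE]
    gap_break <- c(TRUE, diff(d$pos) > max_gap)
    dir_break <- c(TRUE, d$direction[-1] != d$direction[-nrow(d)])
    run <- cumsum(gap_break | dir_break)
    for (g in split(seq_len(nrow(d)), run)) {
      if (length(g) < min_dmcs) next
      md <- mean(d$diff[g])
      if (abs(md) < min_mean_diff) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(d$pos[g]) - 1L, end = max(d$pos[g]),
        n_sites = length(g),
        context_label = modal_context(d$context[g]),
        direction = d$direction[g[1]], mean_diff = md,
        area_stat = NA_real_, source = "merge", dose_group = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_dmr_frame())
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

modal_context <- function(ctx) {
  tab <- sort(table(ctx), decreasing = TRUE)
  names(tab)[1]
}

# Antimode of a 2-component Gaussian mixture on log10 inter-DmC distances.
auto_gap <- function(dmcs, fallback = 100) {
  dists <- unlist(lapply(split(dmcs$pos, dmcs$chrom),
                         function(p) diff(sort(p))))
  dists <- dists[dists > 0]
  if (length(dists) < 2) {
    warning("too few inter-DmC distances for the mixture fit; using gap ",
            fallback)
    return(fallback)
  }
  x <- log10(dists)
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || length(unique(fit$parameters$mean)) < 2) {
    warning("mixture fit failed or degenerate; using gap ", fallback)
    return(fallback)
  }
  mu <- sort(fit$parameters$mean)
  dens <- function(v) {
    p <- fit$parameters
    sum(p$pro * stats::dnorm(v, p$mean, sqrt(p$variance$sigmasq)))
  }
  opt <- stats::optimize(function(v) dens(v), interval = mu)
  10^opt$minimum
}

#' Kernel-smooth per-site methylation levels
#'
#' For each sample, context and contig, every site's smoothed level is a
#' tricube-kernel weighted binomial mean of the raw ratios of sites within
#' `bandwidth_bp`, the kernel weights multiplied by coverage (so deeply
#' covered neighbours count more).  Windows holding fewer than
#' `min_sites_in_window` sites are widened symmetrically (by nearest sites)
#' until the minimum is met.  Contigs with fewer sites of a context than the
#' window minimum are skipped for that context.
#'
#' @param samples list of [sample_set()] (one group or all samples).
#' @param params a [smooth_params()].
#' @return List (per sample) of data frames `chrom`, `pos`, `strand`,
#'   `context`, `cov`, `smoothed`.
#' @export
smooth_methylation <- function(samples, params = smooth_params()) {
  stopifnot(inherits(params, "SmoothParams"))
  lapply(samples, function(s) {
    r <- s$records
    out <- r[, c("chrom", "pos", "strand", "context")]
    out$cov <- r$n_meth + r$n_unmeth
    out$smoothed <- NA_real_
    for (chr in unique(r$chrom)) {
      for (ctx in intersect(c("CG", "CHG", "CHH"), unique(r$context))) {
        idx <- which(r$chrom == chr & r$context == ctx)
        if (length(idx) < params$min_sites_in_window) next
        o <- idx[order(r$pos[idx])]
        out$smoothed[o] <- smooth_one_track(
          r$pos[o], r$n_meth[o], r$n_meth[o] + r$n_unmeth[o], params)
      }
    }
    out
  })
}

# Core smoother on one sorted track; returns smoothed levels.
smooth_one_track <- function(pos, m, cov, params) {
  n <- length(pos)
  h <- params$bandwidth_bp
  mns <- params$min_sites_in_window
  lo <- findInterval(pos - h, pos) + 1L  # first index with pos >= pos-h
  # findInterval gives rightmost index <= value; +1 overshoots when equal
  lo <- pmax(1L, ifelse(lo > 1L & pos[pmax(lo - 1L, 1L)] >= pos - h,
                        lo - 1L, lo))
  hi <- findInterval(pos + h, pos)
  res <- numeric(n)
  for (i in seq_len(n)) {
    a <- lo[i]; b <- hi[i]
    # widen symmetrically by nearest neighbour until the window holds enough
    while (b - a + 1L < mns && (a > 1L || b < n)) {
      d_left <- if (a > 1L) pos[i] - pos[a - 1L] else Inf
      d_right <- if (b < n) pos[b + 1L] - pos[i] else Inf
      if (d_left <= d_right) a <- a - 1L else b <- b + 1L
    }
    j <- a:b
    d <- abs(pos[j] - pos[i])
    h_eff <- max(h, max(d) + 1)
    w <- (1 - (d / h_eff)^3)^3 * cov[j]
    denom <- sum(w)
    res[i] <- if (denom > 0) sum(w * m[j] / pmax(cov[j], 1)) / denom
      else if (cov[i] > 0) m[i] / cov[i] else NA_real_
  }
  res
}

#' Smoothed t-statistic DMR caller
#'
#' Per shared site, `t = (mean_treated - mean_control) / pooled SE` across
#' the replicate smoothed values (pooled-variance two-sample form; zero
#' pooled variance gives t = 0).  Cutoffs are the empirical
#' `t_cutoff_quantile` and `1 - t_cutoff_quantile` quantiles of all t
#' values; candidate regions are maximal runs of consecutive same-sign
#' beyond-cutoff sites, kept when they hold at least `min_sites_per_dmr`
#' sites and `|areaStat| = |sum of member t|` reaches `area_stat_min`.
#'
#' @param smoothed_control,smoothed_treated outputs of
#'   [smooth_methylation()] for the two groups (>= 2 replicates each).
#' @param params a [smooth_params()].
#' @return DMR data frame (`source = "smooth"`, `area_stat` filled).
#' @export
tstat_regions <- function(smoothed_control, smoothed_treated,
                          params = smooth_params()) {
  stopifnot(length(smoothed_control) >= 2, length(smoothed_treated) >= 2)
  key_of <- function(df) paste(df$chrom, df$pos, df$strand, sep = "\r")
  keys <- lapply(c(smoothed_control, smoothed_treated), key_of)
  shared <- Reduce(intersect, keys)
  ref <- smoothed_control[[1]]
  ref <- ref[match(shared, key_of(ref)), c("chrom", "pos", "strand",
                                           "context")]
  vals <- function(group) vapply(group, function(df) {
    df$smoothed[match(shared, key_of(df))]
  }, numeric(length(shared)))
  mc <- vals(smoothed_control)
  mt <- vals(smoothed_treated)
  ok <- stats::complete.cases(mc) & stats::complete.cases(mt)
  ref <- ref[ok, , drop = FALSE]; mc <- mc[ok, , drop = FALSE]
  mt <- mt[ok, , drop = FALSE]
  if (!nrow(ref)) return(empty_dmr_frame())
  n1 <- ncol(mc); n2 <- ncol(mt)
  mean_c <- rowMeans(mc); mean_t <- rowMeans(mt)
  v1 <- apply(mc, 1, stats::var); v2 <- apply(mt, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (mean_t - mean_c) / se, 0)
  cuts <- stats::quantile(t, c(params$t_cutoff_quantile,
                               1 - params$t_cutoff_quantile), names = FALSE)
  state <- ifelse(t <= cuts[1], -1L, ifelse(t >= cuts[2], 1L, 0L))
  out <- list()
  for (chr in unique(ref$chrom)) {
    for (ctx in unique(ref$context)) {
      idx <- which(ref$chrom == chr & ref$context == ctx)
      if (!length(idx)) next
      idx <- idx[order(ref$pos[idx])]
      st <- state[idx]
      run <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
      for (g in split(seq_along(idx), run)) {
        if (st[g[1]] == 0L || length(g) < params$min_sites_per_dmr) next
        ii <- idx[g]
        area <- sum(t[ii])
        if (abs(area) < params$area_stat_min) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = min(ref$pos[ii]) - 1L, end = max(ref$pos[ii]),
          n_sites = length(ii), context_label = ctx,
          direction = if (st[g[1]] > 0) "hyper" else "hypo",
          mean_diff = mean(mean_t[ii] - mean_c[ii]) * 100,
          area_stat = area, source = "smooth", dose_group = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_dmr_frame())
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Convenience smoothing caller on raw samples
#'
#' Smooths both groups with [smooth_methylation()] and calls regions with
#' [tstat_regions()].
#'
#' @inheritParams tstat_regions
#' @param control,treated lists of [sample_set()].
#' @return DMR data frame.
#' @export
call_dmrs_smooth <- function(control, treated, params = smooth_params()) {
  tstat_regions(smooth_methylation(control, params),
                smooth_methylation(treated, params), params)
}

#' Reconcile DMR calls from two doses
#'
#' Regions from the two treated doses are compared by >= 1 bp overlap.
#' Overlapping pairs of opposite direction are direction conflicts and both
#' members are excluded entirely; overlapping same-direction regions are
#' united (interval union) into shared regions (`dose_group = "both"`);
#' the rest are unique to their dose.
#'
#' @param dmrs_5,dmrs_10 DMR data frames from the same caller.
#' @return List with `unique_5`, `unique_10`, `shared`,
#'   `excluded_conflicts`.
#' @export
reconcile_doses <- function(dmrs_5, dmrs_10) {
  d5 <- dmrs_5; d10 <- dmrs_10
  d5$dose_group <- "5"; d10$dose_group <- "10"
  if (!nrow(d5) || !nrow(d10)) {
    return(list(unique_5 = d5, unique_10 = d10,
                shared = empty_dmr_frame(),
                excluded_conflicts = empty_dmr_frame()))
  }
  hits <- GenomicRanges::findOverlaps(dmr_granges(d5), dmr_granges(d10))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  conflict <- d5$direction[q] != d10$direction[s]
  excl5 <- unique(q[conflict]); excl10 <- unique(s[conflict])
  same <- !conflict & !(q %in% excl5) & !(s %in% excl10)
  # union-find over the bipartite same-direction overlap graph
  comp5 <- seq_len(nrow(d5)); parent <- seq_len(nrow(d5) + nrow(d10))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in which(same)) {
    a <- find(q[k]); b <- find(nrow(d5) + s[k])
    if (a != b) parent[b] <- a
  }
  in_shared5 <- unique(q[same]); in_shared10 <- unique(s[same])
  shared <- list()
  if (any(same)) {
    comp_id <- vapply(c(q[same], nrow(d5) + s[same]), find, integer(1))
    members <- split(c(q[same], nrow(d5) + s[same]), comp_id)
    for (mm in members) {
      mm <- unique(mm)
      i5 <- mm[mm <= nrow(d5)]; i10 <- mm[mm > nrow(d5)] - nrow(d5)
      rows <- rbind(d5[i5, , drop = FALSE], d10[i10, , drop = FALSE])
      shared[[length(shared) + 1L]] <- data.frame(
        chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end),
        n_sites = sum(rows$n_sites),
        context_label = modal_context(rep(rows$context_label, rows$n_sites)),
        direction = rows$direction[1],
        mean_diff = stats::weighted.mean(rows$mean_diff, rows$n_sites),
        area_stat = if (all(is.na(rows$area_stat))) NA_real_
          else sum(rows$area_stat, na.rm = TRUE),
        source = rows$source[1], dose_group = "both",
        stringsAsFactors = FALSE)
    }
  }
  shared <- if (length(shared)) do.call(rbind, shared) else empty_dmr_frame()
  shared <- shared[order(shared$chrom, shared$start), , drop = FALSE]
  list(
    unique_5 = d5[setdiff(seq_len(nrow(d5)), c(excl5, in_shared5)), ,
                  drop = FALSE],
    unique_10 = d10[setdiff(seq_len(nrow(d10)), c(excl10, in_shared10)), ,
                    drop = FALSE],
    shared = shared,
    excluded_conflicts = rbind(d5[excl5, , drop = FALSE],
                               d10[excl10, , drop = FALSE])
  )
}

#' High-confidence DMRs supported by both callers
#'
#' Smoothing-caller regions that overlap (>= 1 bp) a merging-caller region
#' of the same direction, flagged `source = "both"`.
#'
#' @param merged DMR data frame from [merge_dmrs()].
#' @param smoothed DMR data frame from [tstat_regions()].
#' @return Subset of `smoothed` with `source = "both"`.
#' @export
intersect_callers <- function(merged, smoothed) {
  if (!nrow(merged) || !nrow(smoothed)) return(empty_dmr_frame())
  hits <- GenomicRanges::findOverlaps(dmr_granges(smoothed),
                                      dmr_granges(merged))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- unique(q[smoothed$direction[q] == merged$direction[s]])
  res <- smoothed[sort(keep), , drop = FALSE]
  if (nrow(res)) res$source <- "both"
  res
}

#' DMR-count stability under replicate subsampling
#'
#' Runs a caller on every pair of k-replicate subsets of the control and
#' treated groups (for k = 2: C(4,2)^2 = 36 combinations; k = 3: 16;
#' k = 4: 1) and reports the DMR count per combination, mirroring the
#' stringency analysis in which fewer replicates inflate lenient-parameter
#' calls.  For the smoothing caller each sample is smoothed once and reused
#' across combinations.
#'
#' @param control,treated lists of [sample_set()] (all replicates).
#' @param params caller parameters: [smooth_params()] for
#'   `caller = "smooth"`, [dmc_params()] for `caller = "merge"`.
#' @param k_values replicate subset sizes.
#' @param caller `"smooth"` or `"merge"`.
#' @param max_gap,min_dmcs,min_mean_diff merging-caller settings (ignored
#'   for the smoothing caller).
#' @return List with `counts` (data frame `k`, `combo`, `n_dmrs`) and
#'   `summary` (mean and sd of counts per k).
#' @export
replicate_stability <- function(control, treated, params = smooth_params(),
                                k_values = c(2, 3, 4),
                                caller = c("smooth", "merge"),
                                max_gap = 100, min_dmcs = 3,
                                min_mean_diff = 10) {
  caller <- match.arg(caller)
  nc <- length(control); nt <- length(treated)
  if (any(k_values > min(nc, nt)))
    stop("k exceeds the number of available replicates")
  if (caller == "smooth") {
    sm_c <- smooth_methylation(control, params)
    sm_t <- smooth_methylation(treated, params)
  }
  rows <- list()
  for (k in k_values) {
    cc <- utils::combn(nc, k, simplify = FALSE)
    ct <- utils::combn(nt, k, simplify = FALSE)
    combo <- 0L
    for (a in cc) for (b in ct) {
      combo <- combo + 1L
      n <- if (caller == "smooth") {
        if (k < 2) stop("smoothing caller needs k >= 2")
        nrow(tstat_regions(sm_c[a], sm_t[b], params))
      } else {
        dmcs <- call_dmcs(control[a], treated[b], params)
        nrow(merge_dmrs(dmcs, max_gap, min_dmcs, min_mean_diff))
      }
      rows[[length(rows) + 1L]] <- data.frame(k = k, combo = combo,
                                              n_dmrs = n)
    }
  }
  counts <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(counts, counts$k), function(d) {
    data.frame(k = d$k[1], n_combos = nrow(d), mean_dmrs = mean(d$n_dmrs),
               sd_dmrs = stats::sd(d$n_dmrs))
  }))
  rownames(summary) <- NULL
  list(counts = counts, summary = summary)
}
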