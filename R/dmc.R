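#' Parameters for differential cytosine calling
#'
#' @param min_diff minimum absolute percent methylation difference between
#'   groups for a site to be retained (default 25).
#' @param q_cutoff q-value threshold (default 0.01).
#' @param min_coverage minimum pooled coverage per group at a site for it to
#'   be tested (default 4).
#' @param top_confidence_fraction fraction of passing sites kept after
#'   ranking by confidence (default 0.25, i.e. the top quartile).
#' @param normalize scale replicate coverages to a common median before
#'   pooling (default TRUE).
#' @return A list of class `DmcCallParams`.
#' @export
dmc_params <- function(min_diff = 25, q_cutoff = 0.01, min_coverage = 4,
                       top_confidence_fraction = 0.25, normalize = TRUE) {
  stopifnot(top_confidence_fraction > 0, top_confidence_fraction <= 1,
            min_coverage >= 0, q_cutoff > 0)
  structure(list(min_diff = as.numeric(min_diff),
                 q_cutoff = as.numeric(q_cutoff),
                 min_coverage = as.numeric(min_coverage),
                 top_confidence_fraction = as.numeric(top_confidence_fraction),
                 normalize = normalize),
            class = "DmcCallParams")
}

#' Normalize replicate coverage to a common median
#'
#' Each sample's counts are scaled by (median of all samples' median
#' coverages) / (its own median coverage) and rounded half-up, which
#' preserves each site's methylation ratio to within rounding.
#'
#' @param samples list of [sample_set()].
#' @return List of rescaled `SampleSet`s.
#' @export
normalize_coverage <- function(samples) {
  stopifnot(length(samples) >= 1)
  meds <- vapply(samples, function(s) {
    cov <- s$records$n_meth + s$records$n_unmeth
    stats::median(cov[cov > 0])
  }, numeric(1))
  if (any(is.na(meds) | meds == 0))
    stop("sample(s) with zero median coverage: ",
         paste(names(samples)[is.na(meds) | meds == 0], collapse = ", "))
  target <- stats::median(meds)
  lapply(samples, function(s) {
    f <- target / stats::median({
      cov <- s$records$n_meth + s$records$n_unmeth
      cov[cov > 0]
    })
    r <- s$records
    r$n_meth <- as.integer(round_half_up(r$n_meth * f))
    r$n_unmeth <- as.integer(round_half_up(r$n_unmeth * f))
    sample_set(r, s$sample_id, s$dose, s$replicate)
  })
}

#' Two-sided Fisher's exact test for one or many 2x2 methylation tables
#'
#' Exact two-sided p-value for the table
#' \\{(meth_c, unmeth_c), (meth_t, unmeth_t)\\}: with margins fixed, the
#' probabilities of all tables whose point (hypergeometric) probability does
#' not exceed the observed one are summed.  Vectorised over sites.
#'
#' @param meth_c,unmeth_c,meth_t,unmeth_t non-negative integer counts
#'   (recycled to common length).
#' @return Numeric vector of p-values; `NA` where a margin is empty.
#' @export
fisher_site_test <- function(meth_c, unmeth_c, meth_t, unmeth_t) {
  n <- max(length(meth_c), length(unmeth_c), length(meth_t),
           length(unmeth_t))
  mc <- rep_len(as.numeric(meth_c), n); uc <- rep_len(as.numeric(unmeth_c), n)
  mt <- rep_len(as.numeric(meth_t), n); ut <- rep_len(as.numeric(unmeth_t), n)
  if (any(c(mc, uc, mt, ut) < 0, na.rm = TRUE)) stop("negative counts")
  vapply(seq_len(n), function(i) {
    n1 <- mc[i] + uc[i]; n2 <- mt[i] + ut[i]; K <- mc[i] + mt[i]
    if (is.na(n1) || is.na(n2) || n1 == 0 || n2 == 0 ||
        K == 0 && (uc[i] + ut[i]) == 0) return(NA_real_)
    support <- max(0, K - n2):min(K, n1)
    d <- stats::dhyper(support, n1, n2, K)
    d0 <- stats::dhyper(mc[i], n1, n2, K)
    min(1, sum(d[d <= d0 * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Step-up adjusted q-values (monotone in p-value rank).
#' @export
adjust_q <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

# Pool replicate counts of one group into a site table keyed by
# chrom/pos/strand/context.
pool_group <- function(samples) {
  recs <- do.call(rbind, lapply(samples, `[[`, "records"))
  key <- paste(recs$chrom, recs$pos, recs$strand, recs$context, sep = "\r")
  m <- rowsum(cbind(recs$n_meth, recs$n_unmeth), key)
  first <- recs[!duplicated(key), c("chrom", "pos", "strand", "context")]
  first <- first[match(rownames(m), paste(first$chrom, first$pos,
                                          first$strand, first$context,
                                          sep = "\r")), ]
  out <- data.frame(first, n_meth = m[, 1], n_unmeth = m[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Call differentially methylated cytosines between two groups
#'
#' Replicates are pooled within each group; each site covered at or above
#' `min_coverage` in both pools is tested with [fisher_site_test()]; BH
#' q-values are computed over the tested sites; sites with
#' `|diff| >= min_diff` percent and `q < q_cutoff` are retained and then
#' ranked by q ascending (ties by `|diff|` descending, then position) and
#' truncated to the top `top_confidence_fraction`.
#'
#' @param control,treated lists of [sample_set()] (the replicates of each
#'   group).
#' @param params a [dmc_params()].
#' @return Data frame of retained DmCs (`chrom`, `pos`, `strand`, `context`,
#'   `ratio_control`, `ratio_treated`, `diff` in percent, `p`, `q`,
#'   `direction`), sorted by position, with attribute `n_tested`.
#' @export
call_dmcs <- function(control, treated, params = dmc_params()) {
  stopifnot(inherits(params, "DmcCallParams"))
  if (params$normalize) {
    all_norm <- normalize_coverage(c(control, treated))
    control <- all_norm[seq_along(control)]
    treated <- all_norm[length(control) + seq_along(treated)]
  }
  pc <- pool_group(control)
  pt <- pool_group(treated)
  key_c <- paste(pc$chrom, pc$pos, pc$strand, sep = "\r")
  key_t <- paste(pt$chrom, pt$pos, pt$strand, sep = "\r")
  shared <- intersect(key_c, key_t)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      ratio_control = numeric(), ratio_treated = numeric(),
                      diff = numeric(), p = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!length(shared)) {
    warning("control and treated groups share no sites")
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  pc <- pc[match(shared, key_c), ]
  pt <- pt[match(shared, key_t), ]
  cov_c <- pc$n_meth + pc$n_unmeth
  cov_t <- pt$n_meth + pt$n_unmeth
  testable <- cov_c >= params$min_coverage & cov_t >= params$min_coverage
  pc <- pc[testable, ]; pt <- pt[testable, ]
  cov_c <- cov_c[testable]; cov_t <- cov_t[testable]
  n_tested <- nrow(pc)
  if (!n_tested) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  ratio_c <- pc$n_meth / cov_c
  ratio_t <- pt$n_meth / cov_t
  diff <- (ratio_t - ratio_c) * 100
  p <- fisher_site_test(pc$n_meth, pc$n_unmeth, pt$n_meth, pt$n_unmeth)
  q <- adjust_q(p)
  keep <- !is.na(p) & abs(diff) >= params$min_diff & q < params$q_cutoff
  res <- data.frame(
    chrom = pc$chrom, pos = pc$pos, strand = pc$strand, context = pc$context,
    ratio_control = ratio_c, ratio_treated = ratio_t, diff = diff,
    p = p, q = q, direction = ifelse(diff > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (nrow(res)) {
    ord <- order(res$q, -abs(res$diff), res$chrom, res$pos)
    n_keep <- ceiling(nrow(res) * params$top_confidence_fraction)
    res <- res[ord[seq_len(n_keep)], , drop = FALSE]
    res <- res[order(res$chrom, res$pos, res$strand), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  res
}

#' Pairwise sample correlation and Ward clustering
#'
#' Pearson correlation of percent methylation over the sites covered in
#' every sample; hierarchical clustering on the distance `1 - r` with
#' Ward's method (`ward.D2`).
#'
#' @param samples list of at least two [sample_set()] sharing at least three
#'   covered sites.
#' @return List with `correlation` (matrix) and `tree` ([stats::hclust]).
#' @export
sample_similarity <- function(samples) {
  stopifnot(length(samples) >= 2)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  tabs <- lapply(samples, function(s) {
    r <- s$records
    cov <- r$n_meth + r$n_unmeth
    r <- r[cov > 0, , drop = FALSE]
    data.frame(key = paste(r$chrom, r$pos, r$strand, sep = "\r"),
               pct = 100 * r$n_meth / (r$n_meth + r$n_unmeth),
               stringsAsFactors = FALSE)
  })
  shared <- Reduce(intersect, lapply(tabs, `[[`, "key"))
  if (length(shared) < 3)
    stop("fewer than 3 sites covered in all samples")
  mat <- vapply(tabs, function(t) t$pct[match(shared, t$key)],
                numeric(length(shared)))
  colnames(mat) <- ids
  r <- stats::cor(mat, method = "pearson")
  tree <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  list(correlation = r, tree = tree)
}
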