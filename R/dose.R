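#' Per-replicate methylation deltas of a DMR at each treated dose
#'
#' For every replicate of the two treated groups, the coverage-weighted mean
#' percent methylation over the DMR's member sites (sites of the DMR's
#' context inside its interval) minus the control-group grand mean (the mean
#' of the control replicates' per-replicate means).  A replicate with no
#' covered member site yields `NA`.
#'
#' @param dmr one row of a DMR data frame.
#' @param samples list of all [sample_set()] replicates (doses 0, 5, 10).
#' @return List of class `DoseDeltas` with `delta5`, `delta10` (numeric
#'   per-replicate vectors), `control_mean`, and `dmr` (the input row).
#' @export
compute_deltas <- function(dmr, samples) {
  doses <- vapply(samples, `[[`, numeric(1), "dose")
  rep_mean <- vapply(samples, function(s) {
    r <- s$records
    sel <- r$chrom == dmr$chrom & r$pos > dmr$start & r$pos <= dmr$end &
      (is.na(dmr$context_label) | r$context == dmr$context_label)
    r <- r[sel, , drop = FALSE]
    cov <- r$n_meth + r$n_unmeth
    if (!nrow(r) || sum(cov) == 0) return(NA_real_)
    100 * sum(r$n_meth) / sum(cov)  # coverage-weighted mean of site ratios
  }, numeric(1))
  ctrl <- rep_mean[doses == 0]
  if (all(is.na(ctrl))) stop("DMR uncovered in every control replicate")
  control_mean <- mean(ctrl, na.rm = TRUE)
  structure(list(delta5 = rep_mean[doses == 5] - control_mean,
                 delta10 = rep_mean[doses == 10] - control_mean,
                 control_mean = control_mean, dmr = dmr),
            class = "DoseDeltas")
}

#' Classify a shared DMR's dose response from its deltas
#'
#' Pooled-variance two-sample Student's t-test of the per-replicate dose-5
#' deltas against the dose-10 deltas at significance `alpha`.  Non-rejection
#' gives `independent`; rejection gives `positive` when the dose-10 shift is
#' larger in magnitude and `inverse` when the dose-5 shift is.  Absolute
#' deltas are compared so hyper- and hypomethylated regions are treated
#' symmetrically.  Degenerate zero-variance input is classified by direct
#' magnitude comparison.
#'
#' @param deltas a [compute_deltas()] result.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance (Student) form; `FALSE` gives
#'   Welch.
#' @return List of class `DoseClassification`: `class`, `basis`
#'   (`"shared_ttest"`), `t_p`, `mean_delta5`, `mean_delta10`, `dmr`.
#' @export
classify_shared <- function(deltas, alpha = 0.05, var_equal = TRUE) {
  d5 <- deltas$delta5[!is.na(deltas$delta5)]
  d10 <- deltas$delta10[!is.na(deltas$delta10)]
  if (length(d5) < 2 || length(d10) < 2) {
    return(structure(list(class = "unclassified", basis = "shared_ttest",
                          t_p = NA_real_, mean_delta5 = mean(d5),
                          mean_delta10 = mean(d10), dmr = deltas$dmr),
                     class = "DoseClassification"))
  }
  m5 <- mean(d5); m10 <- mean(d10)
  if (stats::sd(d5) == 0 && stats::sd(d10) == 0) {
    cls <- if (m5 == m10) "independent"
      else if (abs(m10) > abs(m5)) "positive" else "inverse"
    p <- if (m5 == m10) 1 else 0
  } else {
    p <- stats::t.test(d5, d10, var.equal = var_equal)$p.value
    cls <- if (p >= alpha) "independent"
      else if (abs(m10) > abs(m5)) "positive"
      else if (abs(m5) > abs(m10)) "inverse" else "independent"
  }
  structure(list(class = cls, basis = "shared_ttest", t_p = p,
                 mean_delta5 = m5, mean_delta10 = m10, dmr = deltas$dmr),
            class = "DoseClassification")
}

#' Boundary curves for the dose-response scatter
#'
#' For each significant set (mean dose-5 delta significantly above, or
#' below, the dose-10 delta), fits by least squares both a line through the
#' origin (`y = a x`) and a quadratic through the origin (`y = a x + b x^2`)
#' of mean dose-10 delta on mean dose-5 delta, and reports AIC and BIC for
#' both.  The quadratic is retained as the boundary when both criteria are
#' smaller.  Sets with fewer than `min_points` members yield no curve.
#'
#' @param classifications list of [classify_shared()] results.
#' @param alpha significance level defining the sets.
#' @param min_points minimum points per fitted set (default 5).
#' @return List with elements `inverse_side` and `positive_side`, each
#'   `NULL` or a list with `coef_linear`, `coef_quadratic`, `aic`, `bic`
#'   (2-vectors, linear then quadratic), `use_quadratic`, `n`.
#' @export
fit_boundary_curves <- function(classifications, alpha = 0.05,
                                min_points = 5) {
  tab <- data.frame(
    x = vapply(classifications, `[[`, numeric(1), "mean_delta5"),
    y = vapply(classifications, `[[`, numeric(1), "mean_delta10"),
    p = vapply(classifications, `[[`, numeric(1), "t_p")
  )
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  fit_side <- function(d) {
    if (nrow(d) < min_points) return(NULL)
    lin <- stats::lm(y ~ x - 1, data = d)
    quad <- stats::lm(y ~ x + I(x^2) - 1, data = d)
    aic <- c(stats::AIC(lin), stats::AIC(quad))
    bic <- c(stats::BIC(lin), stats::BIC(quad))
    list(coef_linear = stats::coef(lin), coef_quadratic = stats::coef(quad),
         aic = aic, bic = bic,
         use_quadratic = aic[2] < aic[1] && bic[2] < bic[1], n = nrow(d))
  }
  sig <- tab$p < alpha
  list(
    inverse_side = fit_side(tab[sig & abs(tab$x) > abs(tab$y), ,
                                drop = FALSE]),
    positive_side = fit_side(tab[sig & abs(tab$x) < abs(tab$y), ,
                                 drop = FALSE])
  )
}

#' Classify every reconciled DMR's dose response
#'
#' Regions unique to the 10 percent dose are positive dose-dependent
#' (basis `unique_to_10`); regions unique to the 5 percent dose are inverse
#' dose-dependent (basis `unique_to_5`); shared regions are classified by
#' the replicate t-test ([classify_shared()]).  Boundary curves are fitted
#' over the shared significant sets as a descriptive layer.
#'
#' @param reconciled output of [reconcile_doses()].
#' @param samples list of all [sample_set()] replicates.
#' @param alpha t-test significance level.
#' @param var_equal see [classify_shared()].
#' @return List with `classifications` (data frame `dmr_id`, `chrom`,
#'   `start`, `end`, `class`, `basis`, `mean_delta5`, `mean_delta10`,
#'   `t_p`), `curves` ([fit_boundary_curves()]), and `summary` (counts per
#'   class and basis).
#' @export
classify_all <- function(reconciled, samples, alpha = 0.05,
                         var_equal = TRUE) {
  rows <- list(); shared_cls <- list()
  add_row <- function(dmr, class, basis, m5 = NA, m10 = NA, p = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = dmr$chrom, start = dmr$start, end = dmr$end,
      direction = dmr$direction, class = class, basis = basis,
      mean_delta5 = m5, mean_delta10 = m10, t_p = p,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reconciled$unique_10)))
    add_row(reconciled$unique_10[i, ], "positive", "unique_to_10")
  for (i in seq_len(nrow(reconciled$unique_5)))
    add_row(reconciled$unique_5[i, ], "inverse", "unique_to_5")
  for (i in seq_len(nrow(reconciled$shared))) {
    dmr <- reconciled$shared[i, ]
    cls <- classify_shared(compute_deltas(dmr, samples), alpha, var_equal)
    shared_cls[[length(shared_cls) + 1L]] <- cls
    add_row(dmr, cls$class, cls$basis, cls$mean_delta5, cls$mean_delta10,
            cls$t_p)
  }
  classifications <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), class = character(),
               basis = character(), mean_delta5 = numeric(),
               mean_delta10 = numeric(), t_p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(classifications))
    classifications <- cbind(dmr_id = sprintf("dmr_%04d",
                                              seq_len(nrow(classifications))),
                             classifications)
  summary <- as.data.frame(table(class = classifications$class,
                                 basis = classifications$basis),
                           stringsAsFactors = FALSE)
  summary <- summary[summary$Freq > 0, , drop = FALSE]
  rownames(summary) <- NULL
  list(classifications = classifications,
       curves = fit_boundary_curves(shared_cls, alpha),
       summary = summary)
}
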