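#' Associate DMRs with genomic features within a window
#'
#' Emits a DMR-feature pair whenever the gap between the two intervals is at
#' most `window` bp (overlap counts as gap 0; the boundary is inclusive, so
#' a gap of exactly `window` associates).  A DMR may pair with several
#' features and vice versa; strand is ignored.
#'
#' @param dmrs DMR data frame; an optional `dmr_id` column is respected,
#'   otherwise ids `dmr_<i>` are assigned in row order.
#' @param features feature data frame from [read_features_gff()] or
#'   [simulate_features()].
#' @param window maximum gap in bp (default 2000, the "within 2 kb in either
#'   direction" rule).
#' @return Association data frame `dmr_id`, `feature_id`, `feature_type`,
#'   `gap`.
#' @export
associate_dmrs <- function(dmrs, features, window = 2000) {
  empty <- data.frame(dmr_id = character(), feature_id = character(),
                      feature_type = character(), gap = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(dmrs) || !nrow(features)) return(empty)
  dmr_id <- if ("dmr_id" %in% names(dmrs)) dmrs$dmr_id
    else sprintf("dmr_%d", seq_len(nrow(dmrs)))
  gr_d <- dmr_granges(dmrs)
  gr_f <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end))
  hits <- GenomicRanges::findOverlaps(gr_d, gr_f, maxgap = window)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(gr_d[q], gr_f[s])
  keep <- !is.na(gap) & gap <= window
  res <- data.frame(dmr_id = dmr_id[q], feature_id = features$id[s],
                    feature_type = features$feature_type[s],
                    gap = as.integer(gap), stringsAsFactors = FALSE)[keep, ,
                                                                    drop = FALSE]
  res <- res[order(res$dmr_id, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' DMR-associated gene list
#'
#' Distinct `gene`-type feature ids from an association table.
#'
#' @param assoc output of [associate_dmrs()].
#' @param types feature types to include (default genes only).
#' @return Character vector of feature ids.
#' @export
associated_genes <- function(assoc, types = "gene") {
  sort(unique(assoc$feature_id[assoc$feature_type %in% types]))
}

#' Hypergeometric term enrichment with a normalized-frequency cutoff
#'
#' Per term, with a universe of `N` genes of which `K` carry the term and an
#' input list of `n` genes of which `k` carry it, the enrichment p-value is
#' the hypergeometric upper tail P(X >= k) and the normalized frequency is
#' `(k/n) / (K/N)`.  Terms with `p <= p_cutoff` and ratio strictly above
#' `ratio_cutoff` are retained, sorted by ratio descending.
#'
#' @param genes input gene ids (must be a subset of `universe`).
#' @param term_map data frame with columns `term` and `gene`.
#' @param universe all gene ids under consideration.
#' @param p_cutoff p-value threshold (default 0.05).
#' @param ratio_cutoff normalized-frequency threshold (default 1.5).
#' @return Data frame `term`, `k`, `n`, `K`, `N`, `p`, `ratio`.
#' @export
enrich_terms <- function(genes, term_map, universe, p_cutoff = 0.05,
                         ratio_cutoff = 1.5) {
  stopifnot(all(c("term", "gene") %in% names(term_map)))
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe))
    stop("input gene(s) absent from the universe")
  empty <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE)
  if (!length(genes)) return(empty)
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  N <- length(universe); n <- length(genes)
  rows <- lapply(split(term_map$gene, term_map$term), function(tg) {
    tg <- unique(tg)
    K <- length(tg); k <- sum(genes %in% tg)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(k = k, n = n, K = K, N = N, p = p,
               ratio = (k / n) / (K / N))
  })
  res <- do.call(rbind, rows)
  res <- cbind(term = names(rows), res)
  rownames(res) <- NULL
  res <- res[res$p <= p_cutoff & res$ratio > ratio_cutoff, , drop = FALSE]
  res[order(-res$ratio, res$term), , drop = FALSE]
}

#' Tally associations by feature type, context and direction
#'
#' Cross-tabulates DMR-feature association pairs over
#' feature type x DMR sequence context x DMR direction, in a deterministic
#' row order, with all-zero combinations retained.
#'
#' @param dmrs DMR data frame (`dmr_id` optional, as in
#'   [associate_dmrs()]).
#' @param assoc association table from [associate_dmrs()].
#' @return Data frame `feature_type`, `context`, `direction`, `count`; the
#'   counts sum to `nrow(assoc)`.
#' @export
tally_by_context <- function(dmrs, assoc) {
  dmr_id <- if ("dmr_id" %in% names(dmrs)) dmrs$dmr_id
    else sprintf("dmr_%d", seq_len(nrow(dmrs)))
  ftypes <- sort(unique(c("gene", "transposable_element",
                          assoc$feature_type)))
  grid <- expand.grid(feature_type = ftypes,
                      context = c("CG", "CHG", "CHH"),
                      direction = c("hyper", "hypo"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$feature_type, grid$context, grid$direction), ]
  rownames(grid) <- NULL
  if (!nrow(assoc)) { grid$count <- 0L; return(grid) }
  i <- match(assoc$dmr_id, dmr_id)
  key_a <- paste(assoc$feature_type, dmrs$context_label[i],
                 dmrs$direction[i])
  key_g <- paste(grid$feature_type, grid$context, grid$direction)
  tab <- table(key_a)
  grid$count <- as.integer(ifelse(key_g %in% names(tab), tab[key_g], 0L))
  grid
}
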