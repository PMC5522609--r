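#' Expected gene-set overlap under random placement
#'
#' If a set of `nA` genes and an independent set of `nB` genes are each
#' placed at random in a universe of `N` genes, the expected size of their
#' intersection is `nA/N * nB` (the hypergeometric mean).  The exact
#' fraction `nA/N` is used and the result rounded half away from zero to an
#' integer, reproducing the rounded-proportion arithmetic used when the
#' fraction is quoted to two digits.
#'
#' @param nA,nB set sizes (each <= N).
#' @param N universe size (> 0).
#' @return Expected overlap, rounded to an integer.
#' @export
expected_overlap <- function(nA, nB, N) {
  if (N <= 0) stop("universe size must be positive")
  stopifnot(nA <= N, nB <= N, nA >= 0, nB >= 0)
  round_half_up(nA / N * nB)
}

#' Expected three-way gene-set overlap under random placement
#'
#' Scales the (rounded) pairwise expectation by the third set's fraction of
#' the universe: `round(expected_overlap(nA, nB, N) / N * nC)`.
#'
#' @param nA,nB,nC set sizes (each <= N).
#' @param N universe size (> 0).
#' @return Expected triple overlap, rounded to an integer.
#' @export
expected_triple <- function(nA, nB, nC, N) {
  if (N <= 0) stop("universe size must be positive")
  stopifnot(nC <= N, nC >= 0)
  round_half_up(expected_overlap(nA, nB, N) / N * nC)
}

#' Pearson chi-squared test of independence of two gene sets
#'
#' Builds the 2x2 presence/absence table over the universe
#' (`nAB`, `nA - nAB`; `nB - nAB`, `N - nA - nB + nAB`) and applies
#' Pearson's chi-squared test without continuity correction (df = 1,
#' upper-tail p).
#'
#' @param N universe size.
#' @param nA,nB set sizes.
#' @param nAB observed intersection size.
#' @return List of class `ChiSqResult`: `statistic`, `df`, `p`, `table`.
#' @export
chisq_2x2 <- function(N, nA, nB, nAB) {
  stopifnot(nAB <= min(nA, nB), nA + nB - nAB <= N, nAB >= 0)
  tab <- matrix(c(nAB, nA - nAB, nB - nAB, N - nA - nB + nAB), nrow = 2,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero")
  ht <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, table = tab),
            class = "ChiSqResult")
}

#' @export
print.ChiSqResult <- function(x, ...) {
  cat(sprintf("Pearson chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Venn partition of three gene sets
#'
#' @param A,B,C character vectors of gene ids.
#' @return List with `regions` (named counts `A_only`, `B_only`, `C_only`,
#'   `AB_only`, `AC_only`, `BC_only`, `ABC`), and `uniqueness` (data frame
#'   of per-set unique counts and percentages).  The region counts sum to
#'   `|A U B U C|`.
#' @export
venn_partition <- function(A, B, C = character()) {
  A <- unique(A); B <- unique(B); C <- unique(C)
  all_ids <- union(union(A, B), C)
  inA <- all_ids %in% A; inB <- all_ids %in% B; inC <- all_ids %in% C
  regions <- c(
    A_only = sum(inA & !inB & !inC), B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC), AB_only = sum(inA & inB & !inC),
    AC_only = sum(inA & !inB & inC), BC_only = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
  uniq <- data.frame(
    set = c("A", "B", "C"), size = c(length(A), length(B), length(C)),
    unique = unname(regions[c("A_only", "B_only", "C_only")]),
    stringsAsFactors = FALSE)
  uniq$pct_unique <- ifelse(uniq$size > 0, 100 * uniq$unique / uniq$size, NA)
  list(regions = regions, uniqueness = uniq)
}

#' Set-unique count from partition totals
#'
#' Given a set's size, its pairwise-only intersection counts with the other
#' sets and the triple intersection, the number of members unique to the
#' set is `size - sum(pairwise_only) - triple`.
#'
#' @param size set size.
#' @param pairwise_only vector of pairwise-only intersection counts.
#' @param triple triple-intersection count.
#' @return Integer unique count.
#' @export
venn_unique_count <- function(size, pairwise_only, triple) {
  res <- size - sum(pairwise_only) - triple
  if (res < 0) stop("inconsistent partition counts")
  as.integer(res)
}

#' Chi-squared test of mutual independence of three gene sets
#'
#' Builds the 2x2x2 membership table over the universe and tests mutual
#' independence of the three sets: expected cell counts are
#' `N * prod(marginal presence/absence probabilities)`, the statistic is
#' the Pearson sum over the 8 cells, and the degrees of freedom are
#' `(8 - 1) - 3 = 4`.  This is one defensible construction of a
#' three-stress independence test; it is exposed behind the `three_way`
#' flag of [overlap_report()] rather than as a default.
#'
#' @param N universe size.
#' @param nA,nB,nC set sizes.
#' @param nAB,nAC,nBC pairwise intersection sizes (not pairwise-only).
#' @param nABC triple intersection size.
#' @return List of class `ChiSqResult`: `statistic`, `df`, `p`, `table`
#'   (the 8 observed cell counts).
#' @export
chisq_mutual_independence <- function(N, nA, nB, nC, nAB, nAC, nBC, nABC) {
  obs <- c(
    n111 = nABC, n110 = nAB - nABC, n101 = nAC - nABC, n011 = nBC - nABC,
    n100 = nA - nAB - nAC + nABC, n010 = nB - nAB - nBC + nABC,
    n001 = nC - nAC - nBC + nABC,
    n000 = N - (nA + nB + nC - nAB - nAC - nBC + nABC))
  if (any(obs < 0)) stop("inconsistent intersection counts")
  pA <- nA / N; pB <- nB / N; pC <- nC / N
  pat <- expand.grid(a = c(1, 0), b = c(1, 0), c = c(1, 0))
  pat <- pat[match(names(obs),
                   sprintf("n%d%d%d", pat$a, pat$b, pat$c)), ]
  expd <- N * (pA^pat$a * (1 - pA)^(1 - pat$a)) *
    (pB^pat$b * (1 - pB)^(1 - pat$b)) *
    (pC^pat$c * (1 - pC)^(1 - pat$c))
  if (any(expd == 0)) stop("expected cell count of zero")
  stat <- sum((obs - expd)^2 / expd)
  structure(list(statistic = stat, df = 4L,
                 p = stats::pchisq(stat, 4, lower.tail = FALSE),
                 table = obs),
            class = "ChiSqResult")
}

#' Permutation null distribution of a two-set overlap
#'
#' Draws `reps` independent pairs of uniform random subsets of sizes `nA`
#' and `nB` from `1..N` and records the intersection size.  The mean of the
#' distribution estimates `nA * nB / N` (the hypergeometric mean), serving
#' as a simulation oracle for [expected_overlap()] and [chisq_2x2()].
#'
#' @param nA,nB subset sizes.
#' @param N universe size.
#' @param reps number of draws (>= 1000).
#' @param seed RNG seed.
#' @return Integer vector of `reps` overlap sizes.
#' @export
permutation_overlap_null <- function(nA, nB, N, reps = 10000, seed = 1L) {
  stopifnot(reps >= 1000, nA <= N, nB <= N)
  set.seed(derive_seed(seed, 5L))
  vapply(seq_len(reps), function(i) {
    a <- sample.int(N, nA)
    b <- sample.int(N, nB)
    length(intersect(a, b))
  }, integer(1))
}

#' Cross-stress overlap report
#'
#' Convenience wrapper producing, for three stress gene sets, the Venn
#' partition, the expected pairwise and triple overlaps under random
#' placement, and the pairwise chi-squared independence tests.
#'
#' @param sets named list of three character vectors of gene ids.
#' @param N gene-universe size.
#' @param three_way also compute the 2x2x2 mutual-independence test
#'   ([chisq_mutual_independence()]); off by default.
#' @return List with `partition`, `expected`, `chisq` (and `chisq_three_way`
#'   when requested); serialisable to JSON.
#' @export
overlap_report <- function(sets, N, three_way = FALSE) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  nm <- names(sets)
  sizes <- unname(lengths(lapply(sets, unique)))
  part <- venn_partition(sets[[1]], sets[[2]], sets[[3]])
  pairs <- utils::combn(3, 2, simplify = FALSE)
  expected <- lapply(pairs, function(ij) {
    list(sets = nm[ij],
         expected = expected_overlap(sizes[ij[1]], sizes[ij[2]], N))
  })
  chisq <- lapply(pairs, function(ij) {
    nAB <- length(intersect(unique(sets[[ij[1]]]), unique(sets[[ij[2]]])))
    nA <- sizes[ij[1]]; nB <- sizes[ij[2]]
    # a chi-squared statistic is undefined when a margin is empty (empty
    # set or set spanning the whole universe); report NA rather than fail
    if (nA == 0 || nB == 0 || nA == N || nB == N)
      return(list(sets = nm[ij], observed = nAB, statistic = NA_real_,
                  df = 1L, p = NA_real_))
    ht <- chisq_2x2(N, nA, nB, nAB)
    list(sets = nm[ij], observed = nAB, statistic = ht$statistic,
         df = ht$df, p = ht$p)
  })
  out <- list(partition = part,
              expected = c(expected,
                           list(list(sets = nm,
                                     expected = expected_triple(
                                       sizes[1], sizes[2], sizes[3], N)))),
              chisq = chisq)
  if (three_way) {
    s <- lapply(sets, unique)
    out$chisq_three_way <- tryCatch(
      chisq_mutual_independence(
        N, sizes[1], sizes[2], sizes[3],
        length(intersect(s[[1]], s[[2]])),
        length(intersect(s[[1]], s[[3]])),
        length(intersect(s[[2]], s[[3]])),
        length(Reduce(intersect, s))),
      error = function(e) NULL)
  }
  out
}
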