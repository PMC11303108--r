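## Mann-Whitney U machinery used by the DEG stage.
##
## Two regimes:
##  * both groups <= `exact_max` cells: exact enumeration of the rank-sum
##    null over all choose(nA+nB, nA) group labelings (valid under ties,
##    since midranks are exchangeable under the permutation null);
##  * otherwise: large-sample normal approximation with the standard tie
##    correction of the rank-sum variance, no continuity correction.

rank_sum_one <- function(a, b, exact_max = 8L) {
  nA <- length(a); nB <- length(b); n <- nA + nB
  r <- rank(c(a, b))
  W <- sum(r[seq_len(nA)])               # rank sum of group A
  U <- W - nA * (nA + 1) / 2             # Mann-Whitney U (A over B)
  if (nA <= exact_max && nB <= exact_max) {
    e <- nA * (n + 1) / 2
    combs <- utils::combn(n, nA)
    Wperm <- colSums(matrix(r[combs], nrow = nA))
    p <- mean(abs(Wperm - e) >= abs(W - e) - 1e-9)
  } else {
    mu <- nA * nB / 2
    ties <- table(r)
    sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  c(U = U, p = p)
}

#' Two-group Mann-Whitney tests for every column of a matrix
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test per gene between
#' two disjoint groups of cells. With both groups of size at most
#' `exact_max` the p-value is computed by exact enumeration over all group
#' labelings (correct under ties); otherwise by the tie-corrected normal
#' approximation.
#'
#' @param matA,matB Numeric matrices (cells x genes) with identical column
#'   sets; rows are the cells of each group.
#' @param exact_max Largest per-group size for which exact enumeration is
#'   used (default 8).
#' @return A `data.frame` with columns `gene_id`, `U` (Mann-Whitney U of
#'   group A over group B), `p_value`.
#' @export
rank_sum_matrix <- function(matA, matB, exact_max = 8L) {
  stopifnot(ncol(matA) == ncol(matB))
  res <- vapply(seq_len(ncol(matA)), function(j) {
    rank_sum_one(matA[, j], matB[, j], exact_max = exact_max)
  }, c(U = 0, p = 0))
  ids <- colnames(matA)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(ncol(matA)))
  data.frame(
    gene_id = ids,
    U = res["U", ],
    p_value = res["p", ],
    stringsAsFactors = FALSE
  )
}
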