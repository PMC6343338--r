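#' Block correlation structure for a gene pair
#'
#' Joint correlation matrix of the sites of two genes, partitioned into
#' the within-gene blocks `pp` (m x m), `qq` (n x n) and the cross block
#' `pq` (m x n).  Entries are shrinkage-weighted site correlations.
#'
#' @param pp,qq symmetric within-gene correlation blocks with unit
#'   diagonal.
#' @param pq cross-gene correlation block.
#' @return An object of class `"block_correlation"`.
#' @export
block_correlation <- function(pp, pq, qq) {
  pp <- as.matrix(pp); pq <- as.matrix(pq); qq <- as.matrix(qq)
  if (!all(is.finite(pp)) || !all(is.finite(pq)) || !all(is.finite(qq)))
    stop("non-finite correlation entries")
  if (nrow(pp) != ncol(pp) || nrow(qq) != ncol(qq))
    stop("within-gene blocks must be square")
  if (nrow(pq) != nrow(pp) || ncol(pq) != ncol(qq))
    stop("cross block dimensions do not match the within blocks")
  if (max(abs(pp - t(pp))) > 1e-8 || max(abs(qq - t(qq))) > 1e-8)
    stop("within-gene blocks must be symmetric")
  if (max(abs(c(pp, pq, qq))) > 1 + 1e-8)
    stop("correlation entries must lie in [-1, 1]")
  structure(list(pp = pp, pq = pq, qq = qq), class = "block_correlation")
}

# Moore-Penrose pseudo-inverse, relative singular-value tolerance
pinv <- function(m, rtol = 1e-10) {
  s <- svd(m)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Canonical correlations of a gene pair
#'
#' The squared canonical correlations are the eigenvalues of
#' `pp^-1 pq qq^-1 qp`, computed with pseudo-inverses so that
#' rank-deficient blocks (e.g. exactly collinear relative-usage
#' profiles) are handled without error.  Eigenvalues are clipped to
#' `[0, 1 - 1e-12]` before the square root, so a later log(1 - xi^2)
#' stays finite.
#'
#' @param block a [block_correlation()].
#' @return Numeric vector of `k = min(m, n)` canonical correlations,
#'   sorted descending, each in `[0, 1)`.
#' @export
canonical_correlations <- function(block) {
  stopifnot(inherits(block, "block_correlation"))
  k <- min(nrow(block$pp), nrow(block$qq))
  P <- pinv(block$pp) %*% block$pq %*% pinv(block$qq) %*% t(block$pq)
  ev <- Re(eigen(P, only.values = TRUE)$values)
  ev <- pmin(pmax(ev, 0), 1 - 1e-12)
  sqrt(sort(ev, decreasing = TRUE)[seq_len(k)])
}

#' Sequential significance test of canonical correlations
#'
#' Bartlett-style likelihood-ratio sequence: the statistic for the c-th
#' coefficient is `-[g - (m+n)/2] * sum_{i=c..k} log(1 - xi_i^2)`,
#' referred to a chi-squared distribution with `(m-c+1)(n-c+1)` degrees
#' of freedom.  Coefficient c is declared significant only if tests
#' 1..c all reject at `alpha`; testing stops at the first acceptance.
#'
#' @param xi canonical correlations, descending, each in `[0, 1)`.
#' @param m,n numbers of sites in the two genes.
#' @param g effective sample size (the number of experiments over which
#'   the correlations were estimated); must exceed `(m + n) / 2`.
#' @param alpha significance level (default 0.05).
#' @return A list with `statistic`, `df`, `p_value` (length-k vectors),
#'   `significant` (logical) and `n_significant`.
#' @export
significance_sequence <- function(xi, m, n, g, alpha = 0.05) {
  k <- length(xi)
  if (g <= (m + n) / 2)
    stop("effective sample size g must exceed (m + n)/2")
  if (any(xi < 0 | xi >= 1)) stop("canonical correlations must be in [0, 1)")
  log_terms <- log1p(-xi^2)
  stat <- -(g - (m + n) / 2) * rev(cumsum(rev(log_terms)))
  cs <- seq_len(k)
  df <- (m - cs + 1) * (n - cs + 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  reject <- p <= alpha
  n_sig <- if (all(reject)) k else which(!reject)[1L] - 1L
  list(statistic = stat, df = df, p_value = p,
       significant = cs <= n_sig, n_significant = n_sig)
}

#' Significance-weighted gene-pair weight
#'
#' Combines the canonical correlations within the significant leading
#' run into one scalar: each coefficient with p <= 0.05 contributes its
#' correlation weighted by `-log(p)` (natural log, p floored at 1e-300);
#' the weight is the normalised sum.  No significant coefficient gives
#' weight 0; a single significant coefficient gives exactly its
#' correlation.
#'
#' @param xi canonical correlations, descending.
#' @param test result of [significance_sequence()] for `xi`.
#' @return Weight in `[0, xi[1]]`.
#' @export
pair_weight <- function(xi, test) {
  keep <- test$significant & test$p_value <= 0.05
  if (!any(keep)) return(0)
  if (sum(keep) == 1L) return(xi[keep])  # single-term ratio, exactly
  L <- -log(pmax(test$p_value[keep], 1e-300))
  if (sum(L) == 0) return(0)
  sum(xi[keep] * L) / sum(L)
}
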