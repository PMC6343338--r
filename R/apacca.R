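#' Gene-pair similarity from poly(A)-site canonical correlations
#'
#' Fits the shrinkage canonical-correlation similarity model to a
#' poly(A)-site data set.  Each gene is represented by the block of its
#' sites; for every unordered gene pair the site-site correlation
#' blocks are formed, the canonical correlations extracted, tested
#' sequentially, and combined into one significance-weighted similarity
#' in `[0, 1]`.  The result is a symmetric gene-by-gene weight matrix
#' with a significance mask, ready for hierarchical clustering (via
#' [stats::as.dist()]) or network export (via [significant_pairs()]).
#'
#' Three engines share the interface:
#' \describe{
#'   \item{`"scca"`}{the full model: site correlations use
#'     shrinkage-weighted per-experiment means and errors
#'     ([shrinkage_stats()]), so replicate number and within-experiment
#'     variability inform the similarity.}
#'   \item{`"cca"`}{plain canonical correlation on replicate-averaged
#'     site values (the conventional CCA comparator).}
#'   \item{`"pcc"`}{gene-level Pearson correlation of summed site
#'     counts, mapped to `[0, 1]` as `(1 + r) / 2`; the mask tests
#'     `r != 0` across experiments.}
#' }
#'
#' @param data a filtered, quantified [pac_dataset()].
#' @param measure similarity engine, see Details.
#' @param alpha significance level for the sequential canonical tests
#'   (default 0.05).
#' @param workers number of parallel worker processes over gene-pair
#'   blocks; the result is identical for any value (deterministic
#'   partition, stable reduction order).
#' @return An object of class `"apacca"`: list with `weights` (G x G
#'   symmetric matrix in `[0, 1]`, unit diagonal), `mask` (logical G x G,
#'   TRUE where at least one canonical correlation is significant),
#'   `genes`, `measure`, `alpha`, `g` (effective sample size: the total
#'   number of samples), `quantification` and `call`.
#' @examples
#' set.seed(1)
#' sim <- planted_cluster_dataset(simulation_config(
#'   n_genes = 12, n_experiments = 6, replicates = 2,
#'   n_clusters = 2, effect = 1.5, seed = 1))
#' fit <- apacca(sim$data)
#' fit
#' head(significant_pairs(fit))
#' @export
apacca <- function(data, measure = c("scca", "cca", "pcc"),
                   alpha = 0.05, workers = 1L) {
  measure <- match.arg(measure)
  stopifnot(inherits(data, "pac_dataset"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  genes <- unique(data$sites$gene_id)
  G <- length(genes)
  if (G < 2L) stop("need at least two genes")
  # effective sample size of the canonical tests: the total number of
  # samples, since the CCA is posed on the full replicate-level
  # measurement blocks (under no replication this equals T)
  g_eff <- data$design$n_samples
  cl <- match.call()

  if (measure == "pcc") {
    fit <- pcc_weights(data, alpha)
  } else {
    idx <- gene_site_index(data)
    if (any(lengths(idx) < 1L)) stop("every gene needs at least one site")
    Zn <- site_z_rows(data, measure)
    sizes <- lengths(idx)
    too_big <- outer(sizes, sizes, "+") / 2 >= g_eff
    diag(too_big) <- FALSE
    if (any(too_big))
      stop("some gene pair has (m + n)/2 >= the effective sample size; ",
           "the canonical test statistic is undefined there")
    fit <- pair_weights(Zn, idx, g_eff, alpha, workers)
  }
  W <- fit$weights
  M <- fit$mask
  dimnames(W) <- dimnames(M) <- list(genes, genes)
  diag(W) <- 1
  diag(M) <- TRUE
  structure(list(weights = W, mask = M, genes = genes, measure = measure,
                 alpha = alpha, g = g_eff,
                 quantification = data$quantification, call = cl),
            class = "apacca")
}

# normalized per-site deviation rows; scca uses shrinkage standardization,
# cca uses plain replicate-averaged means
site_z_rows <- function(data, measure) {
  if (measure == "scca") {
    prof <- shrinkage_stats(data$counts, data$design)
    Z <- standardized_deviations(prof)
  } else {
    cols <- design_columns(data$design)
    E <- vapply(cols, function(j)
      rowMeans(data$counts[, j, drop = FALSE]),
      numeric(nrow(data$counts)))
    if (is.null(dim(E))) E <- matrix(E, nrow = 1)
    Z <- E - rowMeans(E)
  }
  nrm <- sqrt(rowSums(Z^2))
  ok <- nrm > 0
  Z[ok, ] <- Z[ok, , drop = FALSE] / nrm[ok]
  Z[!ok, ] <- 0
  Z
}

# weight + mask for all unordered pairs; deterministic under parallelism
pair_weights <- function(Zn, idx, g_eff, alpha, workers) {
  G <- length(idx)
  pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  one_pair <- function(p) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    zi <- Zn[idx[[i]], , drop = FALSE]
    zj <- Zn[idx[[j]], , drop = FALSE]
    pp <- tcrossprod(zi); qq <- tcrossprod(zj); pq <- tcrossprod(zi, zj)
    pp <- clip_corr(pp, unit_diag = TRUE)
    qq <- clip_corr(qq, unit_diag = TRUE)
    pq <- clip_corr(pq)
    xi <- canonical_correlations(block_correlation(pp, pq, qq))
    test <- significance_sequence(xi, nrow(pp), nrow(qq), g_eff, alpha)
    c(pair_weight(xi, test), test$n_significant >= 1L)
  }
  workers <- max(1L, as.integer(workers))
  np <- nrow(pairs)
  res <- if (workers == 1L || np < 2L) {
    lapply(seq_len(np), one_pair)
  } else {
    chunks <- split(seq_len(np), cut(seq_len(np), workers, labels = FALSE))
    unlist(parallel::mclapply(chunks, function(ix)
      lapply(ix, one_pair), mc.cores = workers), recursive = FALSE)
  }
  res <- do.call(rbind, res)
  W <- matrix(0, G, G); M <- matrix(FALSE, G, G)
  W[upper.tri(W)] <- ifelse(res[, 2] > 0, pmin(pmax(res[, 1], 0), 1), 0)
  M[upper.tri(M)] <- res[, 2] > 0
  W <- W + t(W); M <- M | t(M)
  list(weights = W, mask = M)
}

clip_corr <- function(m, unit_diag = FALSE) {
  m[m > 1] <- 1; m[m < -1] <- -1
  if (unit_diag) diag(m) <- 1
  m
}

# gene-level Pearson comparator: summed site counts, replicate-averaged,
# correlated across experiments; w = (1 + r)/2
pcc_weights <- function(data, alpha) {
  prof <- gene_profiles(data)
  Tn <- ncol(prof)
  r <- suppressWarnings(stats::cor(t(prof)))
  r[!is.finite(r)] <- 0
  r <- clip_corr(r)
  # two-sided t test of r != 0 on T experiment points
  tstat <- r * sqrt(pmax(Tn - 2, 0) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = Tn - 2, lower.tail = FALSE)
  list(weights = (1 + r) / 2, mask = p <= alpha)
}

#' @export
print.apacca <- function(x, ...) {
  cat("Gene-pair similarity (", x$measure, " engine): ",
      length(x$genes), " genes, alpha = ", x$alpha,
      ", g = ", x$g, " samples\n", sep = "")
  off <- x$weights[upper.tri(x$weights)]
  msk <- x$mask[upper.tri(x$mask)]
  cat(sprintf("  %d/%d significant pairs; weight range %.3f-%.3f\n",
              sum(msk), length(msk), min(off), max(off)))
  invisible(x)
}

#' @export
summary.apacca <- function(object, ...) {
  off <- object$weights[upper.tri(object$weights)]
  msk <- object$mask[upper.tri(object$mask)]
  out <- list(measure = object$measure, n_genes = length(object$genes),
              n_pairs = length(off), n_significant = sum(msk),
              weight_summary = summary(off), alpha = object$alpha,
              g = object$g)
  class(out) <- "summary.apacca"
  out
}

#' @export
print.summary.apacca <- function(x, ...) {
  cat("Similarity fit (", x$measure, "): ", x$n_genes, " genes, ",
      x$n_pairs, " pairs, ", x$n_significant, " significant at alpha = ",
      x$alpha, "\n", sep = "")
  cat("Pair weights:\n"); print(x$weight_summary)
  invisible(x)
}

#' @export
as.matrix.apacca <- function(x, ...) x$weights

#' Distance matrix from a similarity fit
#'
#' `d = 1 - w`: zero diagonal, symmetric, in `[0, 1]`.
#'
#' @param sim an [apacca()] fit or a symmetric weight matrix in `[0, 1]`.
#' @return Symmetric distance matrix.
#' @export
to_distance <- function(sim) {
  W <- if (inherits(sim, "apacca")) sim$weights else as.matrix(sim)
  if (any(W < 0 | W > 1)) stop("weights must lie in [0, 1]")
  d <- 1 - W
  diag(d) <- 0
  d
}

#' @export
as.dist.apacca <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(to_distance(m), diag = diag, upper = upper)

#' Significant gene pairs as a weighted edge list
#'
#' Unordered pairs whose leading canonical correlation is significant,
#' sorted by descending weight with lexical gene-label tie-breaking --
#' a weighted adjacency export for module-detection tools.
#'
#' @param sim an [apacca()] fit.
#' @return Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
significant_pairs <- function(sim) {
  stopifnot(inherits(sim, "apacca"))
  ut <- which(upper.tri(sim$weights), arr.ind = TRUE)
  keep <- sim$mask[ut]
  ut <- ut[keep, , drop = FALSE]
  a <- sim$genes[ut[, 1L]]; b <- sim$genes[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- sim$weights[ut]
  ord <- order(-w, a, b)
  data.frame(gene_a = a[ord], gene_b = b[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' @importFrom stats as.dist
#' @export
plot.apacca <- function(x, ...) {
  W <- x$weights
  ord <- stats::hclust(stats::as.dist(to_distance(x)),
                       method = "complete")$order
  graphics::image(seq_along(x$genes), seq_along(x$genes),
                  W[ord, ord], xlab = "", ylab = "",
                  main = "Gene-pair similarity", axes = FALSE, ...)
  invisible(x)
}
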