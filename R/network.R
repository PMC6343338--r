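#' Network summaries of a weighted gene adjacency with modules
#'
#' Binarizes the weighted adjacency at `w > tau` and reports the mean
#' eigenvector centrality (EC), the mean local clustering coefficient
#' over nodes of degree >= 2 (ACC), and the Newman modularity of the
#' supplied module partition (MD).
#'
#' @param adjacency symmetric numeric matrix with weights in `[0, 1]`
#'   (e.g. the weight matrix of an [apacca()] fit) or an `apacca`
#'   object.
#' @param modules named integer/character module ids covering the
#'   adjacency's genes.
#' @param tau binarization threshold (default 0.5).
#' @return Named numeric vector `c(EC = ..., ACC = ..., MD = ...)`.
#' @export
network_metrics <- function(adjacency, modules, tau = 0.5) {
  A <- if (inherits(adjacency, "apacca")) adjacency$weights
       else as.matrix(adjacency)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8)
    stop("adjacency must be a symmetric matrix")
  if (any(A < 0 | A > 1)) stop("weights must lie in [0, 1]")
  B <- (A > tau) * 1
  diag(B) <- 0
  if (sum(B) == 0) stop("graph is empty after thresholding at tau = ", tau)
  gr <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  if (!is.null(rownames(A)) && !is.null(names(modules)))
    modules <- modules[rownames(A)]
  if (length(modules) != nrow(A) || anyNA(modules))
    stop("modules must cover every gene in the adjacency")
  ec <- mean(igraph::eigen_centrality(gr)$vector)
  deg <- igraph::degree(gr)
  loc <- igraph::transitivity(gr, type = "local", isolates = "zero")
  acc <- if (any(deg >= 2)) mean(loc[deg >= 2]) else 0
  md <- igraph::modularity(gr, membership = as.integer(factor(modules)))
  c(EC = ec, ACC = acc, MD = md)
}

#' Module eigengenes and hub genes
#'
#' The eigengene of a module is the first principal component of the
#' standardized gene x experiment expression matrix of its members,
#' with the sign chosen so that the mean gene-eigengene correlation is
#' non-negative.  Hub genes correlate with their module eigengene above
#' `threshold`.
#'
#' @param expression numeric gene x experiment matrix with gene row
#'   names (e.g. [gene_profiles()]).
#' @param modules named module ids for the expression rows.
#' @param threshold hub correlation cutoff (default 0.7).
#' @return Named list per module: list with `eigengene` (length-T
#'   vector), `correlations` (per member gene) and `hubs` (character
#'   vector).  Modules of size 1 are skipped with a warning.
#' @export
module_eigengene_hubs <- function(expression, modules, threshold = 0.7) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    stop("expression must have gene row names")
  modules <- modules[rownames(expression)]
  out <- list()
  for (mod in unique(modules)) {
    members <- rownames(expression)[modules == mod]
    if (length(members) < 2L) {
      warning("module '", mod, "' has fewer than 2 genes; skipped")
      next
    }
    X <- expression[members, , drop = FALSE]
    mu <- rowMeans(X)
    sdv <- apply(X, 1, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- (X - mu) / sdv
    sv <- svd(Xs)
    eig <- sv$v[, 1L]
    cors <- suppressWarnings(apply(X, 1, function(x) stats::cor(x, eig)))
    cors[!is.finite(cors)] <- 0
    if (mean(cors) < 0) { eig <- -eig; cors <- -cors }
    out[[as.character(mod)]] <- list(
      eigengene = eig, correlations = cors,
      hubs = members[cors > threshold])
  }
  out
}
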