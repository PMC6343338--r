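#' Hierarchical clustering of genes from a distance matrix
#'
#' Agglomerative clustering with complete linkage (the conventional
#' default for correlation-derived gene distances), cut at each
#' requested number of clusters.
#'
#' @param dist symmetric distance matrix (zero diagonal), a `dist`
#'   object, or an [apacca()] fit.
#' @param k_range integer vector of cluster counts to cut at.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return Object of class `"apa_clustering"`: list with `tree`
#'   (the `hclust` object), `assignments` (named list, one named
#'   integer vector per k) and `k_range`.
#' @export
hierarchical_cluster <- function(dist, k_range = 2:10,
                                 linkage = "complete") {
  d <- as_dist_input(dist)
  G <- attr(d, "Size")
  k_range <- as.integer(k_range)
  if (any(k_range < 1L) || any(k_range > G))
    stop("k_range must lie within [1, number of genes]")
  tree <- stats::hclust(d, method = linkage)
  cuts <- lapply(k_range, function(k) stats::cutree(tree, k = k))
  names(cuts) <- as.character(k_range)
  structure(list(tree = tree, assignments = cuts, k_range = k_range,
                 linkage = linkage),
            class = "apa_clustering")
}

#' @export
print.apa_clustering <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage), cut at k = ",
      paste(x$k_range, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_dist_input <- function(dist) {
  if (inherits(dist, "apacca")) return(stats::as.dist(to_distance(dist)))
  if (inherits(dist, "dist")) return(dist)
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 ||
      any(abs(diag(m)) > 1e-12))
    stop("need a symmetric distance matrix with zero diagonal")
  stats::as.dist(m)
}

#' Estimate the number of clusters by mean silhouette width
#'
#' Cuts the complete-linkage tree at every k in `k_range` and returns
#' the k with the largest mean silhouette width; ties go to the
#' smallest k.
#'
#' @inheritParams hierarchical_cluster
#' @param k_range candidate cluster counts, within `[2, G - 1]`.
#' @return The selected k (integer).
#' @export
estimate_k <- function(dist, k_range = 5:20, linkage = "complete") {
  d <- as_dist_input(dist)
  G <- attr(d, "Size")
  k_range <- sort(as.integer(k_range))
  k_range <- k_range[k_range >= 2L & k_range <= G - 1L]
  if (!length(k_range)) stop("no admissible k in k_range")
  cl <- hierarchical_cluster(d, k_range, linkage)
  sil <- vapply(cl$assignments, function(a)
    mean(cluster::silhouette(a, d)[, "sil_width"]), numeric(1))
  k_range[which.max(sil)]   # which.max takes the first (smallest k) on ties
}

#' Connectivity of a clustering (lower is better)
#'
#' Penalises observations whose nearest neighbours fall in other
#' clusters: the j-th nearest neighbour of i (ties broken by index)
#' contributes 1/j when it is assigned to a different cluster than i.
#'
#' @param dist distance input as in [hierarchical_cluster()].
#' @param assignment integer cluster ids, one per observation.
#' @param L number of nearest neighbours to examine (default 10).
#' @return Non-negative connectivity score.
#' @export
connectivity <- function(dist, assignment, L = 10L) {
  m <- as.matrix(as_dist_input(dist))
  G <- nrow(m)
  L <- as.integer(L)
  if (L >= G) stop("L must be smaller than the number of observations")
  total <- 0
  for (i in seq_len(G)) {
    nn <- order(m[i, -i])            # stable: ties keep index order
    nn <- seq_len(G)[-i][nn][seq_len(L)]
    diff_cl <- assignment[nn] != assignment[i]
    total <- total + sum(diff_cl / seq_len(L))
  }
  total
}

#' Dunn index (higher is better)
#'
#' Smallest between-cluster point-pair distance divided by the largest
#' within-cluster diameter.  Scale invariant.
#'
#' @inheritParams connectivity
#' @return Positive Dunn index.
#' @export
dunn_index <- function(dist, assignment) {
  m <- as.matrix(as_dist_input(dist))
  same <- outer(assignment, assignment, "==")
  diag(same) <- NA
  intra <- m[same & !is.na(same)]
  inter <- m[!same & !is.na(same)]
  if (!length(inter)) stop("need at least two clusters")
  diam <- if (length(intra)) max(intra) else 0
  if (diam == 0)
    stop("degenerate clustering: maximum within-cluster diameter is 0")
  min(inter) / diam
}

#' Stability indices AD and ADM under experiment deletion
#'
#' Deletes each experiment (with all of its replicate columns) in turn,
#' recomputes the similarity with the same engine, re-clusters at `k`,
#' and compares with the full-data clustering.  `AD` averages, over
#' deletions and observations, the full-data distance between an
#' observation and the others sharing its perturbed cluster (singleton
#' perturbed clusters are skipped).  `ADM` averages the Euclidean
#' distance between an observation's cluster centre (mean gene-level
#' expression profile over experiments) in the full versus the
#' perturbed clustering.  Lower is better for both.
#'
#' @param data a filtered, quantified [pac_dataset()] with at least 3
#'   experiments.
#' @param k number of clusters.
#' @param measure,alpha similarity engine options, as in [apacca()].
#' @param linkage linkage method.
#' @return Named numeric vector `c(AD = ..., ADM = ...)`.
#' @export
ad_adm <- function(data, k, measure = "scca", alpha = 0.05,
                   linkage = "complete") {
  stopifnot(inherits(data, "pac_dataset"))
  if (data$design$n_experiments < 3L)
    stop("stability validation needs at least 3 experiments")
  full_fit <- apacca(data, measure = measure, alpha = alpha)
  d_full <- to_distance(full_fit)
  full_cl <- hierarchical_cluster(d_full, k, linkage)$assignments[[1L]]
  prof <- gene_profiles(data)
  centers_full <- cluster_centers(prof, full_cl)

  ad_vals <- c(); adm_vals <- c()
  for (e in data$design$experiments) {
    sub <- drop_experiment(data, e)
    fit <- apacca(sub, measure = measure, alpha = alpha)
    pert_cl <- hierarchical_cluster(to_distance(fit), k,
                                    linkage)$assignments[[1L]]
    centers_pert <- cluster_centers(prof, pert_cl)
    for (i in seq_along(pert_cl)) {
      mates <- which(pert_cl == pert_cl[i])
      mates <- mates[mates != i]
      if (length(mates))
        ad_vals <- c(ad_vals, mean(d_full[i, mates]))
      adm_vals <- c(adm_vals,
                    sqrt(sum((centers_full[as.character(full_cl[i]), ] -
                              centers_pert[as.character(pert_cl[i]), ])^2)))
    }
  }
  c(AD = mean(ad_vals), ADM = mean(adm_vals))
}

cluster_centers <- function(prof, assignment) {
  agg <- rowsum(prof, assignment) / as.vector(table(assignment))
  rownames(agg) <- names(table(assignment))
  agg
}

# subset a dataset to all experiments except `drop`
drop_experiment <- function(data, drop) {
  keep <- data$design$samples$experiment != drop
  design <- experiment_design(data$design$samples[keep, , drop = FALSE])
  pac_dataset(data$sites, data$counts[, keep, drop = FALSE], design,
              quantification = data$quantification)
}

#' Biological homogeneity index (higher is better)
#'
#' For every cluster with at least two annotated genes, the fraction of
#' ordered pairs of distinct annotated genes that share at least one
#' functional class; BHI is the average over eligible clusters.
#'
#' @param assignment named integer cluster ids (names = genes).
#' @param annotation named list: per gene, a character vector of
#'   classes (see [read_annotation()]).
#' @return BHI in `[0, 1]`.
#' @export
bhi <- function(assignment, annotation) {
  if (is.null(names(assignment))) stop("assignment must be named by gene")
  fracs <- c()
  for (cl in unique(assignment)) {
    members <- names(assignment)[assignment == cl]
    ann <- members[members %in% names(annotation)]
    if (length(ann) < 2L) next
    share <- 0L; total <- 0L
    for (a in ann) for (b in ann) {
      if (a == b) next
      total <- total + 1L
      if (length(intersect(annotation[[a]], annotation[[b]])))
        share <- share + 1L
    }
    fracs <- c(fracs, share / total)
  }
  if (!length(fracs))
    stop("no cluster has two or more annotated genes")
  mean(fracs)
}

#' Min-max normalization of validation scores across compared settings
#'
#' Rescales each metric column to `[0, 1]` over all compared
#' (method, k) cells, flipping lower-is-better metrics (CON, AD, ADM)
#' so that larger always means better; constant columns map to 0.5.
#'
#' @param scores data frame of raw validation scores; non-metric
#'   columns (e.g. `method`, `k`) are passed through.
#' @param lower_better metric columns where smaller raw values are
#'   better.
#' @return Data frame of the same shape with metric columns normalized.
#' @export
normalize_scores <- function(scores,
                             lower_better = c("CON", "AD", "ADM")) {
  out <- scores
  for (col in names(scores)) {
    x <- scores[[col]]
    if (!is.numeric(x) || col %in% c("k")) next
    rng <- range(x)
    y <- if (rng[1] == rng[2]) rep(0.5, length(x))
         else (x - rng[1]) / (rng[2] - rng[1])
    if (col %in% lower_better && rng[1] != rng[2]) y <- 1 - y
    out[[col]] <- y
  }
  out
}
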