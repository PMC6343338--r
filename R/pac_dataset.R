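#' Poly(A)-site count data set
#'
#' Container for a site-by-sample count matrix together with the
#' site-to-gene map and the experiment/replicate design.  Counts may be
#' non-integer (normalised abundances are admitted); validation only
#' enforces non-negativity.
#'
#' @param sites data frame with columns `site_id`, `gene_id` and
#'   optionally `chrom`, `strand` (`+`/`-`) and `position` (1-based;
#'   coordinates are carried but never used in computation).
#' @param counts numeric matrix, one row per site and one column per
#'   design sample (column order follows the design).
#' @param design an [experiment_design()] object.
#' @param quantification one of `"raw"`, `"abundance"`, `"relative"`.
#' @return An object of class `"pac_dataset"`.
#' @seealso [read_pac_table()], [filter_sites()], [quantify()]
#' @export
pac_dataset <- function(sites, counts, design,
                        quantification = c("raw", "abundance", "relative")) {
  quantification <- match.arg(quantification)
  sites <- as.data.frame(sites)
  if (!all(c("site_id", "gene_id") %in% names(sites)))
    stop("'sites' needs columns site_id and gene_id")
  sites$site_id <- as.character(sites$site_id)
  sites$gene_id <- as.character(sites$gene_id)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "))
  if ("strand" %in% names(sites) &&
      !all(sites$strand %in% c("+", "-", NA)))
    stop("strand must be '+' or '-'")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(sites))
    stop("counts must have one row per site")
  if (ncol(counts) != design$n_samples)
    stop("design mismatch: counts has ", ncol(counts),
         " columns but the design describes ", design$n_samples, " samples")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  rownames(counts) <- sites$site_id
  colnames(counts) <- design$samples$sample
  if (quantification == "relative")
    check_relative_sums(counts, sites$gene_id)
  structure(list(sites = sites, counts = counts, design = design,
                 quantification = quantification),
            class = "pac_dataset")
}

check_relative_sums <- function(counts, gene_id, tol = 1e-9) {
  sums <- rowsum(counts, gene_id)
  bad <- abs(sums - 1) > tol & abs(sums) > tol
  if (any(bad))
    stop("relative quantification: per-(gene, sample) site values must ",
         "sum to 1 (or all be 0)")
  invisible(TRUE)
}

#' @export
print.pac_dataset <- function(x, ...) {
  cat("Poly(A)-site data set:", nrow(x$counts), "sites,",
      length(unique(x$sites$gene_id)), "genes,",
      ncol(x$counts), "samples\n")
  cat("  quantification:", x$quantification, "\n")
  print(x$design)
  invisible(x)
}

#' @export
dim.pac_dataset <- function(x) dim(x$counts)

#' Number of genes in a poly(A)-site data set
#' @param data a [pac_dataset()].
#' @return Integer count of distinct genes.
#' @export
n_genes <- function(data) length(unique(data$sites$gene_id))

# row indices per gene, preserving site order; genes in first-appearance order
gene_site_index <- function(data) {
  split(seq_len(nrow(data$counts)),
        factor(data$sites$gene_id, levels = unique(data$sites$gene_id)))
}

#' Gene-level expression profiles
#'
#' Sums counts over each gene's sites per sample, then averages the
#' replicates within each experiment, giving a gene x experiment matrix.
#' This is the "overall expression" representation used by gene-level
#' correlation comparisons and by cluster-center computations.
#'
#' @param data a [pac_dataset()].
#' @return Numeric matrix, genes x experiments.
#' @export
gene_profiles <- function(data) {
  per_sample <- rowsum(data$counts,
                       factor(data$sites$gene_id,
                              levels = unique(data$sites$gene_id)))
  cols <- design_columns(data$design)
  prof <- vapply(cols, function(j) rowMeans(per_sample[, j, drop = FALSE]),
                 numeric(nrow(per_sample)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  dimnames(prof) <- list(rownames(per_sample), data$design$experiments)
  prof
}
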