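#' Filter low-abundance sites and single-site genes
#'
#' Removes poly(A) sites supported by fewer than `min_reads` reads in
#' total over all samples, then drops genes left with fewer than two
#' sites (a single-site gene carries no site-usage signal).  An optional
#' `gene_list` restricts the result to externally selected genes, e.g.
#' genes with at least one differentially used site from an external
#' differential-usage test.
#'
#' @param data a [pac_dataset()] with raw counts.
#' @param min_reads minimum total read support per site (default 5).
#' @param gene_list optional character vector of gene ids to keep.
#' @return A list with elements `data` (the filtered [pac_dataset()],
#'   site order preserved) and `report` (named counts of what was
#'   removed).
#' @export
filter_sites <- function(data, min_reads = 5, gene_list = NULL) {
  stopifnot(inherits(data, "pac_dataset"))
  if (data$quantification != "raw")
    stop("filter_sites expects raw counts")
  n_in <- nrow(data$counts)
  genes_in <- unique(data$sites$gene_id)

  keep_site <- rowSums(data$counts) >= min_reads
  n_low <- sum(!keep_site)

  gid <- data$sites$gene_id[keep_site]
  sites_per_gene <- table(gid)
  multi <- names(sites_per_gene)[sites_per_gene >= 2L]
  n_single_genes <- length(setdiff(unique(gid), multi))
  keep_site[keep_site] <- gid %in% multi

  n_not_selected <- 0L
  if (!is.null(gene_list)) {
    sel <- data$sites$gene_id %in% gene_list
    n_not_selected <- length(setdiff(unique(data$sites$gene_id[keep_site]),
                                     gene_list))
    keep_site <- keep_site & sel
  }

  report <- list(
    n_sites_in = n_in,
    n_sites_removed_low_abundance = n_low,
    n_genes_removed_single_site = n_single_genes,
    n_genes_removed_not_selected = n_not_selected,
    n_sites_out = sum(keep_site),
    n_genes_out = length(unique(data$sites$gene_id[keep_site])))

  if (report$n_genes_out == 0L) {
    err <- simpleError("filtering removed every gene")
    err$report <- report
    stop(err)
  }
  out <- pac_dataset(data$sites[keep_site, , drop = FALSE],
                     data$counts[keep_site, , drop = FALSE],
                     data$design, quantification = "raw")
  list(data = out, report = report)
}

#' Quantify poly(A) sites by abundance or relative usage
#'
#' `"abundance"` keeps the read counts as-is.  `"relative"` converts, for
#' each gene and sample, each site's count into its fraction of the
#' gene's total in that sample (site usage); genes with a zero total in
#' a sample get 0 for all their sites there, keeping downstream
#' variances finite.
#'
#' @param data a filtered [pac_dataset()] (every gene with >= 2 sites).
#' @param mode `"abundance"` or `"relative"`.
#' @return A [pac_dataset()] with the chosen quantification.
#' @export
quantify <- function(data, mode = c("abundance", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "pac_dataset"))
  if (mode == "abundance") {
    data$quantification <- "abundance"
    return(data)
  }
  gene <- factor(data$sites$gene_id, levels = unique(data$sites$gene_id))
  totals <- rowsum(data$counts, gene)[as.integer(gene), , drop = FALSE]
  rel <- ifelse(totals > 0, data$counts / totals, 0)
  pac_dataset(data$sites, rel, data$design, quantification = "relative")
}
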