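#' Read a poly(A)-site count table and its sample sheet
#'
#' Both files are tab-delimited UTF-8 with a header row; lines starting
#' with `#` are ignored.  The count table has columns `site_id`,
#' `gene_id`, optional `chrom`/`strand`/`position`, and one count column
#' per sample.  The sample sheet has columns `sample`, `experiment`,
#' `replicate` and must cover exactly the count columns; the returned
#' sample order follows the sheet.
#'
#' @param path path to the count table.
#' @param sample_sheet_path path to the sample sheet.
#' @return A [pac_dataset()] with `quantification = "raw"`.
#' @export
read_pac_table <- function(path, sample_sheet_path) {
  tab <- read_tsv(path)
  sheet <- read_tsv(sample_sheet_path)
  design <- experiment_design(sheet)
  meta_cols <- intersect(c("site_id", "gene_id", "chrom", "strand", "position"),
                         names(tab))
  if (!all(c("site_id", "gene_id") %in% meta_cols))
    stop("count table needs columns site_id and gene_id")
  count_cols <- setdiff(names(tab), meta_cols)
  missing <- setdiff(design$samples$sample, count_cols)
  extra <- setdiff(count_cols, design$samples$sample)
  if (length(missing) || length(extra))
    stop("design mismatch between table and sample sheet",
         if (length(missing)) paste0("; missing columns: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected columns: ",
                                   paste(extra, collapse = ", ")))
  counts <- as.matrix(tab[, design$samples$sample, drop = FALSE])
  if (!is.numeric(counts)) stop("count columns must be numeric")
  pac_dataset(tab[, meta_cols, drop = FALSE], counts, design,
              quantification = "raw")
}

#' Write a poly(A)-site data set as a tab-delimited table
#'
#' Inverse of [read_pac_table()]: `read_pac_table(write_pac_table(x))`
#' restores identical counts and design.
#'
#' @param data a [pac_dataset()].
#' @param path output path for the count table.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_pac_table <- function(data, path, sample_sheet_path = NULL) {
  out <- cbind(data$sites, as.data.frame(data$counts))
  write_tsv(out, path)
  if (!is.null(sample_sheet_path))
    write_tsv(data$design$samples, sample_sheet_path)
  invisible(path)
}

#' Read/write a symmetric labelled matrix (weights or distances)
#'
#' Tab-delimited with row and column gene labels; round trips are exact
#' to within 1e-12.
#'
#' @param m square numeric matrix with identical, unique row/column names.
#' @param path file path.
#' @return `read_matrix` returns the labelled matrix; `write_matrix`
#'   returns `path` invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("matrix must carry identical row and column labels")
  if (anyDuplicated(rownames(m))) stop("labels must be unique")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != ncol(m)) stop("file does not hold a square matrix")
  m
}

#' Read/write gene cluster assignments
#'
#' Two-column tab-delimited file (`gene`, `cluster`), ordered by gene
#' label for deterministic output.
#'
#' @param assignment named vector (names = genes, values = cluster ids).
#' @param path file path.
#' @return `read_clusters` returns a named integer vector;
#'   `write_clusters` returns `path` invisibly.
#' @export
write_clusters <- function(assignment, path) {
  if (length(assignment) == 0L) stop("empty cluster assignment")
  if (is.null(names(assignment))) stop("assignment must be named by gene")
  ord <- order(names(assignment))
  df <- data.frame(gene = names(assignment)[ord],
                   cluster = unname(assignment)[ord])
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- read_tsv(path)
  stats::setNames(as.integer(df$cluster), as.character(df$gene))
}

#' Read a gene-to-functional-class annotation table
#'
#' Tab-delimited with columns `gene` and `class`, one row per
#' gene-class pair (genes may carry several classes).
#'
#' @param path file path.
#' @return Named list: per gene, a character vector of classes.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene", "class") %in% names(df)))
    stop("annotation table needs columns gene and class")
  lapply(split(as.character(df$class), as.character(df$gene)), unique)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}
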