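#' Experiment/replicate design for a poly(A)-site data set
#'
#' Describes how the sample columns of a count table map onto `T`
#' experiments (conditions, tissues, time points ...) with `R(t)`
#' replicates each.  Every downstream statistic -- replicate means and
#' variances, the shrinkage factor, the shrinkage-weighted correlation --
#' is indexed by this design.
#'
#' @param samples data frame with columns `sample` (unique sample ids, in
#'   the order of the count columns), `experiment` (experiment label) and
#'   `replicate` (1-based replicate index within the experiment).
#' @return An object of class `"apa_design"`: a list with elements
#'   `experiments` (ordered unique labels, length `T`), `replicates_of`
#'   (named integer vector, `R(t)` per experiment), `samples` (the
#'   validated data frame), `n_experiments` and `n_samples`.
#' @examples
#' sheet <- data.frame(sample = c("s1", "s2", "s3", "s4"),
#'                     experiment = c("root", "root", "leaf", "leaf"),
#'                     replicate = c(1, 2, 1, 2))
#' experiment_design(sheet)
#' @export
experiment_design <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample", "experiment", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  samples$sample <- as.character(samples$sample)
  samples$experiment <- as.character(samples$experiment)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in sample sheet")
  experiments <- unique(samples$experiment)
  if (length(experiments) < 2L)
    stop("design must contain at least two experiments (T >= 2)")
  reps <- vapply(experiments, function(e) {
    r <- sort(samples$replicate[samples$experiment == e])
    if (!identical(r, seq_along(r)))
      stop("replicate indices for experiment '", e,
           "' must be 1..R(t) with no gaps")
    length(r)
  }, integer(1))
  names(reps) <- experiments
  structure(list(experiments   = experiments,
                 replicates_of = reps,
                 samples       = samples,
                 n_experiments = length(experiments),
                 n_samples     = nrow(samples)),
            class = "apa_design")
}

#' @export
print.apa_design <- function(x, ...) {
  cat("Experiment design:", x$n_experiments, "experiments,",
      x$n_samples, "samples\n")
  cat("  replicates:",
      paste0(x$experiments, "=", x$replicates_of, collapse = ", "), "\n")
  invisible(x)
}

# column indices of each experiment's samples, in design order
design_columns <- function(design) {
  lapply(design$experiments, function(e)
    which(design$samples$experiment == e))
}
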