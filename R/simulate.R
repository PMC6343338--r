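#' Configuration for the poly(A)-site simulator
#'
#' Collects the study-design and noise parameters of the two-step
#' generator: (1) per experiment, each site's abundance is drawn from a
#' binomial with the gene's total depth and the site's usage
#' probability; (2) replicates add normal noise around the experiment
#' value.  An optional planted design groups genes into clusters that
#' share per-experiment shifts of their site-usage log-odds.
#'
#' @param n_genes number of genes to simulate.
#' @param n_experiments number of experiments `T` (>= 2).
#' @param replicates replicates per experiment: a scalar or a length-T
#'   vector `R(t)`.
#' @param noise_mean mean of the replicate noise (default 0).
#' @param noise_scale scale `c` of the default heteroscedastic noise sd
#'   `c * sqrt(base + 1)` (default 0.5, a Poisson-like spread).
#' @param noise_sd optional fixed noise sd overriding `noise_scale`.
#' @param sites_min,sites_max range of sites per generated gene
#'   (uniform; defaults 2 and 4).
#' @param usage_concentration symmetric Dirichlet concentration of the
#'   site-usage probabilities (default 1 = uniform over the simplex;
#'   larger values give balanced usage where every site is informative).
#' @param depth_meanlog,depth_sdlog log-normal parameters of the
#'   per-gene total read depth (defaults log(200) and 0.8; `sdlog = 0`
#'   gives a uniform depth).
#' @param n_clusters,effect planted design: number of clusters and the
#'   log-odds effect size of the shared per-experiment usage shifts
#'   (`effect = 0` or `n_clusters = NULL` plants no structure).
#' @param seed integer seed; a fixed seed makes every generator output
#'   bit-reproducible.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 100L, n_experiments = 8L,
                              replicates = 3L, noise_mean = 0,
                              noise_scale = 0.5, noise_sd = NULL,
                              sites_min = 2L, sites_max = 4L,
                              usage_concentration = 1,
                              depth_meanlog = log(200), depth_sdlog = 0.8,
                              n_clusters = NULL, effect = 0,
                              seed = 1L) {
  if (n_experiments < 2L) stop("need at least two experiments")
  if (sites_min < 2L) stop("simulated genes need at least two sites")
  if (sites_max < sites_min) stop("sites_max must be >= sites_min")
  replicates <- as.integer(replicates)
  if (length(replicates) == 1L)
    replicates <- rep(replicates, n_experiments)
  if (length(replicates) != n_experiments || any(replicates < 1L))
    stop("replicates must be a scalar or length-T vector of counts >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_experiments = as.integer(n_experiments),
                 replicates = replicates, noise_mean = noise_mean,
                 noise_scale = noise_scale, noise_sd = noise_sd,
                 sites_min = as.integer(sites_min),
                 sites_max = as.integer(sites_max),
                 usage_concentration = usage_concentration,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 n_clusters = n_clusters, effect = effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

config_design <- function(config) {
  experiments <- sprintf("exp%d", seq_len(config$n_experiments))
  samples <- do.call(rbind, lapply(seq_along(experiments), function(t)
    data.frame(sample = sprintf("%s_r%d", experiments[t],
                                seq_len(config$replicates[t])),
               experiment = experiments[t],
               replicate = seq_len(config$replicates[t]))))
  experiment_design(samples)
}

#' Site-usage profiles estimated from observed counts
#'
#' Per gene: usage probabilities `p(i) = a(i) / sum(a)` from counts
#' summed over all samples, and total depth `N = round(sum(a))`.
#' These profiles seed the simulator so that synthetic data reproduce
#' the observed abundance distribution.
#'
#' @param data a filtered [pac_dataset()].
#' @return List of per-gene profiles: `gene_id`, `p` (site-usage
#'   probabilities, named by site), `size` (total depth).
#' @export
profile_from_counts <- function(data) {
  stopifnot(inherits(data, "pac_dataset"))
  idx <- gene_site_index(data)
  lapply(names(idx), function(g) {
    a <- rowSums(data$counts[idx[[g]], , drop = FALSE])
    tot <- sum(a)
    if (tot <= 0) stop("gene '", g, "' has zero total count")
    list(gene_id = g, p = a / tot, size = max(1L, round(tot)))
  })
}

# random profiles for de novo simulation (Dirichlet usage, log-normal depth)
random_profiles <- function(config) {
  lapply(seq_len(config$n_genes), function(i) {
    ks <- seq(config$sites_min, config$sites_max)
    k <- if (length(ks) == 1L) ks else sample(ks, 1L)
    gam <- stats::rgamma(k, shape = config$usage_concentration)
    p <- gam / sum(gam)
    names(p) <- sprintf("g%04d_s%d", i, seq_len(k))
    size <- max(20L, round(stats::rlnorm(1, config$depth_meanlog,
                                         config$depth_sdlog)))
    list(gene_id = sprintf("g%04d", i), p = p, size = size)
  })
}

#' Simulate a replicated poly(A)-site data set
#'
#' For every gene, experiment and site, a base abundance is drawn from
#' `Binomial(N, p_i)` (independently per site, so a gene's simulated
#' site counts need not sum to `N`); each replicate observes the base
#' value plus normal noise, rounded and clipped at zero.
#'
#' @param profiles per-gene profiles from [profile_from_counts()] or
#'   `NULL` to draw random profiles per the config.
#' @param config a [simulation_config()].
#' @param usage_shift optional function `(p, gene_index, experiment
#'   index) -> p` perturbing usage probabilities per experiment (used
#'   by the planted-cluster generator).
#' @return A [pac_dataset()] with raw counts.
#' @export
simulate_dataset <- function(profiles = NULL, config = simulation_config(),
                             usage_shift = NULL) {
  set.seed(config$seed)
  if (is.null(profiles)) profiles <- random_profiles(config)
  design <- config_design(config)
  Tn <- config$n_experiments
  sd_of <- function(base)
    if (!is.null(config$noise_sd)) rep(config$noise_sd, length(base))
    else config$noise_scale * sqrt(base + 1)

  rows <- list(); counts <- list()
  for (gi in seq_along(profiles)) {
    pr <- profiles[[gi]]
    k <- length(pr$p)
    site_ids <- if (!is.null(names(pr$p))) names(pr$p)
                else sprintf("%s_s%d", pr$gene_id, seq_len(k))
    mat <- matrix(0, k, design$n_samples)
    col <- 0L
    for (t in seq_len(Tn)) {
      p_t <- if (is.null(usage_shift)) pr$p else usage_shift(pr$p, gi, t)
      base <- stats::rbinom(k, pr$size, p_t)
      for (r in seq_len(config$replicates[t])) {
        col <- col + 1L
        noise <- stats::rnorm(k, config$noise_mean, sd_of(base))
        mat[, col] <- pmax(0, round(base + noise))
      }
    }
    rows[[gi]] <- data.frame(site_id = site_ids, gene_id = pr$gene_id)
    counts[[gi]] <- mat
  }
  pac_dataset(do.call(rbind, rows), do.call(rbind, counts), design,
              quantification = "raw")
}

#' Simulate a data set with planted gene clusters
#'
#' Genes in the same cluster share a per-experiment effect vector that
#' shifts their site-usage log-odds (each site carries a fixed centred
#' loading), so co-clustered genes co-vary across experiments while
#' keeping independent binomial and replicate-noise draws.  With
#' `effect = 0` there is no structure and any clustering agrees with
#' the truth only at chance level.
#'
#' @param config a [simulation_config()] with `n_clusters` set.
#' @return List with `data` (a [pac_dataset()]) and `labels` (named
#'   integer vector of true cluster ids partitioning all genes).
#' @export
planted_cluster_dataset <- function(config) {
  if (is.null(config$n_clusters) || config$n_clusters < 1L)
    stop("config must set n_clusters")
  set.seed(config$seed)
  profiles <- random_profiles(config)
  labels <- rep(seq_len(config$n_clusters),
                length.out = config$n_genes)
  # shared per-cluster experiment effects; per-gene fixed site loadings
  delta <- matrix(stats::rnorm(config$n_clusters * config$n_experiments),
                  config$n_clusters, config$n_experiments)
  loadings <- lapply(profiles, function(pr) {
    k <- length(pr$p)
    l <- seq_len(k) - (k + 1) / 2
    l / sqrt(sum(l^2))
  })
  shift <- function(p, gi, t) {
    eta <- log(pmax(p, 1e-12)) +
      config$effect * loadings[[gi]] * delta[labels[gi], t]
    e <- exp(eta - max(eta))
    e / sum(e)
  }
  # re-seed so the count draws do not depend on how many genes exist
  config2 <- config; config2$seed <- config$seed + 1L
  data <- simulate_dataset(profiles, config2, usage_shift = shift)
  names(labels) <- vapply(profiles, `[[`, character(1), "gene_id")
  list(data = data, labels = labels)
}
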