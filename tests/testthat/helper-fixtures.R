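# shared fixture builders; everything is generated in code

make_design <- function(Tn, reps) {
  if (length(reps) == 1L) reps <- rep(reps, Tn)
  experiment_design(do.call(rbind, lapply(seq_len(Tn), function(t)
    data.frame(sample = sprintf("e%d_r%d", t, seq_len(reps[t])),
               experiment = sprintf("e%d", t),
               replicate = seq_len(reps[t])))))
}

# small random dataset with every gene having n_sites in sites range
make_random_data <- function(n_genes = 6, Tn = 6, reps = 2, seed = 1,
                             sites = 2:3) {
  set.seed(seed)
  design <- make_design(Tn, reps)
  rows <- list(); counts <- list()
  for (i in seq_len(n_genes)) {
    k <- if (length(sites) == 1) sites else sample(sites, 1)
    rows[[i]] <- data.frame(site_id = sprintf("g%02d_s%d", i, seq_len(k)),
                            gene_id = sprintf("g%02d", i))
    counts[[i]] <- matrix(rpois(k * design$n_samples, 50), k)
  }
  pac_dataset(do.call(rbind, rows), do.call(rbind, counts), design)
}

# random joint correlation block via a wide data matrix (always PSD)
make_random_block <- function(m, n, obs = 50, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(obs * (m + n)), obs)
  R <- cor(X)
  block_correlation(R[1:m, 1:m, drop = FALSE],
                    R[1:m, m + 1:n, drop = FALSE],
                    R[m + 1:n, m + 1:n, drop = FALSE])
}

# independent oracle: canonical correlations as singular values of
# Spp^(-1/2) Spq Sqq^(-1/2), with eigendecomposition-based inverse roots
oracle_cca <- function(block, tol = 1e-10) {
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > tol * max(e$values)
    e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep]))
  }
  sv <- svd(inv_sqrt(block$pp) %*% block$pq %*% inv_sqrt(block$qq))$d
  k <- min(nrow(block$pp), nrow(block$qq))
  sort(pmin(sv, 1), decreasing = TRUE)[seq_len(k)]
}

# the controlled planted-cluster fixture used for recovery experiments:
# two-site genes, balanced usage, uniform deep coverage, usage-space
# analysis -- conditions under which every gene is informative
recovery_config <- function(seed, n_genes = 150) {
  simulation_config(n_genes = n_genes, n_experiments = 8, replicates = 3,
                    sites_min = 2, sites_max = 2, usage_concentration = 5,
                    depth_meanlog = log(1000), depth_sdlog = 0,
                    n_clusters = 3, effect = 1.5, seed = seed)
}

# adjusted Rand index between two labelings (chance-corrected agreement)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_ind <- si * sj / n
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}
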