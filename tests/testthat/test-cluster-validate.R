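weights_to_dist <- function(w) {
  d <- 1 - w; diag(d) <- 0; d
}

test_that("hierarchical cuts respect obvious separation and bounds", {
  W <- matrix(0.1, 3, 3); W[1, 2] <- W[2, 1] <- 0.9; diag(W) <- 1
  dimnames(W) <- list(paste0("g", 1:3), paste0("g", 1:3))
  d <- weights_to_dist(W)
  cl <- hierarchical_cluster(d, 1:3)
  a2 <- cl$assignments[["2"]]
  expect_equal(a2[["g1"]], a2[["g2"]])
  expect_false(a2[["g1"]] == a2[["g3"]])
  expect_equal(length(unique(cl$assignments[["3"]])), 3L)
  expect_equal(length(unique(cl$assignments[["1"]])), 1L)
  expect_error(hierarchical_cluster(d, 4), "k_range")
})

test_that("silhouette selects the planted number of blobs", {
  blob_dist <- function(sizes, within = 0.1, between = 0.9) {
    lab <- rep(seq_along(sizes), sizes)
    d <- ifelse(outer(lab, lab, "=="), within, between)
    diag(d) <- 0
    d
  }
  expect_equal(estimate_k(blob_dist(c(5, 5)), 2:8), 2L)
  expect_equal(estimate_k(blob_dist(c(5, 5, 5)), 2:8), 3L)
  # all distances equal: silhouette ties at 0, smallest k wins
  d <- matrix(0.5, 8, 8); diag(d) <- 0
  expect_equal(estimate_k(d, 2:6), 2L)
})

test_that("connectivity matches hand evaluation and its extremes", {
  # 4 points, clusters {1,2} and {3,4}, neighbour lists chosen by distance
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  d[1, 3] <- d[3, 1] <- 0.2   # makes 3 the 2nd neighbour of 1
  d[2, 3] <- d[3, 2] <- 0.3
  d[2, 4] <- d[4, 2] <- 0.4
  # neighbour lists: 1:(2,3), 2:(1,3), 3:(4,1), 4:(3,2)
  a <- c(1, 1, 2, 2)
  expect_equal(connectivity(d, a, L = 2), 4 * (1 / 2))

  # clusters matching the neighbour graph give zero connectivity
  d2 <- ifelse(outer(rep(1:2, each = 3), rep(1:2, each = 3), "=="), 0.1, 0.9)
  diag(d2) <- 0
  expect_equal(connectivity(d2, rep(1:2, each = 3), L = 2), 0)

  # every neighbour in a foreign cluster gives G * (1 + 1/2)
  d3 <- matrix(0.5, 4, 4); diag(d3) <- 0
  expect_equal(connectivity(d3, 1:4, L = 2), 4 * (1 + 1 / 2))
  expect_error(connectivity(d3, 1:4, L = 4), "smaller")
})

test_that("the Dunn index matches hand evaluation and is scale invariant", {
  d <- matrix(4, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 2
  a <- c(1, 1, 2, 2)
  expect_equal(dunn_index(d, a), 2)
  expect_equal(dunn_index(3 * d, a), 2)

  # overlapping clusters: min separation below max diameter
  d[1, 3] <- d[3, 1] <- 0.5
  expect_lt(dunn_index(d, a), 1)
  dz <- matrix(1, 3, 3); diag(dz) <- 0
  expect_error(dunn_index(dz, 1:3), "diameter")
})

test_that("stability indices match a brute-force oracle", {
  d <- make_random_data(n_genes = 12, Tn = 5, reps = 2, seed = 20, sites = 2)
  k <- 3
  got <- ad_adm(d, k)

  # independent re-implementation with explicit loops
  fit_full <- apacca(d)
  d_full <- weights_to_dist(fit_full$weights)
  cl_full <- cutree(hclust(as.dist(d_full), method = "complete"), k)
  prof <- gene_profiles(d)
  cen <- function(assign, cl) {
    members <- which(assign == cl)
    colMeans(prof[members, , drop = FALSE])
  }
  ad_acc <- c(); adm_acc <- c()
  for (e in d$design$experiments) {
    keep <- d$design$samples$experiment != e
    sub <- pac_dataset(d$sites, d$counts[, keep],
                       experiment_design(d$design$samples[keep, ]))
    dp <- weights_to_dist(apacca(sub)$weights)
    cl_p <- cutree(hclust(as.dist(dp), method = "complete"), k)
    for (i in seq_along(cl_p)) {
      mates <- setdiff(which(cl_p == cl_p[i]), i)
      if (length(mates)) ad_acc <- c(ad_acc, mean(d_full[i, mates]))
      adm_acc <- c(adm_acc,
                   sqrt(sum((cen(cl_full, cl_full[i]) -
                             cen(cl_p, cl_p[i]))^2)))
    }
  }
  expect_equal(got[["AD"]], mean(ad_acc), tolerance = 1e-10)
  expect_equal(got[["ADM"]], mean(adm_acc), tolerance = 1e-10)
  expect_gte(got[["AD"]], 0)
  expect_lte(got[["AD"]], max(d_full))
  expect_error(ad_adm(make_random_data(Tn = 2, seed = 1), 2), "3 experiments")
})

test_that("identical perturbed clusterings give zero centre displacement", {
  # two tight planted blobs survive any single-experiment deletion
  sim <- planted_cluster_dataset(
    simulation_config(n_genes = 10, n_experiments = 5, replicates = 2,
                      sites_min = 2, sites_max = 2, usage_concentration = 5,
                      depth_meanlog = log(1000), depth_sdlog = 0,
                      n_clusters = 2, effect = 2, seed = 3))
  got <- ad_adm(quantify(sim$data, "relative"), 2)
  expect_equal(got[["ADM"]], 0)
})

test_that("biological homogeneity counts shared-class ordered pairs", {
  ann <- list(g1 = "A", g2 = "A", g3 = "B")
  expect_equal(bhi(c(g1 = 1, g2 = 1, g3 = 1), ann), 1 / 3)
  expect_equal(bhi(c(g1 = 1, g2 = 1), ann), 1)
  expect_equal(bhi(c(g1 = 1, g3 = 1), ann), 0)
  expect_error(bhi(c(g1 = 1, g3 = 2), ann), "two or more")
  # unannotated genes are ignored, clusters averaged
  ann2 <- list(g1 = "A", g2 = "A", g4 = "B", g5 = "B")
  expect_equal(bhi(c(g1 = 1, g2 = 1, g3 = 1, g4 = 2, g5 = 2), ann2), 1)
})

test_that("score normalization rescales and orients every metric", {
  sc <- data.frame(method = c("a", "b", "c"), k = c(5, 5, 5),
                   DUNN = c(2, 4, 6), CON = c(2, 4, 6), BHI = c(1, 1, 1))
  ns <- normalize_scores(sc)
  expect_equal(ns$DUNN, c(0, 0.5, 1))
  expect_equal(ns$CON, c(1, 0.5, 0))    # lower-is-better flipped
  expect_equal(ns$BHI, rep(0.5, 3))     # constant metric
  expect_equal(ns$k, sc$k)              # passthrough columns untouched
})

test_that("network metrics agree with closed-form graph cases", {
  tri <- matrix(0.9, 3, 3); diag(tri) <- 0
  m <- network_metrics(tri, modules = rep(1, 3))
  expect_equal(m[["ACC"]], 1)

  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 0.9
  ms <- network_metrics(star, modules = rep(1, 4))
  expect_equal(ms[["ACC"]], 0)

  two_cliques <- matrix(0, 6, 6)
  two_cliques[1:3, 1:3] <- 0.9; two_cliques[4:6, 4:6] <- 0.9
  diag(two_cliques) <- 0
  mq <- network_metrics(two_cliques, modules = rep(1:2, each = 3))
  expect_equal(mq[["MD"]], 0.5)
  expect_true(mq[["EC"]] > 0 && mq[["EC"]] <= 1)

  expect_error(network_metrics(matrix(0, 3, 3), rep(1, 3)), "empty")
})

test_that("module eigengenes recover hubs from a planted latent factor", {
  # identical profiles: every gene is a hub
  X <- matrix(rep(c(1, 5, 2, 8, 3), each = 4), 4, byrow = FALSE)
  rownames(X) <- paste0("g", 1:4)
  res <- module_eigengene_hubs(X, c(g1 = 1, g2 = 1, g3 = 1, g4 = 1))
  expect_setequal(res[["1"]]$hubs, rownames(X))

  # an anti-correlated gene is never a hub
  X2 <- rbind(X, g5 = -c(1, 5, 2, 8, 3))
  res2 <- module_eigengene_hubs(X2, setNames(rep(1, 5), rownames(X2)))
  expect_false("g5" %in% res2[["1"]]$hubs)
  expect_lte(res2[["1"]]$correlations[["g5"]], 0)

  # latent factor with loading 0.95: at least 18 of 20 genes recovered
  set.seed(99)
  f <- rnorm(10)
  Y <- t(vapply(1:20, function(i)
    0.95 * f + sqrt(1 - 0.95^2) * rnorm(10), numeric(10)))
  rownames(Y) <- paste0("g", 1:20)
  res3 <- module_eigengene_hubs(Y, setNames(rep(1, 20), rownames(Y)),
                                threshold = 0.7)
  expect_gte(length(res3[["1"]]$hubs), 18)
  expect_warning(
    module_eigengene_hubs(Y, setNames(c(rep(1, 19), 2), rownames(Y))),
    "fewer than 2")
})
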