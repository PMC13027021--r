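test_that("well-separated masses are recovered exactly at k = 2", {
  m <- two_blob_profiles(n_per = 10, sep = 10, sd = 0.01, seed = 2)
  fit <- fit_gmm_tied(m, k = 2, seed = 1, n_restarts = 3)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  expect_true(all(pmax(fit$responsibilities[, 1],
                       fit$responsibilities[, 2]) > 0.999))
  matched <- fit$means[order(fit$means[, 1]), ]
  expect_equal(unname(matched), rbind(rep(0, 3), rep(10, 3)),
               tolerance = 0.05)
})

test_that("parameter counts and BIC follow the tied/full conventions", {
  m <- random_profiles(60, seed = 5)
  tied <- fit_gmm_tied(m, k = 4, seed = 1, n_restarts = 2)
  expect_equal(tied$n_params, 21)  # (k-1) + k*d + d(d+1)/2
  expect_equal(tied$bic,
               -2 * tied$log_likelihood + 21 * log(60), tolerance = 1e-12)
  full <- fit_gmm(m, k = 4, cov_mode = "full", seed = 1, n_restarts = 2)
  expect_equal(full$n_params, 39)  # (k-1) + k*d + k*d(d+1)/2
  # the full model never has lower in-sample log-likelihood
  expect_gte(full$log_likelihood, tied$log_likelihood - 1e-6)
})

test_that("EM log-likelihood is non-decreasing and the model coherent", {
  for (seed in c(3, 9, 27)) {
    m <- random_profiles(50, seed = seed, spread = 0.2)
    fit <- fit_gmm_tied(m, k = 3, seed = seed, n_restarts = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 50),
                 tolerance = 1e-9)
    expect_equal(fit$tied_covariance, t(fit$tied_covariance))
    expect_true(all(eigen(fit$tied_covariance,
                          symmetric = TRUE)$values > 0))
  }
})

test_that("tied six-component fits recover planted modules", {
  cfg <- generator_config(n_genes = 300, ratio_noise_sd = 0.03,
                          outlier_profiles = NULL,
                          n_qc_fail_error = 0, n_qc_fail_lowcount = 0,
                          integer_counts = FALSE, seed = 61)
  panel <- generate_panel(cfg)
  prof <- panel_ratio_profiles(panel)
  fit <- fit_gmm_tied(prof, k = 6, seed = 1, n_restarts = 10)
  truth <- panel$truth$cluster_id
  expect_gt(adjusted_rand_index(fit$labels, truth), 0.9)
  matched <- match_components(fit$labels, truth)
  remap <- vapply(1:6, function(j)
    unique(matched[fit$labels == j]), integer(1))
  reordered <- fit$means[order(remap), ]
  expect_lt(mean(abs(reordered - cfg$cluster_centroids)), 0.05)
})

test_that("an independent EEE mixture fit agrees on the labelling", {
  cfg <- generator_config(n_genes = 150, ratio_noise_sd = 0.04,
                          outlier_profiles = NULL,
                          n_qc_fail_error = 0, n_qc_fail_lowcount = 0,
                          integer_counts = FALSE, seed = 71)
  prof <- panel_ratio_profiles(generate_panel(cfg))
  fit <- fit_gmm_tied(prof, k = 6, seed = 2, n_restarts = 10)
  withr::local_package("mclust")
  ref <- mclust::Mclust(profile_matrix_for_test(prof), G = 6,
                        modelNames = "EEE", verbose = FALSE)
  expect_gt(adjusted_rand_index(fit$labels, ref$classification), 0.85)
})

test_that("the k-means baseline matches exhaustive partition search", {
  m <- two_blob_profiles(n_per = 3, sep = 4, sd = 0.3, seed = 8)
  labels <- fit_kmeans(m, k = 2, seed = 1, n_restarts = 10)
  inertia <- function(assign) {
    sum(vapply(unique(assign), function(cl) {
      mm <- m[assign == cl, , drop = FALSE]
      sum(sweep(mm, 2, colMeans(mm))^2)
    }, numeric(1)))
  }
  # brute force over all 2-partitions of 6 points
  best <- Inf
  for (code in 1:(2^5)) {
    assign <- c(1, as.integer(intToBits(code))[1:5] + 1)
    if (length(unique(assign)) == 2) best <- min(best, inertia(assign))
  }
  expect_equal(unname(attr(labels, "inertia")), best, tolerance = 1e-9)

  sep <- two_blob_profiles(n_per = 5, sep = 10, sd = 0.01, seed = 9)
  expect_equal(adjusted_rand_index(fit_kmeans(sep, 2, seed = 1),
                                   rep(1:2, each = 5)), 1)
  tiny <- m[1:4, ]
  expect_equal(unname(attr(fit_kmeans(tiny, 4, seed = 1), "inertia")), 0)
})

test_that("silhouette means match the per-point a/b definition", {
  m <- two_blob_profiles(n_per = 4, sep = 10, sd = 0.01, seed = 4)
  labels <- rep(1:2, each = 4)
  expect_gt(silhouette_mean(m, labels), 0.99)
  m2 <- random_profiles(8, seed = 14)
  labels2 <- c(1, 2, 1, 2, 2, 1, 3, 3)
  expect_equal(silhouette_mean(m2, labels2),
               naive_silhouette_mean(m2, labels2), tolerance = 1e-12)
  # random labels on one blob: near zero
  blob <- random_profiles(60, seed = 15, spread = 0.05)
  rnd <- withr::with_seed(5, sample(1:3, 60, replace = TRUE))
  expect_lt(abs(silhouette_mean(blob, rnd)), 0.1)
  expect_error(silhouette_mean(m, rep(1, 8)), "two clusters")
})

test_that("the ARI is exact on canonical partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  ab <- adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(ab, pair_count_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  withr::with_seed(6, {
    for (i in 1:20) {
      a <- sample(1:3, 8, replace = TRUE)
      b <- sample(1:3, 8, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   adjusted_rand_index(b, a))               # symmetric
      expect_equal(adjusted_rand_index(a, b),
                   adjusted_rand_index(4 - a, b))           # relabelling
    }
  })
  expect_error(adjusted_rand_index(1:3, 1:4), "same genes")
})

test_that("Mahalanobis distances respect the model covariance", {
  m <- two_blob_profiles(n_per = 10, sep = 5, sd = 0.2, seed = 10)
  fit <- fit_gmm_tied(m, k = 2, seed = 1, n_restarts = 3)
  rep_ <- mahalanobis_boundary(fit, m, threshold = 2.42)
  expect_true(all(rep_$mahalanobis >= 0))
  expect_setequal(rep_$gene_id, rownames(m))
  # agrees with explicit matrix-inverse computation per gene
  for (i in c(1, 7, 15)) {
    g <- rep_$gene_id[i]
    j <- rep_$cluster[i]
    expect_equal(rep_$mahalanobis[i],
                 naive_mahalanobis(m[g, ], fit$means[j, ],
                                   fit$tied_covariance),
                 tolerance = 1e-9)
  }
  # identity covariance: Mahalanobis reduces to Euclidean
  fit_id <- fit
  fit_id$tied_covariance <- diag(3)
  rep_id <- mahalanobis_boundary(fit_id, m)
  eu <- sqrt(rowSums((m[rep_id$gene_id, ] -
                        fit$means[rep_id$cluster, ])^2))
  expect_equal(rep_id$mahalanobis, unname(eu), tolerance = 1e-9)
  # a point at its component mean scores zero
  at_mean <- rbind(m, mu = fit$means[1, ])
  fit2 <- fit
  fit2$labels <- c(fit$labels, mu = 1L)
  fit2$n <- fit$n + 1L
  expect_equal(mahalanobis_boundary(fit2, at_mean)$mahalanobis[
    mahalanobis_boundary(fit2, at_mean)$gene_id == "mu"], 0)
})

test_that("the model scan flags BIC and silhouette optima", {
  m <- two_blob_profiles(n_per = 12, sep = 6, sd = 0.3, seed = 12)
  scan <- model_scan(m, k_range = 2:4, modes = c("tied", "full"),
                     seed = 3, n_restarts = 3)
  expect_equal(nrow(scan), 6)
  expect_equal(sum(scan$best_bic), 1)
  expect_equal(sum(scan$best_silhouette), 1)
  expect_true(all(scan$silhouette_mean >= -1 & scan$silhouette_mean <= 1,
                  na.rm = TRUE))
  expect_equal(scan$n_params[scan$k == 4 & scan$cov_mode == "full"], 39)
  # stored BIC is consistent with the stored log-likelihood everywhere
  expect_equal(scan$bic,
               -2 * scan$log_likelihood + scan$n_params * log(24),
               tolerance = 1e-9)
  # a clean two-mass geometry is silhouette-optimal at k = 2
  expect_equal(scan$k[scan$best_silhouette], 2)
  # determinism: same data, same seeds, same table
  scan2 <- model_scan(m, k_range = 2:4, modes = c("tied", "full"),
                      seed = 3, n_restarts = 3)
  expect_identical(scan, scan2)
})

test_that("leave-one-out ARI is exact on separable data", {
  m <- two_blob_profiles(n_per = 8, sep = 8, sd = 0.05, seed = 18)
  st <- loo_ari(m, k_a = 2, k_b = 2, seed = 4, n_restarts = 3)
  expect_equal(nrow(st$per_gene), 16)
  expect_equal(st$per_gene$ari_a, rep(1, 16))
  expect_equal(st$per_gene$ari_b, rep(1, 16))
  expect_equal(st$mean_diff, 0)
  expect_equal(st$mean_diff, mean(st$per_gene$diff))
})

test_that("a planted bridge point ranks among the destabilizers", {
  m <- bridge_fixture()
  st <- loo_ari(m, k_a = 2, k_b = 3, seed = 6, n_restarts = 10)
  expect_equal(nrow(st$per_gene), nrow(m))
  # removing the bridge flips which blobs the coarse model merges, so it
  # must rank among the strongest destabilizers of k = 2
  ranks <- rank(st$per_gene$diff)
  expect_lte(ranks[st$per_gene$gene_id == "zz_bridge"], 3)
  expect_lt(st$per_gene$ari_a[st$per_gene$gene_id == "zz_bridge"],
            mean(st$per_gene$ari_a[st$per_gene$gene_id != "zz_bridge"]))
})

test_that("transition tables conserve cluster sizes", {
  a <- c(1, 1, 1, 2, 2, 3)
  tt <- transition_table(a, a)
  expect_true(all(tt$table[row(tt$table) != col(tt$table)] == 0))
  expect_equal(unname(tt$row_marginals), c(3, 2, 1))
  b <- c(1, 1, 4, 2, 2, 3)  # cluster 1 split in two
  tt2 <- transition_table(a, b)
  expect_equal(sum(tt2$table["1", ] > 0), 2)
  expect_equal(sum(tt2$table), 6)
  expect_equal(as.integer(tt2$col_marginals),
               as.integer(table(b)[colnames(tt2$table)]))
  expect_error(transition_table(1:3, 1:4), "same genes")

  sk <- sankey_data(tt2, prefix_a = "k3", prefix_b = "k4")
  expect_equal(sum(sk$links$value), 6)
  expect_equal(nrow(sk$nodes), 3 + 4)
  expect_true(all(sk$links$source %in% sk$nodes$id))
})

test_that("mixture fits reject degenerate requests", {
  m <- random_profiles(10, seed = 20)
  expect_error(fit_gmm_tied(m, k = 1), "at least 2")
  expect_error(fit_gmm_tied(m[1:3, ], k = 4), "more genes")
  expect_error(fit_kmeans(m, k = 1), "at least 2")
  expect_error(fit_kmeans(m, k = 11), "exceeds")
})
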