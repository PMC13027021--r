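test_that("pathway centroids average members; the Global Center is exact", {
  m <- rbind(g1 = c(1, 1, 1), g2 = c(1, 1, 3), g3 = c(2, 0.5, 1))
  colnames(m) <- c("r40", "r80", "r300")
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    pathway = c("A", "A", "B"))
  ct <- pathway_centroids(m, ann)
  expect_equal(ct$centroids$n_genes, c(2, 1))
  expect_equal(unlist(ct$centroids[1, c("r40", "r80", "r300")]),
               c(r40 = 1, r80 = 1, r300 = 2))
  # one gene per pathway: centroids are the profiles themselves
  ann1 <- data.frame(gene_id = rownames(m), pathway = rownames(m))
  ct1 <- pathway_centroids(m, ann1)
  expect_equal(unname(as.matrix(ct1$centroids[, c("r40", "r80", "r300")])),
               unname(m))
  # single pathway: centroid equals the global center
  ann_all <- data.frame(gene_id = rownames(m), pathway = "all")
  ct_all <- pathway_centroids(m, ann_all)
  expect_equal(unlist(ct_all$centroids[1, c("r40", "r80", "r300")]),
               ct_all$global_center, ignore_attr = TRUE)
  expect_error(pathway_centroids(m, ann[1:2, ]), "no pathway annotation")
})

test_that("the Global Center equals the count-weighted centroid mean", {
  withr::with_seed(23, {
    m <- random_profiles(40, seed = 23)
    ann <- data.frame(gene_id = rownames(m),
                      pathway = sample(LETTERS[1:5], 40, replace = TRUE))
    ct <- pathway_centroids(m, ann)
    weighted <- global_center_from_centroids(ct$centroids)
    expect_equal(max(abs(weighted - ct$global_center)), 0,
                 tolerance = 1e-12)
  })
})

test_that("distance ranking is a descending permutation with symbol ties", {
  m <- rbind(at_center = c(1, 1, 1), north = c(1, 1, 2),
             south = c(1, 1, 0))  # north/south symmetric about center
  colnames(m) <- c("r40", "r80", "r300")
  rk <- rank_by_centroid_distance(m, c(1, 1, 1))
  expect_equal(rk$gene_id, c("north", "south", "at_center"))
  expect_equal(rk$distance, c(1, 1, 0))
  expect_equal(rk$rank, 1:3)

  # brute-force sort oracle on random profiles
  m2 <- random_profiles(10, seed = 7)
  center <- colMeans(m2)
  rk2 <- rank_by_centroid_distance(m2, center)
  d <- sqrt(rowSums(sweep(m2, 2, center)^2))
  expect_equal(rk2$gene_id, rownames(m2)[order(-d, rownames(m2))])
  expect_true(all(rk2$distance >= 0))
  expect_setequal(rk2$gene_id, rownames(m2))
})

test_that("top-gene selection honours fixed-k and the largest gap", {
  d <- c(10, 9, 8, 1, 0.9)
  rk <- structure(
    data.frame(gene_id = paste0("g", 1:5), distance = d, rank = 1:5),
    class = c("distance_ranking", "data.frame"))
  gap <- select_top_by_gap(rk, mode = "largest_gap", default_k = 2)
  expect_equal(as.character(gap), c("g1", "g2", "g3"))
  expect_equal(attr(gap, "selection"), "largest_gap")

  fixed <- select_top_by_gap(rk, default_k = 4, mode = "fixed_k")
  expect_length(fixed, 4)

  flat <- rk
  flat$distance <- rep(5, 5)
  expect_warning(fb <- select_top_by_gap(flat, default_k = 2,
                                         mode = "largest_gap"),
                 "falling back")
  expect_length(fb, 2)
  expect_error(select_top_by_gap(rk, default_k = 9), "exceeds")
})

test_that("k-distance curves match the exhaustive distance matrix", {
  # unit-spaced colinear points, k = 1: all nearest neighbours at 1
  line <- cbind(r40 = 1:6, r80 = 0, r300 = 0)
  rownames(line) <- paste0("g", 1:6)
  expect_equal(kdist_profile(line, k = 1), rep(1, 6))
  # duplicated points put zeros in the curve
  dup <- rbind(line, g7 = c(1, 0, 0))
  expect_true(any(kdist_profile(dup, k = 1) == 0))
  # brute-force oracle on 30 random profiles
  m <- random_profiles(30, seed = 3)
  expect_equal(kdist_profile(m, k = 5), naive_kdist(m, 5))
  expect_error(kdist_profile(line[1:4, ], k = 5), "at least")
})

test_that("the radius lands at the knee of the k-distance curve", {
  kd <- c(rep(0.1, 8), 0.5, 0.9)          # flat then jumping
  expect_equal(select_epsilon(kd), 0.1)    # value just below the jump
  expect_warning(eps <- select_epsilon(seq(0.1, 1, length.out = 10)),
                 "no discernible knee")
  expect_equal(eps, 0.13)
  expect_equal(select_epsilon(kd, override = 0.2), 0.2)
})

test_that("the chosen radius flags exactly the planted outliers", {
  cfg <- generator_config(n_genes = 110, ratio_noise_sd = 0.03,
                          n_qc_fail_error = 0, n_qc_fail_lowcount = 0,
                          integer_counts = FALSE, seed = 29)
  panel <- generate_panel(cfg)
  prof <- panel_ratio_profiles(panel)
  eps <- select_epsilon(kdist_profile(prof, k = 5))
  labels <- dbscan_profiles(prof, dbscan_config(eps, 5))
  noise <- names(labels)[labels == -1]
  expect_setequal(noise, panel$truth$gene_id[panel$truth$is_outlier])
})

test_that("density clustering handles the degenerate layouts", {
  same <- matrix(1, 6, 3, dimnames = list(paste0("g", 1:6),
                                          c("r40", "r80", "r300")))
  lab <- dbscan_profiles(same, dbscan_config(0.1, 5))
  expect_true(all(lab == 1))
  spread <- diag(3) * 10 + 1
  rownames(spread) <- paste0("g", 1:3)
  colnames(spread) <- c("r40", "r80", "r300")
  expect_true(all(dbscan_profiles(spread, dbscan_config(0.1, 2)) == -1))
})

test_that("density clustering matches the naive reference on random data", {
  for (seed in 1:25) {
    m <- random_profiles(40, seed = seed, spread = 0.15)
    labels <- dbscan_profiles(m, dbscan_config(0.13, 5))
    ref <- naive_dbscan(m, 0.13, 5)
    expect_identical(labels, ref)
  }
})

test_that("labelling is invariant to input row order", {
  m <- random_profiles(35, seed = 51, spread = 0.15)
  base <- dbscan_profiles(m, dbscan_config(0.13, 5))
  perm <- withr::with_seed(1, sample(nrow(m)))
  shuffled <- dbscan_profiles(m[perm, ], dbscan_config(0.13, 5))
  expect_identical(shuffled[names(base)], base)
})

test_that("noise counts respond monotonically to the parameters", {
  m <- random_profiles(60, seed = 77, spread = 0.2)
  n_noise <- function(eps, ms)
    sum(dbscan_profiles(m, dbscan_config(eps, ms)) == -1)
  for (eps in c(0.05, 0.1, 0.2)) {
    expect_gte(n_noise(eps, 5), n_noise(eps + 0.05, 5))    # larger radius
    expect_lte(n_noise(eps, 4), n_noise(eps, 6))           # larger min_samples
  }
})

test_that("the consensus Venn enumerates regions correctly", {
  cv <- consensus_venn(c("a", "b"), c("b", "c"), "b",
                       universe = letters[1:5])
  expect_identical(cv$core, "b")
  expect_equal(unname(cv$counts["centroid"]), 1L)           # a
  expect_equal(unname(cv$counts["dbscan"]), 1L)             # c
  expect_equal(unname(cv$counts["centroid+dbscan+singleton"]), 1L)
  expect_equal(sum(cv$counts), 3L)

  ident <- consensus_venn("x", "x", "x", universe = "x")
  expect_identical(ident$core, "x")
  expect_equal(sum(ident$counts), 1L)

  disj <- consensus_venn("a", "b", "c", universe = letters[1:3])
  expect_length(disj$core, 0)
  expect_error(consensus_venn("z", "b", "c", universe = letters[1:3]),
               "outside the universe")
})
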