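# Brute-force reference implementations used as independent oracles.
# Each is deliberately naive (exhaustive enumeration, O(n^2) scans,
# hand linear algebra) and shares no code with the package paths it
# checks.

# --- DBSCAN reference: union-find over core-core edges ------------------
naive_dbscan <- function(m, eps, min_samples) {
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  n <- nrow(m)
  dm <- as.matrix(dist(m))
  nbr_count <- rowSums(dm <= eps)          # self included
  core <- nbr_count >= min_samples

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in which(core)) for (j in which(core)) {
    if (i < j && dm[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  labels <- rep(-1L, n)
  # number clusters by first (gene-sorted) core member, as discovery order
  roots <- unique(comp[core])
  roots <- roots[order(vapply(roots, function(r) min(which(core & comp == r)),
                              integer(1)))]
  for (ci in seq_along(roots)) labels[core & comp == roots[ci]] <- ci
  # border points: smallest cluster id among core neighbours
  for (i in which(!core)) {
    cn <- labels[dm[i, ] <= eps & core]
    if (length(cn) > 0L) labels[i] <- min(cn)
  }
  names(labels) <- rownames(m)
  labels[order(ord)]
}

# --- ARI by direct pair counting ---------------------------------------
pair_count_ari <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  grow <- function(labels) {
    if (length(labels) == n) return(list(labels))
    mx <- max(labels)
    out <- list()
    for (v in seq_len(mx + 1L))
      out <- c(out, grow(c(labels, v)))
    out
  }
  grow(1L)
}

# --- silhouette by the per-point a/b definition ------------------------
naive_silhouette_mean <- function(m, labels) {
  dm <- as.matrix(dist(m))
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dm[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# --- k-th NN distances by full-matrix scan -----------------------------
naive_kdist <- function(m, k) {
  dm <- as.matrix(dist(m))
  sort(vapply(seq_len(nrow(m)), function(i) sort(dm[i, -i])[k], numeric(1)))
}

# --- Mahalanobis by explicit matrix inverse ----------------------------
naive_mahalanobis <- function(x, mu, sigma) {
  xc <- x - mu
  sqrt(as.numeric(t(xc) %*% solve(sigma) %*% xc))
}

# --- small fixtures ----------------------------------------------------
# counts table for one gene across the four standard concentrations
one_gene_counts <- function(gene = "G1", reps) {
  # reps: named list ppm -> c(rep1, rep2)
  do.call(rbind, lapply(names(reps), function(p)
    data.frame(gene_id = gene, ppm = as.numeric(p),
               rep1 = reps[[p]][1], rep2 = reps[[p]][2],
               stringsAsFactors = FALSE)))
}

# flat counts: every concentration = control * ratio, duplicates exact
flat_counts <- function(gene, base = 100, ratios = c(`40` = 1, `80` = 1,
                                                     `150` = 1, `300` = 1)) {
  one_gene_counts(gene, lapply(as.list(ratios), function(r)
    rep(base * r, 2)))
}

# two well-separated 3-D point masses
two_blob_profiles <- function(n_per = 10, sep = 10, sd = 0.01, seed = 1) {
  withr::with_seed(seed, {
    m <- rbind(
      matrix(rnorm(n_per * 3, 0, sd), ncol = 3),
      matrix(rnorm(n_per * 3, sep, sd), ncol = 3))
    rownames(m) <- sprintf("g%02d", seq_len(2 * n_per))
    colnames(m) <- c("r40", "r80", "r300")
    m
  })
}

# generator config for small panels: no planted outliers or QC failures
small_config <- function(n_genes, seed, ...) {
  generator_config(n_genes = n_genes, outlier_profiles = NULL,
                   n_qc_fail_error = 0, n_qc_fail_lowcount = 0,
                   seed = seed, ...)
}

# deterministic three-blob lattice with one bridge point midway between
# the first two blobs: with the bridge the coarse k = 2 fit merges
# blobs A and B; without it, B and C (gap 2.0 < 2.05) merge instead
bridge_fixture <- function(ab = 2.05, bc = 2) {
  off8 <- as.matrix(expand.grid(c(-0.1, 0.1), c(-0.1, 0.1), c(-0.1, 0.1)))
  off12 <- rbind(off8, as.matrix(expand.grid(c(-0.05, 0.05),
                                             c(-0.05, 0.05), 0))[1:4, ])
  m <- rbind(off12, sweep(off12, 2, -ab), sweep(off12, 2, -(ab + bc)))
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c("r40", "r80", "r300")
  rbind(m, zz_bridge = rep(ab / 2, 3))
}

default_centroids_for_test <- function() {
  generator_config()$cluster_centroids
}

profile_matrix_for_test <- function(profiles) {
  m <- as.matrix(profiles[, c("r40", "r80", "r300")])
  rownames(m) <- profiles$gene_id
  m
}

random_profiles <- function(n, seed, spread = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(1 + rnorm(n * 3, 0, spread), ncol = 3)
    m <- pmax(m, 0.05)
    rownames(m) <- sprintf("g%03d", seq_len(n))
    colnames(m) <- c("r40", "r80", "r300")
    m
  })
}
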