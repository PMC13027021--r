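# Model-selection and robustness diagnostics for the mixture stage.

#' Mean silhouette width of a labelling
#'
#' Standard silhouette with Euclidean distance (via
#' [cluster::silhouette()]), averaged over genes; members of singleton
#' clusters contribute a width of 0.
#'
#' @param profiles ratio profiles.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(profiles, labels) {
  m <- profile_matrix(profiles)
  stopifnot(length(labels) == nrow(m))
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least two clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(m))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (via
#' [mclust::adjustedRandIndex()]); 1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param labels_a,labels_b label vectors over the same genes.
#' @return the ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must cover the same genes")
  r <- mclust::adjustedRandIndex(labels_a, labels_b)
  # chance-correction denominator vanishes only when both partitions are
  # trivial (everything co-clustered or everything split) and therefore
  # identical in pair structure
  if (is.nan(r)) 1 else r
}

#' Scan component counts and covariance modes
#'
#' Fits a mixture for every combination of `k` in `k_range` and
#' covariance mode, recording the mean silhouette of the hard labelling,
#' BIC (`-2L + p log n`, with `p = (k-1) + k d + d(d+1)/2` tied and
#' `(k-1) + k d + k d(d+1)/2` full) and log-likelihood. The BIC-optimal
#' (lowest) and silhouette-optimal (highest) rows are flagged.
#'
#' @param profiles ratio profiles.
#' @param k_range integer vector of component counts.
#' @param modes covariance modes to scan.
#' @param seed master seed (one sub-seed per scan row).
#' @param n_restarts restarts per fit.
#' @return data.frame of class `"model_scan"`: `k`, `cov_mode`,
#'   `silhouette_mean`, `bic`, `log_likelihood`, `n_params`,
#'   `n_restarts`, `best_seed`, `best_bic`, `best_silhouette`.
#' @export
model_scan <- function(profiles, k_range = 2:9,
                       modes = c("tied", "full"), seed = 1L,
                       n_restarts = 10L) {
  m <- profile_matrix(profiles)
  grid <- expand.grid(k = k_range, cov_mode = modes,
                      stringsAsFactors = FALSE)
  seeds <- expand_seed(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_gmm(m, grid$k[i], cov_mode = grid$cov_mode[i],
                   seed = seeds[i], n_restarts = n_restarts)
    sil <- if (length(unique(fit$labels)) >= 2L)
      silhouette_mean(m, fit$labels) else NA_real_
    data.frame(k = grid$k[i], cov_mode = grid$cov_mode[i],
               silhouette_mean = sil, bic = fit$bic,
               log_likelihood = fit$log_likelihood,
               n_params = fit$n_params,
               n_restarts = n_restarts, best_seed = fit$best_seed,
               stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  scan$best_bic <- seq_len(nrow(scan)) == which.min(scan$bic)
  scan$best_silhouette <- seq_len(nrow(scan)) ==
    which.max(ifelse(is.na(scan$silhouette_mean), -Inf,
                     scan$silhouette_mean))
  class(scan) <- c("model_scan", "data.frame")
  scan
}

#' Mahalanobis boundary drivers
#'
#' Distance of each gene from its assigned component mean under the
#' model covariance, `d_M = sqrt((x - mu)' Sigma^-1 (x - mu))` (via
#' [stats::mahalanobis()]). Genes beyond `threshold` are boundary
#' drivers: statistically peripheral to their cluster.
#'
#' @param model a fitted [fit_gmm()] model.
#' @param profiles the profiles the model was fitted on.
#' @param threshold driver cut-off on `d_M`.
#' @return data.frame of class `"boundary_report"`: `gene_id`,
#'   `cluster`, `mahalanobis`, `is_driver`; attribute `threshold`.
#' @export
mahalanobis_boundary <- function(model, profiles, threshold = 2.42) {
  stopifnot(inherits(model, "mixture_model"))
  m <- profile_matrix(profiles)
  stopifnot(nrow(m) == model$n)
  d2 <- numeric(nrow(m))
  for (j in seq_len(model$k)) {
    idx <- which(model$labels == j)
    if (length(idx) == 0L) next
    sigma <- if (model$cov_mode == "tied") model$tied_covariance
             else model$covariances[[j]]
    d2[idx] <- stats::mahalanobis(m[idx, , drop = FALSE],
                                  model$means[j, ], sigma)
  }
  out <- data.frame(gene_id = rownames(m),
                    cluster = as.integer(model$labels),
                    mahalanobis = sqrt(d2),
                    stringsAsFactors = FALSE)
  out$is_driver <- out$mahalanobis > threshold
  out <- out[order(-out$mahalanobis), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("boundary_report", "data.frame")
  out
}

#' Leave-one-out clustering stability (ARI)
#'
#' For two model orders `k_a` and `k_b`: fit each on the full data, then
#' refit after removing each gene in turn (same restart/seed policy,
#' derived from the master seed) and compute the ARI between baseline
#' and reduced labellings on the shared genes. The per-gene difference
#' is `ari_a - ari_b`, so with `k_a = 4, k_b = 6` a negative mean says
#' the 6-component model is the more stable of the two.
#'
#' @param profiles ratio profiles.
#' @param k_a,k_b the two component counts to compare.
#' @param seed master seed.
#' @param n_restarts restarts per fit.
#' @param cov_mode covariance mode for all fits.
#' @return list of class `"stability_report"`: `per_gene` (data.frame
#'   `gene_id`, `ari_a`, `ari_b`, `diff`), `mean_diff`, `k_a`, `k_b`,
#'   `failed` (genes whose refit failed, excluded from the mean).
#' @export
loo_ari <- function(profiles, k_a = 4L, k_b = 6L, seed = 1L,
                    n_restarts = 5L, cov_mode = "tied") {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (n <= max(k_a, k_b) + 1L)
    stop("too few genes for leave-one-out at these component counts")
  seeds <- expand_seed(seed, 2L + 2L * n)
  base_a <- fit_gmm(m, k_a, cov_mode, seed = seeds[1L],
                    n_restarts = n_restarts)
  base_b <- fit_gmm(m, k_b, cov_mode, seed = seeds[2L],
                    n_restarts = n_restarts)
  ari_for <- function(base, k, g, s) {
    fit <- tryCatch(
      fit_gmm(m[-g, , drop = FALSE], k, cov_mode, seed = s,
              n_restarts = n_restarts),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    adjusted_rand_index(base$labels[-g], fit$labels)
  }
  ari_a <- vapply(seq_len(n), function(g)
    ari_for(base_a, k_a, g, seeds[2L + g]), numeric(1))
  ari_b <- vapply(seq_len(n), function(g)
    ari_for(base_b, k_b, g, seeds[2L + n + g]), numeric(1))
  per_gene <- data.frame(gene_id = rownames(m), ari_a = ari_a,
                         ari_b = ari_b, diff = ari_a - ari_b,
                         stringsAsFactors = FALSE)
  failed <- per_gene$gene_id[!is.finite(per_gene$diff)]
  if (length(failed) > 0L)
    warning(sprintf("%d leave-one-out refit(s) failed and were excluded",
                    length(failed)))
  structure(list(per_gene = per_gene,
                 mean_diff = mean(per_gene$diff[is.finite(per_gene$diff)]),
                 k_a = k_a, k_b = k_b, failed = failed,
                 baseline_a = base_a$labels, baseline_b = base_b$labels),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report: leave-one-out ARI, k = %d vs k = %d over %d genes\n",
    x$k_a, x$k_b, nrow(x$per_gene)))
  cat(sprintf("  mean ARI difference (k%d - k%d): %+.4f\n",
              x$k_a, x$k_b, x$mean_diff))
  invisible(x)
}

#' Cluster transition table between two labellings
#'
#' Cross-tabulates the two labellings (e.g. a 4- and a 6-component
#' model) with marginals, for Sankey-style flow displays.
#'
#' @param labels_a,labels_b label vectors over the same genes.
#' @return list of class `"transition_table"`: `table` (contingency
#'   counts A x B), `row_marginals`, `col_marginals`, `n`.
#' @export
transition_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labellings must cover the same genes")
  tab <- table(from = labels_a, to = labels_b)
  structure(list(table = tab,
                 row_marginals = rowSums(tab),
                 col_marginals = colSums(tab),
                 n = length(labels_a)),
            class = "transition_table")
}

#' Sankey-ready node/link export of a transition table
#'
#' @param tt a [transition_table()].
#' @param prefix_a,prefix_b node-label prefixes for the two models.
#' @return list with `nodes` (`id`, `label`, `count`) and `links`
#'   (`source`, `target`, `value`), suitable for
#'   [jsonlite::toJSON()].
#' @export
sankey_data <- function(tt, prefix_a = "A", prefix_b = "B") {
  stopifnot(inherits(tt, "transition_table"))
  tab <- tt$table
  a_ids <- paste0(prefix_a, "-", rownames(tab))
  b_ids <- paste0(prefix_b, "-", colnames(tab))
  nodes <- data.frame(
    id = c(a_ids, b_ids),
    label = c(rownames(tab), colnames(tab)),
    count = c(unname(tt$row_marginals), unname(tt$col_marginals)),
    stringsAsFactors = FALSE)
  idx <- which(tab > 0, arr.ind = TRUE)
  links <- data.frame(
    source = a_ids[idx[, 1L]],
    target = b_ids[idx[, 2L]],
    value = as.integer(tab[idx]),
    stringsAsFactors = FALSE)
  links <- links[order(links$source, links$target), ]
  rownames(links) <- NULL
  list(nodes = nodes, links = links)
}
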