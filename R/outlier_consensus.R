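# Three-way outlier detection in ratio space.
#
# Outliers are genes whose 3-D ratio profile diverges from the bulk:
# (1) by Euclidean distance from the Global Center (the mean profile of
# all genes, equivalently the gene-count-weighted mean of pathway
# centroids); (2) as DBSCAN noise points in ratio space; (3) as genes
# with a singleton trajectory code. The consensus is their Venn overlap.
# Distances are taken on unscaled ratio coordinates, since centroids and
# the DBSCAN radius are stated in raw ratio units.

#' Pathway centroids and the Global Center
#'
#' Per-pathway arithmetic mean ratio profiles and the unweighted mean
#' over all genes (the Global Center). The Global Center equals the
#' gene-count-weighted mean of the pathway centroids — the identity
#' exploited by [global_center_from_centroids()].
#'
#' @param profiles ratio profiles (`gene_id` + `r<ppm>` columns).
#' @param annotation data.frame mapping `gene_id` to a single `pathway`.
#' @return list of class `"centroid_table"`: `centroids` (data.frame
#'   `pathway`, `n_genes`, mean ratio columns) and `global_center`
#'   (named numeric).
#' @export
pathway_centroids <- function(profiles, annotation) {
  m <- profile_matrix(profiles)
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "pathway") %in% names(annotation)))
  if (anyDuplicated(annotation$gene_id))
    stop("each gene must be annotated to exactly one pathway")
  pw <- annotation$pathway[match(rownames(m), annotation$gene_id)]
  if (any(is.na(pw))) {
    missing <- rownames(m)[is.na(pw)][1]
    stop(sprintf("gene '%s' has no pathway annotation", missing))
  }
  split_idx <- split(seq_len(nrow(m)), pw)
  cent <- t(vapply(split_idx, function(i) colMeans(m[i, , drop = FALSE]),
                   numeric(ncol(m))))
  out <- data.frame(pathway = names(split_idx),
                    n_genes = lengths(split_idx),
                    cent, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(centroids = out,
                 global_center = colMeans(m)),
            class = "centroid_table")
}

#' Global Center from pathway centroids and gene counts
#'
#' Gene-count-weighted mean of pathway centroid coordinates. Useful when
#' only the published centroid table (with per-pathway gene counts) is
#' available rather than per-gene profiles.
#'
#' @param centroids data.frame with `n_genes` and ratio columns
#'   (`r40`/`r80`/`r300`-style), one row per pathway.
#' @return named numeric vector, the weighted mean profile.
#' @export
global_center_from_centroids <- function(centroids) {
  stopifnot(is.data.frame(centroids), "n_genes" %in% names(centroids))
  ratio_cols <- grep("^r[0-9]+$", names(centroids), value = TRUE)
  stopifnot(length(ratio_cols) >= 1L)
  w <- centroids$n_genes
  stopifnot(all(w >= 1))
  vapply(centroids[ratio_cols],
         function(col) sum(col * w) / sum(w), numeric(1))
}

#' Rank genes by Euclidean distance from a center
#'
#' @param profiles ratio profiles.
#' @param center numeric vector (e.g. the Global Center).
#' @return data.frame of class `"distance_ranking"`: `gene_id`,
#'   `distance`, `rank`, ordered by descending distance with ties broken
#'   by gene symbol.
#' @export
rank_by_centroid_distance <- function(profiles, center) {
  m <- profile_matrix(profiles)
  stopifnot(length(center) == ncol(m), all(is.finite(center)))
  d <- sqrt(rowSums(sweep(m, 2L, center)^2))
  ord <- order(-d, rownames(m))
  out <- data.frame(gene_id = rownames(m)[ord], distance = d[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("distance_ranking", "data.frame")
  out
}

#' Select the most divergent genes from a distance ranking
#'
#' `"fixed_k"` returns the `k` most distant genes. `"largest_gap"`
#' operationalizes "a clear inflection point in the distance
#' distribution": the cut is placed at the largest consecutive drop
#' within the top half of the sorted distances. If all candidate drops
#' are equal (no discernible inflection) the selection falls back to
#' `default_k` with a warning.
#'
#' @param ranking a [rank_by_centroid_distance()] result.
#' @param default_k number of genes for `fixed_k` (and the fallback).
#' @param mode `"fixed_k"` or `"largest_gap"`.
#' @return character vector of selected genes, with attributes
#'   `selection` (mode actually used) and `cut_index`.
#' @export
select_top_by_gap <- function(ranking, default_k = 6L,
                              mode = c("fixed_k", "largest_gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranking, "distance_ranking"), nrow(ranking) >= 1L)
  n <- nrow(ranking)
  if (default_k > n) stop("default_k exceeds the number of genes")
  if (mode == "fixed_k") {
    sel <- ranking$gene_id[seq_len(default_k)]
    return(structure(sel, selection = "fixed_k", cut_index = default_k))
  }
  drops <- -diff(ranking$distance)
  drops <- drops[seq_len(min(length(drops), ceiling(n / 2)))]
  if (diff(range(drops)) < 1e-12) {
    warning("no discernible inflection in the distance curve; ",
            "falling back to the top ", default_k, " genes")
    sel <- ranking$gene_id[seq_len(default_k)]
    return(structure(sel, selection = "fixed_k_fallback",
                     cut_index = default_k))
  }
  cut <- which.max(drops)
  structure(ranking$gene_id[seq_len(cut)],
            selection = "largest_gap", cut_index = cut)
}

#' Sorted k-th nearest-neighbour distances
#'
#' The k-distance curve used to choose the DBSCAN radius: for each gene
#' the Euclidean distance to its k-th nearest neighbour (self excluded),
#' sorted ascending.
#'
#' @param profiles ratio profiles.
#' @param k neighbour order (default 5, matching `min_samples = 5`).
#' @return numeric vector of length `nrow(profiles)`, ascending.
#' @export
kdist_profile <- function(profiles, k = 5L) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (n < k + 1L) stop(sprintf("need at least %d genes for k = %d", k + 1L, k))
  dm <- as.matrix(stats::dist(m))
  # self excluded by dropping the diagonal entry
  kd <- vapply(seq_len(n), function(i) sort(dm[i, -i])[k], numeric(1))
  sort(kd)
}

#' Choose the DBSCAN radius from the k-distance curve
#'
#' Returns the k-distance value at the point of maximum discrete
#' curvature (largest second difference) of the ascending curve — the
#' "knee" just below the jump into sparse territory. A configured manual
#' radius always wins; a curve with no curvature (e.g. strictly linear)
#' yields the default with a warning.
#'
#' @param kdist ascending k-distance values from [kdist_profile()].
#' @param default radius returned when the curve carries no knee.
#' @param override manual radius; returned as-is when non-`NULL`.
#' @return the chosen radius.
#' @export
select_epsilon <- function(kdist, default = 0.13, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(is.numeric(kdist), length(kdist) >= 3L, !is.unsorted(kdist))
  curv <- diff(kdist, differences = 2L)  # curv[i] = d[i+2] - 2 d[i+1] + d[i]
  if (diff(range(curv)) < 1e-12) {
    warning("k-distance curve has no discernible knee; using default ",
            default)
    return(default)
  }
  kdist[which.max(curv) + 1L]
}

#' DBSCAN configuration
#'
#' @param epsilon neighbourhood radius in ratio-space units.
#' @param min_samples minimum neighbourhood size (self included) for a
#'   core point.
#' @return list of class `"dbscan_config"`.
#' @export
dbscan_config <- function(epsilon = 0.13, min_samples = 5L) {
  stopifnot(epsilon > 0, min_samples >= 1L)
  structure(list(epsilon = epsilon, min_samples = as.integer(min_samples)),
            class = "dbscan_config")
}

#' Density-based clustering of ratio profiles
#'
#' Standard DBSCAN on Euclidean distance: a core point has at least
#' `min_samples` points (itself included) within `epsilon`; clusters are
#' maximal density-connected sets of core points plus their borders.
#' Points are processed in gene-symbol order, and a border point in reach
#' of several clusters joins the first core cluster that reaches it under
#' that order — making the full labelling reproducible, not just the
#' core/noise split.
#'
#' @param profiles ratio profiles.
#' @param config a [dbscan_config()].
#' @return integer vector of cluster labels named by gene (noise = -1,
#'   clusters numbered from 1 in order of discovery).
#' @export
dbscan_profiles <- function(profiles, config = dbscan_config()) {
  stopifnot(inherits(config, "dbscan_config"))
  m <- profile_matrix(profiles)
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  n <- nrow(m)
  dm <- as.matrix(stats::dist(m))
  nbrs <- lapply(seq_len(n), function(i) which(dm[i, ] <= config$epsilon))
  is_core <- lengths(nbrs) >= config$min_samples

  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue) > 0L) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (is.na(labels[j])) {
        labels[j] <- cl              # border or core reached first by cl
        if (is_core[j]) queue <- c(queue, nbrs[[j]])
      } else if (labels[j] == -1L) {
        labels[j] <- cl              # previously unreachable; now bordered
      }
    }
  }
  labels[is.na(labels)] <- -1L
  names(labels) <- rownames(m)
  labels[order(ord)]  # restore input order
}

#' Venn consensus of the three outlier detectors
#'
#' @param centroid_set,dbscan_set,singleton_set character vectors of
#'   outlier genes from the three detectors.
#' @param universe all genes under consideration; every set must be a
#'   subset.
#' @return list of class `"outlier_consensus"`: `membership` (data.frame
#'   `gene_id`, three logical columns), `regions` (named list of genes
#'   per Venn region, names like `"centroid+dbscan"`), `core` (the triple
#'   intersection) and `counts` (per-region sizes).
#' @export
consensus_venn <- function(centroid_set, dbscan_set, singleton_set,
                           universe) {
  sets <- list(centroid = unique(centroid_set),
               dbscan = unique(dbscan_set),
               singleton = unique(singleton_set))
  outside <- setdiff(unlist(sets), universe)
  if (length(outside) > 0L)
    stop(sprintf("gene(s) outside the universe: %s",
                 paste(utils::head(outside, 5), collapse = ", ")))
  all_out <- sort(unique(unlist(sets)))
  membership <- data.frame(
    gene_id = all_out,
    centroid = all_out %in% sets$centroid,
    dbscan = all_out %in% sets$dbscan,
    singleton = all_out %in% sets$singleton,
    stringsAsFactors = FALSE)
  key <- apply(membership[, -1L], 1L, function(b)
    paste(names(sets)[b], collapse = "+"))
  region_names <- c("centroid", "dbscan", "singleton",
                    "centroid+dbscan", "centroid+singleton",
                    "dbscan+singleton", "centroid+dbscan+singleton")
  regions <- lapply(stats::setNames(region_names, region_names),
                    function(r) membership$gene_id[key == r])
  structure(list(membership = membership,
                 regions = regions,
                 core = regions[["centroid+dbscan+singleton"]],
                 counts = lengths(regions)),
            class = "outlier_consensus")
}

#' @export
print.outlier_consensus <- function(x, ...) {
  cat("outlier_consensus:", nrow(x$membership), "genes flagged by >= 1 detector\n")
  print(x$counts)
  cat("core:", if (length(x$core)) paste(x$core, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}
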