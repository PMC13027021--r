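# Bundled reference tables for the published A549 deuterium-response
# panel: pathway-centroid coordinates (with per-pathway gene counts) for
# the 102-gene consensus set, the six-module centroid/membership table
# for the 91-gene core set, and the 11 density-outlier symbols. These
# are the printed summary coordinates the generator defaults are built
# from, and the inputs to the package's reproduction checks.

ref_path <- function(file) {
  system.file("extdata", file, package = "deupanel", mustWork = TRUE)
}

#' Reference pathway centroids (A549 consensus panel)
#'
#' Mean ratio profiles (40/80/300 ppm versus the 150 ppm control) of the
#' ten pathway bins of the 102-gene A549 consensus panel, with the number
#' of member genes per bin. Feeding this table to
#' [global_center_from_centroids()] reproduces the Global Center.
#'
#' @return data.frame `pathway`, `n_genes`, `r40`, `r80`, `r300`,
#'   `example_genes`.
#' @export
a549_pathway_centroids <- function() {
  utils::read.delim(ref_path("pathway_centroids_a549.tsv"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reference six-module mixture centroids (A549 core set)
#'
#' Centroid coordinates and gene memberships of the six tied-covariance
#' mixture modules fitted to the 91-gene outlier-free A549 core set.
#' These centroids are the generator's default module centres.
#'
#' @return data.frame `cluster`, `label`, `r40`, `r80`, `r300`, `genes`
#'   (semicolon-separated symbols).
#' @export
a549_gmm6_clusters <- function() {
  utils::read.delim(ref_path("gmm6_clusters_a549.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference density-outlier gene symbols (A549 panel)
#'
#' The 11 sentinel outliers flagged by DBSCAN in the A549 consensus
#' panel.
#'
#' @return character vector of gene symbols.
#' @export
a549_dbscan_outliers <- function() {
  readLines(ref_path("dbscan_outliers_a549.txt"))
}
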