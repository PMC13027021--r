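# End-to-end orchestration: QC -> consensus curation -> symbolic encoding
# -> centroid geometry -> outlier consensus -> outlier removal -> mixture
# modelling -> boundary/stability/transition reports. Every artifact is
# plain delimited text or JSON; a manifest reconciles gene counts at each
# stage boundary and records every seed and threshold actually applied.

#' Pipeline configuration
#'
#' @param filter a [filter_config()].
#' @param scheme a [symbol_scheme()].
#' @param dbscan a [dbscan_config()]; its `epsilon` is used directly
#'   unless `auto_epsilon` is set.
#' @param auto_epsilon choose the DBSCAN radius from the k-distance knee
#'   ([select_epsilon()]) instead of `dbscan$epsilon`.
#' @param top_k,gap_mode centroid-distance selection, see
#'   [select_top_by_gap()].
#' @param k_choices the component counts fitted and compared (first =
#'   coarse model, second = fine model).
#' @param k_range component counts for the model scan.
#' @param n_restarts EM/k-means restarts throughout.
#' @param mahalanobis_threshold boundary-driver cut-off.
#' @param run_symbols,run_outliers,run_mixture,run_scan,run_stability
#'   stage toggles; a disabled stage leaves no artifacts and downstream
#'   stages degrade gracefully (no outlier stage = mixture runs on all
#'   retained genes).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            scheme = symbol_scheme(),
                            dbscan = dbscan_config(),
                            auto_epsilon = FALSE,
                            top_k = 6L,
                            gap_mode = "fixed_k",
                            k_choices = c(4L, 6L),
                            k_range = 2:9,
                            n_restarts = 10L,
                            mahalanobis_threshold = 2.42,
                            run_symbols = TRUE,
                            run_outliers = TRUE,
                            run_mixture = TRUE,
                            run_scan = FALSE,
                            run_stability = FALSE,
                            seed = 1L) {
  stopifnot(inherits(filter, "filter_config"),
            inherits(scheme, "symbol_scheme"),
            inherits(dbscan, "dbscan_config"),
            length(k_choices) == 2L, all(k_choices >= 2L),
            mahalanobis_threshold > 0)
  structure(list(filter = filter, scheme = scheme, dbscan = dbscan,
                 auto_epsilon = isTRUE(auto_epsilon),
                 top_k = as.integer(top_k), gap_mode = gap_mode,
                 k_choices = as.integer(k_choices),
                 k_range = as.integer(k_range),
                 n_restarts = as.integer(n_restarts),
                 mahalanobis_threshold = mahalanobis_threshold,
                 run_symbols = isTRUE(run_symbols),
                 run_outliers = isTRUE(run_outliers),
                 run_mixture = isTRUE(run_mixture),
                 run_scan = isTRUE(run_scan),
                 run_stability = isTRUE(run_stability),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a duplicate-count table
#'
#' Strict reader for the pipeline's input dialect: tab- (or comma-)
#' separated text with header columns `gene_id`, `ppm`, `rep1`, `rep2`.
#' Malformed rows, negative counts, unexpected concentrations and
#' duplicated (gene, ppm) pairs are rejected with the offending line
#' numbers.
#'
#' @param path input file.
#' @param concentrations expected set of concentrations; `NULL` skips
#'   the check.
#' @return validated data.frame.
#' @export
read_counts <- function(path, concentrations = NULL) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  counts <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  needed <- c("gene_id", "ppm", "rep1", "rep2")
  if (!all(needed %in% names(counts)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(needed, collapse = ", ")))
  counts <- counts[, needed]
  counts$gene_id <- as.character(counts$gene_id)
  for (col in c("ppm", "rep1", "rep2")) {
    if (!is.numeric(counts[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
    counts[[col]] <- as.numeric(counts[[col]])
  }
  line_no <- seq_len(nrow(counts)) + 1L  # +1 for the header line
  bad <- which(!is.finite(counts$rep1) | !is.finite(counts$rep2) |
                 counts$rep1 < 0 | counts$rep2 < 0)
  if (length(bad) > 0L)
    stop(sprintf("negative or malformed counts at line(s) %s",
                 paste(utils::head(line_no[bad], 5), collapse = ", ")))
  if (!is.null(concentrations)) {
    bad <- which(!counts$ppm %in% concentrations)
    if (length(bad) > 0L)
      stop(sprintf("unexpected concentration %g ppm at line %d",
                   counts$ppm[bad[1L]], line_no[bad[1L]]))
  }
  dup <- duplicated(counts[, c("gene_id", "ppm")]) |
    duplicated(counts[, c("gene_id", "ppm")], fromLast = TRUE)
  if (any(dup))
    stop(sprintf(
      "duplicated (gene_id, ppm) pairs at line(s) %s; %s",
      paste(utils::head(line_no[dup], 6), collapse = ", "),
      "resolve multiply-measured records with deduplicate_genes()"))
  counts
}

#' Run the full analysis pipeline
#'
#' @param counts duplicate-count table (data.frame) or path readable by
#'   [read_counts()].
#' @param annotation optional data.frame `gene_id`, `pathway`; when
#'   absent all genes share one bin (the Global Center is unaffected).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every artifact is
#'   written there as TSV/JSON together with `manifest.json` and
#'   `report.txt`.
#' @return list of class `"pipeline_result"` holding every stage
#'   artifact plus `manifest` (stage gene counts, seeds, thresholds).
#' @examples
#' panel <- generate_panel(generator_config(n_genes = 60, seed = 5))
#' res <- run_pipeline(panel$counts,
#'                     config = pipeline_config(n_restarts = 3, seed = 5))
#' res$manifest$stage_counts
#' @export
run_pipeline <- function(counts, annotation = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(counts)) counts <- read_counts(counts)
  stage <- "qc"
  res <- list(config = config)
  seeds <- expand_seed(config$seed, 8L)
  tryCatch({
    counts <- deduplicate_genes(counts, config$filter)
    res$qc <- apply_filters(counts, config$filter)
    res$profiles <- retained_profiles(res$qc)
    n_retained <- nrow(res$profiles)
    stage <- "symbols"
    if (config$run_symbols && n_retained > 0L) {
      res$triplets <- encode_triplet(res$profiles, config$scheme)
      res$census <- census_patterns(res$triplets, res$profiles)
      res$singletons <- find_singletons(res$census)
    }
    stage <- "centroids"
    if (n_retained > 0L) {
      ann <- annotation
      if (is.null(ann))
        ann <- data.frame(gene_id = res$profiles$gene_id,
                          pathway = "all", stringsAsFactors = FALSE)
      res$centroid_table <- pathway_centroids(res$profiles, ann)
    }
    stage <- "outliers"
    outlier_genes <- character(0)
    if (config$run_outliers && n_retained > 0L) {
      res$ranking <- rank_by_centroid_distance(
        res$profiles, res$centroid_table$global_center)
      res$centroid_top <- select_top_by_gap(
        res$ranking, default_k = min(config$top_k, nrow(res$ranking)),
        mode = config$gap_mode)
      res$kdist <- kdist_profile(res$profiles,
                                 k = config$dbscan$min_samples)
      eps <- if (config$auto_epsilon)
        select_epsilon(res$kdist, default = config$dbscan$epsilon)
      else config$dbscan$epsilon
      res$epsilon <- eps
      res$dbscan_labels <- dbscan_profiles(
        res$profiles, dbscan_config(eps, config$dbscan$min_samples))
      dbscan_noise <- names(res$dbscan_labels)[res$dbscan_labels == -1L]
      singles <- if (config$run_symbols) res$singletons else character(0)
      res$consensus <- consensus_venn(
        as.character(res$centroid_top), dbscan_noise, singles,
        universe = res$profiles$gene_id)
      outlier_genes <- dbscan_noise
    }
    res$core_profiles <- res$profiles[
      !res$profiles$gene_id %in% outlier_genes, , drop = FALSE]
    stage <- "mixture"
    if (config$run_mixture && nrow(res$core_profiles) >
          max(config$k_choices)) {
      ka <- config$k_choices[1L]
      kb <- config$k_choices[2L]
      res$model_a <- fit_gmm_tied(res$core_profiles, ka, seed = seeds[1L],
                                  n_restarts = config$n_restarts)
      res$model_b <- fit_gmm_tied(res$core_profiles, kb, seed = seeds[2L],
                                  n_restarts = config$n_restarts)
      res$kmeans_labels <- fit_kmeans(res$core_profiles, kb,
                                      seed = seeds[3L],
                                      n_restarts = config$n_restarts)
      res$silhouettes <- c(
        gmm = silhouette_mean(res$core_profiles, res$model_b$labels),
        kmeans = silhouette_mean(res$core_profiles, res$kmeans_labels))
      res$boundary <- mahalanobis_boundary(
        res$model_b, res$core_profiles,
        threshold = config$mahalanobis_threshold)
      res$transitions <- transition_table(res$model_a$labels,
                                          res$model_b$labels)
      if (config$run_scan)
        res$scan <- model_scan(res$core_profiles, config$k_range,
                               seed = seeds[4L],
                               n_restarts = config$n_restarts)
      if (config$run_stability)
        res$stability <- loo_ari(res$core_profiles, ka, kb,
                                 seed = seeds[5L],
                                 n_restarts = max(3L, config$n_restarts %/% 2L))
    }
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  verdicts <- table(res$qc$verdict)
  res$manifest <- list(
    seed = config$seed,
    stage_seeds = seeds,
    thresholds = list(
      max_total_error = config$filter$max_total_error,
      min_copies = config$filter$min_copies,
      error_method = config$filter$error_method,
      epsilon = if (config$run_outliers) res$epsilon else NA,
      min_samples = config$dbscan$min_samples,
      mahalanobis = config$mahalanobis_threshold),
    stage_counts = list(
      input_genes = nrow(res$qc),
      retained = nrow(res$profiles),
      excluded_error = unname(verdicts["excluded_error"]),
      excluded_lowcount = unname(verdicts["excluded_lowcount"]),
      excluded_nonconsensus = unname(verdicts["excluded_nonconsensus"]),
      outliers_removed = nrow(res$profiles) - nrow(res$core_profiles),
      clustered = if (config$run_mixture) nrow(res$core_profiles) else 0L),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stopifnot(res$manifest$stage_counts$retained +
              sum(verdicts[-1L]) == res$manifest$stage_counts$input_genes)
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  res
}

write_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(x, file) utils::write.table(
    x, file.path(out_dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(as.data.frame(res$qc), "qc_report.tsv")
  tsv(res$profiles, "retained_profiles.tsv")
  if (!is.null(res$census)) tsv(res$census$patterns, "patterns.tsv")
  if (!is.null(res$ranking)) tsv(res$ranking, "centroid_distances.tsv")
  if (!is.null(res$kdist))
    tsv(data.frame(rank = seq_along(res$kdist), kdist = res$kdist),
        "kdist_curve.tsv")
  if (!is.null(res$dbscan_labels))
    tsv(data.frame(gene_id = names(res$dbscan_labels),
                   label = as.integer(res$dbscan_labels)),
        "dbscan_labels.tsv")
  if (!is.null(res$consensus)) {
    jsonlite::write_json(res$consensus$regions,
                         file.path(out_dir, "venn_regions.json"),
                         auto_unbox = FALSE)
    tsv(res$consensus$membership, "outlier_membership.tsv")
  }
  if (!is.null(res$model_b)) {
    model_json <- list(
      k = res$model_b$k, weights = res$model_b$weights,
      means = res$model_b$means,
      tied_covariance = res$model_b$tied_covariance,
      log_likelihood = res$model_b$log_likelihood,
      bic = res$model_b$bic,
      labels = as.list(res$model_b$labels))
    jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    tsv(as.data.frame(res$boundary), "boundary_report.tsv")
    jsonlite::write_json(
      sankey_data(res$transitions,
                  prefix_a = paste0("k", res$model_a$k),
                  prefix_b = paste0("k", res$model_b$k)),
      file.path(out_dir, "sankey.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$scan)) tsv(as.data.frame(res$scan), "model_scan.tsv")
  if (!is.null(res$stability)) tsv(res$stability$per_gene, "stability.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(write_report(res), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Human-readable run summary
#'
#' Renders per-stage gene counts, the centroid table with the Global
#' Center, the pattern census, the outlier consensus and the selected
#' mixture models as plain text. Regenerating the report from the same
#' result yields identical text.
#'
#' @param res a [run_pipeline()] result.
#' @return character vector of report lines (invisibly printable via
#'   `writeLines()`).
#' @export
write_report <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  sc <- res$manifest$stage_counts
  num <- function(x) ifelse(is.na(x), 0L, x)
  lines <- c(
    "== duplicate-panel analysis report ==",
    sprintf("input genes: %d", sc$input_genes),
    sprintf("retained after QC: %d (error-excluded %d, low-count %d, non-consensus %d)",
            sc$retained, num(sc$excluded_error), num(sc$excluded_lowcount),
            num(sc$excluded_nonconsensus)),
    sprintf("outliers removed: %d | clustered: %d",
            sc$outliers_removed, sc$clustered))
  ct <- res$centroid_table
  if (!is.null(ct)) {
    lines <- c(lines, "", "-- centroids --")
    for (i in seq_len(nrow(ct$centroids))) {
      row <- ct$centroids[i, ]
      rc <- grep("^r[0-9]+$", names(ct$centroids), value = TRUE)
      lines <- c(lines, sprintf("%-32s n=%-3d %s", row$pathway, row$n_genes,
                                paste(sprintf("%.3f", unlist(row[rc])),
                                      collapse = " ")))
    }
    lines <- c(lines, sprintf("%-32s n=%-3d %s", "Global Center",
                              sc$retained,
                              paste(sprintf("%.3f", ct$global_center),
                                    collapse = " ")))
  }
  if (!is.null(res$census)) {
    lines <- c(lines, "", "-- trajectory patterns --",
               sprintf("%d of %d theoretical codes realized",
                       res$census$n_observed, res$census$n_theoretical),
               sprintf("singletons: %s",
                       if (length(res$singletons))
                         paste(res$singletons, collapse = ", ")
                       else "(none)"))
  }
  if (!is.null(res$consensus)) {
    lines <- c(lines, "", "-- outlier consensus --",
               sprintf("%s: %d", names(res$consensus$counts),
                       res$consensus$counts))
  }
  if (!is.null(res$model_b) && sc$clustered > 0L) {
    lines <- c(lines, "", "-- mixture modules --",
               sprintf("k = %d tied: logLik %.2f, BIC %.2f",
                       res$model_b$k, res$model_b$log_likelihood,
                       res$model_b$bic),
               sprintf("silhouette: mixture %.3f vs k-means %.3f",
                       res$silhouettes["gmm"], res$silhouettes["kmeans"]),
               sprintf("boundary drivers (d_M > %.2f): %d",
                       attr(res$boundary, "threshold"),
                       sum(res$boundary$is_driver)))
    for (j in seq_len(res$model_b$k)) {
      members <- sort(names(res$model_b$labels)[res$model_b$labels == j])
      lines <- c(lines, sprintf(
        "cluster %d (n=%d, centroid %s): %s", j, length(members),
        paste(sprintf("%.3f", res$model_b$means[j, ]), collapse = " "),
        paste(members, collapse = ",")))
    }
  } else if (sc$retained == 0L) {
    lines <- c(lines, "", "zero genes retained; no clustering performed")
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(write_report(x))
  invisible(x)
}
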