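# Synthetic duplicate-count panels with known ground truth.
#
# The generator emulates a NanoString-style cancer panel measured in
# technical duplicate at four deuterium concentrations (40/80/150/300 ppm,
# 150 ppm = control): log-normal baseline copy numbers at control,
# cluster-structured 3-D ratio profiles around six module centroids, a set
# of planted far-off outlier profiles, and planted QC-failing genes (high
# duplicate error or low control counts). Ground truth (cluster label,
# outlier flag, QC-fail reason, true ratio profile) travels in a sidecar
# table that the analysis pipeline itself never reads.

# Six module centroids in (r40, r80, r300) ratio space with membership
# weights proportional to module size; the layout mirrors a graded
# dose-response in which induction at 300 ppm separates the modules.
default_cluster_centroids <- function() {
  m <- rbind(
    c(0.906, 0.984, 1.666),
    c(0.792, 0.929, 1.565),
    c(0.982, 0.975, 1.460),
    c(0.820, 0.952, 1.343),
    c(0.957, 0.903, 1.264),
    c(0.830, 0.897, 1.180))
  dimnames(m) <- list(paste0("module", 1:6), c("r40", "r80", "r300"))
  m
}

default_cluster_weights <- function() {
  w <- c(17, 18, 13, 17, 9, 17)
  w / sum(w)
}

# Planted density outliers: profiles reconstructed from per-gene percent
# changes of archetypal sentinel responders (drug-efflux V-shape, receptor
# suppression under depletion, strong cytokine induction under enrichment,
# progressive up-trends). They sit well outside the clustered cloud.
default_outlier_profiles <- function() {
  m <- rbind(
    abcb1_like  = c(1.120, 0.585, 1.270),
    fgfr4_like  = c(0.810, 0.810, 0.850),
    mycn_like   = c(1.000, 0.760, 1.010),
    il6_like    = c(1.000, 1.000, 1.990),
    tgfbr2_like = c(1.000, 1.000, 2.050),
    ptk7_like   = c(1.300, 1.050, 1.550),
    bcl3_like   = c(1.280, 1.020, 1.620),
    ptgs2_like  = c(1.220, 1.000, 1.800))
  colnames(m) <- c("r40", "r80", "r300")
  m
}

#' Configuration for the synthetic panel generator
#'
#' Builds and validates the parameter set controlling [generate_panel()].
#' Defaults reproduce the study conditions the package targets: 110 genes
#' entering QC of which 102 survive (6 planted high-error and 2 planted
#' low-count failures), six ratio-space modules with weights proportional
#' to module size, eight planted sentinel-outlier profiles, and duplicate
#' noise whose per-gene coefficient of variation is drawn from
#' `duplicate_cv_range`.
#'
#' @param n_genes number of genes on the panel.
#' @param concentrations ordered deuterium concentrations in ppm.
#' @param control_ppm the control concentration; must be one of
#'   `concentrations`.
#' @param cluster_centroids numeric matrix, one row per module, columns =
#'   ratios at the non-control concentrations.
#' @param cluster_weights module membership probabilities (summing to 1).
#' @param ratio_noise_sd isotropic Gaussian spread of clustered profiles
#'   around their centroid, in ratio units.
#' @param outlier_profiles numeric matrix of planted outlier profiles
#'   (used exactly, without cluster noise); `NULL` for none.
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of the
#'   control-concentration copy-number baseline.
#' @param duplicate_cv_range interval from which each well-behaved gene's
#'   true duplicate CV is drawn; must lie within `[0, 1)`.
#' @param n_qc_fail_error number of planted genes whose duplicate CV
#'   (`qc_fail_cv`) drives the summed propagated ratio error past the
#'   exclusion threshold.
#' @param qc_fail_cv duplicate CV given to error-planted genes.
#' @param n_qc_fail_lowcount number of planted genes with control-mean
#'   copy number below the low-count threshold.
#' @param lowcount_range interval of control baselines for low-count
#'   planted genes.
#' @param integer_counts round replicate counts to whole copy numbers
#'   (floored at zero). Disable for exact zero-noise identities.
#' @param seed master seed; every draw in [generate_panel()] derives from
#'   it.
#' @return a validated list of class `"generator_config"`.
#' @seealso [generate_panel()], [read_generator_config()]
#' @export
generator_config <- function(n_genes = 110L,
                             concentrations = c(40, 80, 150, 300),
                             control_ppm = 150,
                             cluster_centroids = default_cluster_centroids(),
                             cluster_weights = default_cluster_weights(),
                             ratio_noise_sd = 0.10,
                             outlier_profiles = default_outlier_profiles(),
                             baseline_log_mean = log(500),
                             baseline_log_sd = 1.0,
                             duplicate_cv_range = c(0.005, 0.09),
                             n_qc_fail_error = 6L,
                             qc_fail_cv = 0.20,
                             n_qc_fail_lowcount = 2L,
                             lowcount_range = c(5, 15),
                             integer_counts = TRUE,
                             seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("'n_genes' must be a positive integer")
  n_genes <- as.integer(n_genes)
  stopifnot(is.numeric(concentrations), length(concentrations) >= 2L,
            !anyDuplicated(concentrations))
  if (!control_ppm %in% concentrations)
    stop("'control_ppm' must be one of 'concentrations'")
  cluster_centroids <- as.matrix(cluster_centroids)
  if (nrow(cluster_centroids) == 0L)
    stop("'cluster_centroids' must contain at least one centroid")
  non_control <- setdiff(concentrations, control_ppm)
  if (ncol(cluster_centroids) != length(non_control))
    stop("centroids need one column per non-control concentration")
  if (any(cluster_centroids <= 0))
    stop("cluster centroids must be strictly positive")
  if (length(cluster_weights) != nrow(cluster_centroids))
    stop("one weight per centroid required")
  if (any(cluster_weights < 0) || abs(sum(cluster_weights) - 1) > 1e-8)
    stop("'cluster_weights' must be nonnegative and sum to 1")
  if (!is.null(outlier_profiles)) {
    outlier_profiles <- as.matrix(outlier_profiles)
    if (nrow(outlier_profiles) > 0L && any(outlier_profiles <= 0))
      stop("outlier profiles must be strictly positive")
    if (nrow(outlier_profiles) > 0L &&
        ncol(outlier_profiles) != length(non_control))
      stop("outlier profiles need one column per non-control concentration")
  } else {
    outlier_profiles <- matrix(numeric(0), 0L, length(non_control))
  }
  stopifnot(is.numeric(ratio_noise_sd), ratio_noise_sd >= 0)
  stopifnot(length(duplicate_cv_range) == 2L,
            duplicate_cv_range[1] <= duplicate_cv_range[2])
  if (duplicate_cv_range[1] < 0 || duplicate_cv_range[2] >= 1)
    stop("'duplicate_cv_range' must lie within [0, 1)")
  stopifnot(qc_fail_cv >= 0, qc_fail_cv < 1)
  n_qc_fail_error <- as.integer(n_qc_fail_error)
  n_qc_fail_lowcount <- as.integer(n_qc_fail_lowcount)
  stopifnot(n_qc_fail_error >= 0L, n_qc_fail_lowcount >= 0L)
  n_special <- nrow(outlier_profiles) + n_qc_fail_error + n_qc_fail_lowcount
  if (n_special > n_genes)
    stop(sprintf(
      "planted outliers + QC failures (%d) exceed n_genes (%d)",
      n_special, n_genes))
  stop_if_not_scalar_number(seed, "seed")

  structure(list(
    n_genes = n_genes,
    concentrations = as.numeric(concentrations),
    control_ppm = as.numeric(control_ppm),
    cluster_centroids = cluster_centroids,
    cluster_weights = as.numeric(cluster_weights),
    ratio_noise_sd = as.numeric(ratio_noise_sd),
    outlier_profiles = outlier_profiles,
    baseline_log_mean = as.numeric(baseline_log_mean),
    baseline_log_sd = as.numeric(baseline_log_sd),
    duplicate_cv_range = as.numeric(duplicate_cv_range),
    n_qc_fail_error = n_qc_fail_error,
    qc_fail_cv = as.numeric(qc_fail_cv),
    n_qc_fail_lowcount = n_qc_fail_lowcount,
    lowcount_range = as.numeric(lowcount_range),
    integer_counts = isTRUE(integer_counts),
    seed = as.integer(seed)),
    class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Any field of [generator_config()] may appear in the file; missing
#' fields take their defaults. A `seed` must be present in the file or
#' supplied through `seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param seed optional seed overriding (or supplying) the file's.
#' @return a `"generator_config"` object.
#' @export
read_generator_config <- function(path, seed = NULL) {
  stopifnot(file.exists(path))
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(seed)) fields$seed <- seed
  if (is.null(fields$seed))
    stop("a seed must be given in the config file or via 'seed'")
  for (m in c("cluster_centroids", "outlier_profiles"))
    if (!is.null(fields[[m]])) fields[[m]] <- as.matrix(fields[[m]])
  do.call(generator_config, fields)
}

#' Generate a synthetic duplicate-count panel
#'
#' Draws, for each gene, a module membership (or a planted outlier /
#' QC-failure slot), a true ratio profile, a control baseline copy number,
#' and two technical replicates per concentration. Replicates are
#' `expected * (1 +/- cv)` with a random sign, so the duplicate dispersion
#' statistic `|x1 - x2| / (x1 + x2)` of each pair equals the gene's drawn
#' CV (up to integer rounding). Planted outliers use their configured
#' profile exactly; planted QC failures override the gene with a CV that
#' fails the summed-error filter or a control baseline below the copy
#' threshold. Identical configurations (including seed) give identical
#' panels.
#'
#' @param config a [generator_config()].
#' @return an object of class `"synthetic_panel"`: a list with `counts`
#'   (data.frame `gene_id`, `ppm`, `rep1`, `rep2`) and `truth` (data.frame
#'   `gene_id`, `cluster_id`, `is_outlier`, `qc_fail_reason`, plus the
#'   true ratio columns).
#' @examples
#' panel <- generate_panel(generator_config(n_genes = 20, seed = 7))
#' head(panel$counts)
#' table(panel$truth$qc_fail_reason, useNA = "ifany")
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(config) {
  n <- config$n_genes
  conc <- config$concentrations
  non_control <- setdiff(conc, config$control_ppm)
  d <- length(non_control)
  n_out <- nrow(config$outlier_profiles)
  n_err <- config$n_qc_fail_error
  n_low <- config$n_qc_fail_lowcount

  gene_id <- sprintf("G%04d", seq_len(n))
  # roles scattered over the panel so planted genes are not positional
  role <- rep("cluster", n)
  special <- sample.int(n, n_out + n_err + n_low)
  if (n_out > 0L) role[special[seq_len(n_out)]] <- "outlier"
  if (n_err > 0L) role[special[n_out + seq_len(n_err)]] <- "fail_error"
  if (n_low > 0L) role[special[n_out + n_err + seq_len(n_low)]] <- "fail_lowcount"

  cluster_id <- rep(NA_integer_, n)
  is_cluster_like <- role %in% c("cluster", "fail_error", "fail_lowcount")
  drawn <- sample.int(nrow(config$cluster_centroids), sum(is_cluster_like),
                      replace = TRUE, prob = config$cluster_weights)
  cluster_id[is_cluster_like] <- drawn
  # planted failures never enter clustering; truth carries no label for them
  true_profiles <- matrix(NA_real_, n, d,
                          dimnames = list(gene_id, paste0("r", non_control)))
  noise <- matrix(stats::rnorm(n * d, 0, config$ratio_noise_sd), n, d)
  true_profiles[is_cluster_like, ] <-
    config$cluster_centroids[cluster_id[is_cluster_like], , drop = FALSE] +
    noise[is_cluster_like, , drop = FALSE]
  out_idx <- which(role == "outlier")
  if (n_out > 0L)
    true_profiles[out_idx, ] <- config$outlier_profiles
  true_profiles <- pmax(true_profiles, 0.05)  # ratios stay strictly positive
  cluster_id[role != "cluster"] <- NA_integer_

  baseline <- pmax(stats::rlnorm(n, config$baseline_log_mean,
                                 config$baseline_log_sd), 30)
  low_idx <- which(role == "fail_lowcount")
  baseline[low_idx] <- stats::runif(length(low_idx),
                                    config$lowcount_range[1],
                                    config$lowcount_range[2])

  cv <- stats::runif(n, config$duplicate_cv_range[1],
                     config$duplicate_cv_range[2])
  cv[role == "fail_error"] <- config$qc_fail_cv

  # expected counts: baseline at control, baseline * ratio elsewhere
  ratio_full <- cbind(true_profiles, 1)
  colnames(ratio_full) <- c(paste0("r", non_control),
                            paste0("r", config$control_ppm))
  conc_order <- as.character(conc)
  expected <- baseline * ratio_full[, paste0("r", conc_order), drop = FALSE]

  sign_draw <- matrix(sample(c(-1, 1), n * length(conc), replace = TRUE),
                      n, length(conc))
  delta <- sign_draw * cv
  rep1 <- expected * (1 + delta)
  rep2 <- expected * (1 - delta)
  if (config$integer_counts) {
    rep1 <- pmax(round(rep1), 0)
    rep2 <- pmax(round(rep2), 0)
  }

  counts <- data.frame(
    gene_id = rep(gene_id, each = length(conc)),
    ppm = rep(conc, times = n),
    rep1 = as.vector(t(rep1)),
    rep2 = as.vector(t(rep2)),
    stringsAsFactors = FALSE)

  qc_fail_reason <- rep(NA_character_, n)
  qc_fail_reason[role == "fail_error"] <- "error"
  qc_fail_reason[role == "fail_lowcount"] <- "lowcount"
  truth <- data.frame(
    gene_id = gene_id,
    cluster_id = cluster_id,
    is_outlier = role == "outlier",
    qc_fail_reason = qc_fail_reason,
    true_cv = cv,
    stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(true_profiles))
  rownames(truth) <- NULL

  structure(list(counts = counts, truth = truth, config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "synthetic_panel: %d genes x %d concentrations (%d count rows)\n",
    nrow(tr), length(x$config$concentrations), nrow(x$counts)))
  cat(sprintf("  clustered: %d | planted outliers: %d | planted QC fails: %d\n",
              sum(!is.na(tr$cluster_id)), sum(tr$is_outlier),
              sum(!is.na(tr$qc_fail_reason))))
  invisible(x)
}

#' Write a synthetic panel to delimited text
#'
#' Emits the counts table in the pipeline's input dialect (tab-separated,
#' columns `gene_id`, `ppm`, `rep1`, `rep2`) plus a sidecar truth table.
#' The sidecar is for validation only; the analysis pipeline never reads
#' it. Files round-trip losslessly through [read_counts()].
#'
#' @param panel a `"synthetic_panel"` (or any list with `counts` and
#'   `truth` data.frames).
#' @param dir destination directory (created if missing).
#' @param prefix file-name prefix; files are `<prefix>_counts.tsv` and
#'   `<prefix>_truth.tsv`.
#' @return invisibly, a named character vector of the two paths.
#' @export
write_panel <- function(panel, dir, prefix = "panel") {
  stopifnot(is.list(panel), !is.null(panel$counts), !is.null(panel$truth))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  utils::write.table(panel$counts, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Recover the measured ratio profiles implied by a panel's counts
#'
#' Convenience accessor used by tests and examples: mean of the duplicate
#' pair at each concentration divided by the control mean.
#'
#' @param panel a `"synthetic_panel"`.
#' @return data.frame `gene_id`, one `r<ppm>` column per non-control
#'   concentration.
#' @keywords internal
#' @export
panel_ratio_profiles <- function(panel) {
  cfg <- panel$config
  qc <- apply_filters(panel$counts,
                      filter_config(control_ppm = cfg$control_ppm,
                                    max_total_error = Inf, min_copies = 0))
  qc[, c("gene_id", grep("^r[0-9]+$", names(qc), value = TRUE))]
}
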