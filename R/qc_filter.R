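# Duplicate-based quality control.
#
# Each gene is measured as a technical duplicate (x1, x2) at every
# concentration. Dispersion is summarized by the dimensionless statistic
# CV = |x1 - x2| / (x1 + x2); expression ratios versus the control
# concentration carry a propagated relative error combining the CVs of
# numerator and denominator, and the three per-ratio errors are summed
# into a per-gene total. Genes with total error above `max_total_error`
# or control-mean copy number below `min_copies` are excluded; an
# optional consensus gene list restricts the survivors further.

#' QC filter configuration
#'
#' @param max_total_error exclusion threshold on the summed per-ratio
#'   propagated error (strict: only totals above it are excluded).
#' @param min_copies exclusion threshold on the control-mean copy number
#'   (strict: only means below it are excluded).
#' @param control_ppm control concentration in ppm.
#' @param consensus_genes optional character vector of symbols; when
#'   supplied, genes outside it are marked `excluded_nonconsensus`.
#' @param error_method how the two duplicate CVs of a ratio combine:
#'   `"quadrature"` (root-sum-square, the standard propagation for a
#'   quotient of independent measurements) or `"linear"` (plain sum, the
#'   conservative bound).
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(max_total_error = 0.55,
                          min_copies = 20,
                          control_ppm = 150,
                          consensus_genes = NULL,
                          error_method = c("quadrature", "linear")) {
  stopifnot(max_total_error > 0, min_copies >= 0)
  error_method <- match.arg(error_method)
  structure(list(max_total_error = max_total_error,
                 min_copies = min_copies,
                 control_ppm = as.numeric(control_ppm),
                 consensus_genes = consensus_genes,
                 error_method = error_method),
            class = "filter_config")
}

#' Duplicate coefficient of variation
#'
#' `|x1 - x2| / (x1 + x2)`: a dimensionless dispersion measure for a
#' technical duplicate, bounded in `[0, 1]`. The absolute value makes it
#' a proper dispersion measure; the sign of the raw difference carries no
#' information used downstream.
#'
#' @param rep1,rep2 nonnegative replicate counts (vectorized).
#' @return CV in `[0, 1]`.
#' @examples
#' compute_cv(120, 80)  # 0.2
#' @export
compute_cv <- function(rep1, rep2) {
  stopifnot(length(rep1) == length(rep2))
  if (any(rep1 < 0 | rep2 < 0)) stop("replicate counts must be nonnegative")
  s <- rep1 + rep2
  if (any(s == 0))
    stop("CV undefined: both replicates are zero")
  abs(rep1 - rep2) / s
}

#' Expression ratio of a gene at one concentration versus control
#'
#' Ratio of duplicate means: `mean(x1, x2 at ppm) / mean(x1, x2 at
#' control)`.
#'
#' @param counts count rows for a single gene (`ppm`, `rep1`, `rep2`).
#' @param ppm target concentration.
#' @param control_ppm control concentration.
#' @return dimensionless ratio.
#' @export
compute_ratio <- function(counts, ppm, control_ppm = 150) {
  num <- counts[counts$ppm == ppm, , drop = FALSE]
  den <- counts[counts$ppm == control_ppm, , drop = FALSE]
  if (nrow(num) != 1L) stop(sprintf("need exactly one row at %g ppm", ppm))
  if (nrow(den) != 1L)
    stop(sprintf("need exactly one row at control (%g ppm)", control_ppm))
  m_ctrl <- (den$rep1 + den$rep2) / 2
  if (m_ctrl <= 0) stop("control mean must be positive")
  ((num$rep1 + num$rep2) / 2) / m_ctrl
}

#' Propagated relative error of an expression ratio
#'
#' Combines the duplicate CVs of the target and control concentrations.
#' Quadrature (`sqrt(cv_ppm^2 + cv_control^2)`) is the standard
#' propagation for a quotient of independent measurements; the linear sum
#' is available as a conservative alternative.
#'
#' @param cv_ppm,cv_control duplicate CVs in `[0, 1]` (vectorized).
#' @param method `"quadrature"` or `"linear"`.
#' @return relative error, always `>= max(cv_ppm, cv_control)`.
#' @examples
#' propagate_ratio_error(0.3, 0.4)  # 0.5
#' @export
propagate_ratio_error <- function(cv_ppm, cv_control,
                                  method = c("quadrature", "linear")) {
  method <- match.arg(method)
  if (any(cv_ppm < 0 | cv_ppm > 1 | cv_control < 0 | cv_control > 1))
    stop("CVs must lie in [0, 1]")
  if (method == "quadrature") sqrt(cv_ppm^2 + cv_control^2)
  else cv_ppm + cv_control
}

#' Total relative error of a gene
#'
#' Arithmetic sum of the per-ratio propagated errors at the non-control
#' concentrations.
#'
#' @param errors numeric vector of per-ratio errors.
#' @return their sum.
#' @export
total_error <- function(errors) {
  if (any(!is.finite(errors))) stop("per-ratio errors must be finite")
  sum(errors)
}

#' Resolve genes measured more than once
#'
#' Panels occasionally carry repeated measurement records for the same
#' symbol. Records are distinguished by their order of appearance per
#' (gene, ppm); for each multiply-measured symbol the record with the
#' lower total propagated error is kept, ties resolved in favour of the
#' first record in file order. Each dropped record is reported via
#' `message()`.
#'
#' @param counts duplicate-count table (`gene_id`, `ppm`, `rep1`, `rep2`).
#' @param config a [filter_config()] (controls control ppm and error
#'   method used to score records).
#' @return the counts table with one record per symbol.
#' @export
deduplicate_genes <- function(counts, config = filter_config()) {
  check_counts_table(counts, require_unique = FALSE)
  rec <- stats::ave(seq_len(nrow(counts)),
                    counts$gene_id, counts$ppm, FUN = seq_along)
  if (max(rec) == 1L) return(counts)
  keep <- rep(TRUE, nrow(counts))
  for (g in unique(counts$gene_id[rec > 1L])) {
    idx <- which(counts$gene_id == g)
    recs <- sort(unique(rec[idx]))
    errs <- vapply(recs, function(r) {
      sub <- counts[idx[rec[idx] == r], , drop = FALSE]
      record_total_error(sub, config)
    }, numeric(1))
    best <- recs[which.min(errs)]  # which.min takes the first on ties
    for (r in setdiff(recs, best)) {
      message(sprintf(
        "deduplicate_genes: dropping record %d of '%s' (total error %.4g > %.4g)",
        r, g, errs[recs == r], min(errs)))
      keep[idx[rec[idx] == r]] <- FALSE
    }
  }
  counts[keep, , drop = FALSE]
}

record_total_error <- function(sub, config) {
  cvs <- compute_cv(sub$rep1, sub$rep2)
  names(cvs) <- as.character(sub$ppm)
  ctrl <- as.character(config$control_ppm)
  if (!ctrl %in% names(cvs)) return(Inf)
  others <- setdiff(names(cvs), ctrl)
  total_error(propagate_ratio_error(cvs[others], cvs[[ctrl]],
                                    config$error_method))
}

check_counts_table <- function(counts, require_unique = TRUE) {
  needed <- c("gene_id", "ppm", "rep1", "rep2")
  if (!is.data.frame(counts) || !all(needed %in% names(counts)))
    stop("counts must be a data.frame with columns gene_id, ppm, rep1, rep2")
  if (any(!is.finite(counts$rep1)) || any(!is.finite(counts$rep2)) ||
      any(counts$rep1 < 0) || any(counts$rep2 < 0))
    stop("replicate counts must be finite and nonnegative")
  if (require_unique && anyDuplicated(counts[, c("gene_id", "ppm")]))
    stop("duplicated (gene_id, ppm) rows; resolve with deduplicate_genes()")
  invisible(counts)
}

#' Apply the multi-step duplicate-error filter
#'
#' Computes, per gene: the duplicate CV and mean at every concentration,
#' control-normalized expression ratios, per-ratio propagated errors,
#' their total, and a verdict. Exclusion reasons are prioritized
#' `lowcount > error > nonconsensus`; thresholds are strict, so a gene
#' exactly at a threshold is retained. Consensus filtering applies only
#' when `config$consensus_genes` is non-`NULL`.
#'
#' @param counts duplicate-count table with one record per gene and one
#'   row per (gene, ppm).
#' @param config a [filter_config()].
#' @return data.frame of class `"gene_qc"` with one row per gene:
#'   `mean_<ppm>` and `cv_<ppm>` per concentration, `r<ppm>` and
#'   `err_<ppm>` per non-control concentration, `total_error`, `verdict`.
#' @examples
#' panel <- generate_panel(generator_config(n_genes = 30, seed = 2))
#' qc <- apply_filters(panel$counts)
#' table(qc$verdict)
#' @export
apply_filters <- function(counts, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  check_counts_table(counts)
  conc <- sort(unique(counts$ppm))
  if (!config$control_ppm %in% conc)
    stop(sprintf("control concentration %g ppm absent from counts",
                 config$control_ppm))
  genes <- unique(counts$gene_id)
  per_gene <- table(counts$gene_id)
  if (any(per_gene != length(conc))) {
    bad <- names(per_gene)[per_gene != length(conc)]
    stop(sprintf("gene(s) missing a concentration: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }

  counts <- counts[order(match(counts$gene_id, genes), counts$ppm), ]
  n <- length(genes)
  k <- length(conc)
  r1 <- matrix(counts$rep1, n, k, byrow = TRUE)
  r2 <- matrix(counts$rep2, n, k, byrow = TRUE)
  means <- (r1 + r2) / 2
  if (any(r1 + r2 == 0))
    stop("CV undefined: both replicates are zero for some (gene, ppm)")
  cvs <- abs(r1 - r2) / (r1 + r2)
  colnames(means) <- paste0("mean_", conc)
  colnames(cvs) <- paste0("cv_", conc)

  ctrl_i <- which(conc == config$control_ppm)
  others <- setdiff(seq_len(k), ctrl_i)
  ctrl_mean <- means[, ctrl_i]
  ratios <- means[, others, drop = FALSE] / ifelse(ctrl_mean > 0, ctrl_mean, NA)
  colnames(ratios) <- paste0("r", conc[others])
  errs <- propagate_ratio_error(cvs[, others, drop = FALSE],
                                cvs[, ctrl_i], config$error_method)
  colnames(errs) <- paste0("err_", conc[others])
  tot <- rowSums(errs)

  verdict <- rep("retained", n)
  if (!is.null(config$consensus_genes))
    verdict[!genes %in% config$consensus_genes] <- "excluded_nonconsensus"
  verdict[tot > config$max_total_error] <- "excluded_error"
  verdict[ctrl_mean < config$min_copies] <- "excluded_lowcount"

  qc <- data.frame(gene_id = genes, means, cvs, ratios, errs,
                   total_error = tot,
                   verdict = factor(verdict, levels = c(
                     "retained", "excluded_error", "excluded_lowcount",
                     "excluded_nonconsensus")),
                   stringsAsFactors = FALSE)
  rownames(qc) <- NULL
  class(qc) <- c("gene_qc", "data.frame")
  qc
}

#' Ratio profiles of the retained genes
#'
#' @param qc result of [apply_filters()].
#' @return data.frame `gene_id` plus one `r<ppm>` column per non-control
#'   concentration, restricted to retained genes.
#' @export
retained_profiles <- function(qc) {
  stopifnot(inherits(qc, "gene_qc"))
  out <- qc[qc$verdict == "retained",
            c("gene_id", grep("^r[0-9]+$", names(qc), value = TRUE))]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
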