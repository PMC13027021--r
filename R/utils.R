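# Internal helpers shared across modules.

#' Expand a master seed into deterministic sub-seeds
#'
#' One master seed governs every stochastic stage; sub-seeds are drawn from
#' a stream keyed by the master seed so that restarts, leave-one-out refits
#' and generator draws are reproducible yet decoupled.
#'
#' @param seed master seed (single integer).
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
#' @noRd
expand_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Coerce a profiles data.frame (gene_id, r40, r80, r300) to a numeric
# matrix with gene ids as rownames. Accepts matrices unchanged.
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles)))
      rownames(profiles) <- sprintf("g%03d", seq_len(nrow(profiles)))
    storage.mode(profiles) <- "double"
    return(profiles)
  }
  stopifnot(is.data.frame(profiles))
  ratio_cols <- grep("^r[0-9]+$", names(profiles), value = TRUE)
  if (length(ratio_cols) == 0L)
    stop("no ratio columns (r<ppm>) found in profiles")
  ratio_cols <- ratio_cols[order(as.numeric(sub("^r", "", ratio_cols)))]
  m <- as.matrix(profiles[, ratio_cols, drop = FALSE])
  rownames(m) <- if ("gene_id" %in% names(profiles))
    as.character(profiles$gene_id) else sprintf("g%03d", seq_len(nrow(m)))
  storage.mode(m) <- "double"
  m
}

# log(sum(exp(x))) along rows of a matrix, guarded against underflow.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
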