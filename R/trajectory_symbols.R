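# Symbolic encoding of three-point expression trajectories.
#
# Each control-normalized ratio is mapped to one of five symbols —
# strong down (D, <0.70), moderate down (d, [0.70, 0.82)), stable
# (S, [0.82, 1.17]), moderate up (u, (1.17, 1.37]) and strong up
# (U, >1.37) — and a gene's trajectory across the three non-control
# concentrations becomes a three-symbol code over this alphabet
# (5^3 = 125 theoretical codes). The stable band is closed on both ends
# and its neighbours half-open, keeping "stable" maximal: the band width
# (~ +/-17%) is of the order of the measurement noise, so boundary values
# default to "no change".

symbol_levels <- function() c("D", "d", "S", "u", "U")

symbol_arrows <- function() {
  c(D = "↓", d = "↙", S = "→", u = "↗", U = "↑")
}

#' Symbol scheme: the five ratio bands
#'
#' @param down_strong upper bound of the strong-down band.
#' @param down_mod upper bound of the moderate-down band.
#' @param up_mod upper bound of the stable band / lower bound of
#'   moderate-up.
#' @param up_strong lower bound of the strong-up band.
#' @return list of class `"symbol_scheme"`.
#' @export
symbol_scheme <- function(down_strong = 0.70, down_mod = 0.82,
                          up_mod = 1.17, up_strong = 1.37) {
  if (!(0 < down_strong && down_strong < down_mod && down_mod < 1 &&
        1 < up_mod && up_mod < up_strong))
    stop("thresholds must satisfy 0 < down_strong < down_mod < 1 < up_mod < up_strong")
  structure(list(down_strong = down_strong, down_mod = down_mod,
                 up_mod = up_mod, up_strong = up_strong,
                 alphabet = symbol_levels()),
            class = "symbol_scheme")
}

#' Encode one expression ratio as a trajectory symbol
#'
#' Bands partition the positive reals: `D` below `down_strong`, `d` in
#' `[down_strong, down_mod)`, `S` in `[down_mod, up_mod]`, `u` in
#' `(up_mod, up_strong]`, `U` above `up_strong`.
#'
#' @param ratio positive expression ratio(s); vectorized.
#' @param scheme a [symbol_scheme()].
#' @return factor over the ordered alphabet `D < d < S < u < U`.
#' @examples
#' encode_symbol(c(0.585, 1.0, 1.99))
#' @export
encode_symbol <- function(ratio, scheme = symbol_scheme()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratios must be positive and finite")
  sym <- ifelse(ratio < scheme$down_strong, "D",
         ifelse(ratio < scheme$down_mod, "d",
         ifelse(ratio <= scheme$up_mod, "S",
         ifelse(ratio <= scheme$up_strong, "u", "U"))))
  factor(sym, levels = symbol_levels(), ordered = TRUE)
}

#' Encode a ratio profile as a three-symbol trajectory code
#'
#' Positionwise application of [encode_symbol()] in increasing
#' concentration order (40, 80, 300 ppm).
#'
#' @param profiles data.frame with `gene_id` and three `r<ppm>` columns
#'   (or a 3-column matrix).
#' @param scheme a [symbol_scheme()].
#' @return data.frame `gene_id`, `s40`/`s80`/`s300`-style symbol columns,
#'   and `pattern` (the concatenated code, e.g. `"SDu"`).
#' @examples
#' encode_triplet(data.frame(gene_id = "ABCB1_like",
#'                           r40 = 1.122, r80 = 0.585, r300 = 1.268))
#' @export
encode_triplet <- function(profiles, scheme = symbol_scheme()) {
  m <- profile_matrix(profiles)
  if (ncol(m) != 3L) stop("trajectory codes require exactly three ratios")
  syms <- apply(m, 2L, function(col) as.character(encode_symbol(col, scheme)))
  syms <- matrix(syms, nrow = nrow(m))
  ppm <- sub("^r", "s", colnames(m))
  out <- data.frame(gene_id = rownames(m), syms, stringsAsFactors = FALSE)
  names(out) <- c("gene_id", ppm)
  out$pattern <- paste0(syms[, 1], syms[, 2], syms[, 3])
  rownames(out) <- NULL
  out
}

#' Render a trajectory code with arrow glyphs
#'
#' @param pattern character vector of three-letter codes (`D d S u U`).
#' @return the same codes rendered as arrows, space-separated.
#' @export
pattern_arrows <- function(pattern) {
  arr <- symbol_arrows()
  vapply(strsplit(pattern, ""), function(s) paste(arr[s], collapse = " "),
         character(1))
}

#' Census of realized trajectory patterns
#'
#' Groups genes by identical symbol code, counts the distinct realized
#' codes against the 125 theoretically possible ones, and orders patterns
#' by the mean ratio of their members at the highest concentration
#' (descending; ties broken lexicographically on the code).
#'
#' @param triplets result of [encode_triplet()].
#' @param profiles the matching ratio profiles (used for pattern means).
#' @return list of class `"pattern_census"`: `patterns` (data.frame
#'   `pattern`, `arrows`, `n_genes`, mean ratio per concentration,
#'   `genes`), `assignments` (gene -> pattern), `n_theoretical` (125),
#'   `n_observed`.
#' @export
census_patterns <- function(triplets, profiles) {
  stopifnot(nrow(triplets) > 0L, "pattern" %in% names(triplets))
  m <- profile_matrix(profiles)
  m <- m[match(triplets$gene_id, rownames(m)), , drop = FALSE]
  if (any(is.na(m))) stop("every triplet needs a matching profile")
  split_idx <- split(seq_len(nrow(triplets)), triplets$pattern)
  top_col <- ncol(m)  # highest concentration orders the census
  pat <- data.frame(
    pattern = names(split_idx),
    n_genes = lengths(split_idx),
    stringsAsFactors = FALSE)
  means <- t(vapply(split_idx, function(i) colMeans(m[i, , drop = FALSE]),
                    numeric(ncol(m))))
  colnames(means) <- paste0("mean_", colnames(m))
  pat <- cbind(pat, means)
  pat$genes <- vapply(split_idx, function(i)
    paste(sort(triplets$gene_id[i]), collapse = ","), character(1))
  pat$arrows <- pattern_arrows(pat$pattern)
  ord <- order(-means[, top_col], pat$pattern)
  pat <- pat[ord, c("pattern", "arrows", "n_genes",
                    colnames(means), "genes")]
  rownames(pat) <- NULL
  structure(list(
    patterns = pat,
    assignments = stats::setNames(triplets$pattern, triplets$gene_id),
    n_theoretical = length(symbol_levels())^3L,
    n_observed = nrow(pat)),
    class = "pattern_census")
}

#' @export
print.pattern_census <- function(x, ...) {
  cat(sprintf("pattern_census: %d of %d theoretical codes realized over %d genes\n",
              x$n_observed, x$n_theoretical, length(x$assignments)))
  print(utils::head(x$patterns[, c("pattern", "arrows", "n_genes")], 10))
  invisible(x)
}

#' Genes with a trajectory code of their own
#'
#' @param census a [census_patterns()] result.
#' @return character vector of genes whose pattern has exactly one
#'   member, sorted by symbol.
#' @export
find_singletons <- function(census) {
  stopifnot(inherits(census, "pattern_census"))
  single <- census$patterns$pattern[census$patterns$n_genes == 1L]
  sort(names(census$assignments)[census$assignments %in% single])
}
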