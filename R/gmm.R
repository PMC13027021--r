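# Gaussian-mixture engine for 3-D ratio profiles.
#
# EM with either one covariance matrix shared by all components ("tied",
# equal ellipsoids — the default, which regularizes desk-scale data sets
# where per-component covariances overfit) or per-component covariances
# ("full"). Initialization is k-means++-style seeding; the best of
# several restarts by final log-likelihood is kept. The shared (or each)
# covariance is ridge-regularized on the diagonal to stay positive
# definite.

kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(m, 2L, m[centers[1L], ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      centers[j] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(m, 2L, m[centers[j], ])^2))
    }
  }
  m[centers, , drop = FALSE]
}

# log N(x | mu, Sigma) for all rows of m, via the Cholesky factor
log_dmvnorm <- function(m, mu, chol_sigma) {
  d <- ncol(m)
  xc <- sweep(m, 2L, mu)
  z <- backsolve(chol_sigma, t(xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(chol_sigma))) + colSums(z^2))
}

em_once <- function(m, k, cov_mode, tol, max_iter, ridge) {
  n <- nrow(m)
  d <- ncol(m)
  init <- kmeanspp_centers(m, k)
  dists <- vapply(seq_len(k),
                  function(j) rowSums(sweep(m, 2L, init[j, ])^2),
                  numeric(n))
  hard <- max.col(-dists)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), hard)] <- 1

  weights <- means <- NULL
  sigma <- NULL
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    empty <- which(nk < 1e-8)
    for (j in empty) {               # re-seed a starved component
      resp[, j] <- 0
      far <- which.max(-apply(resp, 1L, max))
      resp[far, ] <- 0
      resp[far, j] <- 1
      nk <- colSums(resp)
    }
    weights <- nk / n
    means <- crossprod(resp, m) / nk
    if (cov_mode == "tied") {
      s <- matrix(0, d, d)
      for (j in seq_len(k)) {
        xc <- sweep(m, 2L, means[j, ])
        s <- s + crossprod(xc * resp[, j], xc)
      }
      sigma <- s / n + diag(ridge, d)
      chols <- rep(list(chol(sigma)), k)
    } else {
      sigma <- vector("list", k)
      chols <- vector("list", k)
      for (j in seq_len(k)) {
        xc <- sweep(m, 2L, means[j, ])
        sigma[[j]] <- crossprod(xc * resp[, j], xc) / nk[j] + diag(ridge, d)
        chols[[j]] <- chol(sigma[[j]])
      }
    }
    # E-step
    logp <- vapply(seq_len(k), function(j)
      log(weights[j]) + log_dmvnorm(m, means[j, ], chols[[j]]),
      numeric(n))
    lse <- row_logsumexp(logp)
    new_loglik <- sum(lse)
    resp <- exp(logp - lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(loglik) + 1e-3)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  list(weights = weights, means = means, sigma = sigma,
       responsibilities = resp, log_likelihood = loglik,
       loglik_trace = trace, converged = converged, n_iter = length(trace))
}

gmm_n_params <- function(k, d, cov_mode) {
  cov_terms <- d * (d + 1) / 2
  (k - 1) + k * d + if (cov_mode == "tied") cov_terms else k * cov_terms
}

#' Fit a Gaussian mixture to ratio profiles
#'
#' @param profiles ratio profiles (`gene_id` + `r<ppm>` columns, or a
#'   numeric matrix).
#' @param k number of components (>= 2).
#' @param cov_mode `"tied"` (one shared covariance) or `"full"`
#'   (per-component covariances).
#' @param seed master seed; expands to one sub-seed per restart.
#' @param n_restarts number of k-means++-seeded EM runs; the best final
#'   log-likelihood wins.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap; non-convergence is reported with a
#'   warning and the best iterate returned.
#' @param ridge diagonal regularizer added to every covariance update.
#' @return object of class `"mixture_model"`: `weights`, `means` (k x d),
#'   `tied_covariance` (d x d; or `covariances`, a list, for full mode),
#'   `responsibilities` (n x k), `log_likelihood`, `loglik_trace`,
#'   `n_params`, `bic` (`-2L + p log n`), `labels` (argmax
#'   responsibilities, named by gene), `best_seed`, `converged`.
#' @examples
#' panel <- generate_panel(generator_config(n_genes = 60, seed = 3))
#' pr <- panel_ratio_profiles(panel)
#' fit <- fit_gmm(pr, k = 3, seed = 1, n_restarts = 3)
#' fit$bic
#' @export
fit_gmm <- function(profiles, k, cov_mode = c("tied", "full"),
                    seed = 1L, n_restarts = 10L, tol = 1e-6,
                    max_iter = 500L, ridge = 1e-6) {
  cov_mode <- match.arg(cov_mode)
  m <- profile_matrix(profiles)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(m) <= k) stop("need more genes than components")
  if (any(!is.finite(m))) stop("profiles must be finite")
  seeds <- expand_seed(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seeds[r],
                            em_once(m, k, cov_mode, tol, max_iter, ridge))
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
      best <- fit
      best$best_seed <- seeds[r]
    }
  }
  if (!best$converged)
    warning(sprintf("EM did not converge within %d iterations; %s",
                    max_iter, "returning the best iterate"))
  n <- nrow(m)
  p <- gmm_n_params(k, ncol(m), cov_mode)
  labels <- max.col(best$responsibilities)
  names(labels) <- rownames(m)
  out <- list(k = k, cov_mode = cov_mode,
              weights = as.numeric(best$weights),
              means = best$means,
              responsibilities = best$responsibilities,
              log_likelihood = best$log_likelihood,
              loglik_trace = best$loglik_trace,
              n_params = p,
              bic = -2 * best$log_likelihood + p * log(n),
              labels = labels,
              n = n, d = ncol(m),
              converged = best$converged,
              best_seed = best$best_seed)
  if (cov_mode == "tied") out$tied_covariance <- best$sigma
  else out$covariances <- best$sigma
  class(out) <- "mixture_model"
  out
}

#' @rdname fit_gmm
#' @export
fit_gmm_tied <- function(profiles, k, seed = 1L, n_restarts = 10L,
                         tol = 1e-6, max_iter = 500L, ridge = 1e-6) {
  fit_gmm(profiles, k, cov_mode = "tied", seed = seed,
          n_restarts = n_restarts, tol = tol, max_iter = max_iter,
          ridge = ridge)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: k = %d (%s covariance), n = %d\n",
              x$k, x$cov_mode, x$n))
  cat(sprintf("  logLik = %.2f | BIC = %.2f | p = %d | converged: %s\n",
              x$log_likelihood, x$bic, x$n_params, x$converged))
  cat("  component sizes:", paste(tabulate(x$labels, x$k), collapse = " "),
      "\n")
  invisible(x)
}

#' k-means baseline clustering
#'
#' Lloyd's iterations (via [stats::kmeans()]) from k-means++-style
#' seeding; the restart with the lowest within-cluster sum of squares
#' wins. Deterministic given `seed`.
#'
#' @inheritParams fit_gmm
#' @return integer cluster labels named by gene, with attributes
#'   `inertia` (total within-cluster SS) and `centers`.
#' @export
fit_kmeans <- function(profiles, k, seed = 1L, n_restarts = 10L) {
  m <- profile_matrix(profiles)
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(m)) stop("k exceeds the number of genes")
  seeds <- expand_seed(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- withr::with_seed(seeds[r], {
      centers <- kmeanspp_centers(m, k)
      suppressWarnings(stats::kmeans(m, centers = centers,
                                     algorithm = "Lloyd", iter.max = 100L))
    })
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  names(labels) <- rownames(m)
  attr(labels, "inertia") <- best$tot.withinss
  attr(labels, "centers") <- best$centers
  labels
}

#' Match components of one labelling to a reference
#'
#' Exhaustive maximum-overlap assignment over component permutations
#' (feasible for `k <= 9`, intended for small k): relabels `labels` so
#' that the contingency-table diagonal against `reference` is maximal.
#'
#' @param labels,reference integer label vectors over the same genes.
#' @return `labels` relabelled onto the reference's component ids.
#' @export
match_components <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  ka <- max(labels)
  kb <- max(reference)
  k <- max(ka, kb)
  if (k > 9L) stop("exhaustive matching supported for k <= 9")
  tab <- table(factor(labels, levels = seq_len(k)),
               factor(reference, levels = seq_len(k)))
  perms <- permutations_of(k)
  overlap <- vapply(seq_len(nrow(perms)), function(i)
    sum(tab[cbind(seq_len(k), perms[i, ])]), numeric(1))
  best <- perms[which.max(overlap), ]
  out <- best[labels]
  names(out) <- names(labels)
  out
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
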