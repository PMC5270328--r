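#' Gaussian-mixture clustering of expression profiles
#'
#' Fits a k-component Gaussian mixture with diagonal covariances to gene
#' expression profiles (rows = genes, columns = conditions) by
#' expectation-maximization. Initial means are chosen by a k-means++-style
#' seeding; component variances are floored at `var_floor` to avoid
#' degenerate clusters.
#'
#' @param matrix Numeric matrix of profiles (genes x conditions), or an
#'   `ExpressionMatrix` (log-transform it first for count data; see
#'   [log_cpm()]).
#' @param k Number of mixture components, `1 <= k <= nrow(matrix)`.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param var_floor Lower bound applied to every component variance.
#' @return An object of class `ClusterModel`: list with elements `k`,
#'   `means` (k x d), `variances` (k x d), `weights`, `assignments`
#'   (named integer vector, hard max-posterior labels), `posterior`
#'   (n x k), `loglik`, `loglik_trace`, `seed`, `converged`.
#' @export
fit_gmm <- function(matrix, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                    var_floor = 1e-6) {
  x <- unclass(as.matrix(matrix))
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds number of genes (%d)", k, n))
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(n))

  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  means <- kmeanspp_init(x, k)
  variances <- colSums(scale(x, scale = FALSE)^2) / max(n - 1, 1)
  variances <- matrix(pmax(rep(variances, each = k), var_floor), k, d)
  weights <- rep(1 / k, k)

  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  floored <- FALSE
  resp <- matrix(1, n, 1)
  for (iter in seq_len(max_iter)) {
    lp <- gmm_log_density(x, means, variances, weights)   # n x k
    row_max <- apply(lp, 1, max)
    lse <- row_max + log(rowSums(exp(lp - row_max)))
    ll <- sum(lse)
    if (ll + 1e-9 < prev_ll) {
      warning(sprintf("EM log-likelihood decreased at iteration %d", iter))
    }
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    if (is.finite(prev_ll) && ll - prev_ll < tol) { converged <- TRUE; break }
    prev_ll <- ll

    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- crossprod(resp, x) / nk
    for (j in seq_len(k)) {
      dev2 <- sweep(x, 2, means[j, ], "-")^2
      v <- colSums(resp[, j] * dev2) / nk[j]
      if (any(v < var_floor)) floored <- TRUE
      variances[j, ] <- pmax(v, var_floor)
    }
  }
  if (floored) warning("one or more component variances hit the floor")

  assignments <- max.col(resp, ties.method = "first")
  names(assignments) <- rownames(x)
  structure(list(k = k, means = means, variances = variances,
                 weights = weights, assignments = assignments,
                 posterior = resp, loglik = trace[length(trace)],
                 loglik_trace = trace, seed = seed, converged = converged),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: k = %d, %d genes, log-likelihood %.3f (%s)\n",
              x$k, length(x$assignments), x$loglik,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

# per-component log joint density log(w_j) + sum_d log N(x | mu_jd, s_jd)
gmm_log_density <- function(x, means, variances, weights) {
  n <- nrow(x); k <- nrow(means)
  lp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lp[, j] <- log(weights[j]) -
      0.5 * sum(log(2 * pi * variances[j, ])) -
      0.5 * rowSums(sweep(sweep(x, 2, means[j, ], "-")^2,
                          2, variances[j, ], "/"))
  }
  lp
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Log-likelihood of data under a fitted mixture
#'
#' @param model A `ClusterModel`.
#' @param newdata Numeric matrix with the same number of columns the model
#'   was fitted on.
#' @return Total log-likelihood of `newdata` under the mixture.
#' @export
gmm_loglik <- function(model, newdata) {
  x <- unclass(as.matrix(newdata))
  lp <- gmm_log_density(x, model$means, model$variances, model$weights)
  row_max <- apply(lp, 1, max)
  sum(row_max + log(rowSums(exp(lp - row_max))))
}

#' Select the number of clusters by cross-validation
#'
#' For each candidate k, genes are split into `folds` folds; a mixture is
#' fitted on each training split and scored by the held-out per-gene
#' log-likelihood. The k with the highest mean held-out log-likelihood
#' wins; ties break toward the smallest k.
#'
#' @param matrix Numeric profile matrix (genes x conditions).
#' @param k_range Integer vector of candidate cluster counts.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment and EM starts.
#' @return The selected k (integer), with attribute `cv_loglik` giving the
#'   mean held-out log-likelihood per candidate.
#' @export
select_k <- function(matrix, k_range, folds = 5L, seed = 1L) {
  x <- unclass(as.matrix(matrix))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 1) || any(k_range > nrow(x))) {
    stop("k_range must lie within [1, number of genes]")
  }
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(x)

  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  fold_id <- sample(rep_len(seq_len(folds), n))

  cv <- vapply(k_range, function(k) {
    ll <- 0; held <- 0
    for (f in seq_len(folds)) {
      train <- x[fold_id != f, , drop = FALSE]
      test <- x[fold_id == f, , drop = FALSE]
      if (nrow(train) < k || nrow(test) == 0) return(-Inf)
      fit <- fit_gmm(train, k, seed = seed + 1000L * f + k)
      ll <- ll + gmm_loglik(fit, test)
      held <- held + nrow(test)
    }
    ll / held
  }, numeric(1))

  best <- k_range[which.max(cv)]   # which.max takes the first maximum
  attr(best, "cv_loglik") <- stats::setNames(cv, k_range)
  best
}
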