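#' Clustering configuration
#'
#' Settings for the classification-EM mixture-of-Gaussians engine: the range
#' of candidate cluster counts, the penalized model-selection criterion, and
#' numerical controls. The printed presets of the workflow are
#' [electrode_cluster_config()] (min 5, max 30, BIC) and
#' [tetrode_cluster_config()] (min 30, max 100, AIC); smaller sweeps are
#' appropriate for recordings with few units.
#'
#' @param min_K,max_K Candidate cluster-count range (inclusive).
#' @param penalty `"BIC"` (`-2 logL + p log n`) or `"AIC"` (`-2 logL + 2 p`),
#'   where `p` is the free-parameter count of the mixture and `logL` the
#'   classification log-likelihood.
#' @param K_step Sweep stride: candidate K values are
#'   `seq(min_K, max_K, by = K_step)` (default 1). Wide sweeps over large
#'   banks use a coarser stride.
#' @param restarts Random initializations per K (default 10).
#' @param max_iter Maximum CEM iterations (default 300).
#' @param tol Relative classification log-likelihood change at convergence.
#' @param covariance `"full"`, `"diagonal"`, or `"auto"` (full when the
#'   feature dimension is at most 8, diagonal above).
#' @param var_floor Minimum cluster variance per dimension as a fraction of
#'   the data's global variance (default 0.01). Keeps clusters of
#'   near-identical points - noise-free synthetic waveforms, duplicated
#'   spikes - from collapsing to needle-thin components that nothing else
#'   can join.
#' @param seed RNG seed; the fit is bit-reproducible given the seed.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_K = 1L, max_K = 10L,
                           penalty = c("BIC", "AIC"),
                           K_step = 1L,
                           restarts = 10L, max_iter = 300L, tol = 1e-6,
                           covariance = c("auto", "full", "diagonal"),
                           var_floor = 0.01,
                           seed = 1L) {
  stopifnot(min_K >= 1L, min_K <= max_K, restarts >= 1L, K_step >= 1L,
            var_floor >= 0)
  structure(
    list(min_K = as.integer(min_K), max_K = as.integer(max_K),
         penalty = match.arg(penalty), K_step = as.integer(K_step),
         restarts = as.integer(restarts),
         max_iter = as.integer(max_iter), tol = tol,
         covariance = match.arg(covariance), var_floor = var_floor,
         seed = as.integer(seed)),
    class = "cluster_config"
  )
}

#' @rdname cluster_config
#' @param ... Overrides passed to [cluster_config()].
#' @export
electrode_cluster_config <- function(...) {
  do.call(cluster_config,
          utils::modifyList(list(min_K = 5L, max_K = 30L, penalty = "BIC"),
                            list(...)))
}

#' @rdname cluster_config
#' @export
tetrode_cluster_config <- function(...) {
  do.call(cluster_config,
          utils::modifyList(list(min_K = 30L, max_K = 100L, penalty = "AIC"),
                            list(...)))
}

# n x K matrix of log(w_k) + log N(x; mu_k, cov_k); the diagonal case is a
# single set of matrix products so wide sweeps stay affordable
logpost_all <- function(x, w, means, covs, diagonal) {
  n <- nrow(x); d <- ncol(x); K <- length(w)
  if (diagonal) {
    V <- do.call(rbind, covs)                  # K x d variances
    M <- means
    iv <- 1 / V
    Q <- (x^2) %*% t(iv) - 2 * x %*% t(M * iv) +
      matrix(rowSums(M^2 * iv), n, K, byrow = TRUE)
    ld <- rowSums(log(V))
    sweep(-0.5 * Q, 2L, 0.5 * (d * log(2 * pi) + ld) - log(w), "-")
  } else {
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      out[, k] <- log(w[k]) + cluster_logdens(x, means[k, ], covs[[k]], FALSE)
    }
    out
  }
}

# per-cluster Gaussian log density at all rows of x
cluster_logdens <- function(x, mu, cov, diagonal) {
  d <- ncol(x)
  dx <- sweep(x, 2L, mu)
  if (diagonal) {
    q <- rowSums(sweep(dx^2, 2L, cov, "/"))
    logdet <- sum(log(cov))
  } else {
    R <- chol(cov)
    y <- forwardsolve(t(R), t(dx))
    q <- colSums(y^2)
    logdet <- 2 * sum(log(diag(R)))
  }
  -0.5 * (d * log(2 * pi) + logdet + q)
}

# covariance of rows (hard-assigned members) with a per-dimension variance
# floor, ridged until positive definite
safe_cov <- function(xk, diagonal, warn_env, floor_v = 0) {
  d <- ncol(xk)
  if (diagonal) {
    v <- apply(xk, 2L, stats::var)
    v[!is.finite(v)] <- 0
    if (any(v <= max(floor_v, 0))) {
      pos <- v[v > 0]
      fallback <- max(if (length(pos)) mean(pos) * 1e-6 else 1e-6, 1e-12)
      v <- pmax(v, max(floor_v, fallback))
      if (floor_v == 0 && !warn_env$warned) {
        warning("degenerate cluster variance regularized")
        warn_env$warned <- TRUE
      }
    }
    return(v)
  }
  S <- stats::cov(xk)
  S[!is.finite(S)] <- 0
  if (floor_v > 0) {
    ev <- eigen(S, symmetric = TRUE)
    S <- ev$vectors %*% (pmax(ev$values, floor_v) * t(ev$vectors))
  }
  eps <- mean(diag(S))
  if (!is.finite(eps) || eps <= 0) eps <- 1
  ridge <- 0
  repeat {
    ok <- tryCatch({ chol(S + ridge * diag(d)); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    ridge <- if (ridge == 0) eps * 1e-8 else ridge * 10
    if (floor_v == 0 && !warn_env$warned) {
      warning("singular cluster covariance regularized with a ridge")
      warn_env$warned <- TRUE
    }
  }
  S + ridge * diag(d)
}

# k-means++ seeding on the current RNG stream
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[k], ])^2))
  }
  x[centers, , drop = FALSE]
}

# one CEM run from a k-means++ start; returns model pieces + iteration trace
cem_once <- function(x, K, diagonal, max_iter, tol, warn_env, floor_v = 0) {
  n <- nrow(x)
  ctr <- kmeanspp_centers(x, K)
  dist2 <- sapply(seq_len(K), function(k) rowSums(sweep(x, 2L, ctr[k, ])^2))
  labels <- max.col(-dist2, ties.method = "first")
  cl_history <- numeric(0)
  prev_cl <- -Inf
  for (iter in seq_len(max_iter)) {
    ids <- sort(unique(labels))
    labels <- match(labels, ids)           # drop empty clusters
    K <- length(ids)
    w <- tabulate(labels, K) / n
    means <- matrix(0, K, ncol(x))
    covs <- vector("list", K)
    for (k in seq_len(K)) {
      xk <- x[labels == k, , drop = FALSE]
      means[k, ] <- colMeans(xk)
      covs[[k]] <- safe_cov(xk, diagonal, warn_env, floor_v)
    }
    logp <- logpost_all(x, w, means, covs, diagonal)
    new_labels <- max.col(logp, ties.method = "first")
    cl <- sum(logp[cbind(seq_len(n), new_labels)])
    cl_history <- c(cl_history, cl)
    converged <- identical(new_labels, labels) ||
      (is.finite(prev_cl) && abs(cl - prev_cl) <= tol * abs(prev_cl))
    labels <- new_labels
    prev_cl <- cl
    if (converged) break
  }
  # final M-step statistics consistent with the returned labels
  ids <- sort(unique(labels))
  labels <- match(labels, ids)
  K <- length(ids)
  w <- tabulate(labels, K) / n
  means <- matrix(0, K, ncol(x))
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    xk <- x[labels == k, , drop = FALSE]
    means[k, ] <- colMeans(xk)
    covs[[k]] <- safe_cov(xk, diagonal, warn_env, floor_v)
  }
  logp <- logpost_all(x, w, means, covs, diagonal)
  cl <- sum(logp[cbind(seq_len(n), labels)])
  list(K = K, weights = w, means = means, covariances = covs,
       labels = labels, loglik = cl, cl_history = cl_history)
}

#' Mixture-of-Gaussians clustering by classification EM
#'
#' Hard-assignment EM: the E-step computes per-cluster posteriors, the
#' C-step assigns every point to its maximum-posterior cluster (ties broken
#' toward the lowest cluster index), and the M-step refits weights, means and
#' covariances on the assigned points. Empty clusters are deleted. The sweep
#' over `K` in `[min_K, max_K]` with `restarts` seedings per `K` keeps the
#' model with the best (lowest) penalized score.
#'
#' @param features Numeric matrix `n x d` (z-scored features in the normal
#'   workflow); `n` must exceed `max_K`.
#' @param cfg A [cluster_config()].
#' @return An object of class `cluster_model`: `K`, `weights`, `means`,
#'   `covariances` (list of matrices, or variance vectors when diagonal),
#'   `labels` (1-based, every cluster non-empty), `loglik`,
#'   `penalized_score`, `penalty`, `diagonal`, and `cl_history` (per-iteration
#'   classification log-likelihood of the winning run).
#' @export
cem_cluster <- function(features, cfg = cluster_config()) {
  x <- as.matrix(features)
  n <- nrow(x); d <- ncol(x)
  if (n <= cfg$max_K) stop("need more points than max_K")
  diagonal <- switch(cfg$covariance,
                     full = FALSE, diagonal = TRUE, auto = d > 8L)
  warn_env <- new.env()
  warn_env$warned <- FALSE
  vf <- if (is.null(cfg$var_floor)) 0 else cfg$var_floor
  floor_v <- vf * mean(apply(x, 2L, stats::var))
  if (!is.finite(floor_v)) floor_v <- 0
  set.seed(cfg$seed)
  best <- NULL
  K_step <- if (is.null(cfg$K_step)) 1L else cfg$K_step
  for (K in unique(c(seq(cfg$min_K, cfg$max_K, by = K_step), cfg$max_K))) {
    for (r in seq_len(cfg$restarts)) {
      fit <- cem_once(x, K, diagonal, cfg$max_iter, cfg$tol, warn_env,
                      floor_v)
      p <- (fit$K - 1) + fit$K * d +
        fit$K * if (diagonal) d else d * (d + 1) / 2
      score <- if (cfg$penalty == "BIC") {
        -2 * fit$loglik + p * log(n)
      } else {
        -2 * fit$loglik + 2 * p
      }
      if (is.null(best) || score < best$penalized_score) {
        best <- fit
        best$penalized_score <- score
      }
    }
  }
  best$penalty <- cfg$penalty
  best$diagonal <- diagonal
  class(best) <- "cluster_model"
  best
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, %s = %.1f, logL = %.1f\n",
              x$K, x$penalty, x$penalized_score, x$loglik))
  invisible(x)
}

#' Isolation distance of a cluster
#'
#' Separation measure of a cluster of `n_c` members among other points: the
#' squared Mahalanobis distance (with respect to the cluster's own mean and
#' covariance) of the `n_c`-th closest non-member. Undefined (`NaN`, with a
#' warning) when fewer than `n_c` non-members exist.
#'
#' @param features Numeric feature matrix.
#' @param labels Cluster label per row.
#' @param cluster_id The cluster to score.
#' @return A single number (squared Mahalanobis distance), or `NaN`.
#' @export
isolation_distance <- function(features, labels, cluster_id) {
  x <- as.matrix(features)
  inside <- labels == cluster_id
  nc <- sum(inside)
  if (nc < 2L) return(NaN)
  outside <- which(!inside)
  if (length(outside) < nc) {
    warning("fewer non-members than members; isolation distance undefined")
    return(NaN)
  }
  warn_env <- new.env(); warn_env$warned <- TRUE
  S <- safe_cov(x[inside, , drop = FALSE], diagonal = FALSE, warn_env)
  mu <- colMeans(x[inside, , drop = FALSE])
  R <- chol(S)
  dx <- sweep(x[outside, , drop = FALSE], 2L, mu)
  d2 <- colSums(forwardsolve(t(R), t(dx))^2)
  sort(d2, partial = nc)[nc]
}

#' Fraction of refractory-period violations
#'
#' Fraction of consecutive inter-spike intervals shorter than the refractory
#' period (strictly; an interval of exactly 1 ms is not a violation). Within
#' one unit such intervals indicate contamination by another cell.
#'
#' @param trigger_times Sorted spike times in samples.
#' @param sampling_rate_hz Sampling rate.
#' @param refractory_ms Refractory period in milliseconds (default 1).
#' @return Fraction in `[0, 1]`; 0 when fewer than 2 spikes.
#' @export
isi_violation_fraction <- function(trigger_times, sampling_rate_hz,
                                   refractory_ms = 1.0) {
  if (length(trigger_times) < 2L) return(0)
  isi_ms <- diff(trigger_times) / sampling_rate_hz * 1000
  sum(isi_ms < refractory_ms) / length(isi_ms)
}
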