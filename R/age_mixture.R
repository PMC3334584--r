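# Univariate normal mixture fitting by EM with multiple random and k-means
# starts, component-count selection by BIC, and 95% confidence intervals on
# component means. Used for both duplication-age (mya) and Ks distributions.

.em_once <- function(data, k, mu0, var0, prop0, tol = 1e-8, maxit = 1000,
                     var_floor) {
  n <- length(data)
  mu <- mu0; v <- var0; p <- prop0
  ll_old <- -Inf
  dens <- matrix(0, n, k)
  resp <- dens
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    for (j in seq_len(k))
      dens[, j] <- (p[j] / sqrt(2 * pi * v[j])) *
        exp(-(data - mu[j])^2 / (2 * v[j]))
    rs <- .rowSums(dens, n, k)
    if (any(rs <= 0) || any(!is.finite(rs))) return(NULL)
    ll <- sum(log(rs))
    trace <- c(trace, ll)
    # EM guarantees monotone log-likelihood; a decrease flags a numeric fault
    if (ll < ll_old - 1e-6) return(NULL)
    resp <- dens / rs
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
    nj <- .colSums(resp, n, k)
    if (any(nj < 1e-12)) return(NULL)
    p <- nj / n
    mu <- .colSums(resp * data, n, k) / nj
    # E[x^2] - mu^2 form; the floor guards against cancellation as well as
    # genuine component collapse
    v <- .colSums(resp * data * data, n, k) / nj - mu^2
    if (any(v < var_floor)) return(NULL)
  }
  list(mu = mu, var = v, prop = p, loglik = ll_old, resp = resp, iters = it,
       trace = trace)
}

# k-means++ seeding followed by stats::kmeans, giving start values
.kmeanspp_start <- function(data, k) {
  n <- length(data)
  centers <- numeric(k)
  centers[1] <- data[sample.int(n, 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(data, function(x) min((x - centers[1:(j - 1)])^2),
                   numeric(1))
      if (sum(d2) <= 0) {
        centers[j] <- data[sample.int(n, 1)]
      } else {
        centers[j] <- data[sample.int(n, 1, prob = d2)]
      }
    }
  }
  centers <- unique(centers)
  if (length(centers) < k) return(NULL)
  km <- tryCatch(stats::kmeans(data, centers = matrix(centers, ncol = 1)),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  mu <- as.numeric(km$centers)
  v <- vapply(seq_len(k), function(j) {
    xs <- data[km$cluster == j]
    if (length(xs) > 1) stats::var(xs) else stats::var(data)
  }, numeric(1))
  v[!is.finite(v) | v <= 0] <- stats::var(data)
  list(mu = mu, var = v, prop = tabulate(km$cluster, k) / length(data))
}

#' Fit a k-component univariate normal mixture by EM
#'
#' The EM algorithm is restarted from \code{n_random_starts} random
#' initializations (means uniform on the data range, variances equal to the
#' data variance, equal proportions) and \code{n_kmeans_starts} k-means
#' initializations (k-means++ seeding); the best log-likelihood fit is kept.
#' Iteration stops at a relative log-likelihood change below 1e-8 or 1000
#' iterations. Components are reported sorted by mean.
#'
#' @param data numeric vector (finite), length >= k.
#' @param k number of components (>= 1).
#' @param n_random_starts,n_kmeans_starts numbers of EM starts.
#' @param seed integer seed (the caller's RNG stream is restored).
#' @param split_at optional value: one extra deterministic start seeds two
#'   components on either side of this cut (used to probe for bimodality
#'   around a constraint such as 125 mya); only meaningful for k = 2.
#' @return object of class \code{mixture_fit}: \code{k}, \code{means},
#'   \code{variances}, \code{proportions}, \code{loglik}, \code{bic},
#'   \code{mean_ci95} (matrix lo/hi), \code{responsibilities}, \code{n}.
#' @export
em_fit <- function(data, k, n_random_starts = 100, n_kmeans_starts = 10,
                   seed = 1, split_at = NULL) {
  data <- as.numeric(data)
  if (any(!is.finite(data))) stop("data must be finite")
  n <- length(data)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("need at least k observations")
  var_all <- stats::var(data)
  if (!is.finite(var_all) || var_all <= 0) var_all <- 1e-12
  var_floor <- 1e-8 * var_all
  rng <- range(data)
  best <- NULL
  with_seed(seed, {
    starts <- list()
    if (k == 1) {
      starts[[1]] <- list(mu = mean(data), var = var_all, prop = 1)
    } else {
      for (s in seq_len(n_random_starts))
        starts[[length(starts) + 1]] <- list(
          mu = stats::runif(k, rng[1], rng[2]),
          var = rep(var_all, k),
          prop = rep(1 / k, k))
      for (s in seq_len(n_kmeans_starts)) {
        st <- .kmeanspp_start(data, k)
        if (!is.null(st)) starts[[length(starts) + 1]] <- st
      }
      if (!is.null(split_at) && k == 2 &&
          any(data < split_at) && any(data >= split_at)) {
        lo <- data[data < split_at]; hi <- data[data >= split_at]
        starts[[length(starts) + 1]] <- list(
          mu = c(mean(lo), mean(hi)),
          var = rep(var_all, 2),
          prop = c(length(lo), length(hi)) / n)
      }
    }
    # short EM from every start, then full convergence from the best few
    # basins (standard multi-start economy; the winner is refined at the
    # full 1e-8 tolerance)
    shorts <- vector("list", length(starts))
    for (si in seq_along(starts)) {
      st <- starts[[si]]
      shorts[[si]] <- .em_once(data, k, st$mu, st$var, st$prop,
                               maxit = 30, var_floor = var_floor)
    }
    lls <- vapply(shorts, function(f) if (is.null(f)) -Inf else f$loglik,
                  numeric(1))
    top <- order(lls, decreasing = TRUE)[seq_len(min(3, length(starts)))]
    for (si in top) {
      f0 <- shorts[[si]]
      if (is.null(f0)) next
      fit <- .em_once(data, k, f0$mu, f0$var, f0$prop,
                      var_floor = var_floor)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best))
    stop("all EM starts collapsed to a degenerate component")
  ord <- order(best$mu)
  mu <- best$mu[ord]; v <- best$var[ord]; p <- best$prop[ord]
  resp <- best$resp[, ord, drop = FALSE]
  nj <- colSums(resp)
  ci <- cbind(lo = mu - 1.96 * sqrt(v / nj),
              hi = mu + 1.96 * sqrt(v / nj))
  npar <- 3 * k - 1
  structure(list(k = k, means = mu, variances = v, proportions = p,
                 loglik = best$loglik,
                 bic = -2 * best$loglik + npar * log(n),
                 mean_ci95 = ci, responsibilities = resp, n = n,
                 loglik_trace = best$trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k=%d loglik=%.3f BIC=%.3f\n",
              x$k, x$loglik, x$bic))
  for (j in seq_len(x$k))
    cat(sprintf("  mean %.4g (95%% CI %.4g-%.4g)  sd %.4g  prop %.3f\n",
                x$means[j], x$mean_ci95[j, 1], x$mean_ci95[j, 2],
                sqrt(x$variances[j]), x$proportions[j]))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits each k in \code{k_range} with \code{\link{em_fit}} and returns the
#' fit minimizing BIC = -2 loglik + (3k - 1) log(n); ties go to the smaller
#' k. Component counts whose EM collapses entirely are skipped.
#'
#' @inheritParams em_fit
#' @param k_range candidate component counts (default 1:4).
#' @return the winning \code{mixture_fit}, with the BIC table in attribute
#'   \code{bic_table}.
#' @export
select_by_bic <- function(data, k_range = 1:4, n_random_starts = 100,
                          n_kmeans_starts = 10, seed = 1, split_at = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list()
  for (k in k_range) {
    if (k > length(data)) next
    f <- tryCatch(
      em_fit(data, k, n_random_starts, n_kmeans_starts, seed = seed + k,
             split_at = split_at),
      error = function(e) NULL)
    if (!is.null(f)) fits[[as.character(k)]] <- f
  }
  if (!length(fits)) stop("no component count could be fitted")
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bics)]]  # which.min takes the first (smallest k)
  attr(best, "bic_table") <- data.frame(
    k = as.integer(names(fits)), bic = unname(bics),
    loglik = vapply(fits, `[[`, 0, "loglik"))
  best
}

#' 95% confidence intervals of the component means
#'
#' For component j, mean_j +/- 1.96 * sqrt(variance_j / n_j) with n_j the
#' effective component size (summed responsibilities).
#'
#' @param fit \code{mixture_fit}.
#' @return matrix with columns \code{lo}, \code{hi}, one row per component.
#' @export
component_ci <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  fit$mean_ci95
}

#' Format mixture components as report strings
#'
#' One string per component, \code{"label/rounded-mean/proportion"}:
#' age-scale means (>= 10) are rounded to integers, Ks-scale means to two
#' decimals; proportions are printed to two decimals with trailing zeros
#' trimmed.
#'
#' @param fit \code{mixture_fit}.
#' @param labels component labels (e.g. colors), recycled as needed.
#' @return character vector.
#' @export
format_components <- function(fit, labels = c("green", "blue", "purple",
                                              "yellow")) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k == 0) return(character())
  labels <- rep_len(labels, fit$k)
  vapply(seq_len(fit$k), function(j) {
    m <- fit$means[j]
    mtxt <- if (abs(m) >= 10) sprintf("%d", as.integer(round_half_up(m)))
            else formatC(round_half_up(m, 2), format = "fg")
    ptxt <- formatC(round_half_up(fit$proportions[j], 2), format = "fg")
    paste(labels[j], mtxt, ptxt, sep = "/")
  }, "")
}
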