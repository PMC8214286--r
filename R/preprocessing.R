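# Blood-pool thresholding: a two-component Gaussian mixture separates dark
# myocardium from bright blood; clipping the image at the bright component's
# mean removes intensity texture (and hence spurious edges) inside the pool.

#' Fit a two-component 1-D Gaussian mixture by EM
#'
#' Standard expectation-maximization for a two-component univariate Gaussian
#' mixture. Initialization splits the sample at its median (lower half seeds
#' the low component); variances are floored at `1e-6 * range^2` to prevent
#' collapse onto repeated values. Components are returned sorted by mean.
#'
#' @param pixels numeric vector of at least 16 finite intensities, not all
#'   identical.
#' @param tol relative log-likelihood gain below which EM stops.
#' @param max_iter iteration cap.
#' @param seed optional seed for the (tiny) jitter applied when the median
#'   split leaves one side empty; the default fit is fully deterministic.
#' @return An object of class `gmm2`: `means` (sorted low, high), `sds`,
#'   `weights`, `loglik`, `iterations`, `converged`, and the per-iteration
#'   log-likelihood `trace`.
#' @export
fit_gmm2 <- function(pixels, tol = 1e-6, max_iter = 200L, seed = 0L) {
  x <- as.numeric(pixels)
  .assert(length(x) >= 16L, "need at least 16 pixels to fit a mixture")
  .assert(all(is.finite(x)), "pixel intensities must be finite")
  rg <- diff(range(x))
  if (rg == 0) stop("degenerate intensity distribution: all pixels identical")
  var_floor <- 1e-6 * rg^2

  m <- stats::median(x)
  lo <- x[x <= m]; hi <- x[x > m]
  if (length(hi) == 0L) {  # heavily tied at the median
    if (!is.null(seed)) set.seed(seed)
    split <- x + stats::rnorm(length(x), 0, rg * 1e-8)
    m <- stats::median(split)
    lo <- x[split <= m]; hi <- x[split > m]
  }
  mu <- c(mean(lo), mean(hi))
  s2 <- pmax(c(stats::var(lo) %||% 0, stats::var(hi) %||% 0),
             var_floor, na.rm = TRUE)
  w <- c(length(lo), length(hi)) / length(x)

  loglik_of <- function(mu, s2, w) {
    dens <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1])) +
            w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    sum(log(pmax(dens, .Machine$double.xmin)))
  }
  ll <- loglik_of(mu, s2, w)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: responsibilities of component 2
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    r2 <- d2 / tot
    # M-step
    n2 <- sum(r2); n1 <- length(x) - n2
    if (n1 < 1e-10 || n2 < 1e-10) break  # one component vanished
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    s2 <- pmax(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                 sum(r2 * (x - mu[2])^2) / n2), var_floor)
    w <- c(n1, n2) / length(x)
    ll_new <- loglik_of(mu, s2, w)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  ord <- order(mu)
  structure(list(means = mu[ord], sds = sqrt(s2)[ord], weights = w[ord],
                 loglik = ll, iterations = iter, converged = converged,
                 trace = trace),
            class = "gmm2")
}

#' Blood-pool threshold of a frame
#'
#' Fits [fit_gmm2()] to all pixels of the frame and returns the mean of the
#' higher-intensity component as the clipping threshold.
#'
#' @param frame numeric matrix of intensities.
#' @inheritParams fit_gmm2
#' @return A list of class `threshold_result`: `threshold`, `mixture`,
#'   `iterations`, `converged`.
#' @export
compute_threshold <- function(frame, tol = 1e-6, max_iter = 200L, seed = 0L) {
  fit <- fit_gmm2(as.numeric(frame), tol = tol, max_iter = max_iter,
                  seed = seed)
  structure(list(threshold = fit$means[2], mixture = fit,
                 iterations = fit$iterations, converged = fit$converged),
            class = "threshold_result")
}

#' Clip intensities above a threshold
#'
#' Every pixel above `threshold` is set to `threshold`; an idempotent
#' element-wise minimum that flattens the blood pool.
#'
#' @param frame numeric matrix.
#' @param threshold finite scalar.
#' @return Matrix of the same shape with `pmin(frame, threshold)`.
#' @export
clip_above <- function(frame, threshold) {
  .assert(is.finite(threshold), "threshold must be finite")
  out <- pmin(frame, threshold)
  dim(out) <- dim(frame)
  out
}
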