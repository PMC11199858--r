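# Degree / strength distributions, distribution-family comparison by maximum
# likelihood, and weight-distance decay fits.

#' Node degree or strength
#'
#' Unweighted degree `k` is the count of non-zero links per node; the
#' weighted degree (node strength) is the corresponding row or column sum of
#' weights. For an FLNe network the weighted in-Degree of every connected
#' target is 1 by construction, and 0 otherwise.
#'
#' @param c a [connectome]
#' @param direction `"in"` (column-wise) or `"out"` (row-wise)
#' @param weighted if `TRUE`, return strengths; otherwise link counts
#' @return named numeric vector over nodes
#' @export
node_degree <- function(c, direction = c("in", "out"), weighted = FALSE) {
  direction <- match.arg(direction)
  M <- if (weighted) c$W else (c$W > 0) + 0
  if (direction == "in") colSums(M) else rowSums(M)
}

#' Per-node degree table
#'
#' @param c a [connectome]
#' @return data.frame with k_in, k_out, strength_in, strength_out per node
#' @export
degree_table <- function(c) {
  data.frame(label = c$nodes$label,
             k_in = node_degree(c, "in"), k_out = node_degree(c, "out"),
             strength_in = node_degree(c, "in", weighted = TRUE),
             strength_out = node_degree(c, "out", weighted = TRUE),
             measured = c$nodes$measured,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximum-likelihood fit of a distribution family
#'
#' Fits one of three two-parameter-or-fewer families by closed-form maximum
#' likelihood: exponential (rate = 1/mean), normal (mean, MLE variance) or
#' log-normal (mean and MLE variance of the logs). For the log-scale and
#' exponential families, non-positive samples are excluded and their count
#' reported, since zero weight means an absent link, not a sample.
#'
#' @param samples numeric vector, n >= 2 after exclusions
#' @param family `"exponential"`, `"normal"` or `"lognormal"`
#' @return a `fit_result` list: family, params, log_likelihood, n,
#'   n_excluded
#' @export
fit_family <- function(samples, family = c("exponential", "normal", "lognormal")) {
  family <- match.arg(family)
  samples <- samples[is.finite(samples)]
  n_excluded <- 0L
  if (family %in% c("exponential", "lognormal")) {
    n_excluded <- sum(samples <= 0)
    samples <- samples[samples > 0]
  }
  n <- length(samples)
  if (n < 2) stop("need >= 2 usable samples, got ", n)
  if (stats::sd(samples) == 0) stop("degenerate (zero-variance) sample")
  fit <- switch(family,
    exponential = {
      rate <- 1 / mean(samples)
      list(params = c(rate = rate),
           ll = sum(stats::dexp(samples, rate, log = TRUE)))
    },
    normal = {
      mu <- mean(samples); sig <- sqrt(mean((samples - mu)^2))
      list(params = c(mean = mu, sd = sig),
           ll = sum(stats::dnorm(samples, mu, sig, log = TRUE)))
    },
    lognormal = {
      lx <- log(samples)
      mu <- mean(lx); sig <- sqrt(mean((lx - mu)^2))
      if (sig == 0) stop("degenerate (zero-variance) sample")
      list(params = c(meanlog = mu, sdlog = sig),
           ll = sum(stats::dlnorm(samples, mu, sig, log = TRUE)))
    })
  structure(list(family = family, params = fit$params,
                 log_likelihood = fit$ll, n = n, n_excluded = n_excluded),
            class = "fit_result")
}

#' Compare distribution families by log likelihood
#'
#' Fits each requested family to the same sample and ranks the fits by total
#' log likelihood, descending. Likelihoods are compared bare, without an
#' AIC/BIC penalty: the comparison is between families of (essentially)
#' equal complexity. Ties preserve the requested order.
#'
#' @param samples numeric vector
#' @param families character vector of >= 2 family names
#' @return data.frame ranked by log likelihood with the fitted parameters
#' @export
compare_families <- function(samples,
                             families = c("exponential", "normal", "lognormal")) {
  if (length(families) < 2) stop("need >= 2 families to compare")
  fits <- lapply(families, function(f) fit_family(samples, f))
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  ord <- order(-ll)
  data.frame(family = families[ord],
             log_likelihood = ll[ord],
             n = vapply(fits, function(f) f$n, numeric(1))[ord],
             params = I(lapply(fits, function(f) f$params)[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weight-distance decay fit
#'
#' Ordinary least squares on the log-transformed relation, using only links
#' with positive weight and positive distance (excluded pairs are counted).
#' Exponential model: `ln w ~ d`, decay length `lambda = -1/slope` in mm.
#' Power law: `ln w ~ ln d`, exponent `gamma = -slope`. `r_squared` is the
#' coefficient of determination of the linear fit in the transformed space.
#'
#' @param c a [connectome] with distances attached (see [compute_distances])
#' @param model `"exponential"` or `"powerlaw"`
#' @return a `decay_fit` list: model, lambda or gamma, intercept (on the
#'   natural-log weight scale), r_squared, n, n_excluded
#' @export
weight_distance_fit <- function(c, model = c("exponential", "powerlaw")) {
  model <- match.arg(model)
  if (is.null(c$D)) stop("no distance matrix; call compute_distances() first")
  use <- c$W > 0 & c$D > 0
  n_excluded <- sum(c$W > 0) - sum(use)
  w <- c$W[use]; d <- c$D[use]
  if (length(w) < 3) stop("need >= 3 usable links, got ", length(w))
  if (stats::sd(d) == 0) stop("all link distances equal; decay is unidentifiable")
  x <- if (model == "exponential") d else log(d)
  fit <- stats::lm(log(w) ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((log(w) - mean(log(w)))^2)
  out <- list(model = model, intercept = unname(stats::coef(fit)[1]),
              r_squared = r2,
              n = length(w), n_excluded = n_excluded)
  if (model == "exponential") out$lambda <- -1 / slope else out$gamma <- -slope
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$model == "exponential")
    cat(sprintf("exponential decay: weight ~ exp(-dist / %.3f mm), R^2 = %.3f (n = %d links)\n",
                x$lambda, x$r_squared, x$n))
  else
    cat(sprintf("power-law decay: weight ~ dist^-%.3f, R^2 = %.3f (n = %d links)\n",
                x$gamma, x$r_squared, x$n))
  invisible(x)
}
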