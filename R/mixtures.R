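#' Initialize a two-component mixture from control groups
#'
#' Sets the starting parameters of the two-Gaussian mixture from the
#' empirical mean and unbiased variance of two groups of control
#' peptides: one group not expected to react (the noise component) and
#' one known to react (the signal component). Mixing weights start at
#' (0.9, 0.1) since most peptides are expected not to react.
#'
#' @param nonreactive numeric values of the non-reacting control group.
#' @param reactive numeric values of the reacting control group.
#' @param var_floor lower bound applied to a zero group variance.
#' @return A list with `mu1`, `var1`, `mu2`, `var2`, `pi1`, `pi2`.
#' @export
init_from_controls <- function(nonreactive, reactive, var_floor = 1e-6) {
  if (length(nonreactive) < 2L || length(reactive) < 2L) {
    stop("each control group needs at least 2 values to initialize",
         call. = FALSE)
  }
  v1 <- stats::var(nonreactive)
  v2 <- stats::var(reactive)
  if (v1 <= 0 || v2 <= 0) {
    warning("zero control-group variance floored to ", var_floor)
    v1 <- max(v1, var_floor)
    v2 <- max(v2, var_floor)
  }
  list(mu1 = mean(nonreactive), var1 = v1,
       mu2 = mean(reactive), var2 = v2,
       pi1 = 0.9, pi2 = 0.1)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Standard expectation maximization for the mixture
#' pi1 * N(mu1, var1) + pi2 * N(mu2, var2): the E-step computes each
#' observation's posterior component membership (responsibility), the
#' M-step re-estimates the weighted means, variances and mixing
#' weights. Iteration stops when the relative log-likelihood change
#' falls below `tol` or after `max_iter` iterations. A variance floor
#' is applied at every M-step to prevent component collapse, and the
#' components are relabeled at exit if needed so that `mu1 <= mu2`
#' (component 1 is the noise / non-reactive component).
#'
#' @param values numeric vector of normalized intensities (n >= 4).
#' @param init initial parameters, as from [init_from_controls()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of EM iterations.
#' @param var_floor minimum component variance.
#' @return A `mixture_fit`: the parameters, an n x 2 `responsibilities`
#'   matrix (rows sum to 1), the per-iteration `loglik_trace` and a
#'   `converged` flag.
#' @export
em_fit <- function(values, init, tol = 1e-8, max_iter = 1000L,
                   var_floor = 1e-6) {
  if (any(!is.finite(values))) stop("non-finite values in input", call. = FALSE)
  if (length(values) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  p <- init
  stopifnot(is.finite(p$mu1), is.finite(p$mu2), p$var1 > 0, p$var2 > 0)
  pi1 <- if (is.null(p$pi1)) 0.9 else p$pi1
  pi2 <- 1 - pi1
  mu1 <- p$mu1; mu2 <- p$mu2
  v1 <- max(p$var1, var_floor); v2 <- max(p$var2, var_floor)
  n <- length(values)

  loglik <- function() {
    sum(log(pi1 * stats::dnorm(values, mu1, sqrt(v1)) +
            pi2 * stats::dnorm(values, mu2, sqrt(v2))))
  }
  trace <- loglik()
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities via log densities for numerical stability
    l1 <- log(pi1) + stats::dnorm(values, mu1, sqrt(v1), log = TRUE)
    l2 <- log(pi2) + stats::dnorm(values, mu2, sqrt(v2), log = TRUE)
    m <- pmax(l1, l2)
    r1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    resp <- cbind(r1, 1 - r1)
    # M-step
    n1 <- sum(resp[, 1L]); n2 <- n - n1
    pi1 <- n1 / n; pi2 <- n2 / n
    mu1 <- sum(resp[, 1L] * values) / n1
    mu2 <- sum(resp[, 2L] * values) / n2
    v1 <- max(sum(resp[, 1L] * (values - mu1)^2) / n1, var_floor)
    v2 <- max(sum(resp[, 2L] * (values - mu2)^2) / n2, var_floor)
    ll <- loglik()
    trace <- c(trace, ll)
    prev <- trace[length(trace) - 1L]
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + tol)) {
      converged <- TRUE
      break
    }
  }
  if (mu1 > mu2) {
    tmp <- c(mu1, v1, pi1)
    mu1 <- mu2; v1 <- v2; pi1 <- pi2
    mu2 <- tmp[1L]; v2 <- tmp[2L]; pi2 <- tmp[3L]
    resp <- resp[, 2:1, drop = FALSE]
  }
  colnames(resp) <- c("noise", "signal")
  structure(list(mu1 = mu1, var1 = v1, mu2 = mu2, var2 = v2,
                 pi1 = pi1, pi2 = pi2, responsibilities = resp,
                 loglik_trace = trace, converged = converged,
                 n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit (n=%d, %s): noise N(%.3f, %.3f) w=%.3f | signal N(%.3f, %.3f) w=%.3f\n",
    x$n, if (x$converged) "converged" else "max_iter reached",
    x$mu1, x$var1, x$pi1, x$mu2, x$var2, x$pi2))
  invisible(x)
}

#' Noise-component exceedance probability
#'
#' The probability that a draw from the fitted noise component is at
#' least as large as the observed normalized intensity:
#' `p_hat = 1 - pnorm((value - mu1) / sqrt(var1))`. A value exceeds the
#' noise cutoff when `p_hat < alpha` (strictly), equivalently when the
#' value lies strictly above the upper `alpha` quantile
#' `q_hat = mu1 + qnorm(1 - alpha) * sqrt(var1)` of the noise
#' component. The default `alpha` of 0.05 uses the upper 5% quantile as
#' the reactivity cutoff; it can be adapted to trade sensitivity
#' against specificity.
#'
#' @param value numeric vector of normalized intensities.
#' @param fit a `mixture_fit`.
#' @param alpha upper-tail probability cutoff in (0, 1).
#' @return Data frame with columns `value`, `p_hat`, `cutoff_quantile`
#'   (the `q_hat` implied by `alpha`) and logical `exceeds`.
#' @export
exceedance_prob <- function(value, fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  sd1 <- sqrt(fit$var1)
  p_hat <- stats::pnorm(value, mean = fit$mu1, sd = sd1, lower.tail = FALSE)
  q_hat <- fit$mu1 + stats::qnorm(1 - alpha) * sd1
  data.frame(value = value, p_hat = p_hat, cutoff_quantile = q_hat,
             exceeds = p_hat < alpha)
}

#' Local and call-set false discovery rates from the mixture
#'
#' An alternative, off-by-default calling mode: the local fdr of a
#' value is the posterior probability that it came from the noise
#' component, `pi1 * phi1(v) / (pi1 * phi1(v) + pi2 * phi2(v))`; the
#' FDR of a call set is the mean local fdr over the called values.
#' This leans harder on the normality of the reactive component than
#' the exceedance criterion does.
#'
#' @param values numeric vector of normalized intensities.
#' @param fit a `mixture_fit`.
#' @param threshold call values with local fdr below this threshold.
#' @return A list with `local_fdr` (per value), logical `called`, and
#'   `fdr` (mean local fdr among calls; `NA` if no value is called).
#' @export
posterior_fdr <- function(values, fit, threshold = 0.5) {
  stopifnot(inherits(fit, "mixture_fit"))
  d1 <- fit$pi1 * stats::dnorm(values, fit$mu1, sqrt(fit$var1))
  d2 <- fit$pi2 * stats::dnorm(values, fit$mu2, sqrt(fit$var2))
  denom <- d1 + d2
  local_fdr <- ifelse(denom > 0, d1 / denom, 1)
  called <- local_fdr < threshold
  fdr <- if (any(called)) mean(local_fdr[called]) else NA_real_
  list(local_fdr = local_fdr, called = called, fdr = fdr)
}
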