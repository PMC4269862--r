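#' Akaike Information Criterion
#'
#' `AIC = -2 logL + 2K`, with K the number of optimised parameters
#' (theta included).
#'
#' @param logL log composite likelihood at the maximum.
#' @param K parameter count.
#' @return numeric.
#' @export
aic <- function(logL, K) {
  if (any(K < 0)) stop("K must be non-negative")
  -2 * logL + 2 * K
}

#' Akaike weights of competing models
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with `Delta_i =
#' AIC_i - min AIC` (min-subtraction keeps the exponentials in range).
#' Non-finite AICs get zero weight; at least one must be finite.
#'
#' @param aics numeric vector of AIC values.
#' @return weights summing to one, in the input order.
#' @export
akaike_weights <- function(aics) {
  if (!any(is.finite(aics))) stop("no finite AIC values")
  d <- aics - min(aics[is.finite(aics)])
  w <- ifelse(is.finite(d), exp(-d / 2), 0)
  w / sum(w)
}

#' Fisher-information (Hessian) parameter uncertainties
#'
#' Central finite-difference Hessian of the log composite likelihood at
#' the maximum, in the original parameter space, with relative step
#' `step` refined by one Richardson pass; per-parameter variances are the
#' diagonal of the inverse negated Hessian.  Failures (non-positive
#' variances from a non-concave surface, or a singular matrix) are
#' recorded, not raised.
#'
#' @param loglik_fn function mapping a parameter vector to the log
#'   composite likelihood.
#' @param mle parameter vector at the maximum.
#' @param step relative finite-difference step.
#' @param richardson logical; refine with steps h and h/2.
#' @return list: `sigma` (per-parameter standard errors, NA on failure),
#'   `hessian_ok`, `reason`, `hessian`.
#' @export
fim_uncertainty <- function(loglik_fn, mle, step = 1e-3, richardson = TRUE) {
  H1 <- .fd_hessian(loglik_fn, mle, step)
  H <- if (richardson) (4 * .fd_hessian(loglik_fn, mle, step / 2) - H1) / 3 else H1
  if (any(!is.finite(H)))
    return(list(sigma = rep(NA_real_, length(mle)), hessian_ok = FALSE,
                reason = "non-finite Hessian", hessian = H))
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(cov))
    return(list(sigma = rep(NA_real_, length(mle)), hessian_ok = FALSE,
                reason = "singular Hessian", hessian = H))
  v <- diag(as.matrix(cov))
  if (any(v <= 0))
    return(list(sigma = rep(NA_real_, length(mle)), hessian_ok = FALSE,
                reason = "negative variance", hessian = H))
  sigma <- sqrt(v)
  names(sigma) <- names(mle)
  list(sigma = sigma, hessian_ok = TRUE, reason = NULL, hessian = H)
}

.fd_hessian <- function(f, x, step) {
  K <- length(x)
  h <- step * abs(x)
  H <- matrix(NA_real_, K, K)
  f0 <- f(x)
  for (i in seq_len(K)) {
    ei <- replace(numeric(K), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(K), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' 95% confidence intervals from Hessian uncertainties
#'
#' Symmetric intervals `mle +/- 1.96 sigma`.
#'
#' @param mle parameter estimates.
#' @param sigma per-parameter standard errors.
#' @return matrix with columns `low`, `high` and one row per parameter.
#' @export
ci95 <- function(mle, sigma) {
  if (length(sigma) != length(mle)) stop("mle and sigma lengths differ")
  cbind(low = mle - 1.96 * sigma, high = mle + 1.96 * sigma)
}

#' Empirical coverage of confidence intervals
#'
#' Fraction of replicate intervals containing the true simulated value,
#' per parameter.  Only replicates with a valid Hessian should be passed;
#' the denominator is the number of intervals supplied.
#'
#' @param intervals list of [ci95()] matrices, one per replicate.
#' @param truth true parameter vector.
#' @return list: `coverage` (proportion per parameter), `n` (denominator).
#' @export
coverage <- function(intervals, truth) {
  if (length(intervals) == 0)
    return(list(coverage = rep(NA_real_, length(truth)), n = 0L))
  hits <- sapply(intervals, function(ci)
    ci[, "low"] <= truth & truth <= ci[, "high"])
  hits <- matrix(hits, nrow = length(truth))
  list(coverage = rowMeans(hits), n = length(intervals))
}

#' Compare candidate model fits by AIC
#'
#' @param fits named list of `afs_fit` objects for one replicate.
#' @return list of class `"model_comparison"`: per-candidate table
#'   (`name`, `logL`, `K`, `AIC`, `dAIC`, `weight`), `selected` (argmin
#'   AIC; ties resolved toward the smaller K).
#' @export
compare_models <- function(fits) {
  nm <- vapply(fits, function(f) f$model, character(1))
  K <- vapply(nm, function(m) demographic_model(m)$K, numeric(1))
  logL <- vapply(fits, function(f) f$logL, numeric(1))
  aics <- aic(logL, K)
  w <- akaike_weights(aics)
  tab <- data.frame(name = nm, logL = logL, K = K, AIC = aics,
                    dAIC = aics - min(aics[is.finite(aics)]), weight = w,
                    row.names = NULL)
  ord <- order(aics, K)  # AIC ties resolved by parsimony
  structure(list(table = tab, selected = nm[ord[1]]),
            class = "model_comparison")
}
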