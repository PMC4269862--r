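#' Optimizer settings for composite-likelihood fits
#'
#' @param eps finite-difference step for the quasi-Newton gradient, taken
#'   on the log-parameter scale (so it is a relative step).
#' @param fold starting points are perturbed coordinate-wise by `2^U` with
#'   `U ~ Uniform(-fold, fold)`.
#' @param max_attempts cap on perturb-and-optimise attempts.
#' @param window,required convergence rule: stop once `required` attempts
#'   lie within `window` log-likelihood units of the best attempt.
#' @param maxit iteration cap per quasi-Newton attempt.
#' @return list of class `"optimizer_settings"`.
#' @export
optimizer_settings <- function(eps = 1e-6, fold = 1, max_attempts = 100L,
                               window = 5, required = 3L, maxit = 80L) {
  if (eps <= 0) stop("eps must be positive")
  if (fold < 0) stop("fold must be non-negative")
  if (max_attempts < required) stop("max_attempts must be >= required hits")
  structure(list(eps = eps, fold = fold, max_attempts = as.integer(max_attempts),
                 window = window, required = as.integer(required),
                 maxit = as.integer(maxit)),
            class = "optimizer_settings")
}

#' Poisson composite log-likelihood of a model spectrum given data
#'
#' Treats unmasked cells as independent Poisson counts: `sum(k log m - m
#' - log k!)` over unmasked cells for data count k and model expectation
#' m.  Cells with `m = 0, k = 0` contribute 0; `m = 0, k > 0` gives
#' `-Inf`.
#'
#' @param data observed [afs].
#' @param model expected [afs] of the same shape.
#' @return log composite likelihood (scalar).
#' @export
poisson_loglik <- function(data, model) {
  stopifnot(inherits(data, "afs"), inherits(model, "afs"))
  if (!identical(dim(as.matrix(data$entries)), dim(as.matrix(model$entries))))
    stop("data and model spectra differ in shape")
  keep <- !(data$mask | model$mask)
  k <- data$entries[keep]
  m <- model$entries[keep]
  ll <- rep(0, length(k))
  pos <- m > 0
  ll[pos] <- k[pos] * log(m[pos]) - m[pos] - lgamma(k[pos] + 1)
  ll[!pos & k > 0] <- -Inf
  sum(ll)
}

#' Multiplicative perturbation of a starting point
#'
#' Each coordinate is multiplied by `2^U`, `U ~ Uniform(-fold, fold)`
#' independently, then clipped into the bounds — the protocol used to
#' scatter optimisation starting points.
#'
#' @param start named parameter vector within bounds.
#' @param fold perturbation fold (0 = identity).
#' @param lower,upper bounds for clipping.
#' @param seed optional seed for a reproducible draw.
#' @return perturbed vector.
#' @export
perturb_start <- function(start, fold, lower, upper, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- start * 2^runif(length(start), -fold, fold)
  pmin(pmax(p, lower), upper)
}

#' Single bounded quasi-Newton optimisation attempt
#'
#' Maximises the Poisson composite likelihood over log-transformed
#' parameters with `stats::optim(method = "L-BFGS-B")`; gradients are
#' finite differences of relative step `eps`.  Positivity and bounds hold
#' by construction of the log-space box.
#'
#' @param model a [demographic_model()] or name.
#' @param data observed [afs].
#' @param start named starting vector (within bounds).
#' @param settings an [optimizer_settings()].
#' @param pts grid triple for the diffusion solve.
#' @return list with `par` (end point), `logL`, `start`, `ok` (FALSE when
#'   the likelihood was non-finite at the start or the optimiser failed).
#' @export
optimize_log <- function(model, data, start,
                         settings = optimizer_settings(),
                         pts = grid_scheme(data$sample_sizes)) {
  if (is.character(model)) model <- demographic_model(model)
  start <- pmin(pmax(start[model$param_names], model$lower), model$upper)
  nc <- data$sample_sizes
  pn <- model$param_names
  i_theta <- match("theta", pn)
  keep <- !data$mask
  k_data <- data$entries[keep]
  sum_k <- sum(k_data)
  lgam <- sum(lgamma(k_data + 1))
  # The expected spectrum is linear in theta (linear PDE, source and
  # equilibrium proportional to theta), so one unit-theta solve per shape
  # vector serves every theta; the last solve is cached, which makes the
  # theta direction (and repeated fn/gr calls at one point) free.
  cache <- new.env(parent = emptyenv())
  unit_entries <- function(p) {
    key <- paste(p[-i_theta], collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    pu <- p
    pu[i_theta] <- 1
    m <- tryCatch(expected_afs(model, pu, nc, pts), error = function(e) NULL)
    val <- if (is.null(m)) NULL else m$entries[keep]
    cache$key <- key
    cache$val <- val
    val
  }
  loglik_at <- function(p) {
    u <- unit_entries(p)
    if (is.null(u)) return(-1e18)
    m <- pmax(p[i_theta] * u, 1e-12)  # numerical floor; keeps logL finite
    ll <- sum(k_data * log(m)) - sum(m) - lgam
    if (!is.finite(ll)) -1e18 else ll
  }
  objective <- function(u) loglik_at(setNames(exp(u), pn))
  gradient <- function(u) {
    p <- setNames(exp(u), pn)
    f0 <- loglik_at(p)
    un <- cache$val
    g <- numeric(model$K)
    # analytic in log-theta: d logL / d log theta = sum k - theta * sum m
    g[i_theta] <- if (is.null(un)) 0 else sum_k - p[i_theta] * sum(pmax(un, 0))
    for (i in seq_len(model$K)[-i_theta]) {
      ui <- u
      ui[i] <- ui[i] + settings$eps
      g[i] <- (objective(ui) - f0) / settings$eps
    }
    g
  }
  u0 <- log(start)
  ll0 <- objective(u0)
  if (ll0 <= -1e17)
    return(list(par = start, logL = -Inf, start = start, ok = FALSE))
  fit <- tryCatch(
    optim(u0, objective, gradient, method = "L-BFGS-B",
          lower = log(model$lower), upper = log(model$upper),
          control = list(fnscale = -1, maxit = settings$maxit, factr = 1e10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = start, logL = ll0, start = start, ok = FALSE))
  par <- exp(fit$par)
  names(par) <- model$param_names
  logL <- fit$value
  if (logL < ll0) {  # ascent guarantee: never return worse than the start
    par <- start
    logL <- ll0
  }
  list(par = par, logL = logL, start = start, ok = TRUE)
}

#' Has the repeated-optimisation convergence rule been met?
#'
#' The protocol declares convergence once at least `required` attempts
#' have log-likelihoods within `window` units of the best attempt.
#'
#' @param logLs numeric vector of per-attempt log-likelihoods.
#' @param window,required rule constants (defaults 5 and 3).
#' @return logical.
#' @export
convergence_met <- function(logLs, window = 5, required = 3L) {
  logLs <- logLs[is.finite(logLs)]
  if (length(logLs) < required) return(FALSE)
  sum(logLs >= max(logLs) - window) >= required
}

#' Fit a model with the perturb-and-reoptimise convergence protocol
#'
#' Repeatedly perturbs the starting point and re-optimises until the
#' convergence rule of [convergence_met()] is satisfied or the attempt
#' cap is reached.  The returned estimate is the best attempt's;
#' non-convergence is a recorded state, not an error.  theta's starting
#' value is initialised by optimal scaling: the data's SNP total divided
#' by the unit-theta model total at the starting shape parameters.
#'
#' @param model a [demographic_model()] or name.
#' @param data observed [afs].
#' @param settings an [optimizer_settings()].
#' @param pts grid triple.
#' @param start base starting vector (default: the model's stored starts).
#' @param seed optional integer; attempt a uses seed `seed + a` for its
#'   perturbation, making the whole fit reproducible.
#' @return list of class `"afs_fit"`: `mle`, `logL`, `attempts`,
#'   `converged`, `model`, `trace` (per-attempt start/end/logL).
#' @export
fit_model <- function(model, data, settings = optimizer_settings(),
                      pts = grid_scheme(data$sample_sizes), start = NULL,
                      seed = NULL) {
  if (is.character(model)) model <- demographic_model(model)
  base <- if (is.null(start)) model$start else start
  base <- pmin(pmax(base[model$param_names], model$lower), model$upper)
  names(base) <- model$param_names
  # optimal-scaling initialisation of theta at the base shape
  unit <- base
  unit["theta"] <- 1
  ref <- tryCatch(expected_afs(model, unit, data$sample_sizes, pts),
                  error = function(e) NULL)
  if (!is.null(ref) && total_snps(ref) > 0)
    base["theta"] <- min(max(total_snps(data) / total_snps(ref),
                             model$lower["theta"]), model$upper["theta"])
  logLs <- numeric(0)
  attempts <- list()
  best <- NULL
  for (a in seq_len(settings$max_attempts)) {
    st <- perturb_start(base, settings$fold, model$lower, model$upper,
                        seed = if (is.null(seed)) NULL else seed + a)
    att <- optimize_log(model, data, st, settings, pts)
    attempts[[a]] <- att
    logLs[a] <- att$logL
    if (is.null(best) || (is.finite(att$logL) && att$logL > best$logL))
      best <- att
    if (convergence_met(logLs, settings$window, settings$required)) break
  }
  trace <- data.frame(attempt = seq_along(attempts),
                      logL = logLs)
  structure(list(mle = best$par, logL = best$logL,
                 attempts = length(attempts),
                 converged = convergence_met(logLs, settings$window,
                                             settings$required),
                 model = model$name, trace = trace),
            class = "afs_fit")
}

#' @export
print.afs_fit <- function(x, ...) {
  cat(sprintf("<%s fit: logL = %.3f after %d attempt(s)%s>\n", x$model,
              x$logL, x$attempts, if (x$converged) "" else ", NOT converged"))
  print(signif(x$mle, 4))
  invisible(x)
}
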