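#' Root mean squared error of parameter estimates
#'
#' `sqrt(mean((estimate - truth)^2))` over replicate datasets.
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @param truth simulated true value.
#' @return numeric.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0) stop("need at least one estimate")
  sqrt(mean((estimates - truth)^2))
}

#' Run one design cell: simulate, fit all candidates, compare
#'
#' For each replicate: draws a Poisson dataset around the cell's expected
#' spectrum, fits every candidate model with the convergence protocol,
#' computes AIC and Akaike weights, and (optionally) Hessian
#' uncertainties and 95% CIs for the true-model fit.  Fully reproducible
#' from `(base_seed, cell)` via [replicate_seed()].
#'
#' @param model true (simulated) model name.
#' @param label parameterization label (see [model_params()]).
#' @param n diploid individuals sampled per population.
#' @param reps replicate datasets.
#' @param base_seed study base seed.
#' @param candidates candidate model names (default: the standard
#'   one-population or two-population candidate set).
#' @param settings an [optimizer_settings()].
#' @param uncertainty compute [fim_uncertainty()] for the true-model fit.
#' @param true_params override the preset true parameter values.
#' @param fit_models optional list of [demographic_model()] objects (with
#'   e.g. relaxed bounds) keyed by candidate name, used for fitting.
#' @param start_overrides optional named list of starting vectors per
#'   candidate.
#' @return list of replicate records; each has `model`, `label`, `n`,
#'   `rep`, `seed`, `truth`, `fits`, `comparison`, `uncertainty`, `ci`.
#' @export
run_cell <- function(model, label, n, reps, base_seed = 1L,
                     candidates = NULL, settings = optimizer_settings(),
                     uncertainty = FALSE, true_params = NULL,
                     fit_models = NULL, start_overrides = NULL) {
  true_model <- demographic_model(model)
  if (is.null(candidates))
    candidates <- if (true_model$n_pops == 1L) c("SNM1", "POSG", "NEGG", "BG")
                  else c("SNM2", "ISO", "IM")
  truth <- if (is.null(true_params)) model_params(model, label) else true_params
  nc <- rep(2L * n, true_model$n_pops)
  pts <- grid_scheme(nc)
  expected <- expected_afs(true_model, truth, nc, pts)
  records <- vector("list", reps)
  for (r in seq_len(reps)) {
    seed_r <- replicate_seed(base_seed, model, label, n, r)
    data <- poisson_sample_afs(expected, seed_r)
    fits <- lapply(candidates, function(cand) {
      cm <- if (!is.null(fit_models) && cand %in% names(fit_models))
        fit_models[[cand]] else demographic_model(cand)
      st <- if (!is.null(start_overrides) && cand %in% names(start_overrides))
        start_overrides[[cand]] else NULL
      fit_model(cm, data, settings, pts, start = st,
                seed = replicate_seed(seed_r, cand))
    })
    names(fits) <- candidates
    cmp <- compare_models(fits)
    unc <- ci <- NULL
    if (uncertainty && model %in% candidates) {
      tf <- fits[[model]]
      llfun <- function(p) {
        names(p) <- true_model$param_names
        m <- expected_afs(true_model, p, nc, pts)
        m$entries <- pmax(m$entries, 1e-12)
        poisson_loglik(data, m)
      }
      unc <- fim_uncertainty(llfun, tf$mle)
      if (unc$hessian_ok) ci <- ci95(tf$mle, unc$sigma)
    }
    records[[r]] <- list(model = model, label = label, n = n, rep = r,
                         seed = seed_r, truth = truth, fits = fits,
                         comparison = cmp, uncertainty = unc, ci = ci)
  }
  records
}

# replicates where every candidate fit met the convergence rule
.all_converged <- function(records) {
  vapply(records, function(rec)
    all(vapply(rec$fits, function(f) isTRUE(f$converged), logical(1))),
    logical(1))
}

#' Per-replicate Akaike weight of one candidate
#'
#' @param records output of [run_cell()].
#' @param model candidate name (default: the simulated model).
#' @param converged_only restrict to replicates where all candidates
#'   converged, as the study's exclusions do.
#' @return numeric vector of weights.
#' @export
model_weights <- function(records, model = records[[1]]$model,
                          converged_only = TRUE) {
  keep <- if (converged_only) .all_converged(records) else rep(TRUE, length(records))
  vapply(records[keep], function(rec) {
    tab <- rec$comparison$table
    tab$weight[match(model, tab$name)]
  }, numeric(1))
}

#' Summarise a cell's replicate records
#'
#' Median parameter estimates and RMSE for the true-model fits, the
#' Akaike-weight distribution of the true model (median, quartiles,
#' 1.5 IQR whiskers, outlier count), coverage of the 95% CIs over
#' replicates with a valid Hessian, convergence-failure counts and mean
#' attempts.  Model-selection summaries use only replicates where every
#' candidate converged.
#'
#' @param records output of [run_cell()].
#' @return list of class `"study_summary"`.
#' @export
summarize_study <- function(records) {
  stopifnot(length(records) >= 1)
  truth <- records[[1]]$truth
  model <- records[[1]]$model
  conv <- .all_converged(records)
  true_conv <- vapply(records, function(rec)
    isTRUE(rec$fits[[model]]$converged), logical(1))
  if (sum(true_conv) == 0)
    return(structure(list(empty = TRUE, n_records = length(records)),
                     class = "study_summary"))
  est <- matrix(vapply(records[true_conv], function(rec)
    rec$fits[[model]]$mle[names(truth)], numeric(length(truth))),
    ncol = length(truth), byrow = TRUE, dimnames = list(NULL, names(truth)))
  medians <- apply(est, 2, median)
  rmses <- vapply(names(truth), function(p) rmse(est[, p], truth[[p]]),
                  numeric(1))
  w <- model_weights(records, model)
  qs <- if (length(w)) quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
        else rep(NA_real_, 3)
  iqr <- qs[3] - qs[1]
  inside <- w[w >= qs[1] - 1.5 * iqr & w <= qs[3] + 1.5 * iqr]
  whisk <- if (length(inside)) range(inside) else c(NA_real_, NA_real_)
  cis <- Filter(Negate(is.null), lapply(records, `[[`, "ci"))
  cov <- coverage(cis, truth)
  attempts <- colMeans(t(vapply(records, function(rec)
    vapply(rec$fits, `[[`, numeric(1), "attempts"), numeric(length(records[[1]]$fits)))))
  structure(list(
    empty = FALSE, model = model, label = records[[1]]$label,
    n = records[[1]]$n, truth = truth, n_records = length(records),
    n_all_converged = sum(conv), n_true_converged = sum(true_conv),
    median_est = medians, rmse = rmses,
    weight_quartiles = qs,
    weight_whiskers = if (length(w)) whisk else c(NA_real_, NA_real_),
    weight_outliers = if (length(w))
      sum(w < qs[1] - 1.5 * iqr | w > qs[3] + 1.5 * iqr) else NA_integer_,
    coverage = cov$coverage, coverage_n = cov$n,
    mean_attempts = attempts), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<study_summary: no converged true-model fits>\n")
    return(invisible(x))
  }
  cat(sprintf("<study_summary: %s-%s, n = %d, %d replicates (%d fully converged)>\n",
              x$model, x$label, x$n, x$n_records, x$n_all_converged))
  cat("median estimates:\n"); print(signif(x$median_est, 4))
  cat("RMSE:\n"); print(signif(x$rmse, 4))
  cat(sprintf("true-model Akaike weight quartiles: %.3f / %.3f / %.3f\n",
              x$weight_quartiles[1], x$weight_quartiles[2], x$weight_quartiles[3]))
  invisible(x)
}

#' Recovery of the direction of migration asymmetry
#'
#' Fraction of IM fits whose point estimates satisfy `m_12 > m_21`
#' (strict; ties count as non-recovery), with a companion statistic: the
#' fraction whose two migration CIs are disjoint in the correct order
#' (when uncertainties were computed).
#'
#' @param records output of [run_cell()] containing IM fits.
#' @param converged_only restrict to converged IM fits.
#' @return list: `point` (proportion), `ci_disjoint` (proportion or NA),
#'   `n`.
#' @export
asymmetry_recovery <- function(records, converged_only = TRUE) {
  has_im <- vapply(records, function(rec) "IM" %in% names(rec$fits), logical(1))
  records <- records[has_im]
  if (!length(records)) stop("no IM fits in records")
  if (converged_only)
    records <- records[vapply(records, function(rec)
      isTRUE(rec$fits[["IM"]]$converged), logical(1))]
  m12 <- vapply(records, function(rec) rec$fits[["IM"]]$mle[["m_12"]], numeric(1))
  m21 <- vapply(records, function(rec) rec$fits[["IM"]]$mle[["m_21"]], numeric(1))
  point <- mean(m12 > m21)
  cis <- lapply(records, `[[`, "ci")
  ok <- !vapply(cis, is.null, logical(1))
  cid <- if (any(ok)) {
    mean(vapply(cis[ok], function(ci)
      ci["m_12", "low"] > ci["m_21", "high"], logical(1)))
  } else NA_real_
  list(point = point, ci_disjoint = cid, n = length(records))
}
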