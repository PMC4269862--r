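test_that("Poisson composite likelihood matches hand-evaluated cells", {
  expect_equal(poisson_loglik(one_cell(1), one_cell(1, "expected")), -1)
  expect_equal(poisson_loglik(one_cell(2), one_cell(1, "expected")),
               -1 - log(2))
  # cell-wise maximum over the expectation sits at m = k
  ll <- vapply(c(1.5, 2, 2.5), function(m)
    poisson_loglik(one_cell(2), one_cell(m, "expected")), numeric(1))
  expect_gt(ll[2], ll[1])
  expect_gt(ll[2], ll[3])
  # m = 0 cells: impossible data sink the likelihood, empty cells are free
  expect_identical(poisson_loglik(one_cell(1), one_cell(0, "expected")), -Inf)
  expect_identical(poisson_loglik(one_cell(0), one_cell(0, "expected")), 0)
  expect_error(poisson_loglik(tiny_obs(), one_cell(1, "expected")), "shape")
})

test_that("start perturbation is multiplicative, bounded and seedable", {
  lo <- c(s = 0.01); hi <- c(s = 0.99)
  draws <- vapply(1:200, function(i)
    perturb_start(c(s = 0.25), 1, lo, hi, seed = i), numeric(1))
  expect_true(all(draws >= 0.125 & draws <= 0.5))
  expect_gt(max(draws), 0.4)  # the full 2-fold range is exercised
  expect_lt(min(draws), 0.16)
  expect_identical(perturb_start(c(s = 0.25), 0, lo, hi), c(s = 0.25))
  # 2-fold perturbation about 0.5 reaches [0.125, 0.99-clipped]
  d2 <- vapply(1:200, function(i)
    perturb_start(c(s = 0.5), 2, lo, hi, seed = i), numeric(1))
  expect_true(all(d2 >= 0.125 & d2 <= 0.99))
})

test_that("the convergence rule counts attempts near the best likelihood", {
  expect_true(convergence_met(c(-100, -104.9, -103, -200)))
  expect_false(convergence_met(c(-100, -104.9)))
  expect_false(convergence_met(c(-100, -110, -120, -130)))
  expect_true(convergence_met(c(-5, -5, -5)))
  expect_false(convergence_met(c(-Inf, -Inf, -5, -5)))
})

test_that("self-fit recovers theta on noise-free constant-size data", {
  ex <- expected_afs("SNM1", c(theta = 10000), 20)
  ex$kind <- "observed"
  ex$entries <- round(ex$entries)
  att <- optimize_log("SNM1", ex, start = c(theta = 5000))
  expect_lt(abs(att$par[["theta"]] - 10000) / 10000, 0.01)
  # ascent property and bound compliance
  start_ll <- poisson_loglik(ex, expected_afs("SNM1", c(theta = 5000), 20))
  expect_gte(att$logL, start_ll)
  m <- demographic_model("SNM1")
  expect_true(att$par >= m$lower && att$par <= m$upper)
})

test_that("fold-zero refits converge after exactly the required attempts", {
  ex <- expected_afs("SNM1", c(theta = 2000), 10)
  d <- poisson_sample_afs(ex, 17)
  f <- fit_model("SNM1", d, optimizer_settings(fold = 0, max_attempts = 10),
                 seed = 1)
  expect_true(f$converged)
  expect_equal(f$attempts, 3L)
  expect_equal(length(unique(round(f$trace$logL, 6))), 1L)
})

test_that("the attempt cap returns the best fit flagged as unconverged", {
  ex <- expected_afs("NEGG", model_params("NEGG", "A"), 10)
  d <- poisson_sample_afs(ex, 23)
  f <- fit_model("NEGG", d, optimizer_settings(max_attempts = 3, maxit = 2,
                                               fold = 3), seed = 5)
  expect_equal(f$attempts, 3L)
  expect_true(is.finite(f$logL))
  expect_equal(f$logL, max(f$trace$logL))
  expect_error(optimizer_settings(max_attempts = 2, required = 3),
               "max_attempts")
})

test_that("median estimates approach truth for an ancient decline at n = 50", {
  p <- model_params("NEGG", "A")
  ex <- expected_afs("NEGG", p, 100)
  est <- t(vapply(1:20, function(r) {
    d <- poisson_sample_afs(ex, replicate_seed(99, "NEGG", "A", 50, r))
    fit_model("NEGG", d, fast_settings(), seed = r)$mle
  }, numeric(3)))
  med <- apply(est, 2, median)
  expect_lt(abs(med[1] - p[["theta"]]) / p[["theta"]], 0.10)
  expect_lt(abs(med[2] - p[["eta_D"]]) / p[["eta_D"]], 0.10)
  expect_lt(abs(med[3] - p[["T"]]) / p[["T"]], 0.10)
})
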