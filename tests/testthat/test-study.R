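test_that("RMSE matches hand calculations", {
  expect_equal(rmse(c(1, 3), 2), 1)
  expect_equal(rmse(c(2, 2, 2), 2), 0)
  expect_equal(rmse(5, 2), 3)  # single estimate reduces to |e - truth|
  expect_equal(rmse(c(9, 10, 11), 10), sqrt(2 / 3))
  expect_error(rmse(numeric(0), 1), "at least one")
})

test_that("run_cell produces reproducible records with all candidate fits", {
  set.seed(404)
  recs <- run_cell("NEGG", "A", n = 5, reps = 2, base_seed = 7,
                   settings = fast_settings(max_attempts = 5, maxit = 25))
  expect_length(recs, 2)
  expect_setequal(names(recs[[1]]$fits), c("SNM1", "POSG", "NEGG", "BG"))
  expect_equal(recs[[1]]$truth, model_params("NEGG", "A"))
  set.seed(505)  # ambient RNG state must not matter
  recs2 <- run_cell("NEGG", "A", n = 5, reps = 2, base_seed = 7,
                    settings = fast_settings(max_attempts = 5, maxit = 25))
  expect_identical(vapply(recs, function(r) r$comparison$selected, ""),
                   vapply(recs2, function(r) r$comparison$selected, ""))
  expect_identical(recs[[1]]$fits$NEGG$mle, recs2[[1]]$fits$NEGG$mle)
  expect_length(run_cell("NEGG", "A", 5, reps = 0), 0)
})

test_that("summaries aggregate medians, RMSE, weights and exclusions", {
  mkfit <- function(model, mle, logL, converged = TRUE)
    structure(list(model = model, mle = mle, logL = logL, attempts = 3L,
                   converged = converged), class = "afs_fit")
  mkrec <- function(th, logL_true, logL_alt, conv_alt = TRUE, ci = NULL) {
    fits <- list(SNM1 = mkfit("SNM1", c(theta = th), logL_true),
                 POSG = mkfit("POSG", c(theta = th, eta_G = 1, T = 1),
                              logL_alt, conv_alt))
    list(model = "SNM1", label = "A", n = 5, rep = 1, seed = 1,
         truth = c(theta = 10), fits = fits,
         comparison = compare_models(fits), uncertainty = NULL, ci = ci)
  }
  recs <- list(mkrec(9, -100, -300, ci = ci95(c(theta = 5), 1)),
               mkrec(10, -100, -300, ci = ci95(c(theta = 10), 0.1)),
               mkrec(11, -100, -300, conv_alt = FALSE))
  s <- summarize_study(recs)
  expect_equal(unname(s$median_est["theta"]), 10)
  expect_equal(unname(s$rmse["theta"]), sqrt(2 / 3))
  expect_equal(s$n_all_converged, 2L)        # one replicate excluded
  expect_equal(s$n_true_converged, 3L)
  expect_equal(s$weight_quartiles[2], 1, tolerance = 1e-10)
  expect_equal(s$coverage_n, 2L)
  expect_equal(unname(s$coverage), 0.5)      # truth 10 inside one of two CIs
})

test_that("migration asymmetry recovery counts strict orderings only", {
  mkrec <- function(m12, m21, converged = TRUE) {
    list(fits = list(IM = structure(
      list(model = "IM", mle = c(theta = 1, s = 0.5, eta_1 = 1, eta_2 = 1,
                                 T = 0.1, m_12 = m12, m_21 = m21),
           logL = -1, attempts = 3L, converged = converged),
      class = "afs_fit")), ci = NULL)
  }
  recs <- list(mkrec(10, 1), mkrec(5, 2), mkrec(3, 3), mkrec(1, 4))
  out <- asymmetry_recovery(recs)
  expect_equal(out$point, 0.5)  # the tie counts as non-recovery
  expect_equal(out$n, 4L)
  out2 <- asymmetry_recovery(list(mkrec(10, 1), mkrec(2, 1, FALSE)))
  expect_equal(out2$n, 1L)      # unconverged fits are excluded
  expect_equal(out2$point, 1)
  expect_error(asymmetry_recovery(list(list(fits = list()))), "no IM fits")
})
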