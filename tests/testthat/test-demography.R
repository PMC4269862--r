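test_that("model catalog has the seven models with their parameter counts", {
  K <- c(SNM1 = 1, POSG = 3, NEGG = 3, BG = 4, SNM2 = 1, ISO = 5, IM = 7)
  for (m in names(K)) {
    spec <- demographic_model(m)
    expect_equal(spec$K, unname(K[m]), info = m)
    expect_equal(length(spec$param_names), spec$K, info = m)
    expect_true(all(spec$lower > 0), info = m)
    expect_true(all(spec$upper > spec$lower), info = m)
  }
  expect_error(demographic_model("XYZ"), "unknown")
})

test_that("optimisation bounds follow the study protocol", {
  bg <- demographic_model("BG")
  expect_equal(unname(bg$lower[c("eta_D", "eta_G", "T")]), c(0.001, 1, 0.01))
  expect_equal(unname(bg$upper[c("eta_D", "eta_G", "T")]), c(1, 100, 5))
  im <- demographic_model("IM")
  expect_equal(unname(im$lower[c("s", "eta_1", "T", "m_12")]),
               c(0.01, 0.5, 0.005, 0.1))
  expect_equal(unname(im$upper[c("s", "eta_1", "T", "m_12")]),
               c(0.99, 10, 5, 20))
  # bound overrides, e.g. relaxing T for extremely recent splits
  iso <- demographic_model("ISO", lower = c(T = 0.001))
  expect_equal(unname(iso$lower["T"]), 0.001)
  expect_error(demographic_model("SNM1", lower = c(T = 0.001)), "no parameter")
})

test_that("size trajectories interpolate exponentially between endpoints", {
  nu <- size_trajectory("POSG", c(theta = 6000, eta_G = 5, T = 0.25))
  expect_equal(nu(0), 1)
  expect_equal(nu(0.25), 5)
  expect_equal(nu(0.125), sqrt(5))  # hand evaluation of the interpolation
  nuD <- size_trajectory("NEGG", c(theta = 29000, eta_D = 0.1, T = 0.25))
  expect_equal(nuD(0.25), 0.1)
  nuB <- size_trajectory("BG", c(theta = 1e4, eta_D = 0.1, eta_G = 5, T = 0.25))
  expect_equal(nuB(0), 0.1)   # instantaneous crash at onset
  expect_equal(nuB(0.25), 5)  # exponential recovery to eta_G at present
  tr <- size_trajectory("ISO", c(theta = 7250, s = 0.3, eta_1 = 2,
                                 eta_2 = 1, T = 0.25))
  expect_equal(tr[[1]](0), 0.3)
  expect_equal(tr[[2]](0), 0.7)
  expect_equal(tr[[1]](0.25), 2)
  expect_error(size_trajectory("POSG", c(theta = 6000, eta_G = -5, T = 0.25)),
               "positive")
})

test_that("built-in parameterizations match the study tables", {
  expect_equal(model_params("NEGG", "A"),
               c(theta = 29000, eta_D = 0.1, T = 0.25))
  expect_equal(model_params("NEGG", "B"),
               c(theta = 29000, eta_D = 0.25, T = 0.025))
  expect_equal(model_params("POSG", "A")[["theta"]], 6000)
  expect_equal(model_params("BG", "B"),
               c(theta = 10000, eta_D = 0.25, eta_G = 2.5, T = 0.025))
  expect_equal(model_params("SNM2", "A"), c(theta = 10000))
  expect_equal(model_params("IM", "B"),
               c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1, T = 0.025,
                 m_12 = 10, m_21 = 1))
  expect_equal(model_params("ISO", "extreme-recent")[["T"]], 0.005)
  expect_equal(model_params("NEGG", "extreme-old")[["T"]], 1.5)
  expect_error(model_params("SNM1", "extreme-recent"), "parameterization")

  cat_a <- model_catalog("A")
  expect_setequal(names(cat_a),
                  c("SNM1", "POSG", "NEGG", "BG", "SNM2", "ISO", "IM"))
  expect_setequal(names(model_catalog("extreme-old")),
                  c("SNM1", "POSG", "NEGG", "BG"))
})
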