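test_that("constant-size spectrum reproduces the theta/i closed form", {
  s <- expected_afs("SNM1", c(theta = 10000), n_chrom = 20)
  truth <- snm_closed_form(10000, 20)
  expect_lt(max(abs(s$entries[2:20] - truth) / truth), 0.01)
  # discretisation error shrinks as the grid is refined
  err_at <- function(pts) {
    e <- expected_afs("SNM1", c(theta = 1e4), 20, pts = pts)$entries[2:20]
    max(abs(e - truth) / truth)
  }
  expect_lt(err_at(60), err_at(30))
})

test_that("default grids follow the 2n + 10/20/30 rule", {
  expect_equal(grid_scheme(100), c(110L, 120L, 130L))
  expect_equal(grid_scheme(c(20, 20)), c(30L, 40L, 50L))
})

test_that("Richardson extrapolation recovers quadratic-in-spacing values", {
  h <- 1 / (c(30, 40, 50) - 1)
  a <- 3.7; b <- -2.1; ch <- 11
  specs <- lapply(h, function(hi) {
    afs(rep(a + b * hi + ch * hi^2, 5), 4)
  })
  out <- extrapolate_grids(specs, h)
  expect_equal(out$entries[2:4], rep(a, 3), tolerance = 1e-12)
  # constant values are returned unchanged
  same <- extrapolate_grids(lapply(1:3, function(i) afs(rep(2, 5), 4)), h)
  expect_equal(same$entries[2:4], rep(2, 3))
  expect_error(extrapolate_grids(list(afs(rep(1, 5), 4), afs(rep(1, 7), 6),
                                      afs(rep(1, 5), 4)), h), "shape")
})

test_that("degenerate parameters collapse models onto their special cases", {
  snm <- expected_afs("SNM1", c(theta = 1e4), 20)
  posg1 <- expected_afs("POSG", c(theta = 1e4, eta_G = 1, T = 0.25), 20)
  expect_lt(sum(abs(posg1$entries - snm$entries)) / total_snps(snm), 1e-10)
  # a bottleneck of depth 1 is exactly exponential growth
  posg <- expected_afs("POSG", c(theta = 1e4, eta_G = 5, T = 0.25), 20)
  bg1 <- expected_afs("BG", c(theta = 1e4, eta_D = 1, eta_G = 5, T = 0.25), 20)
  expect_lt(sum(abs(bg1$entries - posg$entries)) / total_snps(posg), 1e-10)
})

test_that("no-divergence joint spectrum marginalises to the 1-D spectrum", {
  s2 <- expected_afs("SNM2", c(theta = 1e4), c(10, 10))
  s1 <- expected_afs("SNM1", c(theta = 1e4), 10)
  marg <- rowSums(s2$entries)
  expect_lt(max(abs(marg[2:10] - s1$entries[2:10]) / s1$entries[2:10]), 0.02)
})

test_that("symmetric two-population histories give exchangeable spectra", {
  im <- expected_afs("IM", c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1,
                             T = 0.25, m_12 = 2, m_21 = 2), c(10, 10))
  expect_lt(max(abs(im$entries - t(im$entries))) / max(im$entries), 1e-5)
})

test_that("IM without migration equals the isolation model", {
  p_iso <- model_params("ISO", "A")
  iso <- expected_afs("ISO", p_iso, c(10, 10))
  im0 <- expected_afs("IM", c(p_iso, m_12 = 1e-12, m_21 = 1e-12), c(10, 10))
  expect_lt(sum(abs(im0$entries - iso$entries)) / total_snps(iso), 1e-6)
  # migration held at its optimisation lower bound stays close to isolation
  imlo <- expected_afs("IM", c(p_iso, m_12 = 0.1, m_21 = 0.1), c(10, 10))
  expect_lt(sum(abs(imlo$entries - iso$entries)) / total_snps(iso), 0.05)
})

test_that("expected spectra are continuous and finite across the bound box", {
  for (p in list(c(theta = 1e3, eta_D = 0.001, T = 0.02),
                 c(theta = 1e3, eta_D = 0.999, T = 5))) {
    s <- expected_afs("NEGG", p, 10)
    expect_true(all(is.finite(s$entries)))
    expect_gt(total_snps(s), 0)
  }
  expect_error(expected_afs("NEGG", c(theta = 1e3, eta_D = -1, T = 0.1), 10),
               "positive")
  expect_error(expected_afs("SNM2", c(theta = 1e3), 10), "sample size")
})
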