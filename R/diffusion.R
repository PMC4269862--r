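#' Default finite-difference grid sizes
#'
#' The grid triple used for Richardson extrapolation: `[2n + 10, 2n + 20,
#' 2n + 30]` points, where n is the number of diploid individuals sampled
#' per population (i.e. `max(n_chrom) + 10/20/30`).
#'
#' @param n_chrom chromosome count(s), one per population.
#' @return Increasing integer vector of three grid sizes.
#' @examples
#' grid_scheme(100)  # 50 diploids -> 110 120 130
#' @export
grid_scheme <- function(n_chrom) {
  as.integer(max(n_chrom) + c(10L, 20L, 30L))
}

#' Expected allele frequency spectrum under a demographic model
#'
#' Solves the neutral Wright-Fisher diffusion for the density of
#' segregating variants by an implicit finite-difference scheme (a
#' direction-split tridiagonal sweep in two dimensions), starting from the
#' exact discrete mutation-drift equilibrium of the ancestral population,
#' integrating through the model's size trajectories (and migration, for
#' IM) for duration T, then binomially sampling the density into
#' frequency classes.  The spectrum is computed on each grid of `pts` and
#' extrapolated cell-wise to zero grid spacing with a quadratic
#' (three-point Richardson) fit, which removes the leading discretisation
#' error.
#'
#' @param model a [demographic_model()] or model name.
#' @param params named parameter vector (see [model_params()] for presets).
#' @param n_chrom chromosome count per population (`2n_i`); length must
#'   equal the model's population count.
#' @param pts integer vector of grid sizes (default [grid_scheme()]).  A
#'   single value skips extrapolation.
#' @return An [afs] of kind `"expected"` with corner cells masked.  Cells
#'   are clamped at zero after extrapolation.
#' @examples
#' s <- expected_afs("SNM1", c(theta = 1000), n_chrom = 10, pts = c(20, 30, 40))
#' total_snps(s)
#' @export
expected_afs <- function(model, params, n_chrom,
                         pts = grid_scheme(n_chrom)) {
  if (is.character(model)) model <- demographic_model(model)
  if (length(n_chrom) != model$n_pops)
    stop("model ", model$name, " needs ", model$n_pops,
         " sample size(s), got ", length(n_chrom))
  pts <- sort(as.integer(pts))
  if (any(pts < max(n_chrom) + 1L))
    stop("grid sizes must be at least 2n + 1")
  hist <- .history(model, params)
  specs <- lapply(pts, function(p) .expected_afs_single(hist, n_chrom, p))
  if (length(pts) == 1L) return(specs[[1L]])
  extrapolate_grids(specs, spacings = 1 / (pts - 1))
}

# Single-grid expected spectrum (no extrapolation); exercised directly by
# convergence tests.  The two-dimensional sweep caps its step count harder
# than the cheap one-dimensional solve; with uniform dt = T/M the
# stepping error stays tied to the grid spacing, which the Richardson
# extrapolation removes.
.expected_afs_single <- function(hist, n_chrom, pts) {
  xx <- seq(0, 1, length.out = pts)
  phi1 <- .equilibrium_phi(hist$theta, xx)
  if (hist$n_pops == 1L) {
    if (hist$T > 0) {
      st <- .time_steps(hist$T, xx[2], .nu_min(hist$nu1, hist$T),
                        max_steps = 1500L)
      phi1 <- .wf_integrate_1d(phi1, xx, hist$nu1(st$mid), st$dt, hist$theta)
    }
    entries <- .sample_phi_1d(phi1, xx, n_chrom)
    return(afs(entries, n_chrom, kind = "expected"))
  }
  if (hist$T > 0) {
    phi2 <- .lift_to_2d(phi1, xx)
    st <- .time_steps(hist$T, xx[2],
                      min(.nu_min(hist$nu1, hist$T), .nu_min(hist$nu2, hist$T)),
                      max_steps = 100L)
    phi2 <- .wf_integrate_2d(phi2, xx, hist$nu1(st$mid), hist$nu2(st$mid),
                             hist$m12, hist$m21, st$dt, hist$theta)
    entries <- .sample_phi_2d(phi2, xx, n_chrom)
  } else {
    # no divergence: both samples drawn from one panmictic density
    entries <- .sample_diag(phi1, xx, n_chrom)
  }
  afs(entries, n_chrom, kind = "expected")
}

#' Richardson extrapolation of sampled spectra over a grid triple
#'
#' Fits, cell by cell, a quadratic in the grid spacing h through the three
#' sampled values and evaluates it at h = 0.
#'
#' @param spectra list of three same-shape [afs] objects from strictly
#'   decreasing spacings.
#' @param spacings the grid spacings (`1 / (pts - 1)`).
#' @return The extrapolated [afs].
#' @export
extrapolate_grids <- function(spectra, spacings) {
  if (length(spectra) != length(spacings))
    stop("need one spacing per spectrum")
  dims <- lapply(spectra, function(s) dim(as.matrix(s$entries)))
  if (length(unique(dims)) != 1L) stop("spectra shapes differ")
  w <- vapply(seq_along(spacings), function(i) {
    prod(spacings[-i] / (spacings[-i] - spacings[i]))
  }, numeric(1))
  entries <- Reduce(`+`, Map(function(s, wi) s$entries * wi, spectra, w))
  entries <- pmax(entries, 0)
  afs(entries, spectra[[1L]]$sample_sizes, kind = "expected",
      mask = spectra[[1L]]$mask)
}

# minimum relative size along an exponential (monotone) trajectory
.nu_min <- function(nu, T) min(nu(c(0, T)))

# Uniform implicit time steps: dt tracks the grid spacing and the fastest
# drift timescale, with floors/caps keeping step counts practical; dt =
# T/M so the end time is hit exactly.  The 15-step floor keeps the
# relative time-truncation error small for very recent events, where the
# freshly split density is sharply peaked.
.time_steps <- function(T, h, nu_min, dtfac = 0.25, max_steps = 3000L) {
  target <- dtfac * h * min(max(nu_min, 0.05), 1)
  M <- min(max(15L, ceiling(T / target)), max_steps)
  dt <- T / M
  list(dt = rep(dt, M), mid = (seq_len(M) - 0.5) * dt)
}

# Mutation-drift equilibrium density of the ancestral population.  With
# influx theta/(2 h^2) at the first interior point, theta/x is the exact
# stationary solution of the discrete operator at every interior node
# (verified in tests by integrating forward); boundary values are set by
# linear extrapolation for use in sampling quadratures.
.equilibrium_phi <- function(theta, xx) {
  phi <- theta / xx
  phi[1] <- max(0, 2 * phi[2] - phi[3])
  phi
}

# Sample a 1-D density into 2n+1 frequency classes.  Integrates
# psi = x phi (finite at the divergent x -> 0 boundary) against
# C(2n,k) x^(k-1) (1-x)^(2n-k) by the trapezoid rule.
.sample_phi_1d <- function(phi, xx, nc) {
  P <- length(xx)
  psi <- xx * phi
  psi[1] <- max(0, 2 * psi[2] - psi[3])
  w <- rep(xx[2] - xx[1], P)
  w[c(1, P)] <- w[1] / 2
  k <- seq_len(nc - 1L)
  lx <- log(xx[-c(1, P)])
  l1x <- log1p(-xx[-c(1, P)])
  G <- exp(outer(lx, k - 1) + outer(l1x, nc - k) +
           rep(lchoose(nc, k), each = P - 2L))
  interior <- as.vector(crossprod(G, (w * psi)[-c(1, P)]))
  # boundary rows: at x=0 the psi-integrand is C(2n,1) for k=1, 0 otherwise;
  # at x=1 it vanishes for every unmasked class
  interior[1] <- interior[1] + w[1] * nc * psi[1]
  c(0, interior, 0)
}

# Binomial-weight matrix on the full k = 0..nc range with direct
# (1-x)^(nc-k) x^k weights; boundary grid points reduce to indicators so
# boundary-line mass lands in the k = 0 / k = nc classes.
.binom_weights <- function(xx, nc) {
  P <- length(xx)
  k <- 0:nc
  G <- matrix(0, P, nc + 1L)
  lx <- log(xx[-c(1, P)])
  l1x <- log1p(-xx[-c(1, P)])
  G[-c(1, P), ] <- exp(outer(lx, k) + outer(l1x, nc - k) +
                       rep(lchoose(nc, k), each = P - 2L))
  G[1, 1] <- 1
  G[P, nc + 1L] <- 1
  G
}

# Joint sampling of a 2-D density (including the boundary lines, which
# hold variants private to one population).
.sample_phi_2d <- function(phi, xx, nc) {
  P <- length(xx)
  w <- rep(xx[2] - xx[1], P)
  w[c(1, P)] <- w[1] / 2
  G1 <- .binom_weights(xx, nc[1])
  G2 <- .binom_weights(xx, nc[2])
  crossprod(G1 * w, phi) %*% (G2 * w)
}

# Joint sampling of two samples from a single panmictic density (the
# no-divergence model): a 1-D quadrature with product binomial weights.
.sample_diag <- function(phi1, xx, nc) {
  P <- length(xx)
  w <- rep(xx[2] - xx[1], P)
  w[c(1, P)] <- w[1] / 2
  G1 <- .binom_weights(xx, nc[1])
  G2 <- .binom_weights(xx, nc[2])
  crossprod(G1, (w * phi1) * G2)
}

# Place the 1-D density on the diagonal of the 2-D grid (a split hands
# both daughters the parental frequency); cell-average scaling by the
# trapezoid cell width keeps the sampled spectrum consistent with the
# 1-D quadrature.
.lift_to_2d <- function(phi1, xx) {
  P <- length(xx)
  w <- rep(xx[2] - xx[1], P)
  w[c(1, P)] <- w[1] / 2
  phi2 <- matrix(0, P, P)
  diag(phi2) <- phi1 / w
  phi2
}
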