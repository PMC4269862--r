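#' Monte-Carlo expected AFS from the structured coalescent
#'
#' Independent cross-check of the diffusion engine: genealogies are
#' sampled under the model's time-rescaled coalescent (piecewise
#' exponential sizes, a split at T, continuous migration simulated by an
#' exponential race, thinning for the time-varying rates).  In
#' `"branch"` mode the per-branch lifetimes are accumulated by the joint
#' descendant configuration of each branch and scaled by theta/2, giving
#' a low-variance estimate of the expected spectrum.  In `"mutation"`
#' mode Poisson mutations are dropped on the branches of `n_loci`
#' independent non-recombining loci with per-locus weight `theta_locus`,
#' emulating ms-style replicate datasets.
#'
#' @param model a [demographic_model()] or name.
#' @param params named parameter vector; `theta` scales branch mode.
#' @param n_chrom chromosomes sampled per population.
#' @param n_genealogies genealogies (branch mode) or loci (mutation mode).
#' @param seed integer seed; results are reproducible given the seed.
#' @param mode `"branch"` (expected spectrum) or `"mutation"` (observed
#'   counts).
#' @param theta_locus per-locus mutation weight in mutation mode.
#' @return An [afs] of kind `"expected"` (branch) or `"observed"`
#'   (mutation).
#' @examples
#' simulate_coalescent_afs("SNM1", c(theta = 100), 4, n_genealogies = 200,
#'                         seed = 1)
#' @export
simulate_coalescent_afs <- function(model, params, n_chrom,
                                    n_genealogies = 1000L, seed = 1L,
                                    mode = c("branch", "mutation"),
                                    theta_locus = 1) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- demographic_model(model)
  if (length(n_chrom) != model$n_pops || any(n_chrom < 1))
    stop("n_chrom must give a positive chromosome count per population")
  if (n_genealogies < 1) stop("need at least one genealogy")
  hist <- .history(model, params)
  set.seed(seed)
  two_pop <- model$n_pops == 2L
  dims <- n_chrom + 1L
  acc <- array(0, dim = if (two_pop) dims else c(dims, 1L))
  for (g in seq_len(n_genealogies)) {
    L <- .sim_genealogy(hist, n_chrom, two_pop)
    if (mode == "mutation") L[] <- rpois(length(L), theta_locus / 2 * L)
    acc <- acc + L
  }
  if (mode == "branch") {
    entries <- hist$theta / 2 * acc / n_genealogies
  } else {
    entries <- acc
  }
  if (!two_pop) entries <- entries[, 1L]
  # the root subtends the whole sample; it is not a branch
  afs(entries, n_chrom, kind = if (mode == "branch") "expected" else "observed")
}

# One genealogy; returns total branch length per descendant configuration
# (d1+1, d2+1).  A lineage's configuration is fixed from its birth to its
# coalescence, so lifetimes are charged per lineage when it ends.
.sim_genealogy <- function(hist, nc, two_pop) {
  dims <- if (two_pop) nc + 1L else c(nc + 1L, 1L)
  L <- array(0, dim = dims)
  if (two_pop) {
    d1 <- c(rep(1L, nc[1]), rep(0L, nc[2]))
    d2 <- c(rep(0L, nc[1]), rep(1L, nc[2]))
    pop <- c(rep(1L, nc[1]), rep(2L, nc[2]))
  } else {
    d1 <- rep(1L, nc[1])
    d2 <- rep(0L, length(d1))
    pop <- rep(1L, length(d1))
  }
  born <- rep(0, length(d1))
  t <- 0
  charge <- function(i, t_end) L[d1[i] + 1L, d2[i] + 1L] <<- L[d1[i] + 1L, d2[i] + 1L] + (t_end - born[i])
  coalesce <- function(pick, t) {
    charge(pick[1], t); charge(pick[2], t)
    d1 <<- c(d1[-pick], d1[pick[1]] + d1[pick[2]])
    d2 <<- c(d2[-pick], d2[pick[1]] + d2[pick[2]])
    pop <<- c(pop[-pick], pop[pick[1]])
    born <<- c(born[-pick], t)
  }
  T <- hist$T
  if (T > 0) {
    # structured phase, backward time t in [0, T]; sizes nu_i(T - t)
    nu1_lo <- .nu_min(hist$nu1, T)
    nu2_lo <- if (two_pop) .nu_min(hist$nu2, T) else Inf
    m12 <- if (two_pop) hist$m12 else 0
    m21 <- if (two_pop) hist$m21 else 0
    while (length(d1) > 1L && t < T) {
      k1 <- sum(pop == 1L); k2 <- length(pop) - k1
      rmax <- k1 * (k1 - 1) / 2 / nu1_lo + k2 * (k2 - 1) / 2 / nu2_lo +
        k1 * m12 + k2 * m21
      if (rmax <= 0) break
      t_next <- t + rexp(1L, rmax)
      if (t_next >= T) break
      t <- t_next
      tau <- T - t
      rc1 <- k1 * (k1 - 1) / 2 / hist$nu1(tau)
      rc2 <- if (two_pop) k2 * (k2 - 1) / 2 / hist$nu2(tau) else 0
      rm1 <- k1 * m12
      rm2 <- k2 * m21
      u <- runif(1L) * rmax
      if (u < rc1) {
        coalesce(sample(which(pop == 1L), 2L), t)
      } else if (u < rc1 + rc2) {
        coalesce(sample(which(pop == 2L), 2L), t)
      } else if (u < rc1 + rc2 + rm1) {
        i <- which(pop == 1L); i <- if (length(i) > 1L) sample(i, 1L) else i
        pop[i] <- 2L
      } else if (u < rc1 + rc2 + rm1 + rm2) {
        i <- which(pop == 2L); i <- if (length(i) > 1L) sample(i, 1L) else i
        pop[i] <- 1L
      }  # else: thinning rejection, no event
    }
    if (length(d1) > 1L) t <- T  # phase boundary; exponentials are memoryless
  }
  # ancestral panmictic phase at the ancestral size (nu = 1)
  while (length(d1) > 1L) {
    k <- length(d1)
    t <- t + rexp(1L, k * (k - 1) / 2)
    coalesce(sample.int(k, 2L), t)
  }
  L
}

#' Anscombe Poisson residuals between a model and data spectrum
#'
#' Variance-stabilised residuals `1.5 * (d^(2/3) - (m^(2/3) -
#' m^(-1/3)/9)) / m^(1/6)` for data count d and model expectation m,
#' approximately standard normal when the data are Poisson around the
#' model.  Masked cells are excluded.
#'
#' @param model expected [afs]; unmasked entries must be positive.
#' @param data observed (or competing expected) [afs], same shape.
#' @return Numeric vector of residuals over unmasked cells.
#' @examples
#' anscombe_residuals(afs(c(0, 1, 1, 0), 3), afs(c(0, 0, 2, 0), 3, "observed"))
#' @export
anscombe_residuals <- function(model, data) {
  stopifnot(inherits(model, "afs"), inherits(data, "afs"))
  if (!identical(dim(as.matrix(model$entries)), dim(as.matrix(data$entries))))
    stop("model and data spectra differ in shape")
  keep <- !(model$mask | data$mask)
  m <- model$entries[keep]
  d <- data$entries[keep]
  if (any(m <= 0)) stop("model expectations must be positive on unmasked cells")
  1.5 * (d^(2 / 3) - (m^(2 / 3) - m^(-1 / 3) / 9)) / m^(1 / 6)
}
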