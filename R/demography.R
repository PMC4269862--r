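#' Demographic model specifications
#'
#' The study's seven models.  One population: `SNM1` (constant size),
#' `POSG` (exponential growth), `NEGG` (exponential decline, "negative
#' growth"), `BG` (instantaneous bottleneck followed by exponential
#' growth).  Two populations: `SNM2` (panmixia, no divergence), `ISO`
#' (split with complete isolation), `IM` (split with continuous
#' migration).  Parameters: `theta = 4 N_A mu L` scales the expected SNP
#' count; sizes `eta_*`, `s` are relative to the ancestral size `N_A`;
#' times `T` are in units of `2 N_A` generations; migration rates `m_ij =
#' 2 N_A M_ij` count migrants into population i from population j.
#'
#' All parameters are strictly positive and are optimised on a log scale
#' within the bounds stored on the model.
#'
#' @param name one of `"SNM1"`, `"POSG"`, `"NEGG"`, `"BG"`, `"SNM2"`,
#'   `"ISO"`, `"IM"`.
#' @param lower,upper optional named vectors overriding individual
#'   optimisation bounds (e.g. relaxing the lower bound on `T` when
#'   fitting extremely recent splits).
#' @return A list of class `"demog_model"` with elements `name`, `n_pops`,
#'   `param_names`, `K`, `lower`, `upper`, `start`.
#' @examples
#' demographic_model("NEGG")$param_names
#' demographic_model("ISO", lower = c(T = 0.001))
#' @export
demographic_model <- function(name, lower = NULL, upper = NULL) {
  specs <- list(
    SNM1 = list(n_pops = 1L, params = "theta"),
    POSG = list(n_pops = 1L, params = c("theta", "eta_G", "T")),
    NEGG = list(n_pops = 1L, params = c("theta", "eta_D", "T")),
    BG   = list(n_pops = 1L, params = c("theta", "eta_D", "eta_G", "T")),
    SNM2 = list(n_pops = 2L, params = "theta"),
    ISO  = list(n_pops = 2L, params = c("theta", "s", "eta_1", "eta_2", "T")),
    IM   = list(n_pops = 2L, params = c("theta", "s", "eta_1", "eta_2", "T",
                                        "m_12", "m_21"))
  )
  if (!name %in% names(specs)) stop("unknown demographic model: ", name)
  sp <- specs[[name]]
  one_pop <- sp$n_pops == 1L
  bound_of <- function(p, side) {
    switch(p,
      theta = c(1e2, 1e6),
      eta_D = c(0.001, 1),
      eta_G = c(1, 100),
      s     = c(0.01, 0.99),
      eta_1 = , eta_2 = c(0.5, 10),
      T     = if (one_pop) c(0.01, 5) else c(0.005, 5),
      m_12  = , m_21 = c(0.1, 20)
    )[side]
  }
  lo <- vapply(sp$params, bound_of, numeric(1), side = 1L)
  hi <- vapply(sp$params, bound_of, numeric(1), side = 2L)
  names(lo) <- names(hi) <- sp$params
  for (p in names(lower)) {
    if (!p %in% sp$params) stop("no parameter ", p, " in model ", name)
    lo[p] <- lower[p]
  }
  for (p in names(upper)) {
    if (!p %in% sp$params) stop("no parameter ", p, " in model ", name)
    hi[p] <- upper[p]
  }
  if (any(lo <= 0)) stop("bounds must be strictly positive (log-scale optimisation)")
  if (any(hi <= lo)) stop("upper bounds must exceed lower bounds")
  # default starts: geometric mid-range, except the conventional s = 0.25
  # starting point; theta is re-initialised from the data by optimal scaling
  start <- sqrt(lo * hi)
  if ("s" %in% sp$params) start["s"] <- 0.25
  if ("theta" %in% sp$params) start["theta"] <- 1e4
  structure(list(name = name, n_pops = sp$n_pops, param_names = sp$params,
                 K = length(sp$params), lower = lo, upper = hi,
                 start = start),
            class = "demog_model")
}

#' Built-in study parameterizations
#'
#' The simulation study's parameter presets: `"A"` (ancient events,
#' T = 0.25), `"B"` (recent events, T = 0.025; asymmetric migration for
#' IM), `"extreme-old"` (one-population A models pushed to T = 1.5) and
#' `"extreme-recent"` (two-population splits at T = 0.005).  Per-model
#' theta values are set so models yield roughly equal SNP totals
#' (~50,000 SNPs for samples of 100 chromosomes under A).
#'
#' @param name model name as in [demographic_model()].
#' @param label parameterization label.
#' @return Named numeric vector of parameter values.
#' @examples
#' model_params("NEGG", "A")
#' @export
model_params <- function(name, label = c("A", "B", "extreme-old", "extreme-recent")) {
  label <- match.arg(label)
  tab <- .preset_table()
  key <- paste(name, label, sep = ".")
  if (!key %in% names(tab))
    stop("no ", label, " parameterization for model ", name)
  tab[[key]]
}

.preset_table <- function() {
  list(
    SNM1.A = c(theta = 10000),
    SNM1.B = c(theta = 10000),
    POSG.A = c(theta = 6000, eta_G = 5, T = 0.25),
    POSG.B = c(theta = 6000, eta_G = 2.5, T = 0.025),
    NEGG.A = c(theta = 29000, eta_D = 0.1, T = 0.25),
    NEGG.B = c(theta = 29000, eta_D = 0.25, T = 0.025),
    BG.A = c(theta = 10000, eta_D = 0.1, eta_G = 5, T = 0.25),
    BG.B = c(theta = 10000, eta_D = 0.25, eta_G = 2.5, T = 0.025),
    SNM2.A = c(theta = 10000),
    SNM2.B = c(theta = 10000),
    ISO.A = c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1, T = 0.25),
    ISO.B = c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1, T = 0.025),
    IM.A = c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1, T = 0.25,
             m_12 = 1, m_21 = 1),
    IM.B = c(theta = 7250, s = 0.5, eta_1 = 1, eta_2 = 1, T = 0.025,
             m_12 = 10, m_21 = 1),
    `SNM1.extreme-old` = c(theta = 10000),
    `POSG.extreme-old` = c(theta = 6000, eta_G = 5, T = 1.5),
    `NEGG.extreme-old` = c(theta = 29000, eta_D = 0.1, T = 1.5),
    `BG.extreme-old` = c(theta = 10000, eta_D = 0.1, eta_G = 5, T = 1.5),
    `SNM2.extreme-recent` = c(theta = 10000),
    `ISO.extreme-recent` = c(theta = 10000, s = 0.5, eta_1 = 1, eta_2 = 1,
                             T = 0.005),
    `IM.extreme-recent` = c(theta = 10000, s = 0.5, eta_1 = 1, eta_2 = 1,
                            T = 0.005, m_12 = 1, m_21 = 1)
  )
}

#' All (model, parameter) presets for a parameterization label
#'
#' @param label as in [model_params()].
#' @return Named list; each element holds `model` (a `demog_model`) and
#'   `params` (its preset values).
#' @export
model_catalog <- function(label = c("A", "B", "extreme-old", "extreme-recent")) {
  label <- match.arg(label)
  tab <- .preset_table()
  keys <- names(tab)[endsWith(names(tab), paste0(".", label))]
  out <- lapply(keys, function(k) {
    nm <- sub("\\..*$", "", k)
    list(model = demographic_model(nm), params = tab[[k]])
  })
  names(out) <- sub("\\..*$", "", keys)
  out
}

#' Relative population-size trajectories
#'
#' Returns the relative effective size nu(tau) (units of the ancestral
#' size) over diffusion time tau in `[0, T]` measured forward from the
#' onset of the event (size change or split).  One-population models
#' return a single function; two-population models return a list with one
#' function per daughter population.  `SNM1`/`SNM2` have no event and
#' return the constant function 1.
#'
#' @param model a [demographic_model()] object or model name.
#' @param params named parameter vector.
#' @return A vectorised function, or a list of two for two populations.
#' @examples
#' size_trajectory("POSG", c(theta = 6000, eta_G = 5, T = 0.25))(0.125)
#' @export
size_trajectory <- function(model, params) {
  if (is.character(model)) model <- demographic_model(model)
  h <- .history(model, params)
  if (model$n_pops == 1L) h$nu1 else list(h$nu1, h$nu2)
}

# Internal canonical event description consumed by both engines.
.history <- function(model, params) {
  if (is.character(model)) model <- demographic_model(model)
  p <- params[model$param_names]
  if (any(is.na(p))) stop("missing parameters: ",
                          paste(model$param_names[is.na(p)], collapse = ", "))
  if (any(p <= 0)) stop("all parameters must be strictly positive")
  expo <- function(from, to, T) {
    force(from); force(to); force(T)
    function(tau) from * (to / from)^(tau / T)
  }
  const1 <- function(tau) rep(1, length(tau))
  h <- switch(model$name,
    SNM1 = list(T = 0, nu1 = const1),
    POSG = list(T = p[["T"]], nu1 = expo(1, p[["eta_G"]], p[["T"]])),
    NEGG = list(T = p[["T"]], nu1 = expo(1, p[["eta_D"]], p[["T"]])),
    BG   = list(T = p[["T"]],
                nu1 = expo(p[["eta_D"]], p[["eta_G"]], p[["T"]])),
    SNM2 = list(T = 0, nu1 = const1, nu2 = const1, m12 = 0, m21 = 0),
    ISO  = list(T = p[["T"]],
                nu1 = expo(p[["s"]], p[["eta_1"]], p[["T"]]),
                nu2 = expo(1 - p[["s"]], p[["eta_2"]], p[["T"]]),
                m12 = 0, m21 = 0),
    IM   = list(T = p[["T"]],
                nu1 = expo(p[["s"]], p[["eta_1"]], p[["T"]]),
                nu2 = expo(1 - p[["s"]], p[["eta_2"]], p[["T"]]),
                m12 = p[["m_12"]], m21 = p[["m_21"]])
  )
  if (model$name %in% c("ISO", "IM") && p[["s"]] >= 1)
    stop("founding fraction s must lie in (0, 1)")
  h$theta <- p[["theta"]]
  h$n_pops <- model$n_pops
  h
}
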