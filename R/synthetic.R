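#' Poisson replicate dataset from an expected spectrum
#'
#' Draws each unmasked cell independently as Poisson around the expected
#' value — the study's data-generating mechanism for independent,
#' unlinked, polarised biallelic SNPs.  The mask is preserved and masked
#' cells are zeroed.
#'
#' @param expected an [afs] of kind `"expected"`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An [afs] of kind `"observed"`.
#' @export
poisson_sample_afs <- function(expected, seed) {
  stopifnot(inherits(expected, "afs"))
  if (expected$kind != "expected")
    stop("poisson_sample_afs needs an expected-kind spectrum")
  set.seed(seed)
  entries <- expected$entries
  keep <- !expected$mask
  entries[keep] <- rpois(sum(keep), expected$entries[keep])
  entries[!keep] <- 0
  afs(entries, expected$sample_sizes, kind = "observed",
      mask = expected$mask, pop_labels = expected$pop_labels)
}

#' Deterministic replicate seed
#'
#' Stable 31-bit hash of the base seed and the replicate's design
#' coordinates, recorded with every replicate so any run can be
#' reproduced in isolation.
#'
#' @param base_seed integer base seed of the study.
#' @param ... design coordinates (model name, parameterization, sample
#'   size, replicate index, ...).
#' @return A positive integer below 2^31.
#' @export
replicate_seed <- function(base_seed, ...) {
  key <- paste(c(base_seed, ...), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Factorial study design
#'
#' The full design crosses models with parameterizations and sample
#' sizes: one-population models at 2, 3, 5, 10, 20, 30 and 50 diploids,
#' two-population models at 1, 2, 3, 5, 10, 20 and 30 diploids per
#' population, 100 replicates per cell (9800 replicates in all).  Reduced
#' designs scale these down.
#'
#' @param models character vector of model names (default: all seven).
#' @param labels parameterization labels.
#' @param sizes_1pop,sizes_2pop diploid sample sizes per configuration.
#' @param reps replicates per design cell.
#' @param base_seed integer base seed.
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(models = c("SNM1", "POSG", "NEGG", "BG",
                                    "SNM2", "ISO", "IM"),
                         labels = c("A", "B"),
                         sizes_1pop = c(2, 3, 5, 10, 20, 30, 50),
                         sizes_2pop = c(1, 2, 3, 5, 10, 20, 30),
                         reps = 100L, base_seed = 1L) {
  if (reps < 1) stop("need at least one replicate per cell")
  if (any(c(sizes_1pop, sizes_2pop) < 1)) stop("sample sizes must be positive")
  structure(list(models = models, labels = labels, sizes_1pop = sizes_1pop,
                 sizes_2pop = sizes_2pop, reps = as.integer(reps),
                 base_seed = as.integer(base_seed)),
            class = "study_design")
}

#' Enumerate a study design into replicate records
#'
#' Deterministically expands a design into one row per replicate with its
#' derived seed.  Data are not simulated here; [run_cell()] realises a
#' cell from the same seeds.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `cell`, `model`, `label`, `n`, `rep`,
#'   `seed`.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  for (m in design$models) {
    np <- demographic_model(m)$n_pops
    sizes <- if (np == 1L) design$sizes_1pop else design$sizes_2pop
    for (lab in design$labels) {
      for (n in sizes) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = paste(m, lab, n, sep = "_"), model = m, label = lab,
          n = n, rep = seq_len(design$reps),
          seed = vapply(seq_len(design$reps), function(r)
            replicate_seed(design$base_seed, m, lab, n, r), integer(1)))
      }
    }
  }
  do.call(rbind, rows)
}
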