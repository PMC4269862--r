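# Small shared fixtures and settings used across test files.

# optimizer settings for quick, deterministic test fits
fast_settings <- function(max_attempts = 10L, fold = 1, maxit = 60L) {
  optimizer_settings(max_attempts = max_attempts, fold = fold, maxit = maxit)
}

# a tiny deterministic observed spectrum: [masked, 3, 2, 1, masked]
tiny_obs <- function() afs(c(0, 3, 2, 1, 0), sample_sizes = 4, kind = "observed")

# one-cell spectra for likelihood arithmetic: a single unmasked cell
one_cell <- function(value, kind = "observed") {
  afs(c(0, value, 0), sample_sizes = 2, kind = kind)
}

# closed-form constant-size expectation E[xi_i] = theta / i
snm_closed_form <- function(theta, n_chrom) theta / seq_len(n_chrom - 1)
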