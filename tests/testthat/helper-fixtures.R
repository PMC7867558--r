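# Shared fixtures. Short synthetic recordings keep the suite fast; the
# spectral estimates at these durations are coarser than at the full five
# minutes but every property tested is duration-invariant.

short_spec <- function(duration_s = 20, ...) {
  cohort_spec(duration_s = duration_s, ...)
}

# Brute-force two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of |d| (tie-free inputs only). Independent of the package's
# signed_rank machinery: recomputes the statistic from scratch per pattern.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# A deterministic random band-power-like spectrum for oracle tests.
random_spectrum <- function(n_ch = 4, seed = 1) {
  set.seed(seed)
  freq <- seq(0, 250, by = 0.5)
  psd <- matrix(stats::rexp(n_ch * length(freq)), n_ch)
  structure(list(freq = freq, psd = psd,
                 labels = paste0("ch", seq_len(n_ch)),
                 n_epochs = 1L, fs = 500),
            class = "eeg_spectrum")
}

sinusoid_recording <- function(freqs, amps = rep(1, length(freqs)),
                               fs = 500, duration_s = 30, n_ch = 2,
                               labels = paste0("ch", seq_len(n_ch))) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- colSums(matrix(amps, length(freqs), length(t)) *
                 sin(outer(2 * pi * freqs, t)))
  if (length(freqs) == 1) x <- amps[1] * sin(2 * pi * freqs * t)
  recording(matrix(rep(x, n_ch), n_ch, byrow = TRUE), fs, labels)
}
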