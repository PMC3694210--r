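# Independent oracles shared by unit and acceptance tests. Written from
# first principles (explicit DFT sums, explicit triangle weights), not via
# the package internals.

# Independent MFSC oracle: explicit DFT sums and triangular mel weights.
oracle_mfsc_frame <- function(wave, sr, center, n_mel = 20, window = 0.025) {
  n_win <- round(window * sr)
  half <- (n_win - 1) / 2
  idx <- round(center * sr + 0.5 - half) + 0:(n_win - 1)
  # symmetric reflection
  n <- length(wave)
  ridx <- vapply(idx, function(i) {
    j <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)
    if (j < n) j + 1 else 2 * n - j
  }, numeric(1))
  seg <- wave[ridx] * (0.54 - 0.46 * cos(2 * pi * (0:(n_win - 1)) / (n_win - 1)))
  n_fft <- 2^ceiling(log2(n_win))
  seg <- c(seg, numeric(n_fft - n_win))
  k <- 0:(n_fft / 2)
  spec <- vapply(k, function(kk) {
    Mod(sum(seg * exp(-2i * pi * kk * (0:(n_fft - 1)) / n_fft)))
  }, numeric(1))
  f_bins <- k * sr / n_fft
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(0, mel(sr / 2), length.out = n_mel + 2))
  vapply(seq_len(n_mel), function(m) {
    w <- pmax(0, pmin((f_bins - edges[m]) / (edges[m + 1] - edges[m]),
                      (edges[m + 2] - f_bins) / (edges[m + 2] - edges[m + 1])))
    log(max(sum(w * spec), 1e-10))
  }, numeric(1))
}

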