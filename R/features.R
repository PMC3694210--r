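# Phone-synchronous feature extraction. Each segmented phone yields exactly
# 10 analysis frames uniformly distributed over its duration ("dynamic
# shift"), so every phone gets a balanced acoustic description regardless of
# its length: a 10 x 60 MFSC block (20 static mel log-spectra + 20 first +
# 20 second derivatives) and, when coil data exist, a 10 x 42 articulatory
# block (14 smoothed positions + velocities + accelerations) on the same
# analysis windows.

N_FRAMES <- 10L
WINDOW_S <- 0.025
N_MEL <- 20L
SMOOTH_S <- 0.015
LOG_FLOOR <- 1e-10

#' Phone-synchronous analysis-window centers
#'
#' Places `n_frames` window centers uniformly over a phone interval: the
#' first center at `start + window/2`, the last at `end - window/2`, so the
#' inter-frame shift is `(duration - window) / (n_frames - 1)`. When the
#' phone is shorter than one window all centers collapse to the midpoint
#' (shift 0) and the windows extend into the surrounding utterance.
#'
#' @param interval numeric length-2, `(start, end)` in seconds, `end > start`.
#' @param n_frames number of frames (default 10).
#' @param window analysis window length in seconds (default 0.025).
#' @return list with `centers` (length `n_frames`) and `shift` (seconds).
#' @export
window_centers <- function(interval, n_frames = N_FRAMES, window = WINDOW_S) {
  start <- interval[1]; end <- interval[2]
  if (!(end > start)) stop("interval must have positive duration")
  dur <- end - start
  if (dur < window) {
    mid <- (start + end) / 2
    return(list(centers = rep(mid, n_frames), shift = 0))
  }
  shift <- (dur - window) / (n_frames - 1)
  centers <- start + window / 2 + shift * (seq_len(n_frames) - 1)
  list(centers = centers, shift = shift)
}

# HTK-style mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mel filters spanning 0..Nyquist, returned as
# an (n_fft/2 + 1) x n_mel weight matrix over DFT bin frequencies.
mel_filterbank <- function(n_mel, n_fft, sample_rate) {
  n_bins <- n_fft %/% 2 + 1L
  f_bins <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(0, hz_to_mel(sample_rate / 2),
                         length.out = n_mel + 2))
  fb <- matrix(0, n_bins, n_mel)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f_bins - lo) / (ce - lo)
    down <- (hi - f_bins) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Finite differences across the 10 phone-synchronous frames using the actual
# inter-frame time shift: two-point slope at the block edges, centered
# differences inside; identically zero when the shift is zero.
dynamic_derivative <- function(block, shift) {
  n <- nrow(block)
  if (shift == 0) return(matrix(0, n, ncol(block)))
  d <- matrix(0, n, ncol(block))
  d[1, ] <- (block[2, ] - block[1, ]) / shift
  d[n, ] <- (block[n, ] - block[n - 1, ]) / shift
  if (n > 2) {
    idx <- 2:(n - 1)
    d[idx, ] <- (block[idx + 1, , drop = FALSE] -
                   block[idx - 1, , drop = FALSE]) / (2 * shift)
  }
  d
}

# Index a signal with symmetric reflection at both edges.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- ((idx - 1L) %% period + period) %% period   # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

#' Extract a 10 x 60 MFSC block for one phone
#'
#' Per frame: Hamming-windowed 25 ms segment (symmetric-reflection padding at
#' the utterance edges), magnitude spectrum, 20 triangular HTK-mel filterbank
#' channels spanning 0-Nyquist, log energies floored at 1e-10. First and
#' second derivatives are taken across the 10 frames with the actual dynamic
#' shift (see [window_centers()]).
#'
#' @param wave numeric waveform of the whole utterance.
#' @param sample_rate audio sampling rate in Hz.
#' @param centers frame-center times from [window_centers()] (list or numeric
#'   vector; a list also supplies the shift, otherwise it is inferred).
#' @param window window length in seconds.
#' @return list of class `acoustic_block`: `values` (10 x 60), `centers`,
#'   `shift`. Columns 1-20 static, 21-40 first derivative, 41-60 second.
#' @export
extract_mfsc_block <- function(wave, sample_rate, centers,
                               window = WINDOW_S) {
  if (length(wave) == 0) stop("empty waveform")
  if (is.list(centers)) {
    shift <- centers$shift
    centers <- centers$centers
  } else {
    shift <- if (length(centers) > 1) centers[2] - centers[1] else 0
  }
  n_win <- max(2L, round(window * sample_rate))
  half <- (n_win - 1) / 2
  n_fft <- 2^ceiling(log2(n_win))
  fb <- mel_filterbank(N_MEL, n_fft, sample_rate)
  ham <- hamming_window(n_win)
  static <- matrix(0, length(centers), N_MEL)
  for (i in seq_along(centers)) {
    c_samp <- centers[i] * sample_rate + 0.5   # 1-based center sample
    idx <- round(c_samp - half) + 0:(n_win - 1)
    if (min(idx) < -length(wave) || max(idx) > 2 * length(wave))
      stop("frame ", i, " lies outside the utterance")
    seg <- wave[reflect_index(idx, length(wave))] * ham
    spec <- Mod(stats::fft(c(seg, numeric(n_fft - n_win))))
    energy <- drop(t(fb) %*% spec[seq_len(n_fft %/% 2 + 1L)])
    static[i, ] <- log(pmax(energy, LOG_FLOOR))
  }
  d1 <- dynamic_derivative(static, shift)
  d2 <- dynamic_derivative(d1, shift)
  structure(list(values = cbind(static, d1, d2), centers = centers,
                 shift = shift),
            class = "acoustic_block")
}

# Centered moving average with an odd window, edges padded by replication.
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1) %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2)[(half + 1):(half + length(x))])
}

#' Extract a 10 x 42 articulatory block for one phone
#'
#' The 200 Hz coil trajectories are smoothed with a 15 ms moving average;
#' velocities and accelerations are centered differences at the trajectory
#' rate (edges by replication). Each of the 42 streams is then averaged
#' within each 25 ms analysis window — the same windows used for the MFSCs —
#' giving a 10 x 42 block. Columns 1-14 positions, 15-28 velocities, 29-42
#' accelerations (coil order tongue tip, blade, dorsum, upper lip, lower lip,
#' upper teeth, lower teeth; x before y).
#'
#' @param coils T x 14 matrix of coil coordinates sampled at `rate` Hz.
#' @param centers frame centers from [window_centers()] (list or numeric).
#' @param rate trajectory sampling rate (default 200 Hz).
#' @param window averaging window in seconds (default 0.025).
#' @return list of class `articulatory_block`: `values` (10 x 42), `centers`.
#' @export
extract_af_block <- function(coils, centers, rate = EMA_RATE,
                             window = WINDOW_S) {
  if (is.list(centers)) centers <- centers$centers
  coils <- as.matrix(coils)
  k <- max(1L, 2L * (round(SMOOTH_S * rate) %/% 2L) + 1L)   # odd, ~15 ms
  if (nrow(coils) < 2L) stop("trajectory shorter than one window")
  smoothed <- apply(coils, 2, moving_average, k = k)
  vel <- apply(smoothed, 2, centered_difference, dt = 1 / rate)
  acc <- apply(vel, 2, centered_difference, dt = 1 / rate)
  streams <- cbind(smoothed, vel, acc)
  t_samp <- (seq_len(nrow(coils)) - 0.5) / rate
  out <- matrix(0, length(centers), ncol(streams))
  half <- window / 2
  for (i in seq_along(centers)) {
    sel <- which(t_samp >= centers[i] - half & t_samp <= centers[i] + half)
    if (length(sel) == 0)      # very short trajectories: nearest sample
      sel <- which.min(abs(t_samp - centers[i]))
    out[i, ] <- colMeans(streams[sel, , drop = FALSE])
  }
  structure(list(values = out, centers = centers),
            class = "articulatory_block")
}

# Centered first difference with replicated edges (two-point slope there).
centered_difference <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Tokenize a corpus into segmented phones with feature blocks
#'
#' One token per segmented phone: always a 10 x 60 acoustic block, plus a
#' 10 x 42 articulatory block when the utterance carries coil trajectories.
#'
#' @param corpus an `artimap_corpus`.
#' @return list of class `artimap_tokens`; each token holds `subject`,
#'   `word_type`, `repetition`, `phone`, `position` (index in the word),
#'   `start`, `end`, `acoustic` (10 x 60), `articulatory` (10 x 42 or NULL),
#'   `shift`.
#' @export
tokenize <- function(corpus) {
  stopifnot(inherits(corpus, "artimap_corpus"))
  tokens <- list()
  k <- 0L
  for (u in corpus$utterances) {
    seg <- u$segmentation
    for (p in seq_len(nrow(seg))) {
      wc <- window_centers(c(seg$start[p], seg$end[p]))
      ab <- extract_mfsc_block(u$wave, corpus$audio_rate, wc)
      afb <- if (!is.null(u$coils)) extract_af_block(u$coils, wc) else NULL
      k <- k + 1L
      tokens[[k]] <- list(
        subject = u$subject, word_type = u$word_type,
        repetition = u$repetition, phone = seg$phone[p], position = p,
        start = seg$start[p], end = seg$end[p],
        acoustic = ab$values,
        articulatory = if (is.null(afb)) NULL else afb$values,
        shift = wc$shift)
    }
  }
  structure(tokens, class = "artimap_tokens")
}

#' Summary table of a token set
#'
#' @param tokens an `artimap_tokens` list.
#' @return data frame with one row per token (subject, word type, repetition,
#'   phone, position, interval, articulatory availability).
#' @export
token_info <- function(tokens) {
  data.frame(
    subject = vapply(tokens, `[[`, "", "subject"),
    word_type = vapply(tokens, `[[`, "", "word_type"),
    repetition = vapply(tokens, `[[`, 0, "repetition"),
    phone = vapply(tokens, `[[`, "", "phone"),
    position = vapply(tokens, `[[`, 0, "position"),
    start = vapply(tokens, `[[`, 0, "start"),
    end = vapply(tokens, `[[`, 0, "end"),
    has_articulatory = vapply(tokens, function(t) !is.null(t$articulatory),
                              logical(1)),
    stringsAsFactors = FALSE)
}

#' Write per-utterance feature tables
#'
#' One tab-delimited file per utterance with token id, phone, and the 600
#' acoustic (+ 420 articulatory, when present) values; column order is 20
#' static, 20 delta, 20 delta-delta per frame for acoustics, and positions /
#' velocities / accelerations (coils tongue tip, blade, dorsum, upper lip,
#' lower lip, upper teeth, lower teeth; x before y) for the articulatory
#' part.
#'
#' @param tokens an `artimap_tokens` list.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_token_features <- function(tokens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- token_info(tokens)
  utt <- interaction(info$subject, info$word_type, info$repetition, drop = TRUE)
  for (lev in levels(utt)) {
    rows <- which(utt == lev)
    mats <- lapply(rows, function(k) {
      t_ <- tokens[[k]]
      v <- as.vector(t(t_$acoustic))
      if (!is.null(t_$articulatory)) v <- c(v, as.vector(t(t_$articulatory)))
      v
    })
    wide <- do.call(rbind, mats)
    df <- cbind(data.frame(token = rows, phone = info$phone[rows]),
                as.data.frame(wide))
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_]", "_", lev), ".tsv"))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
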