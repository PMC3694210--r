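# Synthetic paired audio + articulatory corpus generator. All subjects share
# one articulatory latent (the inventory's phone targets); each subject
# renders it acoustically through her own resonance map (source-filter
# synthesis), which is exactly the inter-speaker variability the
# normalization strategies must remove.

EMA_RATE <- 200          # articulograph sampling rate, Hz
RAMP_S <- 0.030          # cosine transition between phone targets, seconds
RESONANCE_BW <- c(80, 120, 160)        # resonator bandwidths, Hz
RESONANCE_LO <- c(250, 850, 2400)      # control-value-0 frequencies, Hz
RESONANCE_HI <- c(850, 2400, 3400)     # control-value-1 frequencies, Hz

#' Generate a multi-speaker paired audio/EMA corpus
#'
#' Every subject utters every word type exactly `repetitions` times. Coil
#' trajectories are the inventory's per-phone articulatory targets, perturbed
#' per repetition by the subject's coherence noise and joined by 30 ms cosine
#' ramps. The waveform is a source-filter rendering: an impulse train at the
#' subject's fundamental frequency filtered by three time-varying resonators
#' whose frequencies are the subject's sigmoidal map applied to the
#' instantaneous articulatory state. Generation is a pure function of its
#' arguments: identical inputs and seed give identical corpora.
#'
#' @param inventory a [phone_inventory()].
#' @param subjects list of [subject_profile()]s.
#' @param word_types list of [word_type()]s; all symbols must be in the
#'   inventory.
#' @param repetitions repetitions per word type per subject (>= 1).
#' @param seed integer RNG seed for the whole corpus.
#' @param audio_rate audio sampling rate in Hz (default 16000).
#' @return an `artimap_corpus`: list with `utterances` (list of utterance
#'   records: subject, word_type, repetition, wave, coils (T x 14 at 200 Hz),
#'   segmentation data frame with half-open `[start, end)` intervals),
#'   `manifest` data frame, `inventory`, `subjects`, `word_types`,
#'   `audio_rate`.
#' @export
generate_corpus <- function(inventory, subjects, word_types, repetitions,
                            seed, audio_rate = 16000) {
  stopifnot(inherits(inventory, "phone_inventory"))
  if (repetitions < 1) stop("repetitions must be >= 1")
  for (wt in word_types) {
    bad <- setdiff(wt$phones, inventory$symbols)
    if (length(bad))
      stop("word type ", wt$id, " uses unknown phone symbol(s): ",
           paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  utterances <- list()
  rows <- list()
  k <- 0L
  for (sub in subjects) {
    for (wt in word_types) {
      for (rep_i in seq_len(repetitions)) {
        utt <- synthesize_utterance(inventory, sub, wt, rep_i, audio_rate)
        k <- k + 1L
        utterances[[k]] <- utt
        rows[[k]] <- data.frame(
          subject = sub$id, word_type = wt$id, repetition = rep_i,
          intonation = wt$intonation, n_phones = length(wt$phones),
          duration = utt$duration, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(
    list(utterances = utterances, manifest = manifest, inventory = inventory,
         subjects = subjects, word_types = word_types,
         audio_rate = audio_rate, seed = as.integer(seed)),
    class = "artimap_corpus")
}

#' @export
print.artimap_corpus <- function(x, ...) {
  cat(sprintf(
    "<artimap_corpus> %d utterances: %d subjects x %d word types, %.0f Hz audio\n",
    nrow(x$manifest), length(unique(x$manifest$subject)),
    length(unique(x$manifest$word_type)), x$audio_rate))
  invisible(x)
}

# One utterance: durations -> articulatory trajectory -> waveform.
# Consumes RNG in a fixed order (duration jitter, then coherence noise).
synthesize_utterance <- function(inventory, subject, wt, rep_i, audio_rate) {
  phones <- wt$phones
  mu <- unname(inventory$mean_duration[phones])
  jit <- inventory$duration_jitter
  durs <- mu * (1 + jit * stats::runif(length(phones), -1, 1))
  # per-repetition articulatory targets: shared latent + coherence noise
  tgt <- inventory$targets[phones, , drop = FALSE] +
    subject$coherence * matrix(stats::rnorm(length(phones) * 14),
                               nrow = length(phones))
  ends <- cumsum(durs)
  duration <- ends[length(ends)]
  starts <- c(0, ends[-length(ends)])
  n_coil <- max(2L, round(duration * EMA_RATE))
  t_coil <- (seq_len(n_coil) - 0.5) / EMA_RATE
  coils <- trajectory_from_targets(tgt, starts, ends, t_coil)
  colnames(coils) <- coil_coordinate_names()
  wave <- render_waveform(coils, subject, audio_rate, duration)
  seg <- data.frame(phone = phones, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  list(subject = subject$id, word_type = wt$id, repetition = rep_i,
       wave = wave, coils = coils, segmentation = seg,
       duration = duration)
}

# Piecewise-constant targets joined by cosine half-ramps of RAMP_S seconds
# centred on each internal boundary; first/last targets are held at the ends.
trajectory_from_targets <- function(tgt, starts, ends, t_coil) {
  n_seg <- nrow(tgt)
  out <- matrix(0, nrow = length(t_coil), ncol = 14L)
  seg_idx <- findInterval(t_coil, c(starts, ends[n_seg]),
                          rightmost.closed = TRUE)
  seg_idx <- pmin(pmax(seg_idx, 1L), n_seg)
  out <- tgt[seg_idx, , drop = FALSE]
  if (n_seg > 1) {
    half <- RAMP_S / 2
    for (b in seq_len(n_seg - 1)) {
      tb <- ends[b]
      in_ramp <- which(t_coil > tb - half & t_coil < tb + half)
      if (length(in_ramp)) {
        w <- 0.5 * (1 - cos(pi * (t_coil[in_ramp] - (tb - half)) / RAMP_S))
        out[in_ramp, ] <- (1 - w) %o% tgt[b, ] + w %o% tgt[b + 1, ]
      }
    }
  }
  out
}

# Map the instantaneous articulatory state to the 3 resonance frequencies of
# a subject: sigmoid(affine) control values into per-resonance ranges, scaled
# by the subject's vocal-tract-length factor.
resonances_from_state <- function(coils, subject) {
  u <- 1 / (1 + exp(-(coils %*% t(subject$map_weights) +
                        rep(1, nrow(coils)) %o% subject$map_bias)))
  sweep(sweep(u, 2, RESONANCE_HI - RESONANCE_LO, "*"), 2,
        RESONANCE_LO, "+") / subject$vtl_scale
}

# Source-filter synthesis: impulse train at f0 through a cascade of three
# two-pole resonators whose coefficients are updated every EMA frame
# (5 ms blocks), with filter state carried across blocks.
render_waveform <- function(coils, subject, audio_rate, duration) {
  n_samp <- max(1L, round(duration * audio_rate))
  period <- max(1L, round(audio_rate / subject$f0))
  excitation <- numeric(n_samp)
  excitation[seq(1L, n_samp, by = period)] <- 1
  freqs <- resonances_from_state(coils, subject)           # n_coil x 3
  r <- exp(-pi * RESONANCE_BW / audio_rate)
  block <- audio_rate / EMA_RATE                            # samples per frame
  n_blocks <- nrow(coils)
  y <- excitation
  for (j in 1:3) {
    out <- numeric(n_samp)
    state <- c(0, 0)
    theta <- 2 * pi * pmin(freqs[, j], 0.45 * audio_rate) / audio_rate
    a1 <- 2 * r[j] * cos(theta)
    a2 <- -r[j]^2
    for (bl in seq_len(n_blocks)) {
      i0 <- floor((bl - 1) * block) + 1L
      i1 <- min(n_samp, floor(bl * block))
      if (i0 > i1) next
      seg <- stats::filter(y[i0:i1], c(a1[bl], a2),
                           method = "recursive", init = state)
      out[i0:i1] <- seg
      state <- c(out[i1], if (i1 > 1) out[i1 - 1] else state[1])
      if (i1 >= n_samp) break
    }
    y <- out
  }
  peak <- max(abs(y))
  if (peak > 0) y <- 0.9 * y / peak
  y
}

#' Degrade one subject's articulatory coherence
#'
#' Adds white Gaussian noise with standard deviation `factor * 0.02`
#' articulatory units to the chosen subject's coil trajectories (audio
#' untouched), modeling degraded articulograph recordings.
#'
#' @param corpus an `artimap_corpus`.
#' @param subject_id subject whose coils are corrupted.
#' @param factor noise scale factor (>= 0; 0 leaves the corpus unchanged).
#' @param seed RNG seed for the noise.
#' @return the corpus with corrupted coil trajectories.
#' @export
corrupt_coherence <- function(corpus, subject_id, factor, seed) {
  stopifnot(inherits(corpus, "artimap_corpus"))
  if (factor < 0) stop("factor must be >= 0")
  ids <- vapply(corpus$subjects, `[[`, "", "id")
  if (!subject_id %in% ids) stop("unknown subject: ", subject_id)
  if (factor == 0) return(corpus)
  set.seed(as.integer(seed))
  sd_noise <- factor * 0.02
  for (k in seq_along(corpus$utterances)) {
    if (corpus$utterances[[k]]$subject != subject_id) next
    co <- corpus$utterances[[k]]$coils
    corpus$utterances[[k]]$coils <- co +
      matrix(stats::rnorm(length(co), sd = sd_noise), nrow = nrow(co))
  }
  corpus
}

#' Write a corpus to disk
#'
#' One WAV (PCM-16 mono), one tab-delimited coil-trajectory file (one row per
#' 200 Hz sample, 14 named columns) and one tab-delimited label file
#' (`start_s`, `end_s`, `phone`; half-open intervals) per utterance, plus a
#' `manifest.tsv` listing subject, word type, repetition and file paths.
#'
#' @param corpus an `artimap_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus$manifest
  man$wav <- man$coil_file <- man$label_file <- NA_character_
  for (k in seq_along(corpus$utterances)) {
    u <- corpus$utterances[[k]]
    stem <- sprintf("%s_%s_r%02d", u$subject, u$word_type, u$repetition)
    man$wav[k] <- paste0(stem, ".wav")
    man$coil_file[k] <- paste0(stem, "_ema.tsv")
    man$label_file[k] <- paste0(stem, "_lab.tsv")
    write_wav(u$wave, file.path(dir, man$wav[k]), corpus$audio_rate)
    utils::write.table(u$coils, file.path(dir, man$coil_file[k]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    lab <- data.frame(start_s = u$segmentation$start,
                      end_s = u$segmentation$end,
                      phone = u$segmentation$phone)
    utils::write.table(lab, file.path(dir, man$label_file[k]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir corpus directory containing `manifest.tsv`.
#' @return an `artimap_corpus` (without subject profiles or inventory
#'   metadata beyond what the files carry; audio is requantized 16-bit).
#' @export
read_corpus <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv in ", dir)
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  utterances <- vector("list", nrow(man))
  audio_rate <- NULL
  for (k in seq_len(nrow(man))) {
    for (f in c("wav", "coil_file", "label_file")) {
      if (!file.exists(file.path(dir, man[[f]][k])))
        stop("missing file for utterance ", man$subject[k], "/",
             man$word_type[k], " rep ", man$repetition[k], ": ", man[[f]][k])
    }
    wv <- read_wav(file.path(dir, man$wav[k]))
    audio_rate <- wv$sample_rate
    coils <- as.matrix(utils::read.table(
      file.path(dir, man$coil_file[k]), header = TRUE, sep = "\t"))
    lab <- utils::read.table(file.path(dir, man$label_file[k]),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    utterances[[k]] <- list(
      subject = man$subject[k], word_type = man$word_type[k],
      repetition = man$repetition[k], wave = wv$samples, coils = coils,
      segmentation = data.frame(phone = lab$phone, start = lab$start_s,
                                end = lab$end_s, stringsAsFactors = FALSE),
      duration = lab$end_s[nrow(lab)])
  }
  structure(list(utterances = utterances, manifest = man, inventory = NULL,
                 subjects = NULL, word_types = NULL, audio_rate = audio_rate,
                 seed = NA_integer_),
            class = "artimap_corpus")
}
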