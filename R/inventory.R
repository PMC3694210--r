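# Domain types for the synthetic paired audio/EMA corpus: the phone
# inventory (shared articulatory targets), subject profiles (speaker-specific
# articulatory-to-acoustic maps) and word types.

#' Phone inventory with articulatory targets
#'
#' An inventory assigns every phone label an articulatory target: the sagittal
#' x,y coordinates of 7 electromagnetic-articulography coils (tongue tip,
#' tongue blade, tongue dorsum, upper lip, lower lip, upper teeth, lower
#' teeth), 14 values in all, in arbitrary position units. Targets are the
#' shared articulatory latent of the generator: every subject realizes the
#' same target for the same phone, up to coherence noise.
#'
#' @param symbols character vector of unique phone labels.
#' @param targets numeric matrix, one row per phone, 14 columns
#'   (coil-major, x before y).
#' @param mean_duration numeric vector of per-phone mean durations in seconds
#'   (recycled if scalar).
#' @param duration_jitter fraction in `[0, 1)`: realized durations are drawn
#'   uniformly in `mean_duration * (1 +- duration_jitter)`.
#' @return an object of class `phone_inventory`.
#' @export
phone_inventory <- function(symbols, targets, mean_duration = 0.12,
                            duration_jitter = 0.1) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("phone symbols must be unique")
  targets <- as.matrix(targets)
  if (nrow(targets) != length(symbols) || ncol(targets) != 14L)
    stop("targets must be a ", length(symbols), " x 14 matrix")
  if (!all(is.finite(targets))) stop("targets must be finite")
  mean_duration <- rep_len(as.numeric(mean_duration), length(symbols))
  if (any(mean_duration <= 0)) stop("mean durations must be > 0")
  if (duration_jitter < 0 || duration_jitter >= 1)
    stop("duration_jitter must be in [0, 1)")
  rownames(targets) <- symbols
  colnames(targets) <- coil_coordinate_names()
  structure(
    list(symbols = symbols, targets = targets,
         mean_duration = stats::setNames(mean_duration, symbols),
         duration_jitter = duration_jitter),
    class = "phone_inventory")
}

#' @export
print.phone_inventory <- function(x, ...) {
  cat("<phone_inventory> ", length(x$symbols), " phones: ",
      paste(utils::head(x$symbols, 8), collapse = " "),
      if (length(x$symbols) > 8) " ...", "\n", sep = "")
  invisible(x)
}

# Coil layout of the articulograph: 7 coils, sagittal x (anterior-posterior)
# and y (inferior-superior), x before y.
coil_coordinate_names <- function() {
  coils <- c("tt", "tb", "td", "ul", "ll", "ut", "lt")
  as.vector(t(outer(coils, c("x", "y"), paste, sep = "_")))
}

# 43 labels covering the Italian phone set (vowels incl. open-mid qualities,
# geminate-prone consonants listed once, affricates, glides).
italian_phone_labels <- function() {
  c("a", "e", "E", "i", "o", "O", "u",
    "p", "b", "t", "d", "k", "g",
    "f", "v", "s", "z", "S", "ts", "dz", "tS", "dZ",
    "m", "n", "J", "N", "l", "L", "r",
    "j", "w",
    "pp", "bb", "tt", "dd", "kk", "gg", "ff", "ss", "mm", "nn", "ll", "rr")
}

#' Default phone inventory
#'
#' Builds an inventory of `n` phones (up to the full 43-label Italian-style
#' set) with fixed, well-separated articulatory targets. Targets are drawn
#' once from a deterministic internal stream (they define the study
#' conditions, not a tunable), scaled to roughly unit spread.
#'
#' @param n number of phones (default 12, maximum 43).
#' @param mean_duration,duration_jitter see [phone_inventory()].
#' @return a `phone_inventory`.
#' @export
default_inventory <- function(n = 12, mean_duration = 0.12,
                              duration_jitter = 0.1) {
  labels <- italian_phone_labels()
  if (n < 1 || n > length(labels))
    stop("n must be between 1 and ", length(labels))
  targets <- with_local_seed(640913L, {
    matrix(stats::rnorm(length(labels) * 14), ncol = 14)
  })
  phone_inventory(labels[seq_len(n)], targets[seq_len(n), , drop = FALSE],
                  mean_duration, duration_jitter)
}

#' Subject profile: the speaker-specific articulatory-to-acoustic map
#'
#' Each subject renders the shared articulatory state through her own vocal
#' tract: three formant-like resonances whose frequencies are a sigmoidally
#' warped affine function of the 14 coil coordinates, scaled by a vocal-tract
#' length factor, excited at a subject-specific fundamental frequency.
#' `coherence` is the standard deviation (articulatory units) of
#' target-to-target noise across repetitions — the knob that models a subject
#' whose articulatory recordings are incoherent.
#'
#' @param id subject identifier (character).
#' @param map_weights 3 x 14 matrix: affine part of the resonance control map.
#' @param map_bias length-3 numeric: affine offsets.
#' @param vtl_scale vocal-tract length factor multiplying all resonance
#'   frequency ranges (1 = reference tract).
#' @param f0 fundamental frequency in Hz.
#' @param coherence standard deviation of per-repetition articulatory target
#'   noise, in target units; must be >= 0.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(id, map_weights, map_bias, vtl_scale = 1,
                            f0 = 200, coherence = 0.02) {
  map_weights <- as.matrix(map_weights)
  if (!identical(dim(map_weights), c(3L, 14L)))
    stop("map_weights must be 3 x 14")
  if (length(map_bias) != 3L) stop("map_bias must have length 3")
  if (!all(is.finite(map_weights)) || !all(is.finite(map_bias)))
    stop("acoustic-map parameters must be finite")
  if (coherence < 0) stop("coherence must be >= 0")
  if (f0 <= 0 || vtl_scale <= 0) stop("f0 and vtl_scale must be positive")
  structure(
    list(id = as.character(id), map_weights = map_weights,
         map_bias = as.numeric(map_bias), vtl_scale = vtl_scale,
         f0 = f0, coherence = coherence),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: f0 = %.0f Hz, vtl = %.2f, coherence = %.3f\n",
              x$id, x$f0, x$vtl_scale, x$coherence))
  invisible(x)
}

#' Default panel of subjects
#'
#' Five-subject panel emulating a homogeneous speaker group (same dialect,
#' same sex): all subjects share a common base articulatory-to-resonance map,
#' perturbed per subject by `map_spread` (relative), with vocal-tract length
#' factors spread over roughly +-8% and fundamental frequencies between 180
#' and 240 Hz. Subject identity, not the seed, fixes each speaker's map: the
#' panel is a deterministic function of its arguments.
#'
#' @param n number of subjects (default 5).
#' @param coherence articulatory coherence sd shared by all subjects
#'   (default 0.02; recycled, so a vector can single out one subject).
#' @param map_spread relative sd of the per-subject perturbation of the
#'   common map (default 0.2).
#' @return list of [subject_profile()] objects named by id.
#' @export
default_subjects <- function(n = 5, coherence = 0.02, map_spread = 0.2) {
  if (n < 1) stop("need at least one subject")
  coherence <- rep_len(coherence, n)
  with_local_seed(271828L, {
    base_w <- matrix(stats::rnorm(3 * 14, sd = 0.6), nrow = 3)
    base_b <- stats::rnorm(3, sd = 0.3)
    subs <- vector("list", n)
    for (i in seq_len(n)) {
      w <- base_w * (1 + map_spread * matrix(stats::rnorm(42), nrow = 3))
      b <- base_b + map_spread * stats::rnorm(3, sd = 0.3)
      subs[[i]] <- subject_profile(
        id = sprintf("s%02d", i),
        map_weights = w, map_bias = b,
        vtl_scale = 1 + 0.08 * stats::runif(1, -1, 1),
        f0 = stats::runif(1, 180, 240),
        coherence = coherence[i])
    }
    names(subs) <- vapply(subs, `[[`, "", "id")
    subs
  })
}

#' Word type
#'
#' @param id word-type identifier.
#' @param phones character vector of phone symbols (non-empty).
#' @param intonation `"declarative"` or `"question"`; a label only, with no
#'   acoustic consequence in the generator.
#' @return an object of class `word_type`.
#' @export
word_type <- function(id, phones, intonation = c("declarative", "question")) {
  intonation <- match.arg(intonation)
  phones <- as.character(phones)
  if (length(phones) < 1) stop("a word type needs at least one phone")
  structure(list(id = as.character(id), phones = phones,
                 intonation = intonation),
            class = "word_type")
}

#' Default lexicon of word types
#'
#' `n` word types of 3-5 phones drawn from the inventory, alternating
#' declarative and question intonation tags. Deterministic function of its
#' arguments.
#'
#' @param inventory a [phone_inventory()].
#' @param n number of word types (default 12).
#' @param min_len,max_len phone-sequence length range.
#' @return list of [word_type()] objects named by id.
#' @export
default_word_types <- function(inventory, n = 12, min_len = 3, max_len = 5) {
  with_local_seed(314159L, {
    wts <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(seq(min_len, max_len), 1)
      wts[[i]] <- word_type(
        id = sprintf("w%02d", i),
        phones = sample(inventory$symbols, len, replace = TRUE),
        intonation = if (i %% 2 == 0) "question" else "declarative")
    }
    names(wts) <- vapply(wts, `[[`, "", "id")
    wts
  })
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
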