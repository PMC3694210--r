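# Shared fixtures, memoised so expensive corpora and experiment runs are
# built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small noisy corpus: 3 subjects x 4 word types x 3 repetitions, 6 phones.
tiny_corpus <- function() {
  memo("tiny_corpus", function() {
    inv <- default_inventory(6)
    subs <- default_subjects(3, coherence = 0.02)
    wts <- default_word_types(inv, 4)
    generate_corpus(inv, subs, wts, repetitions = 3, seed = 42)
  })
}

tiny_tokens <- function() {
  memo("tiny_tokens", function() tokenize(tiny_corpus()))
}

# Noise-free corpus (coherence 0, duration jitter 0): the shared articulatory
# latent is exactly reproducible across subjects and repetitions.
clean_corpus <- function() {
  memo("clean_corpus", function() {
    inv <- default_inventory(6, duration_jitter = 0)
    subs <- default_subjects(3, coherence = 0)
    wts <- default_word_types(inv, 4)
    generate_corpus(inv, subs, wts, repetitions = 3, seed = 7)
  })
}

clean_tokens <- function() {
  memo("clean_tokens", function() tokenize(clean_corpus()))
}

subset_tokens <- function(tokens, subject) {
  info <- token_info(tokens)
  structure(tokens[info$subject == subject], class = "artimap_tokens")
}

# Default study-condition corpus (5 subjects) used by the acceptance-level
# experiments; heavier, so built lazily and shared by every block needing it.
study_corpus <- function() {
  memo("study_corpus", function() {
    inv <- default_inventory(12)
    subs <- default_subjects(5, coherence = 0.02)
    wts <- default_word_types(inv, 12)
    generate_corpus(inv, subs, wts, repetitions = 3, seed = 101)
  })
}

study_tokens <- function() {
  memo("study_tokens", function() tokenize(study_corpus()))
}

# Experiment configs used at test scale.
fast_mapping_config <- function(seed) {
  train_config(pretrain_epochs = 8, finetune_epochs = 40, seed = seed)
}

fast_classifier_config <- function(seed) {
  train_config(pretrain_epochs = 8, finetune_epochs = 40, seed = seed)
}

# NoNorm vs MotorNorm errors over a small set of listener-centred cells for
# one experiment seed; shared by the directional acceptance checks.
motor_vs_nonorm <- function(exp_seed, tokens = study_tokens(),
                            combos = data.frame(
                              listener = "s01", s1 = c("s02", "s03"),
                              s2 = c("s03", "s04"))) {
  memo(paste0("mvn_", exp_seed, "_", nrow(combos), "_",
              digest_key(tokens)), function() {
    rows <- list(); preds <- list(); k <- 0L
    for (setting in c("T1_2Tr", "T2")) {
      for (strategy in c("NoNorm", "MotorNorm")) {
        for (i in seq_len(nrow(combos))) {
          res <- run_scenario(
            tokens, strategy, setting, listener = combos$listener[i],
            s1 = combos$s1[i],
            s2 = if (setting == "T2") combos$s2[i] else NULL,
            split_seed = exp_seed,
            mapping_config = fast_mapping_config(exp_seed + 100),
            classifier_config = fast_classifier_config(exp_seed + 200),
            classifier_hidden = c(120, 120, 120))
          k <- k + 1L
          rows[[k]] <- data.frame(
            strategy = strategy, setting = setting,
            listener = combos$listener[i], s1 = combos$s1[i],
            s2 = if (setting == "T2") combos$s2[i] else NA_character_,
            error = res$error, stringsAsFactors = FALSE)
          preds[[k]] <- res$predictions
          names(preds)[k] <- paste(strategy, setting, i, sep = "|")
        }
      }
    }
    list(results = do.call(rbind, rows), predictions = preds)
  })
}

# Cheap content key for token sets (distinguishes corrupted variants).
digest_key <- function(tokens) {
  n <- length(tokens)
  v <- tokens[[1]]$articulatory
  if (is.null(v)) v <- tokens[[1]]$acoustic
  paste0(n, "_", format(sum(v) + sum(tokens[[n]]$acoustic), digits = 12))
}
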