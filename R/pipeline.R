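# Scenario and experiment orchestration: one scenario = strategy x setting x
# (listener, S1[, S2]) x split seed, running split -> mapping training ->
# reconstruction -> classifier training -> scoring. run_experiment() sweeps
# combinations and returns a tidy results table; run_pipeline() drives the
# whole generate -> extract -> experiment -> report chain from one config.

#' Run a single classification scenario
#'
#' Executes one experimental cell. The S1 split fraction is 1/3 (`T1_1Tr`)
#' or 2/3 (`T1_2Tr`, `T2`); T2 tests on 1/3 of the held-out speaker S2.
#' Strategies other than NoNorm first train their mapping on the listener +
#' S1-train pairs, then attach reconstructed blocks to all token sets the
#' classifier needs. Reconstruction for test rows uses the same trained
#' mapping as for training rows.
#'
#' @param tokens full `artimap_tokens` for the corpus.
#' @param strategy one of `"NoNorm"`, `"AcouNorm_A"`, `"AcouNorm_B"`,
#'   `"AcouNorm_C"`, `"MotorNorm"`.
#' @param setting `"T1_1Tr"`, `"T1_2Tr"` or `"T2"`.
#' @param listener,s1,s2 subject ids (`s2` only for T2).
#' @param split_seed seed for the S1 (and S2) splits and for training.
#' @param mapping_config [train_config()] for the mapping net.
#' @param classifier_config [train_config()] for the phone classifier.
#' @param classifier_hidden classifier hidden sizes (default
#'   `c(120, 120, 120)`; the full-corpus configuration uses 1500).
#' @param mapping_hidden mapping hidden sizes (default `c(180, 180, 180)`).
#' @param reduced a [reduced_set()] for AcouNorm_C.
#' @param listener_af MotorNorm listener-row AF source (see
#'   [assemble_classifier_dataset()]).
#' @param levels phone label levels (defaults to sorted phones present).
#' @return list of class `scenario_result`: `error`, `predictions` (data
#'   frame truth/predicted), `n_train`, `n_test`, `dropped_pairs`,
#'   `mapping_net` (or NULL), the scenario fields and seeds.
#' @export
run_scenario <- function(tokens, strategy, setting, listener, s1, s2 = NULL,
                         split_seed = 1,
                         mapping_config = train_config(seed = split_seed),
                         classifier_config = train_config(seed = split_seed + 1),
                         classifier_hidden = c(120, 120, 120),
                         mapping_hidden = c(180, 180, 180),
                         reduced = NULL,
                         listener_af = "reconstructed",
                         levels = NULL) {
  strategy <- match.arg(strategy, STRATEGIES)
  setting <- match.arg(setting, SETTINGS)
  if (setting == "T2" && is.null(s2)) stop("T2 requires an S2 subject")
  if (setting != "T2") s2 <- NULL
  ids <- c(listener, s1, s2)
  if (anyDuplicated(ids)) stop("listener, S1 and S2 must be distinct")
  info <- token_info(tokens)
  pick <- function(id) structure(tokens[info$subject == id],
                                 class = "artimap_tokens")
  listener_tokens <- pick(listener)
  fraction <- if (setting == "T1_1Tr") 1 / 3 else 2 / 3
  s1_split <- split_subject(pick(s1), fraction, split_seed)
  test_tokens <- if (setting == "T2") {
    split_subject(pick(s2), 2 / 3, split_seed + 1)$test
  } else {
    s1_split$test
  }
  mapping_net <- NULL
  dropped <- 0L
  if (strategy != "NoNorm") {
    pairs <- build_mapping_pairs(strategy, listener_tokens, s1_split$train,
                                 reduced = reduced)
    assert_listener_only_articulatory(pairs, listener)
    dropped <- pairs$dropped
    mapping_net <- train_mapping(pairs, mapping_config,
                                 hidden = mapping_hidden)
    listener_tokens <- reconstruct(mapping_net, listener_tokens)
    s1_split$train <- reconstruct(mapping_net, s1_split$train)
    test_tokens <- reconstruct(mapping_net, test_tokens)
  }
  ds <- assemble_classifier_dataset(strategy, listener_tokens,
                                    s1_split$train, test_tokens,
                                    listener_af = listener_af)
  if (is.null(levels)) levels <- sort(unique(c(ds$labels_train,
                                               ds$labels_test)))
  spec <- net_spec(ncol(ds$x_train), classifier_hidden, length(levels),
                   "softmax")
  clf <- train_dnn(ds$x_train, ds$labels_train, spec, classifier_config,
                   levels = levels)
  predicted <- classify_dnn(clf, ds$x_test)
  predictions <- data.frame(truth = ds$labels_test, predicted = predicted,
                            stringsAsFactors = FALSE)
  structure(
    list(error = classification_error(predictions),
         predictions = predictions,
         n_train = nrow(ds$x_train), n_test = nrow(ds$x_test),
         dropped_pairs = dropped, mapping_net = mapping_net,
         strategy = strategy, setting = setting, listener = listener,
         s1 = s1, s2 = if (is.null(s2)) NA_character_ else s2,
         split_seed = split_seed),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario> %s %s L=%s S1=%s%s: error %.3f (%d train / %d test)\n",
              x$strategy, x$setting, x$listener, x$s1,
              if (is.na(x$s2)) "" else paste0(" S2=", x$s2),
              x$error, x$n_train, x$n_test))
  invisible(x)
}

#' Run a sweep of scenarios
#'
#' Iterates strategies x settings x subject combinations and returns a tidy
#' results table plus the per-scenario prediction sets (for pooled McNemar
#' comparisons).
#'
#' @param tokens full corpus tokens.
#' @param strategies,settings subsets of the five strategies / three
#'   settings.
#' @param combinations data frame with columns `listener`, `s1` and
#'   (for T2 rows) `s2`; built with [enumerate_scenarios()] if omitted,
#'   using all subjects as listeners.
#' @param split_seed base split seed.
#' @param ... passed to [run_scenario()].
#' @return list with `results` (data frame: listener, s1, s2, strategy,
#'   setting, n_train, n_test, error) and `predictions` (named list).
#' @export
run_experiment <- function(tokens, strategies = STRATEGIES,
                           settings = SETTINGS, combinations = NULL,
                           split_seed = 1, ...) {
  info <- token_info(tokens)
  subjects <- sort(unique(info$subject))
  if (is.null(combinations)) {
    combos <- lapply(subjects, function(l) {
      en <- enumerate_scenarios(subjects, l)
      en$triplets
    })
    combinations <- do.call(rbind, combos)
  }
  if (is.null(combinations$s2)) combinations$s2 <- NA_character_
  rows <- list(); preds <- list(); k <- 0L
  for (setting in settings) {
    need_s2 <- setting == "T2"
    combs <- combinations
    if (!need_s2)
      combs <- unique(combinations[, c("listener", "s1")])
    else
      combs <- combinations[!is.na(combinations$s2), , drop = FALSE]
    for (i in seq_len(nrow(combs))) {
      for (strategy in strategies) {
        res <- run_scenario(tokens, strategy, setting,
                            listener = combs$listener[i], s1 = combs$s1[i],
                            s2 = if (need_s2) combs$s2[i] else NULL,
                            split_seed = split_seed, ...)
        k <- k + 1L
        rows[[k]] <- data.frame(
          listener = res$listener, s1 = res$s1, s2 = res$s2,
          strategy = strategy, setting = setting, n_train = res$n_train,
          n_test = res$n_test, error = res$error, split_seed = split_seed,
          stringsAsFactors = FALSE)
        preds[[k]] <- res$predictions
        names(preds)[k] <- paste(strategy, setting, res$listener, res$s1,
                                 res$s2, sep = "|")
      }
    }
  }
  list(results = do.call(rbind, rows), predictions = preds)
}

#' Experiment configuration
#'
#' Bundles every knob of the pipeline with its default: the corpus
#' conditions, the fixed feature constants (25 ms window, 10 frames, 20 mel
#' channels, 15 ms smoothing — not meant to be changed), the net sizes per
#' role, and the strategy/setting sweep. `classifier_hidden` defaults to the
#' desk-scale 120; the full-corpus configuration is 1500 units per hidden
#' layer with a 43-phone output.
#'
#' @param n_subjects,n_word_types,n_phones,repetitions corpus conditions.
#' @param coherence per-subject articulatory coherence sd.
#' @param corpus_seed seed for corpus generation (independent of the
#'   experiment split seed).
#' @param split_seed base seed for splits and training.
#' @param strategies,settings the sweep.
#' @param classifier_hidden,mapping_hidden net sizes.
#' @param classifier_config,mapping_config [train_config()]s (seeds are
#'   taken from `split_seed` when NULL).
#' @param listener_af MotorNorm listener-row AF source.
#' @param drop_subjects subjects excluded in the aggregated report.
#' @param combinations optional explicit combination table.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 5, n_word_types = 12,
                              n_phones = 12, repetitions = 3,
                              coherence = 0.02, corpus_seed = 101,
                              split_seed = 1,
                              strategies = c("NoNorm", "MotorNorm"),
                              settings = c("T1_2Tr", "T2"),
                              classifier_hidden = c(120, 120, 120),
                              mapping_hidden = c(180, 180, 180),
                              classifier_config = NULL,
                              mapping_config = NULL,
                              listener_af = "reconstructed",
                              drop_subjects = NULL,
                              combinations = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

# Stable hash of the semantic content of a config: canonical deparse ->
# md5. Changes iff a semantic field changes.
config_hash <- function(config) {
  fields <- config[sort(names(config))]
  txt <- paste(deparse(fields, control = c("keepNA", "keepInteger",
                                           "niceNames")),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline from one configuration
#'
#' generate -> tokenize/extract -> run-experiment -> aggregate. Re-running
#' with an identical configuration reproduces identical numbers; every
#' report is stamped with the configuration hash and seeds.
#'
#' @param config an [experiment_config()].
#' @param dry_run validate the configuration and return the plan without
#'   computing.
#' @param verbose print stage progress.
#' @return list of class `pipeline_report`: `results`, `summary` (from
#'   [aggregate_results()]), `predictions`, `config_hash`, `seeds`,
#'   `timings`, `sizes`.
#' @export
run_pipeline <- function(config = experiment_config(), dry_run = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!all(config$strategies %in% STRATEGIES))
    stop("unknown strategy in config")
  if (!all(config$settings %in% SETTINGS)) stop("unknown setting in config")
  hash <- config_hash(config)
  if (dry_run) {
    return(structure(list(config_hash = hash, plan = list(
      n_utterances = config$n_subjects * config$n_word_types *
        config$repetitions,
      cells = length(config$strategies) * length(config$settings)),
      dry_run = TRUE), class = "pipeline_report"))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  inventory <- default_inventory(config$n_phones)
  subjects <- default_subjects(config$n_subjects, config$coherence)
  word_types <- default_word_types(inventory, config$n_word_types)
  corpus <- generate_corpus(inventory, subjects, word_types,
                            config$repetitions, seed = config$corpus_seed)
  timings["generate"] <- tic() - t0
  say("generated %d utterances in %.1fs", nrow(corpus$manifest),
      timings["generate"])
  t0 <- tic()
  tokens <- tokenize(corpus)
  timings["extract"] <- tic() - t0
  say("extracted %d tokens in %.1fs", length(tokens), timings["extract"])
  t0 <- tic()
  mc <- config$mapping_config %||% train_config(seed = config$split_seed)
  cc <- config$classifier_config %||%
    train_config(seed = config$split_seed + 1)
  exp <- run_experiment(tokens, strategies = config$strategies,
                        settings = config$settings,
                        combinations = config$combinations,
                        split_seed = config$split_seed,
                        mapping_config = mc, classifier_config = cc,
                        classifier_hidden = config$classifier_hidden,
                        mapping_hidden = config$mapping_hidden,
                        listener_af = config$listener_af)
  timings["experiment"] <- tic() - t0
  say("ran %d scenarios in %.1fs", nrow(exp$results), timings["experiment"])
  summary <- aggregate_results(exp$results,
                               drop_subjects = config$drop_subjects)
  structure(
    list(results = exp$results, summary = summary,
         predictions = exp$predictions, config_hash = hash,
         seeds = c(corpus = config$corpus_seed, split = config$split_seed),
         timings = timings,
         sizes = c(utterances = nrow(corpus$manifest),
                   tokens = length(tokens))),
    class = "pipeline_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> config ", substr(x$config_hash, 1, 8), "\n", sep = "")
  if (isTRUE(x$dry_run)) { cat("  (dry run)\n"); return(invisible(x)) }
  print(x$summary)
  invisible(x)
}

#' Write the tidy result tables of a pipeline report
#'
#' Tab-delimited per-scenario errors and the aggregate summary.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$results, file.path(dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("config_hash\t", report$config_hash),
               paste0("corpus_seed\t", report$seeds[["corpus"]]),
               paste0("split_seed\t", report$seeds[["split"]])),
             file.path(dir, "run_info.tsv"))
  invisible(dir)
}
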