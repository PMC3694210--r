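# Cross-speaker training-pair construction, the five normalization
# strategies, and the T1/T2 scenario machinery. The central operation is the
# acoustic bootstrap: a speaker's phone realizations are aligned with the
# listener's realizations of the same phoneme in the same word type (matched
# repetition, same position, frame i <-> frame i of the two 10-frame
# blocks), which is what makes a cross-speaker acoustic-to-articulatory
# mapping learnable at all.

STRATEGIES <- c("NoNorm", "AcouNorm_A", "AcouNorm_B", "AcouNorm_C",
                "MotorNorm")
SETTINGS <- c("T1_1Tr", "T1_2Tr", "T2")

#' Split one subject's tokens into train and test by utterance
#'
#' The split is by whole word token (word type x repetition) and stratified
#' by word type, so every word type appears on both sides: per word type,
#' `round(fraction * n_reps)` repetitions (at least 1, at most n_reps - 1)
#' go to training. Deterministic given `seed`.
#'
#' @param tokens an `artimap_tokens` list, all from one subject.
#' @param fraction training fraction (1/3 or 2/3 in the standard settings).
#' @param seed RNG seed.
#' @return list with `train` and `test` token lists (class preserved).
#' @export
split_subject <- function(tokens, fraction, seed) {
  info <- token_info(tokens)
  if (length(unique(info$subject)) != 1)
    stop("split_subject expects tokens of a single subject")
  set.seed(as.integer(seed))
  train_idx <- logical(length(tokens))
  for (wt in sort(unique(info$word_type))) {
    reps <- sort(unique(info$repetition[info$word_type == wt]))
    if (length(reps) < 2)
      stop("word type ", wt, " has fewer than 2 repetitions")
    n_train <- min(length(reps) - 1L, max(1L, round(fraction * length(reps))))
    chosen <- sort(sample(reps, n_train))
    train_idx <- train_idx |
      (info$word_type == wt & info$repetition %in% chosen)
  }
  list(train = structure(tokens[train_idx], class = "artimap_tokens"),
       test = structure(tokens[!train_idx], class = "artimap_tokens"))
}

# 10 x 180 context matrix for one token: frame i = (frame i-1, i, i+1)
# concatenated, block edges replicated.
context_frames <- function(acoustic) {
  n <- nrow(acoustic)
  prv <- acoustic[c(1, seq_len(n - 1)), , drop = FALSE]
  nxt <- acoustic[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  cbind(prv, acoustic, nxt)
}

# Reduced-set output columns within a 60-wide MFSC frame: first k static,
# first k delta, first k delta-delta.
reduced_columns <- function(k) c(seq_len(k), 20 + seq_len(k), 40 + seq_len(k))

#' Reduced acoustic feature set
#'
#' Keeps the first `k` (of 20) static mel coefficients with their first and
#' second derivatives, `3k` features per frame in all.
#'
#' @param k number of retained static coefficients, 1-20.
#' @param warning_flag TRUE when no `k` met the selection criterion and the
#'   full set was returned.
#' @return object of class `reduced_set` with `k` and `columns`.
#' @export
reduced_set <- function(k, warning_flag = FALSE) {
  k <- as.integer(k)
  if (k < 1 || k > 20) stop("k must be between 1 and 20")
  structure(list(k = k, columns = reduced_columns(k),
                 warning_flag = warning_flag),
            class = "reduced_set")
}

# Match tokens of two subjects by (word type, phone position, matched
# repetition): repetitions are paired by sorted rank, up to the smaller
# count. Returns a data frame of index pairs plus the number of source
# tokens that found no partner.
align_tokens <- function(src_tokens, ref_tokens) {
  si <- token_info(src_tokens); ri <- token_info(ref_tokens)
  pairs <- list(); np <- 0L; dropped <- 0L
  for (wt in unique(si$word_type)) {
    s_rows <- which(si$word_type == wt)
    r_rows <- which(ri$word_type == wt)
    if (length(r_rows) == 0) { dropped <- dropped + length(s_rows); next }
    s_reps <- sort(unique(si$repetition[s_rows]))
    r_reps <- sort(unique(ri$repetition[r_rows]))
    n_match <- min(length(s_reps), length(r_reps))
    rep_map <- stats::setNames(r_reps[seq_len(n_match)],
                               s_reps[seq_len(n_match)])
    for (s in s_rows) {
      target_rep <- rep_map[as.character(si$repetition[s])]
      if (is.na(target_rep)) { dropped <- dropped + 1L; next }
      r <- r_rows[ri$repetition[r_rows] == target_rep &
                    ri$position[r_rows] == si$position[s] &
                    ri$phone[r_rows] == si$phone[s]]
      if (length(r) != 1) { dropped <- dropped + 1L; next }
      np <- np + 1L
      pairs[[np]] <- c(src = s, ref = r)
    }
  }
  list(pairs = if (np) as.data.frame(do.call(rbind, pairs)) else
    data.frame(src = integer(), ref = integer()),
    dropped = dropped)
}

# Frame-level rows for a set of (input token, output token) pairs.
# input: 180-wide acoustic context of in_tokens; output: taken from
# out_tokens via `out_get` (a function token -> 10 x d matrix).
pair_rows <- function(in_tokens, out_tokens, pair_idx, out_get, role) {
  xs <- list(); ys <- list(); prov <- list()
  for (j in seq_len(nrow(pair_idx))) {
    ti <- in_tokens[[pair_idx$src[j]]]
    to <- out_tokens[[pair_idx$ref[j]]]
    xs[[j]] <- context_frames(ti$acoustic)
    ys[[j]] <- out_get(to)
    prov[[j]] <- data.frame(
      role = role, in_subject = ti$subject, out_subject = to$subject,
      word_type = ti$word_type, in_repetition = ti$repetition,
      out_repetition = to$repetition, phone = ti$phone,
      position = ti$position, frame = 1:10, stringsAsFactors = FALSE)
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys),
       provenance = do.call(rbind, prov))
}

#' Build mapping training pairs for a normalization strategy
#'
#' Assembles the frame-level input/output pairs that train the
#' acoustic-to-articulatory (MotorNorm) or acoustic-to-acoustic (AcouNorm)
#' mapping. Inputs are always 180-wide acoustic contexts (3 consecutive
#' 60-MFSC frames). Outputs:
#' * `MotorNorm` — listener-audio -> listener-AF self rows plus
#'   S1-audio -> listener-AF cross rows (42 wide);
#' * `AcouNorm_A` — S1-audio -> listener-audio cross rows only (60 wide);
#' * `AcouNorm_B` — listener identity rows plus the cross rows;
#' * `AcouNorm_C` — as B, outputs restricted to the reduced columns.
#'
#' Cross rows pair tokens of the same phoneme of the same word type at the
#' same position, repetitions matched by sorted rank; source tokens with no
#' aligned listener token are dropped and counted.
#'
#' @param strategy one of `"MotorNorm"`, `"AcouNorm_A"`, `"AcouNorm_B"`,
#'   `"AcouNorm_C"`.
#' @param listener_tokens listener tokens (with articulatory blocks for
#'   MotorNorm).
#' @param s1_tokens S1 training tokens.
#' @param reduced a [reduced_set()] (AcouNorm_C only).
#' @return object of class `paired_dataset`: `x`, `y`, `provenance`,
#'   `dropped`, `strategy`.
#' @export
build_mapping_pairs <- function(strategy, listener_tokens, s1_tokens,
                                reduced = NULL) {
  strategy <- match.arg(strategy, setdiff(STRATEGIES, "NoNorm"))
  if (strategy == "MotorNorm") {
    has_af <- all(vapply(listener_tokens,
                         function(t) !is.null(t$articulatory), logical(1)))
    if (!has_af) stop("MotorNorm requires listener articulatory data")
    out_get <- function(t) t$articulatory
  } else if (strategy == "AcouNorm_C") {
    if (is.null(reduced)) stop("AcouNorm_C requires a reduced_set")
    out_get <- function(t) t$acoustic[, reduced$columns, drop = FALSE]
  } else {
    out_get <- function(t) t$acoustic
  }
  al <- align_tokens(s1_tokens, listener_tokens)
  if (nrow(al$pairs) == 0) stop("empty alignment between speaker and listener")
  cross <- pair_rows(s1_tokens, listener_tokens, al$pairs, out_get, "cross")
  parts <- list(cross)
  if (strategy != "AcouNorm_A") {
    self_idx <- data.frame(src = seq_along(listener_tokens),
                           ref = seq_along(listener_tokens))
    parts <- c(list(pair_rows(listener_tokens, listener_tokens, self_idx,
                              out_get, "self")),
               parts)
  }
  structure(
    list(x = do.call(rbind, lapply(parts, `[[`, "x")),
         y = do.call(rbind, lapply(parts, `[[`, "y")),
         provenance = do.call(rbind, lapply(parts, `[[`, "provenance")),
         dropped = al$dropped, strategy = strategy),
    class = "paired_dataset")
}

#' Train the acoustic-to-articulatory / acoustic-to-acoustic mapping
#'
#' A 180-180-180-180-out regression deep net (out = 42 for MotorNorm, 60 for
#' AcouNorm_A/B, 3k for AcouNorm_C) trained on the paired dataset.
#'
#' @param pairs a `paired_dataset` from [build_mapping_pairs()].
#' @param config a [train_config()].
#' @param hidden hidden-layer sizes (default `c(180, 180, 180)`).
#' @return a `trained_net` (linear output).
#' @export
train_mapping <- function(pairs, config, hidden = c(180, 180, 180)) {
  spec <- net_spec(ncol(pairs$x), hidden, ncol(pairs$y), "linear")
  train_dnn(pairs$x, pairs$y, spec, config)
}

#' Reconstruct feature blocks for tokens through a trained mapping
#'
#' Applies the mapping to each token's 10 sliding 3-frame acoustic contexts
#' (edge replication), attaching a 10 x out `reconstructed` block; original
#' blocks are untouched.
#'
#' @param net a `trained_net` regression mapping.
#' @param tokens an `artimap_tokens` list.
#' @return the tokens with `$reconstructed` blocks.
#' @export
reconstruct <- function(net, tokens) {
  for (k in seq_along(tokens)) {
    ctx <- context_frames(tokens[[k]]$acoustic)
    tokens[[k]]$reconstructed <- predict(net, ctx)
  }
  tokens
}

#' Smallest k whose error does not exceed the articulatory reference
#'
#' Pure selection rule: given per-k classification errors for k = 1..20 and
#' the AF-only reference error, returns the smallest k with
#' `errors[k] <= e_af`; if none qualifies, k = 20 with `warning_flag`.
#'
#' @param errors_by_k numeric vector of length 20.
#' @param e_af reference error of the AF-only classifier.
#' @return a [reduced_set()].
#' @export
select_k_from_errors <- function(errors_by_k, e_af) {
  if (length(errors_by_k) != 20) stop("need errors for k = 1..20")
  ok <- which(errors_by_k <= e_af)
  if (length(ok) == 0) return(reduced_set(20L, warning_flag = TRUE))
  reduced_set(min(ok))
}

#' Search the reduced acoustic feature set against the AF benchmark
#'
#' Trains an AF-only phone classifier on a listener split to get the
#' reference error, then scans k = 1..20 acoustic classifiers on the first-k
#' reduced sets and returns the smallest k whose error does not exceed the
#' reference ([select_k_from_errors()]).
#'
#' @param listener_tokens listener tokens with articulatory blocks.
#' @param fraction training fraction for the split.
#' @param config classifier [train_config()].
#' @param seed split seed.
#' @param hidden classifier hidden sizes.
#' @param k_grid candidate k values actually trained (default 1:20; errors
#'   of untrained k are treated as infinite, so the selection only ever
#'   returns a trained k).
#' @return a [reduced_set()] with attribute `errors` (per-k) and `e_af`.
#' @export
select_reduced_featureset <- function(listener_tokens, fraction, config,
                                      seed, hidden = c(120, 120, 120),
                                      k_grid = 1:20) {
  sp <- split_subject(listener_tokens, fraction, seed)
  labs <- function(tl) vapply(tl, `[[`, "", "phone")
  lev <- sort(unique(labs(listener_tokens)))
  flat <- function(tl, get) do.call(rbind, lapply(tl, function(t)
    as.vector(t(get(t)))))
  err_of <- function(x_tr, y_tr, x_te, y_te) {
    # screen columns that are constant in training (e.g. interior-frame
    # velocities of flat trajectories): uninformative, and standardization
    # is undefined for them
    keep <- apply(x_tr, 2, stats::sd) > 0
    if (!any(keep)) stop("all feature columns are constant")
    x_tr <- x_tr[, keep, drop = FALSE]
    x_te <- x_te[, keep, drop = FALSE]
    spec <- net_spec(ncol(x_tr), hidden, length(lev), "softmax")
    net <- train_dnn(x_tr, y_tr, spec, config, levels = lev)
    mean(classify_dnn(net, x_te) != y_te)
  }
  e_af <- err_of(flat(sp$train, function(t) t$articulatory), labs(sp$train),
                 flat(sp$test, function(t) t$articulatory), labs(sp$test))
  errors <- rep(NA_real_, 20)
  for (k in k_grid) {
    cols <- reduced_columns(k)
    errors[k] <- err_of(
      flat(sp$train, function(t) t$acoustic[, cols, drop = FALSE]),
      labs(sp$train),
      flat(sp$test, function(t) t$acoustic[, cols, drop = FALSE]),
      labs(sp$test))
  }
  errors_full <- ifelse(is.na(errors), Inf, errors)
  rs <- select_k_from_errors(errors_full, e_af)
  attr(rs, "errors") <- errors
  attr(rs, "e_af") <- e_af
  rs
}

flatten_tokens <- function(tokens, parts) {
  do.call(rbind, lapply(tokens, function(t) {
    v <- numeric(0)
    if ("acoustic" %in% parts) v <- c(v, as.vector(t(t$acoustic)))
    if ("articulatory" %in% parts) v <- c(v, as.vector(t(t$articulatory)))
    if ("reconstructed" %in% parts) v <- c(v, as.vector(t(t$reconstructed)))
    v
  }))
}

#' Assemble the phone-classifier dataset for one strategy and setting
#'
#' Builds the training/testing feature matrices and labels of the phone
#' classifier. Per-token feature widths: NoNorm 600 (acoustics only);
#' AcouNorm_A 600 (listener rows actual, speaker rows reconstructed);
#' AcouNorm_B 1200 (actual + reconstructed); AcouNorm_C 600 + 30k;
#' MotorNorm 1020 (actual + reconstructed AFs). Reconstructed features for
#' train and test rows come from the same trained mapping. MotorNorm
#' listener rows use reconstructed AFs by default (`listener_af =
#' "reconstructed"`), switchable to the listener's actual AFs.
#'
#' @param strategy one of the five strategies.
#' @param listener_tokens,s1_train_tokens,test_tokens token lists (test
#'   tokens are S1 held-out in T1, S2's test split in T2), already carrying
#'   `$reconstructed` blocks where the strategy requires them.
#' @param listener_af `"reconstructed"` or `"actual"` (MotorNorm only).
#' @return list with `x_train`, `labels_train`, `x_test`, `labels_test`,
#'   `provenance_train`, `provenance_test`.
#' @export
assemble_classifier_dataset <- function(strategy, listener_tokens,
                                        s1_train_tokens, test_tokens,
                                        listener_af = c("reconstructed",
                                                        "actual")) {
  strategy <- match.arg(strategy, STRATEGIES)
  listener_af <- match.arg(listener_af)
  need_rec <- function(tl, who) {
    if (!all(vapply(tl, function(t) !is.null(t$reconstructed), logical(1))))
      stop(strategy, " requires reconstructed blocks for ", who,
           " tokens (run reconstruct() first)")
  }
  parts_of <- switch(
    strategy,
    NoNorm = list(train_l = "acoustic", train_s = "acoustic",
                  test = "acoustic"),
    AcouNorm_A = list(train_l = "acoustic", train_s = "reconstructed",
                      test = "reconstructed"),
    AcouNorm_B = ,
    AcouNorm_C = list(train_l = c("acoustic", "reconstructed"),
                      train_s = c("acoustic", "reconstructed"),
                      test = c("acoustic", "reconstructed")),
    MotorNorm = list(
      train_l = c("acoustic",
                  if (listener_af == "reconstructed") "reconstructed"
                  else "articulatory"),
      train_s = c("acoustic", "reconstructed"),
      test = c("acoustic", "reconstructed")))
  if (any(c(parts_of$train_s, parts_of$test) == "reconstructed")) {
    need_rec(s1_train_tokens, "S1 training")
    need_rec(test_tokens, "test")
    if (any(parts_of$train_l == "reconstructed"))
      need_rec(listener_tokens, "listener")
  }
  labs <- function(tl) vapply(tl, `[[`, "", "phone")
  prov <- function(tl) token_info(tl)
  x_train <- rbind(flatten_tokens(listener_tokens, parts_of$train_l),
                   flatten_tokens(s1_train_tokens, parts_of$train_s))
  list(x_train = x_train,
       labels_train = c(labs(listener_tokens), labs(s1_train_tokens)),
       x_test = flatten_tokens(test_tokens, parts_of$test),
       labels_test = labs(test_tokens),
       provenance_train = rbind(prov(listener_tokens), prov(s1_train_tokens)),
       provenance_test = prov(test_tokens))
}

#' Enumerate listener-centred subject combinations
#'
#' T1: every (listener, S1) pair with S1 != listener. T2: every ordered
#' (listener, S1, S2) triplet with S1, S2 and the listener pairwise
#' distinct. A 5-subject panel gives 4 pairs and 12 triplets per listener.
#'
#' @param subject_ids character vector of subject ids.
#' @param listener the listener id.
#' @return list with `pairs` (data frame listener, s1) and `triplets`
#'   (listener, s1, s2).
#' @export
enumerate_scenarios <- function(subject_ids, listener) {
  if (!listener %in% subject_ids) stop("unknown listener: ", listener)
  others <- setdiff(subject_ids, listener)
  pairs <- data.frame(listener = listener, s1 = others,
                      stringsAsFactors = FALSE)
  tri <- expand.grid(s1 = others, s2 = others, stringsAsFactors = FALSE)
  tri <- tri[tri$s1 != tri$s2, , drop = FALSE]
  triplets <- data.frame(listener = rep(listener, nrow(tri)), s1 = tri$s1,
                         s2 = tri$s2, stringsAsFactors = FALSE)
  rownames(triplets) <- NULL
  list(pairs = pairs, triplets = triplets)
}

#' Assert that articulatory data never leaks from non-listener subjects
#'
#' Checks a `paired_dataset`'s provenance: every articulatory (MotorNorm)
#' output row must come from the listener.
#'
#' @param pairs a `paired_dataset`.
#' @param listener listener id.
#' @return TRUE invisibly; stops otherwise.
#' @export
assert_listener_only_articulatory <- function(pairs, listener) {
  if (pairs$strategy == "MotorNorm" &&
      !all(pairs$provenance$out_subject == listener))
    stop("articulatory outputs from a non-listener subject")
  invisible(TRUE)
}
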