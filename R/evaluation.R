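# Scoring and diagnostics: phone classification error, exact McNemar
# comparison of paired classifiers, relative error reductions, and the four
# Pearson correlations that diagnose articulatory reconstruction (subject
# coherence, listener-speaker motor similarity, reconstruction accuracy
# toward listener and toward speaker).

#' Phone classification error rate
#'
#' @param predictions data frame with columns `truth` and `predicted`
#'   (characters or factors), one row per test token.
#' @return misclassified / total, in `[0, 1]`.
#' @export
classification_error <- function(predictions) {
  if (nrow(predictions) == 0) stop("empty prediction set")
  mean(as.character(predictions$truth) !=
         as.character(predictions$predicted))
}

#' Exact McNemar test for two classifiers on the same test set
#'
#' Counts the discordant tokens (`b`: correct by A only, `c`: correct by B
#' only) and computes the exact two-sided binomial p-value
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `p = 1` when `b + c = 0`.
#'
#' @param preds_a,preds_b data frames with `truth` and `predicted`, same
#'   token set in the same order (same `truth` sequence).
#' @param alpha significance level for the `significant` flag.
#' @return list of class `mcnemar_result`: `b`, `c`, `p_value`,
#'   `significant`.
#' @export
mcnemar_exact <- function(preds_a, preds_b, alpha = 0.05) {
  if (nrow(preds_a) != nrow(preds_b) ||
      !identical(as.character(preds_a$truth), as.character(preds_b$truth)))
    stop("the two prediction sets must cover the same tokens")
  ok_a <- as.character(preds_a$predicted) == as.character(preds_a$truth)
  ok_b <- as.character(preds_b$predicted) == as.character(preds_b$truth)
  b <- sum(ok_a & !ok_b)
  c_ <- sum(!ok_a & ok_b)
  n <- b + c_
  p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
  structure(list(b = b, c = c_, p_value = p, significant = p <= alpha,
                 alpha = alpha),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar> b = %d, c = %d, p = %.4g (%ssignificant at %.2f)\n",
              x$b, x$c, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Relative error reduction
#'
#' @param e_base baseline error (> 0).
#' @param e_new comparison error.
#' @return `(e_base - e_new) / e_base`.
#' @export
relative_error_reduction <- function(e_base, e_new) {
  if (e_base <= 0) stop("baseline error must be > 0")
  (e_base - e_new) / e_base
}

# Pearson correlation per column pair of two aligned matrices.
columnwise_pearson <- function(a, b) {
  if (nrow(a) < 2) stop("fewer than 2 aligned frames")
  vapply(seq_len(ncol(a)), function(j) {
    sa <- stats::sd(a[, j]); sb <- stats::sd(b[, j])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a[, j], b[, j])
  }, numeric(1))
}

# Stack aligned articulatory frames of token pairs; `get_a`/`get_b` pick the
# block of each side.
stack_aligned <- function(tokens_a, tokens_b, pair_idx, get_a, get_b) {
  a <- do.call(rbind, lapply(pair_idx$src, function(k) get_a(tokens_a[[k]])))
  b <- do.call(rbind, lapply(pair_idx$ref, function(k) get_b(tokens_b[[k]])))
  list(a = a, b = b)
}

# All unordered repetition-pair alignments within one subject's tokens:
# same word type, same position, different repetition.
intra_subject_pairs <- function(info) {
  pairs <- list(); np <- 0L
  key <- paste(info$word_type, info$position)
  for (kk in unique(key)) {
    rows <- which(key == kk)
    if (length(rows) < 2) next
    cmb <- utils::combn(rows, 2)
    for (j in seq_len(ncol(cmb))) {
      np <- np + 1L
      pairs[[np]] <- c(src = cmb[1, j], ref = cmb[2, j])
    }
  }
  if (np == 0) return(data.frame(src = integer(), ref = integer()))
  as.data.frame(do.call(rbind, pairs))
}

#' Intra-subject articulatory coherence correlation
#'
#' Pearson correlation, per AF dimension, between a subject's articulatory
#' features extracted from different repetitions of the same word type
#' (aligned frame-by-frame), averaged over the 42 dimensions.
#'
#' @param tokens one subject's tokens with articulatory blocks.
#' @return scalar mean correlation.
#' @export
coherence_correlation <- function(tokens) {
  info <- token_info(tokens)
  pr <- intra_subject_pairs(info)
  if (nrow(pr) == 0) stop("no repeated word types to correlate")
  st <- stack_aligned(tokens, tokens, pr,
                      function(t) t$articulatory, function(t) t$articulatory)
  mean(columnwise_pearson(st$a, st$b), na.rm = TRUE)
}

#' The four reconstruction-diagnostic correlations
#'
#' For one listener and a set of speakers, computes, per AF dimension over
#' aligned frames, then averaged over dimensions, then over speakers:
#' 1. `coherence` — the listener's intra-subject correlation across
#'    repetitions of the same word type;
#' 2. `listener_vs_speaker` — listener actual vs speaker actual AFs;
#' 3. `listener_vs_reconstructed` — listener actual AFs vs AFs reconstructed
#'    from the speaker's acoustics;
#' 4. `speaker_vs_reconstructed` — speaker actual AFs vs the same
#'    reconstructions.
#'
#' @param listener_tokens listener tokens with articulatory blocks.
#' @param speaker_token_sets named list (by speaker id) of speaker token
#'   lists carrying `$articulatory` and `$reconstructed` (from the mapping
#'   applied to that speaker's acoustics).
#' @return list of class `correlation_report` with the four correlations
#'   (2-4 averaged over speakers) and the per-speaker breakdown.
#' @export
four_correlations <- function(listener_tokens, speaker_token_sets) {
  c1 <- coherence_correlation(listener_tokens)
  per_speaker <- lapply(speaker_token_sets, function(sp_tokens) {
    al <- align_tokens(sp_tokens, listener_tokens)
    if (nrow(al$pairs) == 0) stop("no aligned tokens for a speaker")
    actual <- stack_aligned(sp_tokens, listener_tokens, al$pairs,
                            function(t) t$articulatory,
                            function(t) t$articulatory)
    recon <- stack_aligned(sp_tokens, listener_tokens, al$pairs,
                           function(t) t$reconstructed,
                           function(t) t$articulatory)
    c(listener_vs_speaker = mean(columnwise_pearson(actual$b, actual$a),
                                 na.rm = TRUE),
      listener_vs_reconstructed = mean(columnwise_pearson(recon$b, recon$a),
                                       na.rm = TRUE),
      speaker_vs_reconstructed = mean(
        columnwise_pearson(
          do.call(rbind, lapply(sp_tokens, `[[`, "articulatory")),
          do.call(rbind, lapply(sp_tokens, `[[`, "reconstructed"))),
        na.rm = TRUE))
  })
  per_speaker <- do.call(rbind, per_speaker)
  structure(list(coherence = c1,
                 listener_vs_speaker = mean(per_speaker[, 1]),
                 listener_vs_reconstructed = mean(per_speaker[, 2]),
                 speaker_vs_reconstructed = mean(per_speaker[, 3]),
                 per_speaker = per_speaker),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(paste0("<correlation_report>\n",
                     "  coherence (intra-subject):        %.3f\n",
                     "  listener vs speaker actual:       %.3f\n",
                     "  listener actual vs reconstructed: %.3f\n",
                     "  speaker actual vs reconstructed:  %.3f\n"),
              x$coherence, x$listener_vs_speaker,
              x$listener_vs_reconstructed, x$speaker_vs_reconstructed))
  invisible(x)
}

#' Aggregate a results table over subject combinations
#'
#' Mean error per strategy x setting cell, optionally recomputed after
#' dropping every combination that involves the given subjects as listener,
#' S1 or S2.
#'
#' @param results data frame with columns `strategy`, `setting`, `listener`,
#'   `s1`, `s2` (NA for T1), `error`.
#' @param drop_subjects optional character vector of subject ids to exclude.
#' @return data frame strategy x setting with `mean_error`, `n_cells` and,
#'   when subjects are dropped, `mean_error_dropped`, `n_cells_dropped`.
#' @export
aggregate_results <- function(results, drop_subjects = NULL) {
  cells <- unique(results[, c("strategy", "setting")])
  agg_one <- function(df) {
    data.frame(mean_error = mean(df$error), n_cells = nrow(df))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$strategy == cells$strategy[i] &
      results$setting == cells$setting[i]
    if (!any(sel)) stop("missing cell: ", cells$strategy[i], " x ",
                        cells$setting[i])
    row <- cbind(cells[i, , drop = FALSE], agg_one(results[sel, ]))
    if (!is.null(drop_subjects)) {
      keep <- sel & !(results$listener %in% drop_subjects |
                        results$s1 %in% drop_subjects |
                        (!is.na(results$s2) & results$s2 %in% drop_subjects))
      if (!any(keep)) stop("dropping removes all combinations in cell: ",
                           cells$strategy[i], " x ", cells$setting[i])
      d <- agg_one(results[keep, ])
      row$mean_error_dropped <- d$mean_error
      row$n_cells_dropped <- d$n_cells
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Pooled McNemar test over several listener cases
#'
#' Concatenates the per-case prediction pairs of two strategies before
#' applying the exact McNemar test.
#'
#' @param preds_a,preds_b lists of prediction data frames (same cases in the
#'   same order).
#' @param alpha significance level.
#' @return an `mcnemar_result`.
#' @export
pooled_mcnemar <- function(preds_a, preds_b, alpha = 0.05) {
  mcnemar_exact(do.call(rbind, preds_a), do.call(rbind, preds_b),
                alpha = alpha)
}
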