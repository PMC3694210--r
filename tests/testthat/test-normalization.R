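test_that("subject splits are stratified by word type and deterministic", {
  tok <- subset_tokens(tiny_tokens(), "s01")   # 4 word types x 3 reps
  sp <- split_subject(tok, 1 / 3, seed = 9)
  tri <- token_info(sp$train); tei <- token_info(sp$test)
  # exactly 1 repetition per word type in train, 2 in test
  expect_equal(as.vector(table(unique(tri[, c("word_type", "repetition")])$word_type)),
               rep(1L, 4))
  expect_equal(as.vector(table(unique(tei[, c("word_type", "repetition")])$word_type)),
               rep(2L, 4))
  # 2/3 split complements the 1/3 split sizes
  sp2 <- split_subject(tok, 2 / 3, seed = 9)
  expect_equal(length(sp2$train), length(sp$test))
  expect_equal(length(sp2$test), length(sp$train))
  # determinism
  sp3 <- split_subject(tok, 1 / 3, seed = 9)
  expect_identical(token_info(sp3$train), tri)
  # word type with < 2 repetitions is rejected by name
  info <- token_info(tok)
  few <- structure(tok[!(info$word_type == "w02" & info$repetition > 1)],
                   class = "artimap_tokens")
  expect_error(split_subject(few, 1 / 3, seed = 1), "w02")
})

test_that("mapping pairs enumerate cross-subject rows exactly", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  # restrict to 2 word types x 2 repetitions
  keep <- function(tl) {
    info <- token_info(tl)
    structure(tl[info$word_type %in% c("w01", "w02") & info$repetition <= 2],
              class = "artimap_tokens")
  }
  lt2 <- keep(lt); s12 <- keep(s1)
  n_phones <- sum(token_info(
    structure(s12[token_info(s12)$repetition == 1], class = "artimap_tokens")
  )$position > 0)
  pairs <- build_mapping_pairs("MotorNorm", lt2, s12)
  cross <- pairs$provenance[pairs$provenance$role == "cross", ]
  # one row per (word token, phone, frame): 2 word types x 2 reps x phones x 10
  expect_equal(nrow(cross), 2 * n_phones * 10)
  expect_equal(pairs$dropped, 0)
  expect_equal(nrow(pairs$x), nrow(pairs$y))
  expect_equal(ncol(pairs$x), 180)
  expect_equal(ncol(pairs$y), 42)
  # self rows: one per listener token frame
  expect_equal(sum(pairs$provenance$role == "self"), length(lt2) * 10)
  # articulatory outputs only ever come from the listener
  expect_true(all(pairs$provenance$out_subject == "s01"))
  expect_silent(assert_listener_only_articulatory(pairs, "s01"))
})

test_that("tokens without an aligned listener partner are dropped and counted", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  # remove one word type from the listener entirely
  li <- token_info(lt)
  lt_missing <- structure(lt[li$word_type != "w03"], class = "artimap_tokens")
  pairs <- build_mapping_pairs("AcouNorm_A", lt_missing, s1)
  s1i <- token_info(s1)
  expect_equal(pairs$dropped, sum(s1i$word_type == "w03"))
  expect_false("w03" %in% pairs$provenance$word_type)
  # brute-force row count for the remaining word types
  expect_equal(nrow(pairs$x), sum(s1i$word_type != "w03") * 10)
})

test_that("AcouNorm_B contains AcouNorm_A's cross rows plus identity rows", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  pa <- build_mapping_pairs("AcouNorm_A", lt, s1)
  pb <- build_mapping_pairs("AcouNorm_B", lt, s1)
  expect_true(all(pa$provenance$role == "cross"))
  keyify <- function(p) with(p, paste(in_subject, out_subject, word_type,
                                      in_repetition, out_repetition, phone,
                                      position, frame))
  expect_true(all(keyify(pa$provenance) %in% keyify(pb$provenance)))
  self <- pb$provenance[pb$provenance$role == "self", ]
  expect_equal(nrow(self), length(lt) * 10)
  # identity rows: the output frame equals the input's center frame
  self_rows <- which(pb$provenance$role == "self")
  expect_equal(pb$y[self_rows, ], pb$x[self_rows, 61:120],
               ignore_attr = TRUE)
  # output widths per strategy
  expect_equal(ncol(pa$y), 60)
  pc <- build_mapping_pairs("AcouNorm_C", lt, s1, reduced = reduced_set(5))
  expect_equal(ncol(pc$y), 15)
  expect_error(build_mapping_pairs("AcouNorm_C", lt, s1), "reduced")
})

test_that("alignment symmetry: swapping roles preserves the cross row count", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  ab <- build_mapping_pairs("AcouNorm_A", lt, s1)
  ba <- build_mapping_pairs("AcouNorm_A", s1, lt)
  expect_equal(nrow(ab$x), nrow(ba$x))
})

test_that("MotorNorm rejects listeners without articulatory data", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  lt_bare <- structure(lapply(lt, function(t) {
    t$articulatory <- NULL
    t
  }), class = "artimap_tokens")
  expect_error(build_mapping_pairs("MotorNorm", lt_bare, s1),
               "articulatory")
})

test_that("trained mappings recover a known linear articulatory map", {
  # synthetic pairs from a fixed linear map, zero noise
  set.seed(20)
  n <- 600
  x <- matrix(stats::rnorm(n * 12), n, 12)
  A <- matrix(stats::rnorm(12 * 5, sd = 0.6), 12, 5)
  y <- x %*% A
  spec <- net_spec(12, c(30, 30, 30), 5, "linear")
  cfg <- train_config(pretrain_epochs = 5, finetune_epochs = 120,
                      lr_finetune = 0.15, seed = 13)
  hold <- 501:600
  net <- train_dnn(x[-hold, ], y[-hold, ], spec, cfg)
  pred <- predict(net, x[hold, ])
  cors <- vapply(1:5, function(j) stats::cor(pred[, j], y[hold, j]),
                 numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("reconstruct attaches deterministic blocks and preserves counts", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  pairs <- build_mapping_pairs("AcouNorm_B", lt, s1)
  net <- train_mapping(pairs, train_config(pretrain_epochs = 2,
                                           finetune_epochs = 6, seed = 3),
                       hidden = c(40, 40, 40))
  r1 <- reconstruct(net, s1)
  r2 <- reconstruct(net, s1)
  expect_equal(length(r1), length(s1))
  expect_identical(lapply(r1, `[[`, "reconstructed"),
                   lapply(r2, `[[`, "reconstructed"))
  expect_true(all(vapply(r1, function(t)
    identical(dim(t$reconstructed), c(10L, 60L)), logical(1))))
  # originals untouched
  expect_identical(lapply(r1, `[[`, "acoustic"), lapply(s1, `[[`, "acoustic"))
})

test_that("classifier dataset widths and provenance follow the strategy table", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  sp <- split_subject(subset_tokens(tok, "s02"), 2 / 3, seed = 2)
  cfg <- train_config(pretrain_epochs = 2, finetune_epochs = 5, seed = 4)
  widths <- list(NoNorm = 600, AcouNorm_A = 600, AcouNorm_B = 1200,
                 AcouNorm_C = 600 + 30 * 5, MotorNorm = 1020)
  for (strategy in names(widths)) {
    lt_s <- lt; tr_s <- sp$train; te_s <- sp$test
    if (strategy != "NoNorm") {
      red <- if (strategy == "AcouNorm_C") reduced_set(5) else NULL
      pairs <- build_mapping_pairs(strategy, lt, sp$train, reduced = red)
      net <- train_mapping(pairs, cfg, hidden = c(30, 30, 30))
      lt_s <- reconstruct(net, lt)
      tr_s <- reconstruct(net, sp$train)
      te_s <- reconstruct(net, sp$test)
    }
    ds <- assemble_classifier_dataset(strategy, lt_s, tr_s, te_s)
    expect_equal(ncol(ds$x_train), widths[[strategy]])
    expect_equal(ncol(ds$x_test), widths[[strategy]])
    expect_equal(nrow(ds$x_train), length(lt) + length(sp$train))
    expect_equal(nrow(ds$x_test), length(sp$test))
    expect_equal(ds$labels_test, token_info(sp$test)$phone)
    # test rows come only from the held-out speaker
    expect_true(all(ds$provenance_test$subject == "s02"))
  }
  # missing reconstructions are rejected
  expect_error(assemble_classifier_dataset("MotorNorm", lt, sp$train,
                                           sp$test), "reconstruct")
})

test_that("scenario enumeration matches the combinatorial count", {
  ids5 <- sprintf("s%02d", 1:5)
  en <- enumerate_scenarios(ids5, "s03")
  expect_equal(nrow(en$pairs), 4)
  expect_equal(nrow(en$triplets), 12)
  expect_false("s03" %in% c(en$triplets$s1, en$triplets$s2))
  expect_true(all(en$triplets$s1 != en$triplets$s2))
  en2 <- enumerate_scenarios(c("a", "b"), "a")
  expect_equal(nrow(en2$pairs), 1)
  expect_equal(nrow(en2$triplets), 0)
  for (n in 2:6) {
    ids <- letters[1:n]
    en_n <- enumerate_scenarios(ids, "a")
    # brute force over all ordered pairs
    brute <- 0L
    for (x in ids) for (y in ids)
      if (x != "a" && y != "a" && x != y) brute <- brute + 1L
    expect_equal(nrow(en_n$pairs), n - 1)
    expect_equal(nrow(en_n$triplets), brute)
    expect_equal(nrow(en_n$triplets), (n - 1) * (n - 2))
  }
  expect_error(enumerate_scenarios(ids5, "zz"), "unknown")
})

test_that("the reduced-set selection matches an exhaustive scan", {
  # constructed curve with a known first crossing
  errs <- c(0.50, 0.45, 0.39, 0.37, 0.36, rep(0.35, 15))
  rs <- select_k_from_errors(errs, 0.40)
  expect_equal(rs$k, 3)
  expect_equal(rs$columns, c(1:3, 21:23, 41:43))
  expect_false(rs$warning_flag)
  # monotone curve: minimal k by brute-force scan
  set.seed(33)
  for (trial in 1:20) {
    errs <- sort(stats::runif(20, 0.1, 0.6), decreasing = TRUE)
    e_af <- stats::runif(1, 0.05, 0.7)
    rs <- select_k_from_errors(errs, e_af)
    brute <- Inf
    for (k in 20:1) if (errs[k] <= e_af) brute <- k
    if (is.infinite(brute)) {
      expect_equal(rs$k, 20)
      expect_true(rs$warning_flag)
    } else {
      expect_equal(rs$k, brute)
      expect_false(rs$warning_flag)
    }
  }
})

test_that("shuffling word types degrades the learned mapping (acoustic bootstrap)", {
  tok <- clean_tokens()
  lt <- subset_tokens(tok, "s01")
  s1 <- subset_tokens(tok, "s02")
  cfg <- train_config(pretrain_epochs = 3, finetune_epochs = 20, seed = 6)
  heldout_cor <- function(s1_tokens) {
    sp <- split_subject(s1_tokens, 2 / 3, seed = 8)
    pairs <- build_mapping_pairs("MotorNorm", lt, sp$train)
    net <- train_mapping(pairs, cfg, hidden = c(60, 60, 60))
    rec <- reconstruct(net, sp$test)
    al <- artimap:::align_tokens(rec, lt)
    st <- artimap:::stack_aligned(rec, lt, al$pairs,
                                  function(t) t$reconstructed,
                                  function(t) t$articulatory)
    mean(artimap:::columnwise_pearson(st$b, st$a), na.rm = TRUE)
  }
  aligned <- heldout_cor(s1)
  # break the acoustic bootstrap: train on the same inputs but with the
  # listener outputs permuted across word tokens (fixed seed)
  sp <- split_subject(s1, 2 / 3, seed = 8)
  pairs <- build_mapping_pairs("MotorNorm", lt, sp$train)
  set.seed(10)
  perm <- sample.int(nrow(pairs$y))
  pairs$y <- pairs$y[perm, , drop = FALSE]
  net_broken <- train_mapping(pairs, cfg, hidden = c(60, 60, 60))
  rec <- reconstruct(net_broken, sp$test)
  al <- artimap:::align_tokens(rec, lt)
  st <- artimap:::stack_aligned(rec, lt, al$pairs,
                                function(t) t$reconstructed,
                                function(t) t$articulatory)
  broken <- mean(artimap:::columnwise_pearson(st$b, st$a), na.rm = TRUE)
  expect_lt(broken, aligned)
})
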