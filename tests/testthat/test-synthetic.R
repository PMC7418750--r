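test_that("corpus generation is seeded, density-controlled, and span-consistent", {
  w <- world_spec(k = 2, density = 0.5, seed = 7)
  g1 <- generate_corpus(w, 200, seed = 5)
  g2 <- generate_corpus(w, 200, seed = 5)
  expect_identical(lapply(g1$corpus, function(d)
    lapply(d$sentences, function(s) s$tokens)),
    lapply(g2$corpus, function(d) lapply(d$sentences, function(s) s$tokens)))
  expect_identical(g1$gold_spans, g2$gold_spans)
  # density 0 -> no spans
  w0 <- world_spec(density = 0, seed = 7)
  expect_equal(nrow(generate_corpus(w0, 50, seed = 1)$gold_spans), 0L)
  # span count within the binomial 99% interval of its expectation
  n_spans <- nrow(g1$gold_spans)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_spans, bounds[1]); expect_lte(n_spans, bounds[2])
  # recorded spans carry the inserted term tokens (not background)
  sents <- weakner:::corpus_sentences(g1$corpus)
  keys <- paste(vapply(sents, function(s) s$doc_id, ""),
                vapply(sents, function(s) s$sent_index, 1L))
  sp <- g1$gold_spans[1:10, ]
  for (r in seq_len(nrow(sp))) {
    s <- sents[[match(paste(sp$doc_id[r], sp$sent_index[r]), keys)]]
    toks <- s$tokens[sp$token_start[r]:(sp$token_end[r] - 1L)]
    expect_false(any(toks %in% w$background))
  }
})

test_that("a perfect source labels exactly the gold spans", {
  w <- world_spec(k = 1, density = 0.6, seed = 11)
  g <- generate_corpus(w, 150, seed = 2)
  srcs <- generate_sources(w, list(source_spec("perfect", recall = 1)), seed = 3)
  lf <- lf_semantic_type(srcs$perfect, class_map = attr(srcs, "class_map"))
  lm <- build_label_matrix(list(lf), g$corpus)
  gold <- unlist(lapply(g$gold_tags, weakner:::tag_class))
  votes <- lm$L[, 1]
  expect_equal(votes == 1L, gold == 1L)
})

test_that("the precision proxy yields the intended word-level precision", {
  sc <- scenario_mixed_quality()
  g <- generate_corpus(sc$world, sc$n_sentences, seed = 1)
  srcs <- generate_sources(sc$world, sc$specs, seed = 501)
  cm <- attr(srcs, "class_map")
  lf <- lf_semantic_type(srcs$noisy_highrecall, class_map = cm,
                         unmatched = "negative")
  lm <- build_label_matrix(list(lf), g$corpus)
  gold <- unlist(lapply(g$gold_tags, weakner:::tag_class))
  prec <- sum(lm$L[, 1] == 1L & gold == 1L) / sum(lm$L[, 1] == 1L)
  expect_equal(prec, 0.65, tolerance = 0.05 / 0.65)
  # two sources from one seed stream are reproducible and distinct
  srcs2 <- generate_sources(sc$world, sc$specs, seed = 501)
  expect_identical(srcs$precise_a$entries, srcs2$precise_a$entries)
  expect_false(identical(srcs$precise_a$entries, srcs$precise_b$entries))
})

test_that("raw label-matrix generator obeys its stated identities", {
  # accuracy 1, no abstain -> column equals truth
  g <- generate_label_matrix(500, c(0.999999, 0.8), c(0, 0.2), seed = 1)
  expect_equal(g$L[, 1], g$truth)
  # accuracy 0.5 binary -> empirical agreement ~ 0.5
  g2 <- generate_label_matrix(10000, c(0.5, 0.9), c(0, 0), seed = 2)
  expect_equal(mean(g2$L[, 1] == g2$truth), 0.5, tolerance = 0.04)
  # moment identity E[l_i l_j] = a_i a_j (on +/-1 scale) at n = 50000
  acc <- c(0.85, 0.7)
  g3 <- generate_label_matrix(50000, acc, c(0, 0), seed = 3)
  B <- weakner:::binarize_class(g3$L, 1L)
  a <- 2 * acc - 1
  expect_equal(pairwise_moments(B)$M[1, 2], a[1] * a[2],
               tolerance = 0.02 / (a[1] * a[2]))
  # conditional independence given truth: near-zero partial correlation
  resid <- (B == rep(2 * (g3$truth == 1) - 1, 2)) * 1
  expect_lt(abs(stats::cor(resid[, 1], resid[, 2])), 0.02)
})

test_that("the span-disagreement fixture behaves as documented", {
  fx <- span_disagreement_fixture()
  lm <- build_label_matrix(fx$lfs, fx$corpus)
  mv <- majority_vote(lm, default_class = 0L)
  # majority vote keeps only the head word "diabetes"
  expect_equal(which(mv == 1L), 5L)
  # label model with accuracies favoring the full-term sources recovers it
  acc <- ifelse(lm$lf_names %in% fx$full_term_sources, 0.9, 0.7)
  model <- label_model(acc, k = 1)
  expect_equal(which(predict(model, lm) == 1L), 5:7)
  # fixture round-trips through file formats unchanged
  tmp_c <- tempfile(fileext = ".jsonl")
  write_jsonl_corpus(fx$corpus, tmp_c)
  back <- read_jsonl_corpus(tmp_c)
  expect_equal(back[[1]]$sentences[[1]]$tokens,
               fx$corpus[[1]]$sentences[[1]]$tokens)
  tmp_t <- tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(fx$terminologies, function(v)
    data.frame(term = v$entries$term, source = v$name,
               semantic_type = v$entries$type)))
  utils::write.table(rows, tmp_t, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- load_terminologies(tmp_t)
  expect_setequal(back_t$chv$entries$term, fx$terminologies$chv$entries$term)
})
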