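test_that("normalize_term lowercases, preserves abbreviations, and rejects junk", {
  expect_equal(normalize_term("Aspirin"), "aspirin")
  expect_equal(normalize_term("DMD"), "DMD")          # abbreviation keeps case
  expect_equal(normalize_term("Lung Cancer"), c("lung", "cancer"))
  expect_null(normalize_term("a"))                    # single character
  expect_null(normalize_term("42"))                   # pure number
  expect_null(normalize_term("the"))                  # stopword
  expect_null(normalize_term("of the"))               # all stopwords
  # mixed-case short token with >= 2 uppercase letters keeps case
  expect_equal(normalize_term("HbA1c"), "HbA1c")
  # long capitalized word is not an abbreviation
  expect_equal(normalize_term("Pneumonia"), "pneumonia")
})

test_that("terminology construction normalizes and counts rejections", {
  ent <- data.frame(term = c("Aspirin", "the", "Ibuprofen"),
                    type = c("T1", "T1", "T1"))
  v <- terminology("v1", ent)
  expect_equal(nrow(v$entries), 2L)
  expect_equal(attr(v, "n_rejected"), 1L)
  # a term mapped to two types keeps both assignments
  ent2 <- data.frame(term = c("lead", "lead"), type = c("T1", "T2"))
  v2 <- terminology("v2", ent2)
  expect_equal(sort(v2$entries$type), c("T1", "T2"))
  expect_warning(terminology("empty", data.frame(term = "a", type = "T1")),
                 "empty")
})

test_that("terminology TSV loading splits sources and validates columns", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("term\tsource\tsemantic_type",
               "Aspirin\tvA\tT1", "the\tvA\tT1", "fever\tvB\tT1"), tmp)
  out <- load_terminologies(tmp)
  expect_named(out, c("vA", "vB"))
  expect_equal(out$vA$entries$term, "aspirin")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("term\tsemantic_type", "x\tT1"), bad)
  expect_error(load_terminologies(bad), "source")
})

test_that("type distributions are count-normalized with detectable ties", {
  cm <- c(T1 = 1L, T2 = 2L, T0 = 0L)
  vs <- list(toy_terminology("a", list(`1` = "fever")),
             toy_terminology("b", list(`1` = "fever")),
             toy_terminology("c", list(`1` = "fever")))
  d <- build_type_distribution(vs, cm, k = 2)
  expect_equal(unname(d$probs["fever", "1"]), 1)
  # 2 sources disease, 1 chemical -> (2/3, 1/3)
  vs2 <- list(toy_terminology("a", list(`1` = "lead")),
              toy_terminology("b", list(`1` = "lead")),
              toy_terminology("c", list(`2` = "lead")))
  d2 <- build_type_distribution(vs2, cm, k = 2)
  expect_equal(unname(d2$probs["lead", c("1", "2")]), c(2 / 3, 1 / 3))
  # exact tie
  vs3 <- list(toy_terminology("a", list(`1` = "lead")),
              toy_terminology("b", list(`2` = "lead")))
  d3 <- build_type_distribution(vs3, cm, k = 2)
  expect_equal(unname(d3$probs["lead", "1"]), unname(d3$probs["lead", "2"]))
  # rows are probability vectors
  expect_true(all(abs(rowSums(d3$probs) - 1) < 1e-9))
})

test_that("coverage ranking matches a brute-force document scan", {
  set.seed(3)
  vocab <- c("alpha", "beta", "gamma", "delta", "fever", "cough", "rash")
  docs <- lapply(1:10, function(i) {
    toks <- sample(vocab, sample(3:6, 1), replace = TRUE)
    wn_document(paste0("d", i), NA_character_, list(token_sequence(toks)))
  })
  vs <- list(toy_terminology("vb", list(`1` = c("fever", "cough"))),
             toy_terminology("va", list(`1` = c("rash", "delta", "beta"))))
  ranked <- rank_by_coverage(vs, docs)
  # oracle: per term, count documents containing it
  score <- function(terms) sum(sapply(terms, function(t)
    sum(sapply(docs, function(d) t %in% d$sentences[[1]]$tokens))))
  expected <- c(vb = score(c("fever", "cough")),
                va = score(c("rash", "delta", "beta")))
  got <- attr(ranked, "scores")
  expect_equal(sort(got, decreasing = TRUE), sort(expected, decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(unname(got[order(names(got))]), unname(expected[order(names(expected))]))
  # invariant to document order
  ranked2 <- rank_by_coverage(vs, rev(docs))
  expect_equal(attr(ranked2, "scores"), attr(ranked, "scores"))
  # empty corpus: all zero, alphabetical order
  r0 <- rank_by_coverage(vs, list())
  expect_equal(vapply(r0, function(v) v$name, ""), c("va", "vb"))
})

test_that("partitioning conserves terms across label sources", {
  vs <- lapply(1:4, function(i)
    toy_terminology(paste0("v", i),
                    list(`1` = paste0("term", i, letters[1:3]))))
  p <- partition_sources(vs, 2)
  expect_length(p$individual, 2L)
  expect_equal(p$merged$name, "merged_remainder")
  all_terms <- unlist(lapply(vs, function(v) v$entries$term))
  covered <- c(unlist(lapply(p$individual, function(v) v$entries$term)),
               p$merged$entries$term)
  expect_setequal(covered, all_terms)
  expect_equal(length(covered), length(all_terms))  # exactly once
  # boundary cases
  expect_null(partition_sources(vs, 4)$merged)
  p1 <- partition_sources(vs, 1)
  expect_length(p1$individual, 1L)
  expect_equal(length(unique(p1$merged$entries$term)), 9L)
  expect_error(partition_sources(vs, 0), "s must be")
  expect_error(partition_sources(vs, 5), "s must be")
})
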