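cm2 <- c(T0 = 0L, T1 = 1L, T2 = 2L)

test_that("semantic-type LF prefers longest matches and abstains on ties", {
  v <- toy_terminology("v", list(`1` = "lung cancer", `2` = "lung"))
  lf <- lf_semantic_type(v, class_map = cm2)
  doc <- toy_doc("d", list(c("stage", "II", "lung", "cancer", "found")))
  votes <- apply_lf(lf, doc)[[1]]
  expect_equal(votes, c(-1L, -1L, 1L, 1L, -1L))
  # no ontology term -> all unmatched value
  doc2 <- toy_doc("d", list(c("nothing", "to", "see")))
  expect_equal(apply_lf(lf, doc2)[[1]], rep(-1L, 3L))
  lf_neg <- lf_semantic_type(v, class_map = cm2, unmatched = "negative")
  expect_equal(apply_lf(lf_neg, doc2)[[1]], rep(0L, 3L))
  # exact 50/50 type tie -> abstain on the matched tokens
  vs <- list(toy_terminology("a", list(`1` = "lead")),
             toy_terminology("b", list(`2` = "lead")))
  tm <- build_type_distribution(vs, cm2)
  lf_tie <- lf_semantic_type(toy_terminology("a", list(`1` = "lead")),
                             type_map = tm)
  doc3 <- toy_doc("d", list(c("high", "lead", "levels")))
  expect_equal(apply_lf(lf_tie, doc3)[[1]], c(-1L, -1L, -1L))
})

test_that("abbreviation terms match case-sensitively", {
  v <- toy_terminology("v", list(`1` = c("DMD", "aspirin")))
  lf <- lf_semantic_type(v, class_map = cm2)
  doc <- toy_doc("d", list(c("dmd", "DMD", "Aspirin")))
  expect_equal(apply_lf(lf, doc)[[1]], c(-1L, 1L, 1L))
})

test_that("slot-filled patterns label compositional mentions", {
  v <- toy_terminology("v", list(`1` = c("Tylenol", "Acetaminophen")))
  lf <- lf_semantic_type(v, class_map = cm2, slot_patterns = TRUE)
  doc <- toy_doc("d", list(c("gave", "Tylenol", "(", "Acetaminophen", ")", "today")))
  votes <- apply_lf(lf, doc)[[1]]
  expect_equal(votes, c(-1L, 1L, 1L, 1L, 1L, -1L))
  # out-of-ontology inner slot: pattern does not fire, parens stay unmatched
  doc2 <- toy_doc("d", list(c("gave", "Tylenol", "(", "hello", ")", "today")))
  votes2 <- apply_lf(lf, doc2)[[1]]
  expect_equal(votes2, c(-1L, 1L, -1L, -1L, -1L, -1L))
  # a longer plain ontology match covering the region wins over the pattern
  v3 <- toy_terminology("v", list(`1` = c("ab", "cd"),
                                  `2` = "ab ( cd ) ef"))
  lf3 <- lf_semantic_type(v3, class_map = cm2, slot_patterns = TRUE)
  doc3 <- toy_doc("d", list(c("ab", "(", "cd", ")", "ef")))
  expect_equal(apply_lf(lf3, doc3)[[1]], rep(2L, 5L))
})

test_that("synset LF requires two distinct member matches per document", {
  syn <- data.frame(concept_id = "C1",
                    term = c("Duchenne muscular dystrophy", "DMD"),
                    class = 1L)
  lf <- lf_synset(syn)
  doc_both <- toy_doc("d", list(
    c("Duchenne", "muscular", "dystrophy", "was", "diagnosed"),
    c("DMD", "progressed"), c("DMD", "therapy")))
  votes <- apply_lf(lf, doc_both)
  expect_equal(votes[[1]][1:3], rep(1L, 3))
  expect_equal(votes[[2]][1], 1L)      # all occurrences labeled
  expect_equal(votes[[3]][1], 1L)
  # only one member present -> abstain everywhere
  doc_one <- toy_doc("d", list(c("DMD", "progressed")))
  expect_equal(apply_lf(lf, doc_one)[[1]], c(-1L, -1L))
  # monotone: adding text never removes a firing
  doc_more <- toy_doc("d", c(lapply(doc_both$sentences, function(s) s$tokens),
                             list(c("extra", "words"))))
  votes_more <- apply_lf(lf, doc_more)
  expect_equal(votes_more[1:3], votes)
  expect_error(lf_synset(data.frame(concept_id = "C1", term = "only one",
                                    class = 1L)), "fewer than 2")
})

test_that("Schwartz-Hearst links defined short forms to the dictionary", {
  syn <- data.frame(concept_id = "C2", term = c("heart failure", "cardiac failure"),
                    class = 1L)
  lf <- lf_synset(syn, schwartz_hearst = TRUE)
  doc <- toy_doc("d", list(
    c("history", "of", "heart", "failure", "(", "HF", ")", "noted"),
    c("HF", "worsened")))
  votes <- apply_lf(lf, doc)
  expect_equal(votes[[1]][6], 1L)   # the defining mention
  expect_equal(votes[[2]][1], 1L)   # later occurrences
  expect_equal(votes[[1]][3:4], c(1L, 1L))  # long form labeled too
  # without SH mode the out-of-dictionary "HF" cannot fire the synset
  lf0 <- lf_synset(syn, schwartz_hearst = FALSE)
  votes0 <- apply_lf(lf0, doc)
  expect_equal(votes0[[2]][1], -1L)
})

test_that("pattern LFs label matched runs and abstain elsewhere", {
  lf_punct <- lf_pattern("punct", class = 0L, dictionary = c(",", "."))
  doc <- toy_doc("d", list(c("fever", ",", "cough")))
  expect_equal(apply_lf(lf_punct, doc)[[1]], c(-1L, 0L, -1L))
  lf_dose <- lf_pattern("dose", class = 2L, regex = "[0-9]+ ?mg")
  doc2 <- toy_doc("d", list(c("took", "500", "mg", "today")))
  expect_equal(apply_lf(lf_dose, doc2)[[1]], c(-1L, 2L, 2L, -1L))
  doc3 <- toy_doc("d", list(c("nothing", "here")))
  expect_equal(apply_lf(lf_dose, doc3)[[1]], c(-1L, -1L))
  expect_error(lf_pattern("bad", class = 1L, regex = "[unclosed"),
               "invalid regex")
})

test_that("context-window LF finds cues and datetime relations", {
  lf <- lf_context_window("negex", patterns = list(
    list(trigger = "no evidence of", direction = "left", window = 4L,
         class = 2L)))
  doc <- toy_doc("d", list(c("no", "evidence", "of", "pneumonia", "today")))
  spans <- span_table("d", 1L, 4L, 5L, 1L)
  expect_equal(apply_span_lf(lf, doc, spans), 2L)
  # no trigger in window -> abstain
  doc2 <- toy_doc("d", list(c("clear", "evidence", "of", "pneumonia")))
  expect_equal(apply_span_lf(lf, doc2, spans), -1L)

  # datetime heuristic: nearest date in token distance decides the class
  toks <- c(rep("w", 4), "2020-01-05", rep("w", 4), "fever",
            rep("w", 19), "2020-03-10", "w")
  dtlf <- lf_context_window("doctime", datetime_rule = list(
    window = 25L, classes = list(before = 1L, after = 2L, overlap = 3L)))
  doc3 <- wn_document("d", NA_character_, list(token_sequence(toks)),
                      timestamp = as.Date("2020-02-01"))
  sp3 <- span_table("d", 1L, 10L, 11L, 1L)
  # nearest date (distance 5) is older than the document date -> before
  expect_equal(apply_span_lf(dtlf, doc3, sp3), 1L)
  # missing timestamp -> abstain with one message per document
  doc4 <- wn_document("d", NA_character_, list(token_sequence(toks)))
  expect_message(v <- apply_span_lf(dtlf, doc4, sp3), "no timestamp")
  expect_equal(v, -1L)
})

test_that("label matrices line up with corpus tokens", {
  v <- toy_terminology("v", list(`1` = "pneumonia"))
  lf <- lf_semantic_type(v, class_map = cm2)
  doc <- toy_doc("d", list(c("no", "evidence", "of", "pneumonia")))
  lm <- build_label_matrix(list(lf), list(doc))
  expect_equal(dim(lm$L), c(4L, 1L))
  expect_equal(lm$L[, 1], c(-1L, -1L, -1L, 1L))
  expect_equal(lm$index$token_index, 1:4)
  # abstain-only LF column is all -1
  lf_none <- lf_pattern("nothing", class = 1L, dictionary = "zzz")
  lm2 <- build_label_matrix(list(lf, lf_none), list(doc))
  expect_equal(lm2$L[, "nothing"], rep(-1L, 4L))
  expect_error(build_label_matrix(list(lf, lf), list(doc)), "duplicate")
  # round trip through TSV
  tmp <- tempfile(fileext = ".tsv")
  write_label_matrix(lm2, tmp)
  back <- read_label_matrix(tmp)
  expect_equal(unname(back$L), unname(lm2$L))
})

test_that("longest-match labeling is invariant to term insertion order", {
  doc <- toy_doc("d", list(c("acute", "lung", "cancer", "stage")))
  for (terms in list(c("lung cancer", "lung"), c("lung", "lung cancer"))) {
    v <- terminology("v", data.frame(term = terms, type = "T1"))
    lf <- lf_semantic_type(v, class_map = cm2)
    expect_equal(apply_lf(lf, doc)[[1]], c(-1L, 1L, 1L, -1L))
  }
})
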