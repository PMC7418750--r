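# shared test fixtures, built in code

# a tiny pre-tokenized document
toy_doc <- function(doc_id = "d1",
                    sentences = list(c("no", "evidence", "of", "pneumonia"),
                                     c("chest", "pain", "and", "fever")),
                    timestamp = NULL) {
  wn_document(doc_id, NA_character_,
              lapply(sentences, token_sequence), timestamp = timestamp)
}

# terminology from a named list: class -> terms (uses types T0..Tk)
toy_terminology <- function(name, terms_by_class) {
  ent <- do.call(rbind, lapply(names(terms_by_class), function(c)
    data.frame(term = terms_by_class[[c]], type = paste0("T", c),
               stringsAsFactors = FALSE)))
  terminology(name, ent)
}

toy_class_map <- function(k = 1L) stats::setNames(0:k, paste0("T", 0:k))

# brute-force posterior under the generative model: truth ~ prior; source i
# abstains w.p. (1 - propensity_i) independently of truth, votes the truth
# w.p. acc_i, else uniformly among the wrong classes
brute_force_posterior <- function(votes, acc, prior, propensity) {
  k <- length(prior) - 1L
  joint <- vapply(0:k, function(y) {
    p <- prior[y + 1L]
    for (i in seq_along(votes)) {
      v <- votes[i]
      p <- p * if (v == -1L) (1 - propensity[i])
      else propensity[i] * (if (v == y) acc[i] else (1 - acc[i]) / max(1, k))
    }
    p
  }, numeric(1))
  joint / sum(joint)
}

# random non-adjacent span set over a sequence of length n (same-class
# spans separated by at least one O token)
random_span_set <- function(n, k = 2L, doc_id = "d", sent = 1L) {
  starts <- integer(0); ends <- integer(0); classes <- integer(0)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.35) {
      len <- sample(1:min(3L, n - i + 1L), 1)
      starts <- c(starts, i); ends <- c(ends, i + len)
      classes <- c(classes, sample(seq_len(k), 1))
      i <- i + len + 1L   # gap guarantees non-adjacency
    } else i <- i + 1L
  }
  span_table(rep(doc_id, length(starts)), rep(sent, length(starts)),
             starts, ends, classes)
}
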