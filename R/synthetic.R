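# Seeded generators for corpora, terminologies, and raw label matrices with
# known ground truth: the test bed standing in for license-gated
# terminologies and clinical corpora. All generators are pure functions of
# their spec and seed.

.FUNCTION_WORDS <- c("the", "a", "of", "and", "was", "with", "for", "on",
                     "in", "to", "no", "his", "her", "after", "before",
                     "during", "had", "has", "is", "this")

.SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "ka", "le", "mi", "no", "pu",
                "ra", "se", "ti", "vo", "wa", "xe", "zy", "qua", "bre", "plo")

# suffix morphology by entity class; the realistic hook that lets a
# feature-based classifier generalize to unseen lexicon entries
.CLASS_SUFFIXES <- list(c("itis", "oma", "emia", "osis", "pathy"),
                        c("mab", "pril", "statin", "azole", "cillin"),
                        c("scopy", "plasty", "ectomy", "otomy"),
                        c("gen", "ase", "amine", "idine"))
.MODIFIER_SUFFIXES <- c("al", "ic", "ous")
.BACKGROUND_SUFFIXES <- c("er", "ing", "ment", "tion", "ness")

make_words <- function(n, suffixes, syl_min = 2L, syl_max = 3L) {
  words <- character(0)
  while (length(words) < n) {
    stem <- paste(sample(.SYLLABLES, sample(syl_min:syl_max, 1),
                         replace = TRUE), collapse = "")
    w <- paste0(stem, sample(suffixes, 1))
    words <- unique(c(words, w))
  }
  words[seq_len(n)]
}

#' Specify a synthetic world
#'
#' Defines the generating vocabulary for a synthetic corpus: per-class
#' entity lexicons (with a fraction of multi-token terms and abbreviation
#' synonym groups), a background vocabulary disjoint from the lexicons, the
#' entity density, and the sentence-length distribution.
#'
#' Entity words carry class-specific suffix morphology (e.g. disease-like
#' "-itis", "-oma" endings) and background words carry neutral endings, so
#' surface features are informative, as they are for real biomedical terms.
#'
#' @param k number of entity classes (1..4).
#' @param n_lexicon entity terms per class.
#' @param multi_token_frac fraction of lexicon entries that are 2-3 token
#'   terms (modifier words + head word), exercising longest-match logic.
#' @param abbrev_frac fraction of multi-token terms given an all-caps
#'   abbreviation synonym (a synonym group).
#' @param n_background generated background word types (plus a fixed
#'   function-word list).
#' @param density probability, per entity slot, of inserting an entity span
#'   into a sentence.
#' @param entities_max entity slots per sentence (span count per sentence is
#'   Binomial(`entities_max`, `density`)).
#' @param sent_len integer range (min, max) of background tokens per
#'   sentence.
#' @param seed vocabulary-generation seed.
#' @return object of class `world_spec`.
#' @export
world_spec <- function(k = 1L, n_lexicon = 60L, multi_token_frac = 0.3,
                       abbrev_frac = 0.2, n_background = 120L,
                       density = 0.5, entities_max = 1L,
                       sent_len = c(4L, 8L), seed = 42L) {
  stopifnot(k >= 1L, k <= 4L, density >= 0, density <= 1)
  set.seed(seed)
  modifiers <- make_words(12L, .MODIFIER_SUFFIXES)
  background <- c(.FUNCTION_WORDS, make_words(n_background, .BACKGROUND_SUFFIXES))
  lexicon <- list()
  synsets <- data.frame(concept_id = character(0), term = character(0),
                        class = integer(0), stringsAsFactors = FALSE)
  for (c in seq_len(k)) {
    heads <- make_words(n_lexicon, .CLASS_SUFFIXES[[c]])
    n_multi <- round(multi_token_frac * n_lexicon)
    multi_idx <- seq_len(n_multi)
    terms <- heads
    for (i in multi_idx) {
      nmod <- sample(1:2, 1)
      terms[i] <- paste(c(sample(modifiers, nmod), heads[i]), collapse = " ")
    }
    n_ab <- round(abbrev_frac * n_multi)
    if (n_ab > 0) for (i in seq_len(n_ab)) {
      parts <- strsplit(terms[i], " ")[[1]]
      ab <- toupper(paste(substr(parts, 1, 1), collapse = ""))
      synsets <- rbind(synsets,
                       data.frame(concept_id = sprintf("C%d_%d", c, i),
                                  term = c(terms[i], ab),
                                  class = c, stringsAsFactors = FALSE))
    }
    lexicon[[c]] <- terms
  }
  if (any(unlist(lexicon) %in% background))
    stop("lexicon/background collision")
  structure(list(k = as.integer(k), lexicon = lexicon, synsets = synsets,
                 background = background, modifiers = modifiers,
                 density = density, entities_max = as.integer(entities_max),
                 sent_len = as.integer(sent_len), seed = as.integer(seed)),
            class = "world_spec")
}

#' Generate a synthetic corpus with gold annotations
#'
#' Sentences are sampled from the background vocabulary and entity terms are
#' inserted at the world's density; gold spans (and IO tags) are recorded.
#' Deterministic given the world and seed.
#'
#' @param world a [world_spec()].
#' @param n_sentences number of sentences.
#' @param sents_per_doc sentences per document.
#' @param seed corpus seed.
#' @return list with `corpus` (list of documents), `gold_spans`
#'   ([span_table()]), and `gold_tags` (list of IO tag vectors, one per
#'   sentence in corpus order).
#' @export
generate_corpus <- function(world, n_sentences, sents_per_doc = 5L,
                            seed = 1L) {
  if (world$density > 0 && !length(unlist(world$lexicon)))
    stop("empty lexicon with positive density")
  set.seed(seed)
  all_terms <- unlist(world$lexicon)
  term_class <- rep(seq_len(world$k), times = lengths(world$lexicon))
  docs <- list()
  gold <- list()
  gold_tags <- list()
  n_docs <- ceiling(n_sentences / sents_per_doc)
  si <- 0L
  for (di in seq_len(n_docs)) {
    doc_id <- sprintf("doc%04d", di)
    sents <- list()
    n_here <- min(sents_per_doc, n_sentences - si)
    for (sj in seq_len(n_here)) {
      si <- si + 1L
      nbg <- sample(world$sent_len[1]:world$sent_len[2], 1)
      toks <- sample(world$background, nbg, replace = TRUE)
      n_ent <- stats::rbinom(1, world$entities_max, world$density)
      spans <- span_table()
      if (n_ent > 0) {
        picks <- sample(length(all_terms), n_ent, replace = TRUE)
        at <- sort(sample(0:nbg, n_ent, replace = TRUE), decreasing = TRUE)
        for (e in seq_len(n_ent)) {
          et <- strsplit(all_terms[picks[e]], " ")[[1]]
          toks <- append(toks, et, after = at[e])
        }
        # recompute span positions left-to-right after all insertions
        at_sorted <- rev(at); picks_sorted <- rev(picks)
        pos <- 1L; shift <- 0L
        for (e in seq_along(at_sorted)) {
          et_len <- length(strsplit(all_terms[picks_sorted[e]], " ")[[1]])
          start <- at_sorted[e] + shift + 1L
          spans <- rbind(spans,
                         span_table(doc_id, sj, start, start + et_len,
                                    term_class[picks_sorted[e]]))
          shift <- shift + et_len
        }
      }
      sents[[sj]] <- token_sequence(toks, doc_id = doc_id, sent_index = sj)
      gold[[si]] <- spans
      gold_tags[[si]] <- spans_to_tags(spans, length(toks), "IO")
    }
    docs[[di]] <- wn_document(doc_id, NA_character_, sents)
  }
  list(corpus = docs, gold_spans = do.call(rbind, gold),
       gold_tags = gold_tags)
}

#' Specify a synthetic label source
#'
#' @param name source name.
#' @param recall fraction of the true lexicon the source knows.
#' @param spurious precision proxy: fraction of the background vocabulary
#'   spuriously included as (entity-typed) terms; drives the source's
#'   word-level false-positive rate.
#' @param type_error probability that a known term is assigned a wrong
#'   class's semantic type.
#' @return a `source_spec` list.
#' @export
source_spec <- function(name, recall = 1, spurious = 0, type_error = 0) {
  stopifnot(recall >= 0, recall <= 1, spurious >= 0, spurious <= 1,
            type_error >= 0, type_error <= 1)
  structure(list(name = name, recall = recall, spurious = spurious,
                 type_error = type_error), class = "source_spec")
}

#' Generate noisy terminologies from source specifications
#'
#' Each source samples a recall-fraction of the true lexicon, injects
#' spurious background words as entity terms at the precision-proxy rate,
#' and corrupts semantic-type assignments at the stated rate. Semantic
#' types are `"T0".."Tk"` with the identity class map (see the `class_map`
#' attribute of the result).
#'
#' @param world a [world_spec()].
#' @param specs list of [source_spec()]s.
#' @param seed seed.
#' @return named list of `terminology` objects; attribute `class_map` holds
#'   the matching semantic-type map.
#' @export
generate_sources <- function(world, specs, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  set.seed(seed)
  all_terms <- unlist(world$lexicon)
  term_class <- rep(seq_len(world$k), times = lengths(world$lexicon))
  out <- list()
  for (sp in specs) {
    n_keep <- round(sp$recall * length(all_terms))
    keep <- sort(sample(length(all_terms), n_keep))
    cls <- term_class[keep]
    flip <- stats::runif(length(keep)) < sp$type_error
    if (world$k > 1L && any(flip)) {
      cls[flip] <- vapply(cls[flip], function(c)
        sample(setdiff(seq_len(world$k), c), 1), integer(1))
    } else if (world$k == 1L && any(flip)) {
      cls[flip] <- 0L   # only wrong assignment available: the negative type
    }
    terms <- all_terms[keep]
    n_spur <- round(sp$spurious * length(world$background))
    if (n_spur > 0) {
      spur <- sample(world$background, n_spur)
      terms <- c(terms, spur)
      cls <- c(cls, sample(seq_len(world$k), n_spur, replace = TRUE))
    }
    ent <- data.frame(term = terms, type = paste0("T", cls),
                      stringsAsFactors = FALSE)
    out[[sp$name]] <- terminology(sp$name, ent)
  }
  cm <- stats::setNames(0:world$k, paste0("T", 0:world$k))
  attr(out, "class_map") <- cm
  out
}

#' Simulate a raw label matrix with known truth
#'
#' Directly exercises the label model without the text layer: true labels
#' are drawn from the class balance; each labeling function votes the truth
#' with its accuracy, otherwise uniformly among the wrong classes, and
#' abstains independently at its abstain rate.
#'
#' @param n number of instances.
#' @param accuracies per-source probabilities of a correct (non-abstain)
#'   vote, in (0, 1).
#' @param abstain_rates per-source abstain probabilities.
#' @param class_balance probability vector over classes `0..k`.
#' @param seed seed.
#' @return list with `L` (integer vote matrix) and `truth`.
#' @export
generate_label_matrix <- function(n, accuracies, abstain_rates,
                                  class_balance = c(0.5, 0.5), seed = 1L) {
  m <- length(accuracies)
  stopifnot(length(abstain_rates) == m, all(accuracies > 0 & accuracies < 1))
  k <- length(class_balance) - 1L
  set.seed(seed)
  truth <- sample(0:k, n, replace = TRUE, prob = class_balance)
  L <- matrix(-1L, n, m)
  for (j in seq_len(m)) {
    votes <- truth
    wrong <- stats::runif(n) >= accuracies[j]
    if (any(wrong)) {
      votes[wrong] <- vapply(truth[wrong], function(y)
        sample(setdiff(0:k, y), 1), integer(1))
    }
    votes[stats::runif(n) < abstain_rates[j]] <- -1L
    L[, j] <- votes
  }
  colnames(L) <- paste0("lf", seq_len(m))
  list(L = L, truth = truth)
}

#' Worked span-disagreement fixture
#'
#' Reconstructs the canonical failure mode of equal-weight voting on a
#' multi-token entity: a sentence containing "diabetes type 2" labeled by
#' four terminologies, two of which (mth, snomedct) lack the full term and
#' only know "diabetes". With unmatched tokens voted negative, majority
#' vote ties 2-2 on "type 2" and truncates the span to "diabetes"; a label
#' model whose accuracies favor the full-term sources recovers the complete
#' span.
#'
#' @return list with `corpus` (one document), `terminologies` (4 sources),
#'   `class_map`, `gold_spans`, `lfs` (the 4 semantic-type labeling
#'   functions), and `full_term_sources` (names of the sources containing
#'   the complete term).
#' @export
span_disagreement_fixture <- function() {
  toks <- c("The", "patient", "presents", "with", "diabetes", "type", "2",
            "and", "fatigue", ".")
  doc <- wn_document("fixture01", NA_character_,
                     list(token_sequence(toks)))
  mk <- function(name, terms) {
    terminology(name, data.frame(term = terms, type = "T1",
                                 stringsAsFactors = FALSE))
  }
  terminologies <- list(mth = mk("mth", "diabetes"),
                        chv = mk("chv", c("diabetes", "diabetes type 2")),
                        lnc = mk("lnc", "diabetes type 2"),
                        snomedct = mk("snomedct", "diabetes"))
  class_map <- c(T0 = 0L, T1 = 1L)
  lfs <- lapply(terminologies, function(v)
    lf_semantic_type(v, class_map = class_map, unmatched = "negative"))
  list(corpus = list(doc), terminologies = terminologies,
       class_map = class_map,
       gold_spans = span_table("fixture01", 1L, 5L, 8L, 1L),
       lfs = unname(lfs),
       full_term_sources = c("chv", "lnc"))
}

# ---------------------------------------------------------------------------
# Study scenarios (fixed conditions used by the benchmark harnesses)

#' Mixed-quality source scenario
#'
#' The study conditions for comparing the label model against majority vote
#' under source heterogeneity: one high-recall source whose spurious terms
#' bring its word-level precision to about 0.65 is mixed with three
#' high-precision sources, over a corpus dense in entity mentions (about
#' 30% of tokens). All sources vote the negative class on unmatched tokens.
#'
#' @param seed world seed.
#' @return list with `world`, `specs`, and `n_sentences`.
#' @export
scenario_mixed_quality <- function(seed = 42L) {
  world <- world_spec(k = 1L, n_lexicon = 60L, multi_token_frac = 0.3,
                      n_background = 120L, density = 0.8,
                      entities_max = 2L, sent_len = c(4L, 8L), seed = seed)
  specs <- list(source_spec("noisy_highrecall", recall = 0.95, spurious = 0.20),
                source_spec("precise_a", recall = 0.85, spurious = 0.02),
                source_spec("precise_b", recall = 0.85, spurious = 0.02),
                source_spec("precise_c", recall = 0.85, spurious = 0.02))
  list(world = world, specs = specs, n_sentences = 400L)
}

#' Lexicon-holdout generalization scenario
#'
#' The study conditions for the end model's generalization claim: label
#' sources collectively cover only 80% of the entity lexicon; the held-out
#' 20% can never be labeled by any source (the label model scores 0 on
#' those occurrences by construction), but shares suffix morphology with
#' the covered terms, so a feature-based end model can recover it.
#' Negative supervision comes from guideline-style dictionaries of function
#' and common background words.
#'
#' @param seed scenario seed (drives the holdout draw and source sampling).
#' @return list with `world`, `held_out` (term character vector), `lfs`
#'   (ontology + guideline labeling functions), and sizes
#'   `n_train`/`n_test`.
#' @export
scenario_generalization <- function(seed = 1L) {
  world <- world_spec(k = 1L, n_lexicon = 60L, multi_token_frac = 0.3,
                      n_background = 120L, density = 0.8,
                      entities_max = 2L, sent_len = c(4L, 8L), seed = 42L)
  set.seed(seed)
  terms <- world$lexicon[[1]]
  held_out <- sample(terms, round(0.2 * length(terms)))
  known <- setdiff(terms, held_out)
  class_map <- c(T0 = 0L, T1 = 1L)
  mk_src <- function(name) {
    sub <- sample(known, round(0.8 * length(known)))
    terminology(name, data.frame(term = sub, type = "T1",
                                 stringsAsFactors = FALSE))
  }
  onto <- lapply(c("src_a", "src_b", "src_c"), mk_src)
  lfs <- c(lapply(onto, function(v)
             lf_semantic_type(v, class_map = class_map,
                              unmatched = "abstain")),
           list(lf_pattern("guideline_function_words", class = 0L,
                           dictionary = .FUNCTION_WORDS),
                lf_pattern("guideline_common_words", class = 0L,
                           dictionary = sample(world$background,
                                               round(0.7 * length(world$background))))))
  list(world = world, held_out = held_out, lfs = lfs,
       n_train = 400L, n_test = 150L)
}
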