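# Labeling-function templates: semantic-type matching with slot patterns,
# document-scoped synset disambiguation (with Schwartz-Hearst abbreviation
# linking), context-window cue rules, pattern rules, and label-matrix
# construction. Votes are integers in {-1, 0, ..., k}; -1 denotes abstain.

ABSTAIN <- -1L

#' Semantic-type labeling function
#'
#' Greedy longest-match tagging against one terminology: every longest term
#' match (in token length) is assigned the term's most probable entity class
#' under the semantic-type distribution, abstaining on exact argmax ties.
#' Using the longest match disambiguates nested terms (e.g. an anatomy term
#' nested inside a longer disease term).
#'
#' @param term a `terminology`.
#' @param type_map a `semantic_type_map` (see [build_type_distribution()]);
#'   defaults to the distribution implied by this terminology alone.
#' @param class_map required when `type_map` is `NULL`.
#' @param unmatched vote for tokens not covered by any term: `"abstain"`
#'   (default; the terminology stays silent off its vocabulary) or
#'   `"negative"` (vote the negative class 0, asserting "not an entity").
#' @param slot_patterns also apply the compositional pattern `{*} ({*})`:
#'   when a term match is immediately followed by a parenthesized term match
#'   of the same class, the whole region including parentheses is labeled
#'   that class.
#' @param name labeling-function name; defaults to the terminology name.
#' @return object of class `c("lf_semantic_type", "labeling_function")`.
#' @export
lf_semantic_type <- function(term, type_map = NULL, class_map = NULL,
                             unmatched = c("abstain", "negative"),
                             slot_patterns = FALSE, name = term$name) {
  unmatched <- match.arg(unmatched)
  if (is.null(type_map)) {
    if (is.null(class_map))
      stop("either type_map or class_map must be supplied")
    type_map <- build_type_distribution(list(term), class_map)
  }
  terms <- intersect(unique(term$entries$term), rownames(type_map$probs))
  if (!length(terms)) warning("lf '", name, "': no term has a mapped class")
  structure(list(name = name, kind = "semantic_type",
                 index = build_term_index(terms),
                 probs = type_map$probs[terms, , drop = FALSE],
                 k = type_map$k,
                 unmatched = unmatched, slot_patterns = slot_patterns),
            class = c("lf_semantic_type", "labeling_function"))
}

# class choice for a matched term: argmax of its class vector, -1 on a tie
term_vote <- function(lf, term) {
  p <- lf$probs[term, ]
  top <- which(p == max(p))
  if (length(top) > 1L) ABSTAIN else as.integer(colnames(lf$probs)[top])
}

apply_semantic_type <- function(lf, seq) {
  n <- length(seq)
  out <- rep(if (lf$unmatched == "abstain") ABSTAIN else 0L, n)
  if (!n) return(out)
  m <- find_longest_matches(seq, lf$index)
  ties <- attr(m, "ties")
  if (nrow(m)) for (i in seq_len(nrow(m))) {
    v <- term_vote(lf, m$term[i])
    alt <- ties[[i]]
    if (length(alt)) {
      # equal-length competing terms at the same start: prefer the higher
      # class probability, abstain when still tied
      pmaxes <- vapply(c(m$term[i], alt), function(t) max(lf$probs[t, ]),
                       numeric(1))
      best <- which(pmaxes == max(pmaxes))
      if (length(best) > 1L) v <- ABSTAIN
      else if (best != 1L) v <- term_vote(lf, alt[best - 1L])
    }
    out[m$token_start[i]:(m$token_end[i] - 1L)] <- v
  }
  if (lf$slot_patterns && nrow(m) >= 2L) {
    toks <- seq$tokens
    opens <- which(toks == "(")
    for (p in opens) {
      q <- p + 1L
      while (q <= n && toks[q] != ")") q <- q + 1L
      if (q > n) next
      left <- which(m$token_end == p)
      inner <- which(m$token_start == p + 1L & m$token_end == q)
      if (length(left) != 1L || length(inner) != 1L) next
      v1 <- term_vote(lf, m$term[left]); v2 <- term_vote(lf, m$term[inner])
      if (v1 == v2 && v1 != ABSTAIN) {
        region <- m$token_start[left]:q
        # a strictly longer plain ontology match covering the region wins
        covered <- any(m$token_start <= region[1] & m$token_end > q &
                         (m$token_end - m$token_start) > length(region))
        if (!covered) out[region] <- v1
      }
    }
  }
  out
}

#' Synonym-set (synset) labeling function
#'
#' Document-scoped disambiguation: a synset (a set of >= 2 synonymous terms
#' for one concept) fires on a document only when at least two distinct
#' member terms each match somewhere in it; all occurrences of any member
#' term are then labeled the synset's class. This is how an ambiguous short
#' form is trusted only when its long form co-occurs in the same document.
#'
#' With `schwartz_hearst = TRUE`, definitions of the shape
#' `LONG FORM (SF)` are additionally detected with the Schwartz-Hearst
#' character-matching rule; when the recovered long form is a known member
#' term, the short form is linked to the synset for that document even if it
#' is absent from the dictionary, and all its occurrences are labeled.
#'
#' @param synsets data frame with columns `concept_id`, `term`, `class`
#'   (one row per member term; terms are normalized on construction).
#' @param schwartz_hearst enable abbreviation-definition linking.
#' @param name labeling-function name.
#' @return object of class `c("lf_synset", "labeling_function")`.
#' @export
lf_synset <- function(synsets, schwartz_hearst = FALSE, name = "synsets") {
  stopifnot(all(c("concept_id", "term", "class") %in% names(synsets)))
  norm <- vapply(synsets$term, function(t) {
    nt <- normalize_term(t)
    if (is.null(nt)) NA_character_ else paste(nt, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  synsets$term <- norm
  synsets <- unique(synsets[!is.na(norm), , drop = FALSE])
  sizes <- table(synsets$concept_id)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("synset(s) with fewer than 2 member terms: ",
         paste(small, collapse = ", "))
  structure(list(name = name, kind = "synset", synsets = synsets,
                 index = build_term_index(unique(synsets$term)),
                 schwartz_hearst = schwartz_hearst),
            class = c("lf_synset", "labeling_function"))
}

# Schwartz-Hearst: find the long form of `short` in the token window before
# its defining "(", matching short-form characters right-to-left. Returns
# the matched trailing tokens (the long form) or NULL.
sh_long_form <- function(short, prev_tokens) {
  s <- tolower(short)
  max_words <- min(nchar(s) + 5L, nchar(s) * 2L)
  window <- utils::tail(prev_tokens, max_words)
  if (!length(window)) return(NULL)
  long <- paste(window, collapse = " ")
  l <- tolower(long)
  s_chars <- strsplit(s, "")[[1]]
  l_chars <- strsplit(l, "")[[1]]
  si <- length(s_chars); li <- length(l_chars)
  while (si >= 1L) {
    c <- s_chars[si]
    if (!grepl("[a-z0-9]", c)) { si <- si - 1L; next }
    while (li >= 1L &&
           (l_chars[li] != c ||
            (si == 1L && li > 1L && grepl("[a-z0-9]", l_chars[li - 1L]))))
      li <- li - 1L
    if (li < 1L) return(NULL)
    li <- li - 1L
    si <- si - 1L
  }
  # cut to the word containing position li + 1
  char_pos <- li + 1L
  word_starts <- c(1L, which(l_chars == " ") + 1L)
  first_word <- max(which(word_starts <= char_pos))
  window[first_word:length(window)]
}

apply_synset <- function(lf, doc) {
  sents <- doc$sentences
  votes <- lapply(sents, function(s) rep(ABSTAIN, length(s)))
  all_matches <- lapply(sents, function(s) find_longest_matches(s, lf$index))
  matched_terms <- unique(unlist(lapply(all_matches, function(m) m$term)))
  # which synsets fire: >= 2 distinct member terms matched in the document
  fired <- vapply(split(lf$synsets, lf$synsets$concept_id), function(g)
    sum(g$term %in% matched_terms) >= 2L, logical(1))
  fired_ids <- names(fired)[fired]
  # Schwartz-Hearst linking of out-of-dictionary short forms
  extra <- list()  # short form (normalized) -> class
  if (lf$schwartz_hearst) {
    for (s in sents) {
      toks <- s$tokens
      opens <- which(toks == "(")
      for (p in opens) {
        if (p + 2L > length(toks) || toks[p + 2L] != ")") next
        short <- toks[p + 1L]
        if (nchar(short) < 2L || !grepl("[A-Za-z]", short)) next
        long <- sh_long_form(short, toks[seq_len(p - 1L)])
        if (is.null(long)) next
        long_norm <- paste(vapply(long, normalize_token, character(1)),
                           collapse = " ")
        hit <- lf$synsets[lf$synsets$term == long_norm, , drop = FALSE]
        if (nrow(hit)) {
          extra[[short]] <- hit$class[1]
          fired_ids <- union(fired_ids, hit$concept_id[1])
        }
      }
    }
  }
  active <- lf$synsets[lf$synsets$concept_id %in% fired_ids, , drop = FALSE]
  if (!nrow(active) && !length(extra)) return(votes)
  class_of <- stats::setNames(active$class, active$term)
  for (i in seq_along(sents)) {
    m <- all_matches[[i]]
    if (nrow(m)) for (r in seq_len(nrow(m))) {
      cls <- class_of[m$term[r]]
      if (!is.na(cls))
        votes[[i]][m$token_start[r]:(m$token_end[r] - 1L)] <- as.integer(cls)
    }
    if (length(extra)) {
      toks <- sents[[i]]$tokens
      for (sf in names(extra)) {
        hits <- which(toks == sf)
        votes[[i]][hits] <- as.integer(extra[[sf]])
      }
    }
  }
  votes
}

#' Pattern labeling function
#'
#' A regular expression or a small dictionary paired with an emitted class
#' (which may be the negative class 0, e.g. for guideline dictionaries of
#' punctuation, numbers and stopwords). Matched token runs receive the
#' class; all other tokens abstain.
#'
#' @param name labeling-function name.
#' @param class emitted class in `0..k`.
#' @param regex Perl regular expression applied to the detokenized sentence
#'   (tokens joined by single spaces); tokens overlapping a match are
#'   labeled.
#' @param dictionary character vector of (possibly multi-token) entries,
#'   matched case-insensitively as token tuples.
#' @return object of class `c("lf_pattern", "labeling_function")`.
#' @export
lf_pattern <- function(name, class, regex = NULL, dictionary = NULL) {
  if (is.null(regex) == is.null(dictionary))
    stop("supply exactly one of regex or dictionary")
  if (!is.null(regex)) {
    ok <- tryCatch({ suppressWarnings(grepl(regex, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid regex in lf '", name, "': ", regex)
  }
  index <- NULL
  if (!is.null(dictionary))
    index <- build_term_index(tolower(dictionary))
  structure(list(name = name, kind = "pattern", class = as.integer(class),
                 regex = regex, index = index),
            class = c("lf_pattern", "labeling_function"))
}

apply_pattern <- function(lf, seq) {
  n <- length(seq)
  out <- rep(ABSTAIN, n)
  if (!n) return(out)
  if (!is.null(lf$index)) {
    m <- find_longest_matches(seq, lf$index)
    if (nrow(m)) for (i in seq_len(nrow(m)))
      out[m$token_start[i]:(m$token_end[i] - 1L)] <- lf$class
  } else {
    text <- paste(seq$tokens, collapse = " ")
    tok_end <- cumsum(nchar(seq$tokens) + 1L) - 1L
    tok_start <- tok_end - nchar(seq$tokens) + 1L
    mm <- gregexpr(lf$regex, text, perl = TRUE)[[1]]
    if (mm[1] != -1L) {
      for (i in seq_along(mm)) {
        a <- as.integer(mm[i]); b <- a + attr(mm, "match.length")[i] - 1L
        hit <- which(tok_start <= b & tok_end >= a)
        out[hit] <- lf$class
      }
    }
  }
  out
}

#' Context-window cue labeling function (span tasks)
#'
#' Classifies pre-identified entity spans by scanning a token window to the
#' left and/or right of each span for trigger phrases (the NegEx/ConText
#' strategy), or, for document-relative temporality, by locating the nearest
#' explicit datetime mention in token distance and comparing it to the
#' document timestamp.
#'
#' @param name labeling-function name.
#' @param patterns list of cue rules, each a list with elements `trigger`
#'   (phrase, matched case-insensitively as a token tuple), `direction`
#'   (`"left"`, `"right"` or `"either"`), `window` (max token distance,
#'   >= 1) and `class` (emitted class). The first matching rule wins.
#' @param datetime_rule optional list with `window` (max token distance) and
#'   `classes` (named list mapping `before`, `after`, `overlap` to class
#'   ids): the nearest parsed date within the window is compared to the
#'   document timestamp. Documents without a timestamp make the rule
#'   abstain (logged once per document).
#' @return object of class `c("lf_context_window", "labeling_function")`.
#' @export
lf_context_window <- function(name, patterns = list(), datetime_rule = NULL) {
  for (p in patterns) {
    stopifnot(all(c("trigger", "direction", "window", "class") %in% names(p)))
    if (p$window < 1L) stop("cue window must be >= 1")
    if (!p$direction %in% c("left", "right", "either"))
      stop("direction must be left, right or either")
  }
  structure(list(name = name, kind = "context_window", patterns = patterns,
                 datetime_rule = datetime_rule),
            class = c("lf_context_window", "labeling_function"))
}

MONTHS <- c("january", "february", "march", "april", "may", "june", "july",
            "august", "september", "october", "november", "december")

# locate and parse datetime mentions in a token sequence; returns a data
# frame with token_start and date
find_datetimes <- function(toks) {
  out <- data.frame(token_start = integer(0), date = as.Date(character(0)))
  for (i in seq_along(toks)) {
    t <- toks[i]
    d <- NA
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", t)) {
      d <- as.Date(t)
    } else if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", t)) {
      d <- as.Date(t, format = "%m/%d/%Y")
    } else if (tolower(t) %in% MONTHS && i + 1L <= length(toks) &&
               grepl("^\\d{1,2}$", toks[i + 1L])) {
      # "Month D , YYYY" (comma tokenized separately)
      j <- i + 2L
      if (j <= length(toks) && toks[j] == ",") j <- j + 1L
      if (j <= length(toks) && grepl("^\\d{4}$", toks[j])) {
        d <- as.Date(sprintf("%s %s %s", t, toks[i + 1L], toks[j]),
                     format = "%B %d %Y")
      }
    }
    if (!is.na(d) && inherits(d, "Date"))
      out <- rbind(out, data.frame(token_start = i, date = d))
  }
  out
}

# match a trigger phrase (lowercased token tuple) anywhere in a token window
phrase_in <- function(trigger_toks, window_toks) {
  nt <- length(trigger_toks); nw <- length(window_toks)
  if (nt == 0L || nw < nt) return(FALSE)
  wl <- tolower(window_toks)
  for (i in seq_len(nw - nt + 1L))
    if (all(wl[i:(i + nt - 1L)] == trigger_toks)) return(TRUE)
  FALSE
}

#' Apply a context-window labeling function to entity spans
#'
#' @param lf an [lf_context_window()] object.
#' @param doc a document.
#' @param spans a [span_table()] restricted to this document.
#' @return integer vector of votes, one per span row.
#' @export
apply_span_lf <- function(lf, doc, spans) {
  stopifnot(inherits(lf, "lf_context_window"))
  votes <- rep(ABSTAIN, nrow(spans))
  warned_ts <- FALSE
  for (r in seq_len(nrow(spans))) {
    s <- doc$sentences[[spans$sent_index[r]]]
    toks <- s$tokens
    a <- spans$token_start[r]; b <- spans$token_end[r] - 1L
    v <- ABSTAIN
    for (p in lf$patterns) {
      trig <- tolower(strsplit(p$trigger, "\\s+")[[1]])
      left <- if (a > 1L) toks[max(1L, a - p$window):(a - 1L)]
              else character(0)
      right <- if (b + 1L <= length(toks))
        toks[(b + 1L):min(length(toks), b + p$window)] else character(0)
      hit <- switch(p$direction,
                    left = phrase_in(trig, left),
                    right = phrase_in(trig, right),
                    either = phrase_in(trig, left) || phrase_in(trig, right))
      if (hit) { v <- as.integer(p$class); break }
    }
    if (v == ABSTAIN && !is.null(lf$datetime_rule)) {
      if (is.null(doc$timestamp)) {
        if (!warned_ts) {
          message("lf '", lf$name, "': document ", doc$doc_id,
                  " has no timestamp; datetime rule abstains")
          warned_ts <- TRUE
        }
      } else {
        dts <- find_datetimes(toks)
        if (nrow(dts)) {
          dist <- pmin(abs(dts$token_start - a), abs(dts$token_start - b))
          ok <- dist <= lf$datetime_rule$window
          if (any(ok)) {
            nearest <- dts[ok, , drop = FALSE][which.min(dist[ok]), ]
            cl <- lf$datetime_rule$classes
            v <- as.integer(
              if (nearest$date < doc$timestamp) cl$before
              else if (nearest$date > doc$timestamp) cl$after
              else cl$overlap)
          }
        }
      }
    }
    votes[r] <- v
  }
  votes
}

# ---------------------------------------------------------------------------
# Application and matrix construction

#' Apply a token-level labeling function to a document
#'
#' @param lf a labeling function of kind semantic_type, synset or pattern.
#' @param doc a document.
#' @return list of integer vote vectors, one per sentence, each the length
#'   of its sentence.
#' @export
apply_lf <- function(lf, doc) UseMethod("apply_lf")

#' @export
apply_lf.lf_semantic_type <- function(lf, doc)
  lapply(doc$sentences, function(s) apply_semantic_type(lf, s))

#' @export
apply_lf.lf_synset <- function(lf, doc) apply_synset(lf, doc)

#' @export
apply_lf.lf_pattern <- function(lf, doc)
  lapply(doc$sentences, function(s) apply_pattern(lf, s))

#' Build the label matrix
#'
#' Applies every token-level labeling function to every token of the corpus,
#' in corpus order. Column `j` holds labeling function `j`'s votes; values
#' are in `{-1, 0, ..., k}` with -1 = abstain.
#'
#' @param lfs list of labeling functions (unique names).
#' @param corpus list of documents.
#' @return object of class `label_matrix`: list with `L` (integer matrix,
#'   tokens x LFs), `index` (data frame `doc_id`, `sent_index`,
#'   `token_index`) and `lf_names`.
#' @export
build_label_matrix <- function(lfs, corpus) {
  stopifnot(length(lfs) >= 1L)
  nms <- vapply(lfs, function(l) l$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate labeling function names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  index <- do.call(rbind, lapply(corpus, function(d) {
    do.call(rbind, lapply(d$sentences, function(s)
      if (length(s)) data.frame(doc_id = d$doc_id, sent_index = s$sent_index,
                                token_index = seq_len(length(s)),
                                stringsAsFactors = FALSE)))
  }))
  if (is.null(index)) index <- data.frame(doc_id = character(0),
                                          sent_index = integer(0),
                                          token_index = integer(0))
  cols <- lapply(lfs, function(lf) {
    votes <- unlist(lapply(corpus, function(d) unlist(apply_lf(lf, d))))
    if (is.null(votes)) votes <- integer(0)
    as.integer(votes)
  })
  L <- do.call(cbind, cols)
  if (is.null(L)) L <- matrix(integer(0), 0L, length(lfs))
  colnames(L) <- nms
  if (nrow(L) != nrow(index)) stop("vote/token count mismatch")
  structure(list(L = L, index = index, lf_names = nms),
            class = "label_matrix")
}

#' Build a span-level label matrix
#'
#' Rows are pre-identified entity spans; columns are context-window labeling
#' functions applied to each span.
#'
#' @param lfs list of [lf_context_window()] objects.
#' @param corpus list of documents (named or in `doc_id` order).
#' @param spans a [span_table()] over the corpus.
#' @return object of class `label_matrix` whose `index` is the span table.
#' @export
build_span_label_matrix <- function(lfs, corpus, spans) {
  nms <- vapply(lfs, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate labeling function names")
  doc_ids <- vapply(corpus, function(d) d$doc_id, character(1))
  L <- matrix(ABSTAIN, nrow(spans), length(lfs))
  for (j in seq_along(lfs)) {
    for (d in unique(spans$doc_id)) {
      rows <- which(spans$doc_id == d)
      doc <- corpus[[match(d, doc_ids)]]
      L[rows, j] <- apply_span_lf(lfs[[j]], doc, spans[rows, , drop = FALSE])
    }
  }
  colnames(L) <- nms
  structure(list(L = L, index = spans, lf_names = nms),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix: %d rows x %d labeling functions; abstain rate %.3f>\n",
              nrow(x$L), ncol(x$L), mean(x$L == ABSTAIN)))
  invisible(x)
}

#' Write / read a label matrix as TSV
#'
#' Debug-friendly serialization: the row index columns followed by one
#' integer column per labeling function.
#'
#' @param lm a `label_matrix`.
#' @param path output file.
#' @export
write_label_matrix <- function(lm, path) {
  out <- cbind(lm$index, as.data.frame(lm$L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  idx_cols <- intersect(c("doc_id", "sent_index", "token_index",
                          "token_start", "token_end", "class"), names(tab))
  lf_cols <- setdiff(names(tab), idx_cols)
  L <- as.matrix(tab[, lf_cols, drop = FALSE])
  storage.mode(L) <- "integer"
  structure(list(L = L, index = tab[, idx_cols, drop = FALSE],
                 lf_names = lf_cols),
            class = "label_matrix")
}
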