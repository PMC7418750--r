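# Terminology ingestion and organization: normalization, semantic-type
# distributions, coverage ranking, and partitioning into label sources.

#' Normalize a raw term
#'
#' Applies the ontology preprocessing rules: rejects stopwords, pure numbers
#' and single-character terms; lowercases tokens except those classified as
#' abbreviations, which keep their case so that e.g. "DMD" is matched
#' case-sensitively and is not conflated with a lowercase word.
#'
#' A token is treated as an abbreviation iff it is at most
#' `abbrev_max_chars` characters long and either contains two or more
#' uppercase letters or consists entirely of uppercase letters, digits,
#' periods and hyphens with at least one uppercase letter.
#'
#' @param raw a character scalar, the raw term.
#' @param stopwords character vector of lowercase stopwords.
#' @param abbrev_max_chars maximum length of an abbreviation token.
#' @return character vector of normalized tokens, or `NULL` (rejected).
#' @export
normalize_term <- function(raw, stopwords = wn_stopwords(),
                           abbrev_max_chars = 6L) {
  raw <- trimws(raw)
  if (!nzchar(raw)) return(NULL)
  toks <- tokenize(raw)$tokens
  if (!length(toks)) return(NULL)
  is_num <- grepl("^[0-9]+([.,][0-9]+)*$", toks)
  is_stop <- tolower(toks) %in% stopwords
  # reject terms that carry no content: a bare stopword, a pure number,
  # or a single-character string
  if (all(is_num | is_stop)) return(NULL)
  if (sum(nchar(toks)) == 1L) return(NULL)
  vapply(toks, normalize_token, character(1), abbrev_max_chars = abbrev_max_chars,
         USE.NAMES = FALSE)
}

is_abbrev_token <- function(tok, abbrev_max_chars = 6L) {
  n_up <- nchar(gsub("[^A-Z]", "", tok))
  nchar(tok) <= abbrev_max_chars &&
    (n_up >= 2L || (n_up >= 1L && grepl("^[A-Z0-9.\\-]+$", tok)))
}

normalize_token <- function(tok, abbrev_max_chars = 6L) {
  if (is_abbrev_token(tok, abbrev_max_chars)) tok else tolower(tok)
}

#' Construct a terminology
#'
#' One label source: a set of normalized terms with semantic-type
#' assignments. Terms are stored as space-joined normalized token tuples;
#' abbreviation tokens retain case and are matched case-sensitively.
#'
#' @param name source identifier (e.g., a vocabulary abbreviation).
#' @param entries data frame with columns `term` (raw or normalized string)
#'   and `type` (semantic-type id); one row per (term, type) assignment.
#' @param normalize whether to run [normalize_term()] on the entries.
#' @param stopwords,abbrev_max_chars passed to [normalize_term()].
#' @return object of class `terminology`; attribute `n_rejected` counts
#'   entries dropped by normalization.
#' @export
terminology <- function(name, entries, normalize = TRUE,
                        stopwords = wn_stopwords(), abbrev_max_chars = 6L) {
  stopifnot(is.data.frame(entries), all(c("term", "type") %in% names(entries)))
  n_rejected <- 0L
  if (normalize && nrow(entries)) {
    uniq <- unique(entries$term)
    norm <- vapply(uniq, function(t) {
      nt <- normalize_term(t, stopwords, abbrev_max_chars)
      if (is.null(nt)) NA_character_ else paste(nt, collapse = " ")
    }, character(1), USE.NAMES = TRUE)
    mapped <- norm[entries$term]
    n_rejected <- sum(is.na(mapped))
    entries$term <- unname(mapped)
    entries <- entries[!is.na(entries$term), , drop = FALSE]
  }
  entries <- unique(entries[, c("term", "type")])
  rownames(entries) <- NULL
  if (!nrow(entries)) warning("terminology '", name, "' is empty")
  structure(list(name = name, entries = entries),
            class = "terminology", n_rejected = n_rejected)
}

#' @export
print.terminology <- function(x, ...) {
  cat(sprintf("<terminology %s: %d terms, %d (term,type) entries>\n",
              x$name, length(unique(x$entries$term)), nrow(x$entries)))
  invisible(x)
}

#' Load terminologies from TSV or JSON
#'
#' TSV format: header `term<TAB>source<TAB>semantic_type`, one row per
#' assignment. JSON format: `{"name": str, "entries": [{"term": str,
#' "types": [str]}]}`.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @param class_map optional named integer vector mapping semantic-type ids
#'   to class labels (see [read_class_map()]); types absent from the map are
#'   dropped.
#' @return a named list of `terminology` objects (one per source).
#' @export
load_terminologies <- function(path, class_map = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    ent <- do.call(rbind, lapply(rec$entries, function(e)
      data.frame(term = e$term, source = rec$name,
                 type = unlist(e$types), stringsAsFactors = FALSE)))
    tab <- ent
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    names(tab)[names(tab) == "semantic_type"] <- "type"
    missing <- setdiff(c("term", "source", "type"), names(tab))
    if (length(missing))
      stop("terminology file ", path, " lacks column(s): ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(class_map)) {
    keep <- tab$type %in% names(class_map)[class_map >= 0]
    tab <- tab[keep, , drop = FALSE]
  }
  out <- lapply(split(tab, tab$source), function(g)
    terminology(g$source[1], g[, c("term", "type")]))
  out[order(names(out))]
}

#' @rdname load_terminologies
#' @export
load_terminology <- function(path, class_map = NULL) {
  out <- load_terminologies(path, class_map)
  if (length(out) != 1L)
    stop("expected a single source in ", path, "; found ", length(out))
  out[[1]]
}

#' Read a semantic-type class map
#'
#' YAML mapping semantic-type id to integer class label (or -1 to ignore the
#' type). Unlisted types are dropped wherever the map is applied.
#'
#' @param path YAML file path.
#' @return named integer vector.
#' @export
read_class_map <- function(path) {
  m <- yaml::read_yaml(path)
  out <- vapply(m, as.integer, integer(1))
  names(out) <- names(m)
  out
}

#' Build the per-term semantic-type class distribution
#'
#' For each term, counts distinct (terminology, type-mapped class)
#' assignments once and normalizes to a probability vector over the classes
#' `0..k`. Exact argmax ties are detectable downstream: the semantic-type
#' labeling function abstains on them.
#'
#' @param terminologies list of `terminology` objects.
#' @param class_map named integer vector, semantic-type id -> class in
#'   `{-1, 0, ..., k}` (-1 drops the type).
#' @param k number of positive classes; defaults to the map's maximum.
#' @return object of class `semantic_type_map`: list with `probs` (matrix,
#'   terms x classes `0..k`) and `k`.
#' @export
build_type_distribution <- function(terminologies, class_map,
                                    k = max(class_map)) {
  stopifnot(length(terminologies) >= 1L, k >= 1L)
  rows <- do.call(rbind, lapply(terminologies, function(v) {
    ent <- v$entries
    cls <- unname(class_map[ent$type])
    keep <- !is.na(cls) & cls >= 0L
    if (!any(keep)) return(NULL)
    unique(data.frame(source = v$name, term = ent$term[keep],
                      class = cls[keep], stringsAsFactors = FALSE))
  }))
  if (is.null(rows) || !nrow(rows))
    stop("no (term, class) assignments after applying the class map")
  tab <- table(factor(rows$term), factor(rows$class, levels = 0:k))
  probs <- unclass(tab / rowSums(tab))
  structure(list(probs = probs, k = as.integer(k)), class = "semantic_type_map")
}

# ---------------------------------------------------------------------------
# Longest-match machinery (shared by coverage ranking and labeling functions)

# corpus token matches a normalized term token: abbreviation tokens (those
# retaining uppercase) compare case-sensitively, others case-insensitively
match_token <- function(corpus_tok, term_tok) {
  if (grepl("[A-Z]", term_tok)) corpus_tok == term_tok
  else tolower(corpus_tok) == term_tok
}

#' Build a longest-match term index
#'
#' @param terms character vector of normalized (space-joined) terms.
#' @return an index object used by [find_longest_matches()].
#' @keywords internal
build_term_index <- function(terms) {
  terms <- unique(terms)
  tok_list <- strsplit(terms, " ", fixed = TRUE)
  first <- tolower(vapply(tok_list, `[`, character(1), 1L))
  ntok <- lengths(tok_list)
  ord <- order(first, -ntok, terms)
  idx <- split(seq_along(terms)[ord], first[ord])
  structure(list(terms = terms, tok_list = tok_list, ntok = ntok,
                 by_first = idx), class = "term_index")
}

#' Find all longest term matches in a token sequence
#'
#' Greedy left-to-right scan; at each position the longest matching term (in
#' token length) wins and the scan resumes after it, so shorter terms nested
#' inside a chosen match are ignored.
#'
#' @param seq a [token_sequence()].
#' @param index a [build_term_index()] object.
#' @return data frame with columns `token_start`, `token_end` (end-exclusive)
#'   and `term`; zero rows when nothing matches. A `ties` attribute lists,
#'   for each match, the other terms of equal length matching at the same
#'   start (empty for unambiguous matches).
#' @keywords internal
find_longest_matches <- function(seq, index) {
  toks <- seq$tokens
  lower <- tolower(toks)
  n <- length(toks)
  starts <- integer(0); ends <- integer(0); terms <- character(0)
  ties <- list()
  i <- 1L
  while (i <= n) {
    cands <- index$by_first[[lower[i]]]
    hit <- 0L; hit_len <- 0L; hit_ties <- character(0)
    if (!is.null(cands)) {
      for (ci in cands) {       # candidates sorted longest-first
        len <- index$ntok[ci]
        if (hit && len < hit_len) break
        if (i + len - 1L > n) next
        tt <- index$tok_list[[ci]]
        ok <- TRUE
        for (j in seq_len(len)) {
          if (!match_token(toks[i + j - 1L], tt[j])) { ok <- FALSE; break }
        }
        if (ok) {
          if (!hit) { hit <- ci; hit_len <- len }
          else hit_ties <- c(hit_ties, index$terms[ci])
        }
      }
    }
    if (hit) {
      starts <- c(starts, i); ends <- c(ends, i + hit_len)
      terms <- c(terms, index$terms[hit])
      ties[[length(terms)]] <- hit_ties
      i <- i + hit_len
    } else i <- i + 1L
  }
  out <- data.frame(token_start = starts, token_end = ends, term = terms,
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- ties
  out
}

#' Rank terminologies by corpus coverage
#'
#' Coverage of a terminology is each of its terms' document frequency summed
#' over terms, where a term counts for a document only when it occurs as a
#' longest match there (consistent with the labeling-function matcher).
#' Descending order; ties broken by terminology name.
#'
#' @param terminologies list of `terminology` objects.
#' @param corpus list of documents.
#' @return the input list reordered, with a `scores` attribute (named
#'   numeric).
#' @export
rank_by_coverage <- function(terminologies, corpus) {
  scores <- vapply(terminologies, function(v) {
    idx <- build_term_index(unique(v$entries$term))
    sum(vapply(corpus, function(d) {
      matched <- unlist(lapply(d$sentences, function(s)
        find_longest_matches(s, idx)$term))
      length(unique(matched))
    }, numeric(1)))
  }, numeric(1))
  names(scores) <- vapply(terminologies, function(v) v$name, character(1))
  ord <- order(-scores, names(scores))
  out <- terminologies[ord]
  attr(out, "scores") <- scores[ord]
  out
}

#' Partition ranked terminologies into label sources
#'
#' The top `s` terminologies are kept as individual label sources; the
#' remainder is merged into a single union terminology (union of entries),
#' so every input term ends up in exactly one source.
#'
#' @param ranked list of `terminology` objects, ranked (see
#'   [rank_by_coverage()]).
#' @param s partition size, `1 <= s <= length(ranked)`.
#' @return list with `individual` (list of `s` terminologies) and `merged`
#'   (one terminology, or `NULL` when `s` equals the number of sources).
#' @export
partition_sources <- function(ranked, s) {
  n <- length(ranked)
  if (s < 1L || s > n) stop("s must be in [1, ", n, "]")
  individual <- ranked[seq_len(s)]
  merged <- NULL
  if (s < n) {
    rest <- ranked[(s + 1L):n]
    ent <- unique(do.call(rbind, lapply(rest, function(v) v$entries)))
    merged <- terminology("merged_remainder", ent, normalize = FALSE)
  }
  list(individual = individual, merged = merged, s = as.integer(s))
}
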