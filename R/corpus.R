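# Core text data model: documents, token sequences, spans, tag schemes.
#
# Coordinate convention (used everywhere in this package): token and character
# positions are 1-based; intervals are end-exclusive, so a span with
# token_start = 2, token_end = 4 covers tokens 2 and 3.

#' Construct a token sequence
#'
#' A sentence represented as ordered tokens with character offsets into the
#' parent document's text. The unit of word-level labeling.
#'
#' @param tokens character vector of tokens.
#' @param start,end integer vectors of 1-based, end-exclusive character
#'   offsets into the parent text; may be `NULL` for pre-tokenized input
#'   with no source text.
#' @param doc_id parent document identifier.
#' @param sent_index 1-based position of the sentence within its document.
#' @return an object of class `token_sequence`.
#' @export
token_sequence <- function(tokens, start = NULL, end = NULL,
                           doc_id = NA_character_, sent_index = 1L) {
  tokens <- as.character(tokens)
  if (is.null(start)) {
    # synthesize offsets as if tokens were single-space separated
    n <- nchar(tokens)
    end0 <- cumsum(n + 1L)
    start <- if (length(n)) c(1L, utils::head(end0, -1L) + 1L) else integer(0)
    end <- start + n
  }
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(tokens) == length(start), length(start) == length(end))
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("token offsets must be strictly increasing and non-overlapping")
  if (any(end < start)) stop("token end offsets must be >= start offsets")
  structure(list(tokens = tokens, start = start, end = end,
                 doc_id = doc_id, sent_index = as.integer(sent_index)),
            class = "token_sequence")
}

#' @export
length.token_sequence <- function(x) length(x$tokens)

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence doc=%s sent=%d: %s>\n", x$doc_id, x$sent_index,
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Construct a document
#'
#' @param doc_id string identifier.
#' @param text raw character string (may be `NA` for pre-tokenized input).
#' @param sentences list of [token_sequence()] objects, ordered.
#' @param timestamp optional `Date`, the document creation time used by
#'   document-relative temporality rules.
#' @return an object of class `wn_document`.
#' @export
wn_document <- function(doc_id, text = NA_character_, sentences = list(),
                        timestamp = NULL) {
  sentences <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    s$doc_id <- doc_id
    s$sent_index <- i
    s
  })
  if (!is.na(text)) {
    for (s in sentences) {
      if (length(s) &&
          (max(s$end) > nchar(text) + 1L || min(s$start) < 1L))
        stop("token offsets index outside document text")
    }
  }
  structure(list(doc_id = doc_id, text = text, sentences = sentences,
                 timestamp = timestamp),
            class = "wn_document")
}

# ---------------------------------------------------------------------------
# Tokenization (pluggable; this is the default implementation)

.PUNCT_RE <- "[].,;:!?(){}\"'%/[]"

# Split one whitespace-delimited chunk into tokens, peeling leading/trailing
# punctuation. Internal hyphens are preserved; a trailing period is kept
# inside all-caps tokens (e.g. abbreviations like "q.d." stay intact only if
# fully matched as caps+periods).
split_chunk <- function(chunk) {
  toks <- character(0)
  # peel leading punctuation
  while (nchar(chunk) > 1L && grepl(paste0("^", .PUNCT_RE), chunk)) {
    toks <- c(toks, substr(chunk, 1L, 1L))
    chunk <- substr(chunk, 2L, nchar(chunk))
  }
  trail <- character(0)
  is_caps <- function(x) grepl("^[A-Z0-9\\.\\-]+$", x) && grepl("[A-Z]", x)
  while (nchar(chunk) > 1L && grepl(paste0(.PUNCT_RE, "$"), chunk)) {
    last <- substr(chunk, nchar(chunk), nchar(chunk))
    if (last == "." && is_caps(chunk)) break  # keep period inside all-caps
    trail <- c(substr(chunk, nchar(chunk), nchar(chunk)), trail)
    chunk <- substr(chunk, 1L, nchar(chunk) - 1L)
  }
  c(toks, chunk, trail)
}

#' Tokenize raw text into a token sequence
#'
#' Default tokenizer: whitespace split followed by peeling leading/trailing
#' punctuation into their own tokens. Internal hyphens and periods inside
#' all-caps tokens are preserved, which keeps hyphenated terms and dotted
#' abbreviations intact.
#'
#' @param text a character scalar (one sentence).
#' @inheritParams token_sequence
#' @return a [token_sequence()].
#' @export
tokenize <- function(text, doc_id = NA_character_, sent_index = 1L) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L)
    return(token_sequence(character(0), integer(0), integer(0), doc_id, sent_index))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- character(0); tstart <- integer(0); tend <- integer(0)
  for (i in seq_along(starts)) {
    chunk <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    parts <- split_chunk(chunk)
    pos <- starts[i]
    for (p in parts) {
      toks <- c(toks, p)
      tstart <- c(tstart, pos)
      tend <- c(tend, pos + nchar(p))
      pos <- pos + nchar(p)
    }
  }
  token_sequence(toks, tstart, tend, doc_id, sent_index)
}

#' Split text into sentences
#'
#' Default boundary rule: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and an uppercase letter. Pre-split input bypasses this.
#'
#' @param text character scalar.
#' @return character vector of sentence strings (with their original spans
#'   retrievable via attribute `"start"`).
#' @export
split_sentences <- function(text) {
  m <- gregexpr("[\\.\\?!](?=\\s+[A-Z])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    out <- text
    attr(out, "start") <- 1L
    return(out)
  }
  bounds <- as.integer(m)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  sents <- substring(text, starts, ends)
  keep <- grepl("\\S", sents)
  out <- sents[keep]
  attr(out, "start") <- starts[keep]
  out
}

#' Build a document from raw text
#'
#' Runs sentence splitting and tokenization, preserving character offsets
#' into the original text.
#'
#' @inheritParams wn_document
#' @param tokenizer a function `(text, doc_id, sent_index) -> token_sequence`;
#'   defaults to [tokenize()].
#' @return a [wn_document()].
#' @export
read_document <- function(doc_id, text, timestamp = NULL, tokenizer = tokenize) {
  sents <- split_sentences(text)
  starts <- attr(sents, "start")
  seqs <- vector("list", length(sents))
  for (i in seq_along(sents)) {
    ts <- tokenizer(sents[[i]], doc_id, i)
    ts$start <- ts$start + starts[i] - 1L
    ts$end <- ts$end + starts[i] - 1L
    seqs[[i]] <- ts
  }
  seqs <- seqs[vapply(seqs, length, 1L) > 0L]
  wn_document(doc_id, text, seqs, timestamp)
}

# ---------------------------------------------------------------------------
# Spans and tag schemes

#' Construct a span table
#'
#' Spans are stored as a plain data frame, one row per entity span.
#'
#' @param doc_id,sent_index,token_start,token_end,class vectors of equal
#'   length; token coordinates are 1-based, end-exclusive; `class` is a
#'   positive integer entity class id (0 is reserved for "outside").
#' @return a `data.frame` with those five columns.
#' @export
span_table <- function(doc_id = character(0), sent_index = integer(0),
                       token_start = integer(0), token_end = integer(0),
                       class = integer(0)) {
  data.frame(doc_id = as.character(doc_id),
             sent_index = as.integer(sent_index),
             token_start = as.integer(token_start),
             token_end = as.integer(token_end),
             class = as.integer(class),
             stringsAsFactors = FALSE)
}

#' Convert spans to per-token tags
#'
#' Every token inside a span receives the span's class tag under the chosen
#' scheme (`"IO"`: all covered tokens `I-c`; `"BIO"`: first covered token
#' `B-c`); all other tokens are `"O"`.
#'
#' @param spans a [span_table()] for one sentence (columns `token_start`,
#'   `token_end`, `class`).
#' @param seq_len integer, the sentence length in tokens.
#' @param scheme `"IO"` or `"BIO"`.
#' @return character vector of tags with attribute `scheme`.
#' @export
spans_to_tags <- function(spans, seq_len, scheme = c("IO", "BIO")) {
  scheme <- match.arg(scheme)
  tags <- rep("O", seq_len)
  if (nrow(spans)) {
    o <- order(spans$token_start)
    spans <- spans[o, , drop = FALSE]
    if (any(spans$token_start >= spans$token_end) ||
        any(spans$token_start < 1L) || any(spans$token_end > seq_len + 1L))
      stop("span out of range for sequence of length ", seq_len)
    if (nrow(spans) > 1L &&
        any(spans$token_start[-1L] < spans$token_end[-nrow(spans)])) {
      i <- which(spans$token_start[-1L] < spans$token_end[-nrow(spans)])[1L]
      stop(sprintf("overlapping spans: [%d,%d) and [%d,%d)",
                   spans$token_start[i], spans$token_end[i],
                   spans$token_start[i + 1L], spans$token_end[i + 1L]))
    }
    for (i in seq_len(nrow(spans))) {
      idx <- spans$token_start[i]:(spans$token_end[i] - 1L)
      tags[idx] <- paste0("I-", spans$class[i])
      if (scheme == "BIO") tags[idx[1L]] <- paste0("B-", spans$class[i])
    }
  }
  attr(tags, "scheme") <- scheme
  tags
}

tag_class <- function(tags) {
  cls <- rep(0L, length(tags))
  inside <- tags != "O"
  cls[inside] <- as.integer(sub("^[BI]-", "", tags[inside]))
  cls
}

#' Convert per-token tags to spans
#'
#' Maximal contiguous tagged runs become spans. Malformed BIO (an `I-` tag
#' following `O` or a different class) is repaired by treating the `I` as a
#' `B`, with a warning.
#'
#' @param tags character tag vector (`O` / `I-c` / `B-c`).
#' @param doc_id,sent_index identifiers recorded on the output rows.
#' @return a [span_table()].
#' @export
tags_to_spans <- function(tags, doc_id = NA_character_, sent_index = 1L) {
  n <- length(tags)
  cls <- tag_class(tags)
  is_b <- grepl("^B-", tags)
  starts <- integer(0); ends <- integer(0); classes <- integer(0)
  i <- 1L
  any_b <- any(is_b)
  while (i <= n) {
    if (cls[i] == 0L) { i <- i + 1L; next }
    # a run can only start here; in BIO input that start must be a B tag
    if (any_b && grepl("^I-", tags[i])) {
      warning(sprintf("malformed BIO at token %d: I-%d without preceding B; treated as B",
                      i, cls[i]))
    }
    j <- i + 1L
    while (j <= n && cls[j] == cls[i] && !is_b[j]) j <- j + 1L
    starts <- c(starts, i); ends <- c(ends, j); classes <- c(classes, cls[i])
    i <- j
  }
  span_table(rep(doc_id, length(starts)), rep(as.integer(sent_index), length(starts)),
             starts, ends, classes)
}

#' Convert IO tags to BIO
#'
#' The first token of each contiguous same-class run becomes `B-`. Adjacent
#' same-class IO runs cannot be distinguished and collapse into one BIO span;
#' this is an inherent limitation of the IO scheme.
#'
#' @param tags character IO tag vector.
#' @return character BIO tag vector.
#' @export
io_to_bio <- function(tags) {
  cls <- tag_class(tags)
  out <- tags
  n <- length(tags)
  if (n == 0L) { attr(out, "scheme") <- "BIO"; return(out) }
  run_start <- cls != 0L & (c(0L, cls[-n]) != cls | c(TRUE, rep(FALSE, n - 1L)))
  out[run_start] <- paste0("B-", cls[run_start])
  attr(out, "scheme") <- "BIO"
  out
}

# ---------------------------------------------------------------------------
# File formats

#' Read a JSONL corpus
#'
#' One document per line: either `{"doc_id": str, "text": str}` (tokenized
#' here) or pre-tokenized `{"doc_id": str, "sentences": [[tok, ...], ...]}`.
#' An optional `"timestamp"` field (ISO date) is parsed for temporality rules.
#'
#' @param path file path.
#' @param tokenizer tokenizer used for raw-text documents.
#' @return list of [wn_document()] objects.
#' @export
read_jsonl_corpus <- function(path, tokenizer = tokenize) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    ts <- if (!is.null(rec$timestamp)) as.Date(rec$timestamp) else NULL
    if (!is.null(rec$text)) {
      read_document(rec$doc_id, rec$text, timestamp = ts, tokenizer = tokenizer)
    } else {
      sents <- lapply(rec$sentences, function(s)
        token_sequence(unlist(s, use.names = FALSE)))
      wn_document(rec$doc_id, NA_character_, sents, timestamp = ts)
    }
  })
}

#' Write a corpus to JSONL
#'
#' @param corpus list of documents.
#' @param path output file.
#' @export
write_jsonl_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(d) {
    rec <- list(doc_id = d$doc_id)
    if (!is.na(d$text)) rec$text <- d$text
    else rec$sentences <- lapply(d$sentences, function(s) s$tokens)
    if (!is.null(d$timestamp)) rec$timestamp <- format(d$timestamp)
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
}

#' Read CoNLL-style token/tag files
#'
#' One token per line, `token<TAB>tag`, blank line between sentences.
#'
#' @param path file path.
#' @return list with `sentences` (list of token character vectors) and
#'   `tags` (list of tag character vectors).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sents <- list(); tags <- list()
  cur_t <- character(0); cur_g <- character(0)
  flush <- function() {
    if (length(cur_t)) {
      sents[[length(sents) + 1L]] <<- cur_t
      tags[[length(tags) + 1L]] <<- cur_g
      cur_t <<- character(0); cur_g <<- character(0)
    }
  }
  for (l in lines) {
    if (!nzchar(trimws(l))) { flush(); next }
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed CoNLL line: ", l)
    cur_t <- c(cur_t, parts[1]); cur_g <- c(cur_g, parts[2])
  }
  flush()
  list(sentences = sents, tags = tags)
}

#' Write CoNLL-style token/tag files
#'
#' @param sentences list of token character vectors.
#' @param tags list of tag character vectors, parallel to `sentences`.
#' @param path output file.
#' @export
write_conll <- function(sentences, tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sentences)) {
    writeLines(paste(sentences[[i]], tags[[i]], sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

# iterate all sentences of a corpus in order
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus, function(d) d$sentences), recursive = FALSE)
}
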