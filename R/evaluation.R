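# Scoring: exact-span precision/recall/F1 for NER, micro-averaged token
# metrics for span tasks, and method-comparison reports with paired
# significance testing.

prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  data.frame(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Exact-span precision/recall/F1
#'
#' A predicted span scores a true positive only when it is identical to a
#' gold span in sequence, boundaries, and class (exact span matching).
#' Predictions in the IO scheme should be converted to BIO upstream
#' ([io_to_bio()], [tags_to_spans()]) so head-word errors are counted.
#'
#' @param gold,pred [span_table()] data frames over the same corpus.
#' @return one-row data frame: precision, recall, f1 (proportions), and the
#'   tp/fp/fn counts.
#' @export
exact_span_prf <- function(gold, pred) {
  key <- function(s) paste(s$doc_id, s$sent_index, s$token_start,
                           s$token_end, s$class)
  gk <- key(gold); pk <- key(pred)
  if (anyDuplicated(gk) || anyDuplicated(pk))
    warning("duplicate spans collapse in exact matching")
  tp <- length(intersect(gk, pk))
  prf_from_counts(tp, length(unique(pk)) - tp, length(unique(gk)) - tp)
}

#' Token-level precision/recall/F1
#'
#' Per-class counts with a micro average pooling counts over the scored
#' classes (the convention for multi-class span-attribute tasks such as
#' document-relative temporality).
#'
#' @param gold,pred integer class vectors (or tag character vectors) of
#'   equal length.
#' @param classes classes to score; defaults to every class except 0 when
#'   any positive class is present, else all observed classes.
#' @return data frame with one row per class plus a `"micro"` row.
#' @export
token_prf <- function(gold, pred, classes = NULL) {
  if (is.character(gold)) gold <- tag_class(gold)
  if (is.character(pred)) pred <- tag_class(pred)
  if (length(gold) != length(pred))
    stop("gold and pred have different lengths (", length(gold), " vs ",
         length(pred), ")")
  if (is.null(classes)) {
    obs <- sort(unique(c(gold, pred)))
    classes <- if (any(obs >= 1L)) setdiff(obs, 0L) else obs
  }
  rows <- lapply(classes, function(c) {
    out <- prf_from_counts(sum(gold == c & pred == c),
                           sum(pred == c & gold != c),
                           sum(gold == c & pred != c))
    cbind(class = as.character(c), out)
  })
  tab <- do.call(rbind, rows)
  micro <- prf_from_counts(sum(tab$tp), sum(tab$fp), sum(tab$fn))
  rbind(tab, cbind(class = "micro", micro))
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Two-sided paired signed-rank test. Zero differences are ranked together
#' with the non-zero ones and then dropped from the statistic (the Pratt
#' method), with a normal approximation including tie and zero corrections.
#' All-zero differences give p = 1.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks) and `p.value`.
#' @export
wilcoxon_pratt <- function(x, y) {
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) return(list(statistic = 0, p.value = 1))
  V <- sum(r[nz & d > 0])
  n0 <- sum(!nz)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[nz])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = V, p.value = 1))
  z <- (V - mu) / sqrt(sig2)
  list(statistic = V, p.value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare labeling methods across seeded replicates
#'
#' Summarizes per-method F1 as mean and SD over replicates (deterministic
#' methods, e.g. majority vote, may have a single replicate and are
#' reported without SD) and computes the paired two-sided Wilcoxon
#' signed-rank p-value (Pratt zero handling) between requested method
#' pairs. Significance is omitted with a warning when fewer than 5 paired
#' replicates are available.
#'
#' @param scores data frame with columns `method`, `seed`, `f1`.
#' @param pairs list of 2-element character vectors naming method pairs to
#'   test; default: every pair of methods with replicates.
#' @return list with `summary` (per-method mean/sd/n) and `tests` (data
#'   frame of pairwise p-values; may have zero rows).
#' @export
compare_report <- function(scores, pairs = NULL) {
  stopifnot(all(c("method", "seed", "f1") %in% names(scores)))
  summ <- do.call(rbind, lapply(split(scores, scores$method), function(g)
    data.frame(method = g$method[1], n = nrow(g), mean_f1 = mean(g$f1),
               sd_f1 = if (nrow(g) > 1) stats::sd(g$f1) else NA_real_)))
  rownames(summ) <- NULL
  if (is.null(pairs)) {
    reps <- summ$method[summ$n > 1]
    pairs <- if (length(reps) >= 2)
      utils::combn(as.character(reps), 2, simplify = FALSE) else list()
  }
  tests <- data.frame(method_a = character(0), method_b = character(0),
                      n = integer(0), p.value = numeric(0))
  for (pr in pairs) {
    a <- scores[scores$method == pr[1], ]
    b <- scores[scores$method == pr[2], ]
    common <- intersect(a$seed, b$seed)
    if (length(common) < 5L) {
      warning("fewer than 5 paired replicates for ", pr[1], " vs ", pr[2],
              "; significance omitted")
      next
    }
    w <- wilcoxon_pratt(a$f1[match(common, a$seed)],
                        b$f1[match(common, b$seed)])
    tests <- rbind(tests, data.frame(method_a = pr[1], method_b = pr[2],
                                     n = length(common),
                                     p.value = w$p.value))
  }
  list(summary = summ, tests = tests)
}
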