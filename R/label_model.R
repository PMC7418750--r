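# Data-programming label model: combine the label matrix into consensus
# probabilistic labels. Per-source accuracies are estimated without ground
# truth from pairwise agreement rates via the triplet method, then used in a
# naive-Bayes factor model to compute P(Y | Lambda).

#' Majority vote over a label matrix
#'
#' Per token, the mode of the non-abstain votes; when every source abstains
#' or the mode is tied, the default class is emitted.
#'
#' @param lm a `label_matrix` (or a plain integer matrix of votes).
#' @param default_class class emitted on abstain/tie (conventionally the
#'   corpus majority class).
#' @param k number of positive classes; defaults to the matrix maximum.
#' @return integer vector of hard labels, one per row.
#' @export
majority_vote <- function(lm, default_class = 0L, k = NULL) {
  L <- if (inherits(lm, "label_matrix")) lm$L else lm
  if (!nrow(L)) return(integer(0))
  if (is.null(k)) k <- max(1L, max(L))
  counts <- vapply(0:k, function(c) rowSums(L == c), numeric(nrow(L)))
  counts <- matrix(counts, nrow = nrow(L))
  best <- max.col(counts, ties.method = "first") - 1L
  maxcnt <- counts[cbind(seq_len(nrow(counts)), best + 1L)]
  n_at_max <- rowSums(counts == maxcnt)
  out <- best
  out[maxcnt == 0 | n_at_max > 1L] <- as.integer(default_class)
  out
}

# one-vs-rest binarized view of the vote matrix for class c:
# +1 vote for c, -1 vote for any other class, 0 abstain
binarize_class <- function(L, c) {
  B <- matrix(0, nrow(L), ncol(L))
  B[L == c] <- 1
  B[L != c & L != -1L] <- -1
  B
}

#' Pairwise agreement moments
#'
#' Entry (i, j) is the mean of `lambda_i * lambda_j` over the tokens where
#' both sources vote (abstains are excluded pairwise), i.e. the observable
#' product of the two sources' accuracies on the +/-1 scale under
#' independent noise. Pairs with fewer than `min_overlap` co-votes are
#' flagged unreliable and excluded from triplet estimation.
#'
#' @param B a binarized (+1/-1/0) vote matrix (see one-vs-rest views in
#'   [fit_label_model()]).
#' @param min_overlap minimum co-vote count for a reliable pair.
#' @return list with `M` (m x m moment matrix, diagonal 1, `NaN` where a
#'   pair never co-votes), `n_overlap`, and `reliable` (logical matrix).
#' @export
pairwise_moments <- function(B, min_overlap = 25L) {
  V <- (B != 0) * 1
  S <- crossprod(B)
  N <- crossprod(V)
  M <- S / N                       # NaN where N == 0
  diag(M) <- 1
  reliable <- N >= min_overlap
  diag(reliable) <- TRUE
  list(M = M, n_overlap = N, reliable = reliable)
}

#' Triplet-method accuracy estimation
#'
#' Recovers each source's accuracy on the +/-1 scale from products of
#' pairwise moments: for source i and any pair (j, k),
#' `|a_i| = sqrt(|M_ij * M_ik / M_jk|)`. Estimates are aggregated over all
#' valid triplets by the median. Relative signs are taken from the moment
#' signs and the global sign is chosen so that the mean accuracy is
#' positive (sources better than random on average); accuracies are then
#' clamped away from +/-1.
#'
#' @param mom output of [pairwise_moments()].
#' @param eps clamping margin on the probability scale: accuracies are kept
#'   in `[eps, 1 - eps]` after conversion `p = (1 + a) / 2`.
#' @param prior_acc fallback accuracy (probability scale) for sources with
#'   no usable triplet.
#' @param zero_tol triplets whose denominator moment is below this magnitude
#'   are skipped (division guard).
#' @return numeric vector of accuracies on the +/-1 scale, with attribute
#'   `n_triplets` (per-source usable triplet counts).
#' @export
triplet_accuracies <- function(mom, eps = 0.01, prior_acc = 0.7,
                               zero_tol = 0.01) {
  M <- mom$M; R <- mom$reliable
  m <- nrow(M)
  prior_a <- 2 * prior_acc - 1
  mags <- rep(NA_real_, m)
  n_tri <- integer(m)
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    ests <- c()
    if (length(others) >= 2L) {
      pairs <- utils::combn(others, 2L)
      for (p in seq_len(ncol(pairs))) {
        j <- pairs[1, p]; kk <- pairs[2, p]
        if (!R[i, j] || !R[i, kk] || !R[j, kk]) next
        if (!is.finite(M[j, kk]) || abs(M[j, kk]) < zero_tol) next
        if (!is.finite(M[i, j]) || !is.finite(M[i, kk])) next
        ests <- c(ests, sqrt(abs(M[i, j] * M[i, kk] / M[j, kk])))
      }
    }
    n_tri[i] <- length(ests)
    if (length(ests)) mags[i] <- min(1, stats::median(ests))
  }
  mags[is.na(mags)] <- abs(prior_a)
  # relative signs from the moment signs, anchored at the source with the
  # most reliable pairs; global sign so that the mean accuracy is positive
  signs <- rep(1, m)
  ref <- which.max(rowSums(R & is.finite(M)))
  sgn <- sign(M[ref, ])
  sgn[!is.finite(sgn) | sgn == 0] <- 1
  signs <- sgn
  signs[ref] <- 1
  a <- mags * signs
  if (mean(a) < 0) a <- -a
  a <- pmin(pmax(a, 2 * eps - 1), 1 - 2 * eps)
  attr(a, "n_triplets") <- n_tri
  a
}

# gradient refinement of the moment-matching objective
#   sum_{i<j reliable} (M_ij - a_i a_j)^2 + l2 * sum_i (a_i - prior)^2
refine_accuracies <- function(a, mom, prior_a, lr = 0.05, epochs = 100L,
                              l2 = 0.05, eps = 0.01) {
  M <- mom$M; R <- mom$reliable
  W <- R & is.finite(M)
  diag(W) <- FALSE
  M0 <- M; M0[!W] <- 0
  for (e in seq_len(epochs)) {
    outer_a <- tcrossprod(a)
    resid <- (M0 - outer_a) * W
    grad <- -2 * (resid %*% a) + 2 * l2 * (a - prior_a)
    a <- a - lr * as.numeric(grad)
    a <- pmin(pmax(a, 2 * eps - 1), 1 - 2 * eps)
  }
  a
}

#' Construct a label model with known accuracies
#'
#' Used to inject accuracies directly (e.g. from an oracle or for worked
#' examples), skipping estimation.
#'
#' @param accuracies numeric vector (length m, probability scale, shared
#'   across class views) or m x (k+1) matrix of per-class-view accuracies.
#' @param k number of positive classes.
#' @param class_prior probability vector over classes `0..k`; default
#'   uniform.
#' @param propensity per-source non-abstain rates (informational).
#' @param lf_names source names.
#' @return object of class `label_model`.
#' @export
label_model <- function(accuracies, k = 1L,
                        class_prior = rep(1 / (k + 1), k + 1),
                        propensity = NULL, lf_names = NULL) {
  acc <- if (is.matrix(accuracies)) accuracies
         else matrix(accuracies, nrow = length(accuracies), ncol = k + 1L)
  colnames(acc) <- as.character(0:k)
  stopifnot(all(acc > 0 & acc < 1), abs(sum(class_prior) - 1) < 1e-8)
  structure(list(acc = acc, k = as.integer(k),
                 class_prior = class_prior,
                 propensity = propensity,
                 lf_names = lf_names, fitted = FALSE),
            class = "label_model")
}

#' Fit the label model to a label matrix
#'
#' For each class, a one-vs-rest binarized view of the votes yields pairwise
#' agreement moments; the triplet method provides closed-form accuracy
#' estimates, optionally refined by gradient descent on the moment-matching
#' objective with L2 regularization toward a uniform accuracy prior. The
#' class prior is estimated from majority-vote label frequencies unless
#' supplied. With fewer than 3 sources the model degrades to the uniform
#' accuracy prior (a warning is raised); its posterior then ranks sources
#' equally, like majority vote.
#'
#' @param lm a `label_matrix`.
#' @param k number of positive classes; defaults to the matrix maximum.
#' @param config list of tuning knobs, merged over defaults:
#'   `prior_acc` (uniform accuracy prior, probability scale; 0.7),
#'   `refine` (gradient refinement; TRUE), `lr` (0.05), `epochs` (100),
#'   `l2` (0.05), `min_overlap` (25), `eps` (clamp margin; 0.01),
#'   `class_prior` (NULL = estimate from majority vote).
#' @return a fitted `label_model`.
#' @export
fit_label_model <- function(lm, k = NULL, config = list()) {
  L <- if (inherits(lm, "label_matrix")) lm$L else lm
  cfg <- utils::modifyList(list(prior_acc = 0.7, refine = TRUE, lr = 0.05,
                                epochs = 100L, l2 = 0.05, min_overlap = 25L,
                                eps = 0.01, class_prior = NULL), config)
  if (is.null(k)) k <- max(1L, max(L))
  m <- ncol(L)
  prior_a <- 2 * cfg$prior_acc - 1
  acc <- matrix(cfg$prior_acc, m, k + 1L,
                dimnames = list(NULL, as.character(0:k)))
  if (m < 3L) {
    warning("fewer than 3 labeling functions: accuracies fall back to the ",
            "uniform prior (", cfg$prior_acc, ")")
  } else {
    for (c in 0:k) {
      B <- binarize_class(L, c)
      mom <- pairwise_moments(B, cfg$min_overlap)
      a <- triplet_accuracies(mom, eps = cfg$eps, prior_acc = cfg$prior_acc)
      if (isTRUE(cfg$refine))
        a <- refine_accuracies(as.numeric(a), mom, prior_a, lr = cfg$lr,
                               epochs = cfg$epochs, l2 = cfg$l2,
                               eps = cfg$eps)
      if (any(!is.finite(a))) {
        dump <- paste(utils::capture.output(print(round(mom$M, 4))),
                      collapse = "\n")
        stop("non-finite accuracy estimate for class ", c,
             "; moment matrix:\n", dump)
      }
      acc[, as.character(c)] <- (1 + as.numeric(a)) / 2
    }
  }
  class_prior <- cfg$class_prior
  if (is.null(class_prior)) {
    mv <- majority_vote(L, default_class = 0L, k = k)
    class_prior <- as.numeric(table(factor(mv, levels = 0:k)) / length(mv))
    # keep the prior off the simplex boundary
    class_prior <- (class_prior + 1e-3) / sum(class_prior + 1e-3)
  }
  model <- label_model(acc, k = k, class_prior = class_prior,
                       propensity = colMeans(L != -1L),
                       lf_names = if (inherits(lm, "label_matrix")) lm$lf_names)
  model$fitted <- TRUE
  model$config <- cfg
  model
}

#' @export
print.label_model <- function(x, ...) {
  cat(sprintf("<label_model: %d sources, %d+1 classes>\n", nrow(x$acc), x$k))
  cat("accuracies (probability scale, per class view):\n")
  print(round(x$acc, 3))
  cat("class prior:", paste(round(x$class_prior, 3), collapse = " "), "\n")
  invisible(x)
}

#' Posterior token-label probabilities
#'
#' Naive-Bayes combination under the conditional-independence factor model:
#' `P(y | lambda) \propto prior(y) * prod_i f(lambda_i; a_i, y)`, where a
#' source voting the hypothesis class contributes its accuracy, a source
#' voting any other class contributes `(1 - a) / k` (errors spread uniformly
#' over the k wrong classes), and abstains contribute no factor. Tokens on
#' which every source abstains receive the class prior.
#'
#' @param model a `label_model`.
#' @param lm a `label_matrix` (or plain vote matrix).
#' @return list with `probs` (matrix, tokens x classes `0..k`, rows sum to
#'   1) and `covered` (logical; any non-abstain vote).
#' @export
posterior_probs <- function(model, lm) {
  L <- if (inherits(lm, "label_matrix")) lm$L else lm
  k <- model$k
  K <- max(1L, k)                       # number of wrong classes
  n <- nrow(L)
  logscore <- matrix(rep(log(model$class_prior), each = n), n, k + 1L)
  NV <- (L != -1L) * 1
  for (c in 0:k) {
    p <- model$acc[, as.character(c)]
    Vc <- (L == c) * 1
    logscore[, c + 1L] <- logscore[, c + 1L] +
      as.numeric(Vc %*% log(p)) +
      as.numeric((NV - Vc) %*% log((1 - p) / K))
  }
  mx <- apply(logscore, 1L, max)
  probs <- exp(logscore - mx)
  probs <- probs / rowSums(probs)
  covered <- rowSums(NV) > 0
  if (any(!covered))
    probs[!covered, ] <- matrix(rep(model$class_prior, sum(!covered)),
                                ncol = k + 1L, byrow = TRUE)
  colnames(probs) <- as.character(0:k)
  list(probs = probs, covered = covered)
}

#' Hard labels from the label model
#'
#' Argmax of the posterior; exact posterior ties and tokens with no coverage
#' default to `default_class`.
#'
#' @param object a fitted `label_model`.
#' @param lm a `label_matrix`.
#' @param default_class class emitted on ties/no coverage.
#' @param ... unused.
#' @return integer vector of hard labels.
#' @export
predict.label_model <- function(object, lm, default_class = 0L, ...) {
  post <- posterior_probs(object, lm)
  P <- post$probs
  best <- max.col(P, ties.method = "first") - 1L
  maxp <- P[cbind(seq_len(nrow(P)), best + 1L)]
  tied <- rowSums(abs(P - maxp) < 1e-12) > 1L
  best[tied | !post$covered] <- as.integer(default_class)
  best
}

# ---------------------------------------------------------------------------
# Probabilistic-label serialization

#' Write probabilistic labels to JSONL
#'
#' One line per sentence: `{"doc_id": ..., "sent": ..., "probs": [[p0..pk],
#' ...], "covered": [...]}`.
#'
#' @param post output of [posterior_probs()].
#' @param index row index of the label matrix (`doc_id`, `sent_index`,
#'   `token_index`).
#' @param path output file.
#' @export
write_problabels <- function(post, index, path) {
  key <- paste(index$doc_id, index$sent_index)
  con <- file(path, "w")
  on.exit(close(con))
  for (gk in unique(key)) {
    rows <- which(key == gk)
    rec <- list(doc_id = index$doc_id[rows[1]],
                sent = index$sent_index[rows[1]],
                probs = lapply(rows, function(r) unname(post$probs[r, ])),
                covered = post$covered[rows])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_problabels
#' @export
read_problabels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  probs <- list(); covered <- c(); doc <- c(); sent <- c(); tok <- c()
  for (l in lines) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    P <- if (is.matrix(rec$probs)) rec$probs else do.call(rbind, rec$probs)
    probs[[length(probs) + 1L]] <- P
    covered <- c(covered, rec$covered)
    doc <- c(doc, rep(rec$doc_id, nrow(P)))
    sent <- c(sent, rep(rec$sent, nrow(P)))
    tok <- c(tok, seq_len(nrow(P)))
  }
  P <- do.call(rbind, probs)
  colnames(P) <- as.character(seq_len(ncol(P)) - 1L)
  list(probs = P, covered = covered,
       index = data.frame(doc_id = doc, sent_index = sent, token_index = tok,
                          stringsAsFactors = FALSE))
}
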