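# Noise-aware discriminative end model: a per-token softmax classifier over
# pluggable encoder features, trained on the label model's probabilistic
# labels with an expected cross-entropy loss, masking tokens on which every
# labeling function abstained. Trained to generalize beyond dictionary
# coverage (out-of-dictionary synonyms, unseen surface forms).

# deterministic 32-bit string hash (FNV-ish polynomial), used for feature
# hashing and seeded document splits
string_hash <- function(x, mod) {
  vapply(x, function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    h %% mod
  }, numeric(1), USE.NAMES = FALSE)
}

token_shape <- function(tok) {
  s <- gsub("[A-Z]", "X", tok)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "d", s)
  gsub("(.)\\1+", "\\1", s)   # collapse repeats: "Xxxx" -> "Xx"
}

#' Hashed windowed-context encoder
#'
#' The default desk-scale encoder: each token is mapped to a sparse binary
#' feature vector via the hashing trick. Features: the lowercased token,
#' its shape (case/digit pattern), prefix and suffix character n-grams, and
#' the lowercased neighbors within a +/- `window` token context. A stand-in
#' for contextual embeddings that preserves the training semantics
#' (soft labels, abstain masking); precomputed per-token embeddings can be
#' supplied instead via [matrix_encoder()].
#'
#' @param dim hashed feature dimension.
#' @param window neighbor context size in tokens.
#' @param affix_n length of prefix/suffix n-grams.
#' @return an encoder: a function mapping a [token_sequence()] to a sparse
#'   feature matrix (tokens x dim), with attribute `dim`.
#' @export
hashed_encoder <- function(dim = 4096L, window = 2L, affix_n = 3L) {
  enc <- function(seq) {
    toks <- seq$tokens
    n <- length(toks)
    if (!n) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(0L, dim)))
    low <- tolower(toks)
    feats <- vector("list", n)
    for (t in seq_len(n)) {
      f <- c(paste0("w=", low[t]),
             paste0("shape=", token_shape(toks[t])),
             paste0("pfx=", substr(low[t], 1L, affix_n)),
             paste0("sfx=", substr(low[t], max(1L, nchar(low[t]) - affix_n + 1L),
                                   nchar(low[t]))))
      for (o in seq_len(window)) {
        f <- c(f,
               paste0("w-", o, "=", if (t - o >= 1L) low[t - o] else "<s>"),
               paste0("w+", o, "=", if (t + o <= n) low[t + o] else "</s>"))
      }
      feats[[t]] <- f
    }
    nf <- lengths(feats)
    i <- rep(seq_len(n), nf)
    j <- string_hash(unlist(feats), dim) + 1
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(n, dim), use.last.ij = TRUE)
  }
  attr(enc, "feat_dim") <- as.integer(dim)
  enc
}

#' Encoder over precomputed embeddings
#'
#' Hook for externally computed per-token feature vectors (e.g. contextual
#' embeddings): `embeddings` maps `doc_id -> sent_index -> matrix`.
#'
#' @param embeddings nested list of per-sentence numeric matrices.
#' @param dim feature dimension.
#' @return an encoder function.
#' @export
matrix_encoder <- function(embeddings, dim) {
  enc <- function(seq) {
    M <- embeddings[[seq$doc_id]][[seq$sent_index]]
    stopifnot(nrow(M) == length(seq), ncol(M) == dim)
    methods::as(M, "CsparseMatrix")
  }
  attr(enc, "feat_dim") <- as.integer(dim)
  enc
}

#' Assemble the probabilistic training set
#'
#' Attaches per-token soft labels and the abstain mask (FALSE exactly where
#' every labeling function abstained, so those tokens contribute no loss),
#' and splits documents deterministically into train/validation by seeded
#' document hash.
#'
#' @param corpus list of documents.
#' @param post output of [posterior_probs()].
#' @param index label-matrix row index aligned with `post`.
#' @param valid_frac fraction of documents assigned to the validation split.
#' @param seed split seed.
#' @return object of class `prob_dataset`: list of per-sentence records
#'   (`seq`, `soft` matrix, `mask`, `split`).
#' @export
build_training_set <- function(corpus, post, index, valid_frac = 0.2,
                               seed = 1L) {
  key <- paste(index$doc_id, index$sent_index)
  doc_ids <- vapply(corpus, function(d) d$doc_id, character(1))
  split_of <- stats::setNames(
    ifelse(string_hash(paste0(doc_ids, ":", seed), 1000L) < valid_frac * 1000,
           "valid", "train"), doc_ids)
  records <- list()
  for (d in corpus) {
    for (s in d$sentences) {
      gk <- paste(d$doc_id, s$sent_index)
      rows <- which(key == gk)
      if (length(rows) != length(s))
        stop("alignment mismatch at doc ", d$doc_id, " sentence ",
             s$sent_index, ": ", length(rows), " label rows for ",
             length(s), " tokens")
      records[[length(records) + 1L]] <-
        list(seq = s, soft = post$probs[rows, , drop = FALSE],
             mask = post$covered[rows], split = split_of[[d$doc_id]])
    }
  }
  structure(records, class = "prob_dataset")
}

#' Noise-aware expected cross-entropy loss
#'
#' The expected cross-entropy of the predictions with respect to the
#' probabilistic labels: `-sum_y yhat(y) * log pred(y)`, averaged over
#' unmasked tokens. Reduces to standard cross-entropy for one-hot soft
#' labels and is minimized at `pred = soft` (Gibbs' inequality).
#'
#' @param pred matrix of predicted class probabilities (tokens x classes).
#' @param soft matrix of soft labels, same shape.
#' @param mask logical vector; masked-out (FALSE) tokens contribute nothing.
#' @return scalar loss (0 when no token is unmasked).
#' @export
noise_aware_loss <- function(pred, soft, mask = rep(TRUE, nrow(soft))) {
  pred <- as.matrix(pred); soft <- as.matrix(soft)
  stopifnot(identical(dim(pred), dim(soft)))
  if (any(pred[soft > 0] == 0))
    message("noise_aware_loss: zero predicted probability clipped at 1e-12")
  lp <- log(pmax(pred, 1e-12))
  per_tok <- -rowSums(soft * lp)
  if (!any(mask)) return(0)
  mean(per_tok[mask])
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

encode_dataset <- function(records, encoder) {
  X <- do.call(rbind, lapply(records, function(r) encoder(r$seq)))
  soft <- do.call(rbind, lapply(records, function(r) r$soft))
  mask <- unlist(lapply(records, function(r) r$mask))
  list(X = methods::as(X, "CsparseMatrix"), soft = soft, mask = mask)
}

# micro token F1 over entity classes (>= 1) for early stopping
token_f1_entity <- function(pred, gold) {
  tp <- sum(pred == gold & gold >= 1L)
  fp <- sum(pred >= 1L & pred != gold)
  fn <- sum(gold >= 1L & pred != gold)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the noise-aware end model
#'
#' A per-token softmax (multinomial logistic) classifier over encoder
#' features, fit by mini-batch gradient descent on the mean noise-aware
#' loss over unmasked tokens, with a linear-decay learning-rate schedule
#' with a 10% warmup period. When a validation split is present, training
#' early-stops on validation token F1 (micro, entity classes); the weights
#' of the best epoch are kept. Deterministic given the seed.
#'
#' @param dataset a `prob_dataset` from [build_training_set()].
#' @param encoder an encoder (default [hashed_encoder()]).
#' @param config list merged over defaults: `epochs` (30), `lr` (2),
#'   `batch_size` (256), `l2` (1e-4), `seed` (1), `patience` (5),
#'   `min_epochs` (10; burn-in before early stopping may trigger).
#' @return object of class `end_model`.
#' @export
train_end_model <- function(dataset, encoder = hashed_encoder(),
                            config = list()) {
  cfg <- utils::modifyList(list(epochs = 30L, lr = 2, batch_size = 256L,
                                l2 = 1e-4, seed = 1L, patience = 5L,
                                min_epochs = 10L), config)
  train <- dataset[vapply(dataset, function(r) r$split == "train", logical(1))]
  valid <- dataset[vapply(dataset, function(r) r$split == "valid", logical(1))]
  if (!length(train)) stop("no training sentences")
  tr <- encode_dataset(train, encoder)
  if (!any(tr$mask)) stop("zero unmasked training tokens")
  vl <- if (length(valid)) encode_dataset(valid, encoder)
  C <- ncol(tr$soft)
  D <- attr(encoder, "feat_dim")
  W <- matrix(0, D + 1L, C)           # + bias row
  Xm <- tr$X[tr$mask, , drop = FALSE]
  Ym <- tr$soft[tr$mask, , drop = FALSE]
  n <- nrow(Xm)
  nb <- max(1L, ceiling(n / cfg$batch_size))
  total_steps <- cfg$epochs * nb
  warmup <- max(1L, round(0.1 * total_steps))
  step <- 0L
  best <- list(f1 = -Inf, W = W, epoch = 0L)
  bad <- 0L
  set.seed(cfg$seed %% 2147483647)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(nb)) {
      step <- step + 1L
      lr_t <- if (step <= warmup) cfg$lr * step / warmup
              else cfg$lr * max(0, (total_steps - step) / (total_steps - warmup))
      rows <- ord[(((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n))]
      Xb <- Xm[rows, , drop = FALSE]
      Yb <- Ym[rows, , drop = FALSE]
      Z <- as.matrix(Xb %*% W[-1L, , drop = FALSE]) +
        matrix(W[1L, ], nrow(Xb), C, byrow = TRUE)
      P <- softmax_rows(Z)
      G <- (P - Yb) / nrow(Xb)
      W[-1L, ] <- W[-1L, ] - lr_t * (as.matrix(Matrix::crossprod(Xb, G)) +
                                       cfg$l2 * W[-1L, ])
      W[1L, ] <- W[1L, ] - lr_t * colSums(G)
    }
    if (!is.null(vl) && any(vl$mask)) {
      Z <- as.matrix(vl$X %*% W[-1L, , drop = FALSE]) +
        matrix(W[1L, ], nrow(vl$X), C, byrow = TRUE)
      pred <- max.col(Z, ties.method = "first") - 1L
      gold <- max.col(vl$soft, ties.method = "first") - 1L
      f1 <- token_f1_entity(pred[vl$mask], gold[vl$mask])
      if (f1 > best$f1 + 1e-9) {
        best <- list(f1 = f1, W = W, epoch = ep); bad <- 0L
      } else {
        bad <- bad + 1L
        # patience only counts after the burn-in period, so an initial
        # majority-class plateau cannot stop training
        if (ep > cfg$min_epochs && bad >= cfg$patience) break
      }
    } else {
      best <- list(f1 = NA_real_, W = W, epoch = ep)
    }
  }
  structure(list(W = best$W, encoder = encoder, n_classes = C,
                 config = cfg, valid_f1 = best$f1, best_epoch = best$epoch),
            class = "end_model")
}

#' @export
print.end_model <- function(x, ...) {
  cat(sprintf("<end_model: %d classes, dim %d, best epoch %d (valid F1 %s)>\n",
              x$n_classes, attr(x$encoder, "feat_dim"), x$best_epoch,
              ifelse(is.na(x$valid_f1), "n/a", sprintf("%.3f", x$valid_f1))))
  invisible(x)
}

end_model_probs <- function(model, seq) {
  if (!length(seq))
    return(matrix(numeric(0), 0L, model$n_classes,
                  dimnames = list(NULL, as.character(0:(model$n_classes - 1L)))))
  X <- model$encoder(seq)
  Z <- as.matrix(X %*% model$W[-1L, , drop = FALSE]) +
    matrix(model$W[1L, ], nrow(X), model$n_classes, byrow = TRUE)
  P <- softmax_rows(Z)
  colnames(P) <- as.character(0:(model$n_classes - 1L))
  P
}

#' Predict tags for a token sequence
#'
#' Per-token argmax in the IO scheme. For span tasks, supply `head_tokens`
#' (1-based token indices) to classify only the head word of each
#' pre-identified entity; the head word of a span is its first token.
#'
#' @param model a fitted `end_model`.
#' @param seq a [token_sequence()].
#' @param head_tokens optional integer vector of head-token indices.
#' @return for NER mode, a character IO tag vector of sequence length with
#'   attribute `probs`; for span mode, an integer class vector of length
#'   `length(head_tokens)` with attribute `probs`.
#' @export
predict_tags <- function(model, seq, head_tokens = NULL) {
  P <- end_model_probs(model, seq)
  if (!is.null(head_tokens)) {
    P <- P[head_tokens, , drop = FALSE]
    cls <- max.col(P, ties.method = "first") - 1L
    attr(cls, "probs") <- P
    return(cls)
  }
  cls <- if (nrow(P)) max.col(P, ties.method = "first") - 1L else integer(0)
  tags <- ifelse(cls == 0L, "O", paste0("I-", cls))
  attr(tags, "scheme") <- "IO"
  attr(tags, "probs") <- P
  tags
}
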