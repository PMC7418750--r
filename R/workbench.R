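# End-to-end pipeline runner and configuration: label -> fit -> (optional)
# train -> eval, with reproducible, config-hash-stamped artifacts; plus the
# terminology partition sweep.

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", as.integer(string_hash(s, 2^31 - 1)))
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with entries: `corpus`
#' (JSONL path), `terminologies` (TSV path), `class_map` (YAML path),
#' `out_dir`; optional `gold` (CoNLL path), `unmatched`
#' (`"abstain"`/`"negative"`, default abstain), `default_class` (0),
#' `label_model` (config list for [fit_label_model()]), `end_model`
#' (`NULL` to skip, else config list for [train_end_model()]), and `seed`.
#' Seeds are explicit; there are no wall-clock defaults.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("corpus", "terminologies", "class_map", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("pipeline config lacks: ", paste(missing, collapse = ", "))
  for (f in c("corpus", "terminologies", "class_map"))
    if (!file.exists(config[[f]])) stop("missing file: ", config[[f]])
  if (!is.null(config$gold) && !file.exists(config$gold))
    stop("missing file: ", config$gold)
  defaults <- list(unmatched = "abstain", default_class = 0L,
                   label_model = list(), end_model = NULL, seed = 1L)
  config <- utils::modifyList(defaults, config)
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the weak-supervision pipeline
#'
#' Executes label -> fit -> (optional) train -> eval: builds semantic-type
#' labeling functions from the terminologies, applies them to the corpus to
#' form the label matrix, fits the label model, writes probabilistic labels
#' and hard predictions (majority vote and label model; end model when
#' configured), and scores against gold tags when provided. Every artifact
#' record is stamped with the config hash and seed; reruns with the same
#' config and seed are bitwise-reproducible. Set `end_model = NULL` (the
#' default) to use the label model as the final classifier.
#'
#' @param config a [pipeline_config()] (or list / YAML path).
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  report <- list(config_hash = config_hash(unclass(config)),
                 seed = config$seed, stages = list())
  result <- tryCatch({
    corpus <- read_jsonl_corpus(config$corpus)
    class_map <- read_class_map(config$class_map)
    terminologies <- load_terminologies(config$terminologies, class_map)
    k <- max(class_map)

    stage <- "label"
    type_map <- build_type_distribution(terminologies, class_map)
    lfs <- lapply(terminologies, function(v)
      lf_semantic_type(v, type_map = type_map, unmatched = config$unmatched))
    lm <- build_label_matrix(unname(lfs), corpus)
    write_label_matrix(lm, file.path(config$out_dir, "label_matrix.tsv"))
    report$stages$label <- list(n_tokens = nrow(lm$L), n_lfs = ncol(lm$L),
                                abstain_rate = mean(lm$L == -1L))

    stage <- "fit"
    mv <- majority_vote(lm, default_class = config$default_class, k = k)
    model <- fit_label_model(lm, k = k, config = config$label_model)
    post <- posterior_probs(model, lm)
    write_problabels(post, lm$index,
                     file.path(config$out_dir, "problabels.jsonl"))
    lm_pred <- predict(model, lm, default_class = config$default_class)
    report$stages$fit <- list(accuracies = round(model$acc[, "1"], 6),
                              class_prior = round(model$class_prior, 6))

    sent_tokens <- lapply(corpus_sentences(corpus), function(s) s$tokens)
    split_by_sent <- function(x) {
      key <- paste(lm$index$doc_id, lm$index$sent_index)
      unname(split(x, factor(key, levels = unique(key))))
    }
    to_tags <- function(labels)
      lapply(split_by_sent(labels), function(cls)
        ifelse(cls == 0L, "O", paste0("I-", cls)))
    write_conll(sent_tokens, to_tags(mv),
                file.path(config$out_dir, "pred_mv.conll"))
    write_conll(sent_tokens, to_tags(lm_pred),
                file.path(config$out_dir, "pred_lm.conll"))
    preds <- list(mv = mv, lm = lm_pred)

    if (!is.null(config$end_model)) {
      stage <- "train"
      em_cfg <- config$end_model
      em_cfg$seed <- config$seed
      dataset <- build_training_set(corpus, post, lm$index,
                                    seed = config$seed)
      em <- train_end_model(dataset, config = em_cfg)
      ws_tags <- lapply(corpus_sentences(corpus), function(s)
        as.character(predict_tags(em, s)))
      write_conll(sent_tokens, ws_tags,
                  file.path(config$out_dir, "pred_ws.conll"))
      preds$ws <- unlist(lapply(ws_tags, tag_class))
      report$stages$train <- list(best_epoch = em$best_epoch,
                                  valid_f1 = em$valid_f1)
    }

    if (!is.null(config$gold)) {
      stage <- "eval"
      gold <- read_conll(config$gold)
      gold_cls <- unlist(lapply(gold$tags, tag_class))
      metrics <- lapply(preds, function(p) {
        tab <- token_prf(gold_cls, p)
        as.list(tab[tab$class == "micro", c("precision", "recall", "f1")])
      })
      report$stages$eval <- metrics
    }
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "' (artifacts so far in ",
         config$out_dir, "): ", conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(result, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Sweep terminology partition sizes
#'
#' For each partition size `s`, keeps the top-`s` ranked terminologies as
#' individual label sources, merges the remainder into one source, rebuilds
#' the label matrix, fits the label model, and scores majority vote and the
#' label model against gold tags (micro token F1). Reported both raw and
#' relative to the best majority-vote score across the sweep; the best `s`
#' is the label-model argmax.
#'
#' @param terminologies list of `terminology` objects.
#' @param corpus list of documents.
#' @param gold_tags list of gold IO tag vectors, one per sentence in corpus
#'   order.
#' @param class_map named integer class map.
#' @param s_values partition sizes to evaluate (default `1..n`).
#' @param lm_config label-model config.
#' @param unmatched unmatched-token policy for the ontology labeling
#'   functions.
#' @param default_class abstain/tie default.
#' @return data frame with columns `s`, `f1_mv`, `f1_lm`,
#'   `lm_minus_best_mv`; attribute `best_s`.
#' @export
partition_sweep <- function(terminologies, corpus, gold_tags, class_map,
                            s_values = seq_along(terminologies),
                            lm_config = list(), unmatched = "negative",
                            default_class = 0L) {
  stopifnot(length(terminologies) >= 2L)
  k <- max(class_map)
  ranked <- rank_by_coverage(terminologies, corpus)
  gold_cls <- unlist(lapply(gold_tags, tag_class))
  type_map <- build_type_distribution(terminologies, class_map)
  micro_f1 <- function(pred) {
    tab <- token_prf(gold_cls, pred)
    tab$f1[tab$class == "micro"]
  }
  rows <- lapply(s_values, function(s) {
    part <- partition_sources(ranked, s)
    sources <- c(part$individual, if (!is.null(part$merged)) list(part$merged))
    lfs <- lapply(sources, function(v)
      lf_semantic_type(v, type_map = type_map, unmatched = unmatched))
    lm <- build_label_matrix(lfs, corpus)
    mv <- majority_vote(lm, default_class = default_class, k = k)
    f1_lm <- if (ncol(lm$L) >= 3L) {
      model <- fit_label_model(lm, k = k, config = lm_config)
      micro_f1(predict(model, lm, default_class = default_class))
    } else micro_f1(mv)
    data.frame(s = s, f1_mv = micro_f1(mv), f1_lm = f1_lm)
  })
  out <- do.call(rbind, rows)
  out$lm_minus_best_mv <- out$f1_lm - max(out$f1_mv)
  attr(out, "best_s") <- out$s[which.max(out$f1_lm)]
  out
}
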