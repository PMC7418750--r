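#!/usr/bin/env Rscript
# Thin command-line front end over the weakner package.
#
#   Rscript scripts/weakner.R simulate --out DIR [--seed N] [--sentences N] [--k N]
#   Rscript scripts/weakner.R run      --config FILE
#   Rscript scripts/weakner.R sweep    --config FILE [--s 1,2,4] [--out FILE]
#
# `simulate` writes corpus.jsonl, terms.tsv, classes.yaml, gold.conll and a
# manifest.yaml into --out; `run` executes the full pipeline from a YAML
# config (see ?pipeline_config); `sweep` runs the terminology partition
# sweep on a config's inputs.

suppressPackageStartupMessages(library(weakner))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: weakner.R <simulate|run|sweep> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

if (cmd == "simulate") {
  out <- opt("--out"); if (is.null(out)) stop("simulate needs --out")
  seed <- as.integer(opt("--seed", "1"))
  n_sent <- as.integer(opt("--sentences", "200"))
  k <- as.integer(opt("--k", "1"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  w <- world_spec(k = k, density = 0.7, entities_max = 2L, seed = seed)
  g <- generate_corpus(w, n_sent, seed = seed + 1L)
  specs <- list(source_spec("va", recall = 0.9, spurious = 0.05),
                source_spec("vb", recall = 0.7, spurious = 0.02),
                source_spec("vc", recall = 0.6, spurious = 0.02),
                source_spec("vd", recall = 0.5, spurious = 0.10))
  srcs <- generate_sources(w, specs, seed = seed + 2L)
  write_jsonl_corpus(g$corpus, file.path(out, "corpus.jsonl"))
  rows <- do.call(rbind, lapply(srcs, function(v)
    data.frame(term = v$entries$term, source = v$name,
               semantic_type = v$entries$type)))
  utils::write.table(rows, file.path(out, "terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(stats::setNames(as.list(0:k), paste0("T", 0:k)),
                   file.path(out, "classes.yaml"))
  sents <- lapply(unlist(lapply(g$corpus, function(d) d$sentences),
                         recursive = FALSE), function(s) s$tokens)
  write_conll(sents, g$gold_tags, file.path(out, "gold.conll"))
  yaml::write_yaml(list(seed = seed, n_sentences = n_sent, k = k,
                        density = 0.7, entities_max = 2,
                        sources = lapply(specs, unclass)),
                   file.path(out, "manifest.yaml"))
  cat("simulated corpus + sources in", out, "\n")

} else if (cmd == "run") {
  cfg <- opt("--config"); if (is.null(cfg)) stop("run needs --config")
  report <- run_pipeline(cfg)
  cat("pipeline done; report at",
      file.path(pipeline_config(cfg)$out_dir, "report.json"), "\n")
  if (!is.null(report$stages$eval))
    for (m in names(report$stages$eval))
      cat(sprintf("  %s: F1 %.4f\n", m, report$stages$eval[[m]]$f1))

} else if (cmd == "sweep") {
  cfg <- pipeline_config(opt("--config"))
  class_map <- read_class_map(cfg$class_map)
  corpus <- read_jsonl_corpus(cfg$corpus)
  terms <- load_terminologies(cfg$terminologies, class_map)
  gold <- read_conll(cfg$gold)
  s_vals <- as.integer(strsplit(opt("--s", paste(seq_along(terms),
                                                 collapse = ",")), ",")[[1]])
  tab <- partition_sweep(unname(terms), corpus, gold$tags, class_map,
                         s_values = s_vals, unmatched = cfg$unmatched)
  out <- opt("--out")
  if (!is.null(out)) utils::write.table(tab, out, sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  print(tab)
  cat("best s:", attr(tab, "best_s"), "\n")

} else stop("unknown command: ", cmd)
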