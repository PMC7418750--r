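---
title: "Weakly supervised entity classification with weakner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised entity classification with weakner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakner)
```

## The problem

Named-entity recognition and span-attribute classification (negation,
document-relative temporality) in biomedical and clinical text traditionally
require hand-labeled corpora, which are expensive to produce and — for
clinical notes — hard to share. `weakner` instead builds word-level
classifiers from *weak supervision*: many imperfect, programmatic label
sources, chiefly medical terminologies, combined and denoised without any
ground-truth labels.

The pipeline has three stages:

1. **Label.** Each terminology (or rule) becomes a *labeling function*
   $\lambda_j$ that, for every word $x$ in a sentence, emits a vote in
   $\{-1, 0, \dots, k\}$, where $-1$ means *abstain*, $0$ is the negative
   ("not an entity") class and $1..k$ are entity classes. Applied to a
   corpus of $n$ words, $m$ labeling functions form the label matrix
   $\Lambda \in \{-1,0,\dots,k\}^{n \times m}$.
2. **Denoise.** A generative *label model* estimates each source's latent
   accuracy from $\Lambda$ alone and combines the votes into a posterior
   $P(Y \mid \Lambda)$ per word, replacing the equal-weight majority-vote
   baseline.
3. **Generalize.** A discriminative *end model* is trained on the
   probabilistic labels with a noise-aware loss so that it can label
   surface forms no source covers.

## Labeling-function templates

**Semantic-type functions** (`lf_semantic_type()`) wrap one terminology.
Term matching is greedy longest-match (in tokens), left to right, which
disambiguates nested terms: with both "lung" (anatomy) and "lung cancer"
(disease) in the dictionary, the longer disease term wins. A term mapped to
several classes carries a probability vector (its normalized count of
(source, class) assignments, `build_type_distribution()`); matches take the
argmax class and abstain on exact ties. The optional slot pattern
`{*} ({*})` labels compositional mentions such as "Tylenol (Acetaminophen)"
when both slots match same-class terms.

**Synset functions** (`lf_synset()`) implement document-scoped synonym
disambiguation: a concept's synonym set fires only when at least two
distinct member terms occur in the same document, and then labels every
occurrence of every member. With `schwartz_hearst = TRUE`, definitions of
the form "heart failure (HF)" are detected by the Schwartz–Hearst
character-matching rule, linking the short form to the dictionary entry for
the rest of the document even when the abbreviation itself is
out-of-dictionary.

**Context-window functions** (`lf_context_window()`) classify
pre-identified entity spans by scanning a bounded token window to the left
and/or right for cue phrases — the NegEx/ConText strategy for negation —
or, for document-relative temporality, by parsing the nearest explicit
datetime mention (ISO, `MM/DD/YYYY`, or "Month D, YYYY") in token distance
and comparing it with the document timestamp (before / after / overlap).

**Pattern functions** (`lf_pattern()`) wrap a regular expression or a small
dictionary with a fixed emitted class; with class 0 they express guideline
knowledge such as "punctuation, numbers and stopwords are never entities".

### The unmatched-token policy

What should an ontology-derived function vote on a word it does not match?
Both behaviors are legitimate: staying silent (abstain, $-1$) is
conservative, while voting the negative class asserts coverage. The policy
is per-function (`unmatched = "abstain"` or `"negative"`, default abstain).
Two practical notes: the accuracy estimator needs observed *disagreement*,
which all-positive dictionaries voting on disjoint words cannot provide —
either use `"negative"` or add guideline dictionaries of class 0; and the
worked fixture (`span_disagreement_fixture()`) reproduces the classic
failure mode under `"negative"`: two of four sources lack "diabetes type
2", majority vote ties 2–2 on "type 2" and truncates the span, while
accuracy weighting recovers it.

## The label model

Majority vote treats sources as equally reliable. The label model instead
scores each source by its accuracy on the $\pm 1$ scale,
$a_i = E[\lambda_i Y]$, which is not observable — but the product
$a_i a_j = E[\lambda_i Y \lambda_j Y] = E[\lambda_i \lambda_j]$ *is*
observable as the co-voting rate of sources $i$ and $j$, assuming
independent errors. `pairwise_moments()` estimates these rates (abstains
excluded pairwise; pairs with fewer than `min_overlap = 25` co-votes are
flagged unreliable), and `triplet_accuracies()` solves for the magnitudes
closed-form: for any triplet, $|a_i| = \sqrt{|M_{ij} M_{ik} / M_{jk}|}$,
aggregated over all valid triplets by the median. Accuracies are
recoverable only up to a sign; relative signs come from the moment signs
and the global sign is fixed by assuming sources are better than random on
average. Estimates are clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 0.01$ on the probability scale) and optionally refined by
gradient descent on the moment-matching objective
$\sum_{i<j}(M_{ij} - a_i a_j)^2$ with L2 regularization toward a uniform
accuracy prior (default 0.7; the exposed knobs are the learning rate,
epochs, L2 weight and the prior).

Multiclass votes are handled one-vs-rest per class with shared abstains.
The posterior is a naive-Bayes combination under a symmetric
class-conditional noise model: a source votes the true class with
probability $p_i$ and otherwise spreads its error uniformly over the $k$
wrong classes; abstains contribute no factor, and fully-abstained words
receive the class prior (estimated from majority-vote frequencies unless
supplied). This closed form makes exact oracle testing possible: on every
3-source vote configuration the posterior equals brute-force enumeration of
the generative model to $10^{-9}$.

With fewer than three sources the triplet method is undefined; the model
falls back to the uniform accuracy prior with a warning, which makes its
posterior rank sources equally, like majority vote.

The exact estimation objective and optimizer of the matrix-completion
formulation used by large weak-supervision systems are not reproduced here;
moment/triplet estimation with optional gradient refinement is this
package's committed, documented estimator. Source-dependency (correlation)
structure is deliberately not modeled.

## The end model

`train_end_model()` fits a per-token softmax classifier over pluggable
encoder features by mini-batch gradient descent on the *noise-aware loss* —
the expected cross-entropy under the probabilistic labels,
$-\sum_y \hat y(y)\, \log p_w(y \mid x)$ — with all-abstained tokens masked
out of the loss entirely. The learning-rate schedule is linear decay with a
10% warmup period; when a validation split exists (deterministic seeded
document-hash split, `build_training_set()`), training early-stops on
validation token F1 (micro over entity classes) after a burn-in of
`min_epochs = 10` epochs — the burn-in prevents the early all-majority
plateau from stopping training — and the best epoch's weights are kept.
Whether early stopping should monitor token or span F1 is a genuinely open
choice; token F1 is the default because the loss itself is token-level.

The default encoder (`hashed_encoder()`) maps each token to hashed sparse
features: lowercased identity, case/digit shape, prefix/suffix character
3-grams, and the lowercased neighbors within ±2 tokens. It is a desk-scale
stand-in for contextual embeddings that preserves the training semantics
(soft labels, masking); `matrix_encoder()` accepts precomputed per-token
embeddings to emulate the transformer setting. For span tasks the head
word of a span is its first token — the simplest deterministic choice.

## Evaluation

NER is scored by exact span matching (`exact_span_prf()`): a prediction
counts only when sequence, boundaries and class all match, after IO tags
are converted to BIO (`io_to_bio()`) so head-word errors are counted.
Span-attribute tasks use micro-averaged token metrics (`token_prf()`).
`compare_report()` summarizes seeded replicates as mean ± SD and tests
paired differences with a two-sided Wilcoxon signed-rank test; zero
differences are handled by the Pratt method (ranked, then dropped), a
documented choice among the test's variants, with no multiple-comparison
correction across tasks. Scores are stored as proportions and conventionally
reported ×100.

## What the synthetic world emulates — and what it does not

Real terminology-driven weak supervision cannot be redistributed (the
primary vocabulary collections are license-gated), so `weakner` ships
seeded generators that reproduce the *statistical structure* the method
relies on:

* `world_spec()` / `generate_corpus()` — sentences of background words with
  entity terms inserted at a controlled density; 30% of lexicon entries are
  2–3 token terms to exercise longest-match logic; entity words carry
  class-specific suffix morphology ("-itis", "-oma", …) the way real
  disease and drug names do, while background words end neutrally. Span
  counts per sentence are Binomial(`entities_max`, `density`).
* `generate_sources()` — noisy terminologies with controlled recall
  (fraction of the lexicon known), a precision proxy (fraction of the
  background vocabulary spuriously included), and semantic-type corruption.
* `generate_label_matrix()` — vote matrices straight from the label model's
  generative assumptions (correct with probability $a_i$, else uniform
  among wrong classes, independent abstains), for estimator tests with
  known truth.

Two fixed scenarios encode the study conditions used by the benchmark
harnesses. `scenario_mixed_quality()` mixes one high-recall source whose
spurious terms bring its word-level precision to about 0.65 with three
high-precision sources (recall 0.85, 2% spurious), on a corpus where about
30% of tokens belong to entities (sentence length 4–8 background tokens,
up to two entities per sentence at density 0.8, 400 sentences) — chosen so
that equal-weight voting ties on exactly the words where source quality
differs. `scenario_generalization()` lets three overlapping sources cover
80% of the lexicon with the remaining 20% held out of every source, plus
guideline dictionaries (function words and 70% of the background
vocabulary, class 0) for negative supervision; training uses 400 sentences
and evaluation 150.

These worlds are deliberately not clinically realistic language: sentences
are bags of filler words, entity surface forms are morphologically clean,
and source errors are independent by construction. Passing tests therefore
demonstrate that the estimators and training machinery behave as designed
under the model's own assumptions at desk scale — not that any particular
F1 would be attained on real clinical corpora, where correlated source
errors, misspellings and annotation idiosyncrasies all matter. The
correlated-noise case is exactly what the independence assumption excludes,
and what the generator's defaults avoid.

At this scale the terminology partition sweep (`partition_sweep()`)
typically shows the label model *matching* rather than strictly beating the
best majority-vote baseline for some partition sizes; the clear strict
gains appear in the mixed-quality scenario above, where source quality is
heterogeneous by construction.

## Numerical choices and degenerate inputs

* Coordinates are 1-based with end-exclusive spans throughout.
* Longest-match ties at the same start and length prefer the higher class
  probability, then abstain; scanning is leftmost-first greedy.
* Accuracy clamping $\varepsilon = 0.01$; triplet denominators below 0.01
  in magnitude are skipped; sources with no usable triplet fall back to
  the accuracy prior.
* Posterior ties and uncovered tokens default to the majority class
  (`default_class`), mirroring the majority-vote convention.
* Predicted probabilities of exactly 0 at a supported class are clipped at
  $10^{-12}$ in the loss (logged).
* Malformed BIO (`I` after `O` or a class change) is repaired as `B` with
  a warning; empty sequences, empty span lists, all-abstain columns and
  empty terminologies are all defined, warn where useful, and never error.
* All generators and both models are deterministic given their seeds; the
  pipeline runner stamps every report with a config hash and seed, and
  reruns are bitwise identical.

## Problem sizes

The shipped test-bed sizes — 10,000 instances × 8 sources for accuracy
recovery (20 replicates), 400-sentence corpora for the 50-run
mixed-quality comparison and the 20-run generalization harness, 4096-dim
hashed features — were chosen as the smallest scales at which the
estimators' sampling noise is well below the effects being measured; all
headline quantities are recomputed from scratch by `scripts/acceptance.R`.
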