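# weakner

Ontology-driven weak supervision for medical entity classification in R.

`weakner` builds word-level entity classifiers (disease, chemical, drug,
disorder tagging; negation and document-relative temporality of
pre-identified spans) **without hand-labeled training data**. It is aimed at
biomedical/clinical NLP practitioners who have terminologies and rules but
no annotation budget: flat term lists with semantic-type assignments become
labeling functions, their conflicting votes are denoised by a
data-programming label model, and a noise-aware discriminative classifier is
trained on the result so it can generalize beyond dictionary coverage.

## The model

Each of *m* label sources is a labeling function λ_j emitting, per word, a
vote in {−1, 0, …, k} (−1 = abstain, 0 = not-an-entity, 1..k = entity
classes); applied to *n* words they form the label matrix **Λ**. The
equal-weight baseline is majority vote. The label model instead scores each
source by its latent accuracy on the ±1 scale, a_i = E[λ_i·Y]. Although a_i
is unobservable without gold labels, the product
a_i·a_j = E[λ_i·Y·λ_j·Y] = E[λ_i·λ_j] is just the rate at which sources
vote together, so under independent noise the accuracies are recoverable up
to a sign from pairwise agreement moments via source triplets:
|a_i| = sqrt(|M_ij·M_ik / M_jk|). The fitted accuracies feed a naive-Bayes
posterior P(Y | Λ) (abstains contribute no factor), and an end model is
trained on those probabilistic labels ŷ with the noise-aware expected
cross-entropy −Σ_y ŷ(y)·log p_w(y|x), masking words on which every source
abstained.

See `vignette("weak-supervision")` for the full account: labeling-function
templates (longest-match semantic-type tagging, document-scoped synsets with
Schwartz–Hearst abbreviation linking, NegEx-style context windows, pattern
rules), estimator details, and what the synthetic test bed does and does not
demonstrate.

## Worked example

The classic failure mode of equal-weight voting, reconstructed as a
fixture: four terminologies label a sentence containing *diabetes type 2*,
but two of them only know the single word *diabetes*.

```r
library(weakner)
fx  <- span_disagreement_fixture()
lmx <- build_label_matrix(fx$lfs, fx$corpus)
lmx$L
#>       mth chv lnc snomedct
#>  [1,]   0   0   0        0
#>  ...
#>  [5,]   1   1   1        1     # "diabetes"
#>  [6,]   0   1   1        0     # "type"
#>  [7,]   0   1   1        0     # "2"
#>  ...

majority_vote(lmx, default_class = 0L)
#>  [1] 0 0 0 0 1 0 0 0 0 0
```

Majority vote ties 2–2 on "type" and "2" and truncates the entity to the
single word *diabetes*. A label model whose accuracies favor the full-term
sources (0.9 for chv/lnc vs 0.7 for mth/snomedct) re-weights the votes:

```r
model <- label_model(c(0.7, 0.9, 0.9, 0.7), k = 1)
round(posterior_probs(model, lmx)$probs[5:7, ], 3)
#>          0     1
#> [1,] 0.002 0.998
#> [2,] 0.063 0.937
#> [3,] 0.063 0.937
predict(model, lmx)
#>  [1] 0 0 0 0 1 1 1 0 0 0
```

The full span is recovered: P(entity) = 0.937 on the disputed words, so all
three tokens of *diabetes type 2* are labeled.

On larger (synthetic) corpora the accuracies are *fitted*, not injected —
`fit_label_model()` recovers them from agreement statistics alone — and the
whole chain runs from files via `run_pipeline()` or the thin CLI:

```sh
Rscript scripts/weakner.R simulate --out sim --seed 3 --sentences 120
Rscript scripts/weakner.R run --config sim/config.yaml
#> pipeline done; report at sim/out/report.json
#>   mv: F1 0.7444
#>   lm: F1 0.7444
```

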