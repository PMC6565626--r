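---
title: "Measuring semantic density and latent content in speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring semantic density and latent content in speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdens)
```

## The problem

Poverty of content — speech that is adequate in quantity but conveys little
information — is a classic negative indicator of psychosis risk, and implicit
talk about voices and sounds is an early correlate of auditory hallucination.
`semdens` implements two embedding-based markers of these phenomena for
interview transcripts, together with the logistic prediction layer used to
evaluate them and a synthetic-cohort generator that makes the whole chain
testable without clinical data.

## Semantic density by vector unpacking

Each sentence is reduced to its content words (nouns, verbs, adjectives,
adverbs), every content word is looked up as a POS-prefixed lemma key (for
example `NN_voice`) in a word-embedding space, and the sentence vector is the
unit-normalized sum of those embeddings:

$$ y_j = \frac{\sum_{k \in I_j} x_k}{\lVert \sum_{k \in I_j} x_k \rVert}. $$

*Vector unpacking* then asks how many word embeddings are genuinely needed to
rebuild $y_j$. Gradient descent minimizes the Euclidean cost
$E = \tfrac12 \lVert y_j - \sum_i w_i x_i \rVert^2$ over one scalar weight per
candidate word, starting from all-zero weights, with update
$w_i \leftarrow w_i + \eta \sum_k (y_j - \hat y_j)_k \, x_{ik}$. After
iteration $t$, any weight below the growing threshold
$t / (\tau \cdot \text{max iterations})$ is set exactly to zero; by the final
iteration the threshold is $1/\tau$. With the defaults $\tau = 100$ and
5000 iterations, the schedule prunes the candidate lexicon down to a small set
of influential embeddings.

The retained *meaning components* are chosen from the nonzero weights by
F-ratio partitioning: the rank-ordered weights are split at every position
into a high and a low group, each split is scored by the two-group one-way
F ratio (between-group mean square over within-group mean square, with a
size-one group contributing zero within-group variance), and the high group of
the best split is kept. Ties between splits go to the smaller high group,
which is the conservative choice for density. When the resulting density
$D_j = m_j / n_j$ (components per content token, repetitions counted in
$n_j$) falls at or below 0.25 — the signature of heavy word repetition, where
the best split isolates the repeated word — selection is redone once at the
split with the second-highest F ratio. One or two nonzero weights, or a set of
numerically identical weights (for which F is undefined), are all selected. A
participant's score is the mean density over their sentences.

Two comparator measures ship alongside: *idea density* (verbs + adjectives +
adverbs + prepositions + conjunctions over total tokens) and *information
value* (mean and resultant vector length of the unnormalized embeddings).

### Numerical choices

* **Learning rate.** $\eta$ is not dictated by the method; the default 0.01
  is stable for unit-norm lexicons (instability sets in near
  $2/\lambda_{\max}$ of the candidate Gram matrix). A diverging run raises an
  error naming $\eta$ rather than returning garbage.
* **Initialization.** All-zero weights, which is deterministic; the first
  gradient step seeds exactly the words correlated with the sentence vector.
* **Pruning.** The threshold comparison is on the signed value by default,
  so negative weights — which have no reading as meaning components — are
  zeroed as well; magnitude pruning is available as a flag. Pruned weights
  are exactly zero, never merely small.
* **Candidate lexicon.** Defaults to the full embedding space. On toy
  lexicons the nonzero-weight count is bounded by the lexicon size; the
  30–50 nonzero weights typical at full scale are a property of large
  vocabularies and are not asserted at test scale.
* **Degenerate inputs.** Sentences with no in-vocabulary content words, a
  zero resultant, or no nonzero unpacking weights raise a classed
  skip-sentence warning and are excluded from density and cosine analyses.
  $m_j > n_j$ is possible on correlated lexicons and is reported as computed,
  not clamped.

## Latent content analysis

A speaker's sentences are profiled against a large probe vocabulary — by
default the smallest high-frequency prefix covering 95% of corpus tokens —
by taking, for each probe word, the *maximum* cosine between the probe's
embedding and any sentence vector. Because the comparison is against whole
sentence vectors, a probe can score high without ever having been spoken,
which is what makes the content latent. Profiles are averaged within a group
and contrasted against the same profile computed from a baseline corpus of
ordinary conversation (one document per contributor).

The default contrast weight is the group-to-baseline log-enrichment

$$ w(p) = c_g(p)\,\log\!\frac{c_g(p)}{c_b(p)}, $$

with both cosines floored at $10^{-6}$. The term-frequency analog $c_g$
rewards probes the group actually evokes, and dividing by the probe's own
baseline cosine cancels the geometric bias that makes some embeddings score
high against *every* sentence. A variant that scales $c_g$ by
$\log(\bar c_b / c_b(p))$ — the inverse-relative-baseline-prevalence analog
of idf — is provided as `"tfidf-log-ratio"`, but its sign is set by the
baseline column alone, and in our synthetic experiments it systematically
excluded genuinely elevated probes whose baseline cosine sat slightly above
average; it is retained for sensitivity analysis, as is the plain
`"difference"` method. Probe cosines are kept signed throughout.

The top positively weighted probes (50 by default, ties broken
lexicographically) are reduced to two dimensions and clustered with
k-means++ seeding at each candidate $k$ (default 2–10), keeping the labeling
with the highest mean silhouette width. The reducer is pluggable; the
default is PCA, which is deterministic, while stochastic-neighbor methods
can be supplied as a function argument. A probe cluster of interest — for
instance one gathering *voice, sound, hear, chant, loud* — becomes a
*concept vector* (unit-normalized sum of member embeddings), and each
participant's predictor value is the largest cosine between that concept and
their sentence vectors. The number of clusters found on real data is a
data-dependent outcome, not a contract. When no cluster is designated, the
pipeline uses the cluster containing the top-weighted probe, and the
interviewer-speech control is the same analysis run with
`speaker = "interviewer"`.

## Embeddings

Sentence composition and unpacking only require a vocabulary of POS-prefixed
lemma keys mapped to fixed-dimension vectors in which contextually similar
words are close; any word2vec-format file can be loaded. The trainer shipped
with the package is deterministic and count-based: symmetric windowed
co-occurrence counts (window 5), positive pointwise mutual information, and
truncated SVD to the target dimension (200 by default), with SVD signs fixed
for reproducibility. The config records dimension, window, min-count and
epochs; epochs matter only to iterative trainers and are carried as metadata.
Frequency ties in the probe-vocabulary ranking are broken lexicographically.
"95% most common words" is read as cumulative token coverage; a rank-based
alternative is available via `mode = "rank"`.

## Preprocessing

Transcripts arrive as a participant/speaker/utterance table or as
`P:`/`I:`-prefixed plain text. Sentences are split on terminal punctuation,
tokenized, tagged with a pluggable backend, and lemmatized; sentences longer
than 60 tokens are dropped (a parser length cap, not a truncation rule) and
counted. The default backend is a small deterministic rule/lexicon tagger
(closed-class lists, an irregular-verb table, suffix rules with stem repair,
a pronoun+`-s` context repair, and a noun fallback) mapping to the coarse tag
set `NN, VB, JJ, RB, IN, CC, DT, PR, OTHER`; a dictionary backend built from
an embedding-space vocabulary serves synthetic cohorts. The backend name is
recorded in run metadata.

The shuffle control permutes content words within each POS category —
verbs with verbs, nouns with nouns — so that sentence lengths, POS patterns
and the per-POS word multisets are all preserved and only the grouping of
words into sentences is destroyed. Shuffling is scoped to the participant's
transcript by default, keeping per-participant word inventories fixed; a
cohort-wide scope is available.

## The synthetic-cohort generator

`fixture_spec()` describes a small interview-like study: a 48-word
vocabulary in 12 four-word concepts (mean within-concept cosine 0.7,
concepts orthogonally seeded, requiring dimension ≥ concepts), 16 embedding
dimensions, six sentences of 4–8 content words per participant, and a
7-positive/23-negative split mirroring a typical clinical-high-risk training
cohort, with Zipf-distributed token frequencies (exponent 1).

Every participant's token pool is drawn by the same null process, so groups
are exchangeable at the inventory level. The planted effects are:

* **density_effect** — the probability that a positive-group sentence is
  *organized* redundantly, filled with same-concept tokens from the pool
  (near-duplicates, plus literal repeats when the pool holds them). The
  density reduction therefore arises through the unpacking mechanism and
  through sentence organization specifically, which is exactly what the POS
  shuffle undoes: shuffled positive transcripts return to null densities.
* **concept_effect** — a softmax temperature
  ($\propto \exp(\text{effect} \cdot \cos(x_w, t))$) pulling positive-group
  pool draws toward a designated target concept, planting latent content.

Calibration, chosen once: the *strong* settings (`density_effect = 0.8`,
`concept_effect = 6`) are used for detection and AUC studies; the *moderate*
settings (`density_effect = 0.3`, `concept_effect = 0.4`) put the
single-predictor training accuracies near 0.80–0.84 — the regime the
published single-marker models occupy — so that combining the predictors has
room to help and the combined-versus-single comparison is informative. In
model comparisons a tie is counted as "not underperforming": with 30
participants, accuracy moves in steps of 1/30, and at strong effects all
models saturate at 100%.

The generator does **not** emulate grammar, topic drift, disfluencies,
interviewer prompting, out-of-vocabulary speech, or the scale of a real
embedding lexicon. Passing recovery tests therefore demonstrates that the
pipeline's statistical machinery behaves as designed — planted effects are
recovered, nulls stay null — not that clinical effect sizes transfer.

## Prediction layer

Logistic models are fitted by maximum likelihood (IRLS via `glm`). With
seven positives against twenty-three negatives, quasi-complete separation is
a real possibility; it is detected (fitted probabilities pinned within
$10^{-6}$ of 0/1 with diverging coefficients) and handled by a
ridge-penalized IRLS refit ($\lambda = 10^{-4}$ on the slopes), flagged in
the model object so that reported coefficients are always finite and
reproducible. Wald statistics are $(\beta/\text{SE})^2$ on one degree of
freedom; the single-predictor decision boundary is $-\beta_0/\beta_1$, the
predictor value at probability 0.5; classification uses a 0.5 cutoff by
default; undefined confusion ratios (such as precision with no positive
predictions) are reported as `NA`, never as 0. No multiple-testing
correction is applied. A published equation can be wrapped with
`logistic_model()` and evaluated on new data — note that for the printed
voices equation $-(-7.047)/9.744 = 0.723$, which does not match the 0.742
cutoff printed alongside it; the coefficient-derived value is what
`decision_boundary()` returns.

## Problem sizes and reproducibility

Test and acceptance studies run at the generator's default scale (48-word
spaces, 30 participants, six sentences each) with 1200–5000 unpacking
iterations, sizes at which the full suite completes in a few minutes on one
CPU. Every stochastic step takes an explicit seed; pipelines are
deterministic given `(config, seed)`, every written artifact is stamped with
a config hash, and `verify_run()` checks a run directory for hash
consistency.

## Known limitations

* The rule tagger is intentionally small; real transcripts benefit from a
  full parser backend behind the same interface.
* The count-based embedding trainer is adequate for the vocabulary sizes the
  package targets in testing; for large corpora, train skip-gram embeddings
  externally and load them in word2vec text format.
* The semantics of the second-highest-F reselection when the reselected
  density is still at or below the cutoff are undefined; the package
  deliberately does not iterate further.
* Absolute density values depend on the candidate lexicon's correlation
  structure (densities above 1 occur on tightly clustered toy lexicons);
  between-group comparisons are the meaningful quantity.
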