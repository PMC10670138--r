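---
title: "Methods: scoring body-image notes for emotion, sentiment and difficulty areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring body-image notes for emotion, sentiment and difficulty areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notescope)
```

`notescope` scores one short free-text note per patient along four axes:
five-emotion intensity, three-class sentiment, a part-of-speech vocabulary
profile, and the context (negative / positive / mixed / not covered) in
which each of three psychological difficulty areas — body image, acceptance
of the environment, self-esteem — is raised. This vignette documents the
model choices, the tunable parameters, the numerical conventions, and what
the synthetic validation does and does not establish.

## Text normalization

Every arm consumes the same token representation: lowercase, split on any
non-letter character (Unicode letter class, so diacritics survive), which
removes numbers and punctuation as a side effect; stop-words are dropped
before stemming; the remaining tokens are normalized by a pluggable
function. The package deliberately does not hard-code a stemmer: normed
affective word lists exist for many languages and each needs its own
morphology. The default is the identity normalizer, which is exact for the
synthetic corpora used in the tests; for an inflected language a stemmer
should be supplied and **used for the corpus and every lexicon alike**, so
vocabularies align. The demo corpus shows the cost of skipping this: the
surface form "słabe" fails to match the dictionary lemma "słaby" and a
self-esteem mention is missed.

A note whose every token is removed ends with length zero. That is not an
error at preprocessing time (callers may want to count such notes), but
emotion profiling refuses it, because the profile divides by note length.

## Emotion intensity

The affective lexicon assigns each word an intensity for happiness,
sadness, anger, fear and disgust on a base 1–7 scale. Weights are min–max
standardized per emotion over the lexicon's observed values,
`f(x) = (x − min x)/(max x − min x)`, so each emotion column spans [0, 1]
exactly. A constant column is degenerate; it maps to all zeros with a
warning rather than an error, since one flat emotion should not invalidate
the other four. The *dominant emotion* of a word is the argmax of its five
intensities; exact ties resolve in the fixed order happiness, sadness,
anger, fear, disgust, everywhere in the package.

Corpus words absent from the lexicon are interpolated in embedding space
(any word2vec-format vectors; 100 dimensions by default in the synthetic
generator):

* **Centers.** For each emotion, the centroid of the embedded lexicon words
  with that dominant emotion, restricted to words that also occur in the
  corpus — centers should reflect the vocabulary actually in use. If an
  emotion has no corpus member the centroid falls back, with a warning, to
  all embedded lexicon words of that emotion; an emotion with no embedded
  word at all is an error.
* **Matching.** The new word joins the emotion whose centroid is closest by
  cosine similarity.
* **Interpolation.** Its intensities are `Σ_k s_k w_k` over the `n` most
  similar lexicon words *of the matched emotion*. Restricting the neighbour
  pool to the matched emotion is a deliberate choice: without it the
  matching step would have no effect on the result. The weights are the
  shifted cosines `(cos_k + 1)/2`, renormalized to sum to one. Two
  conventions matter here. Normalizing the weights keeps every extended
  intensity a convex combination, hence on the standardized scale — without
  it the output could leave [0, 1]. The cosine shift keeps weights bounded
  and monotone in similarity while avoiding the division-by-zero of
  inverse-distance weighting at duplicate vectors. The matched center's own
  coordinates are *not* blended into the result; the center's only role is
  to select the neighbour pool.

The default neighbour count is `n = 5`, a conventional small-neighbourhood
choice that keeps interpolation local; it is configurable per run.
Extending a word already in the lexicon is the identity, and words with no
embedding vector are skipped and reported, never silently dropped.

A note's profile is `I_e = Σ_s count(s)·intensity_e(s) / N` with `N` the
note length in retained tokens. Words absent even from the extended
lexicon contribute zero *but still count in `N`*: the denominator is the
note's length, not its lexicon coverage, so profiles of sparsely covered
notes are attenuated rather than inflated. Profiles are therefore convex
combinations (plus zeros) of standardized intensities and stay in [0, 1];
duplicating every token changes nothing. Stage-group profiles are plain
arithmetic means with group sizes reported; empty declared groups are
omitted with a warning.

### Validation on synthetic embeddings

The held-out recovery experiment (`evaluate_extension_recovery()`)
generates a 1000-word lexicon — 200 words per emotion, dominant intensity
uniform on [5, 7], others uniform on [1, 3] — and embeddings with the five
cluster centers mutually separated by ten times the within-cluster noise.
Twenty percent of words are held out and re-derived from the rest. Two
design points deserve a note:

* The interpolator is a similarity-weighted within-cluster mean, and
  intensity is independent of a word's position inside its cluster, so the
  error floor is the within-cluster intensity spread (variance
  `(1/3)²/12` per standardized emotion, an RMSE floor near 0.096). The
  experiment therefore uses `n = 50` neighbours — roughly a quarter of a
  cluster — to average the extra `1/n` estimator variance away; this is an
  experiment-design parameter, not a recommendation for real corpora,
  where `n = 5` keeps the interpolation local.
* Dominant-emotion recovery is essentially a test of the center matching;
  at this separation it is expected to be perfect, and the test requires
  at least 95%.

Passing this experiment shows the geometry-driven machinery is correct. It
does **not** show that real embeddings cluster by emotion this cleanly —
real affective structure in embedding space is far noisier, and the
recovery rates reported here should be read as upper bounds.

## Sentiment

The dictionary score of a note is
`s = (#positive − #negative) / #polarity-bearing`, with token
multiplicities, where "polarity-bearing" means any token found in the
polarity lexicon. Neutral-labelled tokens therefore enter the denominator
only, pulling the score toward zero — a neutral word is evidence of
neutrality, not silence. A note with no lexicon word scores exactly 0.

The hybrid decision maps `s` to pseudo-probabilities
(negative `max(−s, 0)`, neutral `1 − |s|`, positive `max(s, 0)`) and blends
them with the classifier's probabilities as `α·dict + (1 − α)·ml`. The
default `α = 0.5` weighs both sources equally; `α = 1` is the pure
dictionary path (also the forced behaviour when no classifier is
supplied), `α = 0` the pure classifier path. The label is the argmax, and
exact ties go to neutral — the symmetric, least-committal class.

The classifier is a *contract*, not a fixed model: anything providing
class probabilities that are nonnegative and sum to one (checked to 1e-9)
plugs in. The shipped reference implementation represents a note by the
count-weighted mean of its token embedding vectors and fits a multinomial
logistic model (`nnet::multinom`). It trains in seconds on synthetic data
and exists to exercise the hybrid path; it makes no claim to match a
large pretrained sequence model, which is precisely why the contract is
the boundary of the package.

## Part-of-speech profile

Tagging is likewise a contract; the shipped tagger is a deterministic
surface-form lookup table, which makes tests reproducible and lets any
external tagger be adapted by writing its output into the same table.
Adjective polarity is assigned by looking the *lemma* up in the polarity
lexicon (adjectives absent from it stay untyped and count only in the
total); verb tense is kept for verbs only; the possessive "MY" is detected
by a configurable surface-form list (Polish forms by default) and
overrides the tagger. The profile is a pure fold over tags — additive over
notes and invariant to note order. Characteristic terms are a
stop-word-filtered frequency ranking with lexicographic tie-breaks;
deliberately simple, since the ranking is descriptive, not inferential.

## Difficulty areas

The corpus becomes a term–document matrix of raw counts (rows: vocabulary,
lexicographic; columns: notes, input order). Raw counts are the default
because the dictionaries themselves are short and unweighted; TF-IDF is
available as a flag. Latent semantic analysis is the truncated SVD
`X ≈ U_k S_k V_kᵀ` with term vectors `U_k S_k` and document vectors
`V_k S_k`. Each area dictionary (positive and negative separately) is
folded in as a pseudo-document: its count vector `q` projected as
`qᵀU_k`, the standard fold-in, which at full rank reproduces the document
vector of an identical real document.

The affiliation of a note to a dictionary is the cosine between the
note's document vector and the folded dictionary, clamped below at zero —
cosine is bounded and scale-free, the clamp makes the "not covered" state
attainable, and together they keep the relative difference within ±100%.
Two numerical conventions: an undefined cosine (zero vector on either
side, e.g. a dictionary none of whose words occur in the corpus) counts
as affiliation 0, and any cosine below 1e-10 is treated as exact zero, so
floating-point residue cannot masquerade as topic coverage.

The context classifier computes
`rel_diff = (W_N − W_P)/max(W_N, W_P) · 100` and applies a threshold of
20%: above it negative, below −20% positive, inside the band mixed, and
`(0, 0)` not covered. A tie at exactly the threshold is mixed, because the
single-context conditions are strict inequalities. The threshold is
configurable; 20 is the operating point the method was designed around.

### Choosing k

The retained dimension defaults to the smallest `k` whose squared singular
values capture 90% of the matrix's squared Frobenius norm. A tempting
alternative — one latent axis per area and polarity, `k = 6` — proved too
coarse in development: once the corpus also contains sentiment, emotion
and filler vocabulary, six dimensions merge the per-area polarity
directions, and balanced (mixed-context) notes pick up spurious relative
differences beyond the 20% band (81% planted-context recovery on the
60-note synthetic corpus, versus 97–100% under the variance rule, which
selects k ≈ 37 there). The variance rule adapts to whatever nuisance
structure the corpus carries and is the package default; `k` remains a
per-run override.

### Agreement scoring

Expert flags per note and area (0 not raised, −1 negative, 1 positive,
2 mixed) map onto the four context labels. Every prediction falls in
exactly one category: consistent; mixed-detected-as-single (expert mixed,
method single-context); single-detected-as-mixed (expert single-context,
method mixed); error (everything else, including missed or hallucinated
coverage). Percentages are per area over scored notes and sum to 100; the
report also gives the expert's negative/positive/mixed shares among
flagged notes. A prediction without a flag is an error by design — silent
partial scoring would bias the percentages.

## The synthetic generator

The generator emulates the *structure* of elicited body-description
corpora, not their language: letter-only synthetic tokens (so they survive
the tokenizer) drawn from disjoint vocabularies for emotion words, area
dictionaries, polarity words and filler. Its defaults mirror the study
conditions the pipeline targets: 50 notes in stage groups of 11
(diagnosis), 32 (treatment) and 7 (palliative care); planted sentiments
29 negative / 10 positive / 11 neutral; embeddings of dimension 100 with
cluster separation 10 and noise 1. Per note it plants 8 tokens per covered
area (4 + 4 for mixed contexts), 4 polarity tokens (2 neutral-labelled for
neutral notes), 3 emotion tokens and 2 filler tokens — enough area signal
that a human reader would also call the context planted, while filler and
cross-arm vocabulary keep the matrices from being block-diagonal toys. The
end-to-end context experiment uses 60 notes with every area raised in a
context drawn uniformly from negative/positive/mixed. All draws are
integer-seeded with no iteration-order dependence, so fixtures are
byte-reproducible across platforms.

What passing on this generator shows: the pipeline recovers structure that
is present, at realistic corpus sizes, through the actual code paths (file
round trips included). What it does not show: robustness to real clinical
language — spelling variation, negation, irony, inflection, topic words
shared between areas — nor the quality of any particular embedding or
tagger. Those enter through the pluggable contracts and must be validated
per deployment.

## Problem sizes and determinism

The test suite and the acceptance script run, as the package's own
choices: 200 random oracle instances for the interpolation formula (each
at most 10 lexicon words), a 1000-word lexicon with 200 held out for
extension recovery, a 60-note corpus (180 note-area pairs) for context
recovery, and 50-note corpora for the sentiment and agreement
bookkeeping checks. Everything completes in well under a minute on one
CPU. All randomness flows from explicit seeds; reruns are bit-identical.

## Known limitations

* Identity normalization is exact only for synthetic text; real inflected
  corpora need a stemmer for the lexicon and corpus alike.
* The note-level emotion profile is a bag-of-words mean: negation ("not
  happy") and intensifiers are invisible to it.
* The "not covered" state requires *exact* zero affiliation (up to the
  1e-10 tolerance); in dense corpora where every note shares latent mass
  with every dictionary, the state effectively disappears and absence must
  be read from small affiliations instead.
* The LSA representation is corpus-dependent: adding notes changes every
  affiliation slightly, so longitudinal comparisons should refit on a
  fixed reference corpus.
* The reference classifier is a linear model over averaged embeddings; it
  exists to exercise the hybrid contract, not to set a benchmark.
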