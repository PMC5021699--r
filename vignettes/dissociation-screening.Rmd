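---
title: "Three-channel dissociation screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-channel dissociation screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissoscreen)
```

## The screening idea

Every spoken phrase carries its affect through more than one channel: the
words chosen (lexical polarity), the contexts those words typically occur in
(semantic orientation), and the tone of voice they are spoken with. In
cognitively healthy speech these channels are redundant — a pleasant memory
is told with positive words, in positive contexts, in a positive tone. The
screening hypothesis implemented here is that early cognitive impairment
weakens this redundancy: the channels *dissociate*, each wandering
independently of the phrase's underlying valence. The package measures that
dissociation and asks whether it is informative enough to classify speakers.

The unit of analysis is the phrase. An interview contributes a few hundred
phrases; each phrase is reduced to a triple

* `polarity` — a signed strength in −5..−1 or 1..5,
* `so_code` — a trinary semantic-orientation code {−1, 0, +1},
* `tone_code` — a trinary tone band {−1, 0, +1},

and the per-group association between channels is tested with Pearson
chi-square, after which the triples (plus the group label) feed a
classification study.

## Channel 1: dictionary polarity

The scorer is a faithful reimplementation of the classical
dictionary-with-modifiers design. Its knowledge base has three lists:
sentiment terms with signed integer strengths (magnitude 1–5), booster terms
with shifts in {−1, +1, +2}, and negators. Scoring walks the token sequence:

* a sentiment token's effective magnitude is its base magnitude plus the
  summed shifts of the *immediately preceding* contiguous booster chain,
  clamped to [1, 5] — boosters change intensity, never sign;
* a negator anywhere in that chain reverses the final sign of the token
  *together with its boosters*: with happy = +3 and very = +1,
  "very happy" = +4 and "not very happy" = −(3 + 1) = −4, not (−3) + 1;
* any token outside the lexicon contributes nothing and breaks a pending
  chain, so inserting fillers between chains never changes a score;
* the phrase keeps the convention of a dual reading: `positive_strength` is
  the strongest positive hit (floor 1), `negative_strength` the strongest
  negative hit (ceiling −1).

The single signed value the rest of the pipeline uses is the dominant side
by magnitude, with ties resolved as scalar +1 and the label "neutral". Two
consequences of this reduction are worth stating because they shape the
synthetic generator below: a scalar of −1 can never be produced (a lone −1
hit ties with the default +1), and scalar +1 always means "neutral". The
scale is therefore effectively {−5..−2} ∪ {+1 (neutral)} ∪ {+2..+5} for
text-scored phrases, while externally supplied training files may use the
full −5..−1/1..5 range.

Tokenization is deliberately minimal — lowercase, split on whitespace,
strip leading/trailing punctuation, no stemming — because every additional
normalization step is another undocumented degree of freedom.

The packaged default lexicon reproduces the documented dictionary *size* —
298 positive and 465 negative sentiment terms — but not any proprietary
word list: beyond a handful of real anchor words (happy +3, good +2,
terrible −4, …) its entries are deterministic pseudo-words, and the files
are labelled synthetic. Only the counts and the rule mechanics matter to
the pipeline; users with a real lexicon load it with `load_lexicon()`.

## Channel 2: SO-PMI semantic orientation

Pointwise mutual information of two terms is
`log2( P(t1 ∧ t2) / (P(t1) P(t2)) )`. The package estimates the
probabilities from a plain-text reference corpus with one document per
line, using *presence* counts — a term counts once per document, a pair
once per document containing both. The co-occurrence window is the
document: this mirrors hit-count semantics ("how often do these terms
appear together somewhere") and is the simplest testable choice.

Probabilities are smoothed with a pseudo-count `s` (default 0.5, add-half):
`P(t) = (c(t) + s) / (n + 2s)`. This keeps every PMI finite, including for
unseen pairs; on corpora with no zero counts the estimates converge to the
unsmoothed closed form as `s → 0`, which is how the closed-form tests are
written.

A phrase's orientation is
`SO = PMI(phrase, "excellent") − PMI(phrase, "poor")` with the seed pair
fixed. Phrase-level PMI is the *mean* of token-level PMI over the phrase's
content tokens (tokens present in the corpus vocabulary) — the mean, rather
than sum, keeps the value comparable across phrase lengths. The trinary
code applies a symmetric threshold τ (default 0.5 bits): `+1` if
`SO ≥ τ`, `−1` if `SO ≤ −τ`, else 0. τ is configurable because the trinary
coding convention does not pin a boundary; 0.5 bits is half a doubling of
association odds, far from the ±3.2 bits the synthetic corpus produces, so
the default is not delicate. Phrases with no content token are coded 0 and
flagged (`so_oov`) rather than silently treated as evidence.

One convention note: the trinary coding here is {+1 excellent, 0 neutral,
−1 poor}. Descriptions of this coding elsewhere are ambiguous about the
role of 0; the training-file usage (0 as the middle band) is the reading
adopted, and the code never guesses beyond it.

## Channel 3: tone bands

The pipeline consumes emotion *labels*, not audio: speech-emotion
recognition is an upstream component with its own trained model, and
re-deriving it is out of scope. The five recognized labels fold into bands
as joy → +1, neutral → 0, anger/sadness/boredom → −1. Joy is the only
unambiguously positive emotion in the set and neutral the only neutral;
boredom is the one judgement call (a low-arousal negative), and the band
map is a config override (`map_emotion(..., band_map = )`) precisely so
that call is not load-bearing.

## Dissociation statistics

For each group, the two text channels are each crossed with tone. The text
channel is collapsed to its sign with neutrals dropped, giving 2 × 3 tables
and therefore 2 degrees of freedom — the df the method is described with;
`binarize = FALSE` gives the full 3 × 3 (df 4) variant. The test is plain
Pearson chi-square without continuity correction, expected counts from the
margins; a flag records whether any expected cell fell below 5. Both
hypotheses one might read into the design are reported separately:
within-group channel–channel association (the primary dissociation
evidence) and each channel against the class label.

The per-phrase concordance rate is the fraction of triples that agree: all
three signs equal and nonzero, or all three neutral. Because a text-scored
neutral phrase carries scalar +1 with the label "neutral", the label (when
present) is what counts as the polarity channel's neutral level; bare
four-column records fall back to the sign of the polarity value.

The chi-square stage is advisory in the end-to-end run: it is computed and
logged before classification, but a dissociated (or concordant) result
never blocks the next stage.

## Classification study

The training file is the four-column per-phrase table (class, polarity,
so_code, tone_code; on disk under the classical header
`class,polarity,pmi,emotion`). Four classifier families run over all seven
non-empty channel subsets: a decision tree (rpart), a small multilayer
perceptron (nnet, 5 hidden units, decay 0.01), naive Bayes over the
discrete features (e1071, Laplace 1 — the desk-scale reading of a Bayesian
network on three features), and an RBF-kernel SVM (e1071, cost 1). All
hyperparameters are pinned in `classifier_config()` and echoed into every
report.

Cross-validation is stratified k-fold (default 10) with metrics computed on
the pooled out-of-fold predictions, positive class = case. Fold assignment
is derived from a canonical ordering of the records, so it depends only on
the record multiset and the seed — shuffling rows cannot change a metric.
Phrases are treated as independent units by default, matching the pooled
design; because that pools phrases from the same speaker across folds, an
optional `groups` argument holds whole interviews out together for a
leakage-free variant.

ROC curves sweep the pooled scores (class probabilities where the family
provides them; min-max-scaled decision values for the SVM, whose Platt
probabilities are not seed-controllable and would break run determinism).
AUC is the trapezoid area, which the tests verify against the
Mann–Whitney rank formulation to 1e−9 and against an independent
implementation.

## The synthetic generator

The generator is the package's study stand-in and is first-class, tested
code. Each phrase draws a latent valence `v` from
`valence_distribution`; in the concordant regime (all control phrases,
and case phrases with probability `1 − dissociation`) each channel
independently equals `v` with probability `concordance` (default 0.95) or
takes a uniformly random other level; dissociated case phrases draw all
three channels independently and uniformly over the three levels —
maximum-entropy decoupling. Non-neutral polarity gets a magnitude from
`magnitude_distribution`; emotion names are drawn uniformly within the
intended band; interviews are metadata only (no serial structure within an
interview).

Defaults and why:

* **Sizes** 60/22 interviews × 300 phrases mirror the study scale the
  generator emulates.
* **Valence (0.60, 0.10, 0.30)** — reminiscence interviews lean positive,
  fully neutral phrases are rare. This was fixed by a one-time design pass
  over four plausible candidates, choosing the most realistic profile that
  reproduces the qualitative outcome pattern the method is built around
  (controls associated, cases independent; single channels weak, the
  triple clearly classifiable). It is a structural default, not a per-run
  tuning knob.
* **Concordance 0.95** — healthy channels are reliable but not perfect;
  at 300 phrases per interview this leaves within-group association
  overwhelming (p ≈ 1e−148 at n = 1000 phrases).
* **Dissociation 1.0** — the case model is full decoupling, the cleanest
  null for the type-I-error surface; partial decoupling is a parameter,
  not a different mechanism.
* **Magnitude (0, 0.38, 0.27, 0.20, 0.15)** — no mass on magnitude 1,
  because the dual-strength reduction makes a lone ±1 hit tie into the
  neutral +1: an intended polarity of ±1 is not recoverable from text, so
  magnitude 1 is reserved as the neutral tie value and `synth_config()`
  rejects configurations that put mass on it.

Phrase text is assembled from the packaged lexicon so that the polarity
scorer recovers the intended value *exactly*: a plain term of the right
strength, a boosted term one step weaker, or a negated term of the opposite
sign, padded with filler words that are in no list. The reference corpus
pairs each phrase's topic word with its seed ("excellent" topics with
*excellent*, "poor" with *poor*, neutral with both equally), which under
add-half smoothing puts topic words ≈ ±3.2 bits from the seeds — far beyond
τ = 0.5 — so orientation recovery is deterministic in practice (the
contract asks only ≥ 95%). `channel_recovery_check()` re-scores the
generated text with the real scorers and reports the agreement.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: natural language (text is template-assembled),
within-interview serial structure such as polarity flips inside a
paragraph, per-speaker effects (channels are i.i.d. given the latent
valence), class-dependent phrase length or vocabulary, and recognizer noise
in the emotion labels. In particular, because the case group differs from
controls only through decoupling, classifiers that can model cross-channel
*interactions* (tree, MLP, SVM) dominate naive Bayes here, whereas reports
on real recordings can find the Bayes family best; the synthetic model is a
mechanism probe, not a performance forecast.

## Numerical and procedural choices

* Chi-square: no Yates correction; degenerate tables (a channel with fewer
  than 2 observed levels in a group) are an error, not a silent NA.
* PMI: smoothing must be strictly positive; τ ≥ 0; OOV phrases are flagged
  neutral.
* Scoring: booster chains clamp magnitudes into [1, 5] at both ends;
  repeated negators toggle; empty phrases are neutral.
* Problem sizes in the test and acceptance surfaces are desk-scale by
  design: the chi-square recovery surface uses 10 interviews × 300 phrases
  per group (and 500 replicates for the type-I-error check), the ablation
  surface 20 control / 12 case interviews × 60 phrases. These sizes give
  the chi-square stage power ≈ 1 where association exists, keep
  Monte-Carlo error on a 500-replicate rejection rate below one percentage
  point, and are an honest analogue — not a reproduction — of the
  full-scale study.
* Determinism: every stochastic step (generation, fold assignment, MLP
  initialization) flows from explicit integer seeds; identical
  configuration yields byte-identical JSON artifacts.

## Known limitations

Beyond the generator's idealizations: the polarity scale cannot express a
lone −1 hit (inherent to the dual-default reduction); SO-PMI with a single
fixed seed pair is sensitive to corpus composition in ways the symmetric
synthetic corpus hides; pooling phrases across speakers in CV leaks speaker
identity (the grouped-CV flag exists for exactly that reason, and on real
data it is the honest default); and the chi-square stage tests association,
not any causal account of why channels decouple.
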