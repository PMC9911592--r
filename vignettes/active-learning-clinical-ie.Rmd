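---
title: "Active learning for clinical information extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for clinical information extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alextract)
library(dplyr)
```

## The problem

Training named-entity recognition (NER) and relation extraction (RE) models
on clinical free text requires expert-annotated data, and expert annotation
time is the binding constraint: radiologists, not GPUs, are the scarce
resource. `alextract` implements a pool-based active-learning workflow that
spends that annotation budget where it buys the most model improvement, and
it does so with an *intrinsic* acquisition signal — one computed from a
self-supervised language model of the raw report text, with no labels and no
task model in the loop. That matters in practice because extrinsic signals
(prediction uncertainty, margins) break whenever the annotation schema
changes, e.g. when a model is carried from one imaging domain to another.

The package covers the full workflow: a general radiology annotation schema,
brat-standoff corpus I/O, IOB and relation-pair sample encoding,
pseudo-perplexity scoring and percentile-band batch selection, the
annotate–train–query cycle with soft labels, strict-span macro-F1
evaluation, and a synthetic corpus generator that makes every stage testable
without access to protected clinical data.

## The annotation schema

`default_schema()` defines 20 entity classes — central clinical concepts
(medical conditions, anatomy, imaging observations, procedures, devices,
substances), descriptors (location, certainty, quality, RadLex-style
modifiers) and specifications (dosing, measurements, temporal information,
dynamics, scores) — and 15 undirected relation classes connecting them.
Relation direction is never meaningful: `Is_located(e1, e2)` and
`Is_located(e2, e1)` are the same assertion, so all relation handling is
canonicalized to offset order. A subset of relations carries argument-type
rules (e.g. `Has_dosing` links a `Dosing` to a `Non_anatomical_substance`);
the rest are unrestricted. The reserved label `no_relation` marks candidate
pairs without an annotated relation and is never itself a schema class.

## Sample encoding

**NER.** Sentences become IOB sequences: the first token of an entity is
tagged `B-<class>`, continuation tokens `I-<class>`, everything else `O`.
Entity spans must align exactly with token boundaries; a misaligned span is
a hard error rather than a silent clip, because clipping corrupts the
round-trip property (`spans_to_iob()` then `iob_to_spans()` is the identity)
that the whole encoding layer is tested against. When *decoding model
predictions*, an orphan `I-` tag is repaired to `B-` and counted, so any tag
sequence decodes.

**RE.** Every unordered pair of distinct entities within a sentence is one
candidate sample: a sentence with `k` entities contributes exactly
`choose(k, 2)` pairs, annotated pairs keep their relation label, and all
remaining pairs are auto-labeled `no_relation`. A sentence with 6 entities
and 4 annotated relations therefore yields 15 samples — 4 positive, 11
negative — and that arithmetic is preserved under the default rule-handling
mode: schema rules *relabel* (flag) rather than delete candidate pairs. A
strict mode that drops pairs allowed by no rule exists for pipelines that
filter candidates before classification; the package asserts neither mode
as the only correct one, since either is defensible when rules are wired
into the classifier's output layer instead.

Because auto-generated negatives dominate, positives are oversampled
(default factor 4) in each retraining call — on the training split only;
the test split always keeps its natural label distribution.

## Pseudo-perplexity acquisition

For a masked language model and a tokenized sentence
`X = (x_1, ..., x_n)`, the pseudo-perplexity is

```
PPL(X) = exp( -(1/n) * sum_i log p(x_i | X_-i) )
```

where each token is masked in turn and predicted from the rest of the
sentence. A sentence the model predicts perfectly scores 1; rare or unusual
content scores higher. Numerical choices: natural logarithms throughout
(matching the exp/log pairing of the definition), and conditional
probabilities floored at `eps = 1e-12` before the log because the quantity
is undefined at zero probability. `pseudo_perplexity()` is verified against
an independently coded brute-force mask-and-score loop to `1e-9`.

**Strategic sampling** selects unlabeled sentences lying in the
(0.75, 0.90] percentile band of *both* pseudo-perplexity and sentence
length. The band's upper bound discards the extreme top decile — outliers:
degenerate or pathological sentences tend to have the most extreme scores —
while still favoring long, surprising sentences, which carry more entities
and relations per unit of annotation effort. Design choices worth stating:

- *"and" is read as intersection* of the two one-dimensional bands, the
  strictest reading; union and sequential-filter variants are available via
  the `combine` argument.
- *Percentiles are empirical ranks* with stable tie-breaking and no
  interpolation — selection needs index sets, not interpolated quantile
  values.
- *If the intersection cannot fill a batch*, the remainder is drawn from the
  union of the bands, then from the whole pool; the fallback level is
  recorded in the selection's attributes.
- *Length is measured in corpus tokens*, not model subwords, so scores are
  comparable across backends; percentile thresholds are recomputed over the
  shrinking pool at each iteration.
- *The scoring model is fitted once* on the full unlabeled pool and kept
  fixed across iterations (scores are cached by model fingerprint); a
  per-iteration refresh is possible by passing a new model, but the default
  mirrors a fixed pretrained scorer.

## The active-learning cycle

`run_cycle()` iterates three phases: (1) an initial random seed set
(default 268 sentences) is annotated and the backends are fitted on it;
(2) a query batch (default 100) is selected by the scheduled strategy and
*pre-annotated* by the current models — these soft labels are shown to the
annotator for correction, which is cheaper than annotating from scratch,
and the fraction accepted unchanged is logged per iteration; (3) the
corrected batch joins the labeled set and both backends are retrained on
the *full* labeled set (not incrementally on the batch). Training always
uses annotator-corrected labels; soft labels are presentation-only and
never enter training uncorrected. The default schedule protocol
(`strategy_schedule(switch_at = 8)`) runs random sampling for seven
iterations and intervenes with strategic sampling from iteration 8.

Stopping: a held-out metric threshold, pool exhaustion, or an iteration cap
(default 50, guarding non-converging configurations). The returned state
carries a machine-readable per-iteration history — batch statistics
(size, mean length, mean pseudo-perplexity, entities per sentence, positive
and negative relation counts), soft-label acceptance, and held-out macro-F1
for both tasks — which `autoplot()` renders as a learning curve.

## Model backends

The three model contracts (masked LM, sequence tagger, relation classifier)
are deliberately minimal so that transformer models can stand behind them;
the shipped reference backends are small, closed-form and fully
deterministic, built to exercise the loop at desk scale — they make no
claim of matching transformer accuracy:

- **Masked LM:** an additively smoothed unigram model
  (`fit_unigram_mlm()`). Context-free, so pseudo-perplexity reduces to a
  geometric mean of unigram surprisals — which is exactly what makes it a
  convenient oracle target for the scoring layer. `mask_tokens()` generates
  masked training pairs (`ceiling(rate * n)` positions per sentence,
  default 15%) for backends that do pretrain.
- **Tagger:** a per-token naive-Bayes classifier over window features
  (lowercased surface, previous/next surfaces, a casing/digit shape).
  Unseen surfaces are scored from context and shape alone, which under
  O-dominated training data falls back to `O`.
- **Relation classifier:** naive Bayes over the unordered entity-class
  pair, a bucketed token distance, and the bag of tokens between the spans
  — all computed on the offset-ordered pair, so symmetry in argument order
  holds by construction.

All three support warm starts by count pooling (`init =` a previous model):
source-domain counts are added to target-domain counts, which is how the
domain-transfer experiments initialize target models from a source corpus.
Ties in scoring break deterministically (alphabetical, `O`/`no_relation`
first), so fits and predictions are bit-reproducible under fixed seeds.

## Evaluation

`macro_f1_ner()` scores strict entity-level matches by default: a true
positive requires exact (sentence, start, end, class) agreement. Token-level
matching is available by flag; strictness is the default because partial
credit hides boundary errors that matter clinically. `macro_f1_re()` aligns
predictions to the gold candidate universe by the canonical pair key and by
default excludes `no_relation` from the macro mean — averaging in the
overwhelming negative class would mask exactly the per-class equality that
motivates macro averaging; a flag includes it to bracket the ambiguity.
In both tasks the macro mean runs over classes with gold or predicted
support, per-class F1 uses the 0-convention, and every report carries its
own confusion counts so all scores are recomputable. `cohen_kappa()`
implements chance-corrected inter-annotator agreement with
marginal-product expected agreement.

## The synthetic corpus generator

Real clinical corpora are private, so the package ships a generator whose
output has the statistical structure the method exploits, without a word of
natural language. Sentences are slot-filled templates over a pseudo-German
syllable vocabulary; entity terms are capitalized, fillers are not; all
annotations are schema-legal by construction and every generated document
passes validation and brat round-tripping.

Three properties are engineered explicitly, because the package's
simulation tests need a controllable ground truth rather than an emergent
accident:

1. **Rare terms exist and surprise the model.** Term and filler draws are
   Zipf-distributed (exponent 1.2), so bottom-decile terms are genuinely
   rare and sentences containing them score measurably higher
   pseudo-perplexity under a model fitted on the corpus.
2. **Minority classes live in longer sentences.** Five entity classes
   (procedures, devices, substances, dosing, scores/grades) appear only in
   the longest medium and the shorter long templates — inside the 75–90
   length band, not in the outlier top decile that the band deliberately
   excludes. One rare relation (`Has_dosing`) rides along with them.
3. **Domain pairs overlap controllably.** `make_domain_pair()` shares a
   configurable fraction of vocabulary (matched by frequency rank, so the
   shared part carries the same Zipf mass in both domains) and of
   templates; non-shared templates are restyled by filler reordering. High
   overlap emulates two modalities read by the same department, low overlap
   a change of modality and anatomy.

Defaults, chosen once: 2000 sentences in documents of 5; a 55/30/15
short/medium/long template mix giving ≈3.8 entities and ≈1.3 annotated
relations per sentence with a ≈6–7% minority-class share; six active
relation classes; relation density 0.9; 30% of entity terms span two
tokens (so `I-` tags are exercised).

What passing these tests does *not* show: the generator has no grammar, no
discontinuous or nested entities, no annotation noise, and its class-given-
surface mapping is unambiguous — all easier than real clinical text. The
simulation results demonstrate that the machinery is correct and that the
acquisition strategy exploits the intended structure, not that any
particular F1 level would be reached on real reports.

## Simulation scale and observed behavior

The package's acceptance checks run the full loop at sizes chosen to keep a
complete run on a single CPU comfortable while leaving the comparisons
clearly resolved: batch enrichment on the default 2000-sentence corpus
(5 seeds); learning curves on a 1200-sentence corpus with a 25% held-out
split, a 100-sentence seed set and five 50-sentence iterations (5 seeds);
domain transfer on 700-sentence domains with 200 target training sentences
(5 seeds × 2 overlap levels). Under these conditions strategic batches
roughly double the minority-class share and raise entities-per-sentence by
~50% relative to random batches; the strategic schedule dominates the
random one on held-out NER macro-F1 in every seed; and warm starts dominate
cold starts with a several-fold larger gain at 0.8 overlap than at 0.2. One
honest nuance: with gold entities given at evaluation time, the reference
RE task saturates by a few hundred training sentences, so the strategic
advantage there is within seed noise at this budget — the dominance signal
is carried by NER. Exact numbers for any seed are reproduced by
`scripts/acceptance.R`.

## Known limitations

- The rule-based sentence splitter and tokenizer are adequate for the
  synthetic corpus and simple report text; production use on real German
  reports should plug a dedicated splitter into the `splitter` argument.
- Nested, discontinuous and cross-sentence annotations are out of scope;
  the validator reports them and the encoders exclude them.
- The reference backends are intentionally weak learners; conclusions
  about absolute F1 do not transfer to transformer backends, only the
  workflow and the relative comparisons do.
- brat `A` (attribute) and `#` (note) records are rejected, not parsed.
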