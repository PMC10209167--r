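---
title: "Publication-wide association studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Publication-wide association studies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

A publication-wide association study (PWAS) treats the biomedical
literature itself as the measurement instrument. Word-embedding models
trained on titles and abstracts place tokens that occur in similar contexts
near each other, so the cosine similarity between a gene token and a
disease token estimates how likely the two are to be written about
together — even if they never have been. Training one model per historical
cut-off year turns this into a prospective experiment: a model trained only
on text up to year $T$ ranks candidate genes for a disease, and the
following years of literature (or clinical-trial records, or interactome
releases) decide which predictions came true.

The package implements the full chain: entity canonicalization, corpus
cleaning and phrase mining, time-sliced embedding training, genome-wide
association ranking with bootstrap baselines, protein–protein and
drug–target link prediction from concatenated embeddings with
positive-unlabeled prospective evaluation, and a synthetic-literature
generator that makes every stage testable against planted ground truth.

## Corpus preparation

**Canonicalization.** Every synonym of a gene or disease is replaced by a
single identifier token (dictionary lookup, longest-leftmost match over the
cleaned token sequence). This is what makes a *genome-wide* ranking
possible: one token per gene rather than one per synonym. Ambiguous
synonyms (mapping to more than one identifier) are dropped rather than
resolved — deterministic and conservative. The match strategy for nested
synonyms is a package choice: the greedy longest match at each position,
which never produces overlapping spans and is idempotent.

**Cleaning.** Text is lower-cased and deaccented; leading section labels
("background:", "abstract:", "introduction:") are stripped; decimal and
percentage numbers are replaced by the single mask token `<number>`. Bare
integers are *not* masked — they are often part of meaningful names ("type
2", "il 6"). The exact rule is the regular expression
`[0-9]+\.[0-9]+\s*%? | [0-9]+\s*%`. Stop words are retained; at full scale
they are a negligible fraction of the vocabulary, and windows are wide
enough that they carry little weight.

**Phrases.** Adjacent token pairs seen at least 10 times with normalized
pointwise mutual information above 0.7 are merged with an underscore; three
passes allow up to 8-grams. NPMI is
$\ln\!\big(p(ab)/(p(a)p(b))\big)\,/\,(-\ln p(ab))$ with all probabilities
normalised by the total token count, so a pair that always co-occurs scores
exactly 1 — the property the 0.7 threshold presupposes. Canonical entity
identifiers never participate in merges: a gene must stay one token to be
rankable.

**Vocabulary.** A slice's vocabulary keeps every token mentioned strictly
more than ten times, plus canonical identifiers at any count of at least
one. An entity never mentioned before the cut-off simply has no vector and
cannot be ranked — historical models legitimately know fewer genes.

## Embedding models

Training is CBOW (or skip-gram) with negative sampling, written as a
single-threaded Rcpp routine with an internal 64-bit linear congruential
generator so that a seed fixes the result bit-for-bit on any platform.
Defaults follow the production configuration for literature models:
dimension 256, window 10 (about the median token distance between a gene
and a disease mention in an abstract), 50 epochs, learning rate decayed
linearly from 0.01 to 0.0001, subsampling threshold $10^{-4}$, five
negative samples. Historical models are trained independently from scratch
per slice — never incrementally — so no information can leak backwards in
time. Multi-worker training is deliberately not offered: reproducibility is
part of the contract here.

The "co-occurrence likelihood" of two tokens is the cosine similarity of
their vectors. A CBOW softmax output would be an alternative reading, but
it scales with vocabulary size and adds nothing at ranking time, where only
the order matters.

## Gene–disease ranking and prospective evaluation

For a disease, every in-vocabulary gene of the universe is scored by cosine
similarity and sorted (ties broken by identifier, so rankings are
permutation-stable). *Novelty* is abstract-level: a pair counts as novel at
cut-off $T$ if no document up to $T$ mentions both identifiers; the first
reported year is the earliest such document. The top-$k$ ($k = 50$) novel
predictions are followed forward: the cumulative fraction first
co-mentioned within $t$ years is the prospective precision curve. The
baseline is the same curve for $k$ genes drawn without replacement from the
novel universe, repeated 10,000 times; dispersion is reported as the
standard deviation across iterations, and significance as the one-sided
empirical $p$-value of the observed terminal precision against the
bootstrap distribution. We rank *novel genes only* and take the top 50 of
them (the alternative — novel genes within the overall top 50 — conflates
ranking quality with rediscovery).

**Contextual linking words** explain a predicted pair: the non-entity
vocabulary tokens ranked by the *minimum* of their similarity to the gene
and to the disease. The minimum demands closeness to both sides; product
and mean combiners are available but secondary.

**Clinical-stage regression.** Target–disease pairs carry a clinical score
(0.1/0.2/0.7/1.0 for phase 1/2/3/approved, 0 if absent; the most advanced
phase wins). Feed-forward regressors on concatenated (gene, disease)
embeddings are tuned over a 60-model grid — 1 or 2 hidden layers, dropout
{0, 0.1, 0.2, 0.3, 0.4}, hidden size {1, 5, 10, 20, 50, 100} — with whole
diseases assigned to train or test (200 test diseases at full scale).
Model selection uses a validation subset carved from *training* diseases.
Selecting on the future test set would leak the evaluation into model
choice, so the package deliberately does not do that even where a quick
read of the field's practice might suggest it.

**Cross-method comparison** maps each method's scores to standard normal
quantiles (`qnorm((rank - 0.5)/n)`); genes a method did not score are first
filled with seeded uniform values between zero and the method's minimum
score, so unscored genes land at the bottom without creating ties.

## Link prediction with positive-unlabeled evaluation

Protein pairs are alphabetically canonicalised; self-interactions are
discarded. Since no true negative interactome exists, negatives are all
pairs among the top 10% of proteins by interaction degree ("sticky"
proteins) that are not known positives — the hardest plausible negatives.
Degree is computed on canonical pairs before any augmentation; ties at the
10% boundary break by symbol order. Features are the two concatenated
embeddings, smaller symbol first; training pairs are augmented with the
reversed order, and scoring canonicalises first, so scores are invariant to
input orientation. The split is protein-level: a random quarter of proteins
and *all* their pairs are test-only; a further tenth of the remaining
proteins provides validation pairs for early stopping.

The prospective (positive-unlabeled) evaluation scores a fixed candidate
pool — the newest release's positives plus the model era's sticky
negatives — with an old-era model, then labels the pool with each release
in turn. Interactions that are positive only in the future count as false
positives at the 0.5 threshold (the threshold is a package choice; the
source analyses do not state one). As releases accumulate, high-scoring
future pairs convert to true positives, so the false-positive count falls
and precision rises — the qualitative signature of a model that was right
early.

Drug–target prediction follows the same template with directional features
(gene embedding first, compound second; the relation is not symmetric) and
a harder negative set: the 400 most frequently targeted proteins crossed
with the 400 least specific compounds, minus known positives. "Least
specific" is read as most reported targets — the reading that makes the
negatives hard, which is the stated purpose. Performance is additionally
stratified by compound promiscuity (1, 2, >2 targets), reporting per-class
precision/recall/F1 within each stratum. Motif-based druggability uses a
one-sided (enrichment) Fisher's exact test per motif against the drugged
gene set; a gene inherits the maximum $-\log_{10} p$ over its motifs. The
variant filter keeps non-synonymous variants with $p < 10^{-9}$ (strict),
at least two studies agreeing in the beta sign, and a model likelihood
strictly above 0.3.

## The synthetic literature generator

Documents are bags of tokens — window-based training consumes co-occurrence
statistics only, so syntax would add cost without adding signal. The
generator plants, with a fixed seed:

* **background** vocabulary shared by all documents;
* **entity mention documents** (one gene/disease/compound plus its topic
  words) so every entity acquires a vector;
* **gene families** sharing family vocabulary (for the cluster-coherence
  statistics);
* **bridge documents**: in the window before a planted pair's emergence
  year, the gene appears with the pair's unique bridge words, and the
  disease appears with the *same* bridge words in separate documents —
  exactly the indirect channel that contextual linking words are meant to
  surface. Direct co-mentions start only at the emergence year, so the
  generator is leak-free by construction;
* **pathway modules** of proteins whose within-module pairs are revealed
  gradually across interactome releases; unrevealed pairs already share
  pathway vocabulary, which is what a positive-unlabeled learner should
  pick up;
* **compound–target co-mentions** with a mix of 1-, 2- and >2-target
  compounds for the promiscuity strata.

Default conditions: 200 genes, 5 diseases, 10 compounds, years 2000–2012,
450 documents per year of 30 tokens, 10 planted associations (2 per
disease) with 5 unique bridge words each and a 3-year bridge window, 4
families of 10 genes, 12 pathway modules of 6 proteins with releases at
2006/2008/2010. Three choices deserve a note. All planted emergences
default to a single cohort year (2009) so that every pair has a full-length
bridge window behind the shared pre-emergence cut-off; with staggered
cohorts (available via `emergence_years`) later pairs have partial,
gene-skewed bridge exposure and bridge recovery measures exposure rather
than the linking-word machinery. The pathway module is sized so that the
10% sticky rule yields a workable negative set at toy scale (with 40
proteins it yields four sticky proteins and about six negative pairs —
untrainable). Bridge documents run at three per side per year so bridge
words clear the more-than-ten-mentions vocabulary floor within a single
window year.

Evaluation trains three yearly CBOW checkpoints (2006–2008) at dimension 64
— the dimension at which the planted structure is already comfortably
recoverable and a full run stays in the minutes range on one core — ranks
each disease's genes with the latest pre-emergence model, compares the
averaged prospective precision of the per-disease top-50 novel predictions
against a 10,000-iteration bootstrap, checks bridge-word recovery in the
top-10 linking words, and runs the positive-unlabeled PPI block with a
single H20-N2-D0.2 classifier (the 60-model grid is exercised by its own
operation; the PU question is about score behaviour, not tuning). The PU
block draws its negatives from the top 20% of proteins by degree rather
than the production 10%: with 72 proteins the 10% rule caps the negative
set at 28 pairs, too few to split into train, validation and test. The 10%
rule remains the default of `sticky_negatives()` itself.

What passing these tests shows — and does not. The generator reproduces the
*statistical skeleton* the method relies on: co-occurrence structure,
vocabulary growth over time, indirect bridge channels, nested releases. It
does not emulate synonym ambiguity at realistic rates, citation dynamics,
topic drift, reporting biases, or the heavy-tailed token distribution of
real abstracts. Recovery of planted signal is therefore a correctness check
of the machinery, not an effect-size forecast for PubMed.

## Numerical and reproducibility choices

* Every stochastic step (corpus generation, vector initialisation and
  sampling, network initialisation, dropout, shuffling, bootstrap draws,
  splits, uniform fills) is seeded; single-worker embedding training makes
  results bit-identical across runs.
* The in-package feed-forward engine uses ReLU hidden layers, inverted
  dropout, Adam, class-balanced loss and early stopping that keeps the
  best-epoch weights. Inputs are standardized per column on training
  statistics: embedding vectors from small corpora are strongly anisotropic
  (almost all pairwise cosines are high), and without scaling the pairwise
  classifiers' convergence depends on initialisation luck. The target classifier stops after two epochs without
  validation improvement; the pairwise trainers (PPI grid, compound zoo,
  clinical regressor) default to many short epochs with 8-example
  minibatches and patience 10 — on few-hundred-example pair datasets a
  patience of two epochs stops Adam during its warm-up.
* MCC is defined as 0 when its denominator vanishes, so degenerate models
  (e.g. one-unit, three-layer networks that collapse to a single class)
  are comparable rather than undefined.
* Ties break lexicographically everywhere a ranking is produced.
* The family-coherence background uses exact all-pairs distances up to
  2,000 genes and a seeded subsample of $10^5$ pairs beyond that.

## Limitations

Dictionary NER cannot resolve genuinely ambiguous synonyms and ignores
abbreviation context; the embedding engine is CPU-bound and not meant for
corpora beyond tens of millions of tokens per slice; cosine similarity is
an uncalibrated score, not a probability; and clinical-stage labels, like
interactome releases, reflect research attention as much as biology — a
ranking that predicts future literature predicts, in part, future fashion.
Transformer models are out of scope by design.
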