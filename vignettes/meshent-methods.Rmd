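---
title: "Maximum-entropy annotation of literature with MeSH terms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy annotation of literature with MeSH terms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshent)
```

## The problem

Biomedical literature databases index articles with headings from a
controlled vocabulary, the Medical Subject Headings (MeSH), organized as a
tree of dotted position codes (`C14.280.400`). Manual indexing cannot keep
pace with literature growth, and many headings are ambiguous English strings,
so a robust automated annotator is needed. `meshent` treats annotation as a
multi-label text-classification problem decomposed into one independent
binary decision per heading: for each term a *context model* is trained that
decides, from the surface evidence of a record, whether the term should
annotate it. Because decisions are independent, models can be applied
sequentially or in parallel and a document may receive any number of labels.

## The model

Each per-term classifier is a two-class conditional exponential
(maximum-entropy) model over binary labeled features. For a document with
feature set $x$ the score of class $c \in \{0, 1\}$ is

$$ s_c(x) = \beta_{c0} + \sum_{j : x_j = 1} \beta_{cj}, \qquad
   p(c = 1 \mid x) = \frac{e^{s_1(x)}}{e^{s_1(x)} + e^{s_0(x)}}, $$

and a zero-mean Gaussian prior with variance $\sigma^2$ penalizes all feature
weights (not the intercepts) to control overfitting on sparse text features.
The weights are estimated by maximizing the penalized conditional
log-likelihood with Newton/IRLS iterations.

Two implementation notes matter for anyone extending the optimizer:

* **Reduced parametrization.** The likelihood depends on the weights only
  through the difference $w = \beta_1 - \beta_0$, while the prior
  $(\lVert\beta_1\rVert^2 + \lVert\beta_0\rVert^2)/2\sigma^2$ is minimized,
  for fixed difference, at the symmetric point $\beta_1 = -\beta_0 = w/2$. The
  optimizer therefore works on $w$ with the equivalent ridge penalty
  $\lVert w\rVert^2 / 4\sigma^2$ — exactly a penalized binary logistic
  regression — and stores the symmetric split. The unpenalized intercepts'
  sum is not identified by the objective; the symmetric convention fixes it
  at zero without affecting any probability.
* **Monotone Newton steps.** Each IRLS step is backtracked (step halving)
  until the penalized objective does not decrease, so the objective trace
  recorded in the model is non-decreasing by construction; convergence is a
  relative objective change below `tol` (default `1e-6`, within
  `max_iter = 100`).

A consequence of the likelihood/prior split worth knowing: duplicating every
training instance doubles the log-likelihood, so the fitted probabilities are
preserved only if the penalty is doubled too, i.e. if `prior_variance` is
*halved*. Duplication alone still never flips the maximum-probability class.

The default `prior_variance = 1.0` is a conventional weakly regularizing
choice; no canonical value exists for this pipeline and the tests do not
explore sensitivity to it.

## Features

Four namespaces of binary features are built per record
(`build_feature_set()`):

* `title:`/`abstract:` — tokens lowercased, split on non-alphanumeric
  boundaries, stop words removed (a fixed ~150-entry function-word list
  shipped as code, `mesh_stopwords()`), then Porter-stemmed. The same token
  in title and abstract yields two distinct features, which is what lets the
  models learn that title evidence is more reliable than abstract evidence.
* `journal:` — the journal name, lowercased with whitespace collapsed.
* `year:` — the publication year is expanded into *before/after* indicators
  over the configured 1950–2010 range: `year:afterY` for every year from
  1951 up to the publication year and `year:beforeY` up to 2009. Both range
  endpoints are excluded so the block has exactly 59 features for every
  in-range year; out-of-range years are clamped into the open range with a
  warning rather than rejected. The constant block size means the year
  signal enters only through *which* indicators flip, not how many.

The year encoding is what lets a model express "published before 1999 is
evidence for this term" when a heading has a publication trend; with a
simulated trend, year features appear among a model's top-ranked positive
features (`ranked_features()`), and a year-only ablation still separates
classes better than chance.

Features are presence indicators — no counts, no tf-idf — since journal and
year features are inherently binary and heading-level lexical evidence is
well captured by presence. Feature strings are `namespace:value` with
lowercase values, so serialized models and feature files are byte-stable.

## Training sets

Positives are all documents gold-annotated with the term, capped at 10,000 by
a seeded uniform draw. Negatives are drawn equal in number to the positives
(when the pool allows; otherwise the whole pool is used and a warning
recorded) from one of three pools, always excluding the positives:

* `random` — any other document;
* `literal` — documents that contain the term literally (contiguous stemmed
  token sequence of the label in title or abstract) but are *not* annotated
  with it — the hard cases an exact matcher gets wrong;
* `literal_distant` (default) — the subset of `literal` whose gold headings
  are all semantically far from the term in the tree.

Literal matching is performed on stemmed token sequences for consistency with
the exact-matching baseline's stemmed matching; synonym matching is available
but off by default, since the emulated phrase query uses the preferred label
only.

Tree distance between terms is $L(t_1) + L(t_2) - 2\,CP(t_1,t_2)$ where $L$
is the minimal number of components over a term's tree numbers (a top-level
code has depth 1) and $CP$ the maximal common-prefix length over tree-number
pairs. On a strict monohierarchy this is the shortest-path edge count through
a virtual root, which is how the tests validate it (a BFS oracle over the
parent/child graph). For polyhierarchic terms the min/max convention yields
the smallest defensible distance, a conservative choice when declaring a
document "distant". A document is distant from a term when the *maximum*
distance between the term and any of its gold headings exceeds the depth
threshold (default 6, strict). The maximum makes one far-away heading
dominate; that is the definition implemented, and its practical effect is
that documents touching any unrelated branch count as distant. Documents with
no gold headings have no defined distance and are skipped with a log entry
rather than silently included.

## Decision threshold

A document is annotated with a term when the positive-class probability
strictly exceeds $t = 0.5 + \delta$. The default $\delta = 0.1$;
`tune_delta()` reproduces the tuning protocol — hold out 10% of the training
set (class-stratified, seeded), train on the rest, and pick the grid value
(0.0–0.4 by 0.1) maximizing validation F, ties toward the smaller offset.
Raising $\delta$ can only shrink the predicted-positive set, so recall is
non-increasing in $\delta$; on well-separated models precision is
non-decreasing, which the acceptance tests assert on fixed splits.

## Evaluation protocol

`cross_validate()` evaluates per term: the term's positive/negative set is
drawn once, partitioned into `folds` (default 10) class-stratified folds,
and each fold is classified by a model trained on the others; tp/fp/fn
accumulate across folds into per-term precision, recall and F
(zero-denominator cases defined as 0), and the macro row is the unweighted
mean over terms. Folds are per-term rather than a global document split
because each classifier is an independent binary problem and the headline
metrics are averages of per-term scores. Negative sets are drawn once per
term before folding, not once per fold. The baselines run under exactly the
same folds: Bernoulli naive Bayes with add-one smoothing (maximum posterior,
empirical prior) and exact matching (fires on stemmed literal containment,
no training). Reports serialize to TSV with a macro/config header; two runs
under the same master seed are byte-identical, because every random draw
derives its stream from the master seed and a stable per-term hash rather
than from iteration order.

## The synthetic study world

The generator (`generator_spec()`, `generate_toy_tree()`,
`generate_corpus()`) produces the structure the method exploits, at desk
scale. Defaults, chosen once as the package's study conditions:

* **Tree**: complete depth-4, branching-2 tree — 30 terms; ~10% of leaves get
  a second position (polyhierarchy). Labels are single vowel-free synthetic
  tokens, so Porter stemming is the identity on them and they can never
  collide with the stop-word list (test isolation by construction).
* **Corpus**: 3,000 documents, each gold-annotated with 1–3 terms drawn from
  the two deepest levels, mirroring the most-specific-heading indexing
  convention of real literature databases. This also makes the depth-6
  distance threshold attainable: on a depth-4 tree a depth-1 term can never
  be farther than 5 from anything, so annotating only deep terms is what
  gives every modeled term a non-empty semantically-distant pool.
  (Occasionally a polyhierarchic leaf still has an empty distant pool —
  its second position shrinks every distance — and is then reported as
  skipped rather than silently dropped.)
* **Signals**: each term's surface token and each of its 3 co-vocabulary
  tokens appear in a positive document's title/abstract with probability
  `signal_strength = 0.9`; background noise tokens from a 120-token
  vocabulary are mixed in at `background_rate = 0.3`; the document's journal
  is the primary term's home journal with probability 0.7; ~2 literal
  mentions of non-gold terms are injected per abstract so literal negative
  pools are populated (documents citing a heading they are not indexed
  with). Ambiguity (`ambiguity_fraction`) pairs deep terms across branches
  and gives each pair a shared surface token while home journals and
  co-vocabularies differ — distinguishable in context, indistinguishable to
  an exact matcher.

What the generator does *not* emulate: realistic lexical statistics (Zipfian
vocabulary, document length variation), hierarchical correlation between a
heading and its ancestors' vocabulary, multi-word headings, real MeSH
topology or scale, and annotation noise. Passing the synthetic recovery tests
therefore shows that the pipeline's machinery is correct and that its
comparative ordering (MaxEnt above naive Bayes above exact matching under
ambiguity) emerges from the modeled mechanisms — it does not certify
performance numbers on real literature.

## Problem sizes used in the tests

The packaged checks run the full 30-term/3,000-document preset for the
recovery and baseline-ordering runs (three seeds for recovery), and smaller
worlds (14-term trees, 300–800 documents, 4–5 folds) for unit-level
behavior; these sizes keep a complete run of the suite in the minutes range
on a single CPU while still exercising every stage at study conditions.

## Known limitations

* The MEDLINE reader is a best-effort import of the tagged plain-text layout
  (PMID/TI/AB/TA/JT/DP/MH with indented continuations); it is not a parser
  for the XML distribution, and headings are resolved by exact
  label/synonym match only.
* `contains_term_literally()` scans stemmed token windows; for very long
  abstracts and many terms the exact-matching baseline is the slow path.
* Per-term models share no statistical strength across the hierarchy; the
  tree enters only through negative selection.
* With `literal_distant`, negative pools are often smaller than the positive
  set at desk scale; the equal-size rule then degrades gracefully (whole
  pool, warning) but per-fold negative counts can be small.
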