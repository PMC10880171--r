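---
title: "Methods: string-semantic score fusion for medical term normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: string-semantic score fusion for medical term normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termlink)
```

## The problem

Medical text in most languages names diseases with terms that have no entry
in a unified reference terminology such as the UMLS. Normalizing such a term
means ranking the entries of a reference concept dictionary — typically the
"Disorders" semantic group of an MRCONSO-style table, where one concept
(CUI) carries many synonymous terms — and reading off the top concepts.
`termlink` implements that ranking as the fusion of two similarity channels
computed between a query's translation variants and every dictionary term,
plus the harness needed to train, evaluate, and stress-test the fusion.

Cross-lingual queries are handled by a translation step modeled as a
provider contract: several engines each propose translations, and the
unified variant set is their de-duplicated union (each variant tagged with
its contributing providers). A knowledge-infused cross-lingual encoder can
skip translation entirely — that mode differs only in the embedder backend
and input language, not in code path.

## The two channels

**String channel.** Every dictionary term is one document. For a character
n-gram $g$ of term $d$,

$$\mathrm{tf}(g,d) = \frac{f_{g,d}}{\sum_{g'} f_{g',d}}, \qquad
\mathrm{idf}(g) = \ln\frac{N}{|\{d : g \in d\}|}, \qquad
w_{g,d} = \mathrm{tf}(g,d)\,\mathrm{idf}(g),$$

with $N$ the dictionary size. The string score is the cosine of the two
sparse vectors, $S_{string}(q,c) = \cos(e^s_q, e^s_c)$. Two idf dialects are
implemented: the literal form above (`"paper"`, the default), under which an
n-gram occurring in every term gets weight exactly 0 and drops out, and the
smoothed library convention $\ln\frac{1+N}{1+df}+1$ (`"smoothed"`), which
keeps all weights positive. Cosine normalization makes the choice of an
additional l2 document-norm moot. N-grams are taken over the whole canonical
string *including* internal spaces — the fragments are subword units, and
crossing token boundaries keeps multiword terms comparable. When several
orders are requested (e.g. $n \in \{2,3\}$) they share one vocabulary and
one tf denominator, so each text still maps to a single vector.

**Semantic channel.** $S_{semantic}(q,c) = \cos(e^d_q, e^d_c)$ over dense
vectors from an embedder backend. The contract fixes the pooling convention
for language-model backends — the final-layer vector of the sequence-start
special token (CLS) — but the package never ships model weights: real
backends run offline and enter through the precomputed-vector file
(`read_dense_vectors()`), while tests use a deterministic toy backend that
hashes character 3-grams to seeded random unit vectors. Vectors are not
normalized at embed time; cosine is scale-invariant and raw outputs stay
inspectable.

All text on both channels passes through one canonical form (NFKC,
lower-case, collapsed whitespace) so the channels always see identical
strings.

## Variant handling

How a multi-variant query should be scored is a genuinely open design point.
`termlink` scores each variant independently and takes, per channel, the
**maximum** over variants before fusion. This is monotone — adding a variant
can never lower the gold candidate's score — which matches the observed
pattern that unified multi-engine translation helps every strategy, and it
gives the evaluation harness a clean invariant to test.

## Fusion schemes

Four schemes fuse the channels:

* `zscore`, `minmax`, `tanh`: each channel is normalized *per query* over
  its candidate scores, then the channels are summed with unit weights.
  Per-query normalization follows score-fusion practice; normalizing over
  the whole dictionary once would make min-max degenerate. The tanh map is
  the conventional robust form $0.5(\tanh(0.01\,z)+1)$ with $z$ the
  population z-score; 0.01 is part of that convention. Degenerate pools
  (zero spread) map to the scheme's fixed point (0 for z-score, 0.5
  otherwise). All three maps are monotone, so they can merge ties but never
  invert an order. Whether trained weights should also apply after
  normalization is unstated in the fusion literature we follow; unit weights
  are the default and `weighted = TRUE` exposes the variant.
* `linear`: $S = \alpha\,S_{semantic} + \beta\,S_{string}$ on the raw
  cosines, with trainable $(\alpha, \beta)$.

## Training the linear combiner

Given labeled queries, each training step mines the current top-$k$
candidates per query ($k = 20$ by default) and maximizes the marginal
probability of the synonymous candidates in the pool:

$$P(n_i \mid q) = \frac{e^{S(n_i,q)}}{\sum_j e^{S(n_j,q)}}, \qquad
P'(q) = \sum_{i\,\text{positive}} P(n_i \mid q), \qquad
\mathcal{L} = -\frac{1}{Q}\sum_q \log P'(q).$$

Only $\alpha$ and $\beta$ are trainable, so the implementation is full-batch
gradient descent with the closed-form gradient
$\partial P'/\partial\alpha = \sum_{i\,\text{pos}} p_i (a_i - \bar a)$
(and symmetrically for $\beta$), rather than a stochastic deep-learning
optimizer: a 2-parameter objective needs no such machinery, and determinism
is worth more. Defaults: init $(1, 1)$, learning rate 0.5, 100 epochs,
re-mining every epoch (iterative hard-candidate mining, the cadence used by
synonym-marginalization trainers). Softmax is computed max-shifted. Pools
whose top-$k$ contains no gold concept are dropped with a reported count —
their log-probability is $-\infty$, and skipping them is the only
finite-loss option that leaves the objective unchanged. A query whose gold
concept is absent from the dictionary altogether violates the training
contract and raises an error instead.

Two properties make this trainer testable without any external data: its
analytic gradient must match central finite differences, and on benchmarks
where only one channel carries signal, the trained weight of the
informative channel must exceed the other's.

## Evaluation

`Acc@n` is the percentage of queries whose gold concept appears in the top
$n$ *distinct concepts*: because synonym-rich dictionaries put many terms on
one concept, duplicate concept ids are collapsed (best rank wins) before
counting, so $n$ refers to concepts, not term rows. `dedup_concepts =
FALSE` preserves the raw term-row reading. Paired system comparisons use
McNemar's test on the discordant counts $(b, c)$: exact two-sided binomial
when $b + c < 25$, continuity-corrected $\chi^2 = (|b-c|-1)^2/(b+c)$
otherwise — standard small-sample practice; the method used is recorded in
the result.

Ties are broken everywhere by dictionary position under a stable sort, so
rankings, reports, and training runs are bit-reproducible.

## The synthetic benchmark generator

Real studies of this pipeline need a licensed UMLS release, commercial
translation engines, and GPU-scale encoders. The generator replaces them
with a desk-scale emulation that preserves the *computational structure*:

* a dictionary of `n_concepts` pseudo-term concepts (2–4 words over a
  20-letter alphabet), each with `synonyms_per_concept` edit-perturbed
  surface variants;
* queries whose "translation variants" are independent edit perturbations
  (rate `string_noise`: per-character substitution plus occasional token
  swap and affix) of a randomly chosen synonym of the gold concept — the
  multiple-noisy-alias structure that round-trip translation induces;
* one latent unit vector per concept, with every term and variant embedded
  as latent $+\ \mathcal{N}(0, \texttt{semantic\_noise})$, l2-normalized —
  synonyms form packed clusters, as self-aligned biomedical encoders
  produce.

`channel_mode` switches off one channel: `semantic_only` replaces query
variants with random strings (string channel becomes background noise);
`string_only` replaces query-side vectors with fresh random unit vectors.
The vector table is keyed by text, so a variant that is an exact string
match of a dictionary term keeps the dictionary-side vector — an embedder
is a function of its input text, and one text cannot carry two vectors. At
the default noise this affects a small fraction of `string_only` queries
and leaves the semantic channel only weakly informative there.

Defaults are fixed once: 500 concepts × 3 synonyms, 400 queries,
`string_noise = 0.15`, `variant_count = 2` (two engines' worth of aliases),
`semantic_noise = 0.3`, `dim = 64`. The noise defaults sit where both
channels are informative but imperfect — string cosines of perturbed
variants stay high while per-coordinate latent noise at dimension 64 keeps
within-concept cosines well separated from, but not trivially above, the
between-concept background. All randomness flows from the single config
seed through scoped generators (`withr::with_seed`), so regeneration is
byte-identical and the global RNG stream is never touched.

What the generator does **not** emulate: real orthography (Chinese or
otherwise), UMLS term-length and ambiguity statistics, engine-specific
translation error profiles, and the semantics a language model actually
learns. Passing tests therefore demonstrate the correctness, determinism,
and ordering properties of the machinery — not clinical-grade accuracy on
real data.

## Numerical choices and degenerate inputs

* Empty texts canonicalize to `""`; readers reject them with named records,
  the dictionary reader skips them with a logged count.
* A text with no in-vocabulary n-grams yields the empty sparse vector; its
  cosine against anything is 0 by convention (likewise any all-zero
  vector).
* `k` larger than the dictionary truncates the pool with a warning.
* Duplicate `(concept, term)` pairs collapse at dictionary construction;
  identical terms under different concepts are kept (real dictionaries are
  ambiguous).
* Scaling $(\alpha, \beta)$ by any $c > 0$ changes softmax values but no
  ranking; the test suite asserts this invariance.

## Problem sizes used by the test suite

Unit tests run on fixtures of 10–60 concepts. The end-to-end property tests
(parameter recovery, linear-dominance ordering) use the full default
conditions — 500 concepts × 3 synonyms, 400 queries, seed 7, 50 training
epochs — which complete in well under a minute each on one CPU. The
`scripts/acceptance.R` runner regenerates the three channel-mode benchmarks
from scratch at a caller-supplied seed and reports Acc@n per strategy,
trained weights, and loss traces.

## Known limitations

* Only the two channel weights are learned; there is no joint fine-tuning
  of the dense encoder and no nonlinear fusion.
* Exact cosine against the whole dictionary per query: appropriate at desk
  scale, not a substitute for an approximate-nearest-neighbor index at
  millions of terms.
* The mock translation provider is table-driven; nothing in the package
  contacts a live engine, and translation quality itself is out of scope.
* Reference weights reported for this method on licensed data
  ($\alpha = 33.11$, $\beta = 7.28$) depend on that data and those engines;
  the package treats them as a reference configuration, not a recovery
  target.
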