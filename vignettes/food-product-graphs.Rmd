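---
title: "Methods: graph learning on consumer food catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph learning on consumer food catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `foodgraph`, the design
decisions behind them, the generative model of the synthetic catalog
simulator, and what evaluation on simulated catalogs does and does not
establish.

## The data model

A catalog row is a consumer food product with a name, a brand, one or more
category tags, a price range `[price_min, price_max]`, and an ordered list of
ingredient mentions. Ingredient mentions are free text and noisy: the same
substance appears under plural forms, capitalization variants and label
boilerplate ("contains …"). `normalize_token()` canonicalizes a mention by
lowercasing, stripping punctuation, removing stop words, and Porter-stemming
each remaining word; multi-word ingredients stay a single token joined by one
space, and entity matching afterwards is exact string equality.

Two text-normalization details are deliberate deviations from a textbook
Porter implementation:

* the final `y -> i` rewrite is applied only when the `y` follows a
  consonant. The unconditional rule maps food terms like *soy* to *soi*,
  which needlessly fragments the vocabulary; the conditional form is the
  refinement most modern stemmer implementations adopt.
* each word is stemmed to a fixed point (the stemmer is re-applied until the
  output stops changing). Single-pass suffix stripping is not idempotent on
  all inputs, and idempotence is what makes write/load round trips and
  re-normalization of already-clean catalogs exact no-ops.

Stop words are a config file (a compact English list plus label boilerplate:
*contains*, *ingredients*, *may*, *traces*, …), so users can extend the list
without touching code.

## Compound ingredients and hierarchy recovery

Many listed ingredients are composite foods. `build_hierarchy()` recovers a
compound-to-constituents map from the catalog itself: an ingredient token is
compound when it equals some product's normalized name after that product's
brand words are removed, and its constituents are the ingredients occurring
in at least a fraction `theta` of the matching products.

* `theta = 0.75` by default. The intent is "ingredients these products almost
  always contain"; 0.75 keeps constituents that appear in 3 of 4 matching
  products while discarding idiosyncratic extras. It is exposed as an
  argument because catalogs with many variants per compound may want a
  stricter cut.
* Entries are inserted in decreasing order of support (number of matching
  products); an entry that would create a cycle is skipped and logged, so the
  map is acyclic by construction. A product listing its own name as an
  ingredient is ignored.
* The recovered map is serialized as editable JSON; automated recovery is a
  heuristic and curation is expected for real catalogs.

`decompose_ingredients()` takes the recursive union to a fixed point
(monotone and idempotent); `contains_target()` answers membership in that
closure without materializing it. Labels for learning always come from
`contains_target()`, so hidden dependencies count as positives, while input
features may or may not be decomposed depending on the evaluation regime.

## Node classification: masked-ingredient detection

Products are encoded as binary bag-of-ingredient rows over the training
vocabulary with the target ingredient's column removed. Masking matters: the
model must infer presence from co-occurrence structure, never read it.
Evaluation-time tokens missing from the training vocabulary are ignored.

The brand graph joins same-brand products into cliques. The GraphSAGE
classifier applies two mean-aggregator layers:

* layer: `h' = relu(W [h ‖ mean of neighbor h] + b)`; a node with no
  neighbors aggregates a zero vector, which makes the layer well defined on
  isolated nodes and makes the whole network collapse to an MLP on an
  edgeless graph. The package exploits this: the MLP kind *is* the same
  two-layer network evaluated with an empty neighborhood, so the
  MLP/GraphSAGE comparison isolates the contribution of the graph rather
  than implementation differences.
* widths: 128 hidden channels; dropout 0.5 on the hidden layer; Adam with
  learning rate 0.01 and weight decay 5e-3 (added to weight gradients, not
  biases); binary cross entropy; at most 400 epochs.
* early stopping: validation accuracy with patience 50, best-validation
  parameters restored. Ties do not count as improvement, so a plateau
  triggers the stop.
* initialization: Glorot-uniform, seeded; with `nthread = 1` boosting and a
  seeded tree fit, every model kind is bit-deterministic given
  `train_config(seed = )`.

The decision tree (Gini) and gradient boosting (100 stages, depth 3,
shrinkage 0.1) consume the ingredients-only regime; the MLP can optionally
concatenate a brand one-hot, in which case brands unseen at prediction time
map to the zero vector. The GraphSAGE model receives brand information only
through topology, which is what lets unseen brands still contribute: their
products form a clique whose aggregated features feed the convolution even
though the brand identity itself was never observed.

Data splits hold out whole brands for the non-decomposed test set (brands
disjoint from training by construction), then randomize the remaining
products into train/validation/decomposed-test with fractions 0.70/0.10/0.10
and about 10 % of brands held out. Training and the decomposed test use
hierarchy-expanded features; the unseen-brand test uses raw features with the
hierarchy consulted only for labels.

## Link prediction: criteria-valid substitution

A substitution edge `s -> t` requires: `s` contains the target (via the
hierarchy), `t` does not, the category sets intersect, and the price points
are within `price_tolerance` (default 0.10). Numerical choices:

* price point = midpoint of `[price_min, price_max]`. The criteria compare
  one "cost" per product; the midpoint is the least-assumptive collapse of a
  range.
* the tolerance is relative to the *source* product (`|m_t − m_s| / m_s`),
  matching the directed semantics: the budget that matters is that of the
  product being replaced. A symmetric reading of "within ±10 % of each other"
  differs only in the band's edge cases.
* raising the tolerance can only add edges (monotonicity), which the test
  suite checks.

`enumerate_substitutions()` computes the exact edge set with sparse
category-incidence algebra and is verified against a brute-force
all-ordered-pairs oracle.

The predictor is a two-layer SAGE encoder (128/128) with an inner-product
decoder and sigmoid. Message passing uses the symmetrized training positives
(supervision stays directed; mean aggregation benefits from both endpoints'
context), and only training edges, so validation/test edges never leak into
the encoder. Each epoch draws a fresh balanced negative sample — uniformly
random ordered non-edges, excluding observed positives but *not*
criteria-checking them (near-negatives that fail a single criterion are
allowed; a strict mode can be built by filtering with
`check_substitution()`). Validation and test use fixed, seeded negative sets
so metrics are comparable across runs and epochs. Early stopping monitors
validation AUC (patience 50). Learning rate is 0.001 for this task.

Accuracy for the link task is measured on balanced held-out sets at the 0.5
threshold; AUC is the Mann–Whitney rank statistic with ties counted one
half. These metrics are internally consistent across runs but not comparable
to absolute numbers obtained on other negative-sampling policies.

## The evaluation protocol

`run_protocol()` runs each target ingredient `n_runs` times with seeds
`base + 0 .. n_runs − 1` (the schedule is recorded in the per-run table),
takes the per-ingredient median of each metric, and reports the mean and
standard deviation of the medians across ingredients — five by default: palm
oil, wheat, milk, egg, soya. A single run with a single ingredient reduces to
that run's metrics, and re-execution with the same base seed reproduces the
table exactly.

## The synthetic catalog simulator

Real catalog data of this kind is commercially licensed, so the package
simulates catalogs whose statistical structure carries every mechanism the
methods rely on:

* **Brand structure.** Each brand has a "house" ingredient subset whose
  sampling odds are multiplied by `1 + beta`, and a scalar brand effect
  `u_b ~ N(0, 1)` entering the target-presence log-odds as `0.4 * beta *
  u_b`. At `beta = 0` both channels vanish: per-brand prevalence matches the
  global rate (checked by chi-squared tests under replication) and the
  brand-label mutual information is minimal, increasing with `beta`.
* **Category structure.** Categories have house ingredients (4x odds), a
  base price (products are lognormal around it, sd `price_sigma = 0.18`),
  and for each target a set of "prone" categories (30 % of categories) in
  which that target's correlate ingredients are common (40x odds) while
  being rare elsewhere. This mirrors how real targets concentrate in product
  classes and makes category and price partially inferable from composition
  — precisely the inference the substitution model must perform.
* **Target presence.** For each of the five planted targets, presence is
  Bernoulli with log-odds `alpha + 0.4*beta*u_b + 2.8 * (number of correlate
  ingredients present in the decomposed ingredient set)`; `alpha` is
  calibrated by root finding so the marginal rate hits `target_base_rate`
  (0.30). The steep correlate coefficient makes presence close to
  deterministic outside a narrow ambiguous band, emulating a catalog where
  composition strongly predicts the target — the regime in which detection
  methods are useful at all.
* **Hidden dependencies.** Planted compounds (10 in the desk preset) are
  composite foods of a home category: their constituents follow that
  category's composition and may include targets (probability 0.5 in prone
  home categories, 0.05 otherwise). Each compound is emitted twice as an
  actual product (two brands, name = brand + compound token) so hierarchy
  recovery has something to find, and listed by other products *with its
  constituents removed* — those products' labels still count the hidden
  constituents, and when the explicit target would be redundant with an
  implied one it is dropped from the label half the time.
* **Surface noise.** Each emitted mention is replaced by an alias (plural or
  case variant) with probability `alias_rate = 0.1`; the raw records then
  pass through the same `load_catalog()` sanitization as user data, which
  must collapse the aliases back to canonical tokens.

The desk preset (1500 products, 40 brands, 300 ingredient tokens, 20
categories, 10 compounds, mean list length 10) is the package's standard
working scale: large enough for stable metrics and full hierarchy recovery,
small enough that the complete test suite and the acceptance script run in
minutes on one CPU. Substitution fixtures tighten prices
(`price_sigma = 0.08`) and reduce categories to 6 so that a material share
of ordered pairs is criteria-valid.

What the simulator does **not** emulate: real ingredient-name morphology
beyond plural/case aliases (no "over 200 names for palm oil"), regional
category taxonomies, nutrition facts, correlated multi-target chemistry, or
adversarial mislabelling. Passing tests on synthetic catalogs therefore
demonstrates that the pipeline recovers the mechanisms it models — masking,
hierarchy, brand/category correlation, criteria structure — not that any
particular accuracy will transfer to a specific commercial dataset.

## Degenerate inputs and error contracts

Empty-after-normalization mentions, empty catalogs, unknown targets, cyclic
hierarchies, single-class training labels, empty positive edge sets,
exhausted negative samplers, self-substitutions and too-few-brands splits
all raise typed conditions (`empty-after-normalization`, `empty-catalog`,
`unknown-target`, `cyclic-hierarchy`, `degenerate-labels`, `no-positives`,
`exhausted`, `insufficient-brands`) rather than producing silent nonsense.

## Known limitations

* Hierarchy recovery requires the compound's name to match an ingredient
  token exactly after brand stripping; paraphrased product names are missed.
* The link predictor's absolute accuracy depends on the negative-sampling
  policy; only AUC-style rank statements are robust to that choice.
* Full-batch training is intended for catalogs up to tens of thousands of
  products; neighbourhood sampling would be needed well beyond that.
* The decoder scores are probabilities under the training objective, not
  calibrated substitutability estimates; ranking, not thresholding, is the
  supported use.
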