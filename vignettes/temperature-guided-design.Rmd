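---
title: "Temperature-guided language modelling for protein design: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-guided language modelling for protein design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermlm` couples a masked protein language model to an
optimal-growth-temperature (OGT) signal, on the premise that the growth
temperature of a protein's host organism correlates with the protein's own
thermal properties. This vignette explains the model, the objectives, the
engineering loop, and the design choices behind them — including what the
bundled synthetic data can and cannot demonstrate.

## The model

The encoder is a pre-LayerNorm transformer with rotary position embeddings
and GELU feed-forward blocks (the ESM-2 block structure at configurable
scale). It maps a tokenized sequence over the 20 canonical amino acids
(plus `<mask>` and `<pad>`) to one hidden vector per residue,
`(h_1, ..., h_L) = Transformer(x_1, ..., x_L)`.

Two heads read those vectors:

* **MLM head.** A linear projection (weight-tied to the input embedding by
  default) with a 20-way softmax: `p_j = MLM(h_j)`, a distribution over the
  residues at position `j`. All mutant scoring flows from these
  distributions.
* **OGT head.** The hidden vectors are LayerNorm-ed (a fresh, learned norm
  — the in-line normalization is read as its own layer, not a reuse of the
  encoder's final norm), pooled by a projection-softmax attention
  (`s_i = softmax(W h_i + b)`, `c = sum_i s_i h_i`), passed through a
  residual two-layer MLP `r = FC2(g(FC1(c))) + c` with `FC1: d -> 4d`,
  `FC2: 4d -> d`, and finally `y = FC4(tanh(FC3(r)))`. `FC3`'s width is not
  pinned down by the architecture sketch; we use `d -> d` (then
  `FC4: d -> 1`), the simplest reading of "an MLP with two fully connected
  layers". The formula itself is unbounded; the stated output contract is a
  temperature between 0 and 100 degC. We therefore train on the raw `y`
  (keeping the printed loss and its gradient intact) and clamp to [0, 100]
  only at inference, controlled by a flag that defaults to on.

`r` doubles as the sequence representation for transfer learning.

The desk-scale preset is 2 layers, 4 heads, embedding 64, maximum length
512 — small enough that pretraining runs in tens of seconds on one CPU
core. The published-scale geometry (33 layers, 20 heads, embedding 1280) is
recorded as a config preset for reference only.

### Implementation notes

No autodiff framework is used: forward and backward passes are written
directly against BLAS, and the analytic gradients of all three objectives
are checked against central finite differences in the test suite (worst
relative error around 1e-4 on random instances). For throughput, a batch of
sequences is concatenated into one `(sum L_i) x d` matrix; LayerNorm,
projections, the rotary rotation and the feed-forward blocks operate on the
stacked matrix, and only the attention products fall back to per-sequence
blocks. Per-sequence results are identical to single-sequence calls up to
BLAS rounding (tested at 1e-10).

## Noising

Training inputs are corrupted by selecting exactly `round(0.2 L)` positions
per sequence as reconstruction targets — an exact count rather than
per-token coin flips, so the 20% total is deterministic and every sequence
contributes targets. Each selected position is independently masked (70%),
substituted by a draw from background amino-acid frequencies (20%), or kept
unchanged (10%); in expectation the mask token covers 14% of all tokens and
substitutions 4%. Two conventions are worth stating because the scheme
leaves them open: the kept 10% are still scored by the reconstruction loss,
and a substitution may coincide with the original residue (sampling is
frequency-proportional, not identity-excluding). The bundled background
table mirrors the natural amino-acid composition of UniProtKB/Swiss-Prot
release averages and can be overridden from a two-column CSV.

## Objectives

* **MLM loss**: negative log-likelihood of the original residue at the
  noised positions. The printed form is a bare sum; we average over noised
  positions by default so the loss scale is length-invariant (the sum is
  available via `reduce = "sum"`). Uniform predictions give `ln 20 ~ 3.00`,
  a useful calibration anchor.
* **OGT loss**: mean-squared error in degC^2. Its raw magnitude (thousands,
  early on) dwarfs the other losses, hence the default total-loss weight of
  0.01 on this term.
* **Correlation alignment**: for a batch of `N` random single-point mutants
  of one sequence (positions uniform, substitutions uniform over the 19
  alternatives; `N = 16` by default — the sample size is an open parameter
  and 16 keeps the Pearson estimate stable without dominating step cost),
  the MLM log-odds scores `S` and raw OGT predictions `T` are aligned by
  `L = 1 - cov(S,T) / (sd(S) sd(T))`, which is 0 at perfect positive
  correlation and 2 at perfect negative correlation. Population (divide by
  `N`) covariance and SDs are used; the ratio is identical under the sample
  convention, the choice is fixed only for bit-reproducibility. If either
  vector has zero variance the loss falls back to 1 with zero gradient and
  a warning, avoiding NaN poisoning early in training. The alignment treats
  the predicted temperatures as fixed targets by default (stop-gradient on
  `T`): the objective exists to feed information back from the OGT
  predictions into the MLM scores, and detaching `T` keeps the OGT head
  shaped by its labels alone. This matters at small scale: the Pearson
  gradient with respect to `T` carries a `1/sd(T)` factor, so while the OGT
  head's predictions barely vary -- the natural state of a briefly trained
  model -- an attached alignment overwhelms the 0.01-weighted MSE signal
  and imprints the (still arbitrary) MLM ranking onto the temperature head.
  `align_stop_gradient` exposes `"scores"` and `"none"` (one shared graph)
  for the other readings. A mean-squared-error
  alignment of the two heads is deliberately not offered as a training
  mode: aligning absolute values of an uncalibrated score is unstable, and
  only the relative ranking is meaningful for engineering.

Training alternates tasks per mini-batch in a fixed round-robin
(MLM, OGT, correlation — the order is configurable; the round-robin is the
least-assuming reading of per-batch alternation), with Adam and a default
learning rate of 1e-4. Desk-scale batches are 1024 tokens with no gradient
accumulation; the published-scale setting (4096 tokens x 32 accumulation
steps) is kept as a preset. For the desk-scale demonstrations in this
package we raise the learning rate to 1e-3: a 2-layer model trained for a
few hundred steps sits in a very different optimization regime from a 650M
parameter model trained for 200k steps, and 1e-4 at this scale moves the
heads too slowly to show the transfer effects the tests exercise.

## Zero-shot scoring

A single mutation is scored by the log-odds ratio at its position,
`Score(i, m | w) = log p_i[m] - log p_i[w]` (natural log). The default mode
reads both probabilities from one forward pass on the intact wild type
("wt-marginal"): the wild-type reconstruction view supports this reading,
saturation scans then cost one encoder pass per model, and antisymmetry
`Score(i, m|w) = -Score(i, w|m)` holds exactly on that pass. The
"masked-marginal" alternative (mask position `i` first; `L` passes per
scan) is a flag, since related models conventionally score that way; which
variant the original work used is not fully determined by its text.
Multisite variants are scored as the sum of their single-site scores in
zero-shot mode — an explicitly additive approximation that ignores
epistasis; the supervised regressor is the tool that can see epistasis.

Candidate filtering removes mutations within 6 angstrom of designated
active-site residues (minimum point-to-point distance over the provided
coordinates; the threshold is closed, exactly 6.0 is excluded — a
documented convention, either closure being defensible). Coordinates come
from a position/x/y/z CSV; producing them (e.g. from a PDB file's CA or
heavy atoms) is left to the user, and the semantics of "distance to a
residue" are whatever atoms the CSV author provides.

## Low-N supervised transfer

Given labeled variants, the backbone (encoder, MLM head, pooling, FC1/FC2)
stays frozen; FC3 and FC4 are freshly rerandomized and trained with MSE at
learning rate 1e-4, batch 16. Freezing is structural: the optimizer's
update set simply excludes everything else, so frozen tensors are
bit-identical afterwards, and because the features `r` are fixed they are
computed once per variant and cached. The number of epochs is chosen by the
dynamic rule: split the data into 5 folds, train on 4 with early stopping
(patience 20, cap 200) on the held-out fold, record the best epoch, and
round the mean (half-up, minimum 1); the final fit uses all labels for that
many epochs with no validation split. Labels are z-scored internally —
assay units vary wildly across campaigns — and predictions are returned on
the original scale. Five seeds are ensembled by averaging predictions.

## The design loop

A campaign starts with a zero-shot round: saturation-scan the wild type
(optionally restricted to a predefined candidate set and/or filtered by the
6-angstrom rule), select the top `K` singles, and measure them. Each
supervised round then (1) fits the regressor on all accumulated labels,
(2) enumerates position-compatible combinations of the *labeled* singles at
the requested orders (two mutations at one position never co-occur;
counting uses elementary symmetric polynomials and pools beyond 200,000
variants are uniformly subsampled with an exact dynamic-programming
sampler), (3) scores the pool, (4) selects per order quota (e.g. top 10
each of 2-, 3-, 4-site) excluding anything already measured, and (5) sends
the selection to the oracle — a synthetic landscape in tests, a per-round
assay CSV in real use. Restricting pools to combinations of labeled singles
follows the campaign design this package mirrors; a flag could widen it,
but unlabeled singles would then enter combinations with no direct
experimental support.

The in-silico directed-evolution harness compares acquisition strategies on
a fully enumerable landscape (defaults: 100 replicates, 2 rounds, 50
variants per round). Round 1 scores by the additive zero-shot proxy (sum of
single effects); round 2 by a ridge regression on mutation-indicator
features fitted to everything measured so far. The ridge baseline is also
available as the campaign scorer: it is exact for additive landscapes,
blind to epistasis, and orders of magnitude cheaper than the transformer
regressor — useful for tests and for isolating what the representation
adds. "Stratified" sampling draws equally from score quartiles; it is our
own construction (the external method it gestures at is not specified here)
and is labelled accordingly.

## Synthetic data

The generators define the study conditions for every test:

* **Families**: a 48-residue consensus; each site mutates independently
  (default rate 0.15) into one of 3 site-specific alternatives with seeded
  preference weights. This mimics a conserved core with variable sites but
  has no phylogenetic correlation structure between sequences.
* **OGT labels**: `base 50 degC + weights . composition + N(0, 3 degC)`,
  clamped to [0, 100]; default per-residue weights are seeded normals with
  SD 120 degC per unit frequency, giving family spreads of roughly 15 degC.
  The signal is pure amino-acid composition — learnable by the pooled head,
  and exactly linear, which is what makes the least-squares recovery check
  (R^2 > 0.99 on clamp-free labels) a sharp oracle. Real OGT signals are
  not linear in composition; passing these tests shows the training
  machinery works, not that the model would learn real thermophily.
* **Landscapes**: a full `L x 20` additive-effect table (zero at the wild
  type, negatively biased `N(-0.5, 0.5)` draws elsewhere — most random
  mutations are deleterious), a designated set of 15 beneficial-leaning
  singles at distinct positions (`|N(0, 0.6)|` effects), and scalar
  epistasis terms on a sparse 25% of position pairs, 90% of them negative —
  echoing the observed large excess of negative over positive epistasis
  without reproducing any exact ratio. Epistasis per pair is
  residue-independent, a simplification of the general residue-pair form.
  Assay noise (SD 0.05) is seeded per variant, so re-querying a variant
  reproduces the same "measurement". The landscape is additive-plus-pairwise
  by construction; it cannot test discovery of higher-order epistasis.

Fixture sets written by `make_fixtures()` are byte-stable for a given seed;
the coordinate file is an idealized alpha-helix CA trace and is labelled
synthetic in its filename.

## Numerical and procedural choices

* Tokens are 1-based and positions follow printed mutant notation
  (`Q786L`); `;` is the canonical separator, `:` accepted on input.
* Scorecard ordering is descending score with ties broken by the canonical
  variant string, so ranks are reproducible across platforms.
* All randomness flows through explicit integer seeds; child seeds derive
  from an FNV-style hash of (seed, stream label), each below 2^31. Two runs
  with the same inputs and seed produce bit-identical checkpoints,
  scorecards and campaign reports.
* LayerNorm uses eps 1e-5; GELU uses the tanh approximation; parameter
  initialization is N(0, 0.02^2) for weights, zeros for biases, ones for
  norm gains.
* The epoch-mean rounding (half-up, minimum 1) and the closed 6-angstrom
  threshold are fixed conventions where the underlying description says
  only "average" and "outside the range".

## Problem sizes used by the checks

The bundled verification runs use: 120,000 tokens for the noising
fractions; a 2,000-sequence training family with 200 held-out sequences and
10 pretraining seeds at 200 alternating steps for the OGT-transfer check;
500 noise-free sequences for weight recovery; 20 seeded campaign replicates
(15 candidate singles, two stacking rounds after zero-shot) with the ridge
scorer; and a 10-single (1,023-variant) landscape with 100 replicates, 2
rounds and budget 50 for the acquisition comparison. These sizes make the
full suite run in well under an hour on a single core while leaving the
stochastic checks comfortable margins.

## Known limitations

* The desk-scale model shares the architecture, objectives and protocols of
  its 650M-parameter inspiration but none of its scale or data; no
  published benchmark number (fitness-prediction correlations, wet-lab hit
  rates, melting-temperature gains) is reproducible here, and none is
  claimed.
* Zero-shot multisite scores are additive by construction; only the
  supervised path can capture epistasis, and the ridge scorer cannot even
  in principle (indicator features are additive).
* The OGT head's clamp means labels at the boundary are uninformative for
  gradient-based learning; the synthetic label generator is tuned so
  clamping is rare but it is not impossible.
* `simulate_directed_evolution` requires a fully enumerable landscape; it
  is a tool for comparing acquisition strategies, not for open-ended
  design.
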