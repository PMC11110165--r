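---
title: "Closed-loop optimization of alkyne iodination conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optimization of alkyne iodination conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnbo)
```

## The problem

Iodination of terminal alkynes can proceed through two routes: an iodide
salt (KI, NaI, TBAI or NH~4~I) oxidized by chloramine-B, or direct
iodination with *N*-iodosuccinimide (NIS), the latter usually assisted by an
acid catalyst (PTSA or AcOH). Finding conditions that convert the substrate
and actually deliver product means searching simultaneously over the route,
the reagent stoichiometries, eleven candidate solvents, the catalyst and the
temperature — for four different aromatic alkynes at once. Exhaustive
screening is out of the question; `rxnbo` implements the closed loop an
autonomous laboratory uses instead: a constrained discrete search space, a
probabilistic surrogate of the outcome, an acquisition rule that proposes a
small batch of experiments per round, and a per-substrate stopping rule that
contracts the space as substrates are solved.

## The feasible grid

Every parameter is discrete: four categorical parameters (substrate,
solvent, iodine source, catalyst) and four ordinal numeric ones
(chloramine equivalents, iodine-source equivalents, catalyst equivalents,
temperature in 10 °C steps). Feasibility is declarative
(`default_constraints()`): temperatures are capped at the solvent boiling
point; the iodinating agent must be at least stoichiometric; NIS is never
combined with chloramine, nor chloramine with the NIS-route acid catalysts;
an iodide salt requires at least 1 eq. of the oxidant; `catalyst == "none"`
pairs exactly with 0 catalyst equivalents. Under these rules every
(substrate, solvent, temperature) cell admits exactly 51 reagent
combinations: 36 on the chloramine route (3 chloramine levels × 4 salts ×
3 salt levels, uncatalyzed) and 15 on the NIS route (3 NIS levels × 5
catalyst/equivalent pairings).

Two solvent rosters ship with the package.

* `default_grid("campaign")` reproduces the grid of the original autonomous
  iodination campaign: the 10 solvents of its printed parameter table, whose
  boiling points admit 59 feasible solvent–temperature cells, giving
  4 × 51 × 59 = **12 036** candidate conditions. Reaching 59 cells requires
  reading the boiling points strictly (methanol boils at 64.7 °C, so the
  65 °C level is infeasible) and capping the aqueous acetonitrile mixture by
  its water component (100 °C); this is the only boiling-point table
  consistent with the published grid size, and the arithmetic above is why
  an 11-solvent roster cannot reproduce it (11 solvents admit at least 63
  cells under any defensible table).
* `default_grid("default")` adds neat acetonitrile — discussed as a distinct
  solvent in the campaign's analysis — for 65 cells and 13 260 points. This
  is the default roster for new campaigns; the boiling-point table is
  editable data (`solvent_boiling_points`), not code.

## Objectives and merit

Outcomes come from HPLC peak areas via linear calibration curves; the
internal standard (acetophenone, charged at the same molar amount as the
substrate) is the proxy for the substrate concentration at *t* = 0.
Conversion is `1 - C_SM / C_IS`, yield is `C_product / C_IS`. Calibration
intercepts make slightly negative or above-one values possible; raw values
are preserved in every record, and clipping to [0, 1] happens only inside
the scalarization. The optimizer maximizes the **merit**

$$m = 0.9\,\mathrm{clip}(\text{yield}) + 0.1\,\mathrm{clip}(\text{conversion}),$$

which prioritizes yield while still rewarding any reactivity. The stopping
rule is deliberately different from the objective: a substrate is finished
once any observation *strictly surpasses* 80 % conversion, after which all
of its grid points are removed from the candidate set. Setting the
threshold to 1 disables stopping (conversions are clipped to [0, 1] and can
never surpass 1), which is how the pure sample-efficiency benchmark below is
run.

## Initial design

The first round is not model-driven: `greedy_diverse_init()` picks points
that maximize the number of never-yet-seen levels over the four categorical
coverage fields (substrate, solvent, iodine source, catalyst), with seeded
uniform tie-breaks. Novelty deliberately ignores the numeric levels so the
initializer is scale-free. On the default roster the binding field is the
11 solvents: coverage of all 23 categorical levels completes at exactly
pick 11, which is why campaigns default to an 11-experiment initial block.

## Surrogate and acquisition

One Gaussian process models the merit of all substrates jointly — the
substrate one-hot block is simply part of the feature vector — which is what
lets conditions learned on one alkyne transfer to the others. Points are
encoded one-hot per categorical parameter plus standardized numeric columns
(location/scale from the declared levels, so the encoding is a function of
the space alone). The kernel is Matérn-5/2 with one length-scale per
parameter block (automatic relevance per block: 8 length-scales), a fitted
signal variance and a fitted noise variance floored at 10^-6^.
Hyperparameters maximize the log marginal likelihood by L-BFGS-B from a
seeded 5-start multi-start (3 starts plus a warm start on refits inside a
campaign); refitting the same data reproduces the same state.

Batches are chosen by expected improvement,

$$\mathrm{EI}(x) = (\mu - m^\* - \xi)\,\Phi(z) + \sigma\,\phi(z), \qquad
  z = (\mu - m^\* - \xi)/\sigma,$$

with exploration offset ξ = 0.01 on the merit scale, and a **constant-liar**
policy for the second point of each batch of 2: a fantasy observation at the
incumbent best merit is imputed at the first pick, the posterior is
re-conditioned with frozen hyperparameters, and EI is recomputed. The liar
keeps the batch from duplicating one optimum; local penalization would do
the same job but the liar is the simplest policy that is exactly
reproducible. All tie-breaks are seeded from the campaign seed through fixed
counters, which makes an interrupted-and-resumed campaign (see
`save_state()`/`load_state()`) bit-identical to an uninterrupted one.

## The synthetic oracle

Real campaign outcomes depend on wet chemistry, so optimizer behavior is
validated against `landscape_config()`, an additive-effects landscape with
route gates that mirrors the qualitative findings of the iodination study:

* a broad chloramine-route optimum — polar solvents (MeOH, CH~3~CN,
  CH~3~CN/H~2~O), temperatures at or below 65 °C, at least stoichiometric
  reagents, no catalyst — whose best cells reach merit 1.0;
* uncatalyzed NIS reactions with both conversion < 0.3 and yield < 0.2
  (diiodovinyl side product);
* a deceptive NIS + PTSA region (electrophilic hydration of the alkyne):
  conversion above 0.8 with near-zero yield, so an optimizer that chased
  conversion alone would be misled;
* small per-substrate shifts (≤ 0.03) so optima transfer between alkynes, as
  observed in the real campaigns;
* independent Gaussian noise (sd 0.05 fraction units) on conversion and
  yield, with raw values allowed slightly outside [0, 1] to mimic
  calibration offsets.

The landscape is *not* a fit to measured data — it exists to give tests a
known ground truth (`ground_truth()` scans the grid noiselessly and reports
the argmax with lowest-index tie-breaks). Yield responses were set so that
conversion exceeds yield everywhere on the chloramine route (conversion
offset +0.06), main effects (solvent up to +0.18, temperature plateau +0.10
below 45 °C with a quadratic penalty above, salts up to +0.10, equivalents
up to +0.13) dominate the substrate shifts, and roughly 2–3 % of the grid
lies within 5 % of the optimal merit.

On this landscape the closed loop reaches a point within 5 % of the
ground-truth optimum merit in a median of well under 40 oracle calls over
20 seeds (stopping disabled, budget 60), strictly beating seeded random
search; with stopping enabled it converges all four substrates in fewer
experiments than random search needs. Passing these tests shows the loop
works on a landscape with the *shape* of the published chemistry; it says
nothing about predicting real yields for new reactions.

## Replaying recorded campaigns

`replay_campaign()` scans any ordered observation history once and reports,
per substrate, the first experiment surpassing the threshold and the number
of experiments spent before convergence, plus the global stop. Because
experiments run in batches of two, the campaign does not halt at the instant
the last substrate converges: the global stop is the index completing the
batch containing the last first-passage (with an 11-experiment initial
block, a last convergence at experiment 22 stops the campaign at 23 — the
partner experiment was already running). Per-substrate counts are exclusive
of the converging experiment; this is the only convention under which the
published per-substrate counts, first-passages and batch structure admit a
consistent history.

`synthetic_campaign_histories()` provides three such histories. They are
synthetic reconstructions, built in code, that realize the published
summary statistics of the three real campaigns (first-passages 17/19/20/22,
stops 23/23/25, shared 11-point initial block with 4 NIS points, 16 of the
49 pooled observations above 80 % conversion, exactly one of them on the
NIS route); every row that those statistics do not pin down is invented
plausibly. They exist so the replay scanner, the charts and the embeddings
can be exercised on realistic data without redistributing the measured data
set.

## Visualization

`embed_points()` projects the one-hot/standardized encoding to two
dimensions with an exact t-SNE (perplexity 10 by default — appropriate for
~50 points; O(n²) gradient descent, 600 iterations, early exaggeration 12
for the first 100). The substrate block is excluded from the dissimilarity
by default so the map shows reaction *conditions*; only seeded
reproducibility is claimed, never coordinate stability across seeds.
`contour_from_values()` rasterizes any per-point scalar (true or predicted
merit, conversion, yield) onto a 200 × 200 mesh by barycentric linear
interpolation on a Delaunay triangulation inside the convex hull — so
elevations are bounded by the data range and exact at the data points —
with nearest-neighbor fill outside so the map is visually complete.
`surrogate_contour()` sets the elevation to the surrogate's predictive mean
at every embedded point, labelled and unlabelled alike, for side-by-side
truth-versus-belief comparison. Both the full-grid and evaluated-points-only
embedding modes are available (embed whatever point set you pass).

## Numerical choices and limitations

* Grid order is lexicographic in the declared option order; all indices are
  stable, so grids, campaigns and files round-trip exactly.
* The GP linear algebra is Cholesky-based; posterior variances are clamped
  at zero before the square root. Degenerate (all-identical) responses fit
  at the noise floor with a warning instead of failing.
* EI at σ = 0 uses the limit max(0, μ − m* − ξ); ties anywhere (EI,
  novelty, argmax) break by a seeded uniform draw.
* Problem sizes in the test suite: brute-force cross-checks run on
  sub-10 000-point spaces and ≤ 25-point GP instances; the sample-efficiency
  benchmark runs 20 seeds × 60 experiments on the full 13 260-point default
  grid.
* The surrogate treats reagents as opaque labels: no SMILES, descriptors or
  mechanistic features, exactly as in the campaign this package models.
  Continuous optimization over temperature or stoichiometry is out of scope
  by design — the method is grid-restricted.
* The interactive oracle trusts operator-entered conversions and yields
  verbatim; chromatogram peak detection is upstream of this package.
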