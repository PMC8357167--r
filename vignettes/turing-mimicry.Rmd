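---
title: "Pattern mimicry by inverse Turing operation: model and methods"
author: "TuringMimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern mimicry by inverse Turing operation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TuringMimic)
```

## The forward model

Turing patterns arise wherever a short-range activating influence competes
with a longer-range inhibiting one. Instead of integrating
reaction–diffusion equations, this package uses the classic discrete
shortcut: a binary cellular automaton whose update rule reads two
neighborhood counts through a paired disc filter. Cells sit on a toroidal
`rows x cols` lattice (both axes wrap, so every cell has a complete
neighborhood and no boundary artifacts enter). For a focal cell, `N1` is
the number of black (state 1) cells at integer offsets `(dr, dc)` with
`dr^2 + dc^2 <= s^2`, and `N2` the number within the full disc of radius
`2s`. All cells update synchronously:

* black if `N1 > w N2 + b`,
* white if `N1 < w N2 - b`,
* unchanged otherwise,

with `b = 0` by default. The counts are computed as one circular
convolution per disc (via FFT; the torus makes circular convolution exact,
and the integer results are recovered by rounding, removing the ~1e-10
numerical noise). A brute-force per-offset count serves as the oracle in
the unit tests.

### Parameters and their meaning

* `s` (cells, `>= 1`, fractional values allowed): the activation radius.
  It sets the pattern wavelength — black features and their spacing scale
  roughly linearly with `s`. The inhibition radius is fixed at `2s`.
* `w` (dimensionless, strictly in `(0, 1)`): the inhibition weight. It
  selects the pattern class. The pivotal quantity is the filter's cell
  count ratio `S1/S2` (about 0.26 for all radii, e.g. `81/317` at
  `s = 5`): an uncorrelated random field has expected edge ratio
  `N1/N2 ≈ S1/S2` everywhere, so `w` near that ratio yields balanced
  stripes, larger `w` sparse black spots, and smaller `w` black-dominated
  fields.
* `b` (counts, `>= 0`): halfwidth of the unchanged band. `b = 0` is the
  standard rule; moderate values (around 2) blur pattern boundaries by
  freezing near-balance cells, and `b >= S2` freezes the whole grid — a
  property the tests use as a sanity bound.

### Numerical and design choices

* Disc membership is inclusive (`<= s^2`), so radii such as 4.5 or 7.5 are
  meaningful without special-casing; the focal cell (distance 0) counts in
  both discs, and `N2` runs over the full outer disc rather than the
  annulus. Both alternatives (excluded focal cell, annulus-only outer
  region) are available as flags on `discPair()` for sensitivity checks,
  but every default and every reported number uses the inclusive,
  full-disc, focal-included convention.
* The update is synchronous — the rule is a convolution followed by a
  pointwise threshold, which is also what makes the inverse operation
  cheap.
* Comparisons are exact floating-point comparisons of the integer `N1`
  against `w * N2`; with short-decimal `w` a tie means a genuinely rational
  balance (e.g. `N1 = 1`, `N2 = 4`, `w = 0.25`) and takes the unchanged
  branch. An all-white or all-black-free field gives `N1 = N2 = 0`, the
  comparison is `0` vs `0`, and nothing changes: no division ever occurs
  in the forward model.
* `runToSteady()` stops at a fixed point (one further update changes
  nothing; `steps` counts updates applied, so an input that is already
  steady reports 1), at a period-2 cycle (synchronous binary automata
  commonly lock into checkerboard-like oscillations; the status is
  reported as `cycle2`, never conflated with a fixed point), or at
  `maxSteps` (default 50). Typical 40×40 runs terminate in roughly 15–20
  updates; most cells stop changing well before the last few flicker out.

## Phase structure, bistability, and how low-w patterns are generated

Balanced Bernoulli(0.5) starts settle into stripes for `w` near `S1/S2`
and spots above it. Below roughly `w = 0.21` (at `s = 5`) something
different happens: a single synchronous update sends an uncorrelated
random field almost entirely black, because the expected per-cell margin
`N1 - w N2` is positive and several standard deviations wide, and the
uniform black state is then absorbing. Patterned steady states still
*exist* in part of this regime — white spots or stripes on black, with
edge ratios balancing at the lower `w` — but they coexist with the uniform
state and the random-start basin belongs to the uniform state. The model
is bistable, and which branch a run reaches depends on the initial
condition, not only on `(s, w)`.

The package therefore provides two documented routes onto the patterned
branch:

* **Sparse seeding** (`generatePattern(..., initDensity = 0.05)`): with
  few initial black cells, most of the field has `N1 = N2 = 0` and sits in
  the unchanged band while the seeds grow rings and arcs around
  themselves. At `s = 5`, `w = 0.2` this yields white-spotted dark
  patterns for essentially every seed. Seeding a growth process from a
  sparse random scatter is the traditional way of running
  activator–inhibitor automata.
* **Quasi-static continuation** (`annealPattern()`): start from a balanced
  random state at a `w` where patterns form directly (default 0.3), lower
  `w` in small decrements (default 0.01), and relax to a steady state at
  each stage, inheriting it as the next initial condition — the numerical
  analogue of tracing a hysteresis branch in an experiment. The branch
  loses stability a little below `w = 0.2`; by `w = 0.175` only a minority
  of seeds (roughly one in ten to twenty) still carry a pattern, and the
  run otherwise ends honestly all-black. Analyses at such weights score
  the surviving patterned runs and report how many there were.

The default initial density remains 0.5: the defaults describe the
standard operating point, and the low-w routes are explicit choices the
caller makes. The package never fabricates a pattern where the dynamics
refuse one.

## The inverse model

On the boundary between black and white regions the update rule balances:
`N1 ≈ w N2`. Edge cells are defined by 4-connected contact on the torus (a
black cell touching at least one white cell, and vice versa;
8-connectivity is available behind a flag but the minimal contact
definition is the default everywhere). For a candidate radius `s'`:

1. compute the per-edge-cell ratios `N1/N2` (with the default filter every
   edge cell sees at least one black cell within distance 1, so ratios lie
   in `(0, 1]` and no division by zero is possible);
2. pool them into a weight estimate `ŵ` — the unweighted grand mean over
   both edge classes (equal class weighting, `estimateW(..., method =
   "classMeans")`, is available as the obvious alternative; on steady
   patterns the two differ by well under 0.01);
3. score the candidate with `index = alpha/alpha_t + beta/beta_t`, where
   `alpha` counts black edge cells with ratio strictly above `ŵ` and
   `beta` white edge cells strictly below; equality cells count toward
   neither side, mirroring the unchanged band of the forward rule.

At the generating radius the pooled `ŵ` separates the two classes almost
perfectly and the index approaches its maximum of 2; at wrong radii the
ratio clouds overlap and the index drops. `scanRadii()` evaluates a
descending ladder of candidates (default 8 to 2 in steps of 0.5), computes
the edge census once (edges do not depend on `s'`), and returns the argmax
with ties resolved to the larger radius — the first encountered in the
scan. On steady 40×40 patterns generated at `w` between 0.225 and 0.30 and
`s` from 3 to 6 the scan recovers the generating radius in essentially
every run and the weight to within a few thousandths; at `s = 7` or 8 the
pattern wavelength `2s` approaches half the domain, patterns degenerate
into one or two blobs, and recovery becomes occasional rather than
reliable. A uniform grid has no edges and raises a classed
degenerate-input error rather than returning a number.

`mimicPattern()` composes the two halves: scan the observed grid, then
regrow a pattern from a fresh seeded random start at the estimated
`(ŝ, ŵ)`. The product is statistical mimicry — matching black fraction,
wavelength and pattern class, not cell-for-cell agreement. Inputs outside
the automaton's repertoire complete the round trip but reproduce poorly:
a fine checkerboard, whose alternation is faster than any disc filter can
track, comes back as an ordinary stripe/spot pattern agreeing with the
input only near chance level. That failure is informative: it delimits
what a Turing-style mechanism can and cannot imitate.

## Photograph preprocessing

`preprocessImage()` turns a grayscale photograph into a model grid in
three steps: 8-bit read (plain PGM or PNG; color PNG collapses by integer
luma `0.299 R + 0.587 G + 0.114 B`), brightness threshold (`state 1` iff
brightness `< threshold`; dark pixels are the figure, so lowering the
threshold from 100 to 25 strictly shrinks the black mask), and
block-majority downsampling to the target mesh (area-proportional blocks
with rounded boundaries; ties go to black). The binarization thresholds
are deliberately plain — no adaptive or histogram-based thresholding — so
that the mapping from photograph to grid is reproducible to the bit.

## What the synthetic generator does and does not emulate

All test inputs are generated in code: seeded Bernoulli fields, block
checkerboards, stripe gratings, and the automaton's own steady patterns.
These exercise every code path — growth, inhibition, convergence,
degeneracy, estimation, round trips — under exactly known conditions, and
the brute-force oracles make the convolution and census verifiable cell by
cell. What they do not emulate is real imagery: gray-level textures with
gradients, noise, and structure at multiple scales. The preprocessing
chain is therefore tested on synthetic gradients and block images, and the
rock-photo style demonstration (`inst/scripts/demo-figures.R`) is
qualitative. Conclusions about natural scenes should rest on real
photographs, not on these fixtures.

## Problem sizes and runtime

The package's own analyses use the standard 40×40 grid: tens of seeded
runs per operating point, full radius scans of ten candidates, and
continuation ladders of a dozen stages — a few seconds in total on one
CPU, since each update is two FFT convolutions on a 1600-cell grid. The
unit-test oracles run on grids up to 20×20 where the double-loop count is
instant.

## Known limitations

* The forward model is strictly two-state and isotropic: no gray levels,
  no elliptical or oriented filters, no asynchronous schedules.
* Estimation needs edges; uniform fields are rejected, and patterns whose
  minority features are few and small (the deep low-w regime) give noisy
  indices and occasionally prefer a neighboring radius.
* The bistable low-w regime means "the pattern at `(s, w)`" is not unique
  there; results in that regime must state the generation route (sparse
  seeding or continuation), as this package does.
* The spots/stripes label in `patternSummary()` is a coarse isoperimetric
  heuristic (threshold 2 on `P^2 / 4 pi A` of minority components),
  adequate for sorting automaton output, not a general shape classifier.
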