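---
title: "Methods: analytical DNA damage yields for light ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytical DNA damage yields for light ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondamage)
```

## The model and its assumptions

Track-structure Monte Carlo simulations score the initial DNA damage
produced in a cell nucleus by individual ion tracks: strand breakage
(SB), single-strand breaks (SSB), double-strand breaks (DSB, opposite
strand breaks within 10 bp), DSB clusters (two or more DSB within
25 bp) and DSB sites (an isolated DSB or one whole cluster). This
package represents such simulation results for fully stripped ions from
hydrogen to neon analytically, with yields expressed per Gy and per Gbp
and the LET (keV/µm) as the only radiation-quality variable.

Two forms are used, chosen by damage class:

* **Dip form** (SB, SSB): $Y(L) = p_1 - (p_2 L)^{p_3} -
  p_4/(1+\ln^2(L/p_5))$. A power-law decrease from the low-LET plateau
  $p_1$, minus a Gaussian bell on the log-LET scale: the simulations
  predict a mild (3–7 %) dip of SB/SSB yields at LET of roughly
  5–20 keV/µm. The logarithm is natural. At $L = p_5$ the dip term
  equals $p_4$ exactly; at $L = p_5 e^{\pm 1}$ it is $p_4/2$.
* **Overkill form** (DSB, DSB clusters, DSB sites):
  $Y(L) = (p_1 + (p_2 L)^{p_3})/(1 + (p_4 L)^{p_5})$. A power-law
  increase modulated by a logistic denominator that reproduces the
  declining effectiveness per unit dose above ~100 keV/µm ("overkill"):
  densely ionizing tracks deposit more damage per site than needed, so
  per-dose effectiveness saturates and falls.

Key structural facts the package enforces:

* $p_1$ (the low-LET yield) is **universal across ions** within one
  (damage class, channel) pair. The database validator flags any
  violation.
* Each model is fitted separately for the **total**, purely **direct**
  (energy deposition to the sugar-phosphate backbone) and purely
  **indirect** (hydroxyl-radical attack) channels. Totals are *not* the
  sum of the two channels: a site broken by both mechanisms counts once
  in the total but in both separate channels, and DSBs frequently
  combine a direct with an indirect break ("hybrid").
* Omitted terms are stored as paired `NA`s, never as zeros — "no
  indication for this term in the data" is distinct from "term with
  value 0". This includes the hydrogen and helium direct-SB fits, where
  the *power-law* term (not the dip) is absent: those yields are
  constant apart from the dip.

Both forms tend to $p_1$ as $L \to 0$. `eval_yield()` accepts
`let = 0` and returns $p_1$ (the dip form is singular at 0 and is never
evaluated there directly).

## Parameters, units, defaults

| quantity | unit | notes |
|---|---|---|
| LET | keV/µm | sole radiation-quality descriptor |
| yield | Gy⁻¹ Gbp⁻¹ | per dose, per gigabasepair |
| $p_1$ | Gy⁻¹ Gbp⁻¹ | universal low-LET yield |
| $p_2$ | µm/keV | inverse-LET scale of the power law |
| $p_3$ | — | power |
| $p_4$ | Gy⁻¹ Gbp⁻¹ (dip) / µm/keV (overkill) | dip depth / inverse overkill scale |
| $p_5$ | keV/µm (dip) / — (overkill) | dip-centre LET / overkill power |
| genome size | Gbp | default 6.6 (human G0/G1 nucleus model) |
| DSB distance | bp | default 10, inclusive |
| cluster distance | bp | default 25, inclusive, centre-to-centre |

The per-cell converter warns above 100 Gy: damage induction is linear
in dose until independent tracks start to overlap in space and time,
i.e. at least up to doses of order 100–1000 Gy; 100 Gy is the
conservative edge of that range and the same ceiling applies to
mixed-field totals.

## Validity windows

The fits must not be extrapolated outside the LET range spanned by the
underlying simulated points, but per-ion ranges are not published. The
package therefore uses documented approximations (`validity_window()`):
`let_min` 0.2 keV/µm for every ion, `let_max` rising with atomic number
from 100 keV/µm (H) to 600 keV/µm (Ne). Outside the window evaluation
still returns the raw model value and sets an `in_validity_range = FALSE`
flag — a warning, never an error, because the windows themselves are
approximate. Far outside the fitted range the dip form can go negative;
the default policy returns the raw value (never silently altering the
model), with `clamp = TRUE` as an explicit opt-in truncation at 0.
The models deliberately do not represent the "hooks" below ~1 MeV/u,
where proximal and distal Bragg-peak points share an LET value but
differ in track structure; the corresponding low-energy points were
excluded from the original fits, and callers refitting data are
expected to exclude them likewise (the fitter takes whatever points it
is given).

## RBE and mixed fields

Because damage induction is linear in dose, RBE (defined as a ratio of
doses at equal effect) reduces to a ratio of yields at equal dose. The
default reference is the low-LET limit of the hydrogen model of the
same damage class and channel ($p_1$); a hydrogen yield at a stated LET
is available as an alternative policy. For a mixed field
$\{(\mathrm{ion}_i, L_i, d_i)\}$ the per-dose yield is the dose-weighted
average $\sum_i d_i Y_i / \sum_i d_i$ — the unique combination under
which expected per-cell counts add across components. It follows that
the mixed yield is a convex combination of component yields and is
invariant under component reordering, splitting and overall dose
rescaling; these invariances are tested to 1e-12. Inter-track
combination effects (breaks from different primaries combining into one
DSB) are outside the model, consistent with per-track scoring.

## The fitting protocol

The shipped parameters came from a two-stage protocol: the universal
$p_1$ adjusted manually per damage class and channel, the remaining
parameters fitted per ion by nonlinear regression. The package
reproduces this with documented surrogates, since loss, weighting,
starting values and convergence criteria were not published:

* **Loss**: summed squared *relative* residuals,
  $\sum_i ((f(L_i)-y_i)/y_i)^2$. Chosen because the only published
  fit-quality metric is the RMS relative deviation and yields span 3+
  orders of magnitude across classes. Optional `1/cv²` weighting exists
  but is off by default (no indication of weighted fitting).
* **Optimizer**: L-BFGS-B in log-parameter space under form-specific
  positivity bounds, from 16 seeded log-uniform multistarts (first
  start at the bounds midpoint), tie-break lowest loss then lowest
  $p_4$; the best start is polished with Nelder–Mead at
  `reltol = 1e-14`. The polish also provides the convergence flag:
  L-BFGS-B line searches can abort (code 52) on numerically flat optima
  even when the fit is excellent. Non-convergence is reported in the
  result, not thrown.
* **$p_1$ adjustment** (`adjust_p1_universal()`): a scan over ±20 %
  around the plateau of the low-LET data at 0.1 %-of-range resolution
  (401 points), refitting the per-ion free parameters at each candidate
  and minimizing the pooled RMS relative deviation. This is an explicit
  automation of the original manual choice, not a reconstruction. After
  the first candidate, refits are warm-started from the previous
  optimum to keep the scan affordable; tests use coarser user-supplied
  grids, which the interface allows.
* **Term selection** (`select_terms()`): both nested variants are
  fitted; the optional $p_4/p_5$ term is kept only when it improves the
  pooled RMS relative deviation by at least 10 % (relative), automating
  the published rule of omitting terms without support in the data.
  `threshold = 0` always keeps the term.

## The synthetic yield generator

`simulate_yield_data()` emulates the statistical scatter of the
simulated yields: multiplicative Gaussian noise
$y = f(L)(1 + cv\,z)$, truncated to positive yields, at the reported
uncertainty levels — coefficients of variation within 1.5 % for total
yields of most classes (2.7 % for separate channels) and up to 10 % for
the rare DSB clusters. Default grids in the tests mirror the ~10–11
energy-derived LET points per ion. What the generator does *not*
emulate: the hooks below 1 MeV/u, LET-dependent (heteroscedastic
beyond the per-point cv) uncertainty, and correlations between points
from shared simulation runs. A green parameter-recovery test therefore
establishes that the fitting protocol inverts the model under honest
independent noise of the stated magnitude — not that it would
reproduce every feature of a real simulation campaign.

## Break sampling and classification

The microscopic rules are implemented exactly: direct breakage
probability rises linearly from 0 at 5 eV to 1 at 37.5 eV deposited to
a single sugar-phosphate group; hydroxyl attacks break with probability
0.65; nothing else breaks strands; base damage is ignored.

The classifier makes three documented choices where the source is
silent:

* "within 10 bp" and "within 25 bp" are **inclusive** (≤), matching
  common usage in the track-structure literature; coordinates are
  0-based integers on a single linear stretch.
* **Pairing**: greedy left-to-right — repeatedly take the leftmost
  unconsumed break, pair it with the nearest unconsumed opposite-strand
  break within 10 bp (ties to the lower position), each break consumed
  at most once. Because earlier breaks are always resolved first, every
  candidate partner lies to the right, and on this proximity structure
  the greedy matching attains maximum cardinality; the test suite
  verifies agreement with an exhaustive-enumeration oracle on 1000
  random dense instances (every instance's full tally must be
  achievable by some maximum-cardinality pairing — distinct maximum
  pairings can differ in cluster structure, and the original pairing
  rule in dense regions is not published).
* **Clusters**: single-linkage chaining of DSB midpoints (floor of the
  two break positions' mean) at ≤ 25 bp centre-to-centre, so a chain of
  DSBs each within 25 bp of the next is one cluster.

A break recorded with both mechanisms at one (position, strand) counts
once in totals, in both direct and indirect SB/SSB sub-tallies, and
renders any DSB containing it hybrid (a DSB is pure-direct or
pure-indirect only if both breaks are single-mechanism). Conservation
(`n_sb_total = n_ssb + 2 n_dsb`, sites = isolated + clusters) holds by
construction and is asserted on every random instance.

`generate_break_pattern()` produces track-like test patterns: Poisson
breaks per track around uniform cluster centres with normal
displacements, fair-coin strands, direct fraction 0.38 (the low-LET
direct share of strand breakage, 64/170). It is a classifier fixture,
not a track-structure simulator: no radial dose profile, no chemistry,
no chromatin geometry.

## Numerical choices

* `peak_yield()`: 1000-point log-spaced grid (endpoints pinned to the
  window) followed by bounded scalar maximization in the bracketing
  interval; ties break to the lowest LET; window-edge maxima set an
  `at_boundary` flag and are not refined past the edge.
* Database serialization uses shortest round-trip float strings and a
  fixed row/column order, so saving is bit-stable and save/load is the
  identity; absent terms are the literal token `NA` in CSV and `null`
  in JSON.
* All randomness (multistart, generators, CLI) flows through explicit
  integer seeds; the RNG state of the caller is saved and restored.

## Known limitations

* Per-ion LET validity windows are approximations; the true fitted
  ranges are not published.
* A handful of database cells were transcribed from a flattened text
  rendering of the parameter tables whose digit grouping is ambiguous;
  a uniform 4-significant-figure convention was applied and verified to
  reproduce the flattened text exactly, but the typeset source remains
  the authority.
* The greedy pairing is a documented choice; in dense regions other
  maximum pairings with different cluster splits exist.
* No energy→LET conversion, no sub-1-MeV/u hooks, no repair,
  aberrations, fragment spectra or survival modelling.
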