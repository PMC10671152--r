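---
title: "Mechanistic gradient retention modeling over a tG–T–tC design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic gradient retention modeling over a tG-T-tC design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lssmodr)
library(dplyr)
```

## The problem

In reversed-phase HPLC method development the goal is to find gradient
conditions — gradient time, column temperature, mobile-phase composition —
under which every analyte of interest is baseline-resolved from its
neighbours, and to know how robust that separation is to small deviations.
Running every candidate method is expensive; mechanistic retention modeling
replaces most of that work with a small calibration design and a
physics-based extrapolation. `lssmodr` implements that workflow for the
three-factor design used in modern analytical quality-by-design (AQbD)
practice: two gradient times (tG), two column temperatures (T), and three
ternary blends of the organic modifier (tC, e.g. acetonitrile/methanol),
giving `3 × 2 × 2 = 12` calibration ("corner") runs.

The motivating application is impurity profiling of ezetimibe and eight of
its related substances on chiral stationary phases operated in
reversed-phase mode; the package ships the published
predicted-versus-experimental validation tables of that study as fixtures
and reproduces their summary statistics exactly.

## The retention model

### Linear solvent strength

For one analyte at fixed temperature and ternary composition, retention
follows the linear solvent strength (LSS) law

$$\log_{10} k(\varphi) = \log_{10} k_w - S\,\varphi,$$

where $k$ is the retention factor, $\varphi$ the organic fraction
(0–1), $\log_{10} k_w$ the extrapolated retention in pure weak solvent and
$S$ the solvent-strength slope. Under a gradient the composition at the
column inlet is the programmed profile delayed by the dwell time
$t_D = V_D/F$; the elution time $t_e$ solves the ideal migration equation

$$\int_0^{t_e} \frac{dt}{t_0\,k(\varphi_{in}(t))} = 1,
\qquad t_R = t_0 + t_e .$$

Because gradient programs are piecewise linear, the integral has a closed
form on every segment, and `predict_retention_time()` walks the segments
(dwell hold, ramp pieces, terminal hold) accumulating migrated fraction
until it reaches 1. No iterative root finding is needed; the solution is
exact to machine precision, which the test suite verifies against the
textbook single-ramp dwell equation (`lss_closed_form_rt()`) over a
parameter sweep, and against direct numerical quadrature of the migration
integral.

Assumptions worth stating: the solute experiences the dwell-delayed
*programmed* composition (intra-column gradient traversal is neglected, the
same idealization underlying the published LSS closed forms); pump mixing
dynamics, pressure and viscosity effects are out of scope; the log-linear
law is taken as exact between the calibrated composition range.

### Peak widths and resolution

Widths use the standard plate-count model at the elution-time retention
factor $k_e$:

$$w_{4\sigma} = \frac{4\,t_0\,(1 + k_e)}{\sqrt{N}},$$

with $N$ defaulting to a reduced plate height of 2.5
($N = L / 2.5 d_p$; 10000 for a 250 mm, 10 µm column). Gradient band
compression is available as a factor but disabled by default — whether the
reference software applies it is not documented, and with matched widths on
both sides of a pair it largely cancels in resolution. Resolution uses the
USP-equivalent half-width form $R_s = 2\,\Delta t_R / (w_1 + w_2)$, and the
critical resolution $R_{s,crit}$ is the minimum over adjacent pairs (ties
resolved to the earlier-eluting pair).

Because the plate count and the dwell volume of the original instrument are
not published, *absolute* retention-time or resolution agreement with the
study's tables is not attainable and is not claimed; what the package
reproduces exactly is the study's validation arithmetic, and what it
verifies by property-based testing is the internal consistency of the
modeling chain.

## Calibration over the cube

Each (T, tC) node contributes two corner runs differing only in tG; the
two retention times determine $(\log_{10} k_w, S)$ at that node.
`fit_node_coefficients()` inverts the *full* forward model (dwell and hold
included) with a damped Newton iteration, seeded by the classical two-run
approximation and backed by a deterministic multi-start grid; residual
ties prefer the smaller $S$. A fit is accepted only when both retention
times are reproduced within $10^{-4}$ min.

Between nodes, both coefficients are interpolated

- **linearly in $1/T$ (kelvin)** — the van't Hoff form, the natural
  two-point law for retention thermodynamics; with only two calibrated
  temperatures nothing richer is identifiable, and $S$ is treated the same
  way rather than assumed constant;
- **quadratically in the ternary fraction** — a Lagrange polynomial through
  the three tC nodes, the minimal law that honors all three levels.

Interpolation reproduces the node coefficients exactly (bit-for-bit, by
construction of the Lagrange basis); an interpolated $S$ that dips below 0
between nodes is clipped with a warning. Temperature extrapolation is
allowed up to 10 °C beyond the calibrated range, with a warning; ternary
queries outside [0, 1] are errors. Flow changes rescale $t_0$ and $t_D$ by
the flow ratio and leave coefficients and plate count untouched — a
documented simplification that mirrors how calibration at 0.5 mL/min is
used to predict methods run at 0.7 mL/min.

## Design-space mapping, MODR and robustness

`compute_resolution_map()` evaluates the virtual chromatogram on a
tG × T × tC grid (defaults 21 × 31 × 11 across the calibrated cube; the
examples and tests use coarser grids, e.g. 5 × 4 × 3, which keep the
demonstrations fast without changing any conclusion — every cell is
independently verified against brute-force recomputation). Elution-order
changes across the cube are handled by re-sorting peaks per cell.
`extract_modr()` filters cells with $R_{s,crit} \ge 1.5$ (baseline
separation); an empty region is a valid and informative outcome — the
study's own all-nine-peaks model has one. `robustness_scan()` evaluates a
full factorial of ±tolerance deviations (2 or 3 levels per varied factor)
around a setpoint and reports nominal, worst and best critical resolution.
Excluding analytes from a simulation never changes the retention of the
remaining peaks; only the pairing changes.

## Peak tracking

Corner-run chromatograms are identified by a mixture-spiking scheme: each
condition is injected once per mixture (a full mixture plus partial
mixtures), so each analyte carries a presence/absence signature across
injections. `assign_peaks()` resolves identities in three stages: signature
matching (peaks matched between injections within 0.1 min — replicate
injections of the same condition, hence a tight window), then within-group
correspondence of observed areas to the nominal spiked concentrations, then
elution order. When a signature group lost a member (e.g. a peak collided
with a neighbour and acquired a corrupted signature), the remaining peaks
are matched to the best-fitting candidate *subset*, accepted only when each
area sits within a plausible response band (×1.6) of its matched
concentration. Two candidates with areas within 10% and equal
concentrations are flagged ambiguous rather than guessed — co-eluting peaks
are inherently ambiguous for this evidence model, and the flags make that
visible instead of hiding it. The proprietary "composite chromatogram"
mechanism of the reference software is not reproduced; this
evidence-combination scheme is the package's own design with equivalent
intent.

Practical spiking advice falls out of the area-matching stage: levels
should be geometrically spaced (the shipped pipeline uses ratio 1.6) so
that rank matching tolerates realistic response-factor differences between
analytes.

## The synthetic-data generator

`sample_truth()` draws ground-truth analyte panels directly at the node
level, in the same law family the calibration assumes: base
$\log_{10} k_w \sim U[1.5, 4.5]$ and $S \sim U[3, 8]$; a van't Hoff slope
equivalent to a 1–3% decrease in $k$ per °C; ternary perturbations
quadratic in $x$ with amplitude ≤ 0.5 ($\log_{10} k_w$) and ≤ 1.5 ($S$);
per-analyte response factors in [0.8, 1.25]. Panels whose corner runs
would elute inside the dwell window or drag past 1.5× the run length are
resampled (bounded attempts), which keeps the simulated retention spans in
the range the calibration design anticipates. A 9-analyte panel carries
the ezetimibe study's compound roster and nominal concentrations.

Noise is additive Gaussian on retention times (default SD 0.02 min between
corner conditions; replicate injections of the *same* condition for
tracking use 0.01 min, since back-to-back injections scatter less than
runs separated by full re-equilibration) and multiplicative Gaussian on
areas (default CV 3%; the tracking stress tests use 5%). The default
retention-time noise was chosen so that fitted-parameter scatter produces
prediction errors of the order reported in gradient-method validation
(a few percent). Everything is deterministic under a fixed seed.

What the generator does **not** emulate: curved $\log k$–$\varphi$
behavior, secondary interactions beyond the LSS law (the very effect the
study invokes to explain its larger errors on the polysaccharide column),
detector drift, carryover, or peak-shape asymmetry. Passing the synthetic
round-trip tests therefore demonstrates the correctness and
self-consistency of the implementation, not that real chiral-phase data
obey the LSS law — the study's own validation tables are the evidence on
that point, and the package reproduces their error statistics as printed.

## Numerical choices

- Segment integrals and their inversion are closed-form; the only iteration
  in the package is the 2-D Newton fit (convergence threshold $10^{-9}$ min
  internally, acceptance at $10^{-4}$ min, bounds
  $\log_{10} k_w \in [-2, 12]$, $S \in [0.1, 100]$).
- Degenerate inputs are handled explicitly: $S = 0$ or flat segments take
  the isocratic branch; unretained solutes ($t_R \le t_0$) are an
  unidentifiability error at fit time; fewer than two peaks yield "no
  critical pair", not $R_s = 0$.
- Reported tables round half-up to 2 decimals at the reporting layer only
  (`glance()`, CSV export); all internal values keep full precision. The
  half-up convention (rather than R's round-half-even) matches how the
  published tables are formatted.
- Percent inputs (organic %, ternary %) are normalized to fractions at the
  file boundary; everything internal is a fraction.

## Problem sizes used in tests and the acceptance script

Property tests run the solver sweep over ~300 parameter combinations, the
noisy-recovery Monte Carlo over 200 replicates of a 9-analyte, 12-run
design (10,800 node fits), end-to-end prediction over 50 setpoints × 9
analytes including a flow change and a two-step gradient, map verification
on a 5 × 4 × 3 grid, and tracking over 100 seeded replicates of an
8-analyte three-mixture scheme. These sizes were chosen to exercise every
code path at desk-scale cost while keeping Monte Carlo margins wide.

## Known limitations

- Absolute predictions require the user's own $t_0$, dwell volume and plate
  count; defaults (porosity 0.68, dwell 1.0 mL, $h = 2.5$) are typical but
  not universal.
- Only the 2 × 2 × 3 design family is supported for calibration — more
  levels are rejected rather than silently generalized.
- The ternary quadratic can oscillate if the three tC levels are very
  unevenly spaced; the package warns when clipping $S$.
- Peak tracking assumes comparable detector response within a signature
  group; wildly different absorptivities call for per-analyte response
  factors in the scheme, or manual curation of the flagged peaks.
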