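---
title: "Modelling C-controlled restriction–modification dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling C-controlled restriction–modification dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmdyn)
```

## The circuit and its model

Type II restriction–modification systems under C-protein control transcribe
C together with the restriction endonuclease R from one promoter (P.CR),
while the methyltransferase M has its own promoter (P.M). C dimerises and
binds two operator sites at P.CR: occupancy of the distal site activates,
occupancy of the proximal site — and the cooperatively formed
dimer-of-dimers spanning both — represses. The same protein therefore closes
a positive and a negative feedback loop on its own operon, and (directly or
indirectly) represses M.

`rmdyn` models P.CR with a statistical-mechanical partition function over
the three bound configurations. Two modelling commitments matter:

* **Full monomer–dimer equilibrium.** The dimerisation constant is of the
  same order as the protein concentrations involved, so neither the
  "all monomer" nor the "all dimer" simplification is defensible. The free
  monomer is the positive root of `c_free + 2 c_free^2 / alpha = c_total`,
  evaluated in the cancellation-safe form
  `2 c_total / (1 + sqrt(1 + 8 c_total / alpha))` (`free_monomer()`). The
  square root is what makes the later analysis non-polynomial.
* **Lumped expression.** Transcription activity maps directly to protein
  production; no mRNA intermediate is modelled. R is co-transcribed with C,
  so total R is proportional to total C (`r_total()`, constant `k_rc`,
  default 1 in arbitrary units since nothing in the deterministic analysis
  fixes it).

After rescaling concentrations by `K_d = sqrt(kd1 * kd2)` and time by the
maximal production rate, five dimensionless parameters remain:

| parameter | meaning | default / preset values |
|---|---|---|
| `p` | distal-vs-proximal binding-strength ratio | 25 (Esp1396I), 20 (AhdI), 5 (EcoRV) |
| `omega` | distal–proximal binding cooperativity | 130, 3000, 1 |
| `alpha` | dimer-formation parameter | 16.9, 5√2, 4.2 |
| `s` | promoter leakage (basal / maximal rate) | 0.2 (Esp1396I), 0.0043 (AhdI), unknown (EcoRV) |
| `r` | overall expression strength `n·phi_m/(lambda·K_d)` | free bifurcation coordinate |

The first three are *internal* — fixed per system by binding measurements
(`infer_internal_params()` maps dissociation constants to them; presets
store the published end values, with symbolic constants such as 5√2 kept as
exact double-precision expressions rather than rounded literals). `s` and
`r` are *external*: `r` rises with plasmid copy number and falls with
growth rate, making it the natural bifurcation parameter, and `s` depends
on global transcription factors, so it is inferred from data where
possible (`fit_s_from_activity()`, `fit_s_from_dynamics()`,
`fit_steady_state_scales()`).

## Steady states, the fold boundary, and the cusp

Steady states are zeros of `s + f(c_free(c_total)) - c_total/r`. Because
activity is bounded by `s + 1`, all roots lie in `[0, r(s+1)]`, so
`steady_states()` brackets sign changes on 2,000 log-spaced points and
refines each bracket by bisection to 1e-12, merging roots closer than 1e-8
relative; stability is the sign of the analytic derivative (the regulated
term's derivative simplifies to `2c(1 - (omega/p)c^4)/den^2`, chained
through `dc_free/dc_total = 1/sqrt(1 + 8 c_total/alpha)`). Root counts
other than 1 or 3 can occur exactly at a fold and are flagged, not raised.

At a saddle-node both the right-hand side and its `c_total`-derivative
vanish. Instead of scanning an `(r, s)` grid, both conditions are solved in
closed form with total C as the curve parameter:
`r = 1/(f'(c_free) · dc_free/dc_total)`, then `s = c_total/r - f(c_free)`.
The admissible range is `c_free < (p/omega)^(1/4)` — beyond it `f' < 0` and
no positive-`r` fold exists. `r` diverges at both ends of the range, so the
parameter grid is log-spaced in `c_free`, which resolves the cusp — the
interior maximum of `s` along the curve and the tip of the bistable wedge.
The unit tests verify each boundary point against the two defining
conditions and against brute-force root counting over an `(r, s)` grid, for
the presets and for randomly drawn internal parameters.

Bifurcation diagrams fix `s` and sweep `r`; the fold interval at that `s`
comes from intersecting the two boundary branches (1-D monotone
interpolation along each branch). The cusp surface repeats this per `s` to
assemble the lower-stable / unstable / upper-stable sheets.
`bistable_region_area()` integrates the width between the fold curves over
leakage, clipped to a plotting window, which is how the package compares
wedge sizes across systems and quantifies that raising `omega` (stronger
repressive cooperativity, stronger negative feedback) shrinks the wedge
while raising `p` (stronger activation) expands it.

## M architectures and the M-to-R ratio

Three repression architectures are implemented on top of the common P.CR
model. Esp1396I: C-dimer repression,
`m_total = phi·r / (1 + gamma·c_free^2)` with `gamma = 5.1`. AhdI: negative
autoregulation by the M dimer, solved from
`m_total·(1 + m_free^2) = phi·r` with its own monomer–dimer map at
`alpha_m = 2√5`; the residual is strictly increasing, so bisection on
`[0, phi·r]` to 1e-12 is both robust and provably convergent — preferred
over Newton because of the square root. EcoRV: promoter overlap — M fires
only when RNA polymerase is absent from P.CR, giving `phi·r` times the
repressed-plus-empty weight fraction. `phi` is only measurable for AhdI
(0.2); for the other two it defaults to 1 and the ratio axis is in
arbitrary units.

One subtlety the implementation surfaced: the often-quoted trend "M-to-R
falls as expression strength rises" is a property of the *regulated
regime*, not of the curves globally. Once C saturates its promoter the
activity returns to the leakage `s`, total C grows like `r·s`, and the
ratio creeps back up toward `phi/s` (for EcoRV at `s = 0.2` the ratio falls
about sixfold up to `r ≈ 3.7` and then rises slowly toward 5; the AhdI
high branch has a shallow minimum near `r ≈ 10`). The tests therefore
assert the decline where it is a theorem of the model: pointwise along the
establishment (low or monostable) branch over the fold-scale window,
pointwise along the high branch within the fold interval, and downward
across the hysteresis jump. On bistable branches the ratio is always
reported per branch, never averaged.

## Synthetic calibration data and the leakage fits

`rm_fixture()` generates the three dataset kinds used to validate the
inference code, applying multiplicative unit-mean log-normal noise whose
coefficient of variation is the requested noise level — the natural model
for reporter and gel-quantification data, where error scales with signal.
Study conditions were fixed once:

* **activity**: 20 points, total C log-spaced on `[1e-3, 10]` (spanning
  basal, activated and repressed regimes), AhdI parameters, true
  `s = 0.0043`;
* **timeseries**: 100 time points on `(0.6, 30]` rescaled time at `r = 10`,
  Esp1396I parameters, true `s = 0.21`. The strength was placed where the
  activation knee shapes the establishment curve: a profiled-information
  analysis showed that at large `r` the trajectory is leakage-dominated and
  `s` trades off almost exactly against the free amplitude and time scale,
  whereas near `r ≈ 10` a 100-point series at 10% noise determines `log s`
  to about ±0.11;
* **steady_vs_n**: six copy numbers on `[5, 60]`, Esp1396I preset, true
  `s = 0.2` — the monostable regime.

The activity fit is linear in `(scale, scale·s)` and solved in closed form,
with a profiled bounded search as fallback when the unconstrained optimum
leaves `s ∈ [0, 1]` (leakage cannot exceed the maximal rate). The dynamics
fit minimises least squares *on the log scale* — the exact maximum
likelihood under the generator's noise — over the full sampled window;
restricting to late times only would discard exactly the points that
identify `s`. For each candidate `s` one trajectory is integrated (lsoda,
rtol 1e-8, atol 1e-10), spline-interpolated, and the amplitude and time
scale are profiled out; `s` itself is located by a 25-point log-grid scan
refined by golden-section, which handles the fold-induced non-convexity
without stochastic multi-starts. The steady-state fit grids `s` on
`[0.001, 1]`, optimises the copy-number scale per grid point with the two
level scales profiled in closed form, and reports whether the best fit is
mono- or bistable; the stable branch used is the establishment path (the
lowest stable state), which is where a system arriving in a naive host
settles.

All fits are unit-invariant: rescaling the data rescales only the
amplitude estimates.

## Stochastic single-cell model

The stochastic module works in absolute molecule counts (only time is
rescaled, one division per unit) because partition noise depends on
absolute numbers. Between divisions the only propensity-changing event is a
C birth, so the kernel simulates C births event-by-event and draws R and M
births in each inter-event interval as Poisson counts — an exact sample of
the jump process, implemented in C++ for speed. R production defaults to an
independent Poisson channel at `k_rc` times the C rate (the simplest
reading of co-transcriptional proportionality); a `cotranscribe` switch
produces R in the same events as C for sensitivity analysis. At division,
plasmids duplicate and every species partitions binomially with probability
1/2; one daughter is followed. There are no degradation channels — dilution
happens only through division, consistent with stable proteins.

Count-unit parameters were chosen once to emulate the experimentally
reported scales: dimerisation constant 1,200 molecules per cell (≈2 µM in
a bacterial volume), the operator and M-promoter constants derived from it
through `alpha` and `gamma`, plasmid number 30, and per-plasmid rates sized
so the effective expression strength is ≈30 and equilibrium R and M counts
are in the low thousands with C in the hundreds. The constitutive baseline
gets constant per-plasmid rates equal to the regulated model's per-cycle
production at its deterministic periodic fixed point (cycle map: integrate
one unit of production, halve, iterate to convergence), which matches the
equilibrium levels by construction — the condition under which noise
comparisons are meaningful. `equilibrium_check()` compares ensemble medians
against that deterministic cycle trajectory and a stationarity criterion.

Summary statistics follow robust conventions: because the M/R distribution
is strongly non-Gaussian under regulation, the spread is reported both as
sd/mean and as IQR/median (quartiles by linear interpolation of order
statistics, R type 7 — the convention matters for small retained samples).
Post-segregational runs start from a regulated equilibrium ensemble with
all plasmids removed; trajectories whose R count reaches zero are excluded
from ratio statistics (and counted), and runs stop at seven divisions while
enough non-zero-R cells remain.

## What the synthetic conditions do and do not show

The generators and simulations emulate the *structure* of the real
experiments — dose–response activity curves, establishment time courses,
steady levels across copy-number variants, single-cell count statistics —
under known ground truth, which is what makes recovery and trend tests
meaningful. They do not reproduce the actual published measurements (which
are not reprinted in numerical form in the source literature), nor real
extrinsic noise structure, cell-volume growth within the cycle, replication
timing of plasmids, or transcriptional bursting beyond the lumped
production channel. Passing tests therefore certify the implementation and
the model's internal predictions, not agreement with any particular
laboratory dataset.

## Problem sizes and numerical defaults

Defaults used by the test-suite and acceptance computations: boundary
curves on 2,000 log-spaced points; root bracketing on 2,000 points
(reduced to 500–800 inside fitting loops, where roots are well separated);
brute-force oracle grids of 25–30 points per axis; stochastic ensembles of
300–800 cells in tests (2,000 is the production default); 25–50 replicate
fits in recovery checks. ODE work uses lsoda at rtol 1e-8 / atol 1e-10;
bisection tolerances are 1e-12 absolute.

## Known limitations

* The stochastic module implements the Esp1396I M architecture only.
* Convergent/overlapping-promoter interference (as in PvuII) and explicit
  post-segregational killing decisions (genome cutting, death) are out of
  scope; the package stops at M/R fluctuation statistics.
* `phi` and `k_rc` are arbitrary-unit constants except where measurements
  pin them (AhdI's `phi = 0.2`), so ratio axes are comparative, not
  absolute.
* EcoRV's leakage is experimentally unknown; both regimes are exposed but
  neither is privileged.
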