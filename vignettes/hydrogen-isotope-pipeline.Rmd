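---
title: "Modeling hydrogen isotope fractionation in plant carbohydrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hydrogen isotope fractionation in plant carbohydrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrofrac)
```

## The problem

The hydrogen isotope composition (δ²H, ‰ VSMOW) of plant carbohydrates and
leaf waxes records both the water a plant used and the biochemistry it ran.
Reading that record takes three linked computations, which this package
implements as one pipeline:

1. **Equilibration reduction.** Carbohydrates carry hydroxyl hydrogen that
   exchanges freely with ambient water, so a raw δ²H measurement mixes the
   biosynthetic signal with whatever water the sample last saw. The dual
   water-vapor equilibration method measures each sample twice, after
   equilibration with two isotopically distinct vapors, and solves for the
   exchangeable fraction and the nonexchangeable (carbon-bound) δ²H.
2. **Apparent fractionation factors.** The autotrophic factor
   ε~a~ = δ²H~compound~ − δ²H~leaf water~ bundles every fractionation between
   leaf water and a leaf compound; the heterotrophic factor
   ε~h~ = δ²H~A~ − δ²H~B~ compares two carbohydrates within or between
   tissues (cellulose–sugars, cellulose–starch, starch–sugars, each within
   leaves, within roots, or root versus leaf).
3. **The two-pool cellulose model.** Cellulose δ²H is modeled as
   δ²H~cell~ = (1−f)(δ²H~leaf water~ + ε~a~\*) + f(δ²H~source water~ + ε~h~\*),
   with literature constants ε~a~\* = −171‰, ε~h~\* = +158‰ and f = 0.36,
   where f is the fraction of cellulose hydrogen that re-exchanged with
   source water during synthesis. The package runs the model forward,
   computes observed-minus-modeled residuals, and inverts it one parameter
   at a time for f or ε~h~\*.

A hydrogen-atom budget module and a synthetic-data generator complete the
pipeline so that every stage is testable end to end without any external
dataset.

## Equilibration reduction

With equilibrated measurements δ~e1~, δ~e2~ against vapors δ~w1~, δ~w2~ and
the equilibrium fractionation α~e−w~, the exchangeable fraction is

x~e~ = (δ~e1~ − δ~e2~) / (α~e−w~ (δ~w1~ − δ~w2~)),

and the nonexchangeable value from one pair is

δ~ne~ = (δ~e~ − x~e~ α~e−w~ δ~w~ − 1000 x~e~ (α~e−w~ − 1)) / (1 − x~e~).

Both are implemented exactly in this delta-notation form, including the
1000(α−1) term. Defaults are the method's standard operating values: vapors
at −160 and −428‰ and α~e−w~ = 1.082, the cellulose value, applied to all
carbohydrate classes (it is configurable per call).

Three numerical policies matter here:

* **No clamping.** x~e~ outside [0, 1] is physically impossible but
  diagnostically precious; the batch reducer flags it
  (`X_E_OUT_OF_RANGE`) and keeps the record.
* **Pair consistency.** Substituting x~e~ into the reduction shows
  algebraically that pair 1 and pair 2 give the *same* δ~ne~; the reducer
  computes both, reports their absolute difference, and flags anything
  above 10⁻⁶‰ (`PAIR_INCONSISTENT`). Since the identity is exact, the flag
  can only fire on data corruption or an externally imposed x~e~ — it is a
  guard, not a statistic.
* **Singularity.** x~e~ = 1 (all hydrogen exchangeable) makes δ~ne~
  undefined and raises an error, as does a degenerate vapor pair
  δ~w1~ = δ~w2~.

Corrections run in the protocol's order: additive offset correction of the
raw equilibrated values against an exchange-free reference foil, then the
x~e~/δ~ne~ reduction from pair 1, then affine scaling to VSMOW against at
least two calibrated standards (two-point mapping, or least squares when
more are supplied). The in-house standard values are laboratory property
and must be user-supplied; the mean x~e~ of typical standards (0 for the
foil, about 0.35 for sucrose, 0.21 for cellulose) is documentation, not a
gate, because those are one laboratory's materials rather than theoretical
constants. The protocol mentions an occasional amount-dependent correction
without a functional form; we left it out of the default path rather than
guess one, which is the one deliberate narrowing of the reduction stage.

```{r}
m <- generate_equilibration_raw(true_delta_ne = c(-80, -120),
                                true_x_e = c(0.35, 0.21),
                                config = synthetic_config(noise_sd = 0))
process_equilibration_batch(m)
```

## Fractionation factors

ε~a~ and ε~h~ are implemented as plain differences, exactly as defined
above. The ratio-space alternative 1000((1000+δ~A~)/(1000+δ~B~) − 1) is
exposed separately as `epsilon_ratio()` and is never silently substituted;
at the δ ranges involved the two differ by several per mil, so conflating
them would be a real error.

Abundance-weighted n-alkane δ²H averages the odd chains C27–C33 after
renormalizing abundances to sum to one; sums outside [0.98, 1.02] are
rejected as data errors rather than silently rescaled.

Tissue offsets pair replicates by index within each treatment and average
the per-treatment means with equal weight. Replicates are distinct plants,
so index pairing is a convention, not a physical match — but treatment-level
summaries are what the factors are reported on, and equal treatment
weighting keeps unbalanced replication (down to n = 3 for cellulose and
alkanes under the harshest treatments) from tilting the grand mean.
Summaries always report n per cell; missing compounds yield absent rows,
never errors.

## The two-pool model and its inversion

`re_forward()` is affine in leaf water, source water and f, which gives the
package three exact, test-enforced identities: inverting for f or ε~h~\*
recovers the generating value to 10⁻⁹; and swapping root water for soil
water shifts every prediction by exactly f·(δ~soil~ − δ~root~).

The inversion is deliberately single-parameter: solve for f holding ε~h~\*
fixed, or for ε~h~\* holding f fixed. A joint fit is unidentifiable from
one equation per treatment, and the scientific question the inversion
serves is precisely "how far does each constant have to move to absorb the
misfit". Out-of-range f (negative, or above 1) is reported with a flag and
never clamped — negative apparent f is a meaningful outcome when measured,
"dynamic" ε~a~ values of sugars or starch replace the −171‰ constant
(`eps_a_mode = "sugars"` or `"starch"`), and clamping would destroy it.
Per-treatment inversion uses treatment-mean inputs by default, with a
per-replicate mode available.

On source water: root and soil water are both proxies, and cryogenic
extraction can leave root water apparently ²H-depleted relative to soil
water (6.7‰ in the generator's default). Because of the affine-shift
identity, the root→soil swap at f = 0.36 moves every prediction by
0.36 × 6.7 = +2.412‰. The package reports the signed shift and leaves
interpretation to the user; which proxy is "right" is a methodological
question the data alone cannot settle.

```{r}
re_forward(-50, -79.3)              # default constants
invert_f(-100, -50, -79.3)          # rearranged for f
source_sensitivity(-50, -86, -86 + 6.7)
```

## Hydrogen-atom budget

Glucose carries 7 carbon-bound hydrogens, partitioned 1:3:3 between NADPH,
water, and triose-phosphate/photorespiratory precursors — stored as integer
counts, which reproduce the conventional 14/43/43% on rounding. An
unbranched n-alkane of n carbons carries 2n+2 (60 for C29); its partition
is stored as the class-level percentages 47/24/29 directly, because 47% of
60 is not an integer and the underlying biosynthetic bookkeeping is
literature input, not something this package re-derives. Those C29
percentages are applied to all chain lengths as a class constant.
Percentages round half away from zero. `mix_delta()` provides the standard
linear mass balance Σ fraction·(δ~s~ + ε~s~) for scenario exploration; it
is a forward calculator, not a fitted model.

## The synthetic-data generator

The generator exists because the experiments it emulates publish effect
sizes, not raw per-plant tables. Its defaults *are* those study
conditions, fixed once:

| Parameter | Default | Meaning |
|---|---|---|
| treatments | 100, 90, 75, 50, 25, 10, 0 | NO₃⁻ % of a 6 mM N gradient |
| n_replicates | 5 | plants per treatment |
| irrigation_water | −79.3‰ | source water |
| vapor_water | −140.0‰ | chamber vapor (recorded, unused) |
| leaf_root_water_offset | +29.6‰ | evaporative leaf enrichment |
| root_soil_water_depletion | 6.7‰ | extraction artifact on root water |
| root_minus_leaf_offsets | S +17.3, St +104.5, C +12.3‰ | tissue enrichment |
| base_eps_a | S −161.8, St −203.8, C −73.5‰ | ε~a~ under nitrate dominance |
| alkane_eps_a | −128.8‰ | flat alkane fractionation |
| treatment_breakpoint | 25 | turning point of the gradient |
| treatment_amplitudes | S 128.8, St 77.6, C 35.4‰ | max leaf range |
| noise_sd | 3‰ | midpoint of the 2–4‰ measurement precision |
| pgm_offsets | St +152.7, S +75.0, C +38.7, alkanes 0‰ | genotype contrast |

The treatment effect is flat through the breakpoint and rises linearly
below it, reaching the full amplitude at 0% nitrate — the simplest shape
consistent with a flat-then-rising gradient with a stated turning point,
since no functional form is published. The base ε~a~ values are the
nitrate-dominated ends of the published per-compound ranges, so that
baseline plus amplitude spans each range. Wild-type baselines for the
genotype experiment (S −150, St −210, C −85, alkanes −140‰) were chosen
once to reproduce the published compound ordering in both genotypes; only
the *offsets* are measured quantities. Cellulose and alkane records are
truncated to three replicates under the two most ammonium-dominated
treatments, mirroring limited sample availability there.

Noise is independent Gaussian per record at 3‰. Between-plant biological
variance is not separately published, so the default deliberately conflates
it with measurement error into one term; the generators draw each record
independently. Consequences for interpreting tests: passing zero-noise
round trips shows the algebra is exactly invertible; passing noisy recovery
shows the estimators are unbiased under *this* noise model. Real data add
plant-level covariance, drift, and non-Gaussian tails the generator does
not emulate, so the tests validate the pipeline's arithmetic and
estimators, not field performance.

All generation is deterministic given the seed (two runs with one seed are
identical), and every downstream stage inverts zero-noise output exactly.

## Problem sizes and numerical choices

The test suite exercises the algebraic identities on 10⁴ randomized
measurements (tolerance 10⁻⁹‰ — pure floating point, since the identities
are exact), noisy recovery at n = 200 equilibrations (2‰ noise, mean x~e~
bias under 0.01) and n = 100–1000 model scenarios (3‰ noise, mean f within
0.02 of truth), sizes at which Monte-Carlo standard errors are an order of
magnitude below the asserted bounds. Ties and degenerate inputs fail loudly:
degenerate vapor pairs, x~e~ = 1, f = 0, and coincident mixing end-members
all raise errors rather than propagate infinities.

## Pipeline and interfaces

`run_pipeline()` composes the stages in methodological order —
equilibration reduction (when raw measurements are supplied), fractionation
tables, model predictions and inversions — writes plain-CSV outputs plus a
JSON run report, halts downstream stages when one fails but always
produces the report, and is byte-deterministic under a fixed configuration.
Tables are CSV-only with explicit headers; δ values are always ‰ VSMOW;
the treatment column carries the nitrate percentage or the genotype label.
A thin command-line wrapper over the same exported functions ships in
`inst/scripts/hydrofrac.R`.

## Known limitations

* Leaf-water evaporative enrichment is an input offset, not a modeled
  quantity: the package does not implement a Craig–Gordon-type model.
* The amount correction of the reduction stage is omitted for lack of a
  published functional form.
* The alkane hydrogen-source percentages are class constants taken from
  the C29 chain.
* Routine inferential statistics (ANOVA, post-hoc tests, PCA, trait
  regressions) are out of scope; the standard R tools apply directly to
  the tables this package emits.
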