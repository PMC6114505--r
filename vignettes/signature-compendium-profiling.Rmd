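---
title: "Profiling LINCS-style signature compendia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling LINCS-style signature compendia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincsprofiler)
```

## The analysis model

A Level-5 style signature is a vector of moderated z-scores over the 978
landmark genes, one signature per (cell line, perturbagen, dose, time)
combination, obtained upstream by collapsing treatment/control replicate
profiles. `lincsprofiler` takes such signatures and their metadata as
given — replicate collapsing and the inference of non-landmark transcripts
are deliberately out of scope — and characterizes the compendium in two
layers: distributional summaries of the experimental metadata, and a
differential-expression activity analysis of the z-scores themselves.

The activity model is a per-gene threshold rule: gene $i$ in signature $j$
is differentially expressed iff $z_{ij} > z_{hi}$ or $z_{ij} < z_{lo}$,
with strict inequalities and defaults $z_{hi} = 2$, $z_{lo} = -2$. Under a
pure-noise signature with $z_{ij} \sim N(0,1)$ the per-gene rate is
$p_0 = 2\Phi(-2) \approx 0.0455$ and the DEG count is
$\mathrm{Bin}(978, p_0)$ with mean $978\,p_0 \approx 44.5$. This null law
is the backbone of the package's verification: the "at least 1 significant
gene" category is saturated even by noise
($P(\ge 1) = 1 - (1-p_0)^{978} \approx 1 - 10^{-20}$), so the informative
categories are the $\ge 50$ and $\ge 100$ tails, where the null
contributes $P(\ge 50) \approx 0.219$ and $P(\ge 100) \approx 10^{-12}$.
Consequently the $\ge 100$ category is a nearly noise-free readout of
planted or real biological activity, which is why the direction and
geometry analyses default to it or to the $\ge 50$ level.

### Cumulative categories and the two-way stratifications

Per-signature DEG totals are tabulated into cumulative categories
"at least $k$" for $k \in \{1, 50, 100\}$ (configurable), for signature
profiles and for distinct small molecules. A molecule is placed in
category $\ge k$ when **any** of its signatures reaches $k$ — equivalently
when its maximum per-signature DEG total does — and in the "none" category
only when all its signatures have zero significant genes. This
best-signature rule is the only self-consistent reading of a cumulative
molecule tally (the alternatives, e.g. requiring all signatures to reach
$k$, break the none + $\ge 1$ = total partition), and it is what the
package implements and tests.

Stratified counts repeat the same tally within cell lines, within
cell × dose-group and within cell × time strata. The dose grouping is a
fixed two-way split at 5 µM, boundary inclusive to low, after canonicalizing
all doses to micromolar — so every nanomolar dose is "low" by
construction. Records without a dose (controls, ligands, genetic
perturbations) are excluded from dose strata, with the excluded count
reported, rather than imputed.

### Change fractions and segment geometry

For a two-level contrast $A \to B$ (low → high dose, or 6 h → 24 h) and a
category level $k \in \{50, 100\}$ the change fraction is

$$f_{X,k} \;=\; \frac{\#\text{profiles}(\ge k \mid X)}{\#\text{profiles}(\ge 1 \mid D(X))},$$

where the denominator stratum $D(X)$ is governed by a convention switch.
Under the default `"stratum"` convention $D(X) = X$: each level is
normalized by its own active-profile count, all four fractions lie in
$[0,1]$ and nest ($f_{X,100} \le f_{X,50}$), and they read directly as "the
percentage of active profiles that are strongly active". Under
`"as_printed"` all four fractions share the level-$A$ denominator
($D(X) = A$), a literal conditional form under which the $B$ fractions may
exceed 1. Both conventions are implemented and tested; `"stratum"` is the
default because percentage-scale activity summaries (and any plot with a
0–100% axis) presuppose it, while the literal form is preserved behind the
switch rather than silently corrected.

The four fractions of a contrast define a line segment over the coded
abscissa $A = 0 \to B = 1$, so the slope is simply $f_B - f_A$ and any
affine recoding of the abscissa rescales both slopes equally, leaving
comparisons unchanged. Two segments $p, q$ (the dose-contrast and
time-contrast segments at the same category level) are classified as

* **intersecting** iff the endpoint differences change sign:
  $(p_A - q_A)(p_B - q_B) < 0$;
* **parallel** iff not intersecting and $|\mathrm{slope}(p) -
  \mathrm{slope}(q)| \le$ `slope_tol`;
* **neither** otherwise.

`slope_tol` is an absolute tolerance on a fraction scale; its default of
0.02 is deliberately tight, appropriate for compendium-scale strata (tens
of thousands of profiles, where fraction standard errors are below 0.005).
At simulation-scale strata of one or two thousand profiles, slope noise is
an order of magnitude larger, and the recovery studies therefore pass
`slope_tol = 0.15` — chosen a priori from the binomial standard errors at
that size, not from observed test outcomes. Emitting `neither` when the
sign test and the slope test disagree is intentional: forcing a binary
parallel/intersecting verdict would overstate certainty exactly in the
ambiguous cases.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `z_hi`, `z_lo` | +2, −2 | z-score | strict DEG thresholds |
| `thresholds` | 1, 50, 100 | genes | cumulative category boundaries |
| `dose_cutoff_um` | 5 | µM | low/high boundary, inclusive to low |
| `times` | 6, 24, 48 | h | analysis-set durations |
| `min_profiles` | 20 000 | profiles | strict (>) cell-selection bound |
| `cap` | 9 | — | histogram overflow ("9+") boundary |
| `slope_tol` | 0.02 | fraction | parallel slope tolerance |
| `convention` | `"stratum"` | — | change-fraction denominators |

Cell-line selection uses a strict inequality (a count of exactly 20,000
does not qualify), with ties broken by descending count then lexicographic
cell id, so the selection is invariant to input row order.

## The synthetic generator

`simulate_metadata()` / `simulate_signatures()` produce a LINCS-shaped
compendium with known ground truth:

* Categories are drawn i.i.d. from a configurable mixture over the six
  categories; the default mixture (45% compound, 30% control, 12%
  overexpression, 8% shRNA, 3% poscon, 2% ligand) reflects the
  compound-and-control dominance typical of perturbational screens.
* Each distinct compound is profiled on the full dose × time grid, so the
  per-compound dose multiplicity equals the number of configured dose
  levels exactly — giving the multiplicity histograms a sharp truth to
  recover. Replicate counts are i.i.d. from a distribution whose default
  puts 99% of mass on 1–8 with mode 3 and a rare tail up to 27.
* Compound (and poscon) signatures carry `n_hits` planted hit genes whose
  z-scores are $N(\pm\mu, 1)$ with signs split 50/50 and
  $\mu = \mu_0\, g(\text{dose})\, h(\text{time})$; all other entries, and
  all control/ligand/genetic signatures, are $N(0,1)$ null. The response
  shapes are the simplest monotone forms consistent with a planted
  *direction*: $g \equiv 1$ (flat), $g(d) = d/d_{\max}$ (increasing),
  $g(d) = d_{\min}/d$ (decreasing), and likewise for $h$.
* The default fixture (`default_sim_config()`) uses nine cell-line labels
  familiar from deeply profiled compendia (A375, A549, HCC515, HA1E,
  HEPG2, HT29, MCF7, PC3, VCAP), doses 0.1/1/5/10 µM, times 6/24/48 h,
  $\mu_0 = 3$, 100 hits, and plants the two qualitative behaviors
  observed in real compendia: activity rising with dose everywhere except
  VCAP, and rising with time except HA1E and HCC515.

Because hits are conditionally independent given $\mu$, the DEG count of a
planted signature is the sum of two independent binomials,
$\mathrm{Bin}(n_{hits}, p_{hit}(\mu)) + \mathrm{Bin}(978 - n_{hits}, p_0)$
with $p_{hit}(\mu) = \Phi(\mu - 2) + \Phi(-\mu - 2)$, and
`deg_tail_prob()` evaluates its tail exactly by convolving the two mass
functions. `expected_category_fractions()` and `expected_fraction_set()`
lift this to design-cell and stratum-level expectations, which serve as
the independent oracle for every stochastic check: the implementation is
never compared against itself.

**What the generator does not emulate.** Real Level-5 signatures have
correlated genes (pathway structure), heavy-tailed and batch-driven noise,
dose–response saturation, molecule-specific effect heterogeneity, and
quality-control structure (wells, plates). Passing tests therefore
demonstrate that the *pipeline arithmetic* — thresholding, categorization,
stratification, fractions, classification — is correct under the stated
stochastic model, not that the biological conclusions drawn from any real
compendium are right. In particular the planted-truth recovery rates say
nothing about gene–gene correlation robustness, which a threshold-count
statistic inherits from the data, not from this package.

## Numerical and interface choices

* **Strict thresholds.** Values exactly at ±2.0 are not significant;
  tests plant exact boundary values to pin this down.
* **Missing values.** `NaN`/`NA` z-scores are ignored per gene (excluded
  from both up and down counts) rather than failing the signature —
  sparse or partially masked fixtures remain usable. The metadata
  sentinel `-666`, empty strings and unparseable numbers all become
  missing doses; unknown dose units warn and yield missing rather than
  guessing a scale; unknown perturbation codes are reported, never
  silently binned, and such rows are dropped with a logged count.
* **Canonical units.** Doses are canonicalized to micromolar before any
  comparison, so dose-multiplicity counts treat 500 nM and 0.5 µM as one
  concentration, and the 5 µM boundary needs no unit logic downstream.
  Times are canonicalized to hours.
* **Degenerate inputs.** Header-only metadata, zero-column matrices, empty
  analysis sets and cells missing a contrast level all return
  well-defined empty/flagged results instead of errors — except where an
  invariant is genuinely violated (duplicate `sig_id`, orphan DEG
  records, zero $\ge 1$ denominators, dimension mismatches), which are
  hard errors naming the offender.
* **Formats.** GCT is fixed at version 1.3 (`#1.3` header, dimension
  line, 10-significant-digit values on write, round-trip error below
  $10^{-6}$); GCTX uses the `/0/DATA/0/matrix` + `/0/META/{ROW,COL}/id`
  HDF5 layout, with a transpose fallback for files written column-major
  by other tool chains. These are the only layouts in circulation for
  landmark-gene z-score matrices.
* **Determinism.** All generator randomness derives from the
  configuration seed, with metadata and signature streams separated by a
  fixed offset, so a manifest (seed + parameters) reproduces every table
  bit-identically; the pipeline test suite verifies this.

## Study sizes used in verification

The package's statistical checks run at sizes chosen to make their error
bars decisive on one CPU in minutes: 10,000 signatures for the null-law
comparison (standard error of the mean DEG count ≈ 0.07); 100 replicates
of 2,000-signature-per-cell designs (1,000 per stratum, $\mu_0 = 3$, 100
hits) for direction recovery; and 100 replicates each of two
2,000-signature geometry designs whose planted classification — verified
analytically from the exact oracle before any simulation — is
`intersecting` (dose response increasing, time flat: the rising dose
segment must cross the flat time segment) and `parallel`
($\mu_0 = 2.5$, both responses increasing, where the pooled low-dose
stratum offsets the dose segment below the time segment at matched
slopes). All recovery requirements are set at 95%.

## Known limitations

* The analysis consumes Level-5-like signatures; nothing upstream
  (bead-level processing, replicate collapsing, non-landmark inference)
  is modelled, and quality-control flags are passed through rather than
  interpreted — which flag set defines a "QC-passed" signature is left to
  the caller's filter.
* Molecule-level categories depend on the best-signature rule described
  above; compendia summarized under a different molecule rule will not
  match numerically.
* The parallel/intersecting classification is a two-point geometry on
  aggregate fractions; it does not test slopes inferentially, and
  `neither` should be read as "undecided at this tolerance".
* The generator's independence assumptions make analytic oracles exact
  but understate the variance that correlated genes induce in real
  threshold counts.
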