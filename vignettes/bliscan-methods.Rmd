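---
title: "Models and methods in bliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bliscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bliscan)
```

bliscan packages the quantitative machinery of a receptor ligand-mapping
workflow built around biolayer interferometry (BLI): sensorgram
simulation, pre-processing, affinity estimation, competition (epitope
binning) quantitation, a sequence-based complementary-hydropathy screen,
and mutagenesis-panel binding-site assignment.  This vignette records
the models, the numerical choices, and the judgement calls, in the way a
methods section would.

## The 1:1 Langmuir sensorgram model

A BLI sensorgram reports optical thickness (nm) against time as analyte
at concentration $C$ binds an immobilised receptor.  Under 1:1 Langmuir
kinetics with association rate $k_{on}$ (M$^{-1}$s$^{-1}$) and
dissociation rate $k_{off}$ (s$^{-1}$), the association phase follows

$$R(t) = R_{eq}\left(1 - e^{-(k_{on} C + k_{off})\,t}\right),\qquad
R_{eq} = \frac{R_{max}\,C}{C + K_D},\qquad K_D = \frac{k_{off}}{k_{on}},$$

and the dissociation phase decays exponentially at $k_{off}$ from the
response at the end of association.  `simulate_1to1_sensorgram()`
evaluates these closed forms on the sampling grid and then adds (i)
i.i.d. Gaussian noise per sample and (ii) a linear baseline drift
applied to *every* channel.  Drift-in-all-channels is deliberate: it is
exactly the artifact that double-reference subtraction is designed to
remove, so simulated plates exercise that pathway honestly.  A
zero-concentration buffer reference and per-concentration pin
references are always emitted.

Biphasic analytes (e.g. heterogeneous oligomers) are modelled as a
weighted sum of two independent 1:1 components
(`simulate_biphasic_sensorgram()`).  This is the simplest model that
produces visibly non-single-exponential dissociation, which is what the
kinetic fitter's model-mismatch diagnostic looks for; it is not an
avidity or rebinding model.

Determinism contract: every generator takes an explicit integer seed,
uses it through a locally scoped RNG (the global `.Random.seed` is
restored), and equal seeds give bit-identical output.

## Double referencing and step alignment

`double_reference()` computes, per sample trace and per step,

corrected = sample − reference(loaded sensor in buffer) − reference(bare pin in analyte),

with each reference linearly interpolated onto the sample's time grid.
Linear interpolation is adequate because BLI sample rates are high
relative to signal curvature.  Both references are subtracted with no
add-back term; a consequence worth knowing is that a drift $d\,t$
present in all three channels leaves $-d\,t$ in the corrected trace
(drift is removed once per reference).  Subtraction precedes step
re-zeroing (`align_to_step_start()`); the order is a convention of this
package, chosen so that the association fit sees data anchored at
$(0, 0)$ after both corrections.

## Affinity estimation

**Steady state.**  `extract_plateau()` averages the final `window_s`
seconds (default 5 s, ≥ 25 points at typical sampling) of the
association step; a plateau from a step that ended well short of
equilibrium (roughly $k_{obs} t < 3$) is flagged.  `fit_steady_state()`
fits $R_{eq}(C) = R_{max} C/(C+K_D)$ by least squares.  $R_{max}$ enters
linearly and is profiled out exactly, leaving a one-dimensional search
over $\log K_D$ run from 7 log-spaced starts spanning
$[\min(C)/100,\ 100\max(C)]$ — deterministic, no RNG in fitting.
Reported $\pm$ values are fit standard errors from the Jacobian at the
optimum (replicate SDs are a different quantity; the label matters).
Degenerate designs are classified, not crashed: all-zero responses give
`no_binding_detected`; a fitted $K_D$ far outside the concentration
window raises an ill-conditioning flag.

**Global kinetics.**  `fit_kinetic_global()` fits a single
$(k_{on}, k_{off}, R_{max})$ jointly to all association and dissociation
segments using the closed-form solutions, over log-parameters
(Nelder–Mead then BFGS) from the same 7-start $K_D$ grid.  Before
fitting, the top-concentration dissociation is compared against the
best single-exponential model; a relative residual above 0.02 sets a
`model_mismatch` flag, the package's operational version of "a 1:1 fit
is not appropriate here".  The 0.02 threshold is an editorial choice:
noiseless 1:1 data sit at ~10⁻⁶ on this statistic while a 50/50 mixture
of $k_{off}$ 0.1 and 10⁻⁴ s⁻¹ sits above 0.03.

**Fold change and classes.**  `fold_change()` returns
$\max(K_D^{var}, K_D^{wt})/\min(\cdot)$ with a direction, rounded
half-up to 2 decimals for tabulation (half-up, not banker's rounding,
matches how binding tables are typically typeset).  `classify_binding()`
uses two thresholds for which no community standard exists, so both are
exposed: $\theta_{resp}$ = 0.02 nm (or 3× the known noise SD, whichever
is larger) for "no binding detected", and $\theta_{frac}$ = 0.5 of the
wild-type plateau for "decreased binding".

## Sequential competition and the overlap fraction

Competition (epitope-binning) experiments load the receptor, expose it
to a first ligand (or buffer), dissociate, then expose it to a second
ligand.  The quantity of interest is the Association-2 gain — response
at the end of Association 2 minus response at its beginning — and the
percent decrease of that gain relative to the no-competitor arm.  By
default each endpoint is a 3-sample median rather than the literal
single sample, a small guard against noise spikes that can be disabled
(`guard = FALSE`).

Real competition data give no mechanism, only magnitudes.  For
simulation the package adopts a shared-site occupancy model with an
epitope-overlap fraction $\varphi \in [0,1]$:

$$\dot\theta_1 = k_{on,1} C_1 (1 - \theta_1 - \varphi\,\theta_2) - k_{off,1}\theta_1,$$

and symmetrically for $\theta_2$, with concentrations switched per
step.  $\varphi = 0$ decouples the ligands exactly; $\varphi = 1$ is a
fully shared site giving complete blockade by a saturating,
non-dissociating competitor.  This is one consistent mechanism spanning
the observed limits, not a claim about any particular ligand pair.  Two
consequences shape the tests:

* A bound of the form $\theta_1 + \theta_2 \le 1$ holds only at
  $\varphi = 1$.  At $\varphi = 0$ the two occupancies refer to
  different sites and can sum towards 2.  The tested invariants are
  therefore $\theta_i \in [0, 1]$ for all $\varphi$, plus the sum bound
  at $\varphi = 1$.
* The exact-independence limit (competed gain = alone gain at
  $\varphi = 0$) requires a non-dissociating first ligand: if ligand 1
  dissociates during Association 2, its signal loss registers as a few
  percent of apparent competition even with zero overlap.  The
  canonical simulated fixtures therefore use $k_{off,1} = 0$ with
  ligand 1 at saturation.

The ODE system is linear within each step but is integrated with an
adaptive Cash–Karp Runge–Kutta (4/5) scheme at absolute tolerance
10⁻¹⁰ on occupancies, written in-package because no ODE solver library
is available in the supported dependency set; for this 2-state,
piecewise-constant-input system the method is comfortably adequate
($k_{on}C$ spans orders of magnitude but remains non-stiff at BLI
scales).

Simulated asymmetry is emergent, not encoded: with a high-affinity,
slow-off ligand A and a weaker, faster ligand B at full overlap,
A-blocks-B exceeds B-blocks-A purely from the kinetics, qualitatively
matching the one-way blockade pattern seen in real ligand pairs.

## The complementary-hydropathy screen

Each residue is assigned its Kyte–Doolittle index (span 9, from Arg
−4.5 to Ile +4.5; no residue is exactly 0, so every residue has a
well-defined sign).  A motif (e.g. a CDR loop or a helix) slides across
the target at step 1, in forward and in reversed residue order, and
each alignment is scored twice:

* **percent match** — the percentage of positions with opposite
  hydropathy signs ("complementary pairs over all matched pairs");
* **degree of complementary hydropathy** —
  $C = \sum_{i=1}^{L} |H(i) - H'(i)| / (9L) \in [0, 1]$,
  where $H, H'$ are the indices of motif and window and $L$ the motif
  length.  $C = 1$ only for Ile/Arg pairing at every position.

A hit passes when percent match > 75 **and** $C$ > 0.5; both
comparisons are strict, reading "greater than" literally.  Design
notes: "complementary pair" is interpreted as opposite-sign pair
(consistent with $C$ rewarding large $|H - H'|$); "reverse orientation"
means reversed residue order, the only reading meaningful for a
hydropathy string; ambiguous residues (B, J, O, U, X, Z) are rejected
rather than skipped, because silently dropping them would change $L$
and hence $C$.  Since every standard residue has nonzero hydropathy,
the alternative reading of the percent-match denominator (sign-defined
pairs only) coincides with $L$ and the ambiguity is moot.

Passing hits are summarised two ways (`screen_region_set()`):
per-residue counts of passing-window coverage, and candidate regions
formed by merging passing windows that overlap or abut (gap ≤ 1).  The
merge rule is an editorial choice — published "clustered hits" rarely
state one — so the raw counts are reported alongside, letting any other
threshold be applied downstream.

**Planted fixtures.**  `plant_complementary_motif()` generates a
motif/target pair whose planted window is opposite in sign at every
position *and* at least 4.6 hydropathy units away per position.  The
gap floor is what makes the fixture a guaranteed *passing* hit
($C \ge 4.6/9 \approx 0.51$): sign opposition alone can produce
complementary windows with $C$ well under 0.5 (e.g. Gly against Ala),
which would make detection tests flaky for no informative reason.
Every residue has at least two admissible partners under the 4.6-unit
rule, so the construction never fails.

## Variant panels and site calls

The bundled panel (`read_panel()`) transcribes measured dissociation
constants and qualitative binding classes for a receptor variant
library against four ligands, with each printed fold change kept as a
string so its decimal precision is known.  `check_fold_table()`
recomputes every fold from the K_D columns and compares at the printed
precision, surfacing one-final-digit rounding mismatches explicitly —
a transcription-integrity check, not a statistical test.

`call_sites()` aggregates per-site verdicts from the strongest effect
among each site's variants: ablating (any no-binding variant) > severe
(≥ 10-fold affinity decrease) > moderate (≥ 2-fold, or a qualitative
decreased-binding call) > neutral, with "enhancing" for sites whose
only ≥ 2-fold effect is an affinity *increase*.  Sites showing both
inhibitory and enhancing variants keep the inhibitory verdict and set
`has_enhancing`; conflicts are reported, not resolved.  The 10× and 2×
thresholds are editorial (the source reasoning is qualitative —
"completely ablated", "did not largely impact") and are exposed as
arguments.  AD-risk-only records (positions outside the structural
sites) never determine a primary site on their own.  The primary site
is the site with the strongest verdict; a second site at moderate or
stronger becomes the secondary.

## What the generator does and does not emulate

The defaults encode the stated experimental world: two-fold
concentration series (62.5–1000 nM for the cytokine/complement designs,
0.012–50 µM for the apolipoprotein design), Gaussian per-sample noise
with 1% of $R_{max}$ as the reference noise level, linear drift, buffer
and pin reference channels, and step durations long enough that
$k_{obs} t_{assoc} \gg 4.6$ (> 99% of plateau) where equilibrium is
assumed.  Not emulated: mass-transport limitation, inter-step
discontinuity spikes, sensor-to-sensor $R_{max}$ variation, analyte
depletion, and rebinding during dissociation.  A green
parameter-recovery test therefore establishes correctness of the
estimators *under the 1:1 (or two-component) model*, not robustness to
every instrument artifact.

Real receptor/ligand sequences are not bundled: the environment this
package is built and tested in has no network access, and typing
sequences from memory would be fabrication.  The bundled FASTA fixture
is a clearly labelled synthetic stand-in generated by the planting
routine; region coordinate annotations (`region_annotations()`) are
bundled as data.  The five ligand-side cluster coordinates are
annotations on the screen's *output* scale and are not claimed to be
the helix boundaries used as screen motifs, which were never published.

## Known limitations

* The kinetic fitter assumes the closed-form 1:1 solution per segment;
  it does not fit the two-component mixture (mixtures are flagged, then
  left for qualitative evaluation, mirroring standard practice).
* The overlap fraction $\varphi$ is a simulator input only; estimating
  it from data would require a ternary-complex model that the package
  deliberately does not include.
* Fold-change standard errors are not propagated from the K_D standard
  errors; fold values are point summaries for tabulation.
* Instrument vendor file formats are out of scope; the plate CSV schema
  is the package's interchange format.
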