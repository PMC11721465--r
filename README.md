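# bliscan

Quantitative machinery for receptor–ligand binding-surface mapping by
biolayer interferometry (BLI), plus a sequence-based
complementary-hydropathy screen for predicting protein–protein binding
regions.

The package is aimed at structural biologists and protein biochemists
who map where ligands engage a receptor by combining three lines of
evidence: affinity shifts across a structure-guided mutant panel,
sequential competition (epitope-binning) experiments, and sequence
complementarity screening. It ships a full synthetic-data layer, so
every estimator is testable against known ground truth without
instrument files.

## What it computes

**1:1 Langmuir kinetics.** Sensorgrams are modelled as
`R(t) = R_eq (1 − exp(−(k_on·C + k_off) t))` with
`R_eq = R_max·C/(C + K_D)` and `K_D = k_off/k_on`. Affinity is
estimated two ways: steady-state isotherm fitting of plateau responses
(`fit_steady_state()`, with `R_max` profiled out exactly) and a global
kinetic fit of all association/dissociation segments
(`fit_kinetic_global()`), which also flags data whose dissociation is
not single-exponential (oligomeric/biphasic analytes).

**Pre-processing.** Plates are long-format CSV tables of
(sensor, step, time, response). `double_reference()` subtracts the
loaded-sensor-in-buffer and bare-pin-in-analyte references per step
after linear interpolation; `align_to_step_start()` re-zeroes a step at
its first sample.

**Competition.** Sequential experiments (ligand 1 → buffer → ligand 2)
are quantified by the Association-2 gain (end minus start of the
second association) and the percent decrease versus the
no-competitor arm. The simulator's shared-site occupancy model
`dθ1/dt = k_on1·C1(1 − θ1 − φ·θ2) − k_off1·θ1` exposes an
epitope-overlap fraction φ ∈ [0, 1] spanning independence (φ = 0) to
full blockade (φ = 1).

**Complementary-hydropathy screen.** Sequences are converted to
Kyte–Doolittle hydropathy maps; a motif slides across the target in
forward and reversed residue order, scoring each window by percent
match (fraction of opposite-sign pairs) and the complementarity degree

    C = Σ |H(i) − H'(i)| / (9·L),   C ∈ [0, 1]

A hit passes when percent match > 75 and C > 0.5; passing hits are
merged into candidate binding regions with per-residue hit counts.

**Site mapping.** `build_panel()` joins a variant table with
per-ligand wild-type references (fold change = `max/min` of the two
K_Ds), `call_sites()` aggregates per-site verdicts
(ablating > severe ≥ 10× > moderate ≥ 2× > neutral, plus enhancing),
and `ligand_site_matrix()` summarises primary binding surfaces across
ligands. A transcribed reference panel for a TREM2-style variant
library against four ligands is bundled.

## Worked example

```r
library(bliscan)

## ground truth: K_D = 16.5 nM receptor-cytokine interaction
params <- kinetic_params(k_on = 1e5, k_off = 1.65e-3)
#> 1:1 kinetics: k_on = 1e+05 M^-1 s^-1, k_off = 0.00165 s^-1, R_max = 1 nm (K_D = 16.5 nM)

## simulate a two-fold series 62.5-1000 nM with 1% noise, then fit back
design <- assay_design(1000e-9 / 2^(4:0), t_assoc = 1500, t_dissoc = 300,
                       sample_rate = 2, noise_sd = 0.01, seed = 42)
plate  <- simulate_1to1_sensorgram(params, design, analyte = "IL-34")
corr   <- double_reference(plate)
fit_steady_state(extract_plateau(corr))
#> Steady-state fit: K_D = 16.6 nM (se 0.7), R_max = 1.003 nm
```

The recovered K_D (16.6 nM) agrees with the generating value within
the fit standard error — the plateau extraction, referencing and
isotherm fit round-trip the ground truth.

```r
## fold change as tabulated in mutagenesis panels (114 vs 16.5 nM)
fold_change(114, 16.5)
#> fold change: 6.91 (down)

## full blockade: saturating, non-dissociating competitor at phi = 1
p1 <- kinetic_params(1e5, 0); p2 <- kinetic_params(1e5, 1e-3)
alone    <- simulate_sequential(sequential_design(p1, p2, 0,     500e-9, overlap = 1))
competed <- simulate_sequential(sequential_design(p1, p2, 10e-6, 500e-9, overlap = 1))
run_competition_pair(alone, competed)
#> Competition: ligand1 pre-bound vs ligand2 (5e-07 M): gain 0.956 -> 0 nm, 100.0% decrease

## hydropathy screen on a planted fixture: guaranteed hit at position 45
fx   <- plant_complementary_motif(planted_motif_spec(9, 140, 45, seed = 202))
hits <- screen(fx$motif, fx$target)
hits[hits$orientation == "forward" & hits$window_start == 45, ]
#>    motif orientation window_start window_end percent_match    degree passes
#> 45 motif     forward           45         53           100 0.6271605   TRUE

## end-to-end site mapping on the bundled variant panel
panel <- build_panel(read_panel())
ligand_site_matrix(lapply(unique(panel$ligand), function(l) call_sites(panel, l)))
#>    ligand hydrophobic     basic basic_adjacent     site2   ad_risk     primary
#> 1   apoE4    ablating  moderate     not_tested enhancing  moderate hydrophobic
#> 2     C1q    moderate  ablating      enhancing   neutral  ablating       basic
#> 3   IL-34     neutral  ablating       moderate   neutral   neutral       basic
#> 4  TDP-43    ablating  moderate     not_tested   neutral   neutral hydrophobic
```

The matrix reads: mutations in the hydrophobic (CDR-loop) site ablate
apoE4 and TDP-43 binding, while C1q and IL-34 are ablated by basic-site
mutations — the two ligand classes engage different receptor surfaces.

A command-line interface with `simulate`, `fit`, `compete`,
`hydroscan` and `sitemap` subcommands is installed at
`system.file("cli", "bliscan", package = "bliscan")` (run with
`Rscript`).

## Package layout

- `R/params.R`, `R/simulate.R` — domain types and the synthetic-data
  generators (1:1, biphasic, sequential competition, planted motifs)
- `R/plate.R` — plate container, CSV I/O, double referencing, alignment
- `R/kinetics.R` — plateau extraction, steady-state and global kinetic
  fits, fold changes, binding classes
- `R/competition.R` — Association-2 gain, percent decrease, pairing
- `R/hydropathy.R` — Kyte–Doolittle maps, screen, hit clustering
- `R/sitemap.R` — variant parsing, panel building, site calls, summary
  matrix
- `vignettes/bliscan-methods.Rmd` — models, numerical choices, and
  limitations in detail
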