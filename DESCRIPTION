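Package: bliscan
Title: Biolayer Interferometry Kinetics, Competition Binning, and
    Complementary-Hydropathy Screening
Version: 0.1.0
Authors@R:
    person("bliscan", "maintainers", email = "bliscan@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of biolayer interferometry (BLI)
    binding experiments, and sequence-based prediction of protein-protein
    binding regions.  Provides a 1:1 Langmuir sensorgram simulator with
    Gaussian noise and baseline drift (plus biphasic mixtures and
    sequential two-ligand competition with a tunable epitope-overlap
    fraction), double-reference subtraction and step alignment for
    sensorgram plates, steady-state isotherm and global 1:1 kinetic
    fitting with fold-change classification of mutant panels,
    quantitation of sequential competition experiments (Association-2
    gain and percent decrease), a bidirectional complementary-hydropathy
    screen on the Kyte-Doolittle scale with hit clustering, and
    mutagenesis-panel binding-site assignment for receptor-ligand
    mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
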