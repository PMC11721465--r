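#' Kinetic parameters for a 1:1 Langmuir binding model
#'
#' @param k_on Association rate constant (M^-1 s^-1, > 0).
#' @param k_off Dissociation rate constant (s^-1, >= 0).
#' @param R_max Saturating response (nm, > 0).
#' @return `kinetic_params` object; `$K_D` is `k_off / k_on` (M).
#' @export
#' @examples
#' kinetic_params(k_on = 1e5, k_off = 1.65e-3)$K_D  # 16.5 nM
kinetic_params <- function(k_on, k_off, R_max = 1) {
  stopifnot(is.numeric(k_on), length(k_on) == 1, is.finite(k_on),
            is.numeric(k_off), length(k_off) == 1, is.finite(k_off),
            is.numeric(R_max), length(R_max) == 1, is.finite(R_max))
  if (k_on <= 0) stop("k_on must be > 0", call. = FALSE)
  if (k_off < 0) stop("k_off must be >= 0", call. = FALSE)
  if (R_max <= 0) stop("R_max must be > 0", call. = FALSE)
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max,
                 K_D = k_off / k_on),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("1:1 kinetics: k_on = %.3g M^-1 s^-1, k_off = %.3g s^-1, R_max = %.3g nm (K_D = %.4g nM)\n",
              x$k_on, x$k_off, x$R_max, x$K_D * 1e9))
  invisible(x)
}

#' Assay design for a concentration-series BLI experiment
#'
#' Concentrations are in molar; a two-fold dilution series such as
#' `1000e-9 / 2^(4:0)` (62.5-1000 nM) is typical.  Noise is i.i.d.
#' Gaussian per sample; drift is linear in time and applied to every
#' channel (it is what double referencing is designed to remove).
#'
#' @param concentrations Analyte concentrations (M, > 0, unique); sorted
#'   ascending on construction.
#' @param t_assoc,t_dissoc Association / dissociation durations (s, > 0).
#' @param t_baseline Baseline duration before association (s, >= 0).
#' @param sample_rate Samples per second (> 0).
#' @param noise_sd Gaussian noise SD (nm, >= 0).
#' @param drift_rate Linear baseline drift (nm/s).
#' @param seed Integer RNG seed (determinism contract: equal seeds give
#'   bit-identical plates).
#' @return `assay_design` object.
#' @export
assay_design <- function(concentrations, t_assoc, t_dissoc,
                         t_baseline = 10, sample_rate = 2,
                         noise_sd = 0, drift_rate = 0, seed = 1L) {
  if (!is.numeric(concentrations) || length(concentrations) < 1 ||
      any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("invalid design: concentrations must be positive and finite",
         call. = FALSE)
  if (anyDuplicated(concentrations))
    stop("invalid design: concentrations must be unique", call. = FALSE)
  if (t_assoc <= 0 || t_dissoc <= 0 || t_baseline < 0 || sample_rate <= 0)
    stop("invalid design: durations and sample_rate must be positive",
         call. = FALSE)
  if (noise_sd < 0) stop("invalid design: noise_sd must be >= 0", call. = FALSE)
  structure(list(concentrations = sort(concentrations),
                 t_assoc = t_assoc, t_dissoc = t_dissoc,
                 t_baseline = t_baseline, sample_rate = sample_rate,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' Design for a sequential (competition) binding experiment
#'
#' Association 1 exposes the sensor to ligand 1 (concentration may be 0
#' for the no-competitor arm), a buffer dissociation follows, then
#' Association 2 exposes it to ligand 2.  `overlap` is the epitope
#' overlap fraction phi in \[0, 1\]: 0 means the two ligands bind
#' independent sites, 1 means a fully shared site.
#'
#' @param params1,params2 [kinetic_params()] for ligand 1 / ligand 2.
#' @param conc1,conc2 Concentrations (M); `conc1 = 0` gives the
#'   ligand-2-alone arm.
#' @param overlap Epitope-overlap fraction phi in \[0, 1\].
#' @param t_assoc1,t_dissoc,t_assoc2 Step durations (s, > 0).
#' @param ligand1,ligand2 Names carried into output metadata.
#' @return `sequential_design` object.
#' @export
sequential_design <- function(params1, params2, conc1, conc2,
                              overlap = 0, t_assoc1 = 300, t_dissoc = 120,
                              t_assoc2 = 300,
                              ligand1 = "ligand1", ligand2 = "ligand2") {
  stopifnot(inherits(params1, "kinetic_params"),
            inherits(params2, "kinetic_params"))
  if (!is.numeric(overlap) || length(overlap) != 1 ||
      overlap < 0 || overlap > 1)
    stop("invalid design: overlap must lie in [0, 1]", call. = FALSE)
  if (conc1 < 0 || conc2 < 0)
    stop("invalid design: concentrations must be >= 0", call. = FALSE)
  if (t_assoc1 <= 0 || t_dissoc <= 0 || t_assoc2 <= 0)
    stop("invalid design: step durations must be > 0", call. = FALSE)
  structure(list(params1 = params1, params2 = params2,
                 conc1 = conc1, conc2 = conc2, overlap = overlap,
                 t_assoc1 = t_assoc1, t_dissoc = t_dissoc,
                 t_assoc2 = t_assoc2,
                 ligand1 = ligand1, ligand2 = ligand2),
            class = "sequential_design")
}

#' Specification of a planted complementary-hydropathy motif fixture
#'
#' @param motif_length,target_length Lengths in residues.
#' @param plant_position 1-based start of the planted window in the
#'   target; the window must fit (`plant_position + motif_length - 1 <=
#'   target_length`).
#' @param seed Integer RNG seed.
#' @return `planted_motif_spec` object.
#' @export
planted_motif_spec <- function(motif_length, target_length, plant_position,
                               seed = 1L) {
  stopifnot(motif_length >= 3, target_length >= motif_length,
            plant_position >= 1)
  if (plant_position + motif_length - 1 > target_length)
    stop("planted window does not fit in target", call. = FALSE)
  structure(list(motif_length = as.integer(motif_length),
                 target_length = as.integer(target_length),
                 plant_position = as.integer(plant_position),
                 seed = as.integer(seed)),
            class = "planted_motif_spec")
}

# run expr with a locally seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
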