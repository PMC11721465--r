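# deterministic 1:1 Langmuir response for one association/dissociation
# cycle; t measured from the start of each phase.
langmuir_association <- function(t, params, conc, R0 = 0) {
  k_obs <- params$k_on * conc + params$k_off
  R_eq <- if (k_obs > 0) params$R_max * params$k_on * conc / k_obs else R0
  R_eq + (R0 - R_eq) * exp(-k_obs * t)
}

langmuir_dissociation <- function(t, params, R_end) {
  R_end * exp(-params$k_off * t)
}

# shared time grid for one step
.step_grid <- function(duration, sample_rate) {
  seq(0, duration, by = 1 / sample_rate)
}

# assemble rows for one sensor: list of (step, t_local, signal) blocks;
# drift and noise apply to the running (global) time axis
.sensor_rows <- function(sensor_id, blocks, analyte, conc, role, design) {
  t0 <- 0
  rows <- lapply(blocks, function(b) {
    tg <- t0 + b$t
    t0 <<- tg[length(tg)] + 1 / design$sample_rate
    data.frame(sensor_id = sensor_id, step = b$step, time_s = tg,
               response_nm = b$signal + design$drift_rate * tg,
               analyte = analyte, concentration_M = conc, role = role,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.add_noise <- function(d, noise_sd) {
  if (noise_sd > 0)
    d$response_nm <- d$response_nm + stats::rnorm(nrow(d), 0, noise_sd)
  d
}

# deterministic assoc1+dissoc signal blocks for one concentration
.cycle_blocks <- function(params_list, fractions, conc, design) {
  ta <- .step_grid(design$t_assoc, design$sample_rate)
  td <- .step_grid(design$t_dissoc, design$sample_rate)
  tb <- .step_grid(design$t_baseline, design$sample_rate)
  assoc <- rep(0, length(ta)); dissoc <- rep(0, length(td))
  for (i in seq_along(params_list)) {
    if (fractions[i] == 0) next
    p <- params_list[[i]]
    pw <- kinetic_params(p$k_on, p$k_off, p$R_max * fractions[i])
    a <- langmuir_association(ta, pw, conc)
    assoc <- assoc + a
    dissoc <- dissoc + langmuir_dissociation(td, pw, a[length(a)])
  }
  list(list(step = "baseline", t = tb, signal = rep(0, length(tb))),
       list(step = "assoc1", t = ta, signal = assoc),
       list(step = "dissoc", t = td, signal = dissoc))
}

.simulate_plate <- function(params_list, fractions, design, analyte) {
  rows <- list()
  for (i in seq_along(design$concentrations)) {
    conc <- design$concentrations[i]
    rows[[length(rows) + 1]] <- .sensor_rows(
      sprintf("S%02d", i), .cycle_blocks(params_list, fractions, conc, design),
      analyte, conc, "sample", design)
    # pin reference: unloaded pin into this analyte concentration (no signal)
    rows[[length(rows) + 1]] <- .sensor_rows(
      sprintf("P%02d", i), .cycle_blocks(params_list, fractions, 0, design),
      analyte, conc, "reference_pin", design)
  }
  # buffer reference: loaded sensor into buffer (zero concentration)
  rows[[length(rows) + 1]] <- .sensor_rows(
    "REF", .cycle_blocks(params_list, fractions, 0, design),
    analyte, 0, "reference_buffer", design)
  d <- do.call(rbind, rows)
  d <- with_local_seed(design$seed, .add_noise(d, design$noise_sd))
  bli_plate(d, metadata = list(analyte = analyte,
                               truth = params_list, fractions = fractions,
                               design = design))
}

#' Simulate a 1:1 Langmuir sensorgram plate
#'
#' One sample sensorgram per concentration in the design, following
#' `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))` with
#' `R_eq = R_max C / (C + K_D)` during association and exponential decay
#' at `k_off` during dissociation.  Gaussian noise and linear baseline
#' drift are added after the deterministic signal, to every channel.
#' A zero-concentration buffer reference ("REF") and one pin reference
#' per concentration are always emitted so that [double_reference()] is
#' applicable downstream.
#'
#' @param params [kinetic_params()] ground truth.
#' @param design [assay_design()].
#' @param analyte Analyte name for metadata.
#' @return `bli_plate`.
#' @export
#' @examples
#' p <- kinetic_params(1e5, 1e-2)          # K_D = 100 nM
#' d <- assay_design(100e-9, t_assoc = 60, t_dissoc = 30)
#' pl <- simulate_1to1_sensorgram(p, d)
simulate_1to1_sensorgram <- function(params, design, analyte = "analyte") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "assay_design"))
  .simulate_plate(list(params), 1, design, analyte)
}

#' Simulate a biphasic (two-component) sensorgram plate
#'
#' The response is the weighted sum of two independent 1:1 components —
#' the simplest model of a heterogeneous (e.g. oligomeric) analyte whose
#' dissociation is visibly non-single-exponential.
#'
#' @param params_a,params_b [kinetic_params()] for the two components.
#' @param fractions Two non-negative weights summing to 1.
#' @inheritParams simulate_1to1_sensorgram
#' @return `bli_plate`.
#' @export
simulate_biphasic_sensorgram <- function(params_a, params_b,
                                         fractions = c(0.5, 0.5),
                                         design, analyte = "analyte") {
  stopifnot(inherits(params_a, "kinetic_params"),
            inherits(params_b, "kinetic_params"),
            inherits(design, "assay_design"))
  if (length(fractions) != 2 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("invalid design: fractions must be two non-negative weights summing to 1",
         call. = FALSE)
  .simulate_plate(list(params_a, params_b), fractions, design, analyte)
}

# right-hand side of the shared-site occupancy model:
# dth1/dt = kon1 C1 (1 - th1 - phi th2) - koff1 th1   (and symmetrically)
.seq_rhs <- function(th, k1, c1, o1, k2, c2, o2, phi) {
  c(k1 * c1 * (1 - th[1] - phi * th[2]) - o1 * th[1],
    k2 * c2 * (1 - th[2] - phi * th[1]) - o2 * th[2])
}

# adaptive Cash-Karp RK45 for the 2-state occupancy system; returns the
# state at each requested output time. atol on occupancies.
.rk45 <- function(th0, times, rhs, atol = 1e-10, rtol = 1e-8) {
  # Cash-Karp tableau
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  out <- matrix(NA_real_, length(times), 2)
  th <- th0
  t <- times[1]
  out[1, ] <- th
  h <- diff(range(times)) / 100 + 1e-12
  for (i in seq_along(times)[-1]) {
    tend <- times[i]
    while (t < tend - 1e-12) {
      h <- min(h, tend - t)
      k <- matrix(0, 6, 2)
      k[1, ] <- rhs(th)
      for (s in 2:6) {
        ths <- th + h * colSums(k[seq_len(s - 1), , drop = FALSE] * a[[s - 1]])
        k[s, ] <- rhs(ths)
      }
      th5 <- th + h * colSums(k * b5)
      th4 <- th + h * colSums(k * b4)
      err <- max(abs(th5 - th4) / (atol + rtol * pmax(abs(th), abs(th5))))
      if (err <= 1) {
        t <- t + h
        th <- th5
        h <- h * min(5, max(0.2, 0.9 * err^-0.2))
      } else {
        h <- h * max(0.1, 0.9 * err^-0.25)
      }
    }
    out[i, ] <- th
  }
  out
}

#' Simulate a sequential (competition) binding experiment
#'
#' Integrates the shared-site occupancy model
#' \deqn{d\theta_1/dt = k_{on,1} C_1(t) (1 - \theta_1 - \phi \theta_2) - k_{off,1} \theta_1}
#' (and symmetrically for ligand 2) across Association 1 (ligand 1
#' only), Dissociation (buffer) and Association 2 (ligand 2 only), with
#' reported response `R_max1 theta1 + R_max2 theta2`.  `phi = 0`
#' decouples the two ligands exactly; `phi = 1` is a fully shared site.
#' Emits a plate with one sample sensor plus buffer and pin references.
#'
#' @param design [sequential_design()].
#' @param sample_rate Samples per second.
#' @param noise_sd Gaussian noise SD (nm).
#' @param drift_rate Linear drift (nm/s).
#' @param seed Integer seed.
#' @param atol Absolute solver tolerance on occupancies.
#' @return `bli_plate` with steps baseline, assoc1, dissoc, assoc2; the
#'   solved occupancies are stored in `metadata$occupancy`.
#' @export
simulate_sequential <- function(design, sample_rate = 2, noise_sd = 0,
                                drift_rate = 0, seed = 1L, atol = 1e-10) {
  stopifnot(inherits(design, "sequential_design"))
  p1 <- design$params1; p2 <- design$params2
  phi <- design$overlap
  tb <- .step_grid(5, sample_rate)
  steps <- list(
    list(step = "baseline", t = tb, c1 = 0, c2 = 0),
    list(step = "assoc1", t = .step_grid(design$t_assoc1, sample_rate),
         c1 = design$conc1, c2 = 0),
    list(step = "dissoc", t = .step_grid(design$t_dissoc, sample_rate),
         c1 = 0, c2 = 0),
    list(step = "assoc2", t = .step_grid(design$t_assoc2, sample_rate),
         c1 = 0, c2 = design$conc2))
  th <- c(0, 0)
  blocks <- list()
  for (b in steps) {
    rhs <- function(x) .seq_rhs(x, p1$k_on, b$c1, p1$k_off,
                                p2$k_on, b$c2, p2$k_off, phi)
    sol <- .rk45(th, b$t, rhs, atol = atol)
    th <- sol[nrow(sol), ]
    blocks[[length(blocks) + 1]] <-
      list(step = b$step, t = b$t,
           signal = p1$R_max * sol[, 1] + p2$R_max * sol[, 2],
           theta = sol)
  }
  dsn <- list(sample_rate = sample_rate, drift_rate = drift_rate,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(dsn) <- "assay_design"
  rows <- list(.sensor_rows("S01", blocks, design$ligand2, design$conc2,
                            "sample", dsn))
  zero_blocks <- lapply(blocks, function(b)
    list(step = b$step, t = b$t, signal = rep(0, length(b$t))))
  rows[[2]] <- .sensor_rows("P01", zero_blocks, design$ligand2,
                            design$conc2, "reference_pin", dsn)
  rows[[3]] <- .sensor_rows("REF", zero_blocks, design$ligand2, 0,
                            "reference_buffer", dsn)
  d <- do.call(rbind, rows)
  d <- with_local_seed(seed, .add_noise(d, noise_sd))
  occupancy <- do.call(rbind, lapply(blocks, function(b)
    data.frame(step = b$step, time_s = b$t,
               theta1 = b$theta[, 1], theta2 = b$theta[, 2])))
  bli_plate(d, metadata = list(design = design, occupancy = occupancy))
}

#' Generate a planted complementary-hydropathy fixture
#'
#' Draws a random motif, then builds a target whose window at
#' `plant_position` is strongly complementary to it: each planted
#' residue is drawn uniformly from the residues of opposite hydropathy
#' sign whose index differs from the motif residue's by at least 4.6.
#' This guarantees that screening the pair finds a forward-orientation
#' hit at the planted position with percent match 100 and degree
#' >= 4.6/9 (about 0.51), i.e. a hit that clears both pass thresholds by
#' construction.  Remaining target residues are uniform over the
#' 20-letter alphabet.
#'
#' @param spec [planted_motif_spec()].
#' @return List with `motif` and `target` sequence strings and
#'   `plant_position`.
#' @export
plant_complementary_motif <- function(spec) {
  stopifnot(inherits(spec, "planted_motif_spec"))
  kd <- kyte_doolittle()
  ab <- names(kd)
  with_local_seed(spec$seed, {
    motif <- sample(ab, spec$motif_length, replace = TRUE)
    target <- sample(ab, spec$target_length, replace = TRUE)
    for (i in seq_len(spec$motif_length)) {
      h <- kd[motif[i]]
      opp <- ab[sign(kd) != sign(h) & abs(kd - h) >= 4.6]
      target[spec$plant_position + i - 1] <-
        opp[sample.int(length(opp), 1)]
    }
    list(motif = paste(motif, collapse = ""),
         target = paste(target, collapse = ""),
         plant_position = spec$plant_position)
  })
}
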