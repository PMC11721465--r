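# step-local time within a data.frame sensorgram step
.step_local <- function(sg, step) {
  d <- sg[sg$step == step, , drop = FALSE]
  if (!nrow(d)) stop("step '", step, "' not present", call. = FALSE)
  d$time_s <- d$time_s - d$time_s[1]
  d
}

#' Extract equilibrium (plateau) responses from a plate
#'
#' For each sample sensorgram, the plateau response `R_eq` is the mean
#' corrected response over the final `window_s` seconds of the
#' association step.  A plateau is flagged as possibly unequilibrated
#' when the observed rise indicates `k_obs * t_assoc < 3` (the step
#' ended well short of equilibrium, so `R_eq` underestimates the true
#' plateau).
#'
#' @param plate `bli_plate` (normally double-referenced).
#' @param window_s Averaging window (s), default 5; must not exceed the
#'   association step length.
#' @param step Association step label (default "assoc1").
#' @return data.frame with `sensor_id`, `concentration_M`, `R_eq`,
#'   `equilibrated`.
#' @export
extract_plateau <- function(plate, window_s = 5, step = "assoc1") {
  ids <- sensor_ids(plate, "sample")
  if (!length(ids)) ids <- sensor_ids(plate)
  out <- lapply(ids, function(sid) {
    sg <- .step_local(sensorgram(plate, sid), step)
    tmax <- sg$time_s[nrow(sg)]
    if (window_s > tmax + 1e-9)
      stop(sprintf("window (%g s) longer than step (%g s)", window_s, tmax),
           call. = FALSE)
    i <- sg$time_s >= tmax - window_s
    R_eq <- mean(sg$response_nm[i])
    # crude equilibration check: compare mid-step to end-of-step level
    mid <- mean(sg$response_nm[sg$time_s >= 0.45 * tmax &
                               sg$time_s <= 0.55 * tmax])
    equil <- if (abs(R_eq) < 1e-12) TRUE else (mid / R_eq) > 0.95
    data.frame(sensor_id = sid,
               concentration_M = sg$concentration_M[1],
               R_eq = R_eq, equilibrated = equil,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$concentration_M), ]
}

# SSE of the isotherm at fixed K_D with R_max profiled out analytically
.iso_sse <- function(log_kd, conc, resp) {
  x <- conc / (conc + exp(log_kd))
  rmax <- sum(resp * x) / sum(x * x)
  sum((resp - rmax * x)^2)
}

#' Fit the steady-state binding isotherm
#'
#' Least-squares fit of `R_eq(C) = R_max C / (C + K_D)` to plateau
#' responses.  `R_max` is profiled out analytically, leaving a 1-D
#' optimisation over `log K_D` run from 7 log-spaced starts spanning
#' `[min(C)/100, 100 max(C)]` (deterministic, no RNG).  All-zero
#' responses return a no-binding classification instead of a fit;
#' a saturated design (fitted K_D far below the lowest concentration)
#' or a failed optimisation is flagged, not raised.
#'
#' @param R_eq Plateau responses (nm), or the data.frame from
#'   [extract_plateau()].
#' @param concentrations Analyte concentrations (M); ignored when
#'   `R_eq` is an `extract_plateau()` table.
#' @param n_starts Number of log-spaced K_D starts (default 7).
#' @return `steady_state_fit` object with `K_D`, `R_max`, `K_D_se`,
#'   `R_max_se` (fit standard errors), fitted `R_eq`, `residual_norm`,
#'   `converged`, `flags`, and `class` ("binding" or
#'   "no_binding_detected").
#' @export
fit_steady_state <- function(R_eq, concentrations = NULL, n_starts = 7L) {
  if (is.data.frame(R_eq)) {
    concentrations <- R_eq$concentration_M
    R_eq <- R_eq$R_eq
  }
  stopifnot(length(R_eq) == length(concentrations))
  if (length(R_eq) < 4)
    stop("need >= 4 concentrations for a steady-state fit", call. = FALSE)
  if (any(!is.finite(R_eq)) || any(!is.finite(concentrations)))
    stop("non-finite input", call. = FALSE)
  if (all(abs(R_eq) < 1e-12))
    return(structure(list(K_D = NA_real_, R_max = NA_real_,
                          K_D_se = NA_real_, R_max_se = NA_real_,
                          R_eq = R_eq, concentrations = concentrations,
                          fitted = rep(0, length(R_eq)),
                          residual_norm = 0, converged = TRUE,
                          flags = character(0),
                          class = "no_binding_detected"),
                     class = "steady_state_fit"))
  lo <- log(min(concentrations) / 100)
  hi <- log(max(concentrations) * 100)
  starts <- seq(lo, hi, length.out = n_starts)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, .iso_sse, conc = concentrations, resp = R_eq,
                   method = "Brent", lower = lo - log(100), upper = hi + log(100),
                   control = list(reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  flags <- character(0)
  converged <- !is.null(best)
  if (!converged) {
    flags <- "optimisation_failed"
    kd <- NA_real_; rmax <- NA_real_; sse <- NA_real_
    kd_se <- NA_real_; rmax_se <- NA_real_
    fitted <- rep(NA_real_, length(R_eq))
  } else {
    kd <- exp(best$par)
    x <- concentrations / (concentrations + kd)
    rmax <- sum(R_eq * x) / sum(x * x)
    fitted <- rmax * x
    sse <- best$value
    if (kd < min(concentrations) / 50)
      flags <- c(flags, "ill_conditioned_saturated")
    if (kd > max(concentrations) * 50)
      flags <- c(flags, "ill_conditioned_weak")
    # fit SEs from the Jacobian at the optimum
    J <- cbind(x, -rmax * concentrations / (concentrations + kd)^2)
    df <- length(R_eq) - 2
    s2 <- if (df > 0) sse / df else NA_real_
    cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
    if (is.null(cv)) {
      flags <- c(flags, "singular_information")
      rmax_se <- NA_real_; kd_se <- NA_real_
    } else {
      rmax_se <- sqrt(cv[1, 1]); kd_se <- sqrt(cv[2, 2])
    }
  }
  structure(list(K_D = kd, R_max = rmax, K_D_se = kd_se, R_max_se = rmax_se,
                 R_eq = R_eq, concentrations = concentrations,
                 fitted = fitted, residual_norm = sqrt(sse),
                 converged = converged, flags = flags, class = "binding"),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  if (x$class == "no_binding_detected") {
    cat("Steady-state fit: no binding detected\n")
  } else {
    cat(sprintf("Steady-state fit: K_D = %.4g nM (se %.2g), R_max = %.4g nm%s\n",
                x$K_D * 1e9, x$K_D_se * 1e9, x$R_max,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

# global 1:1 SSE across all sample sensors of a plate, on the
# closed-form association/dissociation solutions
.kin_sse <- function(par, segs) {
  k_on <- exp(par[1]); k_off <- exp(par[2]); rmax <- exp(par[3])
  p <- list(k_on = k_on, k_off = k_off, R_max = rmax)
  sse <- 0
  for (s in segs) {
    a <- langmuir_association(s$ta, p, s$conc)
    sse <- sse + sum((s$ra - a)^2)
    d <- langmuir_dissociation(s$td, p, a[length(a)])
    sse <- sse + sum((s$rd - d)^2)
  }
  sse
}

# best single-exponential fit a*exp(-k t) to a dissociation trace;
# returns relative RMSE (residual / decay amplitude)
.single_exp_resid <- function(t, r) {
  amp <- r[1] - min(r)
  if (abs(r[1]) < 1e-12 || amp < 1e-9) return(0)
  sse_k <- function(log_k) {
    e <- exp(-exp(log_k) * t)
    a <- sum(r * e) / sum(e * e)
    sum((r - a * e)^2)
  }
  o <- stats::optim(log(0.01), sse_k, method = "Brent",
                    lower = log(1e-8), upper = log(10),
                    control = list(reltol = 1e-13))
  sqrt(o$value / length(r)) / max(abs(r[1]), amp)
}

#' Global 1:1 kinetic fit of a sensorgram plate
#'
#' Fits a single `(k_on, k_off, R_max)` jointly to the association and
#' dissociation segments of every sample sensorgram, by least squares
#' on the closed-form 1:1 solutions, optimising over log-parameters
#' (Nelder-Mead polished by BFGS) from 7 deterministic multi-starts over
#' a K_D grid spanning `[min(C)/100, 100 max(C)]`.  The dissociation
#' data are additionally checked against a single-exponential model: a
#' relative residual above `biphasic_tol` sets a `model_mismatch` flag
#' (the data are not 1:1, e.g. an oligomeric analyte).
#'
#' @param plate `bli_plate` (normally double-referenced), >= 3 sample
#'   concentrations with association and dissociation steps.
#' @param biphasic_tol Relative single-exponential residual above which
#'   the model-mismatch flag is set (default 0.02).
#' @param n_starts Number of K_D multi-starts (default 7).
#' @return `kinetic_fit` with `k_on`, `k_off`, `R_max`, derived `K_D`,
#'   `residual_norm`, `converged`, `flags`, `class`.
#' @export
fit_kinetic_global <- function(plate, biphasic_tol = 0.02, n_starts = 7L) {
  ids <- sensor_ids(plate, "sample")
  if (!length(ids)) ids <- sensor_ids(plate)
  segs <- list()
  concs <- numeric(0)
  for (sid in ids) {
    sg <- sensorgram(plate, sid)
    a <- .step_local(sg, "assoc1")
    d <- .step_local(sg, "dissoc")
    segs[[length(segs) + 1]] <- list(ta = a$time_s, ra = a$response_nm,
                                     td = d$time_s, rd = d$response_nm,
                                     conc = a$concentration_M[1])
    concs <- c(concs, a$concentration_M[1])
  }
  if (length(unique(concs)) < 3)
    stop("need >= 3 concentrations for a global kinetic fit", call. = FALSE)
  max_resp <- max(vapply(segs, function(s) max(abs(s$ra)), numeric(1)))
  if (max_resp < 1e-12)
    return(structure(list(k_on = NA_real_, k_off = NA_real_, R_max = NA_real_,
                          K_D = NA_real_, residual_norm = 0, converged = TRUE,
                          flags = character(0), class = "no_binding_detected"),
                     class = "kinetic_fit"))
  # biphasic diagnostic on the highest-concentration dissociation
  top <- segs[[which.max(concs)]]
  rel_resid <- .single_exp_resid(top$td, top$rd)
  flags <- if (rel_resid > biphasic_tol) "model_mismatch" else character(0)
  kd_starts <- exp(seq(log(min(concs) / 100), log(max(concs) * 100),
                       length.out = n_starts))
  best <- NULL
  for (kd0 in kd_starts) {
    par0 <- log(c(1e5, 1e5 * kd0, max_resp / 0.9))
    o <- tryCatch({
      o1 <- stats::optim(par0, .kin_sse, segs = segs, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      stats::optim(o1$par, .kin_sse, segs = segs, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(structure(list(k_on = NA_real_, k_off = NA_real_, R_max = NA_real_,
                          K_D = NA_real_, residual_norm = NA_real_,
                          converged = FALSE,
                          flags = c(flags, "optimisation_failed"),
                          class = "binding"),
                     class = "kinetic_fit"))
  k_on <- exp(best$par[1]); k_off <- exp(best$par[2])
  structure(list(k_on = k_on, k_off = k_off, R_max = exp(best$par[3]),
                 K_D = k_off / k_on, residual_norm = sqrt(best$value),
                 single_exp_resid = rel_resid,
                 converged = TRUE, flags = flags, class = "binding"),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$class == "no_binding_detected") {
    cat("Kinetic fit: no binding detected\n")
  } else {
    cat(sprintf("1:1 kinetic fit: k_on = %.4g, k_off = %.4g, K_D = %.4g nM%s\n",
                x$k_on, x$k_off, x$K_D * 1e9,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention
#' used for tabulated fold changes; base R's `round()` rounds half to
#' even.
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fold change in affinity between a variant and wild type
#'
#' The ratio `max(K_D_variant, K_D_wt) / min(K_D_variant, K_D_wt)`
#' (always >= 1) with a direction: a variant K_D above WT is a
#' *decrease* in affinity, below WT an *increase*.  `ratio_2dp` is the
#' ratio rounded half-up to 2 decimals for tabulation.
#'
#' @param K_D_variant,K_D_wt Positive dissociation constants (same units).
#' @return `fold_change` object with `ratio`, `ratio_2dp`, `direction`.
#' @export
#' @examples
#' fold_change(55060, 281)  # 195.94, decrease
fold_change <- function(K_D_variant, K_D_wt) {
  if (!is.finite(K_D_variant) || !is.finite(K_D_wt) ||
      K_D_variant <= 0 || K_D_wt <= 0)
    stop("K_D values must be positive and finite", call. = FALSE)
  ratio <- max(K_D_variant, K_D_wt) / min(K_D_variant, K_D_wt)
  direction <- if (K_D_variant > K_D_wt) "decrease"
               else if (K_D_variant < K_D_wt) "increase"
               else "none"
  structure(list(ratio = ratio, ratio_2dp = round_half_up(ratio, 2),
                 direction = direction),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  arrow <- switch(x$direction, decrease = "down", increase = "up", "=")
  cat(sprintf("fold change: %.2f (%s)\n", x$ratio_2dp, arrow))
  invisible(x)
}

#' Classify binding from plateau responses
#'
#' `no_binding_detected` when the top-concentration plateau is below
#' `theta_resp` (default 0.02 nm, or 3x the known noise SD when that is
#' larger); `decreased_binding` when binding is detected but the
#' top-concentration plateau is below fraction `theta_frac` (default
#' 0.5) of the wild-type plateau at the same concentration; otherwise
#' `binding`.
#'
#' @param plate `bli_plate` (double-referenced) for the variant.
#' @param wt_plate Optional WT `bli_plate` for the decreased-binding
#'   comparison.
#' @param theta_resp Response threshold (nm).
#' @param theta_frac Fraction-of-WT threshold.
#' @param noise_sd Known noise SD (nm), if any.
#' @param window_s Plateau window (s).
#' @return One of "binding", "decreased_binding", "no_binding_detected".
#' @export
classify_binding <- function(plate, wt_plate = NULL, theta_resp = 0.02,
                             theta_frac = 0.5, noise_sd = NULL,
                             window_s = 5) {
  if (!is.null(noise_sd)) theta_resp <- max(theta_resp, 3 * noise_sd)
  pl <- extract_plateau(plate, window_s = window_s)
  top <- pl$R_eq[which.max(pl$concentration_M)]
  if (top < theta_resp) return("no_binding_detected")
  if (!is.null(wt_plate)) {
    wt <- extract_plateau(wt_plate, window_s = window_s)
    wt_top <- wt$R_eq[which.max(wt$concentration_M)]
    if (wt_top > 0 && top < theta_frac * wt_top) return("decreased_binding")
  }
  "binding"
}

#' Tabulate fit results as a TSV-ready data.frame
#'
#' @param variant,ligand Labels.
#' @param fit `steady_state_fit` or `kinetic_fit`.
#' @param wt_K_D Optional WT K_D (M) for fold-change columns.
#' @return One-row data.frame with columns `variant, ligand, method,
#'   KD_M, KD_se, kon, koff, Rmax, fold_vs_wt, direction, class, flags`.
#' @export
fit_row <- function(variant, ligand, fit, wt_K_D = NULL) {
  meth <- if (inherits(fit, "kinetic_fit")) "kinetic" else "steady_state"
  fc <- if (!is.null(wt_K_D) && is.finite(fit$K_D) && fit$class == "binding")
    fold_change(fit$K_D, wt_K_D) else NULL
  data.frame(variant = variant, ligand = ligand, method = meth,
             KD_M = fit$K_D,
             KD_se = if (!is.null(fit$K_D_se)) fit$K_D_se else NA_real_,
             kon = if (!is.null(fit$k_on)) fit$k_on else NA_real_,
             koff = if (!is.null(fit$k_off)) fit$k_off else NA_real_,
             Rmax = fit$R_max,
             fold_vs_wt = if (is.null(fc)) NA_real_ else fc$ratio_2dp,
             direction = if (is.null(fc)) NA_character_ else fc$direction,
             class = fit$class,
             flags = paste(fit$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
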