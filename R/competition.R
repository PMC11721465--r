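#' Association-2 response gain of a sequential experiment
#'
#' The binding signal of the second ligand, quantitated as (response at
#' the end of Association 2) minus (response at the beginning of
#' Association 2).  By default each endpoint is the median of the 3
#' samples nearest the step boundary, a guard against single-sample
#' noise spikes; `guard = FALSE` uses the literal first/last samples.
#'
#' @param x Sensorgram data.frame or a `bli_plate` (its first sample
#'   sensor is used).
#' @param guard Use 3-sample median endpoints (default TRUE).
#' @return Gain in nm.
#' @export
association2_gain <- function(x, guard = TRUE) {
  if (inherits(x, "bli_plate")) {
    ids <- sensor_ids(x, "sample")
    if (!length(ids)) ids <- sensor_ids(x)
    x <- sensorgram(x, ids[1])
  }
  d <- x[x$step == "assoc2", , drop = FALSE]
  if (!nrow(d)) stop("no assoc2 step in sensorgram", call. = FALSE)
  n <- nrow(d)
  k <- if (guard) min(3L, n) else 1L
  stats::median(d$response_nm[(n - k + 1):n]) -
    stats::median(d$response_nm[1:k])
}

#' Percent decrease of the competed Association-2 signal
#'
#' `100 (gain_alone - gain_competed) / gain_alone`.  Enhancement (a
#' larger competed gain) yields a negative value; it is not clipped.
#' A non-positive baseline gain is an undefined comparison and is
#' flagged rather than computed.
#'
#' @param gain_alone Association-2 gain of the ligand-2-alone arm (nm).
#' @param gain_competed Gain with the competitor pre-bound (nm).
#' @param digits Rounding for the reported value (default 1 decimal).
#' @return Percent decrease, or `NA` with a warning-free
#'   `"undefined_baseline"` attribute when `gain_alone <= 0`.
#' @export
#' @examples
#' percent_decrease(0.30, 0.10)  # 66.7
percent_decrease <- function(gain_alone, gain_competed, digits = 1) {
  if (!is.finite(gain_alone) || gain_alone <= 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined_baseline"
    return(out)
  }
  round_half_up(100 * (gain_alone - gain_competed) / gain_alone, digits)
}

#' Quantify a sequential competition pair
#'
#' Pairs the no-competitor arm with the competed arm of a sequential
#' experiment, computes each Association-2 gain and the percent
#' decrease, and carries the design metadata.  Both arms must probe the
#' same second ligand at the same concentration.
#'
#' @param plate_alone `bli_plate` of the ligand-2-alone arm.
#' @param plate_competed `bli_plate` with the competitor pre-bound.
#' @param guard Endpoint guard, see [association2_gain()].
#' @return `competition_result` with `delta_R_alone`,
#'   `delta_R_competed`, `percent_decrease`, `ligand1`, `ligand2`,
#'   `conc1_M`, `conc2_M`, `flags`.
#' @export
run_competition_pair <- function(plate_alone, plate_competed, guard = TRUE) {
  da <- plate_alone$data; dc <- plate_competed$data
  l2a <- unique(da$analyte[da$role == "sample"])[1]
  l2c <- unique(dc$analyte[dc$role == "sample"])[1]
  c2a <- unique(da$concentration_M[da$role == "sample"])[1]
  c2c <- unique(dc$concentration_M[dc$role == "sample"])[1]
  if (!identical(l2a, l2c) || !isTRUE(all.equal(c2a, c2c)))
    stop("design mismatch: arms probe different second ligands or concentrations",
         call. = FALSE)
  ga <- association2_gain(plate_alone, guard = guard)
  gc_ <- association2_gain(plate_competed, guard = guard)
  pd <- percent_decrease(ga, gc_)
  des <- plate_competed$metadata$design
  structure(list(delta_R_alone = ga, delta_R_competed = gc_,
                 percent_decrease = as.numeric(pd),
                 ligand1 = if (!is.null(des)) des$ligand1 else NA_character_,
                 ligand2 = l2a,
                 conc1_M = if (!is.null(des)) des$conc1 else NA_real_,
                 conc2_M = c2a,
                 flags = attr(pd, "flag") %||% character(0)),
            class = "competition_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf(
    "Competition: %s pre-bound vs %s (%.3g M): gain %.3g -> %.3g nm, %.1f%% decrease\n",
    x$ligand1, x$ligand2, x$conc2_M, x$delta_R_alone, x$delta_R_competed,
    x$percent_decrease))
  invisible(x)
}

#' Tabulate competition results
#' @param results List of `competition_result` objects.
#' @return data.frame with columns `ligand1, conc1_M, ligand2, conc2_M,
#'   gain_alone_nm, gain_competed_nm, percent_decrease`.
#' @export
competition_table <- function(results) {
  if (inherits(results, "competition_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x)
    data.frame(ligand1 = x$ligand1, conc1_M = x$conc1_M,
               ligand2 = x$ligand2, conc2_M = x$conc2_M,
               gain_alone_nm = x$delta_R_alone,
               gain_competed_nm = x$delta_R_competed,
               percent_decrease = x$percent_decrease,
               stringsAsFactors = FALSE)))
}
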