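# canonical step order for all plates
.step_levels <- c("baseline", "assoc1", "dissoc", "assoc2")

.plate_cols <- c("sensor_id", "step", "time_s", "response_nm",
                 "analyte", "concentration_M", "role")

#' Construct a sensorgram plate
#'
#' A plate is a long-format table of sensorgram samples — one row per
#' (sensor, step, time point) — plus free-form metadata.  Columns:
#' `sensor_id`, `step` (baseline | assoc1 | dissoc | assoc2), `time_s`,
#' `response_nm`, `analyte`, `concentration_M`, `role` (sample |
#' reference_buffer | reference_pin).  Rows are canonically sorted by
#' (sensor, step order, time); time must be strictly increasing within
#' each sensor/step and responses finite.
#'
#' @param data data.frame with the columns above.
#' @param metadata Named list (ligand names, buffer, provenance, ...).
#' @return `bli_plate` object.
#' @export
bli_plate <- function(data, metadata = list()) {
  missing_cols <- setdiff(.plate_cols, names(data))
  if (length(missing_cols))
    stop("plate format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- data[, .plate_cols]
  bad_step <- setdiff(unique(data$step), .step_levels)
  if (length(bad_step))
    stop("plate format error: unknown step label(s) ",
         paste(bad_step, collapse = ", "), call. = FALSE)
  if (any(!is.finite(data$response_nm)))
    stop("plate format error: non-finite response", call. = FALSE)
  ord <- order(data$sensor_id, match(data$step, .step_levels), data$time_s)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  # strict monotonicity of time within each sensor/step
  key <- paste(data$sensor_id, data$step, sep = "\r")
  dup <- which(diff(data$time_s) <= 0 & key[-1] == key[-length(key)])
  if (length(dup))
    stop(sprintf(
      "plate format error: time not strictly increasing in sensor '%s' step '%s'",
      data$sensor_id[dup[1] + 1], data$step[dup[1] + 1]), call. = FALSE)
  structure(list(data = data, metadata = metadata), class = "bli_plate")
}

#' @export
print.bli_plate <- function(x, ...) {
  d <- x$data
  cat(sprintf("BLI plate: %d sensors (%d sample, %d reference), steps: %s\n",
              length(unique(d$sensor_id)),
              length(unique(d$sensor_id[d$role == "sample"])),
              length(unique(d$sensor_id[d$role != "sample"])),
              paste(intersect(.step_levels, unique(d$step)), collapse = " > ")))
  invisible(x)
}

#' Extract one sensorgram from a plate
#'
#' @param plate `bli_plate`.
#' @param sensor_id Sensor identifier.
#' @return data.frame of that sensor's rows (a single sensorgram).
#' @export
sensorgram <- function(plate, sensor_id) {
  d <- plate$data[plate$data$sensor_id == sensor_id, , drop = FALSE]
  if (!nrow(d)) stop("unknown sensor '", sensor_id, "'", call. = FALSE)
  rownames(d) <- NULL
  d
}

#' List sensor ids by role
#' @param plate `bli_plate`.
#' @param role Optional filter: sample, reference_buffer or reference_pin.
#' @return Character vector of sensor ids.
#' @export
sensor_ids <- function(plate, role = NULL) {
  d <- plate$data
  if (!is.null(role)) d <- d[d$role == role, , drop = FALSE]
  unique(d$sensor_id)
}

#' Write a plate to CSV / read a plate from CSV
#'
#' The CSV mirrors the plate schema column-for-column; writing then
#' reading reproduces responses exactly (full double precision) and row
#' order is canonicalised on read, so shuffled files load identically.
#' Readers tolerate Windows line endings and a UTF-8 byte-order mark.
#'
#' @param plate `bli_plate`.
#' @param path File path.
#' @return `read_plate` returns a `bli_plate`; `write_plate` returns
#'   `path` invisibly.
#' @export
write_plate <- function(plate, path) {
  d <- plate$data
  d$time_s <- format(d$time_s, digits = 17, trim = TRUE, scientific = FALSE)
  d$response_nm <- format(d$response_nm, digits = 17, trim = TRUE)
  d$concentration_M <- format(d$concentration_M, digits = 17, trim = TRUE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8-BOM")
  missing_cols <- setdiff(.plate_cols, names(d))
  if (length(missing_cols))
    stop("plate format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bli_plate(d, metadata = list(source = path))
}

# interpolate a reference trace onto the sample grid, per step
.interp_ref <- function(ref, step, times, sensor_id) {
  r <- ref[ref$step == step, , drop = FALSE]
  if (!nrow(r))
    stop(sprintf("reference missing for step '%s' (sample sensor '%s')",
                 step, sensor_id), call. = FALSE)
  eps <- 1e-9
  if (min(times) < min(r$time_s) - eps || max(times) > max(r$time_s) + eps)
    stop(sprintf(
      "interpolation range error: reference grid does not cover sample grid in step '%s'",
      step), call. = FALSE)
  stats::approx(r$time_s, r$response_nm, xout = times, rule = 2)$y
}

#' Double-reference subtraction
#'
#' For each sample sensorgram subtracts (a) the loaded-sensor-into-buffer
#' reference and (b) the biotin-loaded-pin-into-ligand reference,
#' step by step, after linear interpolation of each reference onto the
#' sample's time grid:
#' `corrected = sample - reference_buffer - reference_pin`.
#'
#' Pin references are matched to samples by (analyte, concentration)
#' when several are present; a single pin reference is used for all
#' samples.  The buffer reference is shared across the plate.
#'
#' @param plate `bli_plate` containing sample and reference traces.
#' @return `bli_plate` holding only the corrected sample sensorgrams
#'   (step boundaries and sample counts preserved).
#' @export
double_reference <- function(plate) {
  d <- plate$data
  buf_ids <- unique(d$sensor_id[d$role == "reference_buffer"])
  pin_ids <- unique(d$sensor_id[d$role == "reference_pin"])
  if (!length(buf_ids))
    stop("reference missing: no reference_buffer trace in plate", call. = FALSE)
  if (!length(pin_ids))
    stop("reference missing: no reference_pin trace in plate", call. = FALSE)
  buf <- d[d$sensor_id == buf_ids[1], , drop = FALSE]
  pins <- d[d$role == "reference_pin", , drop = FALSE]
  out <- lapply(sensor_ids(plate, "sample"), function(sid) {
    s <- d[d$sensor_id == sid, , drop = FALSE]
    # pin matched on analyte + concentration, else the only pin trace
    pm <- pins[pins$analyte == s$analyte[1] &
               pins$concentration_M == s$concentration_M[1], , drop = FALSE]
    if (!nrow(pm)) {
      if (length(pin_ids) == 1L) pm <- pins
      else stop(sprintf(
        "reference missing: no reference_pin for analyte '%s' at %g M",
        s$analyte[1], s$concentration_M[1]), call. = FALSE)
    }
    pm <- pm[pm$sensor_id == pm$sensor_id[1], , drop = FALSE]
    for (st in unique(s$step)) {
      i <- s$step == st
      s$response_nm[i] <- s$response_nm[i] -
        .interp_ref(buf, st, s$time_s[i], sid) -
        .interp_ref(pm, st, s$time_s[i], sid)
    }
    s
  })
  md <- plate$metadata
  md$double_referenced <- TRUE
  bli_plate(do.call(rbind, out), metadata = md)
}

#' Re-zero a step at its first sample
#'
#' Shifts one step of a sensorgram (or of every sample sensorgram of a
#' plate) so its first sample maps to (0 s, 0 nm); other steps are
#' untouched.  Idempotent.
#'
#' @param x Sensorgram data.frame or `bli_plate`.
#' @param step_label One of baseline, assoc1, dissoc, assoc2.
#' @return Same type as `x`.
#' @export
align_to_step_start <- function(x, step_label) {
  if (inherits(x, "bli_plate")) {
    d <- x$data
    for (sid in unique(d$sensor_id)) {
      i <- d$sensor_id == sid
      d[i, ] <- align_to_step_start(d[i, , drop = FALSE], step_label)
    }
    return(bli_plate(d, x$metadata))
  }
  i <- x$step == step_label
  if (!any(i)) stop("unknown step label '", step_label, "'", call. = FALSE)
  x$time_s[i] <- x$time_s[i] - x$time_s[i][1]
  x$response_nm[i] <- x$response_nm[i] - x$response_nm[i][1]
  x
}
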