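# Waveform container, unit conversion and delimited-text I/O.
#
# Channels live on disk in the clinical units the instruments report
# (mmHg, L/min, mL); every energy computation converts to SI first so that
# stroke work and power integrals come out in Joules and Watts.

#' Construct a synchronized multichannel waveform record
#'
#' A `waveform_record` holds one measurement: five synchronized channels
#' sampled at a common rate, plus metadata identifying the animal, the
#' experimental condition and the measurement index.
#'
#' @param ecg ECG channel (arbitrary units); only R-wave timing is used.
#' @param p_ao Aortic pressure (mmHg), micromanometer site.
#' @param q_ao Aortic flow (L/min), transit-time probe site.
#' @param p_lv Left-ventricular pressure (mmHg), conductance catheter.
#' @param v_lv Left-ventricular volume (mL), conductance catheter (raw,
#'   uncalibrated).
#' @param fs Sampling rate in Hz (> 0).
#' @param meta Named list of metadata; typically `animal_id`, `condition`,
#'   `measurement_index`, `seed`.
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(ecg, p_ao, q_ao, p_lv, v_lv, fs,
                            meta = list()) {
  chans <- list(ecg = ecg, p_ao = p_ao, q_ao = q_ao, p_lv = p_lv,
                v_lv = v_lv)
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("waveform_record: channel lengths differ (",
         paste(names(lens), lens, sep = "=", collapse = ", "), ")")
  if (lens[[1L]] < 2L)
    stop("waveform_record: channels must have length >= 2")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("waveform_record: fs must be a single positive number")
  for (nm in names(chans)) {
    if (anyNA(chans[[nm]]))
      stop("waveform_record: channel '", nm, "' contains missing samples")
  }
  structure(c(lapply(chans, as.numeric),
              list(fs = as.numeric(fs), meta = meta)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$ecg)
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.2f s)\n",
              n, x$fs, n / x$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","),
                                character(1)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a waveform record
#' @param x A `waveform_record`.
#' @export
record_length <- function(x) {
  stopifnot(inherits(x, "waveform_record"))
  length(x$ecg)
}

#' Convert a clinical-unit value to SI
#'
#' mmHg becomes Pa (x 133.322), L/min becomes m^3/s (/ 60000) and mL becomes
#' m^3 (x 1e-6), so that pressure x flow is Watts and pressure x volume is
#' Joules.
#'
#' @param value Numeric vector.
#' @param unit One of `"mmHg"`, `"L/min"`, `"mL"`.
#' @return Numeric vector in SI units.
#' @examples
#' to_si(1, "mmHg")            # 133.322 Pa
#' to_si(100, "mmHg") * to_si(5, "L/min")  # aortic power in W
#' @export
to_si <- function(value, unit) {
  switch(unit,
         "mmHg"  = value * 133.322,
         "L/min" = value / 60000,
         "mL"    = value * 1e-6,
         stop("to_si: unknown unit '", unit,
              "' (expected mmHg, L/min or mL)"))
}

#' Convert an SI value back to clinical units
#'
#' Exact inverse of [to_si()].
#' @inheritParams to_si
#' @export
from_si <- function(value, unit) {
  switch(unit,
         "mmHg"  = value / 133.322,
         "L/min" = value * 60000,
         "mL"    = value / 1e-6,
         stop("from_si: unknown unit '", unit,
              "' (expected mmHg, L/min or mL)"))
}

.record_columns <- c("time_s", "ecg", "p_ao_mmHg", "q_ao_lpm", "p_lv_mmHg",
                     "v_lv_ml")

#' Write a waveform record to delimited text plus a JSON sidecar
#'
#' The CSV holds columns `time_s, ecg, p_ao_mmHg, q_ao_lpm, p_lv_mmHg,
#' v_lv_ml`; sampling rate and metadata go to `<path>.meta.json`. Values are
#' written with enough digits that [read_record()] reproduces the channels to
#' better than 1e-9 relative.
#'
#' @param record A `waveform_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  n <- record_length(record)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / record$fs,
    ecg = record$ecg,
    p_ao_mmHg = record$p_ao,
    q_ao_lpm = record$q_ao,
    p_lv_mmHg = record$p_lv,
    v_lv_ml = record$v_lv)
  data.table::fwrite(dt, path)
  jsonlite::write_json(c(list(fs = record$fs), record$meta),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a waveform record written by [write_record()]
#'
#' @param path CSV path; `<path>.meta.json` must exist alongside.
#' @return A `waveform_record`.
#' @export
read_record <- function(path) {
  if (!file.exists(path))
    stop("read_record: no such file: ", path)
  side <- paste0(path, ".meta.json")
  if (!file.exists(side))
    stop("read_record: missing metadata sidecar: ", side)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(.record_columns, names(dt))
  if (length(missing_cols))
    stop("read_record: format error, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("read_record: format error, sidecar lacks field 'fs'")
  fs <- as.numeric(meta$fs)
  meta$fs <- NULL
  waveform_record(ecg = dt$ecg, p_ao = dt$p_ao_mmHg, q_ao = dt$q_ao_lpm,
                  p_lv = dt$p_lv_mmHg, v_lv = dt$v_lv_ml, fs = fs,
                  meta = meta)
}

.beat_columns <- c("animal_id", "condition", "measurement_index",
                   "cycle_index", "sw_J", "pwr_integral_J", "sv_mL",
                   "co_Lmin", "map_mmHg", "cpo_W")

#' Write / read a beat table
#'
#' A beat table holds one row per cardiac cycle with the derived scalars:
#' stroke work `sw_J`, cardiac power integral `pwr_integral_J`, stroke
#' volume `sv_mL`, cardiac output `co_Lmin`, mean arterial pressure
#' `map_mmHg` and cardiac power output `cpo_W`, keyed by
#' (animal, condition, measurement, cycle).
#'
#' @param beats A `data.table` containing at least the canonical columns.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a `data.table` for the reader.
#' @export
write_beat_table <- function(beats, path) {
  missing_cols <- setdiff(.beat_columns, names(beats))
  if (length(missing_cols))
    stop("write_beat_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- beats[, paste(animal_id, condition, measurement_index, cycle_index)]
  if (anyDuplicated(key))
    stop("write_beat_table: duplicate (animal, condition, measurement, cycle) keys")
  data.table::fwrite(beats, path)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path))
    stop("read_beat_table: no such file: ", path)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(.beat_columns, names(dt))
  if (length(missing_cols))
    stop("read_beat_table: format error, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dt
}
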