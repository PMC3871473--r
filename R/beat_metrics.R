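# Per-beat energy metrics: cycle segmentation, the cardiac power (PWR)
# curve and its per-cycle integral, PV-loop stroke work, alpha calibration,
# CPO and the oscillatory power fraction.
#
# Conventions (fixed for reproducibility):
#  - cycles run R peak to next R peak, half-open [Rk, Rk+1), 1-based indices;
#  - integrals use the trapezoidal rule at the record's sampling rate,
#    including the closing sample at the span end when it exists;
#  - stroke work is the absolute shoelace area of the (V, P) polygon, so it
#    is invariant to traversal direction and starting sample;
#  - PWR is never floored at zero: small negative diastolic flow (Windkessel
#    back-flow) integrates as measured.

#' Detect R peaks in a synthetic or recorded ECG channel
#'
#' Threshold-plus-local-maximum detector with a 200 ms refractory period:
#' candidate samples are local maxima at or above half the channel maximum;
#' candidates are accepted greedily by amplitude, discarding any within the
#' refractory window of an accepted peak.
#'
#' @param ecg Numeric ECG vector, at least one second long.
#' @param fs Sampling rate (Hz).
#' @return Strictly increasing 1-based sample indices of R peaks.
#' @export
detect_r_peaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n < fs) stop("detect_r_peaks: need at least 1 s of signal")
  m <- max(ecg)
  if (!is.finite(m) || m <= 0 || m <= min(ecg) + 1e-12)
    stop("detect_r_peaks: no peaks found (flat or non-positive signal)")
  thr <- 0.5 * m
  # local maxima (plateau-tolerant via >=) above threshold
  is_max <- c(FALSE, ecg[2:(n - 1)] >= ecg[1:(n - 2)] &
                ecg[2:(n - 1)] >= ecg[3:n], FALSE)
  # endpoints can carry a peak whose flank was cut off
  is_max[1] <- ecg[1] >= ecg[2]
  is_max[n] <- ecg[n] >= ecg[n - 1]
  cand <- which(is_max & ecg >= thr)
  if (!length(cand)) stop("detect_r_peaks: no peaks found above threshold")
  refr <- round(0.2 * fs)
  cand <- cand[order(ecg[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) > refr)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Delimit cardiac cycles between consecutive R peaks
#'
#' Emits one half-open span `[Rk, Rk+1)` per consecutive peak pair. If the
#' record continues past the last peak by at least one near-full RR interval
#' (within 2% of the median RR), a final span ending at the record boundary
#' is emitted too, so that a record whose peaks bracket all cycles yields one
#' span per cycle; genuinely partial trailing cycles are discarded.
#'
#' @param record A [waveform_record()] (only its length is used).
#' @param r_peaks Strictly increasing 1-based peak indices (>= 2 of them).
#' @return A `data.frame` with 1-based inclusive `start` and exclusive `end`.
#' @export
segment_cycles <- function(record, r_peaks) {
  stopifnot(inherits(record, "waveform_record"))
  if (length(r_peaks) < 2)
    stop("segment_cycles: need at least 2 R peaks")
  if (any(diff(r_peaks) <= 0))
    stop("segment_cycles: r_peaks must be strictly increasing")
  n <- record_length(record)
  starts <- r_peaks[-length(r_peaks)]
  ends <- r_peaks[-1]
  rr <- stats::median(diff(r_peaks))
  last <- r_peaks[length(r_peaks)]
  if (last + rr <= n + 1 + 0.02 * rr) {
    starts <- c(starts, last)
    ends <- c(ends, min(last + rr, n + 1))
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Instantaneous cardiac power from aortic pressure and flow
#'
#' `PWR[i] = p_ao[i] * q_ao[i]` after conversion to SI, in Watts. Negative
#' diastolic flow is kept as measured.
#'
#' @param p_ao Aortic pressure (mmHg).
#' @param q_ao Aortic flow (L/min).
#' @return Power series in Watts.
#' @export
power_curve <- function(p_ao, q_ao) {
  if (length(p_ao) != length(q_ao))
    stop("power_curve: pressure and flow lengths differ")
  to_si(p_ao, "mmHg") * to_si(q_ao, "L/min")
}

# trapezoid over samples idx at spacing 1/fs
.trapz <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("trapezoidal integral needs >= 2 samples")
  sum((x[-1] + x[-n]) / 2) / fs
}

# samples belonging to span [start, end): the closing sample `end` is
# included in time integrals when it exists so the integral covers the full
# cycle duration
.span_idx_integral <- function(span, n) {
  if (span$end <= span$start) stop("empty cycle span")
  span$start:min(span$end, n)
}

.span_idx_loop <- function(span, n) {
  if (span$end - span$start < 3) stop("degenerate cycle span (< 3 samples)")
  span$start:min(span$end - 1, n)
}

#' Per-cycle time integral of the power curve
#'
#' Trapezoidal integral of the PWR series over one cycle span; the energy
#' (Joules) delivered to the proximal aorta during that beat.
#'
#' @param pwr Power series in Watts (from [power_curve()]).
#' @param span One row of [segment_cycles()] output (list/row with `start`,
#'   `end`).
#' @param fs Sampling rate (Hz).
#' @return Energy in Joules.
#' @export
pwr_integral <- function(pwr, span, fs) {
  idx <- .span_idx_integral(span, length(pwr))
  .trapz(pwr[idx], fs)
}

#' Stroke work as the area of the pressure-volume loop
#'
#' Absolute shoelace (polygon) area of the `(v_lv, p_lv)` loop over one
#' cycle, converted to SI (Joules). Invariant to the starting sample within
#' the cycle and to traversal direction.
#'
#' @param p_lv LV pressure (mmHg).
#' @param v_lv LV volume (mL), calibrated if a gain correction applies.
#' @param span One cycle span (`start` inclusive, `end` exclusive).
#' @return Stroke work in Joules.
#' @export
stroke_work <- function(p_lv, v_lv, span) {
  idx <- .span_idx_loop(span, length(p_lv))
  p <- to_si(p_lv[idx], "mmHg")
  v <- to_si(v_lv[idx], "mL")
  j <- c(seq_along(idx)[-1], 1L)  # cyclic successor
  abs(sum(v * p[j] - v[j] * p)) / 2
}

#' Alpha calibration of conductance stroke volume
#'
#' The per-animal gain that reconciles conductance-catheter stroke volumes
#' with transit-time flow-probe stroke volumes over baseline cycles:
#' `alpha = mean(sv_conductance) / mean(sv_flowprobe)`. The calibrated
#' volume channel is `v_raw / alpha`. Gain-only by design: PV-loop area is
#' invariant to a volume offset, so no offset term is identifiable or
#' needed.
#'
#' @param sv_conductance_mL Per-cycle stroke volumes from the (raw)
#'   conductance volume channel (max minus min), baseline cycles only.
#' @param sv_flowprobe_mL Per-cycle stroke volumes from integrated aortic
#'   flow, same cycles.
#' @param source_condition Label recorded in the result (default
#'   `"baseline"`).
#' @return List of class `alpha_factor`: `alpha`, `n_cycles_used`,
#'   `source_condition`.
#' @export
alpha_calibration <- function(sv_conductance_mL, sv_flowprobe_mL,
                              source_condition = "baseline") {
  if (length(sv_conductance_mL) < 1 ||
      length(sv_conductance_mL) != length(sv_flowprobe_mL))
    stop("alpha_calibration: need >= 1 paired baseline cycle")
  if (any(sv_conductance_mL <= 0) || any(sv_flowprobe_mL <= 0))
    stop("alpha_calibration: nonpositive stroke volume")
  structure(list(alpha = mean(sv_conductance_mL) / mean(sv_flowprobe_mL),
                 n_cycles_used = length(sv_conductance_mL),
                 source_condition = source_condition),
            class = "alpha_factor")
}

#' Per-beat scalar summary of a record
#'
#' For each cycle span: stroke work on the calibrated volume channel,
#' the PWR integral, stroke volume from integrated aortic flow, mean
#' arterial pressure, cardiac output and cardiac power output
#' (`CPO = MAP x CO` in SI). The raw conductance stroke volume
#' (`sv_cond_raw_mL`, pre-calibration) is included for calibration use.
#'
#' @param record A (measured) [waveform_record()].
#' @param spans Output of [segment_cycles()].
#' @param alpha An `alpha_factor` from [alpha_calibration()], or `NULL` for
#'   an uncalibrated (gain 1) summary.
#' @return A `data.table` with one row per span.
#' @export
beat_summary <- function(record, spans, alpha = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  a <- if (is.null(alpha)) 1 else alpha$alpha
  fs <- record$fs
  n <- record_length(record)
  pwr <- power_curve(record$p_ao, record$q_ao)
  meta <- record$meta
  rows <- lapply(seq_len(nrow(spans)), function(k) {
    span <- spans[k, ]
    idx <- .span_idx_integral(span, n)
    dur <- (length(idx) - 1) / fs
    q_mls <- record$q_ao[idx] * 1000 / 60   # L/min -> mL/s
    sv <- .trapz(q_mls, fs)
    map <- mean(record$p_ao[idx])
    co <- sv / dur * 60 / 1000              # mL/beat -> L/min
    data.table::data.table(
      animal_id = meta$animal_id %||% NA_character_,
      condition = meta$condition %||% NA_character_,
      measurement_index = meta$measurement_index %||% NA_integer_,
      cycle_index = k,
      sw_J = stroke_work(record$p_lv, record$v_lv / a, span),
      pwr_integral_J = pwr_integral(pwr, span, fs),
      sv_mL = sv,
      co_Lmin = co,
      map_mmHg = map,
      cpo_W = to_si(map, "mmHg") * to_si(co, "L/min"),
      sv_cond_raw_mL = max(record$v_lv[idx]) - min(record$v_lv[idx]),
      duration_s = dur)
  })
  data.table::rbindlist(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oscillatory fraction of total hydraulic power
#'
#' Total power is the cycle-averaged PWR integral per unit time; steady
#' power is MAP times mean flow (both in SI). The oscillatory fraction is
#' `1 - steady / total`, clipped at 0 for numerically tiny negatives. In
#' large mammals the oscillatory component is about 15% of the total.
#'
#' @param record A [waveform_record()].
#' @param spans Cycle spans (>= 1).
#' @return Unitless fraction in `[0, 1)`.
#' @export
oscillatory_fraction <- function(record, spans) {
  if (nrow(spans) < 1) stop("oscillatory_fraction: need >= 1 span")
  pwr <- power_curve(record$p_ao, record$q_ao)
  n <- record_length(record)
  fs <- record$fs
  # steady power uses the same trapezoid-weighted time averages as the total
  # so that a constant factor gives exactly zero oscillatory power
  per_span <- vapply(seq_len(nrow(spans)), function(k) {
    span <- spans[k, ]
    idx <- .span_idx_integral(span, n)
    dur <- (length(idx) - 1) / fs
    c(total = pwr_integral(pwr, span, fs) / dur,
      map = .trapz(record$p_ao[idx], fs) / dur,
      flow = .trapz(record$q_ao[idx], fs) / dur)
  }, numeric(3))
  total <- mean(per_span["total", ])
  if (total <= 0) stop("oscillatory_fraction: zero total power")
  steady <- to_si(mean(per_span["map", ]), "mmHg") *
    to_si(mean(per_span["flow", ]), "L/min")
  max(0, 1 - steady / total)
}
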