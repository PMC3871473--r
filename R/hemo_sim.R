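# Synthetic hemodynamics: a time-varying-elastance left ventricle coupled
# through valves to a 3-element Windkessel arterial load, plus a measurement
# model for the catheters and the transit-time flow probe.
#
# The model is the minimal two-state system (LV volume, Windkessel pressure)
# that produces the characteristic porcine waveform morphology: near-zero
# aortic flow in diastole and a power curve dominated by systole. Defaults
# describe a 25-30 kg anesthetized pig.

#' Ventricular parameters for the time-varying elastance model
#'
#' Instantaneous LV pressure is `E(t) * (V - v0)` where `E(t)` interpolates
#' between `e_min` (diastole) and `e_max` (end systole) through a
#' double-cosine activation.
#'
#' @param e_max End-systolic elastance (mmHg/mL).
#' @param e_min Diastolic elastance (mmHg/mL).
#' @param v0 Unstressed volume (mL).
#' @param t_sys_frac Fraction of the cycle spent in systolic activation.
#' @param tau_peak Position of the activation peak as a fraction of
#'   `t_sys_frac` (rise slower than relaxation at the default 0.6).
#' @return A list of class `ventricle_params`.
#' @export
ventricle_params <- function(e_max = 3.5, e_min = 0.13, v0 = 5,
                             t_sys_frac = 0.40, tau_peak = 0.6) {
  if (!(e_max > e_min && e_min > 0))
    stop("ventricle_params: need e_max > e_min > 0")
  if (v0 < 0) stop("ventricle_params: v0 must be >= 0")
  if (!(t_sys_frac > 0 && t_sys_frac < 1))
    stop("ventricle_params: t_sys_frac must be in (0, 1)")
  if (!(tau_peak > 0 && tau_peak < 1))
    stop("ventricle_params: tau_peak must be in (0, 1)")
  structure(list(e_max = e_max, e_min = e_min, v0 = v0,
                 t_sys_frac = t_sys_frac, tau_peak = tau_peak),
            class = "ventricle_params")
}

#' Circulation parameters: valves plus a 3-element Windkessel
#'
#' @param r_valve_ao Aortic valve resistance (mmHg s/mL).
#' @param r_char Characteristic (proximal) arterial resistance (mmHg s/mL).
#' @param r_periph Peripheral resistance (mmHg s/mL).
#' @param c_art Arterial compliance (mL/mmHg).
#' @param p_ven Filling (venous) pressure (mmHg).
#' @param r_mitral Mitral inflow resistance (mmHg s/mL).
#' @param regurg_frac Mitral regurgitant conductance as a fraction of the
#'   forward mitral conductance (0 = competent valve).
#' @return A list of class `circulation_params`.
#' @export
circulation_params <- function(r_valve_ao = 0.010, r_char = 0.035,
                               r_periph = 1.2, c_art = 2.0, p_ven = 8,
                               r_mitral = 0.012, regurg_frac = 0) {
  rs <- c(r_valve_ao = r_valve_ao, r_char = r_char, r_periph = r_periph,
          r_mitral = r_mitral)
  if (any(rs <= 0))
    stop("circulation_params: all resistances must be > 0")
  if (c_art <= 0) stop("circulation_params: c_art must be > 0")
  if (p_ven < 0) stop("circulation_params: p_ven must be >= 0")
  if (regurg_frac < 0 || regurg_frac >= 1)
    stop("circulation_params: regurg_frac must be in [0, 1)")
  structure(list(r_valve_ao = r_valve_ao, r_char = r_char,
                 r_periph = r_periph, c_art = c_art, p_ven = p_ven,
                 r_mitral = r_mitral, regurg_frac = regurg_frac),
            class = "circulation_params")
}

#' Generative description of one synthetic animal
#'
#' `alpha_true` and `volume_offset` describe the conductance catheter's gain
#' and offset error; they exist so that the per-animal alpha calibration has
#' a ground truth to recover.
#'
#' @param animal_id Label.
#' @param heart_rate Beats per minute, in \[50, 200\].
#' @param ventricle A [ventricle_params()] object.
#' @param circulation A [circulation_params()] object.
#' @param alpha_true Conductance volume gain (unitless), in \[0.7, 1.5\].
#' @param volume_offset Conductance volume offset (mL).
#' @return A list of class `animal_spec`.
#' @export
animal_spec <- function(animal_id = "pig1", heart_rate = 90,
                        ventricle = ventricle_params(),
                        circulation = circulation_params(),
                        alpha_true = 1, volume_offset = 0) {
  if (heart_rate < 50 || heart_rate > 200)
    stop("animal_spec: heart_rate must be in [50, 200] beats/min")
  if (alpha_true < 0.7 || alpha_true > 1.5)
    stop("animal_spec: alpha_true must be in [0.7, 1.5]")
  stopifnot(inherits(ventricle, "ventricle_params"),
            inherits(circulation, "circulation_params"))
  structure(list(animal_id = animal_id, heart_rate = heart_rate,
                 ventricle = ventricle, circulation = circulation,
                 alpha_true = alpha_true, volume_offset = volume_offset),
            class = "animal_spec")
}

.condition_names <- c("baseline", "preload_reduced", "afterload_increased",
                      "dobutamine", "nitroprusside", "metoprolol")

# Default intervention multipliers. These are calibration targets chosen so
# that caval banding cuts CO by >= 20% and each drug moves contractility,
# rate and vascular tone in its known direction; they are frozen, not fit.
.default_multipliers <- list(
  baseline            = list(),
  preload_reduced     = list(p_ven = 0.5),
  afterload_increased = list(r_periph = 1.6),
  dobutamine          = list(e_max = 1.5, heart_rate = 1.15, r_periph = 0.9),
  nitroprusside       = list(r_periph = 0.65, p_ven = 0.85),
  metoprolol          = list(e_max = 0.7, heart_rate = 0.85)
)

#' Describe an experimental condition as parameter multipliers
#'
#' The six conditions mirror the in-vivo protocol: mechanical preload
#' reduction (caval banding), mechanical afterload increase (aortic
#' balloon), and dobutamine / nitroprusside / metoprolol steady states.
#'
#' @param name One of `baseline`, `preload_reduced`, `afterload_increased`,
#'   `dobutamine`, `nitroprusside`, `metoprolol`.
#' @param multipliers Named list of positive scale factors applied to animal
#'   parameters (`heart_rate`, any [ventricle_params()] or
#'   [circulation_params()] field). Defaults to the built-in multipliers for
#'   `name`.
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(name, multipliers = NULL) {
  if (!name %in% .condition_names)
    stop("condition_spec: unknown condition '", name, "' (expected one of ",
         paste(.condition_names, collapse = ", "), ")")
  if (is.null(multipliers)) multipliers <- .default_multipliers[[name]]
  if (length(multipliers) &&
      (is.null(names(multipliers)) || any(unlist(multipliers) <= 0)))
    stop("condition_spec: multipliers must be named and > 0")
  structure(list(name = name, multipliers = multipliers),
            class = "condition_spec")
}

#' The six default experimental conditions
#' @return Named list of [condition_spec()] objects in protocol order.
#' @export
default_conditions <- function() {
  setNames(lapply(.condition_names, condition_spec), .condition_names)
}

#' Simulation configuration
#'
#' @param fs Sampling rate (Hz, >= 200; instruments sample at 1000).
#' @param n_cycles Cardiac cycles retained per measurement.
#' @param warmup_cycles Cycles integrated and discarded before recording so
#'   the record is in periodic steady state (>= 5).
#' @param noise_sd Named per-channel additive Gaussian noise SDs, in channel
#'   units (`ecg` a.u., `p_ao`/`p_lv` mmHg, `q_ao` L/min, `v_lv` mL).
#' @param seed Integer seed for the measurement model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 1000, n_cycles = 10, warmup_cycles = 15,
                       noise_sd = c(ecg = 0.02, p_ao = 0.5, q_ao = 0.05,
                                    p_lv = 0.5, v_lv = 0.5),
                       seed = 1L) {
  if (fs < 200) stop("sim_config: fs must be >= 200 Hz")
  if (n_cycles < 1) stop("sim_config: n_cycles must be >= 1")
  if (warmup_cycles < 5) stop("sim_config: warmup_cycles must be >= 5")
  full <- c(ecg = 0, p_ao = 0, q_ao = 0, p_lv = 0, v_lv = 0)
  full[names(noise_sd)] <- noise_sd
  if (any(full < 0)) stop("sim_config: noise SDs must be >= 0")
  structure(list(fs = fs, n_cycles = n_cycles,
                 warmup_cycles = warmup_cycles, noise_sd = full,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Normalized elastance activation
#'
#' The activation `a(t)` rises 0 to 1 over `[0, t_sys_frac * tau_peak]`,
#' falls back to 0 at `t_sys_frac`, and stays 0 for the rest of the cycle;
#' instantaneous elastance is `e_min + (e_max - e_min) * a(t)`.
#'
#' @param t_norm Cycle phase in `[0, 1)` (vectorized).
#' @param params A [ventricle_params()] object.
#' @return Activation values in `[0, 1]`.
#' @export
normalized_elastance <- function(t_norm, params) {
  stopifnot(inherits(params, "ventricle_params"))
  if (any(t_norm < 0 | t_norm >= 1))
    stop("normalized_elastance: t_norm must be in [0, 1)")
  t_pk <- params$t_sys_frac * params$tau_peak
  t_end <- params$t_sys_frac
  a <- numeric(length(t_norm))
  up <- t_norm < t_pk
  down <- !up & t_norm < t_end
  a[up] <- 0.5 * (1 - cos(pi * t_norm[up] / t_pk))
  a[down] <- 0.5 * (1 + cos(pi * (t_norm[down] - t_pk) / (t_end - t_pk)))
  a
}

# flatten an animal_spec to the parameter list the C++ integrator takes
.sim_pars <- function(animal) {
  c(list(period = 60 / animal$heart_rate),
    unclass(animal$ventricle), unclass(animal$circulation))
}

#' Apply a condition's multipliers to an animal
#'
#' Returns a modified copy; `baseline` is the identity.
#'
#' @param base An [animal_spec()].
#' @param cond A [condition_spec()].
#' @return An [animal_spec()] with scaled parameters.
#' @export
apply_condition <- function(base, cond) {
  stopifnot(inherits(base, "animal_spec"), inherits(cond, "condition_spec"))
  out <- base
  for (nm in names(cond$multipliers)) {
    k <- cond$multipliers[[nm]]
    if (nm == "heart_rate") {
      out$heart_rate <- out$heart_rate * k
    } else if (nm %in% names(out$ventricle)) {
      out$ventricle[[nm]] <- out$ventricle[[nm]] * k
    } else if (nm %in% names(out$circulation)) {
      out$circulation[[nm]] <- out$circulation[[nm]] * k
    } else {
      stop("apply_condition: unknown parameter '", nm, "' in multipliers")
    }
  }
  out
}

# Sample indices (1-based) of cycle onsets for a record of n_cycles cycles.
.cycle_onsets <- function(fs, heart_rate, n_cycles) {
  as.integer(round((seq_len(n_cycles) - 1) * fs * 60 / heart_rate)) + 1L
}

#' Simulate the noise-free ("true") channels for one measurement
#'
#' Integrates the elastance-Windkessel system with fixed-step RK4 at the
#' sampling rate, discards `warmup_cycles` cycles so the retained record is
#' in periodic steady state, and emits the five measured channels. The ECG is
#' a synthetic impulse train with one unambiguous R spike at each cycle
#' onset. Ground truth needed by tests (mitral/regurgitant flows in mL/s,
#' onset indices) is attached as attribute `"truth"`.
#'
#' @param animal An [animal_spec()].
#' @param cond A [condition_spec()]; applied before integrating.
#' @param cfg A [sim_config()].
#' @return A noise-free [waveform_record()] (volume channel is the true
#'   volume; see [measurement_model()] for the catheter view).
#' @export
simulate_record <- function(animal, cond = condition_spec("baseline"),
                            cfg = sim_config()) {
  stopifnot(inherits(animal, "animal_spec"), inherits(cfg, "sim_config"))
  a <- apply_condition(animal, cond)
  pars <- .sim_pars(a)
  dt <- 1 / cfg$fs
  period <- pars$period
  n_rec <- round(cfg$n_cycles * cfg$fs * period)

  # start at diastolic equilibrium-ish state, then integrate the warm-up
  v_init <- a$ventricle$v0 +
    a$circulation$p_ven / a$ventricle$e_min * 0.8
  pa_init <- 70
  n_warm <- round(cfg$warmup_cycles * cfg$fs * period)
  warm <- .simulate_ewk(0, v_init, pa_init, n_warm, dt, pars, FALSE)
  run <- .simulate_ewk(warm$t_end, warm$v_end, warm$pa_end, n_rec, dt,
                       pars, TRUE)
  out <- run$out

  onsets <- .cycle_onsets(cfg$fs, a$heart_rate, cfg$n_cycles)
  # phase alignment: warm-up ends mid-rounding, shift onsets to true phase
  # (t_end is an exact multiple of dt; onset k is at phase k*period past the
  # warm-up end only if n_warm*dt is a multiple of the period, which rounding
  # breaks by < half a sample -- ignored, < 0.1% of a cycle)
  ecg <- numeric(n_rec)
  spike <- c(0.2, 0.6, 1, 0.6, 0.2)
  for (o in onsets) {
    idx <- o + (-2:2)
    keep <- idx >= 1 & idx <= n_rec
    ecg[idx[keep]] <- pmax(ecg[idx[keep]], spike[keep])
  }

  rec <- waveform_record(
    ecg = ecg,
    p_ao = out[, "p_ao"],
    q_ao = out[, "q_ao_mls"] * 0.06,  # mL/s -> L/min
    p_lv = out[, "p_lv"],
    v_lv = out[, "v_lv"],
    fs = cfg$fs,
    meta = list(animal_id = a$animal_id, condition = cond$name,
                measurement_index = NA_integer_, seed = cfg$seed,
                heart_rate = a$heart_rate))
  attr(rec, "truth") <- list(
    q_mit_mls = out[, "q_mit_mls"],
    q_reg_mls = out[, "q_reg_mls"],
    onsets = onsets,
    period_samples = cfg$fs * period)
  rec
}

#' Apply the measurement model: catheter gain/offset and channel noise
#'
#' The conductance-catheter volume is reported as
#' `alpha_true * v_true + volume_offset` plus noise; every other channel
#' receives additive Gaussian noise at the configured SD. Fully determined
#' by `cfg$seed`.
#'
#' @param true_record A noise-free record from [simulate_record()].
#' @param animal The [animal_spec()] providing `alpha_true` and
#'   `volume_offset`.
#' @param cfg A [sim_config()]; `noise_sd` and `seed` are used.
#' @return A measured [waveform_record()].
#' @export
measurement_model <- function(true_record, animal, cfg = sim_config()) {
  stopifnot(inherits(true_record, "waveform_record"),
            inherits(animal, "animal_spec"), inherits(cfg, "sim_config"))
  n <- record_length(true_record)
  sds <- cfg$noise_sd
  set.seed(cfg$seed)
  noise <- function(sd) if (sd > 0) rnorm(n, 0, sd) else numeric(n)
  rec <- waveform_record(
    ecg  = true_record$ecg + noise(sds[["ecg"]]),
    p_ao = true_record$p_ao + noise(sds[["p_ao"]]),
    q_ao = true_record$q_ao + noise(sds[["q_ao"]]),
    p_lv = true_record$p_lv + noise(sds[["p_lv"]]),
    v_lv = animal$alpha_true * true_record$v_lv + animal$volume_offset +
      noise(sds[["v_lv"]]),
    fs = true_record$fs,
    meta = true_record$meta)
  attr(rec, "truth") <- attr(true_record, "truth")
  rec
}

#' Draw a cohort of synthetic animals around the species defaults
#'
#' Between-animal variation is seeded lognormal jitter (SD 10%) on heart
#' rate, elastances, vascular tone and filling pressure around the defaults
#' for a 25-30 kg pig; each animal also gets its own conductance gain
#' `alpha_true` (uniform on \[0.85, 1.35\]) and offset.
#'
#' @param n_animals Number of animals.
#' @param seed Integer seed.
#' @return List of [animal_spec()] objects.
#' @export
make_cohort <- function(n_animals = 6, seed = 1L) {
  set.seed(seed)
  jit <- function(x, sdlog = 0.1) x * rlnorm(1, 0, sdlog)
  lapply(seq_len(n_animals), function(i) {
    hr <- min(200, max(50, jit(90)))
    vent <- ventricle_params(
      e_max = jit(3.5), e_min = jit(0.13), v0 = 5,
      t_sys_frac = min(0.5, max(0.25, jit(0.40, 0.05))))
    circ <- circulation_params(
      r_periph = jit(1.2), c_art = jit(2.0), p_ven = jit(8),
      r_valve_ao = 0.010, r_char = jit(0.035), r_mitral = jit(0.012))
    animal_spec(animal_id = sprintf("pig%d", i), heart_rate = hr,
                ventricle = vent, circulation = circ,
                alpha_true = runif(1, 0.85, 1.35),
                volume_offset = runif(1, -5, 15))
  })
}
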