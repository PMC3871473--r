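test_that("R-peak detection recovers generator ground truth", {
  rec <- baseline_record()
  tr <- attr(rec, "truth")
  expect_identical(detect_r_peaks(rec$ecg, rec$fs), tr$onsets)

  expect_error(detect_r_peaks(numeric(2000), 1000), "no peaks")
  expect_error(detect_r_peaks(rep(1, 2000), 1000), "no peaks")
  expect_error(detect_r_peaks(numeric(100), 1000), "1 s")

  set.seed(7)
  noisy <- rec$ecg + rnorm(length(rec$ecg), 0, 0.1 * max(rec$ecg))
  found <- detect_r_peaks(noisy, rec$fs)
  expect_equal(length(found), length(tr$onsets))
  expect_true(all(abs(found - tr$onsets) <= 2))
})

test_that("cycle segmentation follows the R-to-R half-open convention", {
  rec0 <- waveform_record(ecg = numeric(1201), p_ao = numeric(1201),
                          q_ao = numeric(1201), p_lv = numeric(1201),
                          v_lv = numeric(1201), fs = 1000)
  spans <- segment_cycles(rec0, c(1L, 601L, 1201L))
  expect_equal(spans$start, c(1L, 601L))
  expect_equal(spans$end, c(601L, 1201L))

  # a 10-cycle record whose onsets bracket all cycles yields 10 spans
  rec <- baseline_record(n_cycles = 10)
  spans <- segment_cycles(rec, detect_r_peaks(rec$ecg, rec$fs))
  expect_equal(nrow(spans), 10)
  expect_true(all(spans$start < spans$end))
  expect_true(all(spans$end[-10] == spans$start[-1]))  # non-overlap, ordered
  expect_lte(spans$end[10], record_length(rec) + 1)

  expect_error(segment_cycles(rec, 5L), "2 R peaks")
  expect_error(segment_cycles(rec, c(10L, 5L)), "strictly increasing")
})

test_that("power curve is the SI product of pressure and flow", {
  expect_equal(power_curve(100, 5), 13332.2 * 8.3333e-5, tolerance = 1e-5)
  expect_equal(power_curve(rep(80, 10), numeric(10)), numeric(10))
  p <- c(60, 80, 120); q <- c(0.5, 3, 7)
  expect_equal(power_curve(2 * p, q), 2 * power_curve(p, q))
  expect_error(power_curve(1:3, 1:4), "lengths differ")
})

test_that("pwr_integral matches closed-form oracles", {
  fs <- 1000
  # constant 1.1110 W over exactly 1 s
  pwr <- rep(1.1110, 1500)
  expect_equal(pwr_integral(pwr, list(start = 1L, end = 1001L), fs), 1.1110)
  # half-sine flow at constant pressure: closed form P*Q0*2*Ts/pi (SI)
  Ts <- 0.3; P <- 100; Q0 <- 20
  tt <- seq(0, Ts, by = 1 / fs)
  pwr2 <- power_curve(rep(P, length(tt)), Q0 * sin(pi * tt / Ts))
  exact <- to_si(P, "mmHg") * to_si(Q0, "L/min") * 2 * Ts / pi
  got <- pwr_integral(pwr2, list(start = 1L, end = length(tt)), fs)
  expect_lt(abs(got - exact) / exact, 1e-4)
  # zero flow -> zero energy
  expect_equal(pwr_integral(numeric(2000), list(start = 1L, end = 1001L), fs),
               0)
  expect_error(pwr_integral(pwr, list(start = 5L, end = 5L), fs), "empty")
})

test_that("stroke work matches polygon-area oracles and is loop-invariant", {
  # rectangle: P in [0,100] mmHg, V in [40,100] mL -> 13332.2 Pa * 6e-5 m^3
  p <- c(0, 100, 100, 0); v <- c(40, 40, 100, 100)
  span <- list(start = 1L, end = 5L)
  expect_equal(stroke_work(p, v, span), 0.79993, tolerance = 1e-5)
  # traversal direction does not matter
  expect_equal(stroke_work(rev(p), rev(v), span), 0.79993, tolerance = 1e-5)
  # collinear loop has zero area
  expect_equal(stroke_work(c(0, 50, 100, 50), rep(70, 4), span), 0)
  # ellipse with semi-axes a mmHg x b mL -> pi*a*b in SI
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  a <- 40; b <- 25
  pe <- 60 + a * cos(th); ve <- 50 + b * sin(th)
  exact <- pi * to_si(a, "mmHg") * to_si(b, "mL")
  got <- stroke_work(pe, ve, list(start = 1L, end = 1001L))
  expect_lt(abs(got - exact) / exact, 1e-3)
  # starting-point invariance under cyclic rotation
  rot <- c(250:1000, 1:249)
  got_rot <- stroke_work(pe[rot], ve[rot], list(start = 1L, end = 1001L))
  expect_lt(abs(got_rot - got) / got, 1e-9)
  expect_error(stroke_work(p, v, list(start = 1L, end = 3L)), "degenerate")
})

test_that("alpha calibration recovers ratios and generator gain", {
  af <- alpha_calibration(c(66, 66), c(60, 60))
  expect_equal(af$alpha, 1.1)
  expect_equal(alpha_calibration(c(40, 41), c(40, 41))$alpha, 1)
  expect_error(alpha_calibration(c(40, -1), c(40, 40)), "nonpositive")
  expect_error(alpha_calibration(numeric(0), numeric(0)), "baseline cycle")

  # parameter recovery against generator ground truth, noise-free. At the
  # instrument rate (1 kHz) agreement between the flow-probe and conductance
  # stroke volumes is limited by flow quadrature at the valve-opening kink
  # (~1e-5); at 10 kHz the estimator itself is exact to well below 1e-6.
  an <- animal_spec(alpha_true = 1.2, volume_offset = 7)
  cfg1k <- quiet_cfg()
  meas1k <- measurement_model(simulate_record(an, condition_spec("baseline"),
                                              cfg1k), an, cfg1k)
  b1k <- beat_summary(meas1k, truth_spans(meas1k))
  expect_lt(abs(alpha_calibration(b1k$sv_cond_raw_mL, b1k$sv_mL)$alpha -
                  1.2) / 1.2, 1e-4)

  cfg10k <- quiet_cfg(fs = 10000)
  true_rec <- simulate_record(an, condition_spec("baseline"), cfg10k)
  meas <- measurement_model(true_rec, an, cfg10k)
  spans <- truth_spans(meas)
  b <- beat_summary(meas, spans)
  af <- alpha_calibration(b$sv_cond_raw_mL, b$sv_mL)
  expect_lt(abs(af$alpha - 1.2) / 1.2, 1e-6)
  # post-calibration SW equals true-volume SW (offset drops out of the area)
  b_cal <- beat_summary(meas, spans, alpha = af)
  b_true <- beat_summary(true_rec, spans)
  expect_lt(max(abs(b_cal$sw_J - b_true$sw_J) / b_true$sw_J), 1e-6)
})

test_that("beat summary scalars behave in degenerate flow regimes", {
  n <- 3000; fs <- 1000
  mk <- function(q) waveform_record(ecg = numeric(n), p_ao = rep(100, n),
                                    q_ao = rep(q, n), p_lv = rep(50, n),
                                    v_lv = rep(60, n), fs = fs)
  spans <- data.frame(start = c(1L, 1001L), end = c(1001L, 2001L))
  b <- beat_summary(mk(5), spans)
  expect_equal(nrow(b), 2)
  # steady flow limit: total power = steady power, CPO = PWR integral per s
  expect_equal(b$cpo_W, b$pwr_integral_J / b$duration_s, tolerance = 1e-12)
  expect_equal(b$cpo_W[1], 1.1110, tolerance = 1e-4)
  b0 <- beat_summary(mk(0), spans)
  expect_true(all(b0[, c("sv_mL", "co_Lmin", "cpo_W", "pwr_integral_J")] == 0))

  rec <- baseline_record()
  expect_equal(nrow(beat_summary(rec, truth_spans(rec))), 10)
})

test_that("oscillatory fraction matches the closed-form covariance oracle", {
  n <- 4000; fs <- 1000
  spans <- data.frame(start = 1L, end = n + 1L)
  # constant pressure: fraction is exactly 0 whatever the flow
  w <- 2 * pi * 2
  tt <- (seq_len(n) - 1) / fs
  rec_cp <- waveform_record(ecg = numeric(n), p_ao = rep(90, n),
                            q_ao = 4 * (1 + 0.5 * sin(w * tt)),
                            p_lv = numeric(n) + 1, v_lv = numeric(n) + 1,
                            fs = fs)
  expect_equal(oscillatory_fraction(rec_cp, spans), 0, tolerance = 1e-9)
  # p = P0(1+0.2 sin), q = Q0(1+0.5 sin), integer cycles -> 0.05/1.05
  rec_m <- waveform_record(ecg = numeric(n),
                           p_ao = 80 * (1 + 0.2 * sin(w * tt)),
                           q_ao = 4 * (1 + 0.5 * sin(w * tt)),
                           p_lv = numeric(n) + 1, v_lv = numeric(n) + 1,
                           fs = fs)
  expect_equal(oscillatory_fraction(rec_m, spans), 0.05 / 1.05,
               tolerance = 1e-3)
  rec0 <- waveform_record(ecg = numeric(n), p_ao = rep(90, n),
                          q_ao = numeric(n), p_lv = numeric(n),
                          v_lv = numeric(n), fs = fs)
  expect_error(oscillatory_fraction(rec0, spans), "zero total power")
})

test_that("trapezoid integral agrees with a high-resolution rectangle oracle", {
  rec <- baseline_record()
  spans <- truth_spans(rec)
  pwr <- power_curve(rec$p_ao, rec$q_ao)
  n <- record_length(rec)
  for (k in c(1, 5, 9)) {
    span <- spans[k, ]
    idx <- span$start:min(span$end, n)
    # oracle: resample to 10 kHz by linear interpolation, rectangle rule
    t_lo <- (idx - idx[1]) / rec$fs
    t_hi <- seq(0, max(t_lo), by = 1e-4)
    p_hi <- approx(t_lo, pwr[idx], xout = t_hi)$y
    oracle <- sum(p_hi[-length(p_hi)]) * 1e-4
    got <- pwr_integral(pwr, span, rec$fs)
    expect_lt(abs(got - oracle) / oracle, 1e-3)
  }
})

test_that("SW and PWR integral scale linearly with all pressures", {
  rec <- baseline_record()
  spans <- truth_spans(rec)
  k <- 1.7
  scaled <- waveform_record(ecg = rec$ecg, p_ao = k * rec$p_ao,
                            q_ao = rec$q_ao, p_lv = k * rec$p_lv,
                            v_lv = rec$v_lv, fs = rec$fs, meta = rec$meta)
  b1 <- beat_summary(rec, spans)
  b2 <- beat_summary(scaled, spans)
  expect_equal(b2$sw_J, k * b1$sw_J, tolerance = 1e-12)
  expect_equal(b2$pwr_integral_J, k * b1$pwr_integral_J, tolerance = 1e-12)
})

test_that("noise-free protocol beats: PWR bounded below and r > 0.99", {
  # PWR integral >= SW minus the filling-energy term; across conditions the
  # two measures correlate almost perfectly when noise-free
  an <- animal_spec()
  beats <- data.table::rbindlist(lapply(names(default_conditions()),
                                        function(cn) {
    rec <- baseline_record(cond = cn, animal = an)
    beat_summary(rec, truth_spans(rec))
  }))
  # filling energy approx p_ven * SV
  fill <- to_si(8, "mmHg") * to_si(beats$sv_mL, "mL")
  expect_true(all(beats$pwr_integral_J >= beats$sw_J - fill - 1e-9))
  expect_gt(cor(beats$sw_J, beats$pwr_integral_J), 0.99)
})
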