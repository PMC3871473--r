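# Shared fixtures: all generated in code, nothing on disk.

quiet_cfg <- function(n_cycles = 10, seed = 1L, fs = 1000) {
  sim_config(fs = fs, n_cycles = n_cycles,
             noise_sd = c(ecg = 0, p_ao = 0, q_ao = 0, p_lv = 0, v_lv = 0),
             seed = seed)
}

default_animal <- function(...) animal_spec(...)

# noise-free baseline record with ground truth attached
baseline_record <- function(n_cycles = 10, animal = animal_spec(),
                            cond = "baseline", seed = 1L) {
  simulate_record(animal, condition_spec(cond),
                  quiet_cfg(n_cycles = n_cycles, seed = seed))
}

# cycle spans straight from the generator's ground-truth onsets
truth_spans <- function(rec) {
  tr <- attr(rec, "truth")
  n <- record_length(rec)
  on <- tr$onsets
  data.frame(start = on,
             end = c(on[-1], as.integer(min(n + 1, on[length(on)] +
                                              round(tr$period_samples)))))
}

# per-animal random-slope data with known parameters, for recovery tests
gen_mixed_data <- function(beta = c(baseline = 1.2, dobutamine = 1.3),
                           tau = 0.05, sigma = 0.02, n_animals = 6,
                           beats_per_animal = 100, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_animals), function(i) {
    b_i <- rnorm(1, 0, tau)
    x <- runif(beats_per_animal, 0.1, 0.7)
    cond <- rep(names(beta), length.out = beats_per_animal)
    y <- (unname(beta[cond]) + b_i) * x + rnorm(beats_per_animal, 0, sigma)
    data.table::data.table(animal_id = paste0("a", i), condition = cond,
                           sw_J = x, pwr_integral_J = y)
  })
  data.table::rbindlist(rows)
}
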