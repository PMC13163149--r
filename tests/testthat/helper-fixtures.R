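# shared fixtures, built in code at test time

# small eupnea spec used across tests
eupnea_spec <- function(duration = 330, ...) {
  breath_process_spec(mean_ti = 1.7, mean_te = 2.3, sd_ti = 0.15,
                      sd_te = 0.2, sd_amp = 0.1, ar1_rho = 0.3,
                      duration = duration, ...)
}

# deterministic zero-variance breathing: 60 breaths of Ttot 5 s
uniform_truth <- function(duration = 300) {
  simulate_breath_sequence(
    breath_process_spec(mean_ti = 2, mean_te = 3, sd_ti = 0, sd_te = 0,
                        sd_amp = 0, duration = duration), seed = 1)
}

# a resp_signal built directly from samples (bypasses conditioning)
make_signal <- function(t, x, fs = 1 / stats::median(diff(t))) {
  respvar:::new_resp_signal(t, x, fs, list(list(op = "fixture")))
}

# match estimated breaths to true breaths by nearest onset
match_breaths <- function(est, truth, max_gap = 1) {
  m <- vapply(est$onset, function(o) which.min(abs(truth$onset - o)), 0L)
  ok <- abs(est$onset - truth$onset[m]) < max_gap
  list(idx = m, ok = ok)
}

# synthetic subject table for the statistics tests
fake_subjects <- function(n, seed = 1, groups = NULL) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = groups %||% rep(c("patient", "control"), length.out = n),
    age = round(runif(n, 20, 75)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    temperature = round(rnorm(n, 36.5, 0.3), 1),
    heart_rate = round(rnorm(n, 78, 12)),
    pulse_pressure = round(rnorm(n, 46, 10)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
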