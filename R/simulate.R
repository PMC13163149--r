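#' Specify a breath-timing generative process
#'
#' Breath-to-breath inspiratory time (Ti), expiratory time (Te) and
#' amplitude each follow a stationary Gaussian AR(1) process with the
#' stated marginal mean, marginal SD and lag-1 autocorrelation, truncated
#' below at 0.3 s (timing) to keep breaths physiological. Pathological
#' patterns modify the timing sequence: `biot` alternates clusters of 3-5
#' normal breaths with apneic pauses of 10-30 s, `cheyne_stokes`
#' modulates amplitude with a 60-s waxing-waning cycle (breaths at the
#' nadir suppressed), `ataxic` triples the timing SDs, removes
#' autocorrelation and inserts random short pauses.
#'
#' @param mean_ti,mean_te mean inspiratory / expiratory time (s).
#' @param sd_ti,sd_te marginal SD of Ti / Te (s).
#' @param mean_amp,sd_amp mean and SD of breath amplitude
#'   (arbitrary acceleration units; no volume calibration is implied).
#' @param ar1_rho lag-1 autocorrelation of the timing and amplitude
#'   processes, |rho| < 1.
#' @param duration recording length to cover (s).
#' @param pattern one of `"eupnea"`, `"biot"`, `"cheyne_stokes"`, `"ataxic"`.
#' @return object of class `breath_process_spec`.
#' @export
breath_process_spec <- function(mean_ti = 1.7, mean_te = 2.3,
                                sd_ti = 0.15, sd_te = 0.2,
                                mean_amp = 1, sd_amp = 0.1,
                                ar1_rho = 0.3, duration = 330,
                                pattern = c("eupnea", "biot",
                                            "cheyne_stokes", "ataxic")) {
  check_positive(mean_ti, "mean_ti")
  check_positive(mean_te, "mean_te")
  check_nonneg(sd_ti, "sd_ti")
  check_nonneg(sd_te, "sd_te")
  check_positive(mean_amp, "mean_amp")
  check_nonneg(sd_amp, "sd_amp")
  check_positive(duration, "duration")
  if (!is.numeric(ar1_rho) || length(ar1_rho) != 1L || !is.finite(ar1_rho) ||
      abs(ar1_rho) >= 1) {
    stop_param("ar1_rho", "must satisfy |ar1_rho| < 1")
  }
  pattern <- match.arg(pattern)
  structure(list(mean_ti = mean_ti, mean_te = mean_te, sd_ti = sd_ti,
                 sd_te = sd_te, mean_amp = mean_amp, sd_amp = sd_amp,
                 ar1_rho = ar1_rho, duration = duration, pattern = pattern),
            class = "breath_process_spec")
}

# stationary Gaussian AR(1): marginal mean mu, marginal sd s, lag-1 rho
ar1_series <- function(n, mu, s, rho) {
  if (s == 0) return(rep(mu, n))
  z <- rnorm(n)
  x <- numeric(n)
  x[1] <- mu + s * z[1]
  for (i in seq_len(n)[-1]) {
    x[i] <- mu + rho * (x[i - 1] - mu) + s * sqrt(1 - rho^2) * z[i]
  }
  x
}

# assemble a ground-truth breath table from onset-relative Ti/Te/amplitude
# and inter-breath pauses (pause[i] follows breath i)
build_breath_table <- function(ti, te, amp, pause) {
  n <- length(ti)
  ttot <- ti + te
  onset <- cumsum(c(0, head(ttot + pause, -1)))
  data.frame(onset = onset, peak = onset + ti, offset = onset + ttot,
             ti = ti, te = te, ttot = ttot, rate = 60 / ttot,
             ie_ratio = ti / te, amplitude = amp)
}

#' Simulate a ground-truth breath sequence
#'
#' Draws per-breath Ti, Te and amplitude from the AR(1) processes of the
#' spec and lays breaths out on the time axis until the requested
#' duration is covered. Deterministic given `seed`.
#'
#' @param spec a [breath_process_spec()].
#' @param seed integer seed.
#' @return data.frame (one row per breath) with columns `onset`, `peak`,
#'   `offset` (s), `ti`, `te`, `ttot` (s), `rate` (breaths/min),
#'   `ie_ratio`, `amplitude`.
#' @export
simulate_breath_sequence <- function(spec, seed = 1L) {
  if (!inherits(spec, "breath_process_spec")) {
    stop("`spec` must be a breath_process_spec", call. = FALSE)
  }
  with_seed(seed, {
    # generous breath budget, then trim to the first breath ending past
    # `duration`; biot pauses stretch coverage so the budget is ample
    n <- ceiling(spec$duration / (spec$mean_ti + spec$mean_te)) + 20L
    sd_mult <- if (spec$pattern == "ataxic") 3 else 1
    rho <- if (spec$pattern == "ataxic") 0 else spec$ar1_rho
    ti <- pmax(ar1_series(n, spec$mean_ti, spec$sd_ti * sd_mult, rho), 0.3)
    te <- pmax(ar1_series(n, spec$mean_te, spec$sd_te * sd_mult, rho), 0.3)
    amp <- pmax(ar1_series(n, spec$mean_amp, spec$sd_amp, rho),
                0.05 * spec$mean_amp)
    pause <- rep(0, n)
    if (spec$pattern == "biot") {
      # clusters of 3-5 breaths separated by 10-30 s apneas
      i <- 0L
      while (i < n) {
        k <- sample(3:5, 1L)
        i <- min(i + k, n)
        pause[i] <- runif(1, 10, 30)
      }
    } else if (spec$pattern == "ataxic") {
      gap <- runif(n) < 0.15
      pause[gap] <- runif(sum(gap), 2, 10)
    }
    bt <- build_breath_table(ti, te, amp, pause)
    if (spec$pattern == "cheyne_stokes") {
      # 60-s waxing-waning amplitude cycle; nadir breaths suppressed,
      # leaving apneic gaps at the cycle troughs
      mod <- 0.5 * (1 - cos(2 * pi * bt$onset / 60))
      bt$amplitude <- bt$amplitude * pmax(mod, 0.05)
      keep <- mod >= 0.15
      if (any(keep)) bt <- bt[keep, , drop = FALSE]
    }
    last <- if (any(bt$offset >= spec$duration)) {
      min(which(bt$offset >= spec$duration))
    } else nrow(bt)
    bt <- bt[seq_len(last), , drop = FALSE]
    rownames(bt) <- NULL
    bt
  })
}

#' Render a breath sequence as a triaxial accelerometer recording
#'
#' Each breath is a raised-cosine rise over Ti and fall over Te, scaled
#' by its amplitude, projected onto the three sensor axes by a fixed unit
#' orientation vector, then corrupted by a constant per-axis gravity
#' offset, white Gaussian noise and a linear drift ramp.
#'
#' @param truth breath table from [simulate_breath_sequence()].
#' @param fs sampling frequency (Hz); must exceed twice the fastest
#'   instantaneous breath frequency.
#' @param gravity_offset length-3 constant offset added to (ax, ay, az).
#' @param noise_sd white-noise SD (acceleration units).
#' @param drift_rate linear drift slope (units/s), added to every axis.
#' @param orientation length-3 projection vector (normalised internally);
#'   the default places most respiratory power on the z axis.
#' @param seed integer seed (noise only).
#' @param subject_id identifier stored with the recording.
#' @return object of class `raw_recording`: data.frame with columns
#'   `time`, `ax`, `ay`, `az` and attributes `fs`, `subject_id`.
#' @export
render_acceleration <- function(truth, fs = 10, gravity_offset = c(0.2, 0.3, 9.8),
                                noise_sd = 0.05, drift_rate = 0,
                                orientation = c(0.15, 0.25, 0.96),
                                seed = 1L, subject_id = "s1") {
  check_positive(fs, "fs")
  check_nonneg(noise_sd, "noise_sd")
  if (length(gravity_offset) != 3L || length(orientation) != 3L) {
    stop_param("gravity_offset/orientation", "must be length-3 numeric")
  }
  fmax <- 1 / min(truth$ttot)
  if (fs <= 2 * fmax) {
    stop_param("fs", sprintf(
      "must exceed twice the fastest breath frequency (%.2f Hz)", fmax))
  }
  duration <- max(truth$offset)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  # raised-cosine waveform: 0 at onsets/offsets, amplitude at peaks
  idx <- findInterval(t, truth$onset)
  w <- numeric(n)
  inb <- idx >= 1L
  ii <- idx[inb]
  tt <- t[inb]
  rise <- tt < truth$peak[ii]
  fall <- !rise & tt < truth$offset[ii]
  wv <- numeric(sum(inb))
  wv[rise] <- 0.5 * truth$amplitude[ii[rise]] *
    (1 - cos(pi * (tt[rise] - truth$onset[ii[rise]]) / truth$ti[ii[rise]]))
  wv[fall] <- 0.5 * truth$amplitude[ii[fall]] *
    (1 + cos(pi * (tt[fall] - truth$peak[ii[fall]]) / truth$te[ii[fall]]))
  w[inb] <- wv
  u <- orientation / sqrt(sum(orientation^2))
  acc <- outer(w, u)
  acc <- sweep(acc, 2, gravity_offset, "+") + drift_rate * t
  if (noise_sd > 0) {
    acc <- acc + with_seed(seed, matrix(rnorm(3 * n, 0, noise_sd), n, 3))
  }
  rec <- data.frame(time = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
  structure(rec, fs = fs, subject_id = subject_id, class = c("raw_recording", "data.frame"))
}

#' Noise level for a target recording signal-to-noise ratio
#'
#' The SNR of a rendered triaxial recording is defined as total
#' respiratory signal power over total noise power summed across the
#' three channels: the waveform projects onto the axes through a unit
#' orientation vector (total signal variance amp^2 / 8 for the
#' raised-cosine shape) while each axis carries independent noise.
#'
#' @param snr_db target SNR in dB.
#' @param mean_amp mean breath amplitude of the rendered sequence.
#' @return per-axis white-noise SD for [render_acceleration()].
#' @export
snr_noise_sd <- function(snr_db, mean_amp = 1) {
  sig_var <- mean_amp^2 / 8
  sqrt(sig_var / 10^(snr_db / 10) / 3)
}

#' Specify a synthetic cohort
#'
#' Defines a patient and a control arm: group-level breath-process
#' parameters (with multiplicative between-subject jitter), covariate
#' distributions, a linear link from true RV features to the CRS-R mean,
#' and a logistic link to the probability of clinical improvement.
#' Default covariate distributions follow the study population this
#' generator emulates: patients aged 55.8 +/- 17.8 y (13/44 male,
#' temperature 36.6 +/- 0.4 C, heart rate 83.6 +/- 16 bpm, pulse
#' pressure 46.5 +/- 13 mmHg), controls 45.8 +/- 17 y (22/44 male,
#' 36.4 +/- 0.2 C, 71.6 +/- 11.7 bpm, 45.4 +/- 9.8 mmHg). The default
#' patient breath process carries larger timing SDs and stronger
#' autocorrelation, elevating long-term I/E-ratio variability
#' (ie_ratio_sd2) in the patient arm.
#'
#' @param n_patients,n_controls arm sizes.
#' @param patient_spec,control_spec [breath_process_spec()] per arm.
#' @param subject_cv between-subject lognormal CV applied to the breath
#'   process means/SDs (default 0.15).
#' @param covariates list with elements `patient` and `control`, each a
#'   list of `age` (mean, sd), `male_frac`, `temperature` (mean, sd),
#'   `heart_rate` (mean, sd), `pulse_pressure` (mean, sd).
#' @param age_rv_effect slope of a cohort-wide nonlinear age effect added
#'   to every timing SD before simulation (confounding structure the GAM
#'   stage must remove); 0 disables it.
#' @param crsr_link named coefficients (`intercept` plus RV feature
#'   names) for the CRS-R mean; patients only.
#' @param crsr_noise_sd SD of the Gaussian noise on the CRS-R latent
#'   score (score units).
#' @param outcome_link named coefficients for the log-odds of improvement.
#' @param acc_noise_sd,drift_rate accelerometer noise SD and drift slope
#'   passed to [render_acceleration()].
#' @param window_s analysis window used to compute the true RV features
#'   feeding the links (s).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 44L, n_controls = 44L,
                        patient_spec = breath_process_spec(
                          mean_ti = 1.8, mean_te = 2.4, sd_ti = 0.32,
                          sd_te = 0.42, sd_amp = 0.16, ar1_rho = 0.6),
                        control_spec = breath_process_spec(),
                        subject_cv = 0.15,
                        covariates = default_covariates(),
                        age_rv_effect = 0,
                        crsr_link = c(intercept = 18, ie_ratio_sd2 = -28,
                                      rate_sd = -1.2),
                        crsr_noise_sd = 2,
                        outcome_link = c(intercept = 1.6, ie_ratio_sd2 = -6,
                                         amplitude_cv = -2),
                        acc_noise_sd = 0.05, drift_rate = 0.001,
                        window_s = 300) {
  if (!is.numeric(n_patients) || n_patients < 1 ||
      !is.numeric(n_controls) || n_controls < 1) {
    stop_param("n_patients/n_controls", "must be positive counts")
  }
  if (!"intercept" %in% names(crsr_link) ||
      !"intercept" %in% names(outcome_link)) {
    stop_param("crsr_link/outcome_link", "must contain an `intercept` term")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 patient_spec = patient_spec, control_spec = control_spec,
                 subject_cv = subject_cv, covariates = covariates,
                 age_rv_effect = age_rv_effect,
                 crsr_link = crsr_link, crsr_noise_sd = crsr_noise_sd,
                 outcome_link = outcome_link,
                 acc_noise_sd = acc_noise_sd, drift_rate = drift_rate,
                 window_s = window_s),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_covariates <- function() {
  list(
    patient = list(age = c(55.8, 17.8), male_frac = 13 / 44,
                   temperature = c(36.6, 0.4), heart_rate = c(83.6, 16),
                   pulse_pressure = c(46.5, 13)),
    control = list(age = c(45.8, 17), male_frac = 22 / 44,
                   temperature = c(36.4, 0.2), heart_rate = c(71.6, 11.7),
                   pulse_pressure = c(45.4, 9.8))
  )
}

draw_covariates <- function(cv) {
  list(age = round(min(max(rnorm(1, cv$age[1], cv$age[2]), 18), 75)),
       sex = if (runif(1) < cv$male_frac) "male" else "female",
       temperature = round(rnorm(1, cv$temperature[1], cv$temperature[2]), 1),
       heart_rate = round(rnorm(1, cv$heart_rate[1], cv$heart_rate[2])),
       pulse_pressure = round(rnorm(1, cv$pulse_pressure[1],
                                    cv$pulse_pressure[2])))
}

# per-subject multiplicative jitter of the group breath spec
jitter_spec <- function(spec, cv, age = NULL, age_effect = 0) {
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    j <- function(x) x * exp(rnorm(1, -sdl^2 / 2, sdl))
    spec$mean_ti <- j(spec$mean_ti); spec$mean_te <- j(spec$mean_te)
    spec$sd_ti <- j(spec$sd_ti); spec$sd_te <- j(spec$sd_te)
    spec$mean_amp <- j(spec$mean_amp); spec$sd_amp <- j(spec$sd_amp)
  }
  if (age_effect != 0 && !is.null(age)) {
    # smooth, saturating age effect on timing variability
    bump <- age_effect * plogis((age - 50) / 10)
    spec$sd_ti <- spec$sd_ti * (1 + bump)
    spec$sd_te <- spec$sd_te * (1 + bump)
  }
  spec
}

link_value <- function(link, features) {
  v <- unname(link["intercept"])
  for (nm in setdiff(names(link), "intercept")) {
    if (!nm %in% names(features)) {
      stop(sprintf("link references unknown RV feature `%s`", nm),
           call. = FALSE)
    }
    v <- v + link[[nm]] * features[[nm]]
  }
  v
}

#' Simulate a full cohort with ground truth
#'
#' Draws per-subject breath processes and covariates for both arms,
#' computes each subject's true RV feature profile from the ground-truth
#' breath table, attaches CRS-R scores (clamped to 0-23) and Bernoulli
#' improvement outcomes to patients through the configured links, and
#' optionally renders the accelerometer recordings.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed; all subject-level randomness is
#'   derived from it.
#' @param render if `FALSE`, skip accelerometer rendering (ground truth
#'   only; much faster for statistical simulations).
#' @return object of class `cohort`: list with `subjects` (one list per
#'   subject: `recording`, `breath_table`, `features`, `record`) and
#'   `spec`. Use [cohort_subjects()] and [cohort_features()] to extract
#'   the analysis tables.
#' @export
simulate_cohort <- function(spec, seed = 1L, render = TRUE) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec", call. = FALSE)
  }
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    s_i <- child_seed(seed, i)
    sub <- with_seed(s_i, {
      cvs <- draw_covariates(spec$covariates[[g]])
      bspec <- jitter_spec(
        if (g == "patient") spec$patient_spec else spec$control_spec,
        spec$subject_cv, age = cvs$age, age_effect = spec$age_rv_effect)
      list(cvs = cvs, bspec = bspec)
    })
    bt <- simulate_breath_sequence(sub$bspec, seed = child_seed(s_i, 1L))
    feats <- compute_rv_profile(window_select(bt, spec$window_s))
    record <- c(list(subject_id = sprintf("%s_%03d",
                                          substr(g, 1, 3), i),
                     group = g), sub$cvs,
                list(crsr_total = NA_integer_, crsr_latent = NA_real_,
                     outcome = NA_character_))
    if (g == "patient") {
      clin <- with_seed(child_seed(s_i, 2L), {
        latent <- link_value(spec$crsr_link, feats) +
          rnorm(1, 0, spec$crsr_noise_sd)
        pimp <- plogis(link_value(spec$outcome_link, feats))
        list(latent = latent,
             crsr = as.integer(min(max(round(latent), 0), 23)),
             outcome = if (rbinom(1, 1, pimp) == 1) "improved" else "unimproved")
      })
      record$crsr_latent <- clin$latent
      record$crsr_total <- clin$crsr
      record$outcome <- clin$outcome
    }
    rec <- NULL
    if (render) {
      rec <- render_acceleration(
        bt, fs = 10, noise_sd = spec$acc_noise_sd,
        drift_rate = spec$drift_rate, seed = child_seed(s_i, 3L),
        subject_id = record$subject_id)
    }
    subjects[[i]] <- list(recording = rec, breath_table = bt,
                          features = feats, record = record)
  }
  structure(list(subjects = subjects, spec = spec, seed = seed),
            class = "cohort")
}

#' Extract the subject covariate table of a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame, one row per subject: id, group, covariates, CRS-R
#'   total (patients), latent CRS-R before rounding/clamping, outcome.
#' @export
cohort_subjects <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    r <- s$record
    data.frame(subject_id = r$subject_id, group = r$group, age = r$age,
               sex = r$sex, temperature = r$temperature,
               heart_rate = r$heart_rate, pulse_pressure = r$pulse_pressure,
               crsr_total = r$crsr_total, crsr_latent = r$crsr_latent,
               outcome = r$outcome, stringsAsFactors = FALSE)
  }))
}

#' Extract the ground-truth RV feature table of a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame: `subject_id`, `n_breaths`, then the 35 RV metrics.
#' @export
cohort_features <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$record$subject_id,
               n_breaths = attr(s$features, "n_breaths"),
               as.list(unclass(s$features)), stringsAsFactors = FALSE)
  }))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients + %d controls (seed %d)\n",
              x$spec$n_patients, x$spec$n_controls, x$seed))
  invisible(x)
}
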