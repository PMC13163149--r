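#' Read a triaxial accelerometer recording from CSV
#'
#' Expects a header `time,ax,ay,az` with time in seconds. Rows with any
#' unparseable field are dropped with a warning reporting the count. The
#' sampling rate is taken from the median time step and must agree with
#' it within 1%.
#'
#' @param path CSV file path.
#' @param subject_id identifier attached to the recording (defaults to
#'   the file name without extension).
#' @return a `raw_recording` (see [render_acceleration()]).
#' @export
read_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE, strip.white = TRUE)
  need <- c("time", "ax", "ay", "az")
  if (!all(need %in% names(d))) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  d <- d[need]
  num <- suppressWarnings(lapply(d, as.numeric))
  ok <- Reduce(`&`, lapply(num, function(v) !is.na(v)))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("dropped %d unparseable row(s) in %s", n_bad, path),
            call. = FALSE)
  }
  d <- data.frame(lapply(num, `[`, ok))
  if (nrow(d) < 2L) stop("too few valid samples", call. = FALSE)
  if (any(diff(d$time) <= 0)) {
    stop("time column is not strictly increasing", call. = FALSE)
  }
  dt <- stats::median(diff(d$time))
  fs <- 1 / dt
  # occasional larger gaps (dropped rows) are tolerated; systematic
  # disagreement with the median step is not
  if (mean(abs(diff(d$time) - dt) > 0.01 * dt) > 0.01) {
    stop("irregular sampling: time steps deviate > 1% from the median",
         call. = FALSE)
  }
  if (max(d$time) - min(d$time) < 30) {
    stop("too short: recording must cover at least 30 s", call. = FALSE)
  }
  structure(d, fs = fs,
            subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
            class = c("raw_recording", "data.frame"))
}

new_resp_signal <- function(t, x, fs, provenance) {
  structure(list(t = t, x = x, fs = fs, provenance = provenance),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("respiratory signal: %d samples at %g Hz (%.1f s)\n",
              length(x$x), x$fs, max(x$t) - min(x$t)))
  cat("provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                           collapse = " -> "), "\n")
  invisible(x)
}

band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}

#' Select the respiratory axis of a triaxial recording
#'
#' Picks the axis carrying the most spectral power in the respiratory
#' band and returns it mean-removed as a one-dimensional respiratory
#' signal. Ties go to the lowest axis index (x before y before z).
#'
#' @param raw a `raw_recording`.
#' @param band length-2 frequency band (Hz), default 0.1-0.7.
#' @return a `resp_signal` whose provenance records the chosen axis.
#' @export
select_axis <- function(raw, band = c(0.1, 0.7)) {
  fs <- attr(raw, "fs")
  pw <- vapply(c("ax", "ay", "az"),
               function(a) band_power(raw[[a]], fs, band), 0)
  axis <- c("ax", "ay", "az")[which.max(pw)] # which.max: first of ties
  x <- raw[[axis]] - mean(raw[[axis]])
  new_resp_signal(raw$time, x, fs,
                  list(list(op = "select_axis", axis = axis, band = band)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase), preserving breath timing. The default 0.1-0.7 Hz band
#' spans supine breathing rates of 6-42 breaths/min.
#'
#' @param sig a `resp_signal`.
#' @param low,high band edges (Hz); must satisfy 0 < low < high < fs/2.
#' @param order filter order (default 4).
#' @return filtered `resp_signal`.
#' @export
bandpass_filter <- function(sig, low = 0.1, high = 0.7, order = 4L) {
  fs <- sig$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_param("low/high", sprintf(
      "band must satisfy 0 < low < high < fs/2 = %g", fs / 2))
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding keeps the forward-backward pass's start-up
  # transient out of the data (it decays over several 1/low periods)
  n <- length(sig$x)
  pad <- min(n - 1L, ceiling(9 / low * fs))
  xp <- c(2 * sig$x[1] - sig$x[(pad + 1L):2L],
          sig$x,
          2 * sig$x[n] - sig$x[(n - 1L):(n - pad)])
  x <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  new_resp_signal(sig$t, x, fs,
                  c(sig$provenance,
                    list(list(op = "bandpass_filter", low = low, high = high,
                              order = order))))
}

#' Centred moving average
#'
#' Smooths with a centred moving mean; edge windows shrink rather than
#' padding with invented values.
#'
#' @param sig a `resp_signal`.
#' @param window window length in seconds (default 0.5; at least one
#'   sample, at most the signal length).
#' @return smoothed `resp_signal`.
#' @export
moving_average <- function(sig, window = 0.5) {
  n <- length(sig$x)
  k <- max(1L, round(window * sig$fs))
  if (k > n) stop_param("window", "longer than the signal")
  half <- (k - 1L) %/% 2L
  hi_half <- k - 1L - half
  cs <- cumsum(c(0, sig$x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + hi_half, n)
  x <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new_resp_signal(sig$t, x, sig$fs,
                  c(sig$provenance,
                    list(list(op = "moving_average", window = window))))
}

#' Adaptive baseline drift correction
#'
#' Subtracts a rolling-median baseline (default 20-s window). The median
#' is robust to apneic segments, so pathological recordings are detrended
#' without distorting breath amplitudes.
#'
#' @param sig a `resp_signal`.
#' @param window baseline window in seconds (default 20).
#' @return drift-corrected `resp_signal`.
#' @export
correct_drift <- function(sig, window = 20) {
  k <- round(window * sig$fs)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(sig$x) - (1 - length(sig$x) %% 2L))
  if (k < 3L) k <- 3L
  base <- stats::runmed(sig$x, k, endrule = "keep")
  # constant-extend the interior estimate over the outer half-windows:
  # shrinking end windows would track the signal itself
  h <- (k - 1L) %/% 2L
  n <- length(base)
  if (n > 2L * h) {
    base[seq_len(h)] <- base[h + 1L]
    base[(n - h + 1L):n] <- base[n - h]
  }
  new_resp_signal(sig$t, sig$x - base, sig$fs,
                  c(sig$provenance,
                    list(list(op = "correct_drift", window = window))))
}

#' Quality control of a conditioned respiratory signal
#'
#' Run on the axis-selected (unfiltered) signal. Internally band-passes
#' a working copy to assess breathing activity: `apnea_fraction` is the
#' fraction of 5-s windows whose in-window IQR falls below 10% of the
#' global IQR; `biot_pattern` is flagged when that fraction exceeds
#' `apnea_max` and breathing resumes in two or more distinct clusters;
#' `low_snr` when the spectral in-band SNR estimate is below `snr_min`
#' dB; `too_short` below `min_duration` seconds. A recording is usable
#' only when no flag is raised.
#'
#' @param sig a `resp_signal` (axis-selected, before band-pass filtering).
#' @param band respiratory band for the internal filter and SNR estimate.
#' @param apnea_max apnea-fraction threshold (default 0.2).
#' @param snr_min minimum acceptable SNR (dB, default 3).
#' @param min_duration minimum recording length (s, default 300).
#' @return object of class `qc_report`: list with `flags`,
#'   `apnea_fraction`, `snr_db`, `usable`.
#' @export
quality_check <- function(sig, band = c(0.1, 0.7), apnea_max = 0.2,
                          snr_min = 3, min_duration = 300) {
  flags <- character(0)
  dur <- max(sig$t) - min(sig$t)
  if (dur < min_duration) flags <- c(flags, "too_short")

  # spectral SNR: respiratory-band power above the broadband noise floor
  sp <- stats::spec.pgram(stats::ts(sig$x, frequency = sig$fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  inband <- sp$freq >= band[1] & sp$freq <= band[2]
  noise_floor <- stats::median(sp$spec[!inband & sp$freq > band[2]])
  if (!is.finite(noise_floor) || noise_floor <= 0) {
    noise_floor <- .Machine$double.eps
  }
  p_sig <- max(sum(sp$spec[inband]) - noise_floor * sum(inband),
               .Machine$double.eps)
  p_noise <- noise_floor * length(sp$spec)
  snr_db <- 10 * log10(p_sig / p_noise)
  if (snr_db < snr_min) flags <- c(flags, "low_snr")

  # breathing-activity envelope on a smoothed, baseline-removed working
  # copy (a band-passed copy would ring into apneic pauses): a window is
  # apneic when its peak-to-peak excursion falls below 10% of the
  # upper-quantile (breathing) window amplitude, a reference that stays
  # above the noise floor even when most of the recording is apneic
  xf <- if (dur > 45) correct_drift(moving_average(sig, 0.5))$x else sig$x
  apnea_fraction <- 0
  starts <- seq(0, dur - 5, by = 2.5) # 5-s windows, 50% overlap
  if (length(starts) >= 2) {
    t0 <- min(sig$t)
    amp <- vapply(starts, function(s0) {
      v <- xf[sig$t - t0 >= s0 & sig$t - t0 < s0 + 5]
      diff(range(v))
    }, 0)
    quiet <- amp < 0.1 * stats::quantile(amp, 0.9)
    apnea_fraction <- mean(quiet)
    if (apnea_fraction > apnea_max) {
      # clustered resumption: >= 2 separate runs of active windows
      runs <- rle(quiet)
      n_active_runs <- sum(!runs$values)
      if (n_active_runs >= 2) flags <- c(flags, "biot_pattern")
      else flags <- c(flags, "apnea_fraction_high")
    }
  }
  structure(list(flags = flags, apnea_fraction = apnea_fraction,
                 snr_db = snr_db, usable = length(flags) == 0L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %s (apnea fraction %.2f, SNR %.1f dB)\n",
              if (x$usable) "usable" else
                paste("flagged:", paste(x$flags, collapse = ", ")),
              x$apnea_fraction, x$snr_db))
  invisible(x)
}

#' Condition a raw recording into a respiratory waveform
#'
#' Standard conditioning chain: axis selection, quality control,
#' band-pass filtering, moving-average smoothing and rolling-median
#' drift correction. The unfiltered axis-selected signal is kept as an
#' attribute for extremum-time refinement during breath segmentation.
#'
#' @param raw a `raw_recording`.
#' @param band,order band-pass parameters.
#' @param ma_window moving-average window (s).
#' @param qc if `TRUE` (default) run [quality_check()] and attach the
#'   report; conditioning proceeds regardless so callers decide on
#'   exclusion.
#' @return conditioned `resp_signal` with attributes `qc` (a
#'   `qc_report` or `NULL`) and `axis` (the axis-selected signal before
#'   filtering, used for extremum-time refinement).
#' @export
condition_signal <- function(raw, band = c(0.1, 0.7), order = 4L,
                             ma_window = 0.5, qc = TRUE) {
  ax <- select_axis(raw, band)
  report <- if (qc) quality_check(ax, band) else NULL
  out <- correct_drift(moving_average(
    bandpass_filter(ax, band[1], band[2], order), ma_window))
  attr(out, "qc") <- report
  attr(out, "axis") <- ax
  out
}
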