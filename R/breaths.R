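#' Detect alternating troughs and peaks in a conditioned signal
#'
#' Local extrema are screened by topographic prominence (at least
#' `min_prominence_frac` of the signal IQR) and by a minimum separation
#' between same-type extrema (`min_breath_s`, capping the detectable
#' rate). The surviving sequence is forced into strict trough-peak
#' alternation: within any run of same-type extrema only the most
#' extreme sample is kept.
#'
#' @param sig a `resp_signal`.
#' @param min_breath_s minimum breath duration (s, default 1.5 — a
#'   40 breaths/min ceiling).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   signal IQR (default 0.3).
#' @return data.frame with columns `index`, `time`, `value`, `type`
#'   ("trough"/"peak"), strictly alternating.
#' @export
detect_extrema <- function(sig, min_breath_s = 1.5,
                           min_prominence_frac = 0.3) {
  x <- sig$x
  n <- length(x)
  d <- diff(x)
  # local extrema; plateaus resolved to their first sample
  s <- sign(d)
  s[s == 0] <- 1
  turn <- diff(s)
  pk <- which(turn < 0) + 1L
  tr <- which(turn > 0) + 1L
  prom_min <- min_prominence_frac * stats::IQR(x)

  # topographic prominence: saddle heights to the nearest higher extremum
  # on each side (or the series boundary)
  keep_prominent <- function(idx, sign_) {
    if (length(idx) == 0L) return(idx)
    v <- sign_ * x[idx]
    xs <- sign_ * x
    ok <- logical(length(idx))
    for (j in seq_along(idx)) {
      higher_l <- which(v[seq_len(j - 1L)] > v[j])
      lo <- if (length(higher_l)) idx[max(higher_l)] else 1L
      higher_r <- which(v[-seq_len(j)] > v[j])
      hi <- if (length(higher_r)) idx[j + min(higher_r)] else n
      col_l <- min(xs[lo:idx[j]])
      col_r <- min(xs[idx[j]:hi])
      ok[j] <- (v[j] - max(col_l, col_r)) >= prom_min
    }
    idx[ok]
  }
  pk <- keep_prominent(pk, +1)
  tr <- keep_prominent(tr, -1)

  # enforce minimum separation between same-type extrema (keep larger)
  enforce_sep <- function(idx, sign_) {
    min_gap <- round(min_breath_s * sig$fs)
    repeat {
      if (length(idx) < 2L) return(idx)
      gaps <- diff(idx)
      bad <- which(gaps < min_gap)
      if (length(bad) == 0L) return(idx)
      b <- bad[1L]
      drop <- if (sign_ * x[idx[b]] < sign_ * x[idx[b + 1L]]) b else b + 1L
      idx <- idx[-drop]
    }
  }
  pk <- enforce_sep(pk, +1)
  tr <- enforce_sep(tr, -1)

  ev <- rbind(data.frame(index = pk, type = rep("peak", length(pk))),
              data.frame(index = tr, type = rep("trough", length(tr))))
  ev <- ev[order(ev$index), , drop = FALSE]
  if (nrow(ev) >= 2L) {
    # strict alternation: in same-type runs keep the most extreme sample
    r <- rle(ev$type)
    keep <- integer(0)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      run <- seq(pos, pos + r$lengths[k] - 1L)
      vals <- x[ev$index[run]]
      best <- if (r$values[k] == "peak") run[which.max(vals)] else
        run[which.min(vals)]
      keep <- c(keep, best)
      pos <- pos + r$lengths[k]
    }
    ev <- ev[keep, , drop = FALSE]
  }
  if (nrow(ev) < 3L) stop("no breaths detected", call. = FALSE)
  data.frame(index = ev$index, time = sig$t[ev$index],
             value = x[ev$index], type = ev$type, row.names = NULL)
}

#' Refine extremum times on the unprocessed axis signal
#'
#' Band-pass filtering displaces the extrema of asymmetric breaths, and
#' peak-picking on a noisy trace is limited by the flatness of the
#' waveform around its turning points. Refinement therefore re-estimates
#' each extremum on the raw (unsmoothed) axis signal, where the noise is
#' uncorrelated and least squares can exploit the steep breath limbs:
#' first a local quadratic vertex fit around each extremum, then
#' coordinate-wise refits of each extremum's (time, value) against a
#' cosine half-wave segment model spanning its two neighbours, iterated
#' to convergence. The segment model matches the raised-cosine breath
#' shape this package's simulator renders; for other morphologies the
#' quadratic stage alone can be selected.
#'
#' @param extrema alternating extrema from [detect_extrema()].
#' @param ref `resp_signal` to refine against (normally the axis-selected
#'   signal without smoothing or filtering).
#' @param method `"cosine"` (quadratic init + cosine-segment coordinate
#'   descent, default), `"quadratic"` (vertex fit only) or `"none"`.
#' @param half_s half-width of the quadratic fit window (s).
#' @param iters,tol coordinate-descent iteration cap and convergence
#'   tolerance on the largest time move (s).
#' @return extrema data.frame with refined `time` and `value` (the
#'   `index` column refers to the nearest sample).
#' @export
refine_extrema <- function(extrema, ref,
                           method = c("cosine", "quadratic", "none"),
                           half_s = 0.5, iters = 8L, tol = 0.005) {
  method <- match.arg(method)
  if (method == "none") return(extrema)
  t <- ref$t
  x <- ref$x
  fs <- ref$fs
  h <- round(half_s * fs)
  n <- length(x)
  for (j in seq_len(nrow(extrema))) {
    i0 <- which.min(abs(t - extrema$time[j]))
    win <- max(1L, i0 - h):min(n, i0 + h)
    tt <- t[win] - t[i0]
    xx <- if (extrema$type[j] == "trough") -x[win] else x[win]
    b <- stats::.lm.fit(cbind(1, tt, tt^2), xx)$coefficients
    if (b[3] < 0 && abs(-b[2] / (2 * b[3])) <= half_s) {
      extrema$time[j] <- t[i0] - b[2] / (2 * b[3])
    }
  }
  extrema$value <- stats::approx(t, x, extrema$time, rule = 2)$y
  if (method == "quadratic" || nrow(extrema) < 3L) {
    extrema$index <- vapply(extrema$time,
                            function(tm) which.min(abs(t - tm)), 0L)
    return(extrema)
  }
  # coordinate descent on the joint piecewise-cosine least-squares fit:
  # each pass re-optimises one extremum's (time, value) over the segment
  # bracketed by its neighbours, which carries that extremum's entire
  # contribution to the global residual
  seg_model <- function(tl, vl, tm, vm, tr, vr, tt) {
    out <- numeric(length(tt))
    L <- tt <= tm
    out[L] <- vl + (vm - vl) / 2 * (1 - cos(pi * (tt[L] - tl) / (tm - tl)))
    out[!L] <- vm + (vr - vm) / 2 * (1 - cos(pi * (tt[!L] - tm) / (tr - tm)))
    out
  }
  m <- nrow(extrema)
  for (it in seq_len(iters)) {
    max_move <- 0
    for (j in 2:(m - 1L)) {
      tl <- extrema$time[j - 1L]; vl <- extrema$value[j - 1L]
      tr <- extrema$time[j + 1L]; vr <- extrema$value[j + 1L]
      sel <- t > tl & t < tr
      tt <- t[sel]; xx <- x[sel]
      if (length(tt) < 6L) next
      obj <- function(p) {
        if (p[1] <= tl + 0.25 || p[1] >= tr - 0.25) return(1e9)
        sum((seg_model(tl, vl, p[1], p[2], tr, vr, tt) - xx)^2)
      }
      fit <- stats::optim(c(extrema$time[j], extrema$value[j]), obj,
                          control = list(maxit = 200, reltol = 1e-8))
      max_move <- max(max_move, abs(fit$par[1] - extrema$time[j]))
      extrema$time[j] <- fit$par[1]
      extrema$value[j] <- fit$par[2]
    }
    if (max_move < tol) break
  }
  extrema$index <- vapply(extrema$time,
                          function(tm) which.min(abs(t - tm)), 0L)
  extrema
}

#' Segment an extrema sequence into a breath table
#'
#' Each trough-peak-trough triple becomes one breath: inspiration from
#' onset trough to peak (Ti), expiration from peak to the next trough
#' (Te). Partial breaths at the boundaries are dropped. Signal polarity
#' is auto-detected by default: if the rising limb is the longer one in
#' the median breath, the signal is taken as inverted and the extrema
#' roles are swapped (inspiration is typically the shorter limb).
#'
#' @param extrema output of [detect_extrema()].
#' @param sig the `resp_signal` the extrema came from.
#' @param polarity `"auto"` (default), `"up"` (peaks are end-inspiration)
#'   or `"down"`.
#' @return breath-table data.frame: `onset`, `peak`, `offset`, `ti`,
#'   `te`, `ttot`, `rate`, `ie_ratio`, `amplitude`.
#' @export
segment_breaths <- function(extrema, sig, polarity = c("auto", "up", "down")) {
  polarity <- match.arg(polarity)
  make_table <- function(ev) {
    tr <- which(ev$type == "trough")
    rows <- list()
    for (j in tr) {
      if (j + 2L > nrow(ev)) break
      if (ev$type[j + 1L] != "peak" || ev$type[j + 2L] != "trough") next
      onset <- ev$time[j]; peak <- ev$time[j + 1L]; offset <- ev$time[j + 2L]
      amp <- ev$value[j + 1L] - min(ev$value[j], ev$value[j + 2L])
      rows[[length(rows) + 1L]] <-
        data.frame(onset = onset, peak = peak, offset = offset,
                   ti = peak - onset, te = offset - peak,
                   ttot = offset - onset, rate = 60 / (offset - onset),
                   ie_ratio = (peak - onset) / (offset - peak),
                   amplitude = amp)
    }
    if (length(rows) == 0L) stop("no breaths detected", call. = FALSE)
    do.call(rbind, rows)
  }
  flip <- function(ev) {
    ev$type <- ifelse(ev$type == "peak", "trough", "peak")
    ev$value <- -ev$value
    ev
  }
  bt <- make_table(extrema)
  if (polarity == "down" ||
      (polarity == "auto" && stats::median(bt$ti) > stats::median(bt$te))) {
    bt2 <- try(make_table(flip(extrema)), silent = TRUE)
    if (!inherits(bt2, "try-error")) {
      bt2$amplitude <- abs(bt2$amplitude)
      bt <- bt2
    }
  }
  rownames(bt) <- NULL
  bt
}

#' Restrict a breath table to an analysis window
#'
#' Keeps breaths whose onset falls within `duration` seconds of the
#' first complete breath's onset.
#'
#' @param bt breath table.
#' @param duration window length (s, default 300).
#' @return windowed breath table.
#' @export
window_select <- function(bt, duration = 300) {
  span <- max(bt$offset) - min(bt$onset)
  if (span < duration) {
    stop(sprintf("windowing error: recording spans %.1f s < %.1f s window",
                 span, duration), call. = FALSE)
  }
  t0 <- min(bt$onset)
  out <- bt[bt$onset - t0 < duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a breath table from a raw recording
#'
#' Convenience wrapper: condition the signal ([condition_signal()]),
#' detect and refine extrema, segment breaths. Extremum times are
#' refined on the unfiltered (smoothed, drift-corrected) axis signal so
#' band-pass phase distortion of asymmetric breaths cannot bias Ti/Te.
#'
#' @param raw a `raw_recording`.
#' @param band,order,ma_window conditioning parameters
#'   (see [condition_signal()]).
#' @param min_breath_s,min_prominence_frac segmentation thresholds
#'   (see [detect_extrema()]).
#' @param refine extremum-time refinement method (see [refine_extrema()]).
#' @param polarity see [segment_breaths()].
#' @param qc run quality control; if the recording is unusable an error
#'   of class `respvar_qc_error` is raised carrying the report.
#' @return breath table with attribute `qc`.
#' @export
extract_breaths <- function(raw, band = c(0.1, 0.7), order = 4L,
                            ma_window = 0.5, min_breath_s = 1.5,
                            min_prominence_frac = 0.3, refine = "cosine",
                            polarity = "auto", qc = TRUE) {
  sig <- condition_signal(raw, band, order, ma_window, qc = qc)
  report <- attr(sig, "qc")
  if (qc && !report$usable) {
    stop(structure(class = c("respvar_qc_error", "error", "condition"),
                   list(message = sprintf(
                     "recording %s failed QC: %s",
                     attr(raw, "subject_id") %||% "?",
                     paste(report$flags, collapse = ", ")),
                     call = NULL, qc = report)))
  }
  ex <- detect_extrema(sig, min_breath_s, min_prominence_frac)
  ex <- refine_extrema(ex, attr(sig, "axis"), method = refine)
  # the outermost extrema sit in the band-pass edge-transient region and
  # anchor the refinement one-sidedly; drop two at each end so every kept
  # extremum was refined between well-refined neighbours
  if (refine == "cosine" && nrow(ex) >= 7L) {
    ex <- ex[-c(1:2, nrow(ex) - 1L, nrow(ex)), , drop = FALSE]
  }
  bt <- segment_breaths(ex, sig, polarity)
  attr(bt, "qc") <- report
  bt
}
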