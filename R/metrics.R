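#' Time-domain respiratory variability metrics
#'
#' The RV metric suite applied to each per-breath parameter series
#' (rate, Ti, Te, I/E ratio, amplitude): standard deviation, coefficient
#' of variation, root mean square of successive differences (RMSSD),
#' triangular index, and the Poincare plot descriptors SD1, SD2 and
#' ellipse area.
#'
#' @name rv-metrics
NULL

#' Sample standard deviation of a parameter series
#'
#' @param x numeric series (length >= 2).
#' @return sample SD (n - 1 denominator).
#' @export
rv_sd <- function(x) {
  if (length(x) < 2L) stop("`x` must have length >= 2", call. = FALSE)
  stats::sd(x)
}

#' Coefficient of variation
#'
#' @param x numeric series (length >= 2, non-zero mean).
#' @return unitless CV = sd(x) / mean(x).
#' @export
rv_cv <- function(x) {
  if (length(x) < 2L) stop("`x` must have length >= 2", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined: series mean is 0",
                   call. = FALSE)
  stats::sd(x) / m
}

#' Root mean square of successive differences
#'
#' @param x numeric series (length >= 2), in time order; the mean square
#'   is taken over the n - 1 successive differences.
#' @return RMSSD in the units of `x`.
#' @export
rmssd <- function(x) {
  if (length(x) < 2L) stop("`x` must have length >= 2", call. = FALSE)
  d <- diff(x)
  sqrt(mean(d^2))
}

#' Triangular index
#'
#' Geometric dispersion measure borrowed from heart-rate variability:
#' total sample count divided by the count in the modal histogram bin.
#' Bins have fixed width and are anchored at zero, so the index does not
#' depend on the sample range. Values lie in \[1, n\]: 1 for a degenerate
#' (single-bin) series, n when every value occupies its own bin.
#'
#' @param x numeric series (length >= 10).
#' @param bin_width positive bin width in the units of `x`.
#' @return triangular index (unitless, >= 1).
#' @export
triangular_index <- function(x, bin_width) {
  if (length(x) < 10L) stop("`x` must have length >= 10", call. = FALSE)
  check_positive(bin_width, "bin_width")
  idx <- floor(x / bin_width)
  length(x) / max(table(idx))
}

#' Poincare plot descriptors SD1, SD2 and ellipse area
#'
#' From the lag-1 scatter of the series, SD1 is the dispersion
#' perpendicular to the identity line (short-term variability) and SD2
#' the dispersion along it (long-term variability). Both are population
#' (n) standard deviations of the rotated coordinates, the convention
#' under which SD1 equals RMSSD / sqrt(2) for series whose successive
#' differences have zero mean.
#'
#' @param x numeric series (length >= 3).
#' @return named list with `sd1`, `sd2` and `ellipse_area` = pi * sd1 * sd2.
#' @export
poincare <- function(x) {
  if (length(x) < 3L) stop("`x` must have length >= 3", call. = FALSE)
  xi <- x[-length(x)]
  xj <- x[-1L]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sd1 <- pop_sd((xi - xj) / sqrt(2))
  sd2 <- pop_sd((xi + xj) / sqrt(2))
  list(sd1 = sd1, sd2 = sd2, ellipse_area = pi * sd1 * sd2)
}

# default triangular-index bin widths per respiratory parameter;
# amplitude uses a data-driven width (IQR / 10) since its units are arbitrary
tri_bin_width <- function(parameter, x, bin_widths = NULL) {
  defaults <- list(ti = 0.1, te = 0.1, rate = 1, ie_ratio = 0.05)
  bw <- bin_widths[[parameter]] %||% defaults[[parameter]]
  if (is.null(bw)) {
    bw <- stats::IQR(x) / 10
    if (bw <= 0) bw <- max(abs(x), 1) * 1e-6 # degenerate series: single bin
  }
  bw
}

#' Parameters and metrics making up an RV profile
#'
#' @return character vector of the 5 parameter or 7 metric names.
#' @export
rv_parameters <- function() c("rate", "ti", "te", "ie_ratio", "amplitude")

#' @rdname rv_parameters
#' @export
rv_metrics <- function() {
  c("sd", "cv", "rmssd", "tri_index", "sd1", "sd2", "ellipse_area")
}

#' Compute the full RV profile of a breath table
#'
#' Applies the seven RV metrics to each of the five per-breath parameter
#' series, yielding the 35 `<parameter>_<metric>` features used by the
#' group comparison and prediction stages.
#'
#' @param bt breath table (see [segment_breaths()]), normally restricted
#'   to a 300-s analysis window with [window_select()].
#' @param min_breaths minimum breath count for a valid profile (default 10).
#' @param bin_widths optional named list overriding triangular-index bin
#'   widths per parameter.
#' @return object of class `rv_profile`: named numeric vector of the 35
#'   metrics plus attributes `n_breaths` and `window_s`.
#' @export
compute_rv_profile <- function(bt, min_breaths = 10L, bin_widths = NULL) {
  if (!is.data.frame(bt) || nrow(bt) < min_breaths) {
    stop(sprintf("invalid profile: need >= %d breaths, got %d",
                 min_breaths, if (is.data.frame(bt)) nrow(bt) else 0L),
         call. = FALSE)
  }
  series <- list(rate = bt$rate, ti = bt$ti, te = bt$te,
                 ie_ratio = bt$ie_ratio, amplitude = bt$amplitude)
  out <- numeric(0)
  for (p in names(series)) {
    x <- series[[p]]
    pc <- poincare(x)
    vals <- c(sd = rv_sd(x), cv = rv_cv(x), rmssd = rmssd(x),
              tri_index = triangular_index(x, tri_bin_width(p, x, bin_widths)),
              sd1 = pc$sd1, sd2 = pc$sd2, ellipse_area = pc$ellipse_area)
    names(vals) <- paste(p, names(vals), sep = "_")
    out <- c(out, vals)
  }
  window_s <- max(bt$offset) - min(bt$onset)
  structure(out, n_breaths = nrow(bt), window_s = window_s,
            class = "rv_profile")
}

#' @export
print.rv_profile <- function(x, ...) {
  cat(sprintf("RV profile: %d breaths over %.1f s\n",
              attr(x, "n_breaths"), attr(x, "window_s")))
  m <- matrix(unclass(x), nrow = length(rv_parameters()), byrow = TRUE,
              dimnames = list(rv_parameters(), rv_metrics()))
  print(round(m, 4), ...)
  invisible(x)
}
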