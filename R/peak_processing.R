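# Raw spectrum -> calibrated, control-list-matched peaks: rolling-min/mean
# baseline, MAD noise with iterative peak masking, S/N-gated local-maximum
# detection with valley-bounded trapezoidal areas, single-point internal
# recalibration on the 15N standard, and nearest-assignment matching.

# rolling minimum / maximum over +/- k points, edge-padded
.rolling_extreme <- function(x, k, fun) {
  n <- length(x)
  out <- x
  for (s in seq_len(k)) {
    out <- fun(out,
               c(x[(s + 1):n], rep(x[n], s)),
               c(rep(x[1], s), x[1:(n - s)]))
  }
  out
}
.rolling_min <- function(x, k) .rolling_extreme(x, k, pmin)
.rolling_max <- function(x, k) .rolling_extreme(x, k, pmax)

# centered rolling mean over +/- k points, edge-padded
.rolling_mean <- function(x, k) {
  n <- length(x)
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  cs <- cumsum(xp)
  (cs[(2 * k + 1):(n + 2 * k)] - c(0, cs[1:(n - 1)])) / (2 * k + 1)
}

#' Estimate the spectrum baseline
#'
#' Morphological rolling-minimum/rolling-maximum opening over a window wide
#' enough to span any peak, followed by a short rolling mean for noise
#' smoothing. The opening clips peaks narrower than the window while
#' reconstructing smooth monotone backgrounds (such as an exponentially
#' decaying matrix baseline) without the half-window lag a plain rolling
#' minimum introduces.
#'
#' @param spectrum A [mass_spectrum()].
#' @param window Window width in Da; must exceed the grid step and be smaller
#'   than the full m/z range. Default 100 Da (about 25 peak sigmas at the
#'   simulator default).
#' @return Numeric baseline trace, same length as the spectrum.
#' @export
estimate_baseline <- function(spectrum, window = 100) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  step <- stats::median(diff(spectrum$mz))
  if (window <= step) stop("baseline window must exceed the grid step")
  if (window >= diff(range(spectrum$mz))) {
    stop("baseline window must be smaller than the full m/z range")
  }
  k <- max(1L, as.integer(round(window / (2 * step))))
  x <- spectrum$intensity
  n <- length(x)
  # opening on an edge-replicated signal: the dilation then sees an unclipped
  # minimum at the boundary, so monotone baselines are reconstructed exactly
  # up to the spectrum edges
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  opened <- .rolling_max(.rolling_min(xp, k), k)[(k + 1L):(k + n)]
  .rolling_mean(opened, max(1L, k %/% 4L))
}

#' Estimate the noise standard deviation
#'
#' `1.4826 * mad` of the baseline-subtracted residual over peak-free regions,
#' found by iteratively masking points above 3x the current estimate.
#'
#' @param spectrum A [mass_spectrum()] with more than 50 points.
#' @param baseline Baseline trace from [estimate_baseline()] (or zeros).
#' @param max_iter Maximum masking iterations.
#' @return Noise SD (intensity units); `0` for a noise-free trace.
#' @export
estimate_noise <- function(spectrum, baseline = NULL, max_iter = 10L) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (length(spectrum$mz) <= 50) stop("spectrum must have more than 50 points")
  if (is.null(baseline)) baseline <- numeric(length(spectrum$mz))
  r <- spectrum$intensity - baseline
  keep <- rep(TRUE, length(r))
  est <- stats::mad(r[keep], center = stats::median(r[keep]))
  for (i in seq_len(max_iter)) {
    if (est == 0) break
    new_keep <- abs(r - stats::median(r[keep])) <= 3 * est
    if (!any(new_keep)) stop("all points masked while estimating noise")
    if (identical(new_keep, keep)) break
    keep <- new_keep
    est <- stats::mad(r[keep], center = stats::median(r[keep]))
  }
  est
}

#' Detect peaks above a signal-to-noise threshold
#'
#' Strict local maxima of the baseline-subtracted trace whose apex is at least
#' `snr_threshold * noise_sd`. For each peak: the centroid is the
#' intensity-weighted mean m/z over the contiguous region above half-apex; the
#' area is the trapezoidal integral of the baseline-subtracted intensity over
#' the region bounded by the flanking valley minima (a local minimum only
#' qualifies as a boundary once the trace has dropped below half-apex, so a
#' noise dip on a peak flank does not truncate it) or by a +/- 4 sigma-hat
#' window, whichever is narrower, with sigma-hat taken from the full width at
#' half maximum.
#'
#' @param spectrum A [mass_spectrum()].
#' @param baseline Baseline trace (default: zeros).
#' @param noise_sd Noise SD; `0` disables the gate denominator (all local
#'   maxima reported with infinite S/N).
#' @param snr_threshold Detection gate, default 5.
#' @param smooth If `TRUE`, apply an odd-window Savitzky-Golay filter
#'   (`signal::sgolayfilt`) to the subtracted trace before detection.
#' @param smooth_window Odd filter window length (points).
#' @return data.frame of class `peak_list`: `centroid_mz`, `apex_mz`,
#'   `apex_intensity`, `area`, `snr`, `matched_label` (NA until
#'   [match_peaks()]).
#' @export
detect_peaks <- function(spectrum, baseline = NULL, noise_sd = NULL,
                         snr_threshold = 5, smooth = FALSE,
                         smooth_window = 7L) {
  stopifnot(inherits(spectrum, "mass_spectrum"), snr_threshold >= 0)
  m <- spectrum$mz
  if (is.null(baseline)) baseline <- numeric(length(m))
  y <- spectrum$intensity - baseline
  if (smooth) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("smoothing requires the signal package")
    }
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    y <- signal::sgolayfilt(y, p = 2, n = smooth_window)
  }
  if (is.null(noise_sd)) noise_sd <- estimate_noise(spectrum, baseline)
  stopifnot(noise_sd >= 0)
  n <- length(y)
  empty <- data.frame(centroid_mz = numeric(), apex_mz = numeric(),
                      apex_intensity = numeric(), area = numeric(),
                      snr = numeric(), matched_label = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3L) return(empty)
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1]
  snr <- if (noise_sd > 0) y[i] / noise_sd else ifelse(y[i] > 0, Inf, 0)
  apex <- i[is_max & snr >= snr_threshold & y[i] > 0]
  if (!length(apex)) return(empty)
  step <- stats::median(diff(m))
  rows <- lapply(apex, function(a) {
    h <- y[a]
    half <- h / 2
    # contiguous above-half region for centroid and FWHM
    lo <- a
    while (lo > 1L && y[lo - 1L] >= half) lo <- lo - 1L
    hi <- a
    while (hi < n && y[hi + 1L] >= half) hi <- hi + 1L
    reg <- lo:hi
    w <- pmax(y[reg], 0)
    centroid <- if (sum(w) > 0) sum(m[reg] * w) / sum(w) else m[a]
    sigma_hat <- max((m[hi] - m[lo]), step) / 2.3548
    cap <- 4 * sigma_hat
    # integration bounds: walk out to a qualifying valley or the 4-sigma cap
    il <- a
    while (il > 1L && m[a] - m[il - 1L] <= cap &&
           !(y[il] < half && y[il - 1L] > y[il])) il <- il - 1L
    ir <- a
    while (ir < n && m[ir + 1L] - m[a] <= cap &&
           !(y[ir] < half && y[ir + 1L] > y[ir])) ir <- ir + 1L
    seg <- il:ir
    ys <- pmax(y[seg], 0)
    area <- sum(diff(m[seg]) * (ys[-length(ys)] + ys[-1]) / 2)
    data.frame(centroid_mz = centroid, apex_mz = m[a], apex_intensity = h,
               area = area, snr = if (noise_sd > 0) h / noise_sd else Inf,
               matched_label = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Single-point internal recalibration on the standard peak
#'
#' Finds the detected peak nearest the control list's standard entry within a
#' +/- `search_window` Da window (nearest by absolute m/z difference, ties
#' broken toward the larger area) and applies the additive shift
#' `expected - observed` to every centroid. With no standard entry
#' (mutant-ubiquitin mode) the identity model is returned and a message
#' logged.
#'
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param control_list A [build_mass_control_list()].
#' @param search_window Standard search half-window, Da (default 20).
#' @return List with `model` (class `calibration_model`: `shift`,
#'   `anchor_label`, `residual`) and `peaks` (shifted centroids).
#' @export
calibrate <- function(peaks, control_list, search_window = 20) {
  stopifnot(inherits(peaks, "data.frame"),
            inherits(control_list, "mass_control_list"))
  std <- control_list[control_list$role == "standard", , drop = FALSE]
  if (!nrow(std)) {
    message("no standard entry in control list; calibration is the identity")
    model <- structure(list(shift = 0, anchor_label = NA_character_,
                            residual = 0), class = "calibration_model")
    return(list(model = model, peaks = peaks))
  }
  d <- abs(peaks$centroid_mz - std$expected_mz)
  cand <- which(d <= search_window)
  if (!length(cand)) {
    stop("calibration failed: no detected peak within +/-", search_window,
         " Da of the standard (", std$label, " at ",
         round(std$expected_mz, 1), ")")
  }
  # nearest; ties toward higher area
  cand <- cand[order(d[cand], -peaks$area[cand])]
  anchor <- cand[1]
  shift <- std$expected_mz - peaks$centroid_mz[anchor]
  peaks$centroid_mz <- peaks$centroid_mz + shift
  peaks$apex_mz <- peaks$apex_mz + shift
  model <- structure(list(shift = shift, anchor_label = std$label,
                          residual = std$expected_mz -
                            peaks$centroid_mz[anchor]),
                     class = "calibration_model")
  list(model = model, peaks = peaks)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> shift %+.3f Da on %s (residual %.2g Da)\n",
              x$shift, ifelse(is.na(x$anchor_label), "<identity>",
                              x$anchor_label), x$residual))
  invisible(x)
}

#' Match calibrated peaks against the control list
#'
#' Global nearest assignment: all (entry, peak) pairs within the list's match
#' tolerance are processed in ascending absolute m/z difference; each entry
#' claims at most one peak and each peak satisfies at most one entry. Exact
#' distance ties go to the lower-m/z entry (with a warning). Unmatched entries
#' are reported with zero area.
#'
#' @param peaks A `peak_list` (calibrated).
#' @param control_list A [build_mass_control_list()].
#' @return List with `peaks` (the input with `matched_label` filled) and
#'   `matches`: one row per control entry with `label`, `expected_mz`, `role`,
#'   `centroid_mz`, `area`, `snr`, `matched` (logical).
#' @export
match_peaks <- function(peaks, control_list) {
  stopifnot(inherits(peaks, "data.frame"),
            inherits(control_list, "mass_control_list"))
  tol <- attr(control_list, "tolerance")
  if (is.null(tol)) tol <- 5
  ne <- nrow(control_list)
  matches <- data.frame(label = control_list$label,
                        expected_mz = control_list$expected_mz,
                        role = control_list$role,
                        centroid_mz = NA_real_, area = 0, snr = NA_real_,
                        matched = FALSE, stringsAsFactors = FALSE)
  if (nrow(peaks) && ne) {
    pairs <- expand.grid(entry = seq_len(ne), peak = seq_len(nrow(peaks)))
    pairs$d <- abs(control_list$expected_mz[pairs$entry] -
                     peaks$centroid_mz[pairs$peak])
    pairs <- pairs[pairs$d <= tol, , drop = FALSE]
    # ascending distance; exact ties -> lower-m/z entry
    pairs <- pairs[order(pairs$d, control_list$expected_mz[pairs$entry]), ,
                   drop = FALSE]
    used_entry <- logical(ne)
    used_peak <- logical(nrow(peaks))
    if (nrow(pairs) >= 2 && anyDuplicated(pairs[, c("peak", "d")])) {
      warning("peak equidistant from two control entries; ",
              "assigned to the lower-m/z entry")
    }
    for (r in seq_len(nrow(pairs))) {
      e <- pairs$entry[r]; p <- pairs$peak[r]
      if (used_entry[e] || used_peak[p]) next
      used_entry[e] <- TRUE
      used_peak[p] <- TRUE
      matches$centroid_mz[e] <- peaks$centroid_mz[p]
      matches$area[e] <- peaks$area[p]
      matches$snr[e] <- peaks$snr[p]
      matches$matched[e] <- TRUE
      peaks$matched_label[p] <- control_list$label[e]
    }
  }
  list(peaks = peaks, matches = matches)
}
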