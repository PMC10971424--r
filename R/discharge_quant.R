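# Peak areas -> per-well discharge percentages, and replicate aggregation
# into screen heatmaps and time-course summaries.

#' Discharge percentage from the internal-standard ratio
#'
#' The assay's quantification equation:
#' `(adduct_area / standard_area) * (conc_standard / conc_ub) * 100`.
#' Values above 100 are legitimate outputs of the formula and are returned
#' unclamped (flag them downstream, do not hide response problems).
#'
#' @param adduct_area Matched ubiquitin-adduct peak area.
#' @param standard_area 15N-ubiquitin standard peak area, must be > 0.
#' @param conc_standard Standard concentration (uM).
#' @param conc_ub Initial ubiquitin concentration (uM).
#' @return Discharge percentage (>= 0).
#' @examples
#' discharge_percent(1000, 2000, 2, 2)  # 50
#' @export
discharge_percent <- function(adduct_area, standard_area, conc_standard,
                              conc_ub) {
  stopifnot(conc_standard > 0, conc_ub > 0, adduct_area >= 0)
  if (any(standard_area <= 0)) {
    stop("standard peak area must be > 0 (flag the well instead)")
  }
  (adduct_area / standard_area) * (conc_standard / conc_ub) * 100
}

#' Discharge fractions without an internal standard
#'
#' Mutant-ubiquitin mode: the standard is omitted (its peak would overlap the
#' mutant's), so each adduct fraction is its area over the total
#' analyte-plus-adduct area. Fractions plus the unreacted fraction sum to 1.
#'
#' @param adduct_areas Named numeric vector of adduct areas (>= 0).
#' @param analyte_area Unreacted analyte area (>= 0).
#' @return Named vector of fractions in `[0, 1]`.
#' @export
discharge_fraction_no_standard <- function(adduct_areas, analyte_area) {
  stopifnot(all(adduct_areas >= 0), analyte_area >= 0)
  total <- analyte_area + sum(adduct_areas)
  if (total <= 0) stop("all areas are zero: empty well")
  adduct_areas / total
}

#' Quantify one well from its spectrum
#'
#' Full per-spectrum pipeline: baseline estimation, noise estimation,
#' S/N-gated peak detection, single-point recalibration on the 15N standard
#' (skipped in no-standard mode), control-list matching, and the discharge
#' computation. Nothing is silently dropped: failures surface as QC flags.
#'
#' @param spectrum A [mass_spectrum()].
#' @param control_list The well's [build_mass_control_list()].
#' @param conc_ub,conc_standard Concentrations (uM).
#' @param has_standard `FALSE` for mutant-ubiquitin (no-standard) mode, where
#'   fractions are computed by [discharge_fraction_no_standard()] and reported
#'   as percentages.
#' @param snr_threshold Detection gate (default 5).
#' @param baseline_window Baseline window in Da.
#' @return List with `results` (one row per adduct: `adduct`,
#'   `discharge_percent`, `adduct_area`, `standard_area`, `snr`, `flags`),
#'   `calibration`, `peaks` and `matches`.
#' @export
quantify_well <- function(spectrum, control_list, conc_ub = 2,
                          conc_standard = 2, has_standard = TRUE,
                          snr_threshold = 5, baseline_window = 100) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(control_list, "mass_control_list"))
  adduct_entries <- control_list$label[control_list$role == "adduct"]
  flags <- character(0)
  base <- estimate_baseline(spectrum, window = baseline_window)
  noise <- estimate_noise(spectrum, base)
  peaks <- detect_peaks(spectrum, base, noise, snr_threshold = snr_threshold)
  model <- structure(list(shift = 0, anchor_label = NA_character_,
                          residual = 0), class = "calibration_model")
  if (has_standard) {
    cal <- tryCatch(calibrate(peaks, control_list), error = function(e) e)
    if (inherits(cal, "error")) {
      flags <- c(flags, "calibration_failed")
    } else {
      model <- cal$model
      peaks <- cal$peaks
    }
  } else {
    flags <- c(flags, "standard_missing")
  }
  mm <- match_peaks(peaks, control_list)
  matches <- mm$matches
  std_area <- if (has_standard) {
    matches$area[matches$role == "standard"]
  } else NA_real_
  analyte_area <- matches$area[matches$role == "analyte"]
  res <- lapply(adduct_entries, function(al) {
    a <- matches$area[matches$label == al]
    s <- matches$snr[matches$label == al]
    wflags <- flags
    pct <- NA_real_
    if (has_standard) {
      if (!length(std_area) || is.na(std_area) || std_area <= 0) {
        wflags <- c(wflags, "standard_not_detected")
      } else if (!("calibration_failed" %in% wflags)) {
        pct <- discharge_percent(a, std_area, conc_standard, conc_ub)
        if (pct > 100) wflags <- c(wflags, "over_100")
      }
    } else {
      total <- analyte_area + sum(matches$area[matches$role == "adduct"])
      if (total > 0) {
        pct <- 100 * unname(discharge_fraction_no_standard(
          stats::setNames(a, al), analyte_area))
      } else {
        wflags <- c(wflags, "empty_well")
      }
    }
    data.frame(adduct = al, discharge_percent = pct, adduct_area = a,
               standard_area = if (has_standard) std_area else NA_real_,
               snr = s, flags = paste(wflags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, res), calibration = model,
       peaks = mm$peaks, matches = matches)
}

#' Aggregate well results into a screen heatmap matrix
#'
#' Cell value is the mean discharge percentage over valid replicates of each
#' (E2, nucleophile) cell; failed wells (NA percentage) are excluded and
#' counted. Cells with fewer than two valid replicates are flagged, never
#' dropped.
#'
#' @param well_results data.frame with columns `e2`, `nucleophile`,
#'   `discharge_percent` (one row per well x adduct).
#' @return List with `matrix` (E2 x nucleophile mean percentages), `n` (valid
#'   replicate counts), `n_failed`, and `flagged` (logical, n < 2).
#' @export
aggregate_screen <- function(well_results) {
  stopifnot(all(c("e2", "nucleophile", "discharge_percent") %in%
                  names(well_results)))
  if (!nrow(well_results)) {
    return(list(matrix = matrix(numeric(0), 0, 0),
                n = matrix(integer(0), 0, 0),
                n_failed = matrix(integer(0), 0, 0),
                flagged = matrix(logical(0), 0, 0)))
  }
  e2s <- unique(well_results$e2)
  nucs <- unique(well_results$nucleophile)
  f_e2 <- factor(well_results$e2, levels = e2s)
  f_nuc <- factor(well_results$nucleophile, levels = nucs)
  ok <- !is.na(well_results$discharge_percent)
  mean_mat <- tapply(well_results$discharge_percent, list(f_e2, f_nuc),
                     function(v) mean(v, na.rm = TRUE))
  n_mat <- tapply(ok, list(f_e2, f_nuc), sum)
  n_mat[is.na(n_mat)] <- 0L
  fail_mat <- tapply(!ok, list(f_e2, f_nuc), sum)
  fail_mat[is.na(fail_mat)] <- 0L
  list(matrix = mean_mat, n = n_mat, n_failed = fail_mat,
       flagged = n_mat < 2L)
}

#' Time-course summary per (E2, nucleophile, time)
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' discharge percentage across replicates at each time point. With a single
#' valid replicate the mean is reported and the SD is `NA`.
#'
#' @param well_results data.frame with columns `e2`, `nucleophile`,
#'   `time_min`, `discharge_percent`.
#' @return data.frame with `e2`, `nucleophile`, `time_min`, `mean`, `sd`, `n`.
#' @export
time_course <- function(well_results) {
  stopifnot(all(c("e2", "nucleophile", "time_min", "discharge_percent") %in%
                  names(well_results)))
  if (!nrow(well_results)) {
    return(data.frame(e2 = character(), nucleophile = character(),
                      time_min = numeric(), mean = numeric(), sd = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  key <- interaction(well_results$e2, well_results$nucleophile,
                     well_results$time_min, drop = TRUE, sep = "\r")
  out <- lapply(split(well_results, key), function(g) {
    v <- g$discharge_percent[!is.na(g$discharge_percent)]
    data.frame(e2 = g$e2[1], nucleophile = g$nucleophile[1],
               time_min = g$time_min[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$e2, out$nucleophile, out$time_min), , drop = FALSE]
}
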