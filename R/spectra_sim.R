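# Synthetic linear-mode MALDI-TOF spectra with known ground truth, so every
# downstream stage (baseline, detection, calibration, quantification) is
# testable without instrument data.

#' Construct a spectrum simulation specification
#'
#' Defines the peak model and acquisition grid for [simulate_spectrum()]:
#' symmetric Gaussian peaks (unit-apex, so integrated area is proportional to
#' abundance when sigma is shared), a single-exponential matrix baseline
#' decaying from low m/z, additive Gaussian noise, and an additive
#' mass-calibration offset applied to every peak position.
#'
#' @param species data.frame with columns `label`, `mz` (true Da position) and
#'   `abundance` (relative units, >= 0). May have zero rows.
#' @param peak_sigma Gaussian peak width (Da), > 0. Default 4 Da, a realistic
#'   linear-mode width for an ~8.6 kDa protein.
#' @param mz_range,mz_step Acquisition grid `seq(mz_range[1], mz_range[2],
#'   by = mz_step)`. Default 8000–9200 Da at 0.5 Da.
#' @param baseline_amplitude,baseline_decay Baseline
#'   `amplitude * exp(-(m - start) / decay)`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param calibration_offset Additive shift (Da) applied to all peak positions,
#'   emulating miscalibration.
#' @param seed Optional integer; fixes the noise realization.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(species = data.frame(label = character(),
                                                 mz = numeric(),
                                                 abundance = numeric()),
                            peak_sigma = 4, mz_range = c(8000, 9200),
                            mz_step = 0.5, baseline_amplitude = 20,
                            baseline_decay = 300, noise_sd = 1,
                            calibration_offset = 0, seed = NULL) {
  species <- as.data.frame(species)
  stopifnot(all(c("label", "mz", "abundance") %in% names(species)),
            all(species$abundance >= 0), all(species$mz > 0),
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            mz_step > 0, peak_sigma > 0, noise_sd >= 0,
            baseline_amplitude >= 0, baseline_decay > 0)
  structure(list(species = species, peak_sigma = peak_sigma,
                 mz_range = mz_range, mz_step = mz_step,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay, noise_sd = noise_sd,
                 calibration_offset = calibration_offset, seed = seed),
            class = "simulation_spec")
}

#' Construct a mass spectrum
#'
#' @param mz Strictly ascending m/z positions (Da), length >= 2.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity), length(mz) >= 2L)
  if (any(diff(mz) <= 0)) stop("m/z must be strictly ascending")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.1f-%.1f, max intensity %.3g\n",
              length(x$mz), min(x$mz), max(x$mz), max(x$intensity)))
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate one MALDI-TOF spectrum
#'
#' Intensity at each grid point is the sum over species of
#' `abundance * exp(-0.5 * ((m - (mz + offset)) / sigma)^2)`, plus the
#' exponential baseline and additive Gaussian noise; negative values are
#' clipped to zero. Identical spec (including `seed`) gives an identical trace.
#'
#' @param spec A [simulation_spec()].
#' @return A [mass_spectrum()].
#' @export
simulate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$mz_step > spec$peak_sigma) {
    warning("grid step (", spec$mz_step, " Da) exceeds peak sigma (",
            spec$peak_sigma, " Da); peaks will be undersampled")
  }
  m <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$mz_step)
  y <- numeric(length(m))
  if (nrow(spec$species)) {
    for (i in seq_len(nrow(spec$species))) {
      mu <- spec$species$mz[i] + spec$calibration_offset
      y <- y + spec$species$abundance[i] *
        exp(-0.5 * ((m - mu) / spec$peak_sigma)^2)
    }
  }
  y <- y + spec$baseline_amplitude * exp(-(m - m[1]) / spec$baseline_decay)
  if (spec$noise_sd > 0) {
    y <- y + .with_seed(spec$seed, stats::rnorm(length(m), 0, spec$noise_sd))
  }
  mass_spectrum(m, pmax(y, 0))
}

#' Construct a reaction specification for one well
#'
#' @param e2 E2 enzyme label.
#' @param nucleophile Nucleophile label (must exist in [nucleophile_panel()] or
#'   in the supplied panel).
#' @param conc_ub Ubiquitin analyte concentration, uM.
#' @param conc_standard 15N internal standard concentration, uM (ignored when
#'   `has_standard = FALSE`).
#' @param time_min Incubation time, minutes.
#' @param replicate Technical replicate id.
#' @param has_standard `FALSE` for mutant-ubiquitin mode, where the standard is
#'   omitted because its signal would overlap the mutant's.
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(e2, nucleophile, conc_ub = 2, conc_standard = 2,
                          time_min = 60, replicate = 1L, has_standard = TRUE) {
  stopifnot(conc_ub > 0, !has_standard || conc_standard > 0)
  structure(list(e2 = e2, nucleophile = nucleophile, conc_ub = conc_ub,
                 conc_standard = conc_standard, time_min = time_min,
                 replicate = as.integer(replicate),
                 has_standard = isTRUE(has_standard)),
            class = "reaction_spec")
}

#' Simulate the spectrum of one assay well
#'
#' Species abundances follow the assay model with equal molar area response:
#' unreacted analyte is proportional to `(1 - sum(fractions)) * conc_ub`, each
#' adduct to `fraction * conc_ub`, and the standard to `conc_standard`, all
#' scaled by `response` intensity units per uM.
#'
#' @param reaction A [reaction_spec()].
#' @param truth Named numeric vector of true discharge fractions (0–1) keyed by
#'   adduct label; fractions must sum to <= 1.
#' @param control_list The well's [build_mass_control_list()] (defines the true
#'   peak positions).
#' @param response Intensity units per uM of species (apex height scale).
#' @param ... Passed to [simulation_spec()] (peak_sigma, noise_sd,
#'   calibration_offset, seed, ...).
#' @return A [mass_spectrum()].
#' @export
simulate_well <- function(reaction, truth, control_list, response = 100, ...) {
  stopifnot(inherits(reaction, "reaction_spec"),
            inherits(control_list, "mass_control_list"))
  if (any(truth < 0)) stop("discharge fractions must be >= 0")
  if (sum(truth) > 1 + 1e-12) {
    stop("discharge fractions sum to more than 1")
  }
  adducts <- control_list[control_list$role == "adduct", , drop = FALSE]
  missing_lab <- setdiff(names(truth), adducts$label)
  if (length(missing_lab)) {
    stop("truth labels not in control list: ",
         paste(missing_lab, collapse = ", "))
  }
  analyte <- control_list[control_list$role == "analyte", , drop = FALSE]
  standard <- control_list[control_list$role == "standard", , drop = FALSE]
  lab <- analyte$label
  mz <- analyte$expected_mz
  ab <- (1 - sum(truth)) * reaction$conc_ub * response
  for (al in names(truth)) {
    lab <- c(lab, al)
    mz <- c(mz, adducts$expected_mz[adducts$label == al])
    ab <- c(ab, truth[[al]] * reaction$conc_ub * response)
  }
  if (reaction$has_standard) {
    if (!nrow(standard)) stop("control list has no standard entry")
    lab <- c(lab, standard$label)
    mz <- c(mz, standard$expected_mz)
    ab <- c(ab, reaction$conc_standard * response)
  }
  spec <- simulation_spec(species = data.frame(label = lab, mz = mz,
                                               abundance = ab), ...)
  simulate_spectrum(spec)
}

#' Saturating first-order discharge kinetics
#'
#' Convenience ground-truth generator for time-course simulations:
#' `fmax * (1 - exp(-rate * t))`, monotone non-decreasing in `t`.
#'
#' @param time_min Time points (minutes).
#' @param fmax Plateau fraction (0-1).
#' @param rate First-order rate constant (1/min).
#' @return Vector of fractions in `[0, fmax]`.
#' @export
discharge_kinetics <- function(time_min, fmax = 0.9, rate = 0.05) {
  stopifnot(fmax >= 0, fmax <= 1, rate >= 0, all(time_min >= 0))
  fmax * (1 - exp(-rate * time_min))
}

#' Default 23-enzyme screening panel
#'
#' Labels for a 23-member human E2 panel of the kind screened in the discharge
#' assay (canonical lysine-reactive families plus the noncanonical UBE2J and
#' UBE2Q families).
#'
#' @return Character vector of length 23.
#' @export
default_e2_panel <- function() {
  c("UBE2A", "UBE2B", "UBE2C", "UBE2D1", "UBE2D2", "UBE2D3", "UBE2E1",
    "UBE2E2", "UBE2E3", "UBE2G1", "UBE2G2", "UBE2H", "UBE2J1", "UBE2J2",
    "UBE2K", "UBE2L3", "UBE2N", "UBE2Q1", "UBE2Q2", "UBE2QL1", "UBE2R1",
    "UBE2S", "UBE2W")
}

#' Simulate a whole screening plate
#'
#' Generates one spectrum per (E2, nucleophile, replicate, time) combination,
#' writes them to `out_dir` (XY text or mzML) together with a plate manifest
#' CSV carrying the design and the ground truth, and returns the manifest.
#' True discharge fractions are drawn once per (E2, nucleophile) cell from
#' `truth_levels` (technical replicates share the cell truth); per-well
#' calibration offsets are drawn uniformly from `offset_range`.
#'
#' @param out_dir Output directory (created if needed).
#' @param e2s,nucleophile_labels Panel definition; defaults
#'   [default_e2_panel()] and the five-nucleophile panel.
#' @param truth Optional matrix of true fractions (E2 x nucleophile). If
#'   `NULL`, drawn from `truth_levels`.
#' @param truth_levels Discrete fractions sampled for cell truths.
#' @param replicates Technical replicates per cell.
#' @param time_min Incubation time recorded in the manifest.
#' @param conc_ub,conc_standard Concentrations (uM).
#' @param offset_range Per-well calibration offset range (Da).
#' @param response,noise_sd,peak_sigma Peak model parameters (see
#'   [simulate_well()] / [simulation_spec()]).
#' @param format `"xy"` or `"mzML"`.
#' @param seed Integer seed; the whole plate is reproducible under it.
#' @return Manifest data.frame (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`): columns well, file, e2,
#'   nucleophile, time_min, replicate, conc_ub, conc_standard,
#'   calibration_offset, true_fraction.
#' @export
simulate_plate <- function(out_dir, e2s = default_e2_panel(),
                           nucleophile_labels = names(nucleophile_panel()),
                           truth = NULL,
                           truth_levels = c(0, 0.1, 0.25, 0.5, 0.75, 0.9),
                           replicates = 2L, time_min = 60,
                           conc_ub = 2, conc_standard = 2,
                           offset_range = c(-2, 2), response = 100,
                           noise_sd = 1, peak_sigma = 4,
                           format = c("xy", "mzML"), seed = 1L) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- nucleophile_panel()
  bad <- setdiff(nucleophile_labels, names(panel))
  if (length(bad)) stop("unknown nucleophile(s): ", paste(bad, collapse = ", "))
  ub <- molecular_species("Ub", sequence = ubiquitin_sequence())
  .with_seed(seed, {
    if (is.null(truth)) {
      truth <- matrix(sample(truth_levels,
                             length(e2s) * length(nucleophile_labels),
                             replace = TRUE),
                      nrow = length(e2s),
                      dimnames = list(e2s, nucleophile_labels))
    } else {
      stopifnot(is.matrix(truth),
                nrow(truth) == length(e2s),
                ncol(truth) == length(nucleophile_labels))
      dimnames(truth) <- list(e2s, nucleophile_labels)
    }
    rows <- list()
    widx <- 0L
    for (e2 in e2s) {
      for (nuc in nucleophile_labels) {
        cl <- build_mass_control_list(ub, panel[nuc], standard = "15N")
        alab <- .adduct_label("Ub", nuc)
        f <- truth[e2, nuc]
        for (rep_i in seq_len(replicates)) {
          widx <- widx + 1L
          offset <- stats::runif(1, offset_range[1], offset_range[2])
          rx <- reaction_spec(e2, nuc, conc_ub = conc_ub,
                              conc_standard = conc_standard,
                              time_min = time_min, replicate = rep_i)
          sp <- simulate_well(rx, stats::setNames(f, alab), cl,
                              response = response, noise_sd = noise_sd,
                              peak_sigma = peak_sigma,
                              calibration_offset = offset)
          fname <- sprintf("well_%03d.%s", widx,
                           if (format == "xy") "xy" else "mzML")
          write_spectrum(sp, file.path(out_dir, fname), format = format)
          rows[[widx]] <- data.frame(
            well = widx, file = fname, e2 = e2, nucleophile = nuc,
            time_min = time_min, replicate = rep_i, conc_ub = conc_ub,
            conc_standard = conc_standard, calibration_offset = offset,
            true_fraction = f, stringsAsFactors = FALSE)
        }
      }
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    manifest
  })
}

#' Write / read a spectrum
#'
#' XY format is two-column whitespace text (m/z, intensity); mzML goes through
#' the `mzR` Bioconductor backend.
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output file.
#' @param format `"xy"` or `"mzML"`; `read_spectrum()` infers it from the file
#'   extension by default.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a [mass_spectrum()].
#' @export
write_spectrum <- function(spectrum, path, format = c("xy", "mzML")) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (format == "xy") {
    utils::write.table(
      data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
      path, sep = " ", row.names = FALSE, col.names = FALSE)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("mzML output requires the mzR package")
    }
    n <- length(spectrum$mz)
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
      peaksCount = n, totIonCurrent = sum(spectrum$intensity),
      retentionTime = 0, basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
      basePeakIntensity = max(spectrum$intensity), collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
      centroided = FALSE, ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
      scanWindowUpperLimit = NA_real_)
    mzR::writeMSData(list(cbind(mz = spectrum$mz,
                                intensity = spectrum$intensity)),
                     path, header = hdr)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "xy"
  }
  format <- match.arg(format, c("xy", "mzML"))
  if (format == "xy") {
    df <- utils::read.table(path, header = FALSE,
                            col.names = c("mz", "intensity"))
    mass_spectrum(df$mz, df$intensity)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("mzML input requires the mzR package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    p <- mzR::peaks(h, 1L)
    mass_spectrum(p[, 1], p[, 2])
  }
}
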