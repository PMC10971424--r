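# Orchestration: a YAML run configuration and the four user-facing commands
# (simulate, quantify, screen, contacts) tying the stages into reproducible
# runs. QC flags propagate; no row is ever silently dropped.

#' Load a run configuration
#'
#' YAML fields (all optional unless a command requires them): `out_dir`,
#' `seed`, `plate_dir`, `manifest`, `control_list` (CSV path overriding the
#' computed list), `snr_threshold`, `match_tolerance`, `baseline_window`,
#' `replicates`, `time_min`, `conc_ub`, `conc_standard`, `noise_sd`,
#' `peak_sigma`, `offset_range`, `format`, `pdb`, `chain_a`, `chain_b`,
#' `heavy_atom_cutoff`, `cation_pi_cutoff`, `plots`.
#'
#' @param path YAML file, or a named list already in memory.
#' @return A `run_config` list with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else {
    stopifnot(is.list(path))
    path
  }
  defaults <- list(out_dir = "e2discharge_out", seed = 1L,
                   snr_threshold = 5, match_tolerance = 5,
                   baseline_window = 100, replicates = 2L, time_min = 60,
                   conc_ub = 2, conc_standard = 2, noise_sd = 1,
                   peak_sigma = 4, offset_range = c(-2, 2), format = "xy",
                   chain_a = "A", chain_b = "B", heavy_atom_cutoff = 4.5,
                   cation_pi_cutoff = 6.0, plots = FALSE)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  stopifnot(cfg$snr_threshold > 0, cfg$match_tolerance > 0,
            cfg$baseline_window > 0)
  structure(cfg, class = c("run_config", "list"))
}

.log_msg <- function(...) message("[e2discharge] ", ...)

#' Simulate a plate per the run configuration
#'
#' Wraps [simulate_plate()]: writes spectra plus a ground-truth manifest under
#' `out_dir/plate` and returns the manifest.
#'
#' @param config A [load_run_config()] result (or path / list accepted by it).
#' @return Manifest data.frame, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_run_config(config)
  plate_dir <- file.path(config$out_dir, "plate")
  .log_msg("simulating plate into ", plate_dir, " (seed ", config$seed, ")")
  manifest <- simulate_plate(
    plate_dir, replicates = config$replicates, time_min = config$time_min,
    conc_ub = config$conc_ub, conc_standard = config$conc_standard,
    offset_range = config$offset_range, noise_sd = config$noise_sd,
    peak_sigma = config$peak_sigma, format = config$format,
    seed = config$seed)
  .log_msg(nrow(manifest), " wells written")
  invisible(manifest)
}

# control list for one well: computed for its nucleophile, or the
# user-supplied override CSV
.well_control_list <- function(config, nucleophile) {
  if (!is.null(config$control_list)) {
    return(read_mass_control_list(config$control_list,
                                  tolerance = config$match_tolerance))
  }
  ub <- molecular_species("Ub", sequence = ubiquitin_sequence())
  build_mass_control_list(ub, nucleophile_panel()[nucleophile],
                          standard = "15N",
                          tolerance = config$match_tolerance)
}

#' Quantify a simulated or measured plate
#'
#' Reads the plate manifest, processes every spectrum through baseline /
#' detection / calibration / matching, computes discharge percentages, and
#' writes a tidy `well_results.csv` under `out_dir`. Missing or unreadable
#' spectra yield flagged rows, never a crash.
#'
#' @param config A [load_run_config()] result (or path / list). `plate_dir`
#'   defaults to `out_dir/plate`; `manifest` to `plate_dir/manifest.csv`.
#' @return Tidy data.frame: one row per (well, adduct) with columns `well`,
#'   `e2`, `nucleophile`, `time_min`, `replicate`, `adduct`,
#'   `discharge_percent`, `adduct_area`, `standard_area`, `snr`,
#'   `calibration_shift`, `flags`, `file`.
#' @export
run_quantify <- function(config) {
  config <- load_run_config(config)
  plate_dir <- config$plate_dir
  if (is.null(plate_dir)) plate_dir <- file.path(config$out_dir, "plate")
  manifest_path <- config$manifest
  if (is.null(manifest_path)) manifest_path <- file.path(plate_dir,
                                                         "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  n_warn <- 0L
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    w <- manifest[i, ]
    fp <- file.path(plate_dir, w$file)
    base_row <- data.frame(
      well = w$well, e2 = w$e2, nucleophile = w$nucleophile,
      time_min = w$time_min, replicate = w$replicate,
      adduct = .adduct_label("Ub", w$nucleophile),
      discharge_percent = NA_real_, adduct_area = NA_real_,
      standard_area = NA_real_, snr = NA_real_,
      calibration_shift = NA_real_, flags = "", file = w$file,
      stringsAsFactors = FALSE)
    sp <- tryCatch(read_spectrum(fp), error = function(e) e)
    if (inherits(sp, "error")) {
      base_row$flags <- "spectrum_unreadable"
      n_warn <<- n_warn + 1L
      return(base_row)
    }
    cl <- .well_control_list(config, w$nucleophile)
    q <- tryCatch(
      quantify_well(sp, cl, conc_ub = w$conc_ub,
                    conc_standard = w$conc_standard,
                    snr_threshold = config$snr_threshold,
                    baseline_window = config$baseline_window),
      error = function(e) e)
    if (inherits(q, "error")) {
      base_row$flags <- paste0("processing_failed:",
                               conditionMessage(q))
      n_warn <<- n_warn + 1L
      return(base_row)
    }
    r <- q$results
    data.frame(well = w$well, e2 = w$e2, nucleophile = w$nucleophile,
               time_min = w$time_min, replicate = w$replicate,
               adduct = r$adduct, discharge_percent = r$discharge_percent,
               adduct_area = r$adduct_area, standard_area = r$standard_area,
               snr = r$snr, calibration_shift = q$calibration$shift,
               flags = r$flags, file = w$file, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(config$out_dir, "well_results.csv"),
                   row.names = FALSE)
  if (n_warn) .log_msg(n_warn, " well(s) flagged during quantification")
  .log_msg("well results written to ",
           file.path(config$out_dir, "well_results.csv"))
  out
}

#' Aggregate well results into screen outputs
#'
#' Produces the heatmap matrix CSV (mean discharge per E2 x nucleophile cell)
#' and the time-course summary CSV, optionally rendering PNG figures when
#' ggplot2 is available and `plots: true` is set.
#'
#' @param config A [load_run_config()] result (or path / list).
#' @param well_results Optional data.frame from [run_quantify()]; read from
#'   `out_dir/well_results.csv` when missing.
#' @return List with `heatmap` (from [aggregate_screen()]) and `time_course`.
#' @export
run_screen <- function(config, well_results = NULL) {
  config <- load_run_config(config)
  if (is.null(well_results)) {
    path <- file.path(config$out_dir, "well_results.csv")
    if (!file.exists(path)) stop("well results not found: ", path)
    well_results <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  hm <- aggregate_screen(well_results)
  tc <- time_course(well_results)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(hm$matrix),
                   file.path(config$out_dir, "heatmap.csv"))
  utils::write.csv(tc, file.path(config$out_dir, "time_course.csv"),
                   row.names = FALSE)
  if (isTRUE(config$plots)) {
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      p <- plot_screen_heatmap(hm)
      ggplot2::ggsave(file.path(config$out_dir, "heatmap.png"), p,
                      width = 6, height = 8, dpi = 150)
      if (length(unique(tc$time_min)) > 1) {
        ggplot2::ggsave(file.path(config$out_dir, "time_course.png"),
                        plot_time_course(tc), width = 7, height = 5,
                        dpi = 150)
      }
    } else {
      .log_msg("ggplot2 not available; skipping PNG rendering")
    }
  }
  .log_msg("screen outputs written to ", config$out_dir)
  list(heatmap = hm, time_course = tc)
}

#' Classify interface contacts per the run configuration
#'
#' Parses `config$pdb` and writes the combined contact table CSV.
#'
#' @param config A [load_run_config()] result (or path / list) with `pdb`,
#'   `chain_a`, `chain_b` set.
#' @return Contact-record data.frame.
#' @export
run_contacts <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$pdb)) stop("config field 'pdb' is required")
  model <- parse_structure(config$pdb)
  contacts <- interface_contacts(model, config$chain_a, config$chain_b,
                                 heavy_atom_cutoff = config$heavy_atom_cutoff,
                                 cation_pi_cutoff = config$cation_pi_cutoff)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(contacts, file.path(config$out_dir, "contacts.csv"),
                   row.names = FALSE)
  .log_msg(nrow(contacts), " contact(s) written to ",
           file.path(config$out_dir, "contacts.csv"))
  contacts
}
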