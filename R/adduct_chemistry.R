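# Average-mass chemistry for the ubiquitin discharge assay: species masses,
# condensation adducts, 15N labeling and the mass control list used for peak
# matching.

# IUPAC 2021 standard average atomic weights; 15N exact mass 15.0001086.
.atomic_weights <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
.n15_shift <- 15.0001086 - .atomic_weights[["N"]]
.proton_mass <- 1.00728
.water_mass <- 2 * .atomic_weights[["H"]] + .atomic_weights[["O"]] # 18.015

# Residue (amino acid minus water) elemental compositions, one-letter codes.
.residue_formulas <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1)
)

#' Canonical human ubiquitin sequence
#'
#' The 76-residue sequence of mature human ubiquitin, the analyte of the
#' discharge assay.
#'
#' @return A single string of 76 one-letter residue codes.
#' @export
ubiquitin_sequence <- function() {
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
}

#' Construct a molecular species
#'
#' A named chemical entity defined either by an amino-acid sequence (one-letter
#' codes) or by an elemental formula over \{C, H, N, O, S\}.
#'
#' @param label Short text identifier.
#' @param sequence One-letter amino-acid sequence (mutually exclusive with
#'   `formula`).
#' @param formula Elemental formula: either a named count vector (e.g.
#'   `c(C = 6, H = 12, O = 6)`) or a string such as `"C6H12O6"`.
#' @param charge_adduct Number of protons added for (M+nH)n+ reporting.
#' @return An object of class `molecular_species` with the neutral `average_mass`
#'   (Da) precomputed.
#' @examples
#' molecular_species("glucose", formula = "C6H12O6")
#' molecular_species("Ub", sequence = ubiquitin_sequence())
#' @export
molecular_species <- function(label, sequence = NULL, formula = NULL,
                              charge_adduct = 1L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(sequence) == is.null(formula)) {
    stop("exactly one of `sequence` or `formula` must be given")
  }
  if (!is.null(formula)) {
    formula <- parse_formula(formula)
    mass <- mass_from_formula(formula)
  } else {
    mass <- average_mass_from_sequence(sequence) # validates residues
  }
  structure(
    list(label = label, sequence = sequence, formula = formula,
         charge_adduct = as.integer(charge_adduct), average_mass = mass),
    class = "molecular_species"
  )
}

#' @export
print.molecular_species <- function(x, ...) {
  kind <- if (is.null(x$sequence)) "formula" else
    sprintf("%d-residue sequence", nchar(x$sequence))
  cat(sprintf("<molecular_species> %s (%s), average mass %.3f Da\n",
              x$label, kind, x$average_mass))
  invisible(x)
}

#' Parse an elemental formula string
#'
#' @param formula Either a named numeric vector of element counts or a string
#'   like `"C8H16N2O3"` (implicit count 1 allowed, e.g. `"H2O"`).
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (length(formula) && is.null(names(formula))) {
      stop("numeric formula must be a named element -> count vector")
    }
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1
  counts <- tapply(ct, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Average mass from an elemental formula
#'
#' Sums element counts times standard average atomic weights. Supported
#' elements: C, H, N, O, S.
#'
#' @param formula Named count vector or formula string (see [parse_formula()]).
#' @return Average mass in Da; `0` for the empty formula.
#' @examples
#' mass_from_formula("H2O")      # 18.015
#' mass_from_formula("C6H12O6")  # 180.156
#' @export
mass_from_formula <- function(formula) {
  formula <- parse_formula(formula)
  if (!length(formula)) return(0)
  bad <- setdiff(names(formula), names(.atomic_weights))
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  if (any(formula < 0)) stop("element counts must be >= 0")
  sum(.atomic_weights[names(formula)] * formula)
}

#' Average mass of a polypeptide from its sequence
#'
#' Residue average masses summed plus one water for the termini. The neutral
#' average mass is returned; add [proton_mass()] for (M+H)+ reporting.
#'
#' @param sequence One-letter amino-acid string, length >= 1, canonical
#'   residues only.
#' @return Neutral average mass in Da.
#' @examples
#' average_mass_from_sequence("G")  # glycine, 75.067
#' @export
average_mass_from_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nchar(sequence)) stop("sequence must have length >= 1")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_formulas))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  res_mass <- vapply(.residue_formulas, mass_from_formula, numeric(1))
  sum(res_mass[aa]) + .water_mass
}

#' Proton and water mass constants
#'
#' @return `proton_mass()`: the mass added per charge for (M+nH)n+ reporting.
#'   `water_mass()`: the water lost in each condensation (18.015 Da).
#' @export
proton_mass <- function() .proton_mass

#' @rdname proton_mass
#' @export
water_mass <- function() .water_mass

#' Expected m/z of a condensation adduct
#'
#' All bond chemistries formed in the discharge assay (isopeptide with an
#' amine, oxyester with a hydroxyl, thioester with a thiol, amide with an
#' alpha-amine) are condensations releasing one water, so the bond kind is
#' recorded but never changes the arithmetic.
#'
#' @param base_mz (M+H)+ m/z of the unmodified analyte, Da.
#' @param nucleophile A [molecular_species()] (or a bare numeric average mass).
#' @param bond One of `"isopeptide"`, `"oxyester"`, `"thioester"`,
#'   `"alpha-amine"`.
#' @return Expected adduct (M+H)+ m/z in Da.
#' @export
adduct_mass <- function(base_mz, nucleophile,
                        bond = c("isopeptide", "oxyester", "thioester",
                                 "alpha-amine")) {
  bond <- match.arg(bond)
  stopifnot(is.numeric(base_mz), base_mz > 0)
  nmass <- if (inherits(nucleophile, "molecular_species")) {
    nucleophile$average_mass
  } else {
    stopifnot(is.numeric(nucleophile))
    nucleophile
  }
  base_mz + nmass - .water_mass
}

#' m/z shift from uniform 15N labeling
#'
#' @param species_mz Unlabeled m/z, Da.
#' @param nitrogen_count Number of nitrogen atoms replaced (backbone plus side
#'   chains), must be >= 0.
#' @return Labeled m/z: `species_mz + nitrogen_count * (15.0001086 - 14.007)`.
#' @export
isotope_label_mass <- function(species_mz, nitrogen_count) {
  stopifnot(is.numeric(species_mz), is.numeric(nitrogen_count))
  if (any(nitrogen_count < 0)) stop("nitrogen_count must be >= 0")
  species_mz + nitrogen_count * .n15_shift
}

#' Count an element over a peptide sequence
#'
#' @param sequence One-letter amino-acid string.
#' @param element Element symbol, default `"N"` (used for 15N labeling).
#' @return Integer count over residues plus the terminal water.
#' @export
count_element <- function(sequence, element = "N") {
  stopifnot(is.character(sequence), nchar(sequence) >= 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_formulas))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  n <- sum(vapply(aa, function(a) {
    f <- .residue_formulas[[a]]
    if (element %in% names(f)) f[[element]] else 0
  }, numeric(1)))
  water <- c(H = 2, O = 1)
  if (element %in% names(water)) n <- n + water[[element]]
  as.integer(n)
}

#' The standard five-nucleophile panel
#'
#' N-alpha-acetyl-L-lysine, N-acetyl-L-serine, N-acetyl-L-threonine, glycerol
#' and D-glucose — the acceptors screened in the discharge assay, as the
#' acetylated amino-acid forms used as reagents.
#'
#' @return Named list of [molecular_species()].
#' @export
nucleophile_panel <- function() {
  list(
    `Ac-K` = molecular_species("Ac-K", formula = "C8H16N2O3"),
    `Ac-S` = molecular_species("Ac-S", formula = "C5H9NO4"),
    `Ac-T` = molecular_species("Ac-T", formula = "C6H11NO4"),
    glycerol = molecular_species("glycerol", formula = "C3H8O3"),
    glucose = molecular_species("glucose", formula = "C6H12O6")
  )
}

# label of the adduct formed by a nucleophile: Ac-K -> Ub-K, glycerol -> Ub-glycerol
.adduct_label <- function(analyte_label, nucleophile_label) {
  paste0(analyte_label, "-", sub("^Ac-", "", nucleophile_label))
}

#' Build the mass control list
#'
#' Assembles the expected (M+H)+ values against which detected peaks are
#' matched: one analyte entry, one condensation-adduct entry per nucleophile,
#' and optionally the uniformly 15N-labeled internal standard. Computed masses
#' can be overridden entry-by-entry with user-supplied values (e.g. a vendor
#' control list).
#'
#' @param analyte A sequence-defined [molecular_species()] (the ubiquitin
#'   analyte).
#' @param nucleophiles List of [molecular_species()] (may be empty).
#' @param standard `"15N"` to add a uniformly 15N-labeled copy of the analyte
#'   as internal standard, or `NULL` for no-standard (mutant-ubiquitin) mode.
#' @param tolerance Peak-match tolerance in Da (default 5). Entries closer than
#'   `2 * tolerance` trigger an ambiguous-matching warning.
#' @param overrides Named numeric vector label -> m/z replacing computed values.
#' @return A `mass_control_list`: data.frame with columns `label`,
#'   `expected_mz`, `role` (analyte/adduct/standard) and `source`
#'   (computed/override), plus a `tolerance` attribute.
#' @examples
#' ub <- molecular_species("Ub", sequence = ubiquitin_sequence())
#' build_mass_control_list(ub, nucleophile_panel()["Ac-T"], standard = "15N")
#' @export
build_mass_control_list <- function(analyte, nucleophiles = list(),
                                    standard = NULL, tolerance = 5,
                                    overrides = NULL) {
  stopifnot(inherits(analyte, "molecular_species"), tolerance > 0)
  base_mz <- analyte$average_mass + .proton_mass
  labels <- analyte$label
  mz <- base_mz
  role <- "analyte"
  for (nuc in nucleophiles) {
    stopifnot(inherits(nuc, "molecular_species"))
    labels <- c(labels, .adduct_label(analyte$label, nuc$label))
    mz <- c(mz, adduct_mass(base_mz, nuc))
    role <- c(role, "adduct")
  }
  if (!is.null(standard)) {
    if (!identical(standard, "15N")) {
      stop("`standard` must be \"15N\" or NULL")
    }
    if (is.null(analyte$sequence)) {
      stop("15N standard requires a sequence-defined analyte")
    }
    nN <- count_element(analyte$sequence, "N")
    labels <- c(labels, paste0("15N-", analyte$label))
    mz <- c(mz, isotope_label_mass(base_mz, nN))
    role <- c(role, "standard")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate control-list labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  source <- rep("computed", length(labels))
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    unknown <- setdiff(names(overrides), labels)
    if (length(unknown)) {
      stop("override label(s) not in control list: ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(names(overrides), labels)
    mz[idx] <- unname(overrides)
    source[idx] <- "override"
  }
  if (any(mz <= 0)) stop("expected_mz must be > 0")
  cl <- data.frame(label = labels, expected_mz = mz, role = role,
                   source = source, stringsAsFactors = FALSE)
  cl <- structure(cl, tolerance = tolerance,
                  class = c("mass_control_list", "data.frame"))
  gaps <- diff(sort(mz))
  if (any(gaps < 2 * tolerance)) {
    warning("control-list entries closer than 2x match tolerance (",
            2 * tolerance, " Da); peak matching may be ambiguous")
  }
  cl
}

#' Read / write a mass control list as CSV
#'
#' Columns: `label`, `expected_mz`, `role`, `source`.
#'
#' @param path File path.
#' @param x A `mass_control_list`.
#' @param tolerance Match tolerance attached on read (Da).
#' @return `read_mass_control_list()` returns a `mass_control_list`;
#'   `write_mass_control_list()` returns `path` invisibly.
#' @export
write_mass_control_list <- function(x, path) {
  stopifnot(inherits(x, "mass_control_list"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_control_list
#' @export
read_mass_control_list <- function(path, tolerance = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "expected_mz", "role")
  if (!all(need %in% names(df))) {
    stop("control-list CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$source)) df$source <- "override"
  if (anyDuplicated(df$label)) stop("duplicate control-list labels in ", path)
  if (any(df$expected_mz <= 0)) stop("expected_mz must be > 0")
  if (sum(df$role == "standard") > 1) {
    stop("at most one standard entry allowed")
  }
  structure(df[, c("label", "expected_mz", "role", "source")],
            tolerance = tolerance,
            class = c("mass_control_list", "data.frame"))
}
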