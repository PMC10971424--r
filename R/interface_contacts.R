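# Distance-based classification of residue-residue contacts at an
# E2~ubiquitin model interface: hydrophobic and ionic contacts at a
# heavy-atom cutoff, and cation-pi contacts at a 6.0 A
# cation-center-to-ring-centroid cutoff. All cutoffs are inclusive (<=).

.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET",
                      "TRP", "TYR", "GLY")
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

# side-chain carbons considered for hydrophobic contacts; glycine has no side
# chain, so its CA stands in (it is the exposed apolar surface of Gly)
.hydrophobic_atoms <- function(atoms) {
  sc_carbon <- grepl("^C", atoms$elety) & !(atoms$elety %in% c("C", "CA"))
  gly_ca <- atoms$resid == "GLY" & atoms$elety == "CA"
  atoms$resid %in% .apolar_residues & (sc_carbon | gly_ca)
}

.cationic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))
.anionic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.ring_atoms <- list(
  PHE = list(six_ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(six_ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(five_ring = c("CG", "CD1", "NE1", "CE2", "CD2"),
             six_ring = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(five_ring = c("CG", "ND1", "CD2", "CE1", "NE2"))
)

#' Parse a PDB structure
#'
#' Loads all ATOM records (HETATM ignored) through `bio3d::read.pdb`. Where
#' alternate locations are present, the highest-occupancy altloc of each atom
#' is kept.
#'
#' @param path Path to a PDB-format file.
#' @return An object of class `structure_model`: list with an `atoms`
#'   data.frame (`chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`).
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, hex = FALSE, verbose = FALSE)),
    error = function(e) stop("malformed PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  # keep highest-occupancy altloc per (chain, resno, insert, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    at <- at[order(key, -occ), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

.chain_atoms <- function(model, chain) {
  sel <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (!nrow(sel)) stop("chain '", chain, "' not present in model")
  sel
}

# minimum pairwise distance between two coordinate sets
.min_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  sqrt(min(d2))
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# anionic coordinates of a chain: Asp/Glu carboxylates plus the C-terminal
# carboxylate oxygens (O, OXT of the chain's last residue) -- covers ionic
# engagement of the ubiquitin Gly76 C terminus
.anionic_coords <- function(atoms) {
  sel <- rep(FALSE, nrow(atoms))
  for (resn in names(.anionic_atoms)) {
    sel <- sel | (atoms$resid == resn &
                    atoms$elety %in% .anionic_atoms[[resn]])
  }
  cterm <- max(atoms$resno)
  sel <- sel | (atoms$resno == cterm & atoms$elety %in% c("O", "OXT"))
  atoms[sel, , drop = FALSE]
}

.cationic_coords <- function(atoms) {
  sel <- rep(FALSE, nrow(atoms))
  for (resn in names(.cationic_atoms)) {
    sel <- sel | (atoms$resid == resn &
                    atoms$elety %in% .cationic_atoms[[resn]])
  }
  atoms[sel, , drop = FALSE]
}

.residue_split <- function(atoms) {
  split(atoms, paste(atoms$chain, atoms$resno, sep = "\r"))
}

.empty_contacts <- function() {
  data.frame(chain_a = character(), resno_a = integer(),
             resid_a = character(), chain_b = character(),
             resno_b = integer(), resid_b = character(),
             kind = character(), ring = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

.contact_row <- function(ra, rb, kind, dist, ring = NA_character_) {
  data.frame(chain_a = ra$chain[1], resno_a = ra$resno[1],
             resid_a = ra$resid[1], chain_b = rb$chain[1],
             resno_b = rb$resno[1], resid_b = rb$resid[1],
             kind = kind, ring = ring, distance = dist,
             stringsAsFactors = FALSE)
}

#' Hydrophobic and ionic residue contacts between two chains
#'
#' A residue pair is a hydrophobic contact when any side-chain carbon pair of
#' two apolar residues lies within the heavy-atom cutoff (inclusive), and an
#' ionic contact when a cationic side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2;
#' His ND1/NE2) lies within the cutoff of a carboxylate oxygen (Asp/Glu side
#' chains, or the partner chain's C-terminal carboxylate). The minimum
#' qualifying distance is reported per pair and kind.
#'
#' @param model A [parse_structure()] result.
#' @param chain_a,chain_b Chain identifiers; both must be present.
#' @param heavy_atom_cutoff Inclusive cutoff in Angstrom (default 4.5).
#' @return data.frame of contact records: `chain_a`, `resno_a`, `resid_a`,
#'   `chain_b`, `resno_b`, `resid_b`, `kind` (hydrophobic/ionic), `ring`
#'   (`NA`), `distance`.
#' @export
residue_contacts <- function(model, chain_a, chain_b,
                             heavy_atom_cutoff = 4.5) {
  stopifnot(inherits(model, "structure_model"), heavy_atom_cutoff > 0)
  a_atoms <- .chain_atoms(model, chain_a)
  b_atoms <- .chain_atoms(model, chain_b)
  out <- list()
  a_res <- .residue_split(a_atoms)
  b_res <- .residue_split(b_atoms)
  a_anion <- .anionic_coords(a_atoms)
  b_anion <- .anionic_coords(b_atoms)
  for (ra in a_res) {
    for (rb in b_res) {
      # hydrophobic
      ha <- ra[.hydrophobic_atoms(ra), , drop = FALSE]
      hb <- rb[.hydrophobic_atoms(rb), , drop = FALSE]
      if (nrow(ha) && nrow(hb)) {
        d <- .min_dist(.coords(ha), .coords(hb))
        if (d <= heavy_atom_cutoff) {
          out[[length(out) + 1L]] <- .contact_row(ra, rb, "hydrophobic", d)
        }
      }
      # ionic, both polarities
      dmin <- Inf
      ca <- .cationic_coords(ra)
      an_b <- b_anion[b_anion$resno == rb$resno[1], , drop = FALSE]
      if (nrow(ca) && nrow(an_b)) {
        dmin <- min(dmin, .min_dist(.coords(ca), .coords(an_b)))
      }
      cb <- .cationic_coords(rb)
      an_a <- a_anion[a_anion$resno == ra$resno[1], , drop = FALSE]
      if (nrow(cb) && nrow(an_a)) {
        dmin <- min(dmin, .min_dist(.coords(cb), .coords(an_a)))
      }
      if (dmin <= heavy_atom_cutoff) {
        out[[length(out) + 1L]] <- .contact_row(ra, rb, "ionic", dmin)
      }
    }
  }
  if (!length(out)) return(.empty_contacts())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aromatic ring centroid of a residue
#'
#' Geometric mean of the ring-member atom coordinates (Phe/Tyr six-ring, Trp
#' five- and six-rings, His imidazole). For a regular polygon of atoms this is
#' exactly the polygon center.
#'
#' @param model A [parse_structure()] result.
#' @param chain,resno Residue selector.
#' @param ring `"five_ring"` or `"six_ring"` (the residue type determines
#'   which exist).
#' @return Numeric xyz vector.
#' @export
ring_centroid <- function(model, chain, resno, ring = "six_ring") {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms[model$atoms$chain == chain & model$atoms$resno == resno, ,
                    drop = FALSE]
  if (!nrow(at)) stop("residue ", chain, ":", resno, " not found")
  rings <- .ring_atoms[[at$resid[1]]]
  if (is.null(rings) || is.null(rings[[ring]])) {
    stop(at$resid[1], " has no ", ring)
  }
  sel <- at[at$elety %in% rings[[ring]], , drop = FALSE]
  if (nrow(sel) != length(rings[[ring]])) {
    stop("incomplete ", ring, " for ", at$resid[1], " ", resno)
  }
  colMeans(.coords(sel))
}

#' Cation-pi contacts between two chains
#'
#' A contact is recorded when the distance from a cationic group center (Lys
#' NZ; Arg CZ, the guanidinium carbon) to an aromatic ring centroid (Phe/Tyr
#' six-ring; Trp five- and six-rings, tested separately; His imidazole) is
#' within the cutoff, inclusive. Both orientations (cation in `chain_a`, ring
#' in `chain_b` and vice versa) are screened; `partner_a` is always the
#' `chain_a` residue.
#'
#' @inheritParams residue_contacts
#' @param cutoff Inclusive centroid cutoff in Angstrom (default 6.0).
#' @return data.frame of contact records with `kind = "cation_pi"` and `ring`
#'   naming the ring tested on the aromatic partner.
#' @export
cation_pi_contacts <- function(model, chain_a, chain_b, cutoff = 6.0) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  a_atoms <- .chain_atoms(model, chain_a)
  b_atoms <- .chain_atoms(model, chain_b)
  cation_centers <- function(atoms) {
    sel <- (atoms$resid == "LYS" & atoms$elety == "NZ") |
      (atoms$resid == "ARG" & atoms$elety == "CZ")
    atoms[sel, , drop = FALSE]
  }
  ring_list <- function(atoms) {
    out <- list()
    for (rr in .residue_split(atoms)) {
      rings <- .ring_atoms[[rr$resid[1]]]
      if (is.null(rings)) next
      for (rg in names(rings)) {
        sel <- rr[rr$elety %in% rings[[rg]], , drop = FALSE]
        if (nrow(sel) != length(rings[[rg]])) next
        out[[length(out) + 1L]] <- list(res = rr, ring = rg,
                                        centroid = colMeans(.coords(sel)))
      }
    }
    out
  }
  screen <- function(cats, rings, a_is_cation) {
    rows <- list()
    if (!nrow(cats) || !length(rings)) return(rows)
    for (i in seq_len(nrow(cats))) {
      for (rg in rings) {
        d <- sqrt(sum((as.numeric(cats[i, c("x", "y", "z")]) -
                         rg$centroid)^2))
        if (d <= cutoff) {
          rows[[length(rows) + 1L]] <- if (a_is_cation) {
            .contact_row(cats[i, ], rg$res, "cation_pi", d, rg$ring)
          } else {
            .contact_row(rg$res, cats[i, ], "cation_pi", d, rg$ring)
          }
        }
      }
    }
    rows
  }
  out <- c(screen(cation_centers(a_atoms), ring_list(b_atoms), TRUE),
           screen(cation_centers(b_atoms), ring_list(a_atoms), FALSE))
  if (!length(out)) return(.empty_contacts())
  res <- do.call(rbind, out)
  # collapse duplicate (residue pair, ring) records to the minimum distance
  key <- paste(res$chain_a, res$resno_a, res$chain_b, res$resno_b, res$ring,
               sep = "\r")
  res <- res[order(key, res$distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$chain_a, res$resno_a, res$chain_b,
                               res$resno_b, res$ring, sep = "\r")), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All interface contacts between two chains
#'
#' Convenience wrapper combining [residue_contacts()] and
#' [cation_pi_contacts()].
#'
#' @inheritParams residue_contacts
#' @param cation_pi_cutoff Inclusive cation-pi cutoff (default 6.0 A).
#' @return Combined contact-record data.frame.
#' @export
interface_contacts <- function(model, chain_a, chain_b,
                               heavy_atom_cutoff = 4.5,
                               cation_pi_cutoff = 6.0) {
  rbind(residue_contacts(model, chain_a, chain_b, heavy_atom_cutoff),
        cation_pi_contacts(model, chain_a, chain_b, cation_pi_cutoff))
}
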