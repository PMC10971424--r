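# PDB parsing and distance-based interface classification.

test_that("toy PDB parses with exact coordinates; HETATM ignored", {
  p <- write_toy_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1.5, 2.5, 3.5),
    pdb_atom_line(2, "CA", "ALA", "B", 2, -1, 0, 4.25),
    "HETATM    3  O   HOH A 100       0.000   0.000   0.000  1.00  0.00           O"))
  m <- parse_structure(p)
  expect_identical(nrow(m$atoms), 2L)
  expect_identical(m$atoms$x, c(1.5, -1))
  expect_identical(m$atoms$z, c(3.5, 4.25))
})

test_that("highest-occupancy altloc is kept", {
  p <- write_toy_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.4, alt = "B")))
  m <- parse_structure(p)
  expect_identical(nrow(m$atoms), 1L)
  expect_identical(m$atoms$x, 1)
})

test_that("empty or missing files are rejected", {
  empty <- tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(parse_structure(empty))
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "no such file")
})

leu_pair_pdb <- function(dz) {
  write_toy_pdb(c(
    pdb_atom_line(1, "CA", "LEU", "A", 1, 0, 0, -5),
    pdb_atom_line(2, "CD1", "LEU", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "CA", "LEU", "B", 2, 0, 0, dz + 5),
    pdb_atom_line(4, "CD1", "LEU", "B", 2, 0, 0, dz)))
}

test_that("hydrophobic contact boundary is inclusive at the cutoff", {
  m40 <- parse_structure(leu_pair_pdb(4.0))
  c40 <- residue_contacts(m40, "A", "B")
  expect_identical(nrow(c40), 1L)
  expect_identical(c40$kind, "hydrophobic")
  expect_equal(c40$distance, 4.0, tolerance = 1e-9)
  # exactly at 4.5: contact (inclusive)
  expect_identical(nrow(residue_contacts(parse_structure(leu_pair_pdb(4.5)),
                                         "A", "B")), 1L)
  # 4.6 with cutoff 4.5: none
  expect_identical(nrow(residue_contacts(parse_structure(leu_pair_pdb(4.6)),
                                         "A", "B")), 0L)
  expect_error(residue_contacts(m40, "A", "C"), "not present")
})

test_that("ionic contacts pair cations with carboxylates incl. C terminus", {
  # Lys NZ 3 A from a Glu carboxylate oxygen
  p <- write_toy_pdb(c(
    pdb_atom_line(1, "NZ", "LYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "OE1", "GLU", "B", 5, 0, 0, 3),
    pdb_atom_line(3, "OE2", "GLU", "B", 5, 0, 1.5, 3)))
  cc <- residue_contacts(parse_structure(p), "A", "B")
  expect_identical(cc$kind, "ionic")
  expect_equal(cc$distance, 3, tolerance = 1e-9)
  # His imidazole nitrogen against the partner chain's C-terminal carboxylate
  # (the ubiquitin Gly76 engagement)
  p2 <- write_toy_pdb(c(
    pdb_atom_line(1, "NE2", "HIS", "A", 409, 0, 0, 0),
    pdb_atom_line(2, "ND1", "HIS", "A", 409, 0, 1.3, 0.5),
    pdb_atom_line(3, "CA", "GLY", "B", 76, 2, 0, 2),
    pdb_atom_line(4, "O", "GLY", "B", 76, 0, 0, 3.5),
    pdb_atom_line(5, "OXT", "GLY", "B", 76, 1, 0, 4)))
  cc2 <- residue_contacts(parse_structure(p2), "A", "B")
  ionic <- cc2[cc2$kind == "ionic", ]
  expect_identical(nrow(ionic), 1L)
  # minimum qualifying distance: ND1 at (0, 1.3, 0.5) to O at (0, 0, 3.5)
  expect_equal(ionic$distance, sqrt(1.3^2 + 3^2), tolerance = 1e-9)
})

arg_trp_pdb <- function(dz) {
  ring <- ring_atom_lines(c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
                          "TRP", "B", 414, center = c(0, 0, dz),
                          serial_start = 2L)
  write_toy_pdb(c(pdb_atom_line(1, "CZ", "ARG", "A", 74, 0, 0, 0), ring))
}

test_that("cation-pi boundary is inclusive at 6.0 A", {
  m5 <- parse_structure(arg_trp_pdb(5.0))
  cp <- cation_pi_contacts(m5, "A", "B")
  expect_identical(nrow(cp), 1L)
  expect_identical(cp$kind, "cation_pi")
  expect_identical(cp$ring, "six_ring")
  expect_equal(cp$distance, 5.0, tolerance = 1e-9)
  expect_identical(nrow(cation_pi_contacts(parse_structure(arg_trp_pdb(6.0)),
                                           "A", "B")), 1L)
  expect_identical(nrow(cation_pi_contacts(parse_structure(arg_trp_pdb(6.01)),
                                           "A", "B")), 0L)
})

test_that("ring centroid of a regular hexagon is its exact center", {
  p <- write_toy_pdb(ring_atom_lines(
    c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "PHE", "A", 10,
    center = c(2.5, -1.25, 7), radius = 1.39))
  m <- parse_structure(p)
  expect_equal(ring_centroid(m, "A", 10, "six_ring"), c(2.5, -1.25, 7),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(ring_centroid(m, "A", 10, "five_ring"), "no five_ring")
})

test_that("contacts are symmetric under chain swap", {
  p <- write_toy_pdb(c(
    pdb_atom_line(1, "CD1", "LEU", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CD1", "LEU", "B", 2, 0, 0, 4),
    pdb_atom_line(3, "NZ", "LYS", "A", 3, 10, 0, 0),
    pdb_atom_line(4, "OD1", "ASP", "B", 4, 10, 0, 3.2),
    pdb_atom_line(5, "CZ", "ARG", "B", 5, 20, 0, 0),
    ring_atom_lines(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "TYR",
                    "A", 6, center = c(20, 0, 5.5), serial_start = 6L)))
  m <- parse_structure(p)
  ab <- interface_contacts(m, "A", "B")
  ba <- interface_contacts(m, "B", "A")
  expect_identical(nrow(ab), 3L)
  key_ab <- paste(ab$resno_a, ab$resno_b, ab$kind, round(ab$distance, 6))
  key_ba <- paste(ba$resno_b, ba$resno_a, ba$kind, round(ba$distance, 6))
  expect_setequal(key_ab, key_ba)
  expect_true(all(ab$chain_a == "A") && all(ba$chain_a == "B"))
})

test_that("enlarging a cutoff never removes a contact", {
  p <- write_toy_pdb(c(
    pdb_atom_line(1, "CD1", "LEU", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CD1", "LEU", "B", 2, 0, 0, 4.2),
    pdb_atom_line(3, "CZ", "ARG", "A", 3, 10, 0, 0),
    ring_atom_lines(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "PHE",
                    "B", 4, center = c(10, 0, 5.8), serial_start = 4L)))
  m <- parse_structure(p)
  for (cuts in list(c(4.0, 4.5, 6), c(5, 6, 8))) {
    prev <- NULL
    for (cut in cuts) {
      cur <- rbind(residue_contacts(m, "A", "B", heavy_atom_cutoff = cut),
                   cation_pi_contacts(m, "A", "B", cutoff = cut))
      keys <- paste(cur$resno_a, cur$resno_b, cur$kind, cur$ring)
      if (!is.null(prev)) expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})
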