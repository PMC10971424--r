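# Fixture builders shared across tests: toy PDB files written in code and an
# independent brute-force peak-detection oracle.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = substr(name, 1, 1)) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resn, chain, resno, x, y, z, occ, 0, element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# regular polygon of ring atoms in the z = zc plane, centered at (xc, yc, zc)
ring_atom_lines <- function(names, resn, chain, resno, center, radius = 1.4,
                            serial_start = 1L) {
  ang <- 2 * pi * (seq_along(names) - 1) / length(names)
  vapply(seq_along(names), function(i) {
    pdb_atom_line(serial_start + i - 1L, names[i], resn, chain, resno,
                  center[1] + radius * cos(ang[i]),
                  center[2] + radius * sin(ang[i]), center[3])
  }, character(1))
}

# independent oracle: enumerate every strict local maximum of the
# baseline-subtracted trace passing the S/N gate, by explicit looping
brute_force_apexes <- function(spectrum, baseline, noise_sd, threshold = 5) {
  y <- spectrum$intensity - baseline
  idx <- integer(0)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > 0) {
      ok <- if (noise_sd > 0) y[i] / noise_sd >= threshold else TRUE
      if (ok) idx <- c(idx, i)
    }
  }
  spectrum$mz[idx]
}

# one-adduct well fixture used across peak-processing and quantification tests
ub_species <- function() molecular_species("Ub", sequence = ubiquitin_sequence())

well_control_list <- function(nucleophile = "Ac-T") {
  build_mass_control_list(ub_species(), nucleophile_panel()[nucleophile],
                          standard = "15N")
}
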