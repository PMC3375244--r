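# Programmatic PDB fixtures and toy parameter sets shared across tests.

# Format one ATOM/HETATM line per wwPDB v3.3 columns. `element = NA` omits
# columns 77-78 (for testing name-based element resolution).
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", icode = " ", alt = " ",
                          occ = 1.00, b = 0.00, element = NULL) {
  nm <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  line <- sprintf("%-6s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                  record, serial, nm, alt, resname, chain, resno, icode,
                  x, y, z, occ, b)
  if (!is.null(element)) {
    line <- sprintf("%-76s%2s", line, element)
  }
  line
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Single water molecule (O, H1, H2), residue HOH.
water_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_fixture_pdb(c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0.000, 0.000, 0.000,
                  record = "HETATM", element = "O"),
    pdb_atom_line(2, "H1", "HOH", "A", 1, 0.960, 0.000, 0.000,
                  record = "HETATM", element = "H"),
    pdb_atom_line(3, "H2", "HOH", "A", 1, -0.240, 0.930, 0.000,
                  record = "HETATM", element = "H")
  ), path)
}

# Glycylglycine zwitterion-free dipeptide with explicit hydrogens and free
# termini (H1/H2/H3 on the N-terminus, OXT on the C-terminus). Plausible
# covalent geometry; coordinates hand-placed so hydrogens sit within
# covalent range of their heavy atom and the peptide C-N is 1.3 A.
glygly_atoms <- function() {
  # name, resno, x, y, z, element
  rows <- list(
    list("N",   1,  0.00,  0.00, 0.00, "N"),
    list("H1",  1, -0.40,  0.90, 0.00, "H"),
    list("H2",  1, -0.40, -0.90, 0.00, "H"),
    list("H3",  1,  0.30,  0.00, 1.00, "H"),
    list("CA",  1,  1.45,  0.00, 0.00, "C"),
    list("HA2", 1,  1.80, -0.60, 0.80, "H"),
    list("HA3", 1,  1.80, -0.60,-0.80, "H"),
    list("C",   1,  2.00,  1.30, 0.00, "C"),
    list("O",   1,  1.40,  2.30, 0.00, "O"),
    list("N",   2,  3.30,  1.40, 0.00, "N"),
    list("H",   2,  3.70,  0.55, 0.00, "H"),
    list("CA",  2,  4.00,  2.60, 0.00, "C"),
    list("HA2", 2,  3.60,  3.20, 0.80, "H"),
    list("HA3", 2,  3.60,  3.20,-0.80, "H"),
    list("C",   2,  5.50,  2.50, 0.00, "C"),
    list("O",   2,  6.10,  1.50, 0.00, "O"),
    list("OXT", 2,  6.10,  3.60, 0.00, "O")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], resno = r[[2]], x = r[[3]], y = r[[4]],
               z = r[[5]], element = r[[6]], stringsAsFactors = FALSE)
  }))
}

glygly_pdb <- function(path = tempfile(fileext = ".pdb"),
                       with_elements = TRUE, with_hydrogens = TRUE,
                       jitter_seed = NULL, chain = "A") {
  a <- glygly_atoms()
  if (!with_hydrogens) a <- a[a$element != "H", , drop = FALSE]
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    a[c("x", "y", "z")] <- a[c("x", "y", "z")] +
      matrix(stats::runif(3 * nrow(a), -0.05, 0.05), nrow(a))
  }
  lines <- vapply(seq_len(nrow(a)), function(i) {
    pdb_atom_line(i, a$name[i], "GLY", chain, a$resno[i],
                  a$x[i], a$y[i], a$z[i],
                  element = if (with_elements) a$element[i] else NULL)
  }, character(1))
  write_fixture_pdb(lines, path)
}

# Two cysteine residues (heavy atoms only) with SG-SG at 2.05 A.
cys_pair_pdb <- function(path = tempfile(fileext = ".pdb")) {
  mk <- function(serial0, resno, ox) {
    c(
      pdb_atom_line(serial0 + 0, "N",  "CYS", "A", resno, ox + 0.0, 0.0, 0.0, element = "N"),
      pdb_atom_line(serial0 + 1, "CA", "CYS", "A", resno, ox + 1.4, 0.0, 0.0, element = "C"),
      pdb_atom_line(serial0 + 2, "C",  "CYS", "A", resno, ox + 2.0, 1.3, 0.0, element = "C"),
      pdb_atom_line(serial0 + 3, "O",  "CYS", "A", resno, ox + 1.4, 2.3, 0.0, element = "O"),
      pdb_atom_line(serial0 + 4, "CB", "CYS", "A", resno, ox + 2.0, -1.0, 1.0, element = "C"),
      pdb_atom_line(serial0 + 5, "SG", "CYS", "A", resno, ox + 2.0, -1.0, 2.8, element = "S")
    )
  }
  # second SG at (2.0 + dx, -1.0, 2.8) with dx chosen for |SG-SG| = 2.05
  write_fixture_pdb(c(mk(1, 1, 0), mk(7, 2, 2.05)), path)
}

# Lone calcium ion HETATM.
ca_ion_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_fixture_pdb(
    pdb_atom_line(1, "CA", "CA", "B", 90, 0, 0, 0, record = "HETATM",
                  element = "CA"),
    path)
}

# Two-model NMR-style file: water at the origin (model 1) and shifted by
# +5 A in x (model 2).
nmr_two_model_pdb <- function(path = tempfile(fileext = ".pdb")) {
  w <- function(shift) c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0.000 + shift, 0.000, 0.000,
                  record = "HETATM", element = "O"),
    pdb_atom_line(2, "H1", "HOH", "A", 1, 0.960 + shift, 0.000, 0.000,
                  record = "HETATM", element = "H"),
    pdb_atom_line(3, "H2", "HOH", "A", 1, -0.240 + shift, 0.930, 0.000,
                  record = "HETATM", element = "H")
  )
  writeLines(c("MODEL        1", w(0), "ENDMDL",
               "MODEL        2", w(5), "ENDMDL", "END"), path)
  path
}

# Toy parameter set covering water (H, O) under scheme 'E'.
water_params <- function() {
  eem_params("E", k = 0.5,
             table = data.frame(type = c("H", "O"),
                                A = c(2.2, 3.4), B = c(9.0, 8.0)))
}

# 'E' parameters covering all six supported elements (the fixture default).
toy_params_E <- function() eemr:::.eemr_default_true_params()

# 'EX' ground truth covering the types present in the glygly fixture.
toy_params_EX <- function() {
  eem_params("EX", k = 0.4, table = data.frame(
    type = c("H1", "C1", "C2", "N1", "O1", "O2"),
    A = c(2.4, 3.0, 3.3, 3.9, 4.2, 4.6),
    B = c(9.0, 6.5, 6.0, 7.5, 8.8, 8.2)
  ))
}

# A small molecule with arbitrary geometry for solver property tests.
random_molecule <- function(n, seed, elements = c("H", "C", "N", "O"),
                            box = 8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(stats::runif(3 * n, 0, box), n, 3)
    d <- stats::dist(xyz)
    if (n == 1 || min(d) >= 1.0) break
  }
  el <- sample(elements, n, replace = TRUE)
  eem_molecule(paste0("rnd", seed), data.frame(
    element = el, name = paste0(toupper(el), seq_len(n)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ), total_charge = sample(c(-1, 0, 1), 1))
}

# Random 3D rotation matrix (QR-based, seeded).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

transform_molecule <- function(mol, rotation, translation = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  mol$atoms[c("x", "y", "z")] <- xyz
  mol
}

permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  mol$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  if (nrow(mol$bonds) > 0) {
    mol$bonds$i <- inv[mol$bonds$i]
    mol$bonds$j <- inv[mol$bonds$j]
  }
  mol
}
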