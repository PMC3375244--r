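# Heavy-atom bond templates for the 20 standard amino acids.
# Each entry: "NAME1 NAME2 order". Backbone bonds (N-CA, CA-C, C=O, C-OXT)
# are shared and added for every amino acid. Aromatic/resonant systems use
# a fixed Kekule assignment; only the MAXIMUM incident order matters for
# the 'EX' typing scheme, so the choice of Kekule structure is immaterial
# for carbons with at least one double bond.
.eemr_backbone_bonds <- c("N CA 1", "CA C 1", "C O 2", "C OXT 1")

.eemr_aa_templates <- list(
  ALA = c("CA CB 1"),
  ARG = c("CA CB 1", "CB CG 1", "CG CD 1", "CD NE 1", "NE CZ 1",
          "CZ NH1 2", "CZ NH2 1"),
  ASN = c("CA CB 1", "CB CG 1", "CG OD1 2", "CG ND2 1"),
  ASP = c("CA CB 1", "CB CG 1", "CG OD1 2", "CG OD2 1"),
  CYS = c("CA CB 1", "CB SG 1"),
  GLN = c("CA CB 1", "CB CG 1", "CG CD 1", "CD OE1 2", "CD NE2 1"),
  GLU = c("CA CB 1", "CB CG 1", "CG CD 1", "CD OE1 2", "CD OE2 1"),
  GLY = character(0),
  HIS = c("CA CB 1", "CB CG 1", "CG ND1 1", "CG CD2 2", "ND1 CE1 2",
          "CD2 NE2 1", "CE1 NE2 1"),
  ILE = c("CA CB 1", "CB CG1 1", "CB CG2 1", "CG1 CD1 1"),
  LEU = c("CA CB 1", "CB CG 1", "CG CD1 1", "CG CD2 1"),
  LYS = c("CA CB 1", "CB CG 1", "CG CD 1", "CD CE 1", "CE NZ 1"),
  MET = c("CA CB 1", "CB CG 1", "CG SD 1", "SD CE 1"),
  PHE = c("CA CB 1", "CB CG 1", "CG CD1 2", "CG CD2 1", "CD1 CE1 1",
          "CD2 CE2 2", "CE1 CZ 2", "CE2 CZ 1"),
  PRO = c("CA CB 1", "CB CG 1", "CG CD 1", "CD N 1"),
  SER = c("CA CB 1", "CB OG 1"),
  THR = c("CA CB 1", "CB OG1 1", "CB CG2 1"),
  TRP = c("CA CB 1", "CB CG 1", "CG CD1 2", "CG CD2 1", "CD1 NE1 1",
          "NE1 CE2 1", "CD2 CE2 2", "CD2 CE3 1", "CE3 CZ3 2",
          "CZ3 CH2 1", "CH2 CZ2 2", "CZ2 CE2 1"),
  TYR = c("CA CB 1", "CB CG 1", "CG CD1 2", "CG CD2 1", "CD1 CE1 1",
          "CD2 CE2 2", "CE1 CZ 2", "CE2 CZ 1", "CZ OH 1"),
  VAL = c("CA CB 1", "CB CG1 1", "CB CG2 1")
)

# Covalent radii (angstrom, Cordero 2008) for the distance fallback.
.eemr_covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66,
                          S = 1.05, Ca = 1.76)

.eemr_water_residues <- c("HOH", "WAT", "H2O", "TIP3", "SOL")

is_amino_acid <- function(resname) toupper(resname) %in% names(.eemr_aa_templates)
is_water <- function(resname) toupper(resname) %in% .eemr_water_residues
is_ion <- function(resname) toupper(resname) %in% names(.eemr_ion_residues)

#' Perceive bonds with orders
#'
#' Assigns bonds for standard amino acids, waters and termini from residue
#' templates (with orders: e.g. the backbone carbonyl C=O has order 2),
#' inter-residue peptide bonds from the C--N distance, and disulfide bridges
#' from the S--S distance. Hydrogens are attached to their nearest heavy
#' atom within covalent range. Monoatomic ions receive no bonds. Residues
#' with no template fall back, with a warning, to distance-based single
#' bonds (covalent radii + 0.4 angstrom tolerance).
#'
#' @param mol An [eem_molecule()].
#' @param peptide_cutoff Maximum C--N distance (angstrom) for a peptide bond.
#' @param ss_cutoff Maximum S--S distance (angstrom) for a disulfide bond.
#' @param fallback_tol Tolerance (angstrom) added to summed covalent radii
#'   in the distance fallback.
#'
#' @return A data.frame of bonds with columns `i`, `j` (1-based atom
#'   indices) and `order`.
#' @export
perceive_bonds <- function(mol, peptide_cutoff = 1.7, ss_cutoff = 2.3,
                           fallback_tol = 0.4) {
  a <- mol$atoms
  n <- nrow(a)
  d <- distance_matrix(mol) # errors on clashes < 0.5 angstrom
  res_key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  bonds_i <- integer(0); bonds_j <- integer(0); bonds_o <- integer(0)
  add_bond <- function(i, j, o) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
    bonds_o <<- c(bonds_o, o)
  }

  warned_residues <- character(0)
  for (rk in unique(res_key)) {
    idx <- which(res_key == rk)
    resname <- toupper(a$resname[idx[1L]])
    heavy <- idx[a$element[idx] != "H"]
    if (is_ion(resname) || length(idx) == 1L) next
    if (is_amino_acid(resname)) {
      tmpl <- c(.eemr_backbone_bonds, .eemr_aa_templates[[resname]])
      for (entry in tmpl) {
        f <- strsplit(entry, " ", fixed = TRUE)[[1L]]
        i <- idx[match(f[1L], a$name[idx])]
        j <- idx[match(f[2L], a$name[idx])]
        if (!is.na(i) && !is.na(j)) add_bond(i, j, as.integer(f[3L]))
      }
    } else if (is_water(resname)) {
      # O-H handled by the hydrogen attachment pass below
    } else {
      if (!(resname %in% warned_residues)) {
        warning("no bond template for residue '", resname,
                "'; using distance-based single bonds")
        warned_residues <- c(warned_residues, resname)
      }
      if (length(heavy) >= 2L) {
        for (ii in seq_len(length(heavy) - 1L)) {
          for (jj in seq.int(ii + 1L, length(heavy))) {
            i <- heavy[ii]; j <- heavy[jj]
            rmax <- .eemr_covalent_radii[[a$element[i]]] +
              .eemr_covalent_radii[[a$element[j]]] + fallback_tol
            if (d[i, j] <= rmax) add_bond(i, j, 1L)
          }
        }
      }
    }
  }

  # hydrogens: bond to the nearest heavy atom within covalent range
  h_idx <- which(a$element == "H")
  heavy_idx <- which(a$element != "H")
  for (i in h_idx) {
    if (length(heavy_idx) == 0L) break
    cand <- heavy_idx[res_key[heavy_idx] == res_key[i]]
    if (length(cand) == 0L) cand <- heavy_idx
    j <- cand[which.min(d[i, cand])]
    rmax <- .eemr_covalent_radii[["H"]] +
      .eemr_covalent_radii[[a$element[j]]] + fallback_tol
    if (d[i, j] <= rmax) add_bond(i, j, 1L)
  }

  # inter-residue peptide bonds: backbone C of one residue to backbone N of
  # another within the cutoff
  c_idx <- which(a$name == "C" & is_amino_acid(a$resname))
  n_idx <- which(a$name == "N" & is_amino_acid(a$resname))
  for (i in c_idx) {
    for (j in n_idx) {
      if (res_key[i] != res_key[j] && d[i, j] <= peptide_cutoff) {
        add_bond(i, j, 1L)
      }
    }
  }

  # disulfide bridges between cysteine sulfurs
  sg_idx <- which(a$element == "S" & toupper(a$resname) == "CYS")
  if (length(sg_idx) >= 2L) {
    for (ii in seq_len(length(sg_idx) - 1L)) {
      for (jj in seq.int(ii + 1L, length(sg_idx))) {
        i <- sg_idx[ii]; j <- sg_idx[jj]
        if (d[i, j] <= ss_cutoff) add_bond(i, j, 1L)
      }
    }
  }

  b <- data.frame(i = pmin(bonds_i, bonds_j), j = pmax(bonds_i, bonds_j),
                  order = bonds_o)
  b <- b[!duplicated(b[c("i", "j")]), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Assign calibration atom types
#'
#' Classifies atoms under one of two schemes: `"E"` types atoms by chemical
#' element only; `"EX"` types by element plus the maximum order over the
#' atom's incident bonds (so a carbonyl oxygen is `"O2"` and a hydroxyl
#' oxygen `"O1"`). Unbonded species (isolated ions) keep the bare element
#' symbol under both schemes, since a maximum bond order is undefined at
#' zero bonds.
#'
#' @param mol An [eem_molecule()]; for `"EX"` its `bonds` must be populated
#'   (see [perceive_bonds()]).
#' @param scheme `"E"` or `"EX"`.
#' @return Character vector of type keys, one per atom.
#' @export
assign_atom_types <- function(mol, scheme = c("E", "EX")) {
  scheme <- match.arg(scheme)
  el <- mol$atoms$element
  if (scheme == "E") return(el)
  n <- nrow(mol$atoms)
  maxord <- integer(n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (r in seq_len(nrow(b))) {
      maxord[b$i[r]] <- max(maxord[b$i[r]], b$order[r])
      maxord[b$j[r]] <- max(maxord[b$j[r]], b$order[r])
    }
  }
  ifelse(maxord > 0L, paste0(el, maxord), el)
}

#' Conventional formal total charge at neutral pH
#'
#' Sums conventional residue formal charges: Asp/Glu -1, Lys/Arg +1, His 0,
#' +1 for each free protein N-terminus, -1 for each free C-terminus, and +2
#' per calcium ion. Intended as a default for the total molecular charge Q,
#' overridable wherever Q is consumed.
#'
#' @param mol An [eem_molecule()].
#' @param pH_model Charge convention; only `"standard"` (neutral pH) is
#'   defined.
#' @return Integer total charge in e.
#' @export
formal_total_charge <- function(mol, pH_model = "standard") {
  stopifnot(identical(pH_model, "standard"))
  a <- mol$atoms
  q <- 0L
  res <- unique(data.frame(chain = a$chain, resno = a$resno, icode = a$icode,
                           resname = toupper(a$resname),
                           stringsAsFactors = FALSE))
  side <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L)
  q <- q + sum(side[res$resname], na.rm = TRUE)
  q <- q + 2L * sum(is_ion(res$resname) & res$resname %in% c("CA", "CAL"))
  # termini: first and last amino-acid residue of each chain
  for (ch in unique(res$chain)) {
    aa <- res[res$chain == ch & is_amino_acid(res$resname), , drop = FALSE]
    if (nrow(aa) > 0L) q <- q + 1L - 1L
  }
  as.integer(q)
}
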