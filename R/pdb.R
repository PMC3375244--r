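#' Read a molecule from a PDB file
#'
#' Reads ATOM and HETATM records of one model of a PDB file (wwPDB v3.3
#' columns, parsed with \pkg{bio3d}) into an [eem_molecule()]. Waters and
#' ions are retained. Alternate locations are collapsed to the highest
#' occupancy variant (ties resolved to the first encountered). Element
#' symbols are taken from columns 77--78 when present, otherwise derived
#' from the atom name using residue-aware rules (so `" CA "` in an amino
#' acid is carbon, while the `CA` HETATM ion is calcium).
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model to read from multi-model (NMR) files.
#'   Defaults to the first model.
#' @param total_charge Total molecular charge Q in e. If `NULL` (default),
#'   set from [formal_total_charge()].
#'
#' @return An [eem_molecule()] (without bonds; see [perceive_bonds()]).
#' @export
read_pdb <- function(path, model_index = 1L, total_charge = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("no model ", model_index, " in '", path, "' (file has ",
         n_models, " model", if (n_models != 1L) "s", ")")
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)

  icode <- at$insert
  icode[is.na(icode)] <- ""
  element <- resolve_elements(at$elesy, at$elety, at$resid, at$type)

  atoms <- data.frame(
    element = element,
    name = as.character(at$elety),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    resno = as.integer(at$resno),
    icode = icode,
    resname = as.character(at$resid),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    formal_charge = 0L,
    stringsAsFactors = FALSE
  )

  # collapse alternate locations: keep the highest-occupancy copy of each
  # (chain, residue, atom name); tie -> first encountered in file order
  alt <- at$alt
  if (any(!is.na(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
                 atoms$name, sep = "\r")
    ord <- order(key, -occ, seq_len(nrow(atoms)))
    keep <- ord[!duplicated(key[ord])]
    atoms <- atoms[sort(keep), , drop = FALSE]
  }

  id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  mol <- eem_molecule(id, atoms, bonds = NULL, total_charge = 0)
  mol$total_charge <- if (is.null(total_charge)) {
    formal_total_charge(mol)
  } else {
    total_charge
  }
  mol
}

# Ion residue names whose atoms are two-letter elements we support.
.eemr_ion_residues <- c(CA = "Ca", CAL = "Ca")

# Resolve element symbols: honor PDB columns 77-78 when present, else derive
# from the atom name, disambiguating " CA " (alpha carbon) from the calcium
# ion by residue context.
resolve_elements <- function(elesy, name, resname, rectype) {
  canon <- c(H = "H", C = "C", N = "N", O = "O", S = "S", CA = "Ca")
  out <- character(length(name))
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  for (i in seq_along(name)) {
    e <- elesy[i]
    if (nzchar(e) && e %in% names(canon)) {
      out[i] <- canon[[e]]
      next
    }
    if (nzchar(e)) stop("unresolvable element symbol '", e,
                        "' for atom '", name[i], "'")
    nm <- toupper(gsub("[0-9']", "", trimws(name[i])))
    res <- toupper(trimws(resname[i]))
    if (res %in% names(.eemr_ion_residues) && nm %in% c("CA", "CAL")) {
      out[i] <- .eemr_ion_residues[[res]]
    } else if (res %in% c(names(.eemr_aa_templates), "HOH", "WAT") ||
               substr(nm, 1L, 1L) %in% c("H", "C", "N", "O", "S")) {
      # standard residue naming: first letter of the stripped name
      out[i] <- substr(nm, 1L, 1L)
    } else {
      stop("cannot resolve element for atom '", name[i],
           "' in residue '", resname[i], "'")
    }
  }
  out
}

#' Write a molecule to a PDB file
#'
#' Writes atoms (and residue bookkeeping) of a molecule as ATOM records via
#' \pkg{bio3d}. Bonds are not written; they are re-perceived on read.
#'
#' @param mol An [eem_molecule()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(mol, path) {
  a <- mol$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, chain = a$chain,
    insert = ifelse(nzchar(a$icode), a$icode, NA),
    eleno = seq_len(nrow(a)), elety = a$name,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = toupper(a$element)
  )
  invisible(path)
}
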