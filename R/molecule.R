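#' Construct a molecule
#'
#' A molecule is the unit on which EEM operates: an ordered atom table with
#' 3D coordinates (in angstrom), optional bonds with integer orders, residue
#' bookkeeping, and a total molecular charge Q (in elementary charge units e).
#'
#' @param id Molecule identifier string.
#' @param atoms A data.frame with one row per atom and columns
#'   `element`, `name`, `x`, `y`, `z`, `resno`, `icode`, `resname`,
#'   `chain`, `formal_charge`. Missing bookkeeping columns are filled with
#'   defaults (residue 1, chain "A", empty insertion code, formal charge 0).
#' @param bonds A data.frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (integer in 1..3), or `NULL` for no bonds.
#' @param total_charge Total molecular charge Q in e.
#'
#' @return An object of class `eem_molecule`.
#' @export
eem_molecule <- function(id, atoms, bonds = NULL, total_charge = 0) {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(atoms))
  defaults <- list(resno = 1L, icode = "", resname = "UNK",
                   chain = "A", formal_charge = 0L)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  needed <- c("element", "name", "x", "y", "z",
              "resno", "icode", "resname", "chain", "formal_charge")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[needed]
  atoms$element <- as.character(atoms$element)
  atoms$name <- as.character(atoms$name)
  atoms$icode[is.na(atoms$icode)] <- ""
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates")
  }
  unknown <- setdiff(unique(atoms$element), names(.eemr_pauling))
  if (length(unknown) > 0L) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
  mol <- structure(
    list(id = id, atoms = atoms, bonds = bonds,
         total_charge = total_charge),
    class = "eem_molecule"
  )
  validate_molecule(mol)
  mol
}

#' @export
print.eem_molecule <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat("EEM molecule '", x$id, "': ", nrow(x$atoms), " atoms (",
      paste(sprintf("%s:%d", names(comp), as.integer(comp)), collapse = " "),
      "), ", nrow(x$bonds), " bonds, Q = ", x$total_charge, " e\n", sep = "")
  invisible(x)
}

# Internal invariants: bond indices valid, no self bonds, no duplicate pairs,
# bonded atoms at strictly positive distance.
validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b) == 0L) return(invisible(mol))
  if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n)) {
    stop("bond refers to an atom index outside 1..", n)
  }
  if (any(b$i == b$j)) stop("self-bond (i == j) not allowed")
  if (!all(b$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  xyz <- as.matrix(mol$atoms[c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
  if (any(d <= 0)) stop("bonded atoms at zero distance")
  invisible(mol)
}

#' Atom coordinates as a matrix
#'
#' @param mol An `eem_molecule`.
#' @return An n x 3 numeric matrix of coordinates in angstrom.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[c("x", "y", "z")])
}

#' Number of atoms in a molecule
#' @param mol An `eem_molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Pairwise interatomic distance matrix (angstrom); errors on clashes
# (< 0.5 angstrom), which make the EEM electrostatic term meaningless.
distance_matrix <- function(mol, clash_tol = 0.5) {
  d <- as.matrix(stats::dist(coords(mol)))
  off <- d[upper.tri(d)]
  if (length(off) > 0L && any(off < clash_tol)) {
    stop("atomic clash: interatomic distance below ", clash_tol,
         " angstrom in molecule '", mol$id, "'")
  }
  d
}
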