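# Pauling-scale electronegativities (Allred's revision) for the harmonic
# molecular electronegativity used as the calibration target.
.eemr_pauling <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58,
                   Ca = 1.00)

#' Pauling electronegativity table
#'
#' Electronegativities on the Pauling scale (Allred's revised values) for
#' the supported elements, used by [harmonic_electronegativity()].
#'
#' @return Named numeric vector (element -> electronegativity).
#' @export
pauling_electronegativities <- function() .eemr_pauling

#' Assemble the EEM linear system
#'
#' Electronegativity equalization states that every atom's effective
#' electronegativity chi_i = A_i + B_i q_i + k sum_{j != i} q_j / R_ij
#' equals the common molecular value chi_bar, and that the charges sum to
#' the total molecular charge Q. Written for the unknown vector
#' (q_1, ..., q_n, chi_bar), this is an (n+1) x (n+1) linear system: row i
#' has diagonal B_i, off-diagonal k / R_ij, -1 in the last column and
#' right-hand side -A_i; the last row has ones over the charge unknowns,
#' zero in the chi_bar column, and right-hand side Q.
#'
#' @param mol An [eem_molecule()] (bonds required only for scheme `"EX"`).
#' @param params An [eem_params()] covering every atom type present.
#' @param Q Total molecular charge in e; defaults to the molecule's
#'   `total_charge`.
#' @return A list with `matrix` ((n+1) x (n+1)) and `rhs` (length n+1).
#' @export
assemble_system <- function(mol, params, Q = mol$total_charge) {
  types <- assign_atom_types(mol, params$scheme)
  ab <- params_for_types(params, types)
  n <- n_atoms(mol)
  d <- distance_matrix(mol) # errors on clash < 0.5 angstrom
  m <- matrix(0, n + 1L, n + 1L)
  if (n > 1L) {
    m[seq_len(n), seq_len(n)] <- params$k / d
  }
  m[cbind(seq_len(n), seq_len(n))] <- ab$B
  m[seq_len(n), n + 1L] <- -1
  m[n + 1L, seq_len(n)] <- 1
  list(matrix = m, rhs = c(-ab$A, Q))
}

#' Solve EEM charges for one molecule
#'
#' Solves the assembled equalization system by a dense direct method
#' (LAPACK LU factorization, i.e. Gaussian elimination with partial
#' pivoting) for the per-atom charges and the equalized molecular
#' electronegativity chi_bar. The solution is checked a posteriori: the
#' maximum residual must be below `1e-8 * max(1, |Q|)` and the charges must
#' sum to Q within 1e-8.
#'
#' @inheritParams assemble_system
#' @param condition_warn Condition-number estimate above which a warning is
#'   issued (the solve still proceeds unless the matrix is numerically
#'   singular).
#' @return An object of class `eem_charges`: list with `molecule_id`,
#'   `charges` (per-atom, e), and `chi_bar`.
#' @export
solve_charges <- function(mol, params, Q = mol$total_charge,
                          condition_warn = 1e10) {
  sys <- assemble_system(mol, params, Q)
  kap <- kappa(sys$matrix, exact = FALSE)
  if (is.finite(kap) && kap > condition_warn) {
    warning("ill-conditioned EEM system for '", mol$id,
            "': condition estimate ", format(kap, digits = 3))
  }
  sol <- tryCatch(solve(sys$matrix, sys$rhs), error = function(e) {
    stop("singular EEM system for molecule '", mol$id,
         "' (condition estimate ", format(kap, digits = 3), "): ",
         conditionMessage(e))
  })
  n <- n_atoms(mol)
  q <- sol[seq_len(n)]
  chi_bar <- sol[n + 1L]
  resid <- max(abs(sys$matrix %*% sol - sys$rhs))
  if (resid >= 1e-8 * max(1, abs(Q))) {
    stop("EEM solve residual ", format(resid), " exceeds tolerance for '",
         mol$id, "'")
  }
  if (abs(sum(q) - Q) >= 1e-8) {
    stop("charge conservation violated: sum(q) - Q = ",
         format(sum(q) - Q), " for '", mol$id, "'")
  }
  structure(list(molecule_id = mol$id, charges = q, chi_bar = chi_bar),
            class = "eem_charges")
}

#' @export
print.eem_charges <- function(x, ...) {
  cat("EEM charges for '", x$molecule_id, "': ", length(x$charges),
      " atoms, sum(q) = ", format(sum(x$charges)),
      " e, chi_bar = ", format(x$chi_bar), "\n", sep = "")
  invisible(x)
}

#' Per-atom effective electronegativities
#'
#' Evaluates chi_i = A_i + B_i q_i + k sum_{j != i} q_j / R_ij for a given
#' charge vector. For charges produced by [solve_charges()] all values
#' equal chi_bar to within the solver tolerance (the equalization
#' principle); for any other charge vector they generally differ.
#'
#' @inheritParams assemble_system
#' @param charges Numeric per-atom charge vector (e).
#' @return Numeric vector of per-atom effective electronegativities.
#' @export
effective_electronegativity <- function(mol, params, charges) {
  n <- n_atoms(mol)
  if (length(charges) != n) stop("charge vector length mismatch")
  types <- assign_atom_types(mol, params$scheme)
  ab <- params_for_types(params, types)
  d <- distance_matrix(mol)
  coulomb <- if (n > 1L) {
    inv <- 1 / d
    diag(inv) <- 0
    as.numeric(inv %*% charges)
  } else {
    0
  }
  ab$A + ab$B * charges + params$k * coulomb
}

#' Harmonic-average molecular electronegativity
#'
#' Approximates the molecular electronegativity as the harmonic mean of the
#' Pauling electronegativities of all constituent atoms (hydrogens
#' included): n / sum_i (1 / chi_i). This is the calibration target paired
#' with each reference molecule.
#'
#' @param mol An [eem_molecule()].
#' @param table Named element -> electronegativity vector; defaults to the
#'   packaged Pauling-scale table.
#' @return The harmonic mean electronegativity (scalar).
#' @export
harmonic_electronegativity <- function(mol,
                                       table = pauling_electronegativities()) {
  chi <- table[mol$atoms$element]
  if (anyNA(chi)) {
    stop("no tabulated electronegativity for element(s): ",
         paste(unique(mol$atoms$element[is.na(chi)]), collapse = ", "))
  }
  if (any(chi <= 0)) stop("non-positive electronegativity in table")
  length(chi) / sum(1 / chi)
}
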