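# Fixed ground-truth parameter set used as the default forward model:
# an 'E'-scheme table over the six supported elements, with A in [2, 6]
# (effective electronegativities) and B in [4, 10] (effective hardness
# doubled), and k* = 0.4.
.eemr_default_true_params <- function() {
  eem_params("E", k = 0.4, table = data.frame(
    type = c("H", "C", "N", "O", "S", "Ca"),
    A = c(2.5, 3.0, 3.8, 4.4, 3.2, 2.2),
    B = c(9.0, 6.5, 7.5, 8.5, 5.0, 4.5)
  ))
}

#' Specification for synthetic reference fixtures
#'
#' Describes a collection of random molecules with per-atom charges drawn
#' from a known EEM forward model, emulating the role of quantum-chemical
#' reference sets (multi-fragment collections of C/H/N/O/S/Ca atoms with
#' 3D coordinates and per-atom charges) so that calibration, validation
#' and profiling can be exercised with a recoverable ground truth.
#'
#' @param n_molecules Number of molecules to generate.
#' @param atoms_per_molecule Integer range `c(min, max)` of atoms per
#'   molecule.
#' @param element_frequencies Named sampling weights per element; the
#'   default follows the elemental proportions typical of protein
#'   fragments (H and C dominant, traces of S and Ca).
#' @param true_params Ground-truth [eem_params()] of the forward model.
#' @param noise_sigma Standard deviation (e) of i.i.d. Gaussian noise added
#'   to the forward charges, modelling reference-method discrepancy.
#' @param seed Integer seed; all generation is reproducible from it.
#' @param box_size Cubic box edge (angstrom) for coordinate sampling.
#' @param min_dist Minimum interatomic distance enforced by rejection
#'   sampling (angstrom).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 20L,
                         atoms_per_molecule = c(25L, 35L),
                         element_frequencies = c(H = 0.45, C = 0.29,
                                                 N = 0.11, O = 0.12,
                                                 S = 0.02, Ca = 0.01),
                         true_params = .eemr_default_true_params(),
                         noise_sigma = 0,
                         seed = 1L,
                         box_size = 12,
                         min_dist = 1.0) {
  stopifnot(n_molecules >= 1L,
            length(atoms_per_molecule) == 2L,
            atoms_per_molecule[1L] >= 1L,
            atoms_per_molecule[1L] <= atoms_per_molecule[2L],
            all(element_frequencies >= 0), sum(element_frequencies) > 0,
            noise_sigma >= 0, box_size > 0, min_dist >= 1.0)
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_per_molecule = as.integer(atoms_per_molecule),
                 element_frequencies = element_frequencies,
                 true_params = true_params,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 box_size = box_size,
                 min_dist = min_dist),
            class = "fixture_spec")
}

# Rejection-sample n points in a cube with a minimum pairwise distance.
sample_coords <- function(n, box, min_dist, max_tries = 2000L) {
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3L, 0, box)
      if (i == 1L ||
          min(sqrt(rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE],
                                 2L, p)^2))) >= min_dist) {
        xyz[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " atoms at minimum distance ", min_dist,
           " in a box of ", box, " angstrom; increase box_size")
    }
  }
  xyz
}

#' Generate synthetic molecules
#'
#' Draws molecules per a [fixture_spec()]: atom counts uniform in the
#' configured range, elements sampled by frequency, coordinates uniform in
#' a cubic box with minimum-distance rejection, and a simple atom chain of
#' bonds with randomized orders (1 or 2) so both typing schemes have
#' coverage. The first two molecules contain at least one atom of every
#' element in the ground-truth table, guaranteeing every type at least two
#' molecules of coverage. Atoms are grouped into 5-atom `SYN` residues for
#' residue-level bookkeeping. Fully reproducible from the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return A list of [eem_molecule()]s.
#' @export
make_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  elements <- names(spec$element_frequencies)[spec$element_frequencies > 0]
  truth_elements <- unique(sub("[0-9]+$", "", spec$true_params$table$type))
  mols <- vector("list", spec$n_molecules)
  for (m in seq_len(spec$n_molecules)) {
    lo <- spec$atoms_per_molecule[1L]
    hi <- spec$atoms_per_molecule[2L]
    n <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (m <= 2L) n <- max(n, length(truth_elements))
    el <- sample(elements, n, replace = TRUE,
                 prob = spec$element_frequencies[elements])
    if (m <= 2L) el[seq_along(truth_elements)] <- truth_elements
    xyz <- sample_coords(n, spec$box_size, spec$min_dist)
    atoms <- data.frame(
      element = el,
      name = paste0(toupper(el), seq_len(n)),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      resno = (seq_len(n) - 1L) %/% 5L + 1L,
      icode = "", resname = "SYN", chain = "A",
      formal_charge = 0L, stringsAsFactors = FALSE
    )
    bonds <- if (n > 1L) {
      data.frame(i = seq_len(n - 1L), j = seq.int(2L, n),
                 order = sample(1:2, n - 1L, replace = TRUE))
    } else {
      NULL
    }
    mols[[m]] <- eem_molecule(sprintf("syn%03d", m), atoms, bonds,
                              total_charge = 0)
  }
  mols
}

#' Forward-generate reference records from a known EEM model
#'
#' Uses the EEM model itself as the generative process so calibration has
#' a recoverable ground truth: for each molecule a total charge Q is drawn
#' from \{-1, 0, +1\}, charges are solved under `true_params`, and i.i.d.
#' Gaussian noise of standard deviation `noise_sigma` is added. With
#' `noise_sigma = 0` the records are exactly model-consistent. The
#' recorded electronegativity target is the solved equalized value by
#' default (`chi_bar = "solved"`, exact ground truth); choose
#' `chi_bar = "harmonic"` to emulate the harmonic-mean approximation used
#' with real reference data, which introduces a per-molecule offset.
#'
#' @param mols List of [eem_molecule()]s.
#' @param true_params Ground-truth [eem_params()].
#' @param noise_sigma Gaussian noise standard deviation (e).
#' @param seed Integer seed.
#' @param chi_bar `"solved"` or `"harmonic"`.
#' @return A list of [reference_record()]s; each record's molecule carries
#'   its drawn Q as `total_charge`.
#' @export
forward_reference <- function(mols, true_params = .eemr_default_true_params(),
                              noise_sigma = 0, seed = 1L,
                              chi_bar = c("solved", "harmonic")) {
  chi_bar <- match.arg(chi_bar)
  set.seed(seed)
  lapply(mols, function(mol) {
    Q <- sample(c(-1, 0, 1), 1L)
    mol$total_charge <- Q
    cs <- tryCatch(solve_charges(mol, true_params, Q = Q),
                   error = function(e) {
                     stop("forward solve failed for '", mol$id, "': ",
                          conditionMessage(e))
                   })
    ref <- cs$charges +
      if (noise_sigma > 0) stats::rnorm(length(cs$charges), 0, noise_sigma)
      else 0
    target <- if (chi_bar == "solved") cs$chi_bar
              else harmonic_electronegativity(mol)
    reference_record(mol, ref, chi_bar_ref = target)
  })
}

#' Generate a segment-release conformer pair
#'
#' Constructs a conformer pair emulating an activation-type conformational
#' change in which a peripheral segment detaches from the protein core
#' (the motif of large-scale rearrangements such as helix or C-domain
#' release upon activation). The base molecule is a random core cluster
#' plus one probe residue offset from the core surface; the active
#' conformer displaces the probe residue outward by `displacement`
#' angstrom. Because the probe starts coupled to the whole core rather
#' than to one near neighbour, decoupling it exchanges net charge with the
#' entire remainder, so the probe residue carries the largest per-residue
#' net charge transfer by construction -- a recoverable ground truth for
#' the profiling pipeline. The probe is homo-elemental (`probe_element`)
#' so its electronegativity contrast with the mixed core drives a coherent
#' net transfer.
#'
#' @param seed Integer seed.
#' @param probe_element Element of the probe residue's atoms.
#' @param probe_atoms Number of atoms in the probe residue.
#' @param core_atoms Number of atoms in the core cluster.
#' @param box_size Core cluster box edge (angstrom).
#' @param offset Initial gap between core surface and probe (angstrom).
#' @param displacement Outward displacement of the probe residue in the
#'   active conformer (angstrom).
#' @return A list with `a` (base), `b` (released conformer) and
#'   `probe_resno` (the perturbed residue number).
#' @export
make_release_pair <- function(seed, probe_element = "O", probe_atoms = 5L,
                              core_atoms = 25L, box_size = 11,
                              offset = 5, displacement = 10) {
  set.seed(seed)
  core_xyz <- sample_coords(core_atoms, box_size, 1.0)
  core_el <- sample(c("H", "C", "N", "O"), core_atoms, replace = TRUE,
                    prob = c(0.45, 0.30, 0.12, 0.13))
  probe_xyz <- sweep(sample_coords(probe_atoms, 2.5, 1.0), 2L,
                     c(box_size / 2, box_size / 2, box_size + offset), `+`)
  el <- c(core_el, rep(probe_element, probe_atoms))
  n <- core_atoms + probe_atoms
  probe_resno <- (core_atoms - 1L) %/% 5L + 2L
  base <- eem_molecule(sprintf("rel%03d", seed), data.frame(
    element = el, name = paste0(toupper(el), seq_len(n)),
    x = c(core_xyz[, 1L], probe_xyz[, 1L]),
    y = c(core_xyz[, 2L], probe_xyz[, 2L]),
    z = c(core_xyz[, 3L], probe_xyz[, 3L]),
    resno = c((seq_len(core_atoms) - 1L) %/% 5L + 1L,
              rep(probe_resno, probe_atoms)),
    icode = "", resname = "SYN", chain = "A",
    formal_charge = 0L, stringsAsFactors = FALSE
  ), total_charge = 0)
  pair <- make_conformer_pair(base, probe_resno,
                              displacement = displacement, seed = seed)
  pair$probe_resno <- probe_resno
  pair
}

#' Generate a perturbed conformer pair
#'
#' Builds a stand-in for an inactive/active conformation pair: conformer B
#' is the base molecule with the atoms of the listed residues rigidly
#' displaced by `displacement` angstrom, each residue along the outward
#' direction from the centroid of the remaining atoms (emulating a segment
#' swinging away from the core upon activation; the weakened electrostatic
#' environment shifts the moved residue's charges coherently, so the
#' constructed charge transfer concentrates on the perturbed residues by
#' design). If a displacement clashes, seeded random directions are tried
#' instead. Atom sets, names and ordering are identical between the pair,
#' so residue pairing is total.
#'
#' @param base An [eem_molecule()].
#' @param perturbed_residues Integer residue numbers to displace.
#' @param displacement Displacement magnitude (angstrom).
#' @param seed Integer seed.
#' @param max_tries Resampling attempts if a displacement causes a clash.
#' @return A list with elements `a` (base) and `b` (perturbed conformer).
#' @export
make_conformer_pair <- function(base, perturbed_residues, displacement = 1.5,
                                seed = 1L, max_tries = 50L) {
  missing_res <- setdiff(perturbed_residues, base$atoms$resno)
  if (length(missing_res) > 0L) {
    stop("residue(s) not in base molecule: ",
         paste(missing_res, collapse = ", "))
  }
  set.seed(seed)
  for (t in seq_len(max_tries)) {
    b <- base
    b$id <- paste0(base$id, "_active")
    for (res in perturbed_residues) {
      idx <- which(b$atoms$resno == res)
      u <- if (t == 1L && length(idx) < n_atoms(b)) {
        colMeans(coords(b)[idx, , drop = FALSE]) -
          colMeans(coords(b)[-idx, , drop = FALSE])
      } else {
        stats::rnorm(3L)
      }
      if (sqrt(sum(u^2)) < 1e-9) u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      b$atoms[idx, c("x", "y", "z")] <-
        b$atoms[idx, c("x", "y", "z")] +
        matrix(displacement * u, length(idx), 3L, byrow = TRUE)
    }
    ok <- tryCatch({ distance_matrix(b); TRUE },
                   error = function(e) FALSE)
    if (ok) return(list(a = base, b = b))
  }
  stop("could not displace residues without clashes after ", max_tries,
       " attempts; reduce displacement")
}
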