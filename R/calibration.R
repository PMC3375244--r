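#' Reference calibration record
#'
#' One calibration observation group: a molecule together with its
#' per-atom reference charges (e.g. quantum-chemical Mulliken charges) and
#' the molecular electronegativity used as the equalization target for that
#' molecule. When not supplied, the target defaults to the harmonic average
#' of the atoms' Pauling electronegativities, the convention used when the
#' true equalized value is unknown.
#'
#' @param mol An [eem_molecule()].
#' @param ref_charges Numeric per-atom reference charges (e).
#' @param chi_bar_ref Molecular electronegativity target (> 0); default
#'   [harmonic_electronegativity()].
#' @return An object of class `eem_reference`.
#' @export
reference_record <- function(mol, ref_charges,
                             chi_bar_ref = harmonic_electronegativity(mol)) {
  if (length(ref_charges) != n_atoms(mol)) {
    stop("reference charge count does not match atom count for '",
         mol$id, "'")
  }
  if (!is.finite(chi_bar_ref) || chi_bar_ref <= 0) {
    stop("chi_bar_ref must be positive and finite")
  }
  structure(list(molecule = mol, ref_charges = as.numeric(ref_charges),
                 chi_bar_ref = chi_bar_ref),
            class = "eem_reference")
}

#' Regression rows for EEM calibration
#'
#' Rearranges the per-atom equalization equation into a line in (A, B):
#' for atom i, `y_i = chi_bar_ref - k * sum_{j != i} q_j / R_ij` and
#' `x_i = q_i`, so that `y = A + B x` within each atom type. Rows are
#' grouped by atom type under the requested scheme; reference charges and
#' actual interatomic distances supply the known quantities.
#'
#' @param records List of [reference_record()]s.
#' @param scheme Atom typing scheme, `"E"` or `"EX"`.
#' @param k Electrostatic adjusting factor.
#' @return Named list (one element per atom type) of data.frames with
#'   columns `x`, `y`, `mol_id`.
#' @export
build_regression_rows <- function(records, scheme = c("E", "EX"), k) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (rec in records) {
    mol <- rec$molecule
    q <- rec$ref_charges
    n <- n_atoms(mol)
    types <- assign_atom_types(mol, scheme)
    coulomb <- if (n > 1L) {
      inv <- 1 / distance_matrix(mol)
      diag(inv) <- 0
      as.numeric(inv %*% q)
    } else {
      0
    }
    y <- rec$chi_bar_ref - k * coulomb
    df <- data.frame(x = q, y = y, mol_id = mol$id,
                     stringsAsFactors = FALSE)
    for (ty in unique(types)) {
      rows[[ty]] <- rbind(rows[[ty]], df[types == ty, , drop = FALSE])
    }
  }
  rows
}

#' Least-squares fit of (A, B) per atom type
#'
#' Ordinary least squares of `y = A + B x` within each atom type. The
#' full design matrix is block-diagonal across types (each row involves
#' only its own type's parameters), so the per-type fits jointly minimize
#' the global residual sum of squares.
#'
#' @param rows Grouped regression rows from [build_regression_rows()].
#' @return A data.frame with columns `type`, `A`, `B`, `n` (row count).
#' @export
fit_parameters <- function(rows) {
  out <- lapply(names(rows), function(ty) {
    df <- rows[[ty]]
    if (nrow(df) < 2L) {
      stop("atom type '", ty, "' has fewer than 2 observations")
    }
    if (max(df$x) - min(df$x) <= 0) {
      stop("atom type '", ty, "' has zero variance in reference charges")
    }
    fit <- stats::lm.fit(cbind(1, df$x), df$y)
    data.frame(type = ty, A = fit$coefficients[[1L]],
               B = fit$coefficients[[2L]], n = nrow(df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Agreement statistics between two charge vectors
#'
#' Scores one molecule's computed charges against its reference charges:
#' squared Pearson correlation `r2`, root mean square deviation `rmsd`,
#' and mean absolute difference `d` (both in e). R^2 is invariant to any
#' affine transformation -- identical, shifted and even sign-flipped charge
#' sets all score R^2 = 1 -- which is why the two deviation statistics are
#' always reported alongside it. For degenerate (constant) vectors R^2 is
#' 1 when the vectors are numerically identical and `NA` otherwise.
#'
#' @param charges Computed per-atom charges (e).
#' @param ref_charges Reference per-atom charges (e), same length.
#' @return Named numeric vector `c(r2, rmsd, d)`.
#' @export
charge_agreement <- function(charges, ref_charges) {
  stopifnot(length(charges) == length(ref_charges))
  diff <- charges - ref_charges
  degenerate <- length(charges) < 2L ||
    stats::sd(charges) == 0 || stats::sd(ref_charges) == 0
  r2 <- if (degenerate) {
    if (all(abs(diff) < 1e-12)) 1 else NA_real_
  } else {
    stats::cor(charges, ref_charges)^2
  }
  c(r2 = r2, rmsd = sqrt(mean(diff^2)), d = mean(abs(diff)))
}

#' Validate an EEM parameter set against reference charges
#'
#' Solves EEM charges for every record (with Q equal to the sum of that
#' molecule's reference charges, so charge conservation never penalizes
#' the comparison) and scores agreement per molecule by the squared
#' Pearson correlation R^2, the root mean square deviation, and the mean
#' absolute difference, then averages over molecules. R^2 is blind to sign
#' and scale, which is why the two deviation statistics accompany it.
#'
#' @param params An [eem_params()].
#' @param records List of [reference_record()]s.
#' @return An object of class `eem_validation`: list with `R_avg`,
#'   `RMSD_avg`, `D_avg` and a `per_molecule` data.frame.
#' @export
eem_validate <- function(params, records) {
  per <- lapply(records, function(rec) {
    mol <- rec$molecule
    Q <- sum(rec$ref_charges)
    cs <- tryCatch(solve_charges(mol, params, Q = Q), error = identity)
    if (inherits(cs, "error")) {
      warning("EEM solve failed for '", mol$id, "': ",
              conditionMessage(cs), "; excluded from statistics")
      return(data.frame(id = mol$id, r2 = NA_real_, rmsd = NA_real_,
                        d = NA_real_, n = n_atoms(mol),
                        stringsAsFactors = FALSE))
    }
    stats <- charge_agreement(cs$charges, rec$ref_charges)
    data.frame(id = mol$id, r2 = stats[["r2"]],
               rmsd = stats[["rmsd"]], d = stats[["d"]],
               n = n_atoms(mol), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(R_avg = mean(per$r2, na.rm = TRUE),
                 RMSD_avg = mean(per$rmsd, na.rm = TRUE),
                 D_avg = mean(per$d, na.rm = TRUE),
                 per_molecule = per),
            class = "eem_validation")
}

#' @export
print.eem_validation <- function(x, ...) {
  cat("EEM validation over ", nrow(x$per_molecule), " molecules:\n",
      "  R_avg    = ", format(x$R_avg, digits = 6), "\n",
      "  RMSD_avg = ", format(x$RMSD_avg, digits = 6), " e\n",
      "  D_avg    = ", format(x$D_avg, digits = 6), " e\n", sep = "")
  invisible(x)
}

#' Calibrate an EEM model
#'
#' Fits an EEM parameter set to reference charges. For each candidate k in
#' the grid, the per-atom equalization equations are rearranged into lines
#' in (A, B), grouped by atom type, and fitted by ordinary least squares;
#' the fitted model is then scored by internal validation (re-solving the
#' EEM charges of the training molecules and averaging per-molecule R^2).
#' The returned model uses the k with the best internal R_avg (ties go to
#' the smallest k).
#'
#' @param records List of [reference_record()]s.
#' @param scheme Atom typing scheme, `"E"` or `"EX"`.
#' @param k_grid Positive candidate values for the electrostatic adjusting
#'   factor. The default spans 0.05 to 1.50 in steps of 0.05.
#' @param min_obs_warn Warn for any atom type with fewer observations than
#'   this (the hard minimum is 2).
#'
#' @return An object of class `eem_fit` with components `params`
#'   ([eem_params()]), `k_grid`, `k_scores` (internal R_avg per k),
#'   `internal` ([eem_validate()] result at the selected k),
#'   `type_counts`, and `call`. Supports `print`, `summary`, `coef`,
#'   `predict` and `plot`.
#'
#' @examples
#' spec <- fixture_spec(n_molecules = 6, atoms_per_molecule = c(6, 10),
#'                      seed = 7)
#' mols <- make_molecules(spec)
#' recs <- forward_reference(mols, spec$true_params, noise_sigma = 0,
#'                           seed = 7)
#' fit <- eem_calibrate(recs, scheme = "E", k_grid = c(0.2, 0.4, 0.6))
#' coef(fit)
#' @export
eem_calibrate <- function(records, scheme = c("E", "EX"),
                          k_grid = seq(0.05, 1.50, by = 0.05),
                          min_obs_warn = 30L) {
  scheme <- match.arg(scheme)
  if (length(records) == 0L) stop("no reference records supplied")
  if (length(k_grid) == 0L || any(!is.finite(k_grid)) || any(k_grid <= 0)) {
    stop("k_grid must be a non-empty vector of positive values")
  }
  k_grid <- sort(unique(k_grid))
  scores <- rep(NA_real_, length(k_grid))
  fits <- vector("list", length(k_grid))
  failures <- character(0)
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    res <- tryCatch({
      rows <- build_regression_rows(records, scheme, k)
      tab <- fit_parameters(rows)
      params <- eem_params(scheme, k, tab[c("type", "A", "B")])
      val <- eem_validate(params, records)
      list(params = params, val = val, counts = stats::setNames(tab$n, tab$type))
    }, error = identity)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("k=", format(k), ": ",
                                     conditionMessage(res)))
      next
    }
    fits[[i]] <- res
    scores[i] <- res$val$R_avg
  }
  if (all(is.na(scores))) {
    stop("calibration failed for every k in the grid:\n  ",
         paste(failures, collapse = "\n  "))
  }
  best <- which(scores == max(scores, na.rm = TRUE))[1L] # grid sorted: tie -> smallest k
  chosen <- fits[[best]]
  low <- chosen$counts[chosen$counts < min_obs_warn]
  if (length(low) > 0L) {
    warning("fewer than ", min_obs_warn, " observations for type(s): ",
            paste(sprintf("%s (%d)", names(low), low), collapse = ", "))
  }
  structure(list(params = chosen$params,
                 k_grid = k_grid,
                 k_scores = stats::setNames(scores, format(k_grid)),
                 internal = chosen$val,
                 type_counts = chosen$counts,
                 n_molecules = length(records),
                 call = match.call()),
            class = "eem_fit")
}

#' @export
print.eem_fit <- function(x, ...) {
  cat("EEM model fit (scheme '", x$params$scheme, "')\n", sep = "")
  cat("  molecules: ", x$n_molecules,
      ", atom types: ", nrow(x$params$table), "\n", sep = "")
  cat("  selected k = ", format(x$params$k),
      " (internal R_avg = ", format(x$internal$R_avg, digits = 6),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.eem_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.eem_fit")
}

#' @export
print.summary.eem_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nParameters:\n")
  tab <- fit$params$table
  tab$n_obs <- as.integer(fit$type_counts[tab$type])
  print(tab, row.names = FALSE)
  cat("\nInternal validation:\n")
  print(fit$internal)
  cat("\nk grid (internal R_avg):\n")
  print(round(fit$k_scores, 6))
  invisible(x)
}

#' @export
coef.eem_fit <- function(object, ...) {
  tab <- object$params$table
  m <- as.matrix(tab[c("A", "B")])
  rownames(m) <- tab$type
  m
}

#' Predict EEM charges with a calibrated model
#'
#' @param object An `eem_fit` from [eem_calibrate()].
#' @param mol An [eem_molecule()].
#' @param Q Total molecular charge (e); defaults to the molecule's.
#' @param ... Unused.
#' @return An `eem_charges` object (see [solve_charges()]).
#' @export
predict.eem_fit <- function(object, mol, Q = mol$total_charge, ...) {
  solve_charges(mol, object$params, Q = Q)
}

#' @export
plot.eem_fit <- function(x, ...) {
  graphics::plot(x$k_grid, x$k_scores, type = "b", pch = 16,
                 xlab = "k (electrostatic adjusting factor)",
                 ylab = expression(R[avg] ~ "(internal)"), ...)
  graphics::abline(v = x$params$k, lty = 2)
  invisible(x)
}
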