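#' Pair residues between two conformations
#'
#' Matches residues of two structures of the same protein on
#' (chain, residue number, insertion code); a residue-name mismatch at a
#' matched position is an error. Within each paired residue, atoms are
#' matched by name; atoms present in only one structure are reported, not
#' dropped silently. Chains listed in `exclude_chains` (e.g. a bound
#' activator peptide present in only one structure) are removed before
#' pairing.
#'
#' @param mol_a,mol_b The two [eem_molecule()]s (conventionally inactive
#'   and active conformations).
#' @param exclude_chains Character vector of chain identifiers to exclude.
#' @return A data.frame with one row per paired residue: `chain`, `resno`,
#'   `icode`, `resname`, `n_common`, `n_only_a`, `n_only_b`, plus
#'   list-columns `idx_a`, `idx_b` (full residue atom indices) and
#'   `common_a`, `common_b` (name-matched atom indices, aligned).
#' @export
pair_residues <- function(mol_a, mol_b, exclude_chains = character(0)) {
  split_res <- function(mol) {
    a <- mol$atoms
    keep <- !(a$chain %in% exclude_chains)
    idx <- which(keep)
    key <- paste(a$chain[idx], a$resno[idx], a$icode[idx], sep = "\r")
    split(idx, key)
  }
  ra <- split_res(mol_a)
  rb <- split_res(mol_b)
  common_keys <- intersect(names(ra), names(rb))
  if (length(common_keys) == 0L) stop("no residues in common")
  out <- lapply(common_keys, function(key) {
    ia <- ra[[key]]; ib <- rb[[key]]
    na_ <- mol_a$atoms[ia, , drop = FALSE]
    nb_ <- mol_b$atoms[ib, , drop = FALSE]
    if (na_$resname[1L] != nb_$resname[1L]) {
      stop("residue name conflict at chain ", na_$chain[1L], " ",
           na_$resno[1L], na_$icode[1L], ": '", na_$resname[1L],
           "' vs '", nb_$resname[1L], "'")
    }
    if (anyDuplicated(na_$name) || anyDuplicated(nb_$name)) {
      stop("duplicate atom names within residue ", na_$chain[1L], " ",
           na_$resno[1L])
    }
    m <- match(na_$name, nb_$name)
    matched <- which(!is.na(m))
    data.frame(chain = na_$chain[1L], resno = na_$resno[1L],
               icode = na_$icode[1L], resname = na_$resname[1L],
               n_common = length(matched),
               n_only_a = length(ia) - length(matched),
               n_only_b = length(ib) - length(matched),
               idx_a = I(list(ia)), idx_b = I(list(ib)),
               common_a = I(list(ia[matched])),
               common_b = I(list(ib[m[matched]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue net charge transfer
#'
#' For each paired residue, the net charge difference between the two
#' conformations: `delta_q = |sum_b q - sum_a q|`, each sum running over
#' the structure's FULL residue atom set, with `direction` the sign of the
#' underlying signed difference (+1 when the residue becomes more positive
#' in structure b). This measures charge transferred to or from the
#' residue as a unit. Set `mode = "sum_abs"` for the alternative reading,
#' the sum of per-atom absolute differences over name-matched atoms.
#'
#' @param pairing Residue pairing from [pair_residues()].
#' @param charges_a,charges_b `eem_charges` (or bare numeric vectors) for
#'   the two structures, in atom order.
#' @param mode `"net"` (default) or `"sum_abs"`.
#' @return A data.frame with `chain`, `resno`, `icode`, `resname`,
#'   `delta_q` (>= 0), `direction` (-1, 0, +1).
#' @export
delta_q_res <- function(pairing, charges_a, charges_b, mode = c("net", "sum_abs")) {
  mode <- match.arg(mode)
  qa <- if (inherits(charges_a, "eem_charges")) charges_a$charges else charges_a
  qb <- if (inherits(charges_b, "eem_charges")) charges_b$charges else charges_b
  signed <- vapply(seq_len(nrow(pairing)), function(r) {
    sum(qb[pairing$idx_b[[r]]]) - sum(qa[pairing$idx_a[[r]]])
  }, numeric(1))
  delta <- if (mode == "net") {
    abs(signed)
  } else {
    vapply(seq_len(nrow(pairing)), function(r) {
      sum(abs(qb[pairing$common_b[[r]]] - qa[pairing$common_a[[r]]]))
    }, numeric(1))
  }
  data.frame(pairing[c("chain", "resno", "icode", "resname")],
             delta_q = delta, direction = sign(signed),
             stringsAsFactors = FALSE)
}

#' Per-residue charge redistribution (RMSD)
#'
#' Root mean square per-atom charge difference within each residue,
#' computed over name-matched atoms:
#' `sqrt(mean((q_b - q_a)^2))`. This captures intra-residue charge
#' redistribution even when the residue's net charge is unchanged.
#' Residues with zero common atoms are excluded with a warning.
#'
#' @inheritParams delta_q_res
#' @return A data.frame with `chain`, `resno`, `icode`, `resname`,
#'   `rmsd_q` (>= 0), `n_common`.
#' @export
rmsd_res <- function(pairing, charges_a, charges_b) {
  qa <- if (inherits(charges_a, "eem_charges")) charges_a$charges else charges_a
  qb <- if (inherits(charges_b, "eem_charges")) charges_b$charges else charges_b
  empty <- pairing$n_common == 0L
  if (any(empty)) {
    warning(sum(empty), " residue(s) with no name-matched atoms excluded ",
            "from RMSD")
    pairing <- pairing[!empty, , drop = FALSE]
  }
  rmsd <- vapply(seq_len(nrow(pairing)), function(r) {
    dq <- qb[pairing$common_b[[r]]] - qa[pairing$common_a[[r]]]
    sqrt(mean(dq^2))
  }, numeric(1))
  data.frame(pairing[c("chain", "resno", "icode", "resname")],
             rmsd_q = rmsd, n_common = pairing$n_common,
             stringsAsFactors = FALSE)
}

#' Flag residues with outstanding charge changes
#'
#' A residue is flagged when its statistic exceeds the mean plus one
#' standard deviation of that statistic over all scored residues
#' (population standard deviation; strict inequality, so a degenerate
#' all-equal distribution yields no flags). Applied independently to the
#' net transfer `delta_q` and the redistribution `rmsd_q`.
#'
#' @param deltas A data.frame containing `delta_q` and/or `rmsd_q` columns
#'   (as produced by [profile_report()] internals).
#' @return The input with logical columns `sig_dq` / `sig_rmsd` added, and
#'   attributes `thresholds` (named list of mean, sd, threshold per
#'   statistic).
#' @export
flag_significant <- function(deltas) {
  if (nrow(deltas) < 2L) stop("need at least 2 residues to flag")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  thresholds <- list()
  if (!is.null(deltas$delta_q)) {
    m <- mean(deltas$delta_q); s <- pop_sd(deltas$delta_q)
    deltas$sig_dq <- deltas$delta_q > m + s
    thresholds$delta_q <- c(mean = m, sd = s, threshold = m + s)
  }
  if (!is.null(deltas$rmsd_q)) {
    m <- mean(deltas$rmsd_q); s <- pop_sd(deltas$rmsd_q)
    deltas$sig_rmsd <- deltas$rmsd_q > m + s
    thresholds$rmsd_q <- c(mean = m, sd = s, threshold = m + s)
  }
  attr(deltas, "thresholds") <- thresholds
  deltas
}

#' Per-residue charge-transfer profile between two conformations
#'
#' Full comparison pipeline for two conformations of the same protein:
#' solve EEM charges for both structures, pair residues, compute the net
#' per-residue charge transfer and the intra-residue charge RMSD, and flag
#' residues one standard deviation above average on either statistic.
#' Chains in `exclude_chains` are excluded from pairing and from the
#' flagging statistics but remain in the charge solve of their structure
#' (a bound peptide still polarizes the protein).
#'
#' @param mol_a,mol_b [eem_molecule()]s for the two conformations (a =
#'   reference/inactive, b = active).
#' @param params An [eem_params()] or `eem_fit`.
#' @param Q_a,Q_b Total molecular charges; default to each molecule's
#'   `total_charge`.
#' @param exclude_chains Chains excluded from pairing (not from solving).
#' @param delta_mode Net-transfer convention, see [delta_q_res()].
#' @return An object of class `eem_profile`: a data.frame with one row per
#'   paired residue (`chain`, `resno`, `icode`, `resname`, `delta_q`,
#'   `direction`, `rmsd_q`, `n_common`, `sig_dq`, `sig_rmsd`) with
#'   attributes `thresholds`, `Q` and `chi_bar` used, and `unpaired` atom
#'   counts.
#' @export
profile_report <- function(mol_a, mol_b, params,
                           Q_a = mol_a$total_charge,
                           Q_b = mol_b$total_charge,
                           exclude_chains = character(0),
                           delta_mode = c("net", "sum_abs")) {
  if (inherits(params, "eem_fit")) params <- params$params
  delta_mode <- match.arg(delta_mode)
  require_hydrogens(mol_a)
  require_hydrogens(mol_b)
  ca <- solve_charges(mol_a, params, Q = Q_a)
  cb <- solve_charges(mol_b, params, Q = Q_b)
  pairing <- pair_residues(mol_a, mol_b, exclude_chains)
  dq <- delta_q_res(pairing, ca, cb, mode = delta_mode)
  rq <- rmsd_res(pairing, ca, cb)
  key <- function(d) paste(d$chain, d$resno, d$icode, sep = "\r")
  tab <- dq
  tab$rmsd_q <- rq$rmsd_q[match(key(dq), key(rq))]
  tab$n_common <- rq$n_common[match(key(dq), key(rq))]
  tab <- flag_significant(tab)
  structure(tab,
            class = c("eem_profile", "data.frame"),
            thresholds = attr(tab, "thresholds"),
            Q = c(a = Q_a, b = Q_b),
            chi_bar = c(a = ca$chi_bar, b = cb$chi_bar),
            delta_mode = delta_mode,
            n_unmatched = c(only_a = sum(pairing$n_only_a),
                            only_b = sum(pairing$n_only_b)))
}

#' @export
print.eem_profile <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Per-residue charge-transfer profile: ", nrow(x), " residues\n",
      sep = "")
  cat(sprintf("  delta_q: mean %.6f, sd %.6f, threshold %.6f e\n",
              th$delta_q[["mean"]], th$delta_q[["sd"]],
              th$delta_q[["threshold"]]))
  cat(sprintf("  rmsd_q : mean %.6f, sd %.6f, threshold %.6f e\n",
              th$rmsd_q[["mean"]], th$rmsd_q[["sd"]],
              th$rmsd_q[["threshold"]]))
  flagged <- x[x$sig_dq | x$sig_rmsd, , drop = FALSE]
  flagged <- flagged[order(-flagged$delta_q), , drop = FALSE]
  if (nrow(flagged) == 0L) {
    cat("  no residues flagged\n")
  } else {
    cat("  flagged residues (descending delta_q):\n")
    print.data.frame(flagged, row.names = FALSE)
  }
  invisible(x)
}

#' Write a charge-transfer profile to disk
#'
#' Writes the per-residue table as TSV (6-decimal charges) and a JSON
#' summary carrying the flagging thresholds, the total charges and solved
#' molecular electronegativities, and the net-transfer convention used.
#'
#' @param profile An `eem_profile` from [profile_report()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the profile.
#' @export
write_profile <- function(profile, tsv_path, json_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- as.data.frame(profile)
    out$delta_q <- sprintf("%.6f", out$delta_q)
    out$rmsd_q <- sprintf("%.6f", out$rmsd_q)
    names(out) <- c("chain", "resnum", "icode", "resname", "delta_q",
                    "direction", "rmsd_q", "n_common", "sig_dq",
                    "sig_rmsd")
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    th <- attr(profile, "thresholds")
    summary <- list(
      n_residues = nrow(profile),
      delta_mode = attr(profile, "delta_mode"),
      thresholds = lapply(th, as.list),
      Q = as.list(attr(profile, "Q")),
      chi_bar = as.list(attr(profile, "chi_bar")),
      flagged_delta_q = profile$resno[profile$sig_dq],
      flagged_rmsd_q = profile$resno[profile$sig_rmsd]
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(profile)
}

# Charge calculation on protein structures requires explicit hydrogens:
# the reference models are all-atom, and a heavy-atom-only solve would be
# meaningless. No hydrogen addition is attempted.
require_hydrogens <- function(mol) {
  has_aa <- any(is_amino_acid(mol$atoms$resname))
  if (has_aa && !any(mol$atoms$element == "H")) {
    stop("structure '", mol$id, "' contains amino-acid residues but no ",
         "hydrogens; EEM charges require an all-atom structure. Add ",
         "hydrogens with a structure-preparation tool before computing ",
         "charges.")
  }
  invisible(mol)
}
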