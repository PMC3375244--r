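#' Read / write per-atom charge tables
#'
#' Tabular carrier for reference (e.g. quantum-chemical Mulliken) or
#' computed per-atom charges. The on-disk format is TSV with header
#' `mol_id  atom_index  atom_name  charge`, where `atom_index` is 0-based
#' and matches file atom order, and charges are printed with at least six
#' decimals. No charge-sum check is performed at the I/O layer.
#'
#' @param path Path to a charge TSV file.
#' @return A data.frame with columns `mol_id`, `atom_index` (0-based),
#'   `atom_name`, `charge`.
#' @export
read_charge_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "numeric"))
  expected <- c("mol_id", "atom_index", "atom_name", "charge")
  if (!identical(names(tab), expected)) {
    stop("charge table '", path, "' must have header: ",
         paste(expected, collapse = "\t"))
  }
  dup <- tab[duplicated(tab[c("mol_id", "atom_index")]), , drop = FALSE]
  if (nrow(dup) > 0L) {
    stop("duplicate atom_index in charge table '", path, "': ",
         paste(unique(dup$atom_index), collapse = ", "))
  }
  tab
}

#' @rdname read_charge_table
#' @param table A charge table data.frame as returned by
#'   [read_charge_table()] or built by [charge_table()].
#' @param digits Decimal places for charges (>= 6).
#' @export
write_charge_table <- function(table, path, digits = 9L) {
  stopifnot(digits >= 6L)
  out <- table
  out$charge <- sprintf(paste0("%.", digits, "f"), table$charge)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a charge table for a molecule
#'
#' @param mol An [eem_molecule()].
#' @param charges Numeric vector of per-atom charges (e), in atom order.
#' @return A charge table data.frame (0-based `atom_index`).
#' @export
charge_table <- function(mol, charges) {
  if (length(charges) != n_atoms(mol)) {
    stop("charge count (", length(charges), ") does not match atom count (",
         n_atoms(mol), ") of molecule '", mol$id, "'")
  }
  data.frame(mol_id = mol$id,
             atom_index = seq_len(n_atoms(mol)) - 1L,
             atom_name = mol$atoms$name,
             charge = as.numeric(charges),
             stringsAsFactors = FALSE)
}

# Extract the charge vector of a table in molecule atom order, validating
# the count against the molecule when one is attached.
charges_from_table <- function(table, mol = NULL) {
  tab <- table[order(table$atom_index), , drop = FALSE]
  if (!is.null(mol) && nrow(tab) != n_atoms(mol)) {
    stop("charge table has ", nrow(tab), " entries but molecule '",
         mol$id, "' has ", n_atoms(mol), " atoms")
  }
  tab$charge
}
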