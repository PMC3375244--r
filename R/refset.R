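#' Write a reference set directory
#'
#' A reference set on disk is a directory of paired files `<id>.pdb` and
#' `<id>.charges.tsv` plus a `manifest.tsv` listing molecule ids, total
#' charges and the per-molecule electronegativity targets (the manifest
#' preserves a forward model's exact target; without it the reader falls
#' back to the harmonic-mean approximation).
#'
#' @param records List of [reference_record()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_refset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in records) {
    mol <- rec$molecule
    write_pdb(mol, file.path(dir, paste0(mol$id, ".pdb")))
    write_charge_table(charge_table(mol, rec$ref_charges),
                       file.path(dir, paste0(mol$id, ".charges.tsv")))
  }
  manifest <- data.frame(
    id = vapply(records, function(r) r$molecule$id, character(1)),
    total_charge = vapply(records, function(r)
      sum(r$ref_charges), numeric(1)),
    chi_bar = vapply(records, function(r) r$chi_bar_ref, numeric(1))
  )
  manifest$total_charge <- sprintf("%.9f", manifest$total_charge)
  manifest$chi_bar <- sprintf("%.9f", manifest$chi_bar)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference set directory
#'
#' Reads the manifest, each molecule's PDB file (perceiving bonds so both
#' typing schemes are available) and its reference charge table. The
#' electronegativity target comes from the manifest's `chi_bar` column
#' when present, otherwise from [harmonic_electronegativity()].
#'
#' @param dir Reference set directory (see [write_refset()]).
#' @param quiet Suppress bond-perception warnings for residues without
#'   templates (synthetic fixtures).
#' @return A list of [reference_record()]s.
#' @export
read_refset <- function(dir, quiet = TRUE) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("reference set manifest not found: ", manifest_path)
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (is.null(manifest$id)) stop("manifest lacks an 'id' column")
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    pdb_path <- file.path(dir, paste0(id, ".pdb"))
    tsv_path <- file.path(dir, paste0(id, ".charges.tsv"))
    if (!file.exists(pdb_path) || !file.exists(tsv_path)) {
      stop("reference set entry '", id, "' is missing its .pdb or ",
           ".charges.tsv file")
    }
    Q <- if (!is.null(manifest$total_charge)) manifest$total_charge[i]
         else NULL
    mol <- read_pdb(pdb_path, total_charge = Q)
    mol$id <- id
    mol$bonds <- if (quiet) suppressWarnings(perceive_bonds(mol))
                 else perceive_bonds(mol)
    ref <- charges_from_table(read_charge_table(tsv_path), mol)
    chi <- if (!is.null(manifest$chi_bar) && is.finite(manifest$chi_bar[i])) {
      manifest$chi_bar[i]
    } else {
      harmonic_electronegativity(mol)
    }
    reference_record(mol, ref, chi_bar_ref = chi)
  })
}
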