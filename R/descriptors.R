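#' Assemble a property-based descriptor matrix
#'
#' Builds one of the four property-based feature spaces from a
#' reaction-record table:
#' \describe{
#'   \item{I}{net charge, atom count, molecular weight, cavity volume,
#'     plus the eight reactant frontier-orbital energies (12 features).}
#'   \item{II}{the eight reactant orbital energies alone (HOMO-1, HOMO,
#'     LUMO, LUMO+1 for spin-up and spin-down).}
#'   \item{III}{the spin-up HOMO alone -- the spin-up channel lies above
#'     spin-down for the open-shell oxidation reactants, so it is the
#'     physically meaningful single-orbital feature.}
#'   \item{IV}{the eight *product* orbital energies (the product-side
#'     analogue of II).}
#' }
#' Feature order is fixed and identical between calls, guarding
#' against training/serving skew. Atom counts include hydrogens.
#'
#' @param records A tibble of reaction records (see
#'   [load_reaction_table()]).
#' @param kind `"I"`, `"II"`, `"III"`, or `"IV"`.
#' @return A tibble of numeric features, rows aligned with `records`.
#' @export
assemble_property_descriptor <- function(records, kind = c("I", "II", "III", "IV")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(records))
  records <- as_tibble(records)
  cols <- switch(kind,
    I = c("net_charge", "n_atoms", "molecular_weight", "cavity_volume",
          .orbital_cols()),
    II = .orbital_cols(),
    III = "homo_up",
    IV = .orbital_cols("product_")
  )
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    abort(paste0("descriptor ", kind, " needs field(s) missing from the records: ",
                 paste(missing, collapse = ", ")))
  }
  out <- records[cols]
  bad <- names(out)[!purrr::map_lgl(out, is.numeric)]
  if (length(bad)) {
    abort(paste0("descriptor ", kind, ": non-numeric field(s) ",
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Assemble the structure-based (FP) descriptor matrix
#'
#' Fingerprints every record's SMILES via [compute_fingerprint()] and
#' appends the net charge: 1025 features per sample.
#'
#' @param records A tibble with `smiles` and `net_charge`.
#' @param bits,radius,chiral Passed to [compute_fingerprint()].
#' @return A tibble of 0/1 bit columns plus `net_charge`.
#' @export
assemble_fp_descriptor <- function(records, bits = 1024L, radius = 3L,
                                   chiral = TRUE) {
  stopifnot(is.data.frame(records))
  for (nm in c("smiles", "net_charge")) {
    if (!nm %in% names(records)) {
      abort(paste0("descriptor FP needs field missing from the records: ", nm))
    }
  }
  compute_fingerprint(records$smiles, records$net_charge, bits = bits,
                      radius = radius, chiral = chiral)
}

#' Featurize records with any of the five descriptors
#'
#' Dispatches to [assemble_property_descriptor()] for kinds I-IV and
#' [assemble_fp_descriptor()] for `"FP"`.
#'
#' @param records A tibble of reaction records.
#' @param kind One of `"I"`, `"II"`, `"III"`, `"IV"`, `"FP"`.
#' @param ... Passed to the FP assembler.
#' @return A tibble of features, rows aligned with `records`.
#' @export
featurize_records <- function(records, kind = c("I", "II", "III", "IV", "FP"),
                              ...) {
  kind <- match.arg(kind)
  if (kind == "FP") assemble_fp_descriptor(records, ...)
  else assemble_property_descriptor(records, kind)
}
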