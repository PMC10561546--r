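# Bridge to RDKit through the system python. No R cheminformatics
# toolkit is assumed; SMILES work is delegated to a bundled helper
# script and exchanged as temporary CSV files, one batched call per
# request.

.python_binary <- function() {
  py <- getOption("squarescheme.python", Sys.which("python"))
  if (!nzchar(py)) {
    abort(paste0("No `python` found on PATH (needed for RDKit-based SMILES ",
                 "operations). Set options(squarescheme.python = ...) to the ",
                 "interpreter of an environment providing rdkit."))
  }
  py
}

.rdkit_call <- function(mode, smiles, extra_args = character()) {
  script <- system.file("python", "rdkit_tools.py", package = "squarescheme")
  if (!nzchar(script)) abort("bundled rdkit_tools.py not found; reinstall the package")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  readr::write_csv(tibble(smiles = smiles), fin, progress = FALSE)
  status <- system2(.python_binary(), c(script, mode, fin, fout, extra_args),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    abort(sprintf("rdkit helper failed (mode %s, status %s)", mode, status))
  }
  readr::read_csv(fout, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Canonicalize SMILES strings
#'
#' Isomeric canonical SMILES via RDKit (chirality retained). Unparsable
#' inputs yield `NA` with a warning; use the `details` attribute-free
#' tabular form [canonicalize_smiles_table()] to inspect failures.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where unparsable).
#' @export
canonicalize_smiles <- function(smiles) {
  tab <- canonicalize_smiles_table(smiles)
  bad <- sum(!tab$ok)
  if (bad > 0) {
    warn(sprintf("%d SMILES string(s) could not be parsed; returned as NA", bad))
  }
  ifelse(tab$ok, tab$canonical, NA_character_)
}

#' @rdname canonicalize_smiles
#' @return For the tabular form, a tibble with `smiles`, `ok`,
#'   `canonical`, `error`.
#' @export
canonicalize_smiles_table <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(tibble(smiles = character(), ok = logical(),
                  canonical = character(), error = character()))
  }
  res <- .rdkit_call("canon", smiles)
  tibble(smiles = smiles, ok = res$ok == "1",
         canonical = res$canonical, error = res$error)
}

#' Extended-connectivity fingerprint descriptor (FP)
#'
#' Hashed circular (Morgan/ECFP-style) fingerprints of radius 3 over
#' 1024 bits, chirality-aware, with the sample's net charge appended as
#' the final feature: 1025 dimensions in total. Bits are 0/1; the
#' charge entry is the integer net charge. Deterministic for identical
#' canonical structures, so two SMILES spellings of one molecule give
#' identical rows.
#'
#' @param smiles Character vector of SMILES strings.
#' @param net_charge Integer vector of net charges (recycled if scalar).
#' @param bits Fingerprint length before the charge entry (default 1024).
#' @param radius Circular-environment radius (default 3).
#' @param chiral Include chirality in the atom environments (default TRUE).
#' @return A tibble with `bits` fingerprint columns (`fp_0001`, ...)
#'   and a final `net_charge` column; one row per input.
#' @examples
#' \donttest{
#' compute_fingerprint("O=C1C=CC(=O)C=C1", 0)[, 1:6]
#' }
#' @export
compute_fingerprint <- function(smiles, net_charge, bits = 1024L, radius = 3L,
                                chiral = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  net_charge <- rep_len(as.integer(net_charge), length(smiles))
  res <- .rdkit_call("fp", smiles,
                     c(as.integer(bits), as.integer(radius),
                       if (isTRUE(chiral)) "1" else "0"))
  if (any(res$ok != "1")) {
    bad <- which(res$ok != "1")
    abort(paste0("unparsable SMILES at position(s) ",
                 paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
                 ": ", res$error[bad[1L]]))
  }
  mat <- matrix(0L, nrow = length(smiles), ncol = bits)
  for (i in seq_along(smiles)) {
    mat[i, ] <- as.integer(strsplit(res$bits[i], "", fixed = TRUE)[[1L]])
  }
  colnames(mat) <- sprintf("fp_%04d", seq_len(bits))
  out <- as_tibble(mat)
  out$net_charge <- net_charge
  out
}

#' Fingerprint collision check across bit lengths
#'
#' Counts how many *distinct* molecules share a fingerprint bit-vector
#' at a given length: the number of distinct canonical structures minus
#' the number of distinct fingerprints. Zero means the bit length is
#' sufficient to give every molecule a unique vector.
#'
#' @param smiles_list Character vector of SMILES (duplicates and
#'   unparsable entries are dropped after canonicalization).
#' @param bit_length Fingerprint length to test.
#' @param radius,chiral Passed to [compute_fingerprint()].
#' @return Integer collision count.
#' @export
check_fingerprint_uniqueness <- function(smiles_list, bit_length = 1024L,
                                         radius = 3L, chiral = TRUE) {
  stopifnot(is.character(smiles_list), length(smiles_list) >= 1L)
  tab <- canonicalize_smiles_table(smiles_list)
  mols <- unique(tab$canonical[tab$ok])
  if (length(mols) == 0L) return(0L)
  fp <- compute_fingerprint(mols, 0L, bits = bit_length, radius = radius,
                            chiral = chiral)
  keys <- apply(as.matrix(fp[, seq_len(bit_length)]), 1L, paste, collapse = "")
  length(mols) - length(unique(keys))
}
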