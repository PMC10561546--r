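#' The nine-state lattice of a two-proton two-electron square scheme
#'
#' A molecule QH2 releasing up to two electrons and two protons visits
#' nine protonation/charge states arranged on a 3x3 lattice: columns
#' count electrons removed (0-2), rows protons removed (0-2). States
#' are indexed `3 * protons_removed + electrons_removed`, so 0 is the
#' fully reduced, fully protonated QH2 and 8 the fully oxidized Q.
#'
#' @return A tibble with one row per state: `index`, `label`,
#'   `electrons_removed`, `protons_removed`, `net_charge`
#'   (= electrons_removed - protons_removed).
#' @examples
#' state_lattice()
#' @export
state_lattice <- function() {
  p <- rep(0:2, each = 3L)
  e <- rep(0:2, times = 3L)
  tibble(
    index = 3L * p + e,
    label = c("QH2", "QH2+", "QH2^2+",
              "QH-", "QH", "QH+",
              "Q^2-", "Q-", "Q"),
    electrons_removed = e,
    protons_removed = p,
    net_charge = e - p
  )
}

# label -> index lookup, tolerant of a few common spellings
.state_label_index <- function(labels) {
  lat <- state_lattice()
  norm <- function(x) {
    x <- gsub("\\s+", "", x)
    x <- gsub("\\^", "", x)
    toupper(x)
  }
  lat$index[match(norm(labels), norm(lat$label))]
}

#' Validate and normalize a species-state table
#'
#' Takes a data frame describing the (possibly partial) set of states
#' of one molecule and returns it joined with the canonical lattice.
#' States may be identified by `index` (0-8) or by `label`; free
#' energies are aqueous Gibbs free energies in Hartree.
#'
#' @param data A data frame with column `g_aq_hartree` and either
#'   `index` or `label`. Optional columns (`smiles`, orbital energies,
#'   `molecular_weight`, `cavity_volume`, `n_atoms`) are carried along.
#' @param k A [thermo_constants()] object used for the single
#'   Hartree-to-kJ/mol conversion performed at ingestion.
#'
#' @return A tibble with the lattice columns, `g_aq_hartree`, and
#'   `g_aq_kj` (kJ/mol), one row per distinct state.
#' @export
species_states <- function(data, k = thermo_constants()) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of species states.")
  data <- as_tibble(data)
  if (!"g_aq_hartree" %in% names(data)) {
    abort("`data` must have a `g_aq_hartree` column (aqueous Gibbs free energy, Hartree).")
  }
  if ("index" %in% names(data)) {
    idx <- as.integer(data$index)
  } else if ("label" %in% names(data)) {
    idx <- .state_label_index(data$label)
    if (anyNA(idx)) {
      bad <- unique(data$label[is.na(idx)])
      abort(paste0("Unknown state label(s): ", paste(bad, collapse = ", "),
                   ". Valid labels: ", paste(state_lattice()$label, collapse = ", ")))
    }
  } else {
    abort("`data` must identify states by `index` (0-8) or `label`.")
  }
  if (any(!is.finite(idx)) || any(idx < 0L | idx > 8L)) {
    abort("State `index` must be an integer in 0..8.")
  }
  if (anyDuplicated(idx)) abort("Duplicate state indices in `data`.")

  lat <- state_lattice()
  keep <- data[setdiff(names(data), c("index", "label", names(lat)))]
  out <- dplyr::bind_cols(lat[match(idx, lat$index), ], keep)
  out$g_aq_kj <- hartree_to_kj(out$g_aq_hartree, k)
  dplyr::arrange(out, .data$index)
}
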