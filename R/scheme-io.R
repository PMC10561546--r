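#' Read a free-energy table
#'
#' Reads the CSV input of the scheme builder: one row per species
#' state with columns `molecule_id`, `state_label` (or `index`), and
#' `g_aq_hartree`; optional `smiles` and `net_charge` columns are
#' carried along. Several molecules may share one file.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per (molecule, state).
#' @export
read_free_energy_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("free-energy table not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"molecule_id" %in% names(df)) df$molecule_id <- "molecule"
  if (!"g_aq_hartree" %in% names(df)) {
    abort("free-energy table must have a `g_aq_hartree` column")
  }
  if (!any(c("state_label", "label", "index") %in% names(df))) {
    abort("free-energy table must identify states via `state_label` or `index`")
  }
  if ("state_label" %in% names(df)) df <- dplyr::rename(df, label = "state_label")
  as_tibble(df)
}

#' Build one scheme per molecule from a free-energy table
#'
#' @param data A tibble as returned by [read_free_energy_table()].
#' @param refs A [reference_set()].
#' @param k A [thermo_constants()] object.
#' @return A named list of `square_scheme` objects, one per
#'   `molecule_id` in `data`.
#' @export
build_schemes <- function(data, refs, k = thermo_constants()) {
  stopifnot(is.data.frame(data))
  split(as_tibble(data), data$molecule_id) |>
    purrr::imap(function(df, id) {
      build_square_scheme(df[setdiff(names(df), "molecule_id")], refs, k,
                          molecule_id = id)
    })
}

# Serialize numbers at the database convention of three decimals.
.fmt3 <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = 3))
}

#' Write a scheme edge report
#'
#' One CSV row per derived edge with the database's three-decimal
#' serialization convention. Values are kept at full precision inside
#' the `square_scheme` object; rounding happens here only.
#'
#' @param scheme A `square_scheme`, or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheme_report <- function(scheme, path) {
  schemes <- if (inherits(scheme, "square_scheme")) list(scheme) else scheme
  stopifnot(all(purrr::map_lgl(schemes, inherits, "square_scheme")))
  rows <- purrr::map(schemes, function(s) {
    dplyr::mutate(s$edges, molecule_id = s$molecule_id, .before = 1L)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::transmute(
      molecule_id = .data$molecule_id,
      name = .data$name,
      kind = .data$kind,
      reactant = .data$reactant_label,
      product = .data$product_label,
      dg_kj_mol = .fmt3(.data$dg_kj_mol),
      observable = .fmt3(.data$observable),
      unit = .data$unit
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
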