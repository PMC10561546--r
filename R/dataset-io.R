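# Canonical reaction-table schema. The deposited CSVs' exact headers
# are not normative, so a user column mapping can adapt any dialect to
# these names.

.orbital_cols <- function(prefix = "") {
  paste0(prefix, c("homo_m1_up", "homo_up", "lumo_up", "lumo_p1_up",
                   "homo_m1_down", "homo_down", "lumo_down", "lumo_p1_down"))
}

#' Canonical reaction-record column names
#'
#' @return Character vector of the canonical schema: identification
#'   (`reaction_kind`, `reaction_name`, `smiles`, `net_charge`), bulk
#'   properties (`molecular_weight` in atomic units, `cavity_volume` in
#'   cubic Angstrom, `n_atoms`), eight reactant frontier-orbital
#'   energies and eight optional `product_`-prefixed ones (Hartree),
#'   and `target` (E_red or E0 in V vs SHE, or pKa).
#' @export
reaction_table_columns <- function() {
  c("reaction_kind", "reaction_name", "smiles", "net_charge",
    "molecular_weight", "cavity_volume", "n_atoms",
    .orbital_cols(), .orbital_cols("product_"), "target")
}

#' Load a reaction table
#'
#' Reads a CSV of reaction records for one reaction kind (ET, PT, or
#' PET), validating against the canonical schema. Rows failing
#' validation (missing/non-finite target, unusable net charge, empty
#' SMILES) are collected in an error report attached as the `"errors"`
#' attribute -- they are excluded from the records but never silently
#' dropped. Surviving rows keep their file order.
#'
#' @param path CSV file path.
#' @param kind `"ET"`, `"PT"`, or `"PET"`; stamped into
#'   `reaction_kind` and checked against the file's column if present.
#' @param col_map Optional named character vector mapping canonical
#'   names to the file's actual column names, e.g.
#'   `c(smiles = "SMILES", target = "E_red")`.
#' @param expected_count Optional expected record count; a mismatch is
#'   reported as a message, never an error.
#' @return A tibble of validated records (attribute `"errors"` holds
#'   the error report; see [validation_errors()]).
#' @export
load_reaction_table <- function(path, kind = c("ET", "PT", "PET"),
                                col_map = NULL, expected_count = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("reaction table not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    hit <- col_map[col_map %in% names(df)]
    names(df)[match(hit, names(df))] <- names(hit)
  }
  required <- c("smiles", "net_charge", "target")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("unmappable columns: required field(s) ",
                 paste(missing, collapse = ", "),
                 " not found; available candidates: ",
                 paste(names(df), collapse = ", "),
                 ". Supply `col_map` to adapt the dialect."))
  }
  df$reaction_kind <- kind
  keep <- intersect(reaction_table_columns(), names(df))
  df <- df[c(keep, setdiff(names(df), keep))]
  df <- as_tibble(df)
  df$.row <- seq_len(nrow(df))

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  reasons <- rep(NA_character_, nrow(df))
  tgt <- num_or_na(df$target)
  chg <- num_or_na(df$net_charge)
  bad_target <- !is.finite(tgt)
  bad_charge <- !is.finite(chg) | chg != round(chg)
  bad_smiles <- is.na(df$smiles) | !nzchar(trimws(as.character(df$smiles)))
  reasons[bad_smiles] <- "missing SMILES"
  reasons[bad_charge] <- "net_charge not an integer"
  reasons[bad_target] <- "missing or non-finite target"
  bad <- !is.na(reasons)

  errors <- tibble(row = df$.row[bad], reason = reasons[bad])
  records <- df[!bad, , drop = FALSE]
  records$target <- tgt[!bad]
  records$net_charge <- as.integer(chg[!bad])
  records$.row <- NULL
  if (!is.null(expected_count) && nrow(records) != expected_count) {
    inform(sprintf("loaded %d records; expected count was %d",
                   nrow(records), expected_count))
  }
  attr(records, "errors") <- errors
  attr(records, "kind") <- kind
  records
}

#' Error report of a loaded reaction table
#'
#' @param records A tibble returned by [load_reaction_table()] (or
#'   [deduplicate_records()]).
#' @return A tibble with `row` and `reason` for each rejected row.
#' @export
validation_errors <- function(records) {
  attr(records, "errors") %||%
    tibble(row = integer(), reason = character())
}

#' Deduplicate reaction records by canonical structure
#'
#' Molecules drawn differently (e.g. by rotational symmetry) collapse
#' to one canonical isomeric SMILES; records sharing
#' `(canonical SMILES, net charge)` are duplicates and only the first
#' occurrence is kept, preserving input order. Records whose SMILES
#' cannot be parsed are quarantined in the error report rather than
#' aborting the batch.
#'
#' @param records A tibble with `smiles` and `net_charge` columns.
#' @return A list with `records` (kept rows, original order, plus a
#'   `canonical_smiles` column), `removed` (count of duplicates
#'   dropped), and `errors` (unparsable rows).
#' @export
deduplicate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("smiles", "net_charge") %in% names(records))) {
    abort("`records` must have `smiles` and `net_charge` columns")
  }
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(list(records = records, removed = 0L,
                errors = tibble(row = integer(), reason = character())))
  }
  canon <- canonicalize_smiles_table(records$smiles)
  bad <- !canon$ok
  errors <- tibble(row = which(bad),
                   reason = paste0("unparsable SMILES: ", records$smiles[bad]))
  kept <- records[!bad, , drop = FALSE]
  kept$canonical_smiles <- canon$canonical[!bad]
  key <- paste(kept$canonical_smiles, kept$net_charge, sep = "|")
  first <- !duplicated(key)
  out <- kept[first, , drop = FALSE]
  attr(out, "errors") <- errors
  list(records = out, removed = sum(!first), errors = errors)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ dialect: an atom count, a comment line, then one
#' `element x y z` row per atom. Only metadata is extracted; no
#' geometry processing is done.
#'
#' @param path File path.
#' @return A tibble with `element`, `x`, `y`, `z` (Angstrom) and the
#'   comment line as attribute `"comment"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort(sprintf("XYZ file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !nzchar(trimws(lines[1L]))) {
    abort(sprintf("XYZ parse error at line 1 of %s: missing atom count", path))
  }
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L) {
    abort(sprintf("XYZ parse error at line 1 of %s: atom count not an integer", path))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- i + 2L
    if (ln > length(lines) || !nzchar(trimws(lines[ln]))) {
      abort(sprintf("XYZ parse error at line %d of %s: expected %d atom rows, found %d",
                    ln, path, n, i - 1L))
    }
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    coords <- suppressWarnings(as.numeric(parts[2:4]))
    if (length(parts) < 4L || any(!is.finite(coords))) {
      abort(sprintf("XYZ parse error at line %d of %s: expected `element x y z`",
                    ln, path))
    }
    rows[[i]] <- tibble(element = parts[1L], x = coords[1L],
                        y = coords[2L], z = coords[3L])
  }
  out <- if (n > 0L) dplyr::bind_rows(rows) else
    tibble(element = character(), x = double(), y = double(), z = double())
  attr(out, "comment") <- if (length(lines) >= 2L) lines[2L] else ""
  out
}

#' Write a reaction table
#'
#' Serializes records in the canonical column order with every numeric
#' field written to three decimals (the database convention). A
#' write/read round trip is lossless at that precision.
#'
#' @param records A tibble of reaction records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- as_tibble(records)
  keep <- intersect(reaction_table_columns(), names(records))
  out <- records[c(keep, setdiff(names(records), keep))]
  is_int_col <- function(nm) nm %in% c("net_charge", "n_atoms")
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- if (is_int_col(nm)) as.character(as.integer(out[[nm]]))
                   else .fmt3(out[[nm]])
    }
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Validate a loaded reaction-data deposit
#'
#' Checks a set of loaded tables against expected record counts and
#' target extrema (for example the published deposit's 49278
#' property-based samples, 49271 after structure deduplication, and
#' E_red extrema of -1.629 and 2.426 V). Purely diagnostic: returns a
#' check table, never errors on a mismatch.
#'
#' @param records A tibble of records (e.g. concatenated ET/PT tables).
#' @param expected_records Expected row count, or `NA` to skip.
#' @param expected_after_dedup Expected row count after
#'   [deduplicate_records()], or `NA` to skip.
#' @param target_range Expected `c(min, max)` of `target`, or `NULL`.
#' @param tol Tolerance for extrema comparison (default 5e-4, half of
#'   the three-decimal serialization step).
#' @return A tibble with `check`, `expected`, `actual`, `pass`.
#' @export
validate_compbatpet <- function(records, expected_records = NA,
                                expected_after_dedup = NA,
                                target_range = NULL, tol = 5e-4) {
  stopifnot(is.data.frame(records))
  rows <- list(tibble(check = "record count",
                      expected = as.numeric(expected_records),
                      actual = as.numeric(nrow(records)),
                      pass = is.na(expected_records) |
                        nrow(records) == expected_records))
  if (!is.na(expected_after_dedup)) {
    dd <- deduplicate_records(records)
    rows <- c(rows, list(tibble(check = "record count after SMILES dedup",
                                expected = as.numeric(expected_after_dedup),
                                actual = as.numeric(nrow(dd$records)),
                                pass = nrow(dd$records) == expected_after_dedup)))
  }
  if (!is.null(target_range)) {
    rows <- c(rows, list(
      tibble(check = c("target minimum", "target maximum"),
             expected = as.numeric(target_range),
             actual = range(records$target),
             pass = abs(range(records$target) - target_range) <= tol)))
  }
  dplyr::bind_rows(rows)
}
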