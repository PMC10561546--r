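test_that("reaction tables load, validate, and report bad rows", {
  recs <- make_reaction_records(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(recs, path)
  got <- load_reaction_table(path, "ET")
  expect_equal(nrow(got), 10L)
  expect_true(all(got$reaction_kind == "ET"))
  expect_equal(nrow(validation_errors(got)), 0L)

  # a missing target lands in the error report, not in the records
  recs2 <- recs
  recs2$target[3] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(recs2, path2)
  got2 <- load_reaction_table(path2, "ET")
  expect_equal(nrow(got2), 9L)
  err <- validation_errors(got2)
  expect_equal(err$row, 3L)
  expect_match(err$reason, "target")
  # surviving rows keep their order
  expect_equal(got2$smiles, recs$smiles[-3])

  # unmappable schema errors list the available candidates
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(structure = "C", charge = 0), path3)
  expect_error(load_reaction_table(path3, "ET"), "unmappable columns")
  expect_error(load_reaction_table(path3, "ET"), "structure")
  # ... and a column mapping resolves the dialect
  readr::write_csv(tibble::tibble(structure = "C", charge = 0, y = 1.5), path3)
  got3 <- load_reaction_table(path3, "PT",
                              col_map = c(smiles = "structure",
                                          net_charge = "charge", target = "y"))
  expect_equal(got3$smiles, "C")
  expect_message(load_reaction_table(path2, "ET", expected_count = 10L),
                 "expected count")
})

test_that("deduplication keys on canonical SMILES and net charge", {
  bq <- c("O=C1C=CC(=O)C=C1", "C1=CC(=O)C=CC1=O") # same molecule, two spellings
  recs <- tibble::tibble(smiles = c(bq, bq[1]), net_charge = c(0L, 0L, -1L),
                         target = c(1, 2, 3))
  dd <- deduplicate_records(recs)
  expect_equal(dd$removed, 1L)
  expect_equal(nrow(dd$records), 2L)
  # first occurrence kept, order stable, charge part of the key
  expect_equal(dd$records$target, c(1, 3))
  # idempotent
  dd2 <- deduplicate_records(dd$records)
  expect_equal(dd2$removed, 0L)
  # unparsable SMILES quarantined, not fatal
  recs3 <- tibble::tibble(smiles = c(bq[1], "not_a_smiles"),
                          net_charge = c(0L, 0L))
  dd3 <- deduplicate_records(recs3)
  expect_equal(nrow(dd3$records), 1L)
  expect_equal(dd3$errors$row, 2L)
  expect_match(dd3$errors$reason, "unparsable")
})

test_that("XYZ files parse with line-accurate errors", {
  h2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen dimer", "H 0.0 0.0 0.0", "H 0.0 0.0 0.74"), h2)
  atoms <- read_xyz(h2)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$element, c("H", "H"))
  expect_equal(attr(atoms, "comment"), "hydrogen dimer")

  blank <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(), blank)
  expect_error(read_xyz(blank), "line 1")

  short <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "truncated", "H 0 0 0", "H 0 0 0.74"), short)
  expect_error(read_xyz(short), "expected 3 atom rows, found 2")

  garbled <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "bad row", "H zero 0 0"), garbled)
  expect_error(read_xyz(garbled), "element x y z")
})

test_that("reaction tables round-trip losslessly at three decimals", {
  recs <- make_reaction_records(100, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(recs, path)
  back <- load_reaction_table(path, "ET")
  for (nm in c("molecular_weight", "cavity_volume", "target", "homo_up")) {
    expect_equal(back[[nm]], recs[[nm]], tolerance = 1e-12)
  }
  expect_equal(back$smiles, recs$smiles)
  # the rounding rule itself
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(tibble::tibble(smiles = "C", net_charge = 0L,
                                      target = 0.12345), path2)
  expect_match(paste(readLines(path2), collapse = "\n"), "0\\.123")
  # empty in, empty out
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(recs[0, ], path3)
  expect_equal(nrow(load_reaction_table(path3, "ET")), 0L)
})

test_that("deposit validation reports counts and extrema diagnostics", {
  recs <- make_reaction_records(20, seed = 3)
  chk <- validate_compbatpet(recs, expected_records = 20,
                             target_range = range(recs$target))
  expect_true(all(chk$pass))
  chk2 <- validate_compbatpet(recs, expected_records = 19,
                              target_range = range(recs$target) + 1)
  expect_false(chk2$pass[chk2$check == "record count"])
  expect_false(all(chk2$pass[grepl("target", chk2$check)]))
})
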