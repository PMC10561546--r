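test_that("state lattice encodes the nine-state bookkeeping", {
  lat <- state_lattice()
  expect_equal(nrow(lat), 9L)
  expect_equal(lat$index, 3L * lat$protons_removed + lat$electrons_removed)
  expect_equal(lat$net_charge, lat$electrons_removed - lat$protons_removed)
  expect_equal(lat$label[lat$index == 0], "QH2")
  expect_equal(lat$label[lat$index == 8], "Q")
  # labels uniquely determined by (electrons_removed, protons_removed)
  expect_false(anyDuplicated(lat$label) > 0)
})

test_that("species_states validates identification and units", {
  k <- thermo_constants()
  st <- species_states(data.frame(label = c("QH2", "Q"),
                                  g_aq_hartree = c(-500, -499)), k)
  expect_equal(st$index, c(0L, 8L))
  expect_equal(st$g_aq_kj, c(-500, -499) * k$hartree_to_kj_per_mol)
  expect_error(species_states(data.frame(label = "XYZ", g_aq_hartree = 1)),
               "Unknown state label")
  expect_error(species_states(data.frame(index = c(0, 0),
                                         g_aq_hartree = c(1, 2))),
               "Duplicate")
  expect_error(species_states(data.frame(index = 0)), "g_aq_hartree")
})

test_that("a full scheme yields exactly 6 ET + 6 PT + 4 PET edges", {
  gen <- generate_square_scheme(scheme_gen_config(seed = 1))
  counts <- table(gen$scheme$edges$kind)
  expect_equal(unname(counts[c("ET", "PT", "PET")]), c(6L, 6L, 4L),
               ignore_attr = TRUE)
  expect_setequal(
    gen$scheme$edges$name[gen$scheme$edges$kind == "PET"],
    c("PET04", "PET15", "PET37", "PET48"))
})

test_that("partial schemes derive what they can and omit the rest with a warning", {
  full <- generate_square_scheme(scheme_gen_config(seed = 5))$scheme
  refs <- full$references
  st <- full$states
  # states QH (4), Q- (7), Q (8): PET48 and PT47 present -> ET78 derivable
  with_47_8 <- build_square_scheme(st[st$index %in% c(4L, 7L, 8L), ], refs) |>
    suppressWarnings()
  expect_true(all(c("PET48", "PT47", "ET78") %in% with_47_8$edges$name))
  expect_equal(scheme_edge(with_47_8, "ET78"), scheme_edge(full, "ET78"))
  # drop state 7: the PT47 leg disappears and ET78 with it
  w <- testthat::capture_warnings(
    without_7 <- build_square_scheme(st[st$index %in% c(4L, 8L), ], refs))
  expect_true(any(grepl("ET78 omitted", w)))
  expect_false("ET78" %in% without_7$edges$name)
  expect_true("PET48" %in% without_7$edges$name)
  # nothing derivable at all is an error
  expect_error(suppressWarnings(
    build_square_scheme(st[st$index == 2L, ], refs)), "No reaction edge")
})

test_that("Hess closure holds for every decomposition Eq-7 pairs", {
  pairs <- list(c("PET04", "ET01", "PT14"), c("PET15", "ET12", "PT25"),
                c("PET37", "ET34", "PT47"), c("PET48", "ET45", "PT58"),
                c("PET37", "ET67", "PT36"), c("PET48", "ET78", "PT47"))
  for (seed in 1:10) {
    s <- generate_square_scheme(scheme_gen_config(seed = seed))$scheme
    dg <- setNames(s$edges$dg_kj_mol, s$edges$name)
    for (p in pairs) {
      expect_lt(abs(dg[[p[1]]] - dg[[p[2]]] - dg[[p[3]]]), 1e-9)
    }
  }
})

test_that("planted observables are recovered through the forward build", {
  for (seed in c(2, 17, 303)) {
    gen <- generate_square_scheme(scheme_gen_config(seed = seed))
    s <- gen$scheme
    for (nm in names(gen$planted$pka_scaled)) {
      expect_equal(scheme_edge(s, nm), gen$planted$pka_scaled[[nm]],
                   tolerance = 1e-9)
    }
    for (nm in names(gen$planted$e0)) {
      expect_equal(scheme_edge(s, nm), gen$planted$e0[[nm]],
                   tolerance = 1e-9)
    }
    for (nm in names(gen$planted$e_red)) {
      expect_equal(scheme_edge(s, nm), gen$planted$e_red[[nm]],
                   tolerance = 1e-6)
    }
  }
})

test_that("specific planted values land on the named edges", {
  s <- scheme_from_observables(
    c(PT03 = 4, PT14 = -2, PT25 = -6, PT36 = 11, PT47 = 2, PT58 = 2.0),
    e0_pet04 = 0.5, e0_pet48 = 0.30)
  expect_equal(scheme_edge(s, "PT58"), 2.0, tolerance = 1e-9)
  expect_equal(scheme_edge(s, "PET48"), 0.30, tolerance = 1e-9)
})

test_that("scheme reports serialize at three decimals and round-trip", {
  gen <- generate_square_scheme(scheme_gen_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scheme_report(gen$scheme, path)
  rep <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_equal(nrow(rep), nrow(gen$scheme$edges))
  # three-decimal convention: serialized strings match rounded values
  expect_equal(as.numeric(rep$observable),
               round(gen$scheme$edges$observable[
                 match(rep$name, gen$scheme$edges$name)], 3))
  expect_true(all(grepl("^-?\\d+\\.\\d{3}$", rep$dg_kj_mol)))
})

test_that("free-energy tables load and build per-molecule schemes", {
  fx <- system.file("extdata", "peaq_states_synthetic.csv",
                    package = "squarescheme")
  refs_file <- system.file("extdata", "references.json",
                           package = "squarescheme")
  refs_json <- jsonlite::read_json(refs_file, simplifyVector = TRUE)
  refs <- reference_set(g_h2_gas = refs_json$g_h2_gas,
                        ref_acid_g_ha = refs_json$ref_acid_g_ha,
                        ref_acid_g_a = refs_json$ref_acid_g_a,
                        pka_ref = refs_json$pka_ref)
  tab <- read_free_energy_table(fx)
  schemes <- build_schemes(tab, refs)
  expect_length(schemes, 1L)
  s <- schemes[[1L]]
  expect_equal(scheme_edge(s, "PET48"), -0.159, tolerance = 1e-6)
  expect_equal(scheme_edge(s, "PET04"), -0.352, tolerance = 1e-6)
  expect_equal(scheme_edge(s, "PT47"), 5, tolerance = 1e-6)
})
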