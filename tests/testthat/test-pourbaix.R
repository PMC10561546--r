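test_that("Nernst correction shifts potentials by -0.0592 (n_p/n_e) per pH", {
  k <- thermo_constants()
  expect_equal(nernst_potential(0.7, 2, 2, 0, k), 0.7)
  expect_equal(nernst_potential(0, 1, 1, 1, k) - nernst_potential(0, 1, 1, 0, k),
               -nernst_slope(k))
  # the published worked example: -0.048 V at pH 0 -> about -0.52 V at pH 8
  expect_equal(nernst_potential(-0.048, 2, 2, 8, k), -0.52, tolerance = 0.01)
  expect_error(nernst_potential(0, 1, 0, 7, k), "not an electrochemical step")
})

test_that("overall two-electron potential combines the two PET diagonals", {
  sym <- scheme_from_observables(
    c(PT03 = 6, PT14 = -2, PT25 = -7, PT36 = 12, PT47 = 4, PT58 = -4),
    e0_pet04 = 0.4, e0_pet48 = 0.4)
  expect_equal(overall_two_electron_potential(sym), 0.4)
  expect_equal(overall_two_electron_potential(sym, mode = "sum"), 0.8)
  asym <- scheme_from_observables(
    c(PT03 = 6, PT14 = -2, PT25 = -7, PT36 = 12, PT47 = 4, PT58 = -4),
    e0_pet04 = 0.2, e0_pet48 = 0.4)
  expect_equal(overall_two_electron_potential(asym), 0.3)
  # the printed pH-0 overall value arises as the dG-consistent mean
  printed <- scheme_from_observables(
    c(PT03 = 6, PT14 = -2, PT25 = -7, PT36 = 12, PT47 = 4, PT58 = -4),
    e0_pet04 = -0.159, e0_pet48 = 0.063)
  expect_equal(overall_two_electron_potential(printed), -0.048)
  partial <- suppressWarnings(build_square_scheme(
    sym$states[sym$states$index %in% c(0L, 4L), ], sym$references))
  expect_error(overall_two_electron_potential(partial), "PET48")
})

test_that("extreme corners of the (pH, E) plane are QH2 and Q", {
  for (seed in c(3, 14)) {
    s <- generate_square_scheme(scheme_gen_config(seed = seed))$scheme
    expect_equal(predominant_species(s, -5, -4), 0L)
    expect_equal(predominant_species(s, 20, 4), 8L)
  }
  partial <- example_peaq_scheme()
  partial$states <- partial$states[1:5, ]
  expect_error(predominant_species(partial, 7, 0), "incomplete scheme")
})

test_that("predominance agrees with an independent grand-potential oracle", {
  withr::with_seed(99, {
    for (seed in sample.int(10000, 8)) {
      s <- generate_square_scheme(scheme_gen_config(seed = seed))$scheme
      grid <- tidyr::expand_grid(ph = seq(0, 14, length.out = 60),
                                 e = seq(-1.5, 1.5, length.out = 60))
      got <- predominant_species(s, grid$ph, grid$e)
      want <- oracle_predominant(s, grid$ph, grid$e)
      expect_equal(got, want)
    }
  })
})

test_that("speciation is monotone along pH and potential", {
  lat <- state_lattice()
  for (seed in c(6, 28)) {
    s <- generate_square_scheme(scheme_gen_config(seed = seed))$scheme
    for (e in c(-1.2, -0.3, 0.4, 1.2)) {
      idx <- predominant_species(s, seq(0, 14, by = 0.1), e)
      expect_true(all(diff(lat$protons_removed[idx + 1L]) >= 0))
    }
    for (ph in c(0, 4.5, 9, 14)) {
      idx <- predominant_species(s, ph, seq(1.5, -1.5, by = -0.05))
      expect_true(all(diff(lat$electrons_removed[idx + 1L]) <= 0))
    }
  }
})

test_that("boundary lines obey the slope law and sit at the right places", {
  s <- example_peaq_scheme()
  pm <- pourbaix_boundaries(s)
  ns <- nernst_slope(thermo_constants())
  sloped <- pm$boundaries[pm$boundaries$type == "sloped", ]
  expect_gt(nrow(sloped), 0)
  expect_equal(sloped$slope, -ns * sloped$n_p / sloped$n_e, tolerance = 1e-6)
  vert <- pm$boundaries[pm$boundaries$type == "vertical", ]
  expect_setequal(round(vert$ph, 6), c(5, 8, 13))  # the pKa_scaled values
  # one-electron boundaries pass through E = E0 at pH 0
  qh2_qh <- sloped[sloped$label_a == "QH2" & sloped$label_b == "QH", ]
  expect_equal(qh2_qh$intercept, -0.352, tolerance = 1e-9)
  qh_q <- sloped[sloped$label_a == "QH" & sloped$label_b == "Q", ]
  expect_equal(qh_q$intercept, -0.159, tolerance = 1e-9)
  # grid labels equal predominant_species everywhere by construction
  expect_equal(pm$grid$state_index,
               predominant_species(s, pm$grid$ph, pm$grid$e))
  expect_error(pourbaix_boundaries(s, ph_window = c(3, 3)), "empty window")
})

test_that("every label transition on the grid is explained by a boundary", {
  s <- generate_square_scheme(scheme_gen_config(seed = 77))$scheme
  pm <- pourbaix_boundaries(s, resolution = 0.1)
  g <- pm$grid
  b <- pm$boundaries
  explained <- function(ph1, e1, i1, ph2, e2, i2) {
    cand <- b[(b$state_a == i1 & b$state_b == i2) |
                (b$state_a == i2 & b$state_b == i1), ]
    if (nrow(cand) == 0) return(FALSE)
    mid_ph <- (ph1 + ph2) / 2; mid_e <- (e1 + e2) / 2
    any(ifelse(cand$type == "vertical",
               abs(cand$ph - mid_ph) <= 0.1 + 1e-9 &
                 mid_e >= cand$e_min - 0.2 & mid_e <= cand$e_max + 0.2,
               abs(cand$intercept + cand$slope * mid_ph - mid_e) <= 0.2 &
                 mid_ph >= cand$ph_min - 0.2 & mid_ph <= cand$ph_max + 0.2))
  }
  wide <- tidyr::pivot_wider(g, names_from = "e", values_from = "state_index",
                             id_cols = "ph")
  mat <- as.matrix(wide[, -1])
  phs <- wide$ph
  es <- as.numeric(colnames(wide)[-1])
  bad <- 0L
  for (i in seq_len(nrow(mat))) {
    jj <- which(diff(mat[i, ]) != 0)
    for (j in jj) {
      if (!explained(phs[i], es[j], mat[i, j], phs[i], es[j + 1], mat[i, j + 1]))
        bad <- bad + 1L
    }
  }
  for (j in seq_len(ncol(mat))) {
    ii <- which(diff(mat[, j]) != 0)
    for (i in ii) {
      if (!explained(phs[i], es[j], mat[i, j], phs[i + 1], es[j], mat[i + 1, j]))
        bad <- bad + 1L
    }
  }
  expect_equal(bad, 0L)
})

test_that("boundary parameters are resolution-independent", {
  s <- example_peaq_scheme()
  key <- function(pm) {
    b <- pm$boundaries[order(pm$boundaries$state_a, pm$boundaries$state_b), ]
    b[c("state_a", "state_b", "slope", "intercept", "ph")]
  }
  expect_equal(key(pourbaix_boundaries(s, resolution = 0.05)),
               key(pourbaix_boundaries(s, resolution = 0.1)))
})

test_that("the worked example reproduces the published pathway bands", {
  s <- example_peaq_scheme()
  expect_equal(classify_reduction_pathway(s, 3), c("PET", "PET"))
  expect_equal(classify_reduction_pathway(s, 6.5), c("ET", "PET", "PT"))
  expect_equal(classify_reduction_pathway(s, 10), c("ET", "PET"))
  expect_equal(classify_reduction_pathway(s, 14), c("ET", "ET"))
  bands <- pathway_bands(s)
  expect_equal(bands$pathway,
               c("PET-PET", "ET-PET-PT", "ET-PET", "ET-ET"))
  expect_equal(bands$ph_min, c(0, 5, 8, 13), tolerance = 1e-9)
  expect_equal(bands$ph_max, c(5, 8, 13, 14), tolerance = 1e-9)
})

test_that("pathway bands partition any scheme's pH window", {
  for (seed in c(12, 44, 91)) {
    s <- generate_square_scheme(scheme_gen_config(seed = seed))$scheme
    bands <- pathway_bands(s, c(0, 14))
    expect_equal(bands$ph_min[1], 0)
    expect_equal(bands$ph_max[nrow(bands)], 14)
    if (nrow(bands) > 1) {
      expect_equal(bands$ph_min[-1], bands$ph_max[-nrow(bands)])
    }
  }
})

test_that("pathway classification errors name the missing edges", {
  full <- example_peaq_scheme()
  partial <- suppressWarnings(build_square_scheme(
    full$states[full$states$index %in% c(4L, 8L), ], full$references))
  expect_error(classify_reduction_pathway(partial, 7), "PT47")
})

test_that("autoplot renders a Pourbaix map", {
  pm <- pourbaix_boundaries(example_peaq_scheme(), resolution = 0.25)
  p <- autoplot(pm)
  expect_s3_class(p, "ggplot")
})
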