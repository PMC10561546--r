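#' Reference energies for the computational SHE and isodesmic pKa
#'
#' The square-scheme observables need two references: the gas-phase H2
#' free energy (half of it plays the role of the standard hydrogen
#' electrode for every H+ + e- pair released) and the aqueous proton
#' free energy. The proton is not computed directly; it is calibrated
#' from a reference acid of known experimental pKa (formic acid,
#' pKa = 3.77, by default) so that systematic solvation errors cancel.
#'
#' @param g_h2_gas Gas-phase Gibbs free energy of H2, Hartree.
#' @param ref_acid_g_ha,ref_acid_g_a Aqueous free energies of the
#'   reference acid HA and its conjugate base A-, Hartree. May be
#'   omitted when `g_proton_aq` is supplied directly.
#' @param pka_ref Experimental pKa of the reference acid (default 3.77,
#'   formic acid).
#' @param g_proton_aq Aqueous proton free energy, Hartree. If `NULL`
#'   (default) it is calibrated from the reference acid via
#'   [calibrate_proton_free_energy()].
#' @param k A [thermo_constants()] object.
#'
#' @return An object of class `reference_set`.
#' @examples
#' reference_set(g_h2_gas = -1.17, ref_acid_g_ha = -189.0,
#'               ref_acid_g_a = -188.5)
#' @export
reference_set <- function(g_h2_gas, ref_acid_g_ha = NULL, ref_acid_g_a = NULL,
                          pka_ref = 3.77, g_proton_aq = NULL,
                          k = thermo_constants()) {
  if (!is.numeric(g_h2_gas) || !is.finite(g_h2_gas)) {
    abort("`g_h2_gas` must be a finite number (Hartree).")
  }
  if (is.null(g_proton_aq)) {
    if (is.null(ref_acid_g_ha) || is.null(ref_acid_g_a)) {
      abort("Supply either `g_proton_aq` or both reference-acid energies.")
    }
    g_proton_aq <- calibrate_proton_free_energy(ref_acid_g_ha, ref_acid_g_a,
                                                pka_ref, k)
  }
  structure(
    list(g_h2_gas = g_h2_gas, g_proton_aq = g_proton_aq, pka_ref = pka_ref,
         ref_acid_g_ha = ref_acid_g_ha, ref_acid_g_a = ref_acid_g_a),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>\n")
  cat(sprintf("  G(H2, gas) = %.6f Ha, G(H+, aq) = %.6f Ha, pKa_ref = %.2f\n",
              x$g_h2_gas, x$g_proton_aq, x$pka_ref))
  invisible(x)
}

#' Calibrate the aqueous proton free energy from a reference acid
#'
#' Inverts the isodesmic pKa relation: given the free energies of a
#' reference acid HA and its conjugate base A- and the acid's
#' experimental pKa, returns the G(H+, aq) for which the computed pKa
#' of HA reproduces the experimental value exactly:
#' `G(H+) = RT ln10 * pKa_ref - G(A-) + G(HA)` (all in Hartree).
#'
#' @param ref_acid_g_ha,ref_acid_g_a Free energies of HA and A-, Hartree.
#' @param pka_ref Experimental reference pKa (default 3.77).
#' @param k A [thermo_constants()] object.
#' @return G(H+, aq) in Hartree.
#' @examples
#' k <- thermo_constants()
#' gh <- calibrate_proton_free_energy(-189, -188.5, 3.77, k)
#' # round trip recovers the reference pKa
#' ((-188.5 + gh - (-189)) * k$hartree_to_kj_per_mol) / rt_ln10(k)
#' @export
calibrate_proton_free_energy <- function(ref_acid_g_ha, ref_acid_g_a,
                                         pka_ref = 3.77,
                                         k = thermo_constants()) {
  vals <- c(ref_acid_g_ha, ref_acid_g_a, pka_ref)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals))) {
    abort("Reference-acid free energies and `pka_ref` must be finite numbers.")
  }
  rt_ln10(k) * pka_ref / k$hartree_to_kj_per_mol - ref_acid_g_a + ref_acid_g_ha
}

# Accept a one-row data frame or named list describing a species state.
.as_state <- function(x, arg = "state") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort(sprintf("`%s` must be a single state (one row).", arg))
    x <- as.list(x)
  }
  if (!is.list(x)) abort(sprintf("`%s` must be a one-row data frame or named list.", arg))
  need <- c("electrons_removed", "protons_removed", "g_aq_hartree")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("`%s` is missing field(s): %s", arg, paste(miss, collapse = ", ")))
  }
  x
}

#' Free-energy change of a proton-electron transfer (PET) step
#'
#' Energetics of a concerted `red -> ox + H+ + e-` step under the
#' computational standard hydrogen electrode: the released proton and
#' electron are referenced to half a gas-phase H2 molecule, so
#' `dG_PET = G(product) + G(H2, gas)/2 - G(reactant)`. No additional
#' absolute-potential constant is applied; the H2/2 term *is* the SHE
#' reference, and `E0 = dG_PET / F` is directly a potential on the SHE
#' scale (reported, per IUPAC convention, as the reduction potential of
#' the couple).
#'
#' @param reactant,product One-row data frames (or named lists) with at
#'   least `electrons_removed`, `protons_removed`, `g_aq_hartree`. The
#'   product must be the reactant with exactly one electron and one
#'   proton removed.
#' @param refs A [reference_set()].
#' @param k A [thermo_constants()] object.
#' @return dG_PET in kJ/mol.
#' @examples
#' r <- list(electrons_removed = 0, protons_removed = 0, g_aq_hartree = -500)
#' p <- list(electrons_removed = 1, protons_removed = 1, g_aq_hartree = -499.4)
#' compute_dg_pet(r, p, reference_set(g_h2_gas = -1.17, g_proton_aq = -0.49))
#' @export
compute_dg_pet <- function(reactant, product, refs, k = thermo_constants()) {
  reactant <- .as_state(reactant, "reactant")
  product <- .as_state(product, "product")
  if (!inherits(refs, "reference_set")) abort("`refs` must be a reference_set.")
  de <- product$electrons_removed - reactant$electrons_removed
  dp <- product$protons_removed - reactant$protons_removed
  if (!isTRUE(de == 1L && dp == 1L)) {
    abort("not a PET pair: product must have exactly one more electron and one more proton removed")
  }
  g <- c(reactant$g_aq_hartree, product$g_aq_hartree)
  if (any(!is.finite(g))) abort("incomplete state: missing aqueous free energy")
  if (!is.finite(refs$g_h2_gas)) abort("incomplete state: missing G(H2, gas)")
  hartree_to_kj(product$g_aq_hartree + refs$g_h2_gas / 2 - reactant$g_aq_hartree, k)
}

#' Raw isodesmic pKa of a proton-transfer (PT) step
#'
#' `dG_PT = G(deprotonated) + G(H+, aq) - G(protonated)` with the
#' calibrated aqueous proton energy, and `pKa = dG_PT / (RT ln10)`.
#' This is the uncorrected ("raw") value; [scale_pka()] applies the
#' empirical linear correction used for reporting.
#'
#' @param protonated,deprotonated One-row data frames or named lists;
#'   the deprotonated state must be the protonated one minus exactly
#'   one proton (same electron count).
#' @inheritParams compute_dg_pet
#' @return The raw (unscaled) pKa, dimensionless.
#' @export
compute_pka_raw <- function(protonated, deprotonated, refs, k = thermo_constants()) {
  protonated <- .as_state(protonated, "protonated")
  deprotonated <- .as_state(deprotonated, "deprotonated")
  if (!inherits(refs, "reference_set")) abort("`refs` must be a reference_set.")
  de <- deprotonated$electrons_removed - protonated$electrons_removed
  dp <- deprotonated$protons_removed - protonated$protons_removed
  if (!isTRUE(de == 0L && dp == 1L)) {
    abort("not a PT pair: deprotonated state must differ by exactly one removed proton")
  }
  if (is.null(refs$g_proton_aq) || !is.finite(refs$g_proton_aq)) {
    abort("uncalibrated reference: G(H+, aq) is not available; calibrate it first")
  }
  g <- c(protonated$g_aq_hartree, deprotonated$g_aq_hartree)
  if (any(!is.finite(g))) abort("incomplete state: missing aqueous free energy")
  dg_pt <- hartree_to_kj(deprotonated$g_aq_hartree + refs$g_proton_aq -
                           protonated$g_aq_hartree, k)
  dg_pt / rt_ln10(k)
}

#' Empirical pKa scaling
#'
#' Linear correction mapping raw isodesmic pKa values onto the
#' experimental scale: `pKa_scaled = 0.49 * pKa_raw + 3.2`. The
#' correction compensates shortcomings of the implicit solvation model
#' behind the free energies. [unscale_pka()] is the exact inverse, and
#' [pka_scaled_to_dg()] maps a scaled pKa back to the scaled
#' proton-transfer free energy `dG_PT_scaled = RT ln10 * pKa_scaled`
#' used when decomposing PET steps.
#'
#' @param pka_raw,pka_scaled Numeric vectors of pKa values.
#' @param k A [thermo_constants()] object.
#' @return Numeric vector (pKa units, or kJ/mol for
#'   `pka_scaled_to_dg()`).
#' @examples
#' scale_pka(10) # 8.1
#' unscale_pka(scale_pka(-4.2))
#' @export
scale_pka <- function(pka_raw) {
  stopifnot(is.numeric(pka_raw))
  0.49 * pka_raw + 3.2
}

#' @rdname scale_pka
#' @export
unscale_pka <- function(pka_scaled) {
  stopifnot(is.numeric(pka_scaled))
  (pka_scaled - 3.2) / 0.49
}

#' @rdname scale_pka
#' @export
pka_scaled_to_dg <- function(pka_scaled, k = thermo_constants()) {
  rt_ln10(k) * pka_scaled
}

#' Free-energy change of a pure electron-transfer (ET) step
#'
#' An ET step is obtained as the difference between a PET step and the
#' scaled PT step that completes the thermodynamic cycle:
#' `dG_ET = dG_PET - RT ln10 * pKa_scaled`. The associated reduction
#' potential is `E_red = dG_ET / F` (V vs SHE).
#'
#' @param dg_pet PET free-energy change, kJ/mol.
#' @param pka_scaled Scaled pKa of the completing PT leg.
#' @param k A [thermo_constants()] object.
#' @return dG_ET in kJ/mol.
#' @export
compute_dg_et <- function(dg_pet, pka_scaled, k = thermo_constants()) {
  stopifnot(is.numeric(dg_pet), is.numeric(pka_scaled))
  if (any(!is.finite(dg_pet)) || any(!is.finite(pka_scaled))) {
    abort("`dg_pet` and `pka_scaled` must be finite.")
  }
  dg_pet - pka_scaled_to_dg(pka_scaled, k)
}

# Edge catalogue ------------------------------------------------------------

# The four PET diagonals (reactant -> reactant + 4).
.pet_edges <- function() {
  r <- c(0L, 1L, 3L, 4L)
  tibble(name = sprintf("PET%d%d", r, r + 4L), reactant = r, product = r + 4L)
}

# The six PT verticals (protonated r -> deprotonated r + 3).
.pt_edges <- function() {
  r <- 0:5
  tibble(name = sprintf("PT%d%d", r, r + 3L), reactant = r, product = r + 3L)
}

# The six ET horizontals and the (PET, PT) legs that define each via the
# PET/PT difference. Edges in rows p = 0, 1 take the PET leaving their own
# reactant; the p = 2 row has no outgoing PET, so ET67/ET78 take the PET
# arriving at their product and the PT connecting the two reactants.
.et_edges <- function() {
  tibble(
    name = c("ET01", "ET12", "ET34", "ET45", "ET67", "ET78"),
    reactant = c(0L, 1L, 3L, 4L, 6L, 7L),
    product = c(1L, 2L, 4L, 5L, 7L, 8L),
    pet_leg = c("PET04", "PET15", "PET37", "PET48", "PET37", "PET48"),
    pt_leg = c("PT14", "PT25", "PT47", "PT58", "PT36", "PT47")
  )
}

#' Build a square scheme from species free energies
#'
#' Derives every obtainable reaction edge of the nine-state lattice:
#' the four PET diagonals from the computational-SHE free-energy
#' difference, the six PT verticals from the isodesmic pKa with the
#' empirical scaling applied, and the six ET horizontals as
#' PET-minus-scaled-PT differences. ET edges whose completing PET or PT
#' leg cannot be formed from the supplied states are omitted with a
#' warning rather than an error, so partial state sets are usable.
#'
#' Edge free energies are for the oxidation direction as written
#' (`red -> ox + H+ and/or e-`); the reported potentials
#' `E0 = dG_PET/F` and `E_red = dG_ET/F` are, per IUPAC convention, the
#' reduction potentials of the same couples on the SHE scale. For PT
#' edges `dg_kj_mol` holds the *scaled* proton-transfer energy
#' `RT ln10 * pKa_scaled` (the quantity entering the ET decomposition);
#' the raw pKa is kept in its own column. All values are carried at
#' full precision; rounding to three decimals happens only in
#' [write_scheme_report()].
#'
#' @param states A data frame of species states (see [species_states()];
#'   a pre-validated tibble from that function is also accepted). Any
#'   subset of the nine states may be present.
#' @param refs A [reference_set()].
#' @param k A [thermo_constants()] object.
#' @param molecule_id Identifier carried into reports.
#'
#' @return An object of class `square_scheme`: a list with `molecule_id`,
#'   `states` (tibble), `references`, `constants`, and `edges`, a tibble
#'   with columns `name`, `kind` (ET/PT/PET), `reactant_index`,
#'   `product_index`, `reactant_label`, `product_label`, `dg_kj_mol`,
#'   `pka_raw`, `observable`, `unit`.
#' @examples
#' refs <- reference_set(g_h2_gas = -1.17, g_proton_aq = -0.49)
#' st <- data.frame(index = 0:8, g_aq_hartree = -500 + 0.05 * (0:8))
#' scheme <- build_square_scheme(st, refs)
#' tidy(scheme)
#' @export
build_square_scheme <- function(states, refs, k = thermo_constants(),
                                molecule_id = "molecule") {
  if (!inherits(refs, "reference_set")) abort("`refs` must be a reference_set.")
  if (!is.data.frame(states)) abort("`states` must be a data frame.")
  if (!all(c("index", "electrons_removed", "g_aq_kj") %in% names(states))) {
    states <- species_states(states, k)
  }
  lat <- state_lattice()
  g <- setNames(rep(NA_real_, 9L), as.character(0:8))
  g[as.character(states$index)] <- states$g_aq_kj
  have <- function(i) is.finite(g[as.character(i)])
  gh2_half <- hartree_to_kj(refs$g_h2_gas, k) / 2
  gh <- if (is.finite(refs$g_proton_aq %||% NA_real_)) {
    hartree_to_kj(refs$g_proton_aq, k)
  } else {
    NA_real_
  }
  rtl <- rt_ln10(k)

  edge_row <- function(name, kind, r, p, dg, pka_raw, obs, unit) {
    tibble(name = name, kind = kind,
           reactant_index = r, product_index = p,
           reactant_label = lat$label[lat$index == r],
           product_label = lat$label[lat$index == p],
           dg_kj_mol = dg, pka_raw = pka_raw, observable = obs, unit = unit)
  }

  pet <- .pet_edges()
  pet_rows <- purrr::pmap(pet, function(name, reactant, product) {
    if (!have(reactant) || !have(product) || !is.finite(gh2_half)) return(NULL)
    dg <- g[[as.character(product)]] + gh2_half - g[[as.character(reactant)]]
    edge_row(name, "PET", reactant, product, dg, NA_real_,
             kj_to_volts(dg, k), "V vs SHE")
  })

  pt <- .pt_edges()
  pt_rows <- purrr::pmap(pt, function(name, reactant, product) {
    if (!have(reactant) || !have(product) || !is.finite(gh)) return(NULL)
    dg_raw <- g[[as.character(product)]] + gh - g[[as.character(reactant)]]
    pka_raw <- dg_raw / rtl
    pka_s <- scale_pka(pka_raw)
    edge_row(name, "PT", reactant, product, pka_scaled_to_dg(pka_s, k),
             pka_raw, pka_s, "pKa")
  })

  done <- dplyr::bind_rows(c(pet_rows, pt_rows))
  et_rows <- purrr::pmap(.et_edges(), function(name, reactant, product,
                                               pet_leg, pt_leg) {
    pet_dg <- done$dg_kj_mol[done$name == pet_leg]
    pt_obs <- done$observable[done$name == pt_leg]
    if (length(pet_dg) != 1L || length(pt_obs) != 1L) {
      missing_legs <- c(pet_leg, pt_leg)[c(length(pet_dg) != 1L, length(pt_obs) != 1L)]
      warn(sprintf("%s omitted: completing leg(s) %s not derivable from the supplied states",
                   name, paste(missing_legs, collapse = ", ")))
      return(NULL)
    }
    dg <- compute_dg_et(pet_dg, pt_obs, k)
    edge_row(name, "ET", reactant, product, dg, NA_real_,
             kj_to_volts(dg, k), "V vs SHE")
  })

  edges <- dplyr::bind_rows(c(et_rows, list(done)))
  if (nrow(edges) == 0L) {
    abort("No reaction edge is derivable from the supplied states and references.")
  }
  edges <- edges[order(match(edges$kind, c("ET", "PT", "PET")), edges$reactant_index), ]
  structure(
    list(molecule_id = molecule_id, states = states, references = refs,
         constants = k, edges = as_tibble(edges)),
    class = "square_scheme"
  )
}

#' @export
print.square_scheme <- function(x, ...) {
  cat(sprintf("<square_scheme> %s: %d states, %d edges (%s)\n",
              x$molecule_id, nrow(x$states), nrow(x$edges),
              paste(sprintf("%d %s", table(x$edges$kind)[c("ET", "PT", "PET")],
                            c("ET", "PT", "PET")), collapse = ", ")))
  print(x$edges)
  invisible(x)
}

#' Tidy a square scheme into its edge table
#'
#' @param x A `square_scheme`.
#' @param ... Unused.
#' @return The edge tibble (one row per derived ET/PT/PET reaction).
#' @method tidy square_scheme
#' @export
tidy.square_scheme <- function(x, ...) x$edges

#' Retrieve a single edge from a scheme
#'
#' @param scheme A `square_scheme`.
#' @param name Edge name such as `"PET48"` or `"PT03"`.
#' @param observable If `TRUE` (default) return the edge's observable
#'   (E0, E_red, or scaled pKa); otherwise the full one-row tibble.
#' @return A number or a one-row tibble.
#' @export
scheme_edge <- function(scheme, name, observable = TRUE) {
  stopifnot(inherits(scheme, "square_scheme"))
  row <- scheme$edges[scheme$edges$name == name, ]
  if (nrow(row) != 1L) abort(sprintf("edge %s is not present in this scheme", name))
  if (observable) row$observable else row
}
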