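#' Nernst pH correction of a standard potential
#'
#' For a couple transferring `n_e` electrons and `n_p` protons with all
#' non-proton activities at unity, the potential shifts linearly with
#' pH: `E(pH) = E0 - (RT ln10 / F) * (n_p / n_e) * pH`.
#'
#' @param e_standard Standard (pH 0) potential, V vs SHE.
#' @param n_p,n_e Numbers of protons and electrons transferred
#'   (`n_e >= 1`).
#' @param ph Solution pH (vectorized).
#' @param k A [thermo_constants()] object.
#' @return Potential(s) in V vs SHE.
#' @examples
#' nernst_potential(-0.048, n_p = 2, n_e = 2, ph = 8) # ~ -0.52
#' @export
nernst_potential <- function(e_standard, n_p, n_e, ph, k = thermo_constants()) {
  if (!is.numeric(n_e) || any(n_e < 1)) {
    abort("not an electrochemical step: `n_e` must be >= 1")
  }
  stopifnot(is.numeric(e_standard), is.numeric(n_p), is.numeric(ph))
  e_standard - nernst_slope(k) * (n_p / n_e) * ph
}

#' Overall two-electron two-proton potential of a scheme
#'
#' Combines the two main-diagonal PET steps (QH2 -> QH and QH -> Q)
#' into the potential of the overall `QH2 <-> Q + 2H+ + 2e-` couple.
#' The default `"mean"` mode returns `(E0_PET04 + E0_PET48) / 2`, the
#' free-energy-consistent value for which `2F * E` equals the summed
#' reaction free energy (and the value whose Nernst slope is
#' -0.0592 V/pH for n_p = n_e = 2). `"sum"` mode returns the literal
#' sum of the two PET potentials.
#'
#' @param scheme A `square_scheme` with PET04 and PET48 edges.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return A single potential, V vs SHE.
#' @export
overall_two_electron_potential <- function(scheme, mode = c("mean", "sum")) {
  stopifnot(inherits(scheme, "square_scheme"))
  mode <- match.arg(mode)
  for (nm in c("PET04", "PET48")) {
    if (!nm %in% scheme$edges$name) {
      abort(sprintf("missing edge %s: cannot form the overall two-electron couple", nm))
    }
  }
  tot <- scheme_edge(scheme, "PET04") + scheme_edge(scheme, "PET48")
  if (mode == "mean") tot / 2 else tot
}

# Effective state energies (kJ/mol) consistent with the *scaled*
# observables. The six scaled PT edges plus PET04/PET48 span the nine
# states, so walking that tree from state 0 assigns each state an
# energy whose pairwise differences reproduce pKa_scaled and the
# planted PET potentials exactly. Raw g_aq would misplace PT boundaries
# at the unscaled pKa.
.effective_energies <- function(scheme) {
  k <- scheme$constants
  refs <- scheme$references
  need <- c(.pt_edges()$name, "PET04", "PET48")
  missing <- setdiff(need, scheme$edges$name)
  if (length(missing)) {
    abort(paste0("incomplete scheme: effective energies need edges ",
                 paste(missing, collapse = ", ")))
  }
  gh <- hartree_to_kj(refs$g_proton_aq, k)
  gh2_half <- hartree_to_kj(refs$g_h2_gas, k) / 2
  dg <- setNames(scheme$edges$dg_kj_mol, scheme$edges$name)

  ge <- numeric(9L)
  st0 <- scheme$states$g_aq_kj[scheme$states$index == 0L]
  ge[1L] <- if (length(st0) == 1L) st0 else 0
  ge[4L] <- ge[1L] - gh + dg[["PT03"]]
  ge[7L] <- ge[4L] - gh + dg[["PT36"]]
  ge[5L] <- ge[1L] + dg[["PET04"]] - gh2_half
  ge[2L] <- ge[5L] + gh - dg[["PT14"]]
  ge[8L] <- ge[5L] - gh + dg[["PT47"]]
  ge[9L] <- ge[5L] + dg[["PET48"]] - gh2_half
  ge[6L] <- ge[9L] + gh - dg[["PT58"]]
  ge[3L] <- ge[6L] + gh - dg[["PT25"]]
  list(ge = ge, gh = gh, gh2_half = gh2_half)
}

# Grand potentials for all states over vectors of (ph, e): returns an
# n x 9 matrix. State i holds (2 - protons_removed) protons and
# (2 - electrons_removed) electrons relative to Q; each attached proton
# costs mu_H = G(H+) - RT ln10 * pH and each attached electron
# mu_e = G(H2)/2 - G(H+) - F*E (the H+/e- pair is referenced to H2/2).
.grand_potential <- function(scheme, ph, e) {
  k <- scheme$constants
  eff <- .effective_energies(scheme)
  lat <- state_lattice()
  rtl <- rt_ln10(k)
  np <- 2 - lat$protons_removed
  ne <- 2 - lat$electrons_removed
  mu_h <- eff$gh - rtl * ph                      # per proton, kJ/mol
  mu_e <- eff$gh2_half - eff$gh - k$F * e / 1000 # per electron, kJ/mol
  gt <- matrix(eff$ge, nrow = length(ph), ncol = 9L, byrow = TRUE)
  gt - outer(mu_h, np) - outer(mu_e, ne)
}

# preference order for exact ties: deprotonated first, then oxidized
.tie_order <- function() {
  lat <- state_lattice()
  lat$index[order(-lat$protons_removed, -lat$electrons_removed)]
}

#' Thermodynamically predominant state at given pH and potential
#'
#' Minimizes the grand potential over all nine states: each state's
#' effective free energy (consistent with the scaled pKa values) is
#' charged for its attached protons at `mu_H(pH)` and electrons at
#' `mu_e(E)`. Ties are resolved toward the state with fewer attached
#' protons, then fewer attached electrons, so at `pH = pKa` exactly the
#' deprotonated species is reported.
#'
#' @param scheme A complete `square_scheme` (all nine states).
#' @param ph,e Vectors of pH and potential (V vs SHE); recycled to a
#'   common length.
#' @param k Unused; the scheme carries its constants. Kept for call
#'   symmetry with the other operations.
#' @return Integer vector of predominant state indices (0-8).
#' @examples
#' s <- example_peaq_scheme()
#' predominant_species(s, ph = c(0, 14), e = c(-1.2, 1.2))
#' @export
predominant_species <- function(scheme, ph, e, k = NULL) {
  stopifnot(inherits(scheme, "square_scheme"))
  if (nrow(scheme$states) < 9L) {
    abort("incomplete scheme: predominance needs all nine states")
  }
  n <- max(length(ph), length(e))
  ph <- rep_len(as.numeric(ph), n)
  e <- rep_len(as.numeric(e), n)
  gt <- .grand_potential(scheme, ph, e)
  mins <- do.call(pmin, asplit(gt, 2L))
  out <- rep(NA_integer_, n)
  for (idx in .tie_order()) {
    sel <- is.na(out) & gt[, idx + 1L] <= mins + 1e-9
    out[sel] <- idx
  }
  out
}

#' Pourbaix predominance map with analytic boundaries
#'
#' Builds the predominance diagram over a (pH, E) window: grid cells
#' labelled by [predominant_species()], analytic boundary segments
#' between adjacent regions, and the reduction-pathway bands of
#' [classify_reduction_pathway()]. Boundaries between states differing
#' only in protonation are vertical lines at `pH = pKa_scaled`; all
#' others are lines of slope `-(RT ln10 / F) * (n_p / n_e)` V/pH for
#' the separating couple.
#'
#' @param scheme A complete `square_scheme`.
#' @param ph_window,e_window Two-element ranges (default 0-14 pH and
#'   -1.5..1.5 V, the aqueous electrochemical window).
#' @param resolution Grid spacing in pH (and V) units, default 0.05.
#' @param k Unused; the scheme carries its constants. Kept for call
#'   symmetry with the other operations.
#' @return An object of class `pourbaix_map`: list with `grid`
#'   (tibble: ph, e, state_index, label), `boundaries` (tibble: states,
#'   labels, n_p, n_e, slope V/pH, intercept V at pH 0, extent), and
#'   `pathway_bands` (see [pathway_bands()]).
#' @export
pourbaix_boundaries <- function(scheme, ph_window = c(0, 14),
                                e_window = c(-1.5, 1.5),
                                resolution = 0.05, k = NULL) {
  stopifnot(inherits(scheme, "square_scheme"))
  if (length(ph_window) != 2L || diff(ph_window) <= 0 ||
      length(e_window) != 2L || diff(e_window) <= 0) {
    abort("empty window: ph_window and e_window must have positive width")
  }
  kc <- scheme$constants
  lat <- state_lattice()
  eff <- .effective_energies(scheme)
  rtl <- rt_ln10(kc)

  ph_grid <- seq(ph_window[1L], ph_window[2L], by = resolution)
  e_grid <- seq(e_window[1L], e_window[2L], by = resolution)
  cells <- tidyr::expand_grid(ph = ph_grid, e = e_grid)
  cells$state_index <- predominant_species(scheme, cells$ph, cells$e)
  cells$label <- lat$label[cells$state_index + 1L]

  present <- sort(unique(cells$state_index))
  # Gt_i(ph, E) = const_i + rtl*(2-p_i)*ph + (F/1000)*(2-e_i)*E
  const_i <- eff$ge - (2 - lat$protons_removed) * eff$gh -
    (2 - lat$electrons_removed) * (eff$gh2_half - eff$gh)
  cph <- rtl * (2 - lat$protons_removed)
  ce <- kc$F / 1000 * (2 - lat$electrons_removed)

  seg_rows <- list()
  n_samp <- 801L
  joint_min <- function(ph, e, i, j) {
    gt <- .grand_potential(scheme, ph, e)
    pair <- pmin(gt[, i + 1L], gt[, j + 1L])
    mins <- do.call(pmin, asplit(gt, 2L))
    as.vector(pair <= mins + 1e-7)
  }
  runs_to_ranges <- function(t, on) {
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths > 1L)
    lapply(keep, function(q) c(t[starts[q]], t[ends[q]]))
  }
  for (a in seq_along(present)) {
    for (b in seq_len(a - 1L)) {
      i <- present[a]; j <- present[b]
      dph <- cph[i + 1L] - cph[j + 1L]
      de <- ce[i + 1L] - ce[j + 1L]
      dc <- const_i[i + 1L] - const_i[j + 1L]
      n_p <- abs(lat$protons_removed[i + 1L] - lat$protons_removed[j + 1L])
      n_e <- abs(lat$electrons_removed[i + 1L] - lat$electrons_removed[j + 1L])
      if (de == 0) { # pure PT couple: vertical at pH = pKa (possibly multi-proton)
        ph0 <- -dc / dph
        if (ph0 < ph_window[1L] || ph0 > ph_window[2L]) next
        tt <- seq(e_window[1L], e_window[2L], length.out = n_samp)
        rngs <- runs_to_ranges(tt, joint_min(rep(ph0, n_samp), tt, i, j))
        for (r in rngs) {
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            state_a = j, state_b = i,
            label_a = lat$label[j + 1L], label_b = lat$label[i + 1L],
            n_p = n_p, n_e = n_e, type = "vertical",
            slope = NA_real_, intercept = NA_real_, ph = ph0,
            ph_min = ph0, ph_max = ph0, e_min = r[1L], e_max = r[2L])
        }
      } else { # E(ph) line; slope in V/pH
        slope <- -dph / de
        icept <- -dc / de
        tt <- seq(ph_window[1L], ph_window[2L], length.out = n_samp)
        ee <- icept + slope * tt
        ok <- ee >= e_window[1L] & ee <= e_window[2L]
        on <- ok & joint_min(tt, ee, i, j)
        rngs <- runs_to_ranges(tt, on)
        for (r in rngs) {
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            state_a = j, state_b = i,
            label_a = lat$label[j + 1L], label_b = lat$label[i + 1L],
            n_p = n_p, n_e = n_e, type = "sloped",
            slope = slope, intercept = icept, ph = NA_real_,
            ph_min = r[1L], ph_max = r[2L],
            e_min = icept + slope * r[1L], e_max = icept + slope * r[2L])
        }
      }
    }
  }
  boundaries <- if (length(seg_rows)) dplyr::bind_rows(seg_rows) else
    tibble(state_a = integer(), state_b = integer(), label_a = character(),
           label_b = character(), n_p = integer(), n_e = integer(),
           type = character(), slope = double(), intercept = double(),
           ph = double(), ph_min = double(), ph_max = double(),
           e_min = double(), e_max = double())

  structure(
    list(molecule_id = scheme$molecule_id, grid = cells,
         boundaries = boundaries,
         pathway_bands = pathway_bands(scheme, ph_window),
         ph_window = ph_window, e_window = e_window,
         resolution = resolution),
    class = "pourbaix_map"
  )
}

#' @export
print.pourbaix_map <- function(x, ...) {
  cat(sprintf("<pourbaix_map> %s: pH %.4g..%.4g, E %.4g..%.4g V (res %.3g)\n",
              x$molecule_id, x$ph_window[1], x$ph_window[2],
              x$e_window[1], x$e_window[2], x$resolution))
  cat(sprintf("  %d grid cells, %d boundary segments, %d pathway bands\n",
              nrow(x$grid), nrow(x$boundaries), nrow(x$pathway_bands)))
  invisible(x)
}

#' Tidy a Pourbaix map into its cell grid
#'
#' @param x A `pourbaix_map`.
#' @param ... Unused.
#' @return The grid tibble (ph, e, state_index, label).
#' @method tidy pourbaix_map
#' @export
tidy.pourbaix_map <- function(x, ...) x$grid

#' Plot a Pourbaix map
#'
#' Predominance regions as filled tiles with the analytic boundary
#' segments drawn on top.
#'
#' @param object A `pourbaix_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pourbaix_map
#' @export
autoplot.pourbaix_map <- function(object, ...) {
  b <- object$boundaries
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$ph, y = .data$e)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
    ggplot2::geom_segment(
      data = b[b$type == "sloped", ],
      ggplot2::aes(x = .data$ph_min, xend = .data$ph_max,
                   y = .data$e_min, yend = .data$e_max),
      inherit.aes = FALSE, linewidth = 0.4) +
    ggplot2::geom_segment(
      data = b[b$type == "vertical", ],
      ggplot2::aes(x = .data$ph, xend = .data$ph,
                   y = .data$e_min, yend = .data$e_max),
      inherit.aes = FALSE, linewidth = 0.4) +
    ggplot2::labs(x = "pH", y = "E (V vs SHE)", fill = "species",
                  title = object$molecule_id)
}

# PT edge connecting protonated state r to deprotonated r+3, if present.
.pt_pka <- function(scheme, r_prot) {
  nm <- sprintf("PT%d%d", r_prot, r_prot + 3L)
  row <- scheme$edges[scheme$edges$name == nm, ]
  if (nrow(row) != 1L) return(structure(NA_real_, names = nm))
  structure(row$observable, names = nm)
}

#' Classify the reduction pathway at a given pH
#'
#' Walks the two electron additions of the reduction `Q -> QH2`
#' (or as far as protonation allows). At each addition the electron
#' arrives together with a proton (PET) when the pH lies below the
#' scaled pKa of the protonated product, and alone (ET) otherwise; a
#' PET step is followed by a further protonation (PT) when the reduced
#' state's conjugate acid is stable at this pH.
#'
#' @param scheme A `square_scheme` carrying the PT edges the walk
#'   needs (a full scheme always qualifies).
#' @param ph Solution pH (scalar).
#' @return Character vector of ordered step labels, e.g.
#'   `c("ET", "PET", "PT")`.
#' @examples
#' classify_reduction_pathway(example_peaq_scheme(), ph = 10)
#' @export
classify_reduction_pathway <- function(scheme, ph) {
  stopifnot(inherits(scheme, "square_scheme"), is.numeric(ph), length(ph) == 1L)
  lat <- state_lattice()
  s <- 8L
  steps <- character()
  missing <- character()
  pka_at <- function(r_prot) {
    v <- .pt_pka(scheme, r_prot)
    if (is.na(v)) missing <<- c(missing, names(v))
    v
  }
  for (addition in 1:2) {
    p_rem <- lat$protons_removed[s + 1L]
    pet_ok <- FALSE
    if (p_rem >= 1L) {
      pka <- pka_at(s - 4L)
      pet_ok <- isTRUE(ph < pka)
    }
    if (pet_ok) {
      steps <- c(steps, "PET")
      s <- s - 4L
    } else {
      steps <- c(steps, "ET")
      s <- s - 1L
    }
    # trailing protonation of the fresh reduction product
    if (lat$protons_removed[s + 1L] >= 1L) {
      pka <- pka_at(s - 3L)
      if (isTRUE(ph < pka)) {
        steps <- c(steps, "PT")
        s <- s - 3L
      }
    }
  }
  if (length(missing)) {
    abort(paste0("missing edge(s) required for pathway classification: ",
                 paste(unique(missing), collapse = ", ")))
  }
  steps
}

#' Reduction-pathway bands across a pH window
#'
#' Partitions the pH axis into maximal intervals over which
#' [classify_reduction_pathway()] returns the same step sequence.
#' Band edges are the scaled pKa values of the scheme's PT edges.
#'
#' @param scheme A `square_scheme`.
#' @param ph_window Two-element pH range (default 0-14).
#' @return A tibble with `ph_min`, `ph_max`, `pathway` (collapsed
#'   labels such as `"ET-PET-PT"`), and `steps` (list column).
#' @export
pathway_bands <- function(scheme, ph_window = c(0, 14)) {
  stopifnot(inherits(scheme, "square_scheme"))
  if (length(ph_window) != 2L || diff(ph_window) <= 0) {
    abort("empty window: `ph_window` must have positive width")
  }
  pt <- scheme$edges[scheme$edges$kind == "PT", ]
  cuts <- sort(unique(pt$observable))
  cuts <- cuts[cuts > ph_window[1L] & cuts < ph_window[2L]]
  lo <- c(ph_window[1L], cuts)
  hi <- c(cuts, ph_window[2L])
  seqs <- purrr::map(0.5 * (lo + hi), ~ classify_reduction_pathway(scheme, .x))
  key <- purrr::map_chr(seqs, paste, collapse = "-")
  grp <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  tibble(ph_min = lo, ph_max = hi, pathway = key, steps = seqs) |>
    dplyr::group_by(grp2 = grp) |>
    dplyr::summarise(ph_min = min(.data$ph_min), ph_max = max(.data$ph_max),
                     pathway = .data$pathway[1L],
                     steps = .data$steps[1L], .groups = "drop") |>
    dplyr::select(-"grp2")
}
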