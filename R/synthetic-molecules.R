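# Quinone-like core templates with numbered substitution sites. Six
# cores (benzo-, naphtho-, anthra- and phenanthrenequinone-like); this
# is a deliberately small synthetic library for download-free testing,
# not a reproduction of the published 15-core set.
.core_templates <- function() {
  list(
    pBQ  = "O=C1C{1}=C{2}C(=O)C{3}=C{4}1",
    oBQ  = "O=C1C{1}=C{2}C{3}=C{4}C1=O",
    NQ14 = "O=C1C{1}=C{2}C(=O)c2c{3}c{4}c{5}c{6}c12",
    NQ12 = "O=C1C(=O)C{1}=C{2}c2c{3}c{4}c{5}c{6}c12",
    AQ   = "O=C1c2c{1}c{2}c{3}c{4}c2C(=O)c2c{5}c{6}c{7}c{8}c12",
    PQ   = "O=C1C(=O)c2c{1}c{2}c{3}c{4}c2-c2c{5}c{6}c{7}c{8}c12"
  )
}

# The nine decoration groups as SMILES branch fragments.
.functional_groups <- function() {
  c(CH3 = "C", CF3 = "C(F)(F)F", OCH3 = "OC", C2H3 = "C=C", F = "F",
    CN = "C#N", NO2 = "[N+](=O)[O-]", OCOCH3 = "OC(C)=O",
    CO2CH3 = "C(=O)OC")
}

.render_template <- function(template, assignment) {
  n_sites <- length(gregexpr("\\{", template)[[1L]])
  for (i in seq_len(n_sites)) {
    sub <- assignment[as.character(i)]
    rep <- if (is.na(sub)) "" else paste0("(", sub, ")")
    template <- sub(sprintf("\\{%d\\}", i), rep, template)
  }
  template
}

# Enumerate every core x {1,2}-substituent decoration, canonicalize,
# and deduplicate. Cached per session: the library is deterministic.
.library_env <- new.env(parent = emptyenv())

.enumerate_library <- function() {
  if (!is.null(.library_env$lib)) return(.library_env$lib)
  groups <- .functional_groups()
  rows <- list()
  for (core in names(.core_templates())) {
    template <- .core_templates()[[core]]
    n_sites <- length(gregexpr("\\{", template)[[1L]])
    for (s1 in seq_len(n_sites)) {
      for (g1 in names(groups)) {
        a <- setNames(groups[[g1]], as.character(s1))
        rows[[length(rows) + 1L]] <- tibble(
          core = core, groups = g1, n_subs = 1L,
          smiles = .render_template(template, a))
        for (s2 in seq_len(n_sites)) {
          if (s2 <= s1) next
          for (g2 in names(groups)) {
            a2 <- setNames(c(groups[[g1]], groups[[g2]]),
                           as.character(c(s1, s2)))
            rows[[length(rows) + 1L]] <- tibble(
              core = core, groups = paste(g1, g2, sep = "+"), n_subs = 2L,
              smiles = .render_template(template, a2))
          }
        }
      }
    }
  }
  lib <- dplyr::bind_rows(rows)
  canon <- canonicalize_smiles_table(lib$smiles)
  if (any(!canon$ok)) {
    abort(sprintf("internal error: %d template renderings failed to parse (first: %s)",
                  sum(!canon$ok), lib$smiles[!canon$ok][1L]))
  }
  lib$smiles <- canon$canonical
  lib <- lib[!duplicated(lib$smiles), , drop = FALSE]
  .library_env$lib <- lib
  lib
}

#' Generate a synthetic quinone-like molecule library
#'
#' Draws `n` distinct molecules from the enumerated decoration space of
#' six quinone-like cores bearing one or two of the nine standard
#' functional groups (methyl, trifluoromethyl, methoxy, vinyl, fluoro,
#' cyano, nitro, acetoxy, methyl ester). All SMILES are canonical
#' isomeric forms and unique; generation is deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param n Number of molecules (at most the enumerable library size).
#' @return A tibble with `smiles` (canonical), `core`, `groups`,
#'   `n_subs`.
#' @examples
#' \donttest{
#' generate_molecule_library(seed = 1, n = 5)
#' }
#' @export
generate_molecule_library <- function(seed = 1L, n = 50L) {
  stopifnot(n >= 1L)
  lib <- .enumerate_library()
  if (n > nrow(lib)) {
    abort(sprintf("n = %d exceeds the enumerable library size (%d)", n, nrow(lib)))
  }
  with_seed(seed, lib[sample.int(nrow(lib), n), , drop = FALSE])
}

#' Generate a planted-signal dataset for surrogate-model testing
#'
#' Two ground-truth families:
#' \describe{
#'   \item{fingerprint_bits}{targets are a weighted sum over
#'     `n_signal_bits` designated fingerprint bits of real library
#'     molecules plus Gaussian noise -- a recoverable structural signal
#'     for FP-descriptor models.}
#'   \item{orbital_linear}{targets follow `slope * HOMO_up + intercept`
#'     plus noise over a synthetic eight-orbital feature block,
#'     mirroring the inverse HOMO/potential correlation of the
#'     chemistry.}
#' }
#'
#' @param seed Integer seed.
#' @param n Number of samples (>= 50).
#' @param noise_sd Gaussian noise standard deviation (target units).
#' @param signal_kind `"fingerprint_bits"` or `"orbital_linear"`.
#' @param n_signal_bits Number of designated bits (fingerprint mode).
#' @param slope,intercept Linear law for the orbital mode; the default
#'   slope is negative (higher-lying HOMO, lower potential).
#' @return A list with `features` (tibble), `targets` (numeric vector)
#'   and `truth` (a description of the planted signal).
#' @export
generate_ml_dataset <- function(seed = 1L, n = 500L, noise_sd = 0.01,
                                signal_kind = c("fingerprint_bits",
                                                "orbital_linear"),
                                n_signal_bits = 5L, slope = -8, intercept = -2) {
  signal_kind <- match.arg(signal_kind)
  stopifnot(n >= 50L)
  if (signal_kind == "fingerprint_bits") {
    lib <- .enumerate_library()
    with_seed(seed, {
      idx <- if (n <= nrow(lib)) sample.int(nrow(lib), n)
             else sample.int(nrow(lib), n, replace = TRUE)
      charges <- sample(-2:2, n, replace = TRUE)
      fp <- compute_fingerprint(lib$smiles[idx], charges)
      bits <- as.matrix(fp[, seq_len(ncol(fp) - 1L)])
      prev <- colMeans(bits)
      informative <- which(prev >= 0.15 & prev <= 0.85)
      if (length(informative) < n_signal_bits) {
        informative <- order(pmin(prev, 1 - prev), decreasing = TRUE)[
          seq_len(max(n_signal_bits, 10L))]
      }
      signal <- sample(informative, n_signal_bits)
      w <- stats::runif(n_signal_bits, 0.5, 1.5) *
        sample(c(-1, 1), n_signal_bits, replace = TRUE)
      y <- as.numeric(bits[, signal, drop = FALSE] %*% w) +
        stats::rnorm(n, 0, noise_sd)
      list(features = fp, targets = y,
           truth = list(kind = signal_kind,
                        signal_features = colnames(bits)[signal],
                        weights = w, noise_sd = noise_sd))
    })
  } else {
    with_seed(seed, {
      homo_up <- stats::runif(n, -0.35, -0.15)
      # non-signal orbitals are independent draws in plausible windows so
      # the planted signal is attributable to homo_up alone
      orb <- function(lo, hi) stats::runif(n, lo, hi)
      feats <- tibble(
        homo_m1_up = orb(-0.42, -0.20),
        homo_up = homo_up,
        lumo_up = orb(-0.10, 0.10),
        lumo_p1_up = orb(-0.02, 0.18),
        homo_m1_down = orb(-0.44, -0.22),
        homo_down = orb(-0.37, -0.17),
        lumo_down = orb(-0.09, 0.11),
        lumo_p1_down = orb(-0.01, 0.19)
      )
      y <- slope * homo_up + intercept + stats::rnorm(n, 0, noise_sd)
      list(features = feats, targets = y,
           truth = list(kind = signal_kind, signal_features = "homo_up",
                        slope = slope, intercept = intercept,
                        noise_sd = noise_sd))
    })
  }
}
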