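# Shared fixtures and independent oracles used across the suite.

make_refs <- function(gh2 = -1.17, gh = -0.47, k = thermo_constants()) {
  # reference acid constructed so the calibrated proton energy is `gh`
  g_ha <- -189.75
  g_a <- rt_ln10(k) * 3.77 / k$hartree_to_kj_per_mol + g_ha - gh
  reference_set(g_h2_gas = gh2, ref_acid_g_ha = g_ha, ref_acid_g_a = g_a,
                pka_ref = 3.77, k = k)
}

state_row <- function(e, p, g) {
  list(electrons_removed = e, protons_removed = p, g_aq_hartree = g)
}

# Independent grand-potential oracle: reconstructs state energies from
# the scheme's *observables* in a zero-gauge (G(H+) = G(H2) = 0), then
# minimizes. Written from the defining relations, not the package
# internals; same tie-break (deprotonated, then oxidized).
oracle_predominant <- function(scheme, ph, e) {
  k <- scheme$constants
  rtl <- rt_ln10(k)
  obs <- setNames(scheme$edges$observable, scheme$edges$name)
  ge <- numeric(9L) # ge[i + 1] is state i
  ge[4] <- ge[1] + rtl * obs[["PT03"]]
  ge[7] <- ge[4] + rtl * obs[["PT36"]]
  ge[5] <- ge[1] + obs[["PET04"]] * k$F / 1000
  ge[2] <- ge[5] - rtl * obs[["PT14"]]
  ge[8] <- ge[5] + rtl * obs[["PT47"]]
  ge[9] <- ge[5] + obs[["PET48"]] * k$F / 1000
  ge[6] <- ge[9] - rtl * obs[["PT58"]]
  ge[3] <- ge[6] - rtl * obs[["PT25"]]
  lat <- state_lattice()
  n <- max(length(ph), length(e))
  ph <- rep_len(ph, n); e <- rep_len(e, n)
  out <- integer(n)
  pref <- lat$index[order(-lat$protons_removed, -lat$electrons_removed)]
  for (i in seq_len(n)) {
    gt <- ge + (2 - lat$protons_removed) * rtl * ph[i] +
      (2 - lat$electrons_removed) * k$F * e[i] / 1000
    cand <- which(gt <= min(gt) + 1e-9) - 1L
    out[i] <- pref[pref %in% cand][1L]
  }
  out
}

# Brute-force Shapley values of a fitted forest at one sample, by
# subset enumeration of the per-tree conditional expectation.
brute_shap <- function(fit, x) {
  expval <- function(tr, S) {
    rec <- function(node) {
      f <- tr$feature[node + 1L]
      if (f < 0L) return(tr$value[node + 1L])
      if ((f + 1L) %in% S) {
        if (x[f + 1L] <= tr$threshold[node + 1L]) rec(tr$left[node + 1L])
        else rec(tr$right[node + 1L])
      } else {
        l <- tr$left[node + 1L]; r <- tr$right[node + 1L]
        (tr$cover[l + 1L] * rec(l) + tr$cover[r + 1L] * rec(r)) /
          tr$cover[node + 1L]
      }
    }
    rec(0L)
  }
  p <- length(x)
  phi <- numeric(p)
  for (tr in fit$trees) {
    for (i in seq_len(p)) {
      others <- setdiff(seq_len(p), i)
      for (sz in 0:length(others)) {
        ss <- if (sz == 0L) list(integer(0)) else
          utils::combn(others, sz, simplify = FALSE)
        w <- factorial(sz) * factorial(p - sz - 1L) / factorial(p)
        for (S in ss) {
          phi[i] <- phi[i] + w * (expval(tr, c(S, i)) - expval(tr, S))
        }
      }
    }
  }
  phi / length(fit$trees)
}

# Ten distinct small quinone-like molecules for fingerprint tests.
ten_cores <- function() {
  c("O=C1C=CC(=O)C=C1", "O=C1C=CC=CC1=O", "O=C1C=CC(=O)c2ccccc12",
    "O=C1C(=O)C=Cc2ccccc12", "O=C1c2ccccc2C(=O)c2ccccc12",
    "CC1=CC(=O)C=CC1=O", "O=C1C=CC(=O)C(F)=C1", "N#CC1=CC(=O)C=CC1=O",
    "COC1=CC(=O)C=CC1=O", "O=C1C=CC(=O)C([N+](=O)[O-])=C1")
}

make_reaction_records <- function(n = 10L, kind = "ET", seed = 1L) {
  withr::with_seed(seed, {
    smi <- sample(ten_cores(), n, replace = n > 10L)
    homo <- runif(n, -0.35, -0.15)
    tibble::tibble(
      reaction_kind = kind,
      reaction_name = paste0(kind, "01"),
      smiles = smi,
      net_charge = sample(-1:1, n, replace = TRUE),
      molecular_weight = round(runif(n, 100, 300), 3),
      cavity_volume = round(runif(n, 120, 350), 3),
      n_atoms = sample(10:30, n, replace = TRUE),
      homo_m1_up = round(homo - 0.03, 3), homo_up = round(homo, 3),
      lumo_up = round(homo + 0.25, 3), lumo_p1_up = round(homo + 0.35, 3),
      homo_m1_down = round(homo - 0.04, 3), homo_down = round(homo - 0.01, 3),
      lumo_down = round(homo + 0.26, 3), lumo_p1_down = round(homo + 0.36, 3),
      target = round(runif(n, -1, 2), 3)
    )
  })
}
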