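# Independent oracles used across the suite. These deliberately recompute
# quantities through a different route than the implementation under test.

# Exhaustive binomial upper-tail P(X >= m) by direct summation in log space.
oracle_binom_tail <- function(m, n, p) {
  if (m <= 0) return(1)
  k <- m:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Elemental composition of a theoretical fragment row, built atom-wise:
# residues in range + side modifications in range + terminal adjustments
# + (partner peptide - NH3) when the fragment carries the crosslink.
oracle_fragment_composition <- function(iso, row) {
  side_seq <- if (row$side == "alpha") iso$alpha else iso$beta
  dea <- if (row$side == "alpha") iso$deamidation else integer(0)
  ox <- if (row$side == "alpha") iso$oxidation else integer(0)
  sub <- substring(side_seq, row$start, row$end)
  dea_in <- dea[dea >= row$start & dea <= row$end] - row$start + 1L
  ox_in <- ox[ox >= row$start & ox <= row$end] - row$start + 1L
  comp <- peptide_composition(sub, deamidation = dea_in, oxidation = ox_in)
  h2o <- elem_comp(H = 2, O = 1); nh3 <- elem_comp(N = 1, H = 3)
  co <- elem_comp(C = 1, O = 1)
  # peptide_composition includes one water; b/a/internal ions have none
  if (row$type %in% c("b", "a", "internal")) comp <- comp - h2o
  if (row$type == "a") comp <- comp - co
  if (row$carries_partner) {
    stopifnot(row$partner_form == "full")
    partner_seq <- if (row$side == "alpha") iso$beta else iso$alpha
    pdea <- if (row$side == "alpha") integer(0) else iso$deamidation
    pox <- if (row$side == "alpha") integer(0) else iso$oxidation
    comp <- comp + peptide_composition(partner_seq, deamidation = pdea,
                                       oxidation = pox) - nh3
  }
  if (row$loss == "H2O") comp <- comp - h2o
  if (row$loss == "NH3") comp <- comp - nh3
  comp
}

oracle_fragment_mz <- function(iso, row) {
  (monoisotopic_mass(oracle_fragment_composition(iso, row)) +
     row$charge * PROTON_MASS) / row$charge
}

# Exhaustive isotopologue enumeration for small compositions (<= ~30 atoms),
# aggregated by nominal neutron offset. Independent of the convolution code.
oracle_isotope_enum <- function(comp, n_peaks) {
  tabs <- list(
    C = list(off = c(0L, 1L), ab = c(0.9893, 0.0107)),
    H = list(off = c(0L, 1L), ab = c(0.999885, 0.000115)),
    N = list(off = c(0L, 1L), ab = c(0.99636, 0.00364)),
    O = list(off = c(0L, 1L, 2L), ab = c(0.99757, 0.00038, 0.00205)),
    S = list(off = c(0L, 1L, 2L, 4L), ab = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  # per element: enumerate counts over isotopes via recursion
  elem_dist <- function(off, ab, count) {
    dist <- stats::setNames(1, "0")
    for (i in seq_len(count)) {
      new <- list()
      for (key in names(dist)) {
        base <- as.integer(key)
        for (j in seq_along(off)) {
          k <- as.character(base + off[j])
          new[[k]] <- (new[[k]] %||% 0) + dist[[key]] * ab[j]
        }
      }
      dist <- unlist(new)
    }
    dist
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  total <- stats::setNames(1, "0")
  for (e in names(comp)) {
    d <- elem_dist(tabs[[e]]$off, tabs[[e]]$ab, comp[[e]])
    new <- list()
    for (k1 in names(total)) for (k2 in names(d)) {
      k <- as.character(as.integer(k1) + as.integer(k2))
      new[[k]] <- (new[[k]] %||% 0) + total[[k1]] * d[[k2]]
    }
    total <- unlist(new)
  }
  off <- as.integer(names(total))
  p <- numeric(n_peaks)
  for (i in seq_along(off)) if (off[i] < n_peaks) p[off[i] + 1L] <- total[i]
  p / sum(p)
}

# Brute-force digestion oracle: every substring whose termini are cleavage
# boundaries and whose internal boundary count is within the budget.
oracle_digest <- function(protein, enzymes, max_missed) {
  n <- nchar(protein)
  sites <- cleavage_sites(protein, enzymes)
  bounds <- c(0L, sites, n)
  out <- character(0)
  for (s in 1:n) for (e in s:n) {
    if (!((s - 1L) %in% bounds && e %in% bounds)) next
    internal <- sum(sites >= s & sites < e)
    if (internal > max_missed) next
    out <- c(out, substring(protein, s, e))
  }
  sort(unique(out))
}

# A perfect spectrum of an isopeptide: every theoretical fragment at its
# exact m/z, unit-free intensities, plus the exact precursor envelope.
perfect_spectrum <- function(iso, charge = 2L, rt = 30,
                             config = fragment_config(), id = NULL) {
  fr <- enumerate_fragments(iso, config)
  sp <- ms2_spectrum(fr$mz, rep(100, nrow(fr)),
                     precursor_mz = mass_to_mz(precursor_mass(iso), charge),
                     precursor_charge = charge, rt = rt,
                     id = id %||% iso$id %||% "perfect")
  comp <- peptide_composition(iso$alpha, deamidation = iso$deamidation,
                              oxidation = iso$oxidation) +
    xlink_modification_composition(iso$beta)
  sp$precursor_envelope <- isotope_distribution(comp, 4L)$abundance
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
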