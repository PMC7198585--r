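iso_w2 <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2, id = "W2")

test_that("isopeptide construction enforces the crosslink chemistry", {
  expect_error(isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 1), "Q in alpha")
  expect_error(isopeptide("AQIPQQL", "AGGR", alpha_q_pos = 2), "exactly one K")
  expect_error(isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2,
                          deamidation = 2), "crosslinked Q")
  expect_error(isopeptide("AQIPQQNNL", "FLKNAGR", alpha_q_pos = 2,
                          deamidation = c(5, 6, 7, 8), oxidation = integer(0),
                          max_mods = 4), "variable modifications")
  expect_identical(iso_w2$beta_k_pos, 3L)
})

test_that("precursor mass is alpha + beta - NH3 and shifts by deamidation", {
  m <- precursor_mass(iso_w2)
  expect_equal(m - peptide_mass("AQIPQQL"),
               monoisotopic_mass(xlink_modification_composition("FLKNAGR")),
               tolerance = 1e-9)
  # symmetric in which side carries the modification
  expect_equal(m,
               peptide_mass("FLKNAGR") +
                 monoisotopic_mass(peptide_composition("AQIPQQL") -
                                     elem_comp(N = 1, H = 3)),
               tolerance = 1e-9)
  iso_de <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2, deamidation = 5)
  expect_equal(precursor_mass(iso_de) - m, 0.9840156, tolerance = 1e-6)
  expect_equal(unname(precursor_mz(iso_w2, 2)),
               (m + 2 * PROTON_MASS) / 2, tolerance = 1e-10)
})

test_that("plain singly-charged b+y count is 2(n-1) per side", {
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  fr <- enumerate_fragments(iso_w2, cfg)
  expect_identical(sum(fr$side == "alpha"), 2L * (nchar("AQIPQQL") - 1L))
  expect_identical(sum(fr$side == "beta"), 2L * (nchar("FLKNAGR") - 1L))
  expect_false(any(duplicated(fr[, c("side", "type", "start", "end", "loss", "charge")])))
})

test_that("fragments excluding the crosslink site are unshifted, spanning ions carry the partner", {
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  fr <- enumerate_fragments(iso_w2, cfg)
  b1 <- fr[fr$side == "alpha" & fr$type == "b" & fr$index == 1, ]
  expect_false(b1$carries_partner)
  expect_equal(b1$mz, mass_to_mz(monoisotopic_mass(parse_formula("C3H5NO")), 1),
               tolerance = 1e-9)
  pshift <- monoisotopic_mass(xlink_modification_composition("FLKNAGR"))
  for (j in 6:7 - 1) {  # y6 covers Q2 of the 7-mer
    yj <- fr[fr$side == "alpha" & fr$type == "y" & fr$index == 6, ]
    expect_true(yj$carries_partner)
    expect_equal(yj$mz - mass_to_mz(peptide_mass(substring("AQIPQQL", 2, 7)), 1),
                 pshift, tolerance = 1e-9)
  }
})

test_that("internal ions are interior, bounded, and b-type", {
  fr <- enumerate_fragments(iso_w2, fragment_config(internal_length = c(2, 4)))
  int <- fr[fr$type == "internal", ]
  expect_true(all(int$start >= 2))
  expect_true(all(int$end <= ifelse(int$side == "alpha", 6, 6)))
  expect_true(all(int$end - int$start + 1 >= 2 & int$end - int$start + 1 <= 4))
})

test_that("neutral losses follow residue-content rules", {
  fr <- enumerate_fragments(iso_w2, fragment_config(max_charge = 1, internal = FALSE))
  # alpha b2 = AQ: contains Q -> NH3 allowed, no S/T/E/D and partner carried -> H2O via partner
  b2 <- fr[fr$side == "alpha" & fr$type == "b" & fr$index == 2, ]
  expect_true("NH3" %in% b2$loss)
  b1 <- fr[fr$side == "alpha" & fr$type == "b" & fr$index == 1, ]  # "A" alone
  expect_identical(b1$loss, "none")
  always <- enumerate_fragments(iso_w2, fragment_config(loss_mode = "always",
                                                        max_charge = 1, internal = FALSE))
  expect_gt(nrow(always), nrow(fr))
})

test_that("every enumerated m/z is reproduced by the composition-summation oracle", {
  iso <- isopeptide("VQGQGIIQPQQPAQL", "FLKNAGR", alpha_q_pos = 10, deamidation = 4)
  fr <- enumerate_fragments(iso, fragment_config())
  set.seed(4)
  idx <- sample(nrow(fr), 150)
  want <- vapply(idx, function(i) oracle_fragment_mz(iso, fr[i, ]), numeric(1))
  expect_equal(fr$mz[idx], want, tolerance = 1e-6)
})

test_that("complementary b/y pairs sum to the side-local precursor plus water", {
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  iso <- isopeptide("WQTPEQSR", "AVKGFR", alpha_q_pos = 2)
  fr <- enumerate_fragments(iso, cfg)
  n <- nchar("WQTPEQSR")
  total <- precursor_mass(iso)  # alpha + partner - NH3 (spanning ions included)
  for (i in seq_len(n - 1)) {
    b <- fr[fr$side == "alpha" & fr$type == "b" & fr$index == i, "mz"]
    y <- fr[fr$side == "alpha" & fr$type == "y" & fr$index == n - i, "mz"]
    expect_equal((b - PROTON_MASS) + (y - PROTON_MASS), total, tolerance = 1e-8)
  }
})

test_that("truncated-partner spanning ions extend the enumeration when enabled", {
  fr0 <- enumerate_fragments(iso_w2, fragment_config(max_charge = 1, internal = FALSE))
  fr1 <- enumerate_fragments(iso_w2, fragment_config(max_charge = 1, internal = FALSE,
                                                     truncated_partner = TRUE))
  expect_gt(nrow(fr1), nrow(fr0))
  expect_true(any(grepl("^[by][0-9]+$", fr1$partner_form)))
  # a truncated partner fragment still contains the partner's crosslink residue
  bforms <- unique(fr1$partner_form[grepl("^b", fr1$partner_form) &
                                      fr1$side == "alpha"])
  expect_true(all(as.integer(sub("b", "", bforms)) >= iso_w2$beta_k_pos))
})

test_that("peak matching is one-to-one, nearest-first, intensity tie-broken", {
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  fr <- enumerate_fragments(iso_w2, cfg)
  sp <- list(mz = fr$mz, intensity = rep(1, nrow(fr)))
  expect_identical(nrow(match_fragments(sp, fr, 0.5)), nrow(fr))
  # a single peak displaced beyond tolerance -> unmatched
  one <- fr[1, , drop = FALSE]
  expect_identical(nrow(match_fragments(list(mz = one$mz + 0.6, intensity = 1),
                                        one, 0.5)), 0L)
  # two peaks within tolerance: nearer wins; exact tie -> higher intensity
  sp3 <- list(mz = sort(c(one$mz - 0.3, one$mz + 0.1, one$mz + 0.45)),
              intensity = c(5, 1, 9))
  m3 <- match_fragments(sp3, one, 0.5)
  expect_equal(m3$obs_mz, one$mz + 0.1, tolerance = 1e-9)
  sp4 <- list(mz = c(one$mz - 0.2, one$mz + 0.2), intensity = c(1, 7))
  m4 <- match_fragments(sp4, one, 0.5)
  expect_equal(m4$obs_intensity, 7)
})
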