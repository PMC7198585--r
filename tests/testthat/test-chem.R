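test_that("elemental composition arithmetic is element-wise and signed", {
  a <- elem_comp(C = 2, H = 5, N = 1, O = 2)
  b <- elem_comp(H = 2, O = 1)
  expect_true((a + b) == elem_comp(C = 2, H = 7, N = 1, O = 3))
  expect_true((a - a) == elem_comp())
  dea <- elem_comp(H = -1, N = -1, O = 1)
  expect_true(any(unclass(dea) < 0))
  expect_true((a + dea) == elem_comp(C = 2, H = 4, O = 3))
})

test_that("formula formatting and parsing are inverse functions", {
  for (f in c("C36H57N11O9", "C43H62N16O11S", "H2O", "C17H31N7O5", "S")) {
    expect_identical(format_formula(parse_formula(f)), f)
  }
  expect_error(parse_formula("C36H57xx"), "parse")
  expect_identical(parse_formula(""), elem_comp())
})

test_that("peptide compositions sum residues plus one water, with mods", {
  expect_identical(format_formula(peptide_composition("G")), "C2H5NO2")
  expect_identical(format_formula(peptide_composition("QKR")), "C17H34N8O5")
  expect_identical(format_formula(peptide_composition("FLKNAGR")), "C36H60N12O9")
  # deamidation: -H -N +O; oxidation: +O
  base <- peptide_composition("QMR")
  expect_true(peptide_composition("QMR", deamidation = 1) ==
                base + elem_comp(H = -1, N = -1, O = 1))
  expect_true(peptide_composition("QMR", oxidation = 2) == base + elem_comp(O = 1))
  expect_error(peptide_composition("QBZ"), "position 2")
  expect_error(peptide_composition("QMR", deamidation = 2), "position 2")
  expect_error(peptide_composition(""), "non-empty")
})

test_that("concatenation additivity: comp(s1 s2) = comp(s1) + comp(s2) - H2O", {
  set.seed(1)
  aa <- names(glutenxl:::.RESIDUE_FORMULAS)
  h2o <- elem_comp(H = 2, O = 1)
  for (i in 1:20) {
    s1 <- paste(sample(aa, sample(1:12, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_true(peptide_composition(paste0(s1, s2)) ==
                  peptide_composition(s1) + peptide_composition(s2) - h2o)
  }
})

test_that("the seven TG2 crosslink modifications reproduce the printed formulas", {
  printed <- c(FLKNAGR = "C36H57N11O9", WKNHGCQR = "C43H62N16O11S",
               ISTKSVGR = "C35H63N11O12", LAEKEETGMAMR = "C55H93N15O20S2",
               DLYLENPEIKIR = "C68H108N16O21", QKR = "C17H31N7O5",
               AVKGFR = "C31H49N9O7")
  for (pep in names(printed)) {
    expect_identical(format_formula(xlink_modification_composition(pep)),
                     unname(printed[pep]), label = pep)
  }
  expect_error(xlink_modification_composition("AGQR"), "lysine")
})

test_that("monoisotopic masses are linear and match IUPAC atomic masses", {
  expect_identical(monoisotopic_mass(elem_comp()), 0)
  expect_equal(monoisotopic_mass(parse_formula("H2O")), 18.0105646, tolerance = 1e-7)
  expect_equal(monoisotopic_mass(elem_comp(H = -1, N = -1, O = 1)),
               0.9840156, tolerance = 1e-7)
  expect_error(monoisotopic_mass(elem_comp(Xx = 1)), "mass entry")
  # the NH3 subtraction identity, to 1e-9 Da
  for (pep in TG2_DONOR_PEPTIDES) {
    expect_equal(monoisotopic_mass(xlink_modification_composition(pep)),
                 monoisotopic_mass(peptide_composition(pep)) -
                   monoisotopic_mass(elem_comp(N = 1, H = 3)),
                 tolerance = 1e-9)
  }
})

test_that("average mass exceeds monoisotopic mass for C-rich molecules", {
  comp <- peptide_composition("FLKNAGR")
  expect_gt(average_mass(comp), monoisotopic_mass(comp))
})

test_that("m/z conversion is protonation bookkeeping and inverts", {
  m <- 1583.8776
  for (z in 1:5) {
    expect_equal(mass_to_mz(m, z), (m + z * PROTON_MASS) / z)
    expect_equal(mz_to_mass(mass_to_mz(m, z), z), m, tolerance = 1e-10)
  }
})

test_that("isotope distributions match elementary expectations", {
  h <- isotope_distribution(elem_comp(H = 1), 2)
  expect_equal(h$abundance, c(0.999885, 0.000115) / sum(c(0.999885, 0.000115)),
               tolerance = 1e-12)
  c100 <- isotope_distribution(parse_formula("C100"), 2)
  expect_equal(c100$abundance[2] / c100$abundance[1], 100 * 0.0107 / 0.9893,
               tolerance = 1e-10)
  d <- isotope_distribution(peptide_composition("QKR"), 5)
  expect_equal(sum(d$abundance), 1, tolerance = 1e-12)
  expect_true(all(diff(d$abundance[which.max(d$abundance):5]) <= 0))
  expect_error(isotope_distribution(elem_comp(H = -1, O = 1), 2), "physical")
})

test_that("isotope convolution agrees with exhaustive enumeration", {
  comps <- list(parse_formula("H2O"), parse_formula("C3H5NOS"),
                peptide_composition("QKR") - elem_comp(C = 10, H = 20),
                elem_comp(C = 10, H = 12, N = 4, O = 3),
                elem_comp(C = 5, S = 3))
  for (comp in comps) {
    comp <- elem_comp(unclass(comp)[unclass(comp) > 0])
    got <- isotope_distribution(comp, 4)$abundance
    want <- oracle_isotope_enum(comp, 4)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("residue table constants are internally consistent", {
  rt <- residue_table()
  expect_true(rt$water == elem_comp(H = 2, O = 1))
  expect_true(rt$ammonia == elem_comp(N = 1, H = 3))
  # cysteine ships unalkylated (free thiol): required by the WKNHGCQR formula
  expect_true(rt$C == parse_formula("C3H5NOS"))
  expect_identical(
    format_formula(peptide_composition("WKNHGCQR", carbamidomethyl = TRUE)),
    format_formula(peptide_composition("WKNHGCQR") + rt$carbamidomethyl))
})
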