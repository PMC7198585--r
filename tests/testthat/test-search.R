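test_that("binomial score matches the exhaustive-tail oracle and is monotone", {
  expect_identical(score_match(0, 20, 0.05), 0)
  grid <- expand.grid(n = c(5, 20, 60), p = c(0.01, 0.05, 0.2))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]; p <- grid$p[g]
    scores <- vapply(0:n, function(m) score_match(m, n, p), numeric(1))
    expect_true(all(diff(scores) > 0))
    for (m in c(1, ceiling(n / 3), n)) {
      # agreement asserted on the tail probability itself, to 1e-9
      expect_lt(abs(10^(-score_match(m, n, p) / 10) - oracle_binom_tail(m, n, p)),
                1e-9)
      expect_equal(score_match(m, n, p),
                   -10 * log10(oracle_binom_tail(m, n, p)), tolerance = 1e-6)
    }
  }
  expect_error(score_match(1, 0, 0.1), "theoretical")
})

test_that("chance-match probability scales with peak density and window", {
  sp <- list(mz = seq(200, 1200, by = 10), intensity = rep(1, 101))
  expect_equal(chance_match_prob(sp, 0.5), 101 * 1 / 1000, tolerance = 1e-12)
  expect_equal(chance_match_prob(list(mz = numeric(0)), 0.5), 1e-6)
})

test_that("site localization is a softmax over placements and sums to one", {
  iso <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2)
  sp <- perfect_spectrum(iso)
  placements <- lapply(c(2, 5, 6), function(q)
    isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = q))
  loc <- localize_sites(sp, placements)
  expect_equal(sum(loc$placements$prob), 1, tolerance = 1e-12)
  xl <- loc$sites[loc$sites$kind == "crosslink", ]
  expect_equal(sum(xl$prob), 1, tolerance = 1e-12)
  expect_gt(xl$prob[xl$pos == 2], 0.75)
  expect_true(xl$localized[xl$pos == 2])
  # a single admissible placement has probability one
  loc1 <- localize_sites(sp, placements[1])
  expect_equal(loc1$placements$prob, 1)
})

test_that("placements with identical matched evidence split probability equally", {
  iso <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2)
  # spectrum with only ions common to Q5/Q6 placements (nothing between them)
  p5 <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 5)
  p6 <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 6)
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  f5 <- enumerate_fragments(p5, cfg); f6 <- enumerate_fragments(p6, cfg)
  common <- intersect(round(f5$mz, 6), round(f6$mz, 6))
  sp <- ms2_spectrum(common, rep(1, length(common)), precursor_mz = 500)
  loc <- localize_sites(sp, list(p5, p6),
                        search_config(fragment = cfg))
  expect_equal(loc$placements$prob, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("site-determining b-ion ladders localize the crosslink above threshold", {
  # Q10 vs Q11 of a gamma-gliadin-like 15-mer: b6-b10 pin the site to Q10
  iso10 <- isopeptide("VQGQGIIQPQQPAQL", "FLKNAGR", alpha_q_pos = 10, deamidation = 4)
  cfg <- fragment_config(ion_types = c("b", "y"), losses = character(0),
                         max_charge = 1, internal = FALSE)
  fr <- enumerate_fragments(iso10, cfg)
  keep <- fr[fr$side == "beta" | (fr$type == "b" & fr$index %in% 5:11), ]
  sp <- ms2_spectrum(keep$mz, rep(1, nrow(keep)),
                     precursor_mz = mass_to_mz(precursor_mass(iso10), 2))
  placements <- lapply(setdiff(which(strsplit("VQGQGIIQPQQPAQL", "")[[1]] == "Q"), 4),
                       function(q) isopeptide("VQGQGIIQPQQPAQL", "FLKNAGR",
                                              alpha_q_pos = q, deamidation = 4))
  loc <- localize_sites(sp, placements, search_config(fragment = cfg))
  xl <- loc$sites[loc$sites$kind == "crosslink", ]
  expect_gt(xl$prob[xl$pos == 10], 0.75)
  expect_true(all(xl$prob[xl$pos != 10] < 0.25))
})

test_that("a full-coverage synthetic spectrum is identified rank-1 with its sites", {
  gluten <- load_gluten_proteins()
  iso <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2)
  sp <- perfect_spectrum(iso, charge = 2)
  res <- run_discovery_search(list(sp), gluten, "FLKNAGR", search_config())
  expect_identical(nrow(res), 1L)
  expect_identical(res$alpha, "AQIPQQL")
  expect_identical(res$q_pos, 2L)
  expect_identical(res$deamidation, "")
  expect_gt(res$score, 40)
  expect_gt(res$q_prob, 0.75)
  expect_gt(res$idotp, 0.99)
})

test_that("empty and malformed spectra are handled gracefully", {
  gluten <- load_gluten_proteins()
  expect_identical(nrow(run_discovery_search(list(), gluten, "FLKNAGR")), 0L)
  expect_warning(
    res <- run_discovery_search(list(list(id = "bad", mz = NULL)),
                                gluten, "FLKNAGR"),
    "malformed")
  expect_identical(nrow(res), 0L)
})

test_that("noise-only spectra from negative controls never clear the score threshold", {
  set.seed(5)
  gluten <- load_gluten_proteins()
  cfg <- search_config()
  for (i in 1:10) {
    sp <- ms2_spectrum(runif(50, 100, 1500), rlnorm(50, 5, 1),
                       precursor_mz = runif(1, 400, 1100),
                       precursor_charge = sample(2:4, 1), rt = 10)
    res <- run_discovery_search(list(sp), gluten, "FLKNAGR", cfg)
    expect_identical(nrow(res), 0L)
  }
})

test_that("shuffled decoys lose to the true sequence on true-positive spectra", {
  set.seed(6)
  gluten <- load_gluten_proteins()
  cfg <- search_config(fragment = fragment_config(internal = FALSE, max_charge = 2))
  wins <- 0L; trials <- 0L
  for (alpha in c("AQIPQQL", "WQIPEQSR", "VQGQGIIQPQQPAQL", "WQTPEQSR")) {
    for (rep_ in 1:5) {
      q <- which(strsplit(alpha, "")[[1]] == "Q")[1]
      iso <- isopeptide(alpha, "FLKNAGR", alpha_q_pos = q)
      sp <- perfect_spectrum(iso, config = cfg$fragment)
      res <- run_discovery_search(list(sp), gluten, "FLKNAGR",
                                  cfg, include_decoys = TRUE)
      trials <- trials + 1L
      if (nrow(res) == 1L && !res$decoy && res$alpha == alpha) wins <- wins + 1L
    }
  }
  expect_gte(wins / trials, 0.95)
})

test_that("reciprocal alpha-base and beta-base searches agree", {
  iso <- isopeptide("VQGQGIIQPQQPAQL", "FLKNAGR", alpha_q_pos = 10, deamidation = 4)
  sp <- perfect_spectrum(iso, charge = 3)
  base_a <- data.frame(sequence = "VQGQGIIQPQQPAQL", protein = "g", start = 1,
                       end = 15, missed = 0, nterm_specific = TRUE,
                       cterm_specific = TRUE, stringsAsFactors = FALSE)
  base_b <- data.frame(sequence = "FLKNAGR", protein = "TG2", start = 1,
                       end = 7, missed = 1, nterm_specific = TRUE,
                       cterm_specific = TRUE, stringsAsFactors = FALSE)
  ra <- run_discovery_search(list(sp), base_a, "FLKNAGR", search_config())
  rb <- run_discovery_search(list(sp), base_b, "VQGQGIIQPQQPAQL",
                             search_config(), base_side = "beta",
                             partner_deamidation = 4)
  expect_identical(ra$alpha, rb$alpha)
  expect_identical(ra$q_pos, rb$q_pos)
  expect_equal(ra$precursor_mz, rb$precursor_mz, tolerance = 1e-9)
})

test_that("rank-1 identification accuracy exceeds 95% at 80% coverage with noise", {
  cfg <- simulation_config(seed = 21, n_proteins = 10, n_isopeptides = 34,
                           coverage = 0.8, noise_peaks = 25)
  man <- generate_reference_set(cfg)
  sim <- simulate_dda_run(man, cfg)
  scfg <- search_config(fragment = fragment_config(internal = FALSE, max_charge = 2),
                        max_placements = 32)
  pep <- digest_database(man$proteins, enzymes = scfg$enzymes, max_missed = 2,
                         min_length = 5, max_length = 30)
  truth <- man$truth
  n_total <- 0L; n_correct <- 0L
  for (rn in paste0("S", 1:3)) {
    for (sp in sim$runs[[rn]]) {
      id <- sub("^S[0-9]+_", "", sp$id)
      tr <- truth[truth$id == id, ]
      res <- run_discovery_search(list(sp), pep, tr$beta, scfg)
      n_total <- n_total + 1L
      if (nrow(res) == 1L && res$alpha == tr$alpha && res$q_pos == tr$q_pos)
        n_correct <- n_correct + 1L
    }
  }
  expect_gte(n_total, 100L)
  expect_gte(n_correct / n_total, 0.95)
})

test_that("YAML configuration round-trips into a search config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("precursor_tol_ppm: 10", "min_score: 25", "max_missed: 1"), path)
  cfg <- read_search_config(path)
  expect_equal(cfg$precursor_tol_ppm, 10)
  expect_equal(cfg$min_score, 25)
  expect_identical(cfg$max_missed, 1L)
  writeLines("bogus_key: 1", path)
  expect_error(read_search_config(path), "unknown configuration")
})
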