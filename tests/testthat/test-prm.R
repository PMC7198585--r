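iso_a <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2, id = "isoA")
iso_b <- isopeptide("WQTPEQSR", "AVKGFR", alpha_q_pos = 2, id = "isoB")

test_that("isolation lists cover both representations at every charge", {
  tab <- build_isolation_list(list(iso_a), charges = 2:3)
  expect_identical(nrow(tab), 4L)
  expect_setequal(unique(sub(".*\\|", "", tab$name)), c("alpha-base", "beta-base"))
  for (z in 2:3) {
    rows <- tab[tab$charge == z, ]
    expect_equal(rows$mz[1], rows$mz[2], tolerance = 1e-9)  # same molecule
    expect_equal(rows$mz[1], round(mass_to_mz(precursor_mass(iso_a), z), 6),
                 tolerance = 1e-6)
  }
  # round trip through the TSV dialect is exact
  path <- tempfile(fileext = ".tsv")
  write_isolation_list(tab, path)
  expect_identical(read_isolation_list(path), tab)
})

test_that("PRM transitions are loss-free singly charged b/y ions", {
  tr <- prm_transitions(iso_a)
  expect_setequal(unique(tr$type), c("b", "y"))
  # 2(n-1) singly charged b+y ions per side
  expect_identical(nrow(tr), 2L * (nchar("AQIPQQL") - 1L) +
                     2L * (nchar("FLKNAGR") - 1L))
})

test_that("chromatogram extraction respects the isolation window", {
  sim <- simulate_prm_run(list(isoA = iso_a), simulation_config(seed = 31))
  tr <- prm_transitions(iso_a)
  pmz <- mass_to_mz(precursor_mass(iso_a), 2)
  ch <- extract_chromatograms(sim$runs$PS1, pmz, tr, tol = 0.5)
  expect_gt(length(ch$rt), 10)
  expect_identical(ncol(ch$intensity), nrow(tr))
  # a far-away precursor collects no scans; empty chromatogram, not an error
  ch0 <- extract_chromatograms(sim$runs$PS1, pmz + 50, tr, tol = 0.5)
  expect_identical(length(ch0$rt), 0L)
})

test_that("peak picking recovers apex and area of a Gaussian trace", {
  rt <- seq(0, 2, by = 0.02)
  y <- 1000 * exp(-(rt - 1)^2 / (2 * 0.1^2))
  pk <- pick_peak(rt, y)
  expect_true(pk$detected)
  expect_equal(pk$apex_rt, 1, tolerance = 0.02)
  # trapezoidal area vs the analytic Gaussian integral, within 5%
  expect_equal(pk$area, 1000 * 0.1 * sqrt(2 * pi), tolerance = 0.05)
  expect_false(pick_peak(rt, rep(0, length(rt)))$detected)
})

test_that("co-eluting transitions confirm; dropouts and controls reject", {
  cfg <- simulation_config(seed = 32)
  isos <- list(isoA = iso_a, isoB = iso_b)
  sim <- simulate_prm_run(isos, cfg)
  ev <- list()
  for (rn in names(sim$runs)) {
    for (id in names(isos)) {
      tr <- prm_transitions(isos[[id]])
      ch <- extract_chromatograms(sim$runs[[rn]],
                                  mass_to_mz(precursor_mass(isos[[id]]), 2), tr)
      sm <- summarize_prm_target(ch)
      ev[[length(ev) + 1L]] <- data.frame(isopeptide = id, run = rn,
                                          n_coeluting_by = sm$n_coeluting_by,
                                          max_series = sm$max_series,
                                          apex_rt = sm$apex_rt)
    }
  }
  ev <- do.call(rbind, ev)
  verdicts <- prm_confirm(ev, sim$design)
  expect_identical(verdicts$verdict, c("confirmed", "confirmed"))
  # all transitions co-elute at the same apex
  expect_true(all(ev$n_coeluting_by[ev$run == "PS1"] >= 7))
  # discovery retention time consistency is enforced when provided
  off <- prm_confirm(ev, sim$design,
                     discovery_rt = c(isoA = sim$apex_rt[["isoA"]] + 5,
                                      isoB = sim$apex_rt[["isoB"]]))
  expect_match(off$reasons[off$isopeptide == "isoA"], "retention-time")
  expect_identical(off$verdict[off$isopeptide == "isoB"], "confirmed")
})

test_that("six transitions or control signals are insufficient", {
  d <- run_design("PS1", "PC1")
  ev <- data.frame(isopeptide = "x", run = c("PS1", "PC1"),
                   n_coeluting_by = c(6L, 0L), max_series = c(4L, 0L),
                   apex_rt = c(20, NA))
  expect_match(prm_confirm(ev, d)$reasons, "min-fragments")
  ev$n_coeluting_by <- c(9L, 2L)
  expect_match(prm_confirm(ev, d)$reasons, "negative-control")
  ev$n_coeluting_by <- c(9L, 0L)
  expect_identical(prm_confirm(ev, d)$verdict, "confirmed")
  expect_error(prm_confirm(ev, list(samples = "PS1", controls = NULL)), "controls")
})

test_that("PRM verdicts are monotone in transition count and series length", {
  d <- run_design(paste0("PS", 1:3), "PC1")
  base <- data.frame(isopeptide = "x", run = paste0("PS", 1:3),
                     n_coeluting_by = 5L, max_series = 2L, apex_rt = 20)
  rank_v <- function(v) match(v, c("rejected", "confirmed"))
  prev <- rank_v(prm_confirm(base, d)$verdict)
  for (step in 1:4) {
    base$n_coeluting_by <- base$n_coeluting_by + 1L
    base$max_series <- base$max_series + 1L
    cur <- rank_v(prm_confirm(base, d)$verdict)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_identical(prev, 2L)
})

test_that("site-determining transitions assign the injected site exhaustively", {
  alpha <- "VQGQGIIQPQQPAQL"
  qs <- c(8, 10, 11)
  for (true_q in qs) {
    cands <- lapply(qs, function(q) isopeptide(alpha, "FLKNAGR", alpha_q_pos = q))
    names(cands) <- paste0("Q", qs)
    # inject only the true site's transitions; withhold the others entirely
    sim <- simulate_prm_run(stats::setNames(cands[paste0("Q", true_q)], "t"),
                            simulation_config(seed = 33 + true_q))
    res <- assign_prm_site(sim$runs$PS1, cands, charge = 2)
    expect_identical(res$assigned, paste0("Q", true_q))
  }
})

test_that("simulated PRM runs are seed-deterministic", {
  a <- simulate_prm_run(list(isoA = iso_a), simulation_config(seed = 40))
  b <- simulate_prm_run(list(isoA = iso_a), simulation_config(seed = 40))
  expect_identical(a$runs, b$runs)
  expect_identical(a$expected$expected, "confirmed")
})
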