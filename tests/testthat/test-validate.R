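test_that("consecutive series counts runs within a single ladder only", {
  expect_identical(
    max_consecutive_series(data.frame(side = "alpha", type = "b", index = 6:8)), 3L)
  expect_identical(max_consecutive_series(data.frame(side = character(0),
                                                     type = character(0),
                                                     index = integer(0))), 0L)
  m <- data.frame(side = "alpha", type = c("b", "b", "y", "y", "y", "y"),
                  index = c(2, 3, 5, 6, 7, 8))
  expect_identical(max_consecutive_series(m), 4L)  # b and y ladders never join
  # charge and loss variants collapse onto the same ladder index
  m2 <- data.frame(side = "alpha", type = "b", index = c(4, 4, 5, 5, 6),
                   charge = c(1, 2, 1, 2, 1), loss = c("none", "NH3", "none", "H2O", "none"))
  expect_identical(max_consecutive_series(m2), 3L)
  # ladders on different sides are distinct
  m3 <- data.frame(side = c("alpha", "beta"), type = "b", index = c(3, 4))
  expect_identical(max_consecutive_series(m3), 1L)
})

test_that("idotp is the cosine of expected and observed envelopes", {
  expect_equal(idotp(c(0.6, 0.3, 0.1), c(1.2, 0.6, 0.2)), 1, tolerance = 1e-12)
  expect_equal(idotp(c(1, 0), c(0, 1)), 0)
  # hand-computed: 0.43 / (sqrt(0.46) * sqrt(0.42))
  expect_equal(idotp(c(0.6, 0.3, 0.1), c(0.5, 0.4, 0.1)),
               0.43 / (sqrt(0.46) * sqrt(0.42)), tolerance = 1e-12)
  expect_error(idotp(c(0.6, 0.4), c(0, 0)), "zero")
  expect_error(idotp(c(0.6, 0.4), c(1, -1)), "non-negative")
  expect_error(idotp(c(0.6, 0.4), c(1, 1, 1)), "length")
})

ev_row <- function(iso = "x", run = "S1", rt = 30, n_by = 10, series = 4,
                   idp = 0.99, q = 0.95) {
  data.frame(isopeptide = iso, run = run, rt = rt, n_by = n_by,
             max_series = series, idotp = idp, q_prob = q,
             stringsAsFactors = FALSE)
}
full_ev <- function(...) do.call(rbind, lapply(paste0("S", 1:3), function(r) ev_row(run = r, ...)))
design3 <- run_design(paste0("S", 1:3), paste0("C", 1:3))

test_that("the confirmation rules fire with enumerated reason codes", {
  expect_identical(apply_confirmation(full_ev(), design3)$verdict, "confirmed")
  r <- apply_confirmation(full_ev(n_by = 6), design3)
  expect_identical(r$verdict, "rejected")
  expect_identical(r$reasons, "min-fragments")
  r <- apply_confirmation(full_ev(q = 0.74), design3)
  expect_identical(r$verdict, "ambiguous-site")
  expect_identical(r$reasons, "localization")
  r <- apply_confirmation(rbind(full_ev(), ev_row(run = "C2")), design3)
  expect_identical(r$verdict, "rejected")
  expect_match(r$reasons, "negative-control")
  r <- apply_confirmation(full_ev()[1:2, ], design3)
  expect_match(r$reasons, "replicates")
  r <- apply_confirmation(full_ev(series = 2), design3)
  expect_match(r$reasons, "consecutive-series")
  r <- apply_confirmation(full_ev(idp = 0.85), design3)
  expect_match(r$reasons, "idotp")
  ev <- full_ev(); ev$rt <- c(30, 30, 32)
  expect_match(apply_confirmation(ev, design3)$reasons, "retention-time")
  # verdict is reconstructable: confirmed iff the reason set is empty
  for (ev2 in list(full_ev(), full_ev(n_by = 3), full_ev(q = 0.5))) {
    r2 <- apply_confirmation(ev2, design3)
    expect_identical(r2$verdict == "confirmed", r2$reasons == "")
  }
})

test_that("design errors are explicit", {
  expect_error(run_design(character(0), "C1"), "sample")
  expect_error(run_design("S1", character(0)), "control")
  expect_error(run_design("S1", "S1"), "both")
  expect_error(apply_confirmation(ev_row(run = "S9"), design3), "not in the design")
  expect_error(apply_confirmation(full_ev()[, -3], design3), "missing column")
})

test_that("k-of-n replicate policy is configurable", {
  two <- full_ev()[1:2, ]
  expect_identical(apply_confirmation(two, design3)$verdict, "rejected")
  expect_identical(
    apply_confirmation(two, design3,
                       confirmation_thresholds(k_of_n = 2))$verdict[1],
    "confirmed")
})

test_that("verdicts are threshold-monotone under single-value improvements", {
  set.seed(8)
  rank_v <- function(v) match(v, c("rejected", "ambiguous-site", "confirmed"))
  for (i in 1:40) {
    ev <- full_ev(n_by = sample(4:10, 1), series = sample(1:5, 1),
                  idp = runif(1, 0.8, 1), q = runif(1, 0.5, 1))
    before <- rank_v(apply_confirmation(ev, design3)$verdict)
    col <- sample(c("n_by", "max_series", "idotp", "q_prob"), 1)
    ev2 <- ev
    ev2[[col]] <- ev2[[col]] + if (col %in% c("n_by", "max_series")) 2 else 0.2
    after <- rank_v(apply_confirmation(ev2, design3)$verdict)
    expect_gte(after, before)
  }
})

test_that("confirmation reports are written with a verdict summary", {
  path <- tempfile(fileext = ".tsv")
  r <- apply_confirmation(full_ev(), design3)
  expect_message(write_confirmation_report(r, path), "confirmed=1")
  expect_identical(utils::read.delim(path)$verdict, "confirmed")
})
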