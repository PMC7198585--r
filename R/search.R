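# Discovery-mode identification: candidate isopeptides per spectrum, binomial
# match scoring, and crosslink/deamidation site-localization probabilities.
#
# The score is an explicit binomial survival score (not a clone of any search
# engine's proprietary formula): -10*log10 P(X >= matched) with X ~
# Binomial(theoretical, p) and p the per-fragment chance-match probability
# estimated from the spectrum's peak density.

#' Search configuration
#'
#' @param precursor_tol_ppm precursor mass tolerance in ppm (default 4.5).
#' @param fragment_tol fragment tolerance in Da (default 0.5).
#' @param deamidation allow variable deamidation at N/Q (+0.984 Da).
#' @param oxidation allow variable oxidation at M (+15.995 Da).
#' @param max_mods maximum variable modifications per peptide, counting the
#'   crosslink modification (default 5).
#' @param min_score minimum score for (modified) peptide matches (default 40).
#' @param enzymes digestion enzymes for the base database.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_length,max_length candidate peptide length bounds (default 5-30).
#' @param localization_threshold probability above which a site is called
#'   localized (default 0.75).
#' @param max_placements cap on site placements scored per candidate.
#' @param fragment a \code{\link{fragment_config}}.
#' @param charges precursor charges tried when a spectrum lacks one.
#' @return a config list.
#' @export
search_config <- function(precursor_tol_ppm = 4.5, fragment_tol = 0.5,
                          deamidation = TRUE, oxidation = FALSE,
                          max_mods = 5L, min_score = 40,
                          enzymes = c("trypsin", "pepsin", "chymotrypsin"),
                          max_missed = 2L, min_length = 5L, max_length = 30L,
                          localization_threshold = 0.75,
                          max_placements = 200L,
                          fragment = fragment_config(),
                          charges = 2:5) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol > 0, max_mods >= 1L,
            localization_threshold > 0, localization_threshold < 1)
  list(precursor_tol_ppm = precursor_tol_ppm, fragment_tol = fragment_tol,
       deamidation = isTRUE(deamidation), oxidation = isTRUE(oxidation),
       max_mods = as.integer(max_mods), min_score = min_score,
       enzymes = enzymes, max_missed = as.integer(max_missed),
       min_length = as.integer(min_length), max_length = as.integer(max_length),
       localization_threshold = localization_threshold,
       max_placements = as.integer(max_placements),
       fragment = fragment, charges = as.integer(charges))
}

#' Per-fragment chance-match probability of a spectrum
#'
#' Estimated as peak density times the matching window width (2 * tol),
#' clamped to (1e-6, 0.99).
#'
#' @param spectrum a spectrum list.
#' @param tol fragment tolerance in Da.
#' @return probability that a random theoretical m/z matches some peak.
#' @export
chance_match_prob <- function(spectrum, tol) {
  n <- length(spectrum$mz)
  if (n == 0L) return(1e-6)
  span <- max(spectrum$mz) - min(spectrum$mz)
  if (span <= 0) span <- 2 * tol
  min(max(n * 2 * tol / span, 1e-6), 0.99)
}

#' Binomial survival score of a fragment match
#'
#' \code{-10 * log10 P(X >= matched)} with \code{X ~ Binomial(theoretical, p)}.
#' Zero matches score 0; the score is strictly increasing in the number of
#' matched fragments.
#'
#' @param matched_count matched theoretical fragments (0..theoretical).
#' @param theoretical_count total theoretical fragments (> 0).
#' @param p_chance per-fragment chance-match probability in (0, 1).
#' @return non-negative score.
#' @export
score_match <- function(matched_count, theoretical_count, p_chance) {
  stopifnot(theoretical_count > 0, matched_count >= 0,
            matched_count <= theoretical_count, p_chance > 0, p_chance < 1)
  if (matched_count == 0) return(0)
  logp <- stats::pbinom(matched_count - 1, theoretical_count, p_chance,
                        lower.tail = FALSE, log.p = TRUE)
  -10 * logp / log(10)
}

# Unique b/y fragment count (side, type, index), collapsing charge and loss.
.count_by_fragments <- function(matched) {
  m <- matched[matched$type %in% c("b", "y"), , drop = FALSE]
  if (nrow(m) == 0L) return(0L)
  nrow(unique(m[, c("side", "type", "index")]))
}

# Best deamidation combination for a fixed crosslink site, by dynamic
# programming over the b/y ladder: the number of deamidations within a
# prefix shifts its b ions by k * 0.984 Da (and the complementary y ions by
# (n_dea - k) * 0.984), so the observed ladders determine the increment
# profile. Exact when the distinguishing ions are present; used only when
# exhaustive combination enumeration would exceed the placement cap.
.best_dea_combo <- function(spectrum, sequence, q_pos, n_dea, partner_mass,
                            tol, zmax = 2L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  P <- c(0, cumsum(.side_residue_masses(sequence)))
  dd <- 0.984015585
  h2o <- .loss_masses[["H2O"]]
  eligible <- res %in% c("N", "Q") & seq_len(n) != q_pos
  if (sum(eligible) < n_dea) return(NULL)
  mz <- spectrum$mz
  # closeness-weighted match quality in [0, 1]: exact hits count more than
  # far ones, which separates true ladder ions (small jitter) from chance
  # co-incidences in dense spectra
  peak_gain <- function(m, z) {
    x <- (m + z * PROTON_MASS) / z
    i <- findInterval(x, mz)
    d <- Inf
    if (i >= 1L) d <- min(d, abs(mz[i] - x))
    if (i < length(mz)) d <- min(d, abs(mz[i + 1L] - x))
    if (d > tol) 0 else (tol - d) / tol
  }
  nh3 <- .loss_masses[["NH3"]]
  co <- 12 + 15.99491461956
  # only charge states that can discriminate the deamidation shift carry
  # information here: the shift is dd/z, which must exceed the tolerance
  zs <- seq_len(zmax)
  zs <- zs[dd / zs > tol]
  if (!length(zs)) zs <- 1L
  gain <- function(i, k) {
    b <- P[i + 1L] + k * dd + if (i >= q_pos) partner_mass else 0
    y <- (P[n + 1L] - P[i + 1L]) + h2o + (n_dea - k) * dd +
      if (q_pos > i) partner_mass else 0
    g <- 0
    for (z in zs) {
      g <- g + peak_gain(b, z) + peak_gain(y, z) + peak_gain(b - co, z) +
        peak_gain(b - nh3, z) + peak_gain(y - nh3, z)
    }
    g
  }
  NEG <- -1e9
  dp <- matrix(NEG, nrow = n + 1L, ncol = n_dea + 1L)
  choice <- matrix(0L, nrow = n + 1L, ncol = n_dea + 1L)  # 1 = dea at residue i
  dp[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (k in 0:n_dea) {
      stay <- dp[i, k + 1L]
      inc <- if (eligible[i] && k >= 1L) dp[i, k] else NEG
      if (max(stay, inc) <= NEG / 2) next
      take_inc <- inc > stay
      g <- if (i < n) gain(i, k) else 0L
      dp[i + 1L, k + 1L] <- max(stay, inc) + g
      choice[i + 1L, k + 1L] <- as.integer(take_inc)
    }
  }
  if (dp[n + 1L, n_dea + 1L] <= NEG / 2) return(NULL)
  sites <- integer(0)
  k <- n_dea
  for (i in n:1) {
    if (choice[i + 1L, k + 1L] == 1L) {
      sites <- c(i, sites)
      k <- k - 1L
    }
  }
  sites
}

# Admissible site placements for a gluten-side sequence given counts of
# deamidations/oxidations implied by the precursor mass.
.placements <- function(sequence, n_dea, n_ox, max_placements) {
  res <- strsplit(sequence, "")[[1]]
  qpos <- which(res == "Q")
  if (!length(qpos)) return(list())
  nq_sites <- which(res %in% c("N", "Q"))
  m_sites <- which(res == "M")
  if (n_ox > length(m_sites)) return(list())
  # combn over index positions: combn(x, m) with scalar x means seq_len(x)
  combos <- function(pool, m) {
    if (m == 0L) return(list(integer(0)))
    lapply(utils::combn(seq_along(pool), m, simplify = FALSE),
           function(i) pool[i])
  }
  ox_sets <- combos(m_sites, n_ox)
  out <- list()
  for (q in qpos) {
    dea_pool <- setdiff(nq_sites, q)
    if (n_dea > length(dea_pool)) next
    dea_sets <- combos(dea_pool, n_dea)
    for (ds in dea_sets) for (os in ox_sets) {
      out[[length(out) + 1L]] <- list(q_pos = q, deamidation = ds, oxidation = os)
      if (length(out) >= max_placements) return(out)
    }
  }
  out
}

#' Localize crosslink and deamidation sites
#'
#' Scores each admissible site placement with the binomial score on its own
#' theoretical fragment set, converts scores to placement probabilities by a
#' softmax over \code{10^(score/10)}, and sums placement probabilities per
#' site. Sites above the threshold are flagged localized.
#'
#' @param spectrum a spectrum list.
#' @param placements list of \code{\link{isopeptide}} objects differing only
#'   in crosslink/deamidation/oxidation positions.
#' @param config a \code{\link{search_config}}.
#' @return list with \code{placements} (data.frame: q_pos, deamidation,
#'   score, prob) and \code{sites} (data.frame: kind, pos, prob, localized).
#' @export
localize_sites <- function(spectrum, placements, config = search_config()) {
  stopifnot(length(placements) >= 1L)
  p_chance <- chance_match_prob(spectrum, config$fragment_tol)
  scores <- numeric(length(placements))
  matched_n <- integer(length(placements))
  for (i in seq_along(placements)) {
    fr <- enumerate_fragments(placements[[i]], config$fragment)
    mm <- match_fragments(spectrum, fr, config$fragment_tol)
    matched_n[i] <- nrow(mm)
    scores[i] <- score_match(nrow(mm), nrow(fr), p_chance)
  }
  .localization_from_scores(placements, scores, matched_n, config)
}

# softmax over 10^(score/10) and per-site aggregation; shared by
# localize_sites and the discovery search (which already has the scores)
.localization_from_scores <- function(placements, scores, matched_n, config) {
  w <- 10^((scores - max(scores)) / 10)
  prob <- w / sum(w)
  pl <- data.frame(
    q_pos = vapply(placements, function(x) x$alpha_q_pos, integer(1)),
    deamidation = vapply(placements, function(x) paste(x$deamidation, collapse = ","), character(1)),
    oxidation = vapply(placements, function(x) paste(x$oxidation, collapse = ","), character(1)),
    score = scores, n_matched = matched_n, prob = prob,
    stringsAsFactors = FALSE)
  qsites <- sort(unique(pl$q_pos))
  site_rows <- lapply(qsites, function(q)
    data.frame(kind = "crosslink", pos = q, prob = sum(prob[pl$q_pos == q])))
  dsites <- sort(unique(unlist(lapply(placements, function(x) x$deamidation))))
  site_rows <- c(site_rows, lapply(dsites, function(d) {
    has <- vapply(placements, function(x) d %in% x$deamidation, logical(1))
    data.frame(kind = "deamidation", pos = d, prob = sum(prob[has]))
  }))
  sites <- do.call(rbind, site_rows)
  sites$localized <- sites$prob > config$localization_threshold
  list(placements = pl, sites = sites)
}

#' Shuffled-sequence decoy peptide
#'
#' Shuffles the interior residues (termini fixed) with the current RNG state;
#' seed upstream for reproducibility.
#'
#' @param sequence peptide sequence.
#' @return shuffled sequence of identical composition.
#' @export
make_decoy <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n <= 3L) return(paste(rev(res), collapse = ""))
  mid <- res[2:(n - 1L)]
  paste(c(res[1L], sample(mid), res[n]), collapse = "")
}

#' Discovery search for crosslinked isopeptides
#'
#' For each MS2 spectrum, candidates are digested base-side peptides whose
#' mass plus the active crosslink modification (partner peptide minus NH3)
#' plus deamidation/oxidation deltas matches the precursor within the ppm
#' tolerance. Each candidate is expanded over admissible site placements,
#' scored, and ranked; matches below \code{min_score} are removed.
#'
#' The base side is the gluten side by default (\code{base_side = "alpha"}:
#' gluten database digested, one TG2 peptide as the modification). The
#' reciprocal representation (\code{base_side = "beta"}) digests the TG2
#' sequence, selects single-lysine tryptic peptides, and applies a fixed,
#' previously identified gluten peptide (with its deamidations) as the
#' modification; both representations describe the same molecule and yield
#' identical precursor masses and spanning-ion sets.
#'
#' @param spectra list of spectrum lists (or a file path readable by
#'   \code{\link{read_spectra}}).
#' @param base_db named character vector of protein sequences (the digested
#'   side), or a peptide data.frame as from \code{\link{digest_database}}.
#' @param partner_peptide the fixed partner sequence (a TG2 donor peptide
#'   when \code{base_side = "alpha"}; a gluten peptide when \code{"beta"}).
#' @param config a \code{\link{search_config}}.
#' @param base_side \code{"alpha"} or \code{"beta"}.
#' @param partner_deamidation fixed deamidation positions on a gluten
#'   partner (\code{base_side = "beta"} only).
#' @param partner_q_pos crosslinked Q of the gluten partner
#'   (\code{base_side = "beta"} only; default: all Qs are tried).
#' @param include_decoys add one shuffled decoy per candidate peptide to the
#'   candidate pool (protein id prefixed \code{DECOY_}).
#' @return data.frame of rank-1 matches per spectrum (columns: spectrum id,
#'   rt, precursor m/z/charge, alpha/beta sequences, sites, score, matched
#'   fragment counts, localization probabilities, idotp when the spectrum
#'   carries a precursor isotope envelope), with per-spectrum localization
#'   detail in \code{attr(, "localization")}.
#' @export
run_discovery_search <- function(spectra, base_db, partner_peptide,
                                 config = search_config(),
                                 base_side = c("alpha", "beta"),
                                 partner_deamidation = integer(0),
                                 partner_q_pos = NULL,
                                 include_decoys = FALSE) {
  base_side <- match.arg(base_side)
  if (is.character(spectra) && length(spectra) == 1L) spectra <- read_spectra(spectra)
  empty <- data.frame(spectrum = character(0), rt = numeric(0),
                      precursor_mz = numeric(0), charge = integer(0),
                      alpha = character(0), beta = character(0),
                      protein = character(0), q_pos = integer(0),
                      deamidation = character(0), oxidation = character(0),
                      score = numeric(0), n_matched = integer(0),
                      n_theoretical = integer(0), n_by = integer(0),
                      max_series = integer(0), q_prob = numeric(0),
                      idotp = numeric(0), decoy = logical(0),
                      stringsAsFactors = FALSE)
  if (length(spectra) == 0L) return(empty)
  # candidate pool
  if (is.data.frame(base_db)) {
    pep <- base_db
  } else {
    if (length(base_db) == 0L) stop("base database is empty")
    pep <- digest_database(base_db, enzymes = config$enzymes,
                           max_missed = config$max_missed,
                           min_length = config$min_length,
                           max_length = config$max_length)
  }
  if (base_side == "alpha") {
    pep <- pep[grepl("Q", pep$sequence, fixed = TRUE), , drop = FALSE]
    if (!grepl("K", partner_peptide, fixed = TRUE))
      stop("partner (TG2) peptide must contain a lysine")
  } else {
    nk <- vapply(strsplit(pep$sequence, ""), function(r) sum(r == "K"), integer(1))
    pep <- pep[nk == 1L, , drop = FALSE]
    if (!grepl("Q", partner_peptide, fixed = TRUE))
      stop("partner (gluten) peptide must contain a glutamine")
  }
  pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
  if (include_decoys && nrow(pep)) {
    dec <- pep
    dec$sequence <- vapply(pep$sequence, make_decoy, character(1), USE.NAMES = FALSE)
    dec$protein <- paste0("DECOY_", dec$protein)
    keepres <- if (base_side == "alpha") "Q" else "K"
    dec <- dec[grepl(keepres, dec$sequence, fixed = TRUE), , drop = FALSE]
    pep <- rbind(pep, dec)
  }
  if (nrow(pep) == 0L) return(empty)
  base_mass <- vapply(pep$sequence, peptide_mass, numeric(1), USE.NAMES = FALSE)
  ord <- order(base_mass)
  pep <- pep[ord, , drop = FALSE]; base_mass <- base_mass[ord]
  dd <- 0.984015585  # deamidation mass delta
  ox <- .ELEMENTS$O$mono
  partner_modmass <- if (base_side == "alpha") {
    monoisotopic_mass(xlink_modification_composition(partner_peptide))
  } else {
    monoisotopic_mass(peptide_composition(partner_peptide,
                                          deamidation = partner_deamidation)) -
      monoisotopic_mass(elem_comp(N = 1L, H = 3L))
  }
  rows <- list(); loc_detail <- list()
  for (sp in spectra) {
    if (is.null(sp$mz) || is.null(sp$precursor_mz) || is.na(sp$precursor_mz)) {
      warning("skipping malformed spectrum record",
              if (!is.null(sp$id)) paste0(" '", sp$id, "'"))
      next
    }
    zs <- if (!is.na(sp$precursor_charge)) sp$precursor_charge else config$charges
    p_chance <- chance_match_prob(sp, config$fragment_tol)
    best <- NULL; best_placements <- NULL
    for (z in zs) {
      M <- mz_to_mass(sp$precursor_mz, z)
      tol <- config$precursor_tol_ppm * 1e-6 * M
      ndea_max <- if (config$deamidation) config$max_mods - 1L else 0L
      nox_max <- if (config$oxidation) config$max_mods - 1L else 0L
      for (n_dea in 0:ndea_max) for (n_ox in 0:nox_max) {
        if (1L + n_dea + n_ox > config$max_mods) next
        target <- M - partner_modmass - n_dea * dd - n_ox * ox
        lo <- findInterval(target - tol, base_mass) + 1L
        hi <- findInterval(target + tol, base_mass)
        if (hi < lo) next
        for (ci in lo:hi) {
          seqc <- pep$sequence[ci]
          if (base_side == "alpha") {
            res_c <- strsplit(seqc, "")[[1]]
            nq_pool <- sum(res_c %in% c("N", "Q")) - 1L
            n_combos <- length(which(res_c == "Q")) *
              choose(max(nq_pool, 0L), n_dea)
            if (n_ox == 0L && n_combos > config$max_placements) {
              # ladder-profile DP: one best deamidation set per crosslink site
              pls <- list()
              for (q in which(res_c == "Q")) {
                dea <- .best_dea_combo(sp, seqc, q, n_dea, partner_modmass,
                                       config$fragment_tol)
                if (!is.null(dea))
                  pls[[length(pls) + 1L]] <- list(q_pos = q, deamidation = dea,
                                                  oxidation = integer(0))
              }
            } else {
              pls <- .placements(seqc, n_dea, n_ox, config$max_placements)
            }
            isos <- lapply(pls, function(p)
              isopeptide(alpha = seqc, beta = partner_peptide,
                         alpha_q_pos = p$q_pos, deamidation = p$deamidation,
                         oxidation = p$oxidation, charges = z,
                         max_mods = config$max_mods))
          } else {
            if (n_dea > 0L || n_ox > 0L) next  # partner mods are fixed
            qcand <- if (is.null(partner_q_pos))
              which(strsplit(partner_peptide, "")[[1]] == "Q") else partner_q_pos
            qcand <- setdiff(qcand, partner_deamidation)
            isos <- lapply(qcand, function(q)
              isopeptide(alpha = partner_peptide, beta = seqc,
                         alpha_q_pos = q, deamidation = partner_deamidation,
                         charges = z, max_mods = config$max_mods))
          }
          if (!length(isos)) next
          sc <- numeric(length(isos)); nm <- integer(length(isos))
          nth <- integer(length(isos)); nby <- integer(length(isos))
          mser <- integer(length(isos))
          for (i in seq_along(isos)) {
            fr <- enumerate_fragments(isos[[i]], config$fragment)
            mm <- match_fragments(sp, fr, config$fragment_tol)
            sc[i] <- score_match(nrow(mm), nrow(fr), p_chance)
            nm[i] <- nrow(mm); nth[i] <- nrow(fr)
            nby[i] <- .count_by_fragments(mm)
            mser[i] <- max_consecutive_series(mm)
          }
          bi <- order(-sc, -nm, vapply(isos, function(x) x$alpha, character(1)))[1]
          cand <- list(iso = isos[[bi]], score = sc[bi], n_matched = nm[bi],
                       n_theoretical = nth[bi], n_by = nby[bi],
                       max_series = mser[bi], charge = z,
                       protein = pep$protein[ci],
                       decoy = startsWith(pep$protein[ci], "DECOY_"),
                       all_isos = isos, all_scores = sc, all_matched = nm)
          if (is.null(best) || cand$score > best$score ||
              (cand$score == best$score &&
               (cand$n_matched > best$n_matched ||
                (cand$n_matched == best$n_matched &&
                 cand$iso$alpha < best$iso$alpha)))) {
            best <- cand
          }
        }
      }
    }
    if (is.null(best) || best$score < config$min_score) next
    loc <- .localization_from_scores(best$all_isos, best$all_scores,
                                     best$all_matched, config)
    qrow <- loc$sites[loc$sites$kind == "crosslink" &
                      loc$sites$pos == best$iso$alpha_q_pos, , drop = FALSE]
    idotp_val <- NA_real_
    if (!is.null(sp$precursor_envelope)) {
      comp <- peptide_composition(best$iso$alpha,
                                  deamidation = best$iso$deamidation,
                                  oxidation = best$iso$oxidation) +
        xlink_modification_composition(best$iso$beta)
      expd <- isotope_distribution(comp, length(sp$precursor_envelope))
      idotp_val <- idotp(expd$abundance, sp$precursor_envelope)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum = if (is.null(sp$id)) NA_character_ else sp$id,
      rt = sp$rt, precursor_mz = sp$precursor_mz, charge = best$charge,
      alpha = best$iso$alpha, beta = best$iso$beta, protein = best$protein,
      q_pos = best$iso$alpha_q_pos,
      deamidation = paste(best$iso$deamidation, collapse = ","),
      oxidation = paste(best$iso$oxidation, collapse = ","),
      score = best$score, n_matched = best$n_matched,
      n_theoretical = best$n_theoretical, n_by = best$n_by,
      max_series = best$max_series,
      q_prob = if (nrow(qrow)) qrow$prob else NA_real_,
      idotp = idotp_val, decoy = best$decoy,
      stringsAsFactors = FALSE)
    loc_detail[[if (is.null(sp$id)) length(loc_detail) + 1L else sp$id]] <- loc
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "localization") <- loc_detail
  out
}

#' Read a search configuration from a YAML file
#'
#' Recognized keys are the arguments of \code{\link{search_config}};
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a \code{\link{search_config}} list.
#' @export
read_search_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(search_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(search_config, vals)
}
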