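# Seeded ground-truth generator: gluten-like proteins, true isopeptides,
# DDA spectra with configurable fragment coverage and noise, negative
# controls, and PRM chromatographic traces. Every stage of the pipeline is
# testable against the emitted manifest without any external data.

#' Simulation configuration
#'
#' Defaults emulate a realistic acquisition design: proline/glutamine-rich repetitive
#' gluten-like sequences, triplicate samples plus triplicate negative
#' controls (in which isopeptides are absent), precursor charges 2-5, and
#' crosslink sites biased toward the preferred Q motifs.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_proteins,protein_length number and length range of generated
#'   gluten-like proteins.
#' @param residue_freqs target frequencies for the enriched residues
#'   (Q/P/F/L); the remainder is spread over the other residues (no K/C,
#'   matching prolamin composition).
#' @param n_isopeptides number of true isopeptides to inject.
#' @param motif_bias probability that a crosslink site is drawn from the
#'   preferred (QXP/QXPF*/QXXF*) contexts when one exists.
#' @param deamidation_prob per-site deamidation probability for eligible
#'   N/Q (max 4 per peptide).
#' @param coverage fraction of theoretical fragments injected per spectrum.
#' @param noise_peaks number of uniform random noise peaks per spectrum.
#' @param n_samples,n_controls replicate design.
#' @param charge_probs named probabilities for precursor charges 2-5.
#' @param rt_range gradient window (minutes); \code{rt_jitter} replicate RT
#'   standard deviation (minutes).
#' @param mz_jitter uniform fragment m/z jitter half-width in Da (must stay
#'   below the matching tolerance).
#' @param intensity_meanlog,intensity_sdlog log-normal fragment intensity
#'   parameters.
#' @param envelope_peaks,envelope_noise precursor isotope envelope length
#'   and multiplicative log-normal noise (sdlog).
#' @param prm_peak_width,prm_dt PRM Gaussian peak sigma and scan interval
#'   (minutes).
#' @return a config list.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 8L, protein_length = c(200L, 400L),
                              residue_freqs = c(Q = 0.30, P = 0.20, F = 0.05, L = 0.08),
                              n_isopeptides = 20L, motif_bias = 0.7,
                              deamidation_prob = 0.25,
                              coverage = 0.8, noise_peaks = 25L,
                              n_samples = 3L, n_controls = 3L,
                              charge_probs = c("2" = 0.4, "3" = 0.4, "4" = 0.15, "5" = 0.05),
                              rt_range = c(5, 60), rt_jitter = 0.1,
                              mz_jitter = 0.15,
                              intensity_meanlog = log(1000), intensity_sdlog = 0.5,
                              envelope_peaks = 4L, envelope_noise = 0.01,
                              prm_peak_width = 0.1, prm_dt = 0.02) {
  stopifnot(all(residue_freqs >= 0), sum(residue_freqs) < 1,
            motif_bias >= 0, motif_bias <= 1,
            deamidation_prob >= 0, deamidation_prob <= 1,
            coverage >= 0, coverage <= 1, noise_peaks >= 0,
            n_samples >= 1L, n_controls >= 1L,
            abs(sum(charge_probs) - 1) < 1e-8, mz_jitter >= 0)
  as.list(environment())
}

.SIM_ALPHABET <- function(freqs) {
  aa <- setdiff(names(.RESIDUE_FORMULAS), c("K", "C"))
  p <- stats::setNames(rep((1 - sum(freqs)) / (length(aa) - length(freqs)), length(aa)), aa)
  p[names(freqs)] <- freqs
  p
}

#' Generate a gluten-like reference set with ground-truth isopeptides
#'
#' Proteins are drawn residue-wise at the configured Q/P-rich frequencies
#' (emulating the repetitive prolamin domains); true isopeptides pair
#' digested Q-containing gluten peptides with one of the seven TG2 donor
#' peptides, with the crosslink Q drawn per the motif bias and deamidations
#' added at the configured rate.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param fasta_path optional path: write the proteins as FASTA (the header
#'   comment echoes the seed).
#' @return manifest list: \code{proteins} (named vector),
#'   \code{isopeptides} (named list of \code{\link{isopeptide}}),
#'   \code{truth} (data.frame of the injected species), \code{config}.
#' @export
generate_reference_set <- function(config = simulation_config(), fasta_path = NULL) {
  set.seed(config$seed)
  p <- .SIM_ALPHABET(config$residue_freqs)
  lens <- sample(seq(config$protein_length[1], config$protein_length[2]),
                 config$n_proteins, replace = TRUE)
  proteins <- stats::setNames(vapply(lens, function(n)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""),
    character(1)), paste0("sim_prot_", seq_len(config$n_proteins)))
  pep <- digest_database(proteins, enzymes = c("trypsin", "pepsin", "chymotrypsin"),
                         max_missed = 2L, min_length = 6L, max_length = 25L)
  pep <- pep[grepl("Q", pep$sequence, fixed = TRUE), , drop = FALSE]
  pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
  if (nrow(pep) < config$n_isopeptides)
    stop("infeasible config: only ", nrow(pep),
         " Q-containing digested peptides available for ",
         config$n_isopeptides, " requested isopeptides")
  pref_sites <- lapply(pep$sequence, function(s) {
    qs <- which(strsplit(s, "")[[1]] == "Q")
    qs[vapply(qs, function(q) classify_glutamine_context(s, q), character(1)) %in%
         c("QXP", "QXPF*", "QXXF*")]
  })
  use_pref <- stats::runif(config$n_isopeptides) < config$motif_bias
  has_pref <- lengths(pref_sites) > 0L
  if (sum(use_pref) > sum(has_pref))
    stop("infeasible config: motif bias requires ", sum(use_pref),
         " peptides with preferred Q contexts but only ", sum(has_pref),
         " are available")
  avail <- rep(TRUE, nrow(pep))
  idx <- integer(config$n_isopeptides)
  for (i in order(!use_pref)) {  # preferred draws first, then unconstrained
    pool <- which(avail & (!use_pref[i] | has_pref))
    idx[i] <- pool[sample.int(length(pool), 1L)]
    avail[idx[i]] <- FALSE
  }
  chosen <- pep[idx, , drop = FALSE]
  isos <- list(); rows <- list()
  for (i in seq_len(config$n_isopeptides)) {
    seqc <- chosen$sequence[i]
    res <- strsplit(seqc, "")[[1]]
    qs <- which(res == "Q")
    pref <- pref_sites[[idx[i]]]
    q <- if (use_pref[i])
      pref[sample.int(length(pref), 1L)] else qs[sample.int(length(qs), 1L)]
    beta <- TG2_DONOR_PEPTIDES[[sample.int(length(TG2_DONOR_PEPTIDES), 1L)]]
    dea_pool <- setdiff(which(res %in% c("N", "Q")), q)
    dea <- dea_pool[stats::runif(length(dea_pool)) < config$deamidation_prob]
    if (length(dea) > 4L) dea <- sort(sample(dea, 4L))
    id <- sprintf("sim_iso_%02d", i)
    isos[[id]] <- isopeptide(alpha = seqc, beta = beta, alpha_q_pos = q,
                             deamidation = dea, id = id)
    rows[[i]] <- data.frame(id = id, alpha = seqc, beta = beta, q_pos = q,
                            deamidation = paste(dea, collapse = ","),
                            protein = chosen$protein[i],
                            motif = classify_glutamine_context(seqc, q),
                            stringsAsFactors = FALSE)
  }
  if (!is.null(fasta_path)) {
    names(proteins) <- paste0(names(proteins), " seed=", config$seed)
    write_fasta(proteins, fasta_path)
    names(proteins) <- sub(" .*", "", names(proteins))
  }
  list(proteins = proteins, isopeptides = isos,
       truth = do.call(rbind, rows), config = config)
}

# one DDA spectrum for an isopeptide (or, with iso = NULL, a plain peptide)
.sim_spectrum <- function(config, iso = NULL, sequence = NULL, charge = 2L,
                          rt = 30, id = "scan") {
  if (!is.null(iso)) {
    fr <- enumerate_fragments(iso, fragment_config())
    comp <- peptide_composition(iso$alpha, deamidation = iso$deamidation) +
      xlink_modification_composition(iso$beta)
    M <- precursor_mass(iso)
  } else {
    # plain (non-crosslinked) peptide: b/y ions at charges 1-2
    rm <- .side_residue_masses(sequence)
    n <- length(rm); cs <- c(0, cumsum(rm))
    h2o <- .loss_masses[["H2O"]]
    mzs <- numeric(0)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (z in 1:2) {
          mzs <- c(mzs, mass_to_mz(cs[i + 1L], z), mass_to_mz(cs[n + 1L] - cs[n - i + 1L] + h2o, z))
        }
      }
    }
    fr <- data.frame(mz = mzs)
    comp <- peptide_composition(sequence)
    M <- monoisotopic_mass(comp)
  }
  nkeep <- max(1L, floor(config$coverage * nrow(fr)))
  keep <- sort(sample(nrow(fr), nkeep))
  mz <- fr$mz[keep] + stats::runif(nkeep, -config$mz_jitter, config$mz_jitter)
  intensity <- stats::rlnorm(nkeep, config$intensity_meanlog, config$intensity_sdlog)
  if (config$noise_peaks > 0L) {
    mz <- c(mz, stats::runif(config$noise_peaks, 100, 1800))
    intensity <- c(intensity, stats::rlnorm(config$noise_peaks,
                                            config$intensity_meanlog - 2,
                                            config$intensity_sdlog))
  }
  env <- isotope_distribution(comp, config$envelope_peaks)$abundance
  env <- env * stats::rlnorm(length(env), 0, config$envelope_noise)
  sp <- ms2_spectrum(mz, intensity, precursor_mz = mass_to_mz(M, charge),
                     precursor_charge = charge, rt = rt, id = id)
  sp$precursor_envelope <- env
  sp
}

#' Simulate discovery (DDA) runs for samples and negative controls
#'
#' Every true isopeptide yields one MS2 spectrum in every sample replicate
#' (a seeded fragment subset at the configured coverage, with m/z jitter and
#' noise peaks); negative-control runs contain only spectra of the
#' non-crosslinked gluten peptides. Retention times are drawn once per
#' species and jittered across replicates.
#'
#' @param manifest from \code{\link{generate_reference_set}}.
#' @param config a \code{\link{simulation_config}} (defaults to the
#'   manifest's).
#' @param out_dir optional directory: each run is written as MGF
#'   (\code{<label>.mgf}) with the seed echoed in the header.
#' @return list with \code{runs} (named list: label -> list of spectra),
#'   \code{design} (a \code{\link{run_design}}), and \code{truth}
#'   (per-spectrum provenance data.frame).
#' @export
simulate_dda_run <- function(manifest, config = manifest$config, out_dir = NULL) {
  set.seed(config$seed + 1L)
  isos <- manifest$isopeptides
  zs <- as.integer(names(config$charge_probs))
  rt_base <- stats::setNames(
    stats::runif(length(isos), config$rt_range[1], config$rt_range[2]), names(isos))
  charge <- stats::setNames(
    zs[sample.int(length(zs), length(isos), replace = TRUE, prob = config$charge_probs)],
    names(isos))
  samples <- paste0("S", seq_len(config$n_samples))
  controls <- paste0("C", seq_len(config$n_controls))
  runs <- stats::setNames(vector("list", length(samples) + length(controls)),
                          c(samples, controls))
  prov <- list()
  for (rn in samples) {
    sps <- list()
    for (id in names(isos)) {
      rt <- rt_base[[id]] + stats::rnorm(1, 0, config$rt_jitter)
      sid <- paste(rn, id, sep = "_")
      sps[[sid]] <- .sim_spectrum(config, iso = isos[[id]],
                                  charge = charge[[id]], rt = rt, id = sid)
      prov[[length(prov) + 1L]] <- data.frame(run = rn, spectrum = sid,
                                              source = id, kind = "isopeptide",
                                              stringsAsFactors = FALSE)
    }
    runs[[rn]] <- sps
  }
  for (rn in controls) {
    sps <- list()
    for (id in names(isos)) {
      rt <- rt_base[[id]] + stats::rnorm(1, 0, config$rt_jitter)
      sid <- paste(rn, id, "plain", sep = "_")
      sps[[sid]] <- .sim_spectrum(config, sequence = isos[[id]]$alpha,
                                  charge = min(charge[[id]], 3L), rt = rt, id = sid)
      prov[[length(prov) + 1L]] <- data.frame(run = rn, spectrum = sid,
                                              source = isos[[id]]$alpha,
                                              kind = "plain-peptide",
                                              stringsAsFactors = FALSE)
    }
    runs[[rn]] <- sps
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (rn in names(runs))
      write_mgf(runs[[rn]], file.path(out_dir, paste0(rn, ".mgf")),
                header = paste0("run=", rn, " seed=", config$seed))
  }
  list(runs = runs, design = run_design(samples, controls),
       truth = do.call(rbind, prov), rt = rt_base, charge = charge)
}

#' Simulate unscheduled PRM runs for a set of targets
#'
#' Gaussian elution profiles per transition with configurable apex and
#' width; site-determining transitions can be withheld per isopeptide via
#' \code{dropout}. Control runs carry matched scan grids with zero signal.
#' The expected verdict per isopeptide is emitted alongside.
#'
#' @param isos named list of \code{\link{isopeptide}} objects.
#' @param config a \code{\link{simulation_config}}.
#' @param charge precursor charge used for all targets.
#' @param dropout optional named list: isopeptide id -> m/z vector of
#'   transitions to withhold (e.g. the determining ions of a rejected site).
#' @param out_dir optional directory: runs written as minimal mzML.
#' @return list with \code{runs} (label -> list of MS2 scans),
#'   \code{design}, \code{apex_rt} (named), and \code{expected}
#'   (data.frame: isopeptide, expected verdict).
#' @export
simulate_prm_run <- function(isos, config = simulation_config(), charge = 2L,
                             dropout = NULL, out_dir = NULL) {
  set.seed(config$seed + 2L)
  samples <- paste0("PS", seq_len(config$n_samples))
  controls <- paste0("PC", seq_len(config$n_controls))
  apex <- stats::setNames(
    stats::runif(length(isos), config$rt_range[1], config$rt_range[2]), names(isos))
  runs <- stats::setNames(vector("list", length(samples) + length(controls)),
                          c(samples, controls))
  expected <- list()
  for (rn in c(samples, controls)) {
    sps <- list()
    for (id in names(isos)) {
      iso <- isos[[id]]
      tr <- prm_transitions(iso)
      drop_mz <- if (!is.null(dropout) && id %in% names(dropout)) dropout[[id]] else numeric(0)
      keep <- vapply(tr$mz, function(m) all(abs(m - drop_mz) > 1e-6), logical(1))
      pmz <- mass_to_mz(precursor_mass(iso), charge)
      amp <- stats::rlnorm(nrow(tr), config$intensity_meanlog, config$intensity_sdlog)
      times <- seq(apex[[id]] - 0.5, apex[[id]] + 0.5, by = config$prm_dt)
      for (ti in seq_along(times)) {
        g <- exp(-(times[ti] - apex[[id]])^2 / (2 * config$prm_peak_width^2))
        inject <- rn %in% samples
        mz <- tr$mz[keep]
        intensity <- if (inject) amp[keep] * g else rep(0, sum(keep))
        nz <- intensity > 1e-6
        sid <- paste(rn, id, ti, sep = "_")
        sps[[sid]] <- ms2_spectrum(mz[nz], intensity[nz], precursor_mz = pmz,
                                   precursor_charge = charge, rt = times[ti],
                                   id = sid, iso_mz = pmz, iso_width = 1.7)
      }
    }
    runs[[rn]] <- sps
  }
  for (id in names(isos)) {
    tr <- prm_transitions(isos[[id]])
    drop_mz <- if (!is.null(dropout) && id %in% names(dropout)) dropout[[id]] else numeric(0)
    nkept <- sum(vapply(tr$mz, function(m) all(abs(m - drop_mz) > 1e-6), logical(1)))
    expected[[id]] <- data.frame(
      isopeptide = id,
      expected = if (nkept >= 7L) "confirmed" else "rejected",
      stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (rn in names(runs))
      write_mzml(runs[[rn]], file.path(out_dir, paste0(rn, ".mzML")),
                 header = paste0("run=", rn, " seed=", config$seed))
  }
  list(runs = runs, design = run_design(samples, controls), apex_rt = apex,
       expected = do.call(rbind, expected))
}
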