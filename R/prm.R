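# Targeted (PRM) validation: isolation-list export for confirmed/ambiguous
# isopeptides in both representations, chromatogram extraction from PRM runs,
# deterministic peak picking, and the PRM confirmation rules.

#' Build a PRM isolation list
#'
#' One row per (isopeptide, representation, precursor charge); both the
#' alpha-base (gluten peptide modified by the TG2 peptide) and beta-base
#' (reversed) representations of each isopeptide are included and have
#' identical precursor m/z. Duplicate rows are collapsed.
#'
#' @param isopeptides list of \code{\link{isopeptide}} objects (ids used as
#'   names).
#' @param charges precursor charge range (default 2:3; must be <= 5).
#' @return data.frame with columns \code{mz}, \code{charge}, \code{polarity},
#'   \code{start}, \code{end}, \code{name} (encodes id + representation).
#' @export
build_isolation_list <- function(isopeptides, charges = 2:3) {
  stopifnot(length(isopeptides) >= 1L, all(charges >= 1L), all(charges <= 5L))
  rows <- list()
  for (i in seq_along(isopeptides)) {
    iso <- isopeptides[[i]]
    id <- if (!is.null(iso$id)) iso$id else
      if (!is.null(names(isopeptides))) names(isopeptides)[i] else paste0("iso", i)
    M <- precursor_mass(iso)
    for (rep_ in c("alpha-base", "beta-base")) for (z in charges) {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = round(mass_to_mz(M, z), 6), charge = z, polarity = "Positive",
        start = NA_real_, end = NA_real_,
        name = paste(id, rep_, sep = "|"), stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Write / read an isolation list as TSV
#'
#' A vendor-neutral TSV dialect with columns (m/z, charge, polarity, start,
#' end, name); importing an exported list reproduces the target set exactly.
#'
#' @param targets data.frame from \code{\link{build_isolation_list}}.
#' @param path TSV path.
#' @return \code{write_isolation_list}: \code{path} invisibly;
#'   \code{read_isolation_list}: the targets data.frame.
#' @export
write_isolation_list <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isolation_list
#' @export
read_isolation_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mz", "charge", "polarity", "start", "end", "name") %in% names(df)))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df
}

#' PRM transition list of an isopeptide
#'
#' Singly-charged, loss-free b/y fragments of both sides (the usual PRM
#' transitions); site-determining transitions between alternative crosslink
#' placements are those whose m/z differs between the placements.
#'
#' @param iso an \code{\link{isopeptide}}.
#' @return data.frame of transitions (side, type, index, mz, carries_partner).
#' @export
prm_transitions <- function(iso) {
  fr <- enumerate_fragments(iso, fragment_config(ion_types = c("b", "y"),
                                                 losses = character(0),
                                                 max_charge = 1L,
                                                 internal = FALSE))
  fr[, c("side", "type", "index", "mz", "carries_partner")]
}

#' Extract PRM chromatograms for one target
#'
#' Collects MS2 scans whose quadrupole isolation window contains the target
#' precursor, ordered by retention time; per-transition intensity is the
#' summed intensity of peaks within the fragment tolerance of the transition
#' m/z.
#'
#' @param spectra list of PRM MS2 spectrum lists (with \code{iso_mz},
#'   \code{iso_width}, \code{rt}).
#' @param precursor_mz target precursor m/z.
#' @param transitions data.frame with at least \code{mz} (e.g. from
#'   \code{\link{prm_transitions}}).
#' @param tol fragment tolerance in Da (default 0.5, the discovery fragment
#'   tolerance).
#' @param iso_width isolation width (Th) used when a scan does not carry one.
#' @return list with \code{rt} (scan times), \code{intensity} (matrix, scans
#'   x transitions), \code{transitions}, \code{precursor_mz}. Zero matched
#'   scans yields empty traces, not an error.
#' @export
extract_chromatograms <- function(spectra, precursor_mz, transitions,
                                  tol = 0.5, iso_width = 1.7) {
  stopifnot(tol > 0)
  sel <- vapply(spectra, function(sp) {
    if (is.null(sp$ms_level) || sp$ms_level != 2L) return(FALSE)
    w <- if (!is.null(sp$iso_width) && !is.na(sp$iso_width)) sp$iso_width else iso_width
    ctr <- if (!is.null(sp$iso_mz) && !is.na(sp$iso_mz)) sp$iso_mz else sp$precursor_mz
    abs(ctr - precursor_mz) <= w / 2
  }, logical(1))
  scans <- spectra[sel]
  if (length(scans)) scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  mat <- matrix(0, nrow = length(scans), ncol = nrow(transitions))
  for (i in seq_along(scans)) {
    sp <- scans[[i]]
    for (j in seq_len(nrow(transitions))) {
      hit <- abs(sp$mz - transitions$mz[j]) <= tol
      if (any(hit)) mat[i, j] <- sum(sp$intensity[hit])
    }
  }
  list(rt = rts, intensity = mat, transitions = transitions,
       precursor_mz = precursor_mz)
}

#' Pick a chromatographic peak from a single trace
#'
#' Deterministic rule: baseline is the median of the trace; the peak is the
#' contiguous region around the apex where the signal stays above baseline
#' plus 5 percent of the apex-over-baseline height; the area is the
#' trapezoidal integral of the background-subtracted region.
#'
#' @param rt scan times (strictly increasing).
#' @param intensity trace intensities.
#' @return list with \code{detected}, \code{apex_rt}, \code{apex_intensity},
#'   \code{bounds} (index range), \code{area}.
#' @export
pick_peak <- function(rt, intensity) {
  none <- list(detected = FALSE, apex_rt = NA_real_, apex_intensity = 0,
               bounds = c(NA_integer_, NA_integer_), area = 0)
  if (length(rt) < 3L || all(intensity <= 0)) return(none)
  stopifnot(length(rt) == length(intensity), !is.unsorted(rt, strictly = TRUE))
  base <- stats::median(intensity)
  apex <- which.max(intensity)
  height <- intensity[apex] - base
  if (height <= 0) return(none)
  thr <- base + 0.05 * height
  lo <- apex; while (lo > 1L && intensity[lo - 1L] > thr) lo <- lo - 1L
  hi <- apex; while (hi < length(rt) && intensity[hi + 1L] > thr) hi <- hi + 1L
  if (hi <= lo) return(none)
  seg <- lo:hi
  y <- pmax(intensity[seg] - base, 0)
  area <- sum(diff(rt[seg]) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(detected = TRUE, apex_rt = rt[apex], apex_intensity = intensity[apex],
       bounds = c(lo, hi), area = area)
}

#' Summarize PRM chromatograms of one target in one run
#'
#' Peak-picks every transition trace and reports the co-eluting detections
#' (apex within \code{rt_co} of the median apex of detected b/y transitions).
#'
#' @param chrom list from \code{\link{extract_chromatograms}}.
#' @param rt_co co-elution window in minutes (default 0.2).
#' @return list with \code{transitions} (the input transitions plus detected /
#'   apex_rt / area / coeluting columns), \code{apex_rt} (consensus),
#'   \code{n_coeluting_by}, \code{max_series}.
#' @export
summarize_prm_target <- function(chrom, rt_co = 0.2) {
  tr <- chrom$transitions
  n <- nrow(tr)
  det <- logical(n); apexes <- rep(NA_real_, n); areas <- numeric(n)
  for (j in seq_len(n)) {
    pk <- pick_peak(chrom$rt, if (nrow(chrom$intensity)) chrom$intensity[, j] else numeric(0))
    det[j] <- pk$detected; apexes[j] <- pk$apex_rt; areas[j] <- pk$area
  }
  tr$detected <- det; tr$apex_rt <- apexes; tr$area <- areas
  isby <- tr$type %in% c("b", "y")
  consensus <- if (any(det & isby)) stats::median(apexes[det & isby]) else NA_real_
  tr$coeluting <- det & !is.na(apexes) & !is.na(consensus) &
    abs(apexes - consensus) <= rt_co
  co <- tr[tr$coeluting & isby, , drop = FALSE]
  list(transitions = tr, apex_rt = consensus,
       n_coeluting_by = if (nrow(co)) nrow(unique(co[, c("side", "type", "index")])) else 0L,
       max_series = max_consecutive_series(co))
}

#' Assign a crosslink/deamidation site from PRM site-determining transitions
#'
#' Between each pair of candidate placements, the determining transitions of
#' one placement are those whose m/z does not occur in the other's transition
#' list (beyond twice the tolerance). A site is assigned when exactly one
#' candidate dominates every alternative: its pairwise determining
#' transitions are detected while the alternative's are not.
#'
#' @param spectra PRM spectra of the run.
#' @param candidates named list of \code{\link{isopeptide}} objects (one per
#'   candidate site placement; names label the sites).
#' @param charge precursor charge used for extraction.
#' @param tol fragment tolerance in Da.
#' @return list with \code{assigned} (site name or NA), \code{support}
#'   (named count of detected pairwise-determining transitions per
#'   candidate).
#' @export
assign_prm_site <- function(spectra, candidates, charge = 2L, tol = 0.5) {
  stopifnot(length(candidates) >= 2L, !is.null(names(candidates)))
  trans <- lapply(candidates, prm_transitions)
  nc <- length(candidates)
  # one extraction over the union of all candidate transitions
  union_mz <- sort(unique(round(unlist(lapply(trans, `[[`, "mz")), 6)))
  chrom <- extract_chromatograms(
    spectra, mass_to_mz(precursor_mass(candidates[[1L]]), charge),
    data.frame(side = NA, type = "t", index = NA, mz = union_mz), tol = tol)
  sm <- summarize_prm_target(chrom)
  detected_mz <- union_mz[sm$transitions$detected]
  is_detected <- function(m) length(detected_mz) &&
    any(abs(detected_mz - m) <= tol)
  det_pair <- matrix(FALSE, nc, nc)  # [k, j]: a k-vs-j determining ion detected
  support <- stats::setNames(integer(nc), names(candidates))
  for (k in seq_len(nc)) for (j in seq_len(nc)) {
    if (k == j) next
    unique_kj <- trans[[k]]$mz[vapply(trans[[k]]$mz, function(m)
      all(abs(m - trans[[j]]$mz) > 2 * tol), logical(1))]
    hits <- vapply(unique_kj, is_detected, logical(1))
    det_pair[k, j] <- any(hits)
    support[k] <- support[k] + sum(hits)
  }
  dominates <- vapply(seq_len(nc), function(k)
    all(vapply(seq_len(nc)[-k], function(j)
      det_pair[k, j] && !det_pair[j, k], logical(1))), logical(1))
  assigned <- if (sum(dominates) == 1L) names(candidates)[dominates] else NA_character_
  list(assigned = assigned, support = support)
}

#' Apply the PRM confirmation rules
#'
#' Evidence rows are per (isopeptide, run): confirmed iff >=
#' \code{min_by} co-eluting b/y transitions in every sample replicate, a
#' consecutive ladder >= \code{min_series}, retention time consistent with
#' the discovery identification (when given), precursor idotp above
#' threshold where precursor traces exist, and no detected signals in any
#' negative control. Verdicts are monotone in transition count and series
#' length.
#'
#' @param evidence data.frame with columns \code{isopeptide}, \code{run},
#'   \code{n_coeluting_by}, \code{max_series}, \code{apex_rt}, and optional
#'   \code{idotp} and \code{detected} (control rows: any detected signal).
#' @param design a \code{\link{run_design}}.
#' @param thresholds a \code{\link{confirmation_thresholds}} (rt_tol is the
#'   discovery-vs-PRM retention time window).
#' @param discovery_rt optional named numeric of discovery retention times
#'   per isopeptide.
#' @return data.frame of verdicts with reason codes, as in
#'   \code{\link{apply_confirmation}} (without the localization criterion;
#'   site assignment is handled by \code{\link{assign_prm_site}}).
#' @export
prm_confirm <- function(evidence, design,
                        thresholds = confirmation_thresholds(),
                        discovery_rt = NULL) {
  req <- c("isopeptide", "run", "n_coeluting_by", "max_series", "apex_rt")
  miss <- setdiff(req, names(evidence))
  if (length(miss)) stop("evidence is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(design$controls) || !length(design$controls))
    stop("design error: PRM confirmation requires negative controls")
  ids <- unique(evidence$isopeptide)
  rows <- lapply(ids, function(id) {
    ev <- evidence[evidence$isopeptide == id, , drop = FALSE]
    smp <- ev[ev$run %in% design$samples, , drop = FALSE]
    ctl <- ev[ev$run %in% design$controls, , drop = FALSE]
    reasons <- character(0)
    det_smp <- smp[smp$n_coeluting_by > 0L, , drop = FALSE]
    if (length(unique(det_smp$run)) < length(design$samples))
      reasons <- c(reasons, "replicates")
    n_by <- if (nrow(smp)) max(smp$n_coeluting_by) else 0L
    if (n_by < thresholds$min_by) reasons <- c(reasons, "min-fragments")
    mser <- if (nrow(smp)) max(smp$max_series) else 0L
    if (mser < thresholds$min_series) reasons <- c(reasons, "consecutive-series")
    ctl_hit <- if ("detected" %in% names(ctl)) any(ctl$detected)
               else any(ctl$n_coeluting_by > 0L)
    if (nrow(ctl) && ctl_hit) reasons <- c(reasons, "negative-control")
    if ("idotp" %in% names(smp) && any(!is.na(smp$idotp)) &&
        min(smp$idotp, na.rm = TRUE) <= thresholds$min_idotp)
      reasons <- c(reasons, "idotp")
    if (!is.null(discovery_rt) && id %in% names(discovery_rt) && nrow(det_smp)) {
      if (any(abs(det_smp$apex_rt - discovery_rt[[id]]) > thresholds$rt_tol, na.rm = TRUE))
        reasons <- c(reasons, "retention-time")
    }
    data.frame(isopeptide = id,
               verdict = if (!length(reasons)) "confirmed" else "rejected",
               reasons = paste(reasons, collapse = ","),
               n_by = n_by, max_series = mser,
               control_detections = if (nrow(ctl)) sum(ctl$n_coeluting_by > 0L) else 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
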