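# Confirmation criteria applied to discovery results across replicates and
# negative controls: reproducible detection in all sample replicates, absence
# from controls, >= 7 b/y fragments, >= 3 consecutive fragments in one
# ladder, precursor idotp > 0.9, consistent retention times, and crosslink
# localization above the probability threshold.

#' Longest consecutive fragment-ion series
#'
#' Length of the longest run of consecutive ladder indices within one
#' (side, ion type) ladder; loss variants and charge states collapse onto
#' the same index, and runs never join different ladders.
#'
#' @param matched data.frame with columns \code{side}, \code{type},
#'   \code{index} (e.g. from \code{\link{match_fragments}}).
#' @return integer run length (0 for an empty set).
#' @examples
#' max_consecutive_series(data.frame(side = "alpha", type = "b", index = 6:8))  # 3
#' @export
max_consecutive_series <- function(matched) {
  if (is.null(matched) || nrow(matched) == 0L) return(0L)
  m <- matched[!is.na(matched$index), , drop = FALSE]
  if (nrow(m) == 0L) return(0L)
  best <- 0L
  for (key in unique(paste(m$side, m$type))) {
    idx <- sort(unique(m$index[paste(m$side, m$type) == key]))
    r <- 1L; cur <- 1L
    if (length(idx) > 1L) {
      for (i in 2:length(idx)) {
        cur <- if (idx[i] == idx[i - 1L] + 1L) cur + 1L else 1L
        r <- max(r, cur)
      }
    }
    best <- max(best, r)
  }
  best
}

#' Isotope-distribution dot product (idotp)
#'
#' Cosine similarity between the expected precursor isotope envelope and the
#' observed intensity vector, in [0, 1].
#'
#' @param expected expected relative abundances (length >= 2).
#' @param observed observed intensities, non-negative, not all zero, same
#'   length as \code{expected}.
#' @return value in [0, 1]; 1 means identical shape.
#' @export
idotp <- function(expected, observed) {
  stopifnot(length(expected) == length(observed), length(expected) >= 2L)
  if (any(observed < 0)) stop("observed intensities must be non-negative")
  if (all(observed == 0)) stop("observed envelope is all zero")
  sum(expected * observed) / sqrt(sum(expected^2) * sum(observed^2))
}

#' Confirmation thresholds
#'
#' @param min_by minimum identified b/y fragments (default 7).
#' @param min_series minimum consecutive fragments in one ladder (default 3).
#' @param min_idotp precursor idotp must exceed this (default 0.9).
#' @param localization_threshold crosslink localization probability above
#'   which the site counts as localized (default 0.75).
#' @param rt_tol replicate retention-time tolerance in minutes: maximum
#'   allowed deviation from the replicate median (default 0.5).
#' @param k_of_n number of sample replicates a detection is required in;
#'   \code{NULL} (default) means all of them.
#' @return a threshold list.
#' @export
confirmation_thresholds <- function(min_by = 7L, min_series = 3L,
                                    min_idotp = 0.9,
                                    localization_threshold = 0.75,
                                    rt_tol = 0.5, k_of_n = NULL) {
  list(min_by = as.integer(min_by), min_series = as.integer(min_series),
       min_idotp = min_idotp, localization_threshold = localization_threshold,
       rt_tol = rt_tol, k_of_n = k_of_n)
}

#' Run-design manifest
#'
#' @param samples character vector of sample replicate run ids.
#' @param controls character vector of negative-control run ids.
#' @return a design list; errors if either group is empty.
#' @export
run_design <- function(samples, controls) {
  if (length(samples) < 1L) stop("design error: at least one sample replicate is required")
  if (length(controls) < 1L) stop("design error: at least one negative control is required")
  if (length(intersect(samples, controls)))
    stop("design error: runs cannot be both sample and control")
  list(samples = samples, controls = controls)
}

#' Apply the confirmation criteria to grouped evidence
#'
#' Evidence rows are per-detection (one row per isopeptide per run in which
#' it was detected). An isopeptide is \code{confirmed} iff it is detected in
#' all sample replicates (or \code{k_of_n}), absent from every negative
#' control, has >= \code{min_by} matched b/y fragments, a consecutive series
#' >= \code{min_series}, idotp > \code{min_idotp}, replicate retention times
#' within tolerance, and crosslink localization above the threshold; with
#' everything but localization passing the verdict is \code{ambiguous-site},
#' otherwise \code{rejected}. Reason codes enumerate every failed criterion,
#' so the verdict is reconstructable from them.
#'
#' @param evidence data.frame with columns \code{isopeptide} (grouping key),
#'   \code{run} (run id), \code{rt}, \code{n_by}, \code{max_series},
#'   \code{idotp}, \code{q_prob}. Runs must appear in the design.
#' @param design a \code{\link{run_design}}.
#' @param thresholds a \code{\link{confirmation_thresholds}}.
#' @return data.frame with one row per isopeptide: verdict
#'   (\code{confirmed} / \code{ambiguous-site} / \code{rejected}), reasons
#'   (comma-separated codes, empty when confirmed), and the aggregated
#'   evidence values the verdict was computed from.
#' @export
apply_confirmation <- function(evidence, design,
                               thresholds = confirmation_thresholds()) {
  req <- c("isopeptide", "run", "rt", "n_by", "max_series", "idotp", "q_prob")
  miss <- setdiff(req, names(evidence))
  if (length(miss)) stop("evidence is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(evidence$run), c(design$samples, design$controls))
  if (length(unknown))
    stop("design error: evidence references run(s) not in the design: ",
         paste(unknown, collapse = ", "))
  need_n <- if (is.null(thresholds$k_of_n)) length(design$samples)
            else min(thresholds$k_of_n, length(design$samples))
  ids <- unique(evidence$isopeptide)
  rows <- lapply(ids, function(id) {
    ev <- evidence[evidence$isopeptide == id, , drop = FALSE]
    smp <- ev[ev$run %in% design$samples, , drop = FALSE]
    ctl <- ev[ev$run %in% design$controls, , drop = FALSE]
    reasons <- character(0)
    n_reps <- length(unique(smp$run))
    if (n_reps < need_n) reasons <- c(reasons, "replicates")
    if (nrow(ctl) > 0L) reasons <- c(reasons, "negative-control")
    n_by <- if (nrow(smp)) max(smp$n_by) else 0L
    if (n_by < thresholds$min_by) reasons <- c(reasons, "min-fragments")
    mser <- if (nrow(smp)) max(smp$max_series) else 0L
    if (mser < thresholds$min_series) reasons <- c(reasons, "consecutive-series")
    idp <- if (nrow(smp) && !all(is.na(smp$idotp))) min(smp$idotp, na.rm = TRUE) else NA_real_
    if (is.na(idp) || idp <= thresholds$min_idotp) reasons <- c(reasons, "idotp")
    rt_dev <- if (nrow(smp) >= 2L) max(abs(smp$rt - stats::median(smp$rt))) else 0
    if (!is.na(rt_dev) && rt_dev > thresholds$rt_tol)
      reasons <- c(reasons, "retention-time")
    q_prob <- if (nrow(smp) && !all(is.na(smp$q_prob))) max(smp$q_prob, na.rm = TRUE) else NA_real_
    localized <- !is.na(q_prob) && q_prob > thresholds$localization_threshold
    hard_fail <- length(reasons) > 0L
    if (!localized) reasons <- c(reasons, "localization")
    verdict <- if (!length(reasons)) "confirmed"
               else if (!hard_fail) "ambiguous-site"
               else "rejected"
    data.frame(isopeptide = id, verdict = verdict,
               reasons = paste(reasons, collapse = ","),
               n_replicates = n_reps, control_detections = nrow(ctl),
               n_by = n_by, max_series = mser, idotp = idp,
               rt_deviation = rt_dev, q_prob = q_prob,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a confirmation report
#'
#' TSV of the verdict table plus a human-readable count summary attribute.
#' @param report data.frame from \code{\link{apply_confirmation}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly; prints a per-verdict count summary.
#' @export
write_confirmation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- table(report$verdict)
  message("verdicts: ", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "))
  invisible(path)
}
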