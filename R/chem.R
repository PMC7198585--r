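# Elemental-composition arithmetic and mass/isotope calculations.
#
# All mass bookkeeping in the package goes through signed element-count
# vectors ("elem_comp"); m/z values are monoisotopic throughout, since the
# matching tolerances (4.5 ppm precursors) are meaningless on average masses.

# Monoisotopic atomic masses and isotope tables (IUPAC 2013 values).
# Isotope entries are ordered by neutron offset from the principal isotope.
.ELEMENTS <- list(
  C = list(mono = 12.0,
           offsets = c(0L, 1L),
           masses = c(12.0, 13.0033548378),
           abund = c(0.9893, 0.0107)),
  H = list(mono = 1.00782503207,
           offsets = c(0L, 1L),
           masses = c(1.00782503207, 2.0141017778),
           abund = c(0.999885, 0.000115)),
  N = list(mono = 14.0030740048,
           offsets = c(0L, 1L),
           masses = c(14.0030740048, 15.0001088982),
           abund = c(0.99636, 0.00364)),
  O = list(mono = 15.99491461956,
           offsets = c(0L, 1L, 2L),
           masses = c(15.99491461956, 16.99913170, 17.9991610),
           abund = c(0.99757, 0.00038, 0.00205)),
  S = list(mono = 31.97207100,
           offsets = c(0L, 1L, 2L, 4L),
           masses = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abund = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Mass of a proton in Da (used for charging: m/z = (M + z * proton) / z)
#' @export
PROTON_MASS <- 1.007276466

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector of signed atom counts
#' (class \code{elem_comp}). Compositions of physical molecules have all
#' counts >= 0; deltas such as deamidation (\code{-H -N +O}) may be negative.
#' Addition and subtraction are element-wise via the usual operators.
#'
#' @param ... named integer counts, e.g. \code{elem_comp(C = 2, H = 5, N = 1, O = 2)},
#'   or a single named numeric vector.
#' @return an \code{elem_comp} object.
#' @examples
#' elem_comp(H = 2, O = 1) + elem_comp(C = 1)
#' @export
elem_comp <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    x <- args[[1]]
  } else {
    x <- unlist(args)
  }
  if (length(x) == 0L) x <- stats::setNames(integer(0), character(0))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all counts must be named by element symbol")
  if (any(x != round(x))) stop("atom counts must be integers")
  tab <- tapply(as.integer(round(x)), names(x), sum)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out <- out[out != 0L]
  structure(as.integer(out), names = names(out), class = "elem_comp")
}

.as_elem_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  elem_comp(x)
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (.Generic %in% c("<", ">", "<=", ">=", "!=")) {
    # scalar comparisons on the raw counts (e.g. any(comp < 0))
    return(get(.Generic)(unclass(e1), unclass(e2)))
  }
  if (!.Generic %in% c("+", "-", "*", "==")) stop("unsupported operation for elem_comp: ", .Generic)
  if (.Generic == "*") {
    if (is.numeric(e2) && length(e2) == 1L) return(elem_comp(unclass(e1) * e2))
    if (is.numeric(e1) && length(e1) == 1L) return(elem_comp(unclass(e2) * e1))
    stop("elem_comp can only be multiplied by a scalar")
  }
  a <- .as_elem_comp(e1); b <- .as_elem_comp(e2)
  els <- union(names(a), names(b))
  av <- stats::setNames(integer(length(els)), els); av[names(a)] <- a
  bv <- stats::setNames(integer(length(els)), els); bv[names(b)] <- b
  if (.Generic == "==") return(all(av == bv))
  if (.Generic == "-") bv <- -bv
  elem_comp(av + bv)
}

#' Format an elemental composition as a Hill-like formula string
#'
#' C first, then H, then the remaining elements alphabetically; a count of 1
#' is implicit (e.g. \code{"C43H62N16O11S"}). \code{parse_formula()} is the
#' exact inverse.
#'
#' @param comp an \code{elem_comp}.
#' @return a formula string.
#' @export
format_formula <- function(comp) {
  comp <- .as_elem_comp(comp)
  if (length(comp) == 0L) return("")
  if (any(comp < 0L)) stop("cannot format a composition with negative counts")
  els <- names(comp)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- comp[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Parse a Hill-like formula string
#'
#' @param x a string such as \code{"C36H57N11O9"}; implicit count 1 allowed.
#' @return an \code{elem_comp}.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(elem_comp())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  els <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  elem_comp(stats::setNames(cnt, els))
}

#' @export
print.elem_comp <- function(x, ...) {
  if (any(x < 0L)) {
    cat("<elem_comp delta>", paste0(ifelse(x > 0, "+", ""), unclass(x), names(x), collapse = " "), "\n")
  } else {
    cat("<elem_comp>", format_formula(x), "\n")
  }
  invisible(x)
}

# Residue (amino-acid minus water) compositions; cysteine as free thiol.
.RESIDUE_FORMULAS <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Residue, water and ammonia compositions
#'
#' Fixed constants behind all peptide mass arithmetic. Cysteine is the free
#' thiol (no alkylation) by default; carbamidomethylation is available as an
#' optional modification in \code{\link{peptide_composition}}.
#'
#' @return \code{residue_table()}: a named list of \code{elem_comp}, one per
#'   standard residue plus \code{water}, \code{ammonia}, \code{co} (carbon
#'   monoxide, for a-ions) and \code{carbamidomethyl}.
#' @export
residue_table <- function() {
  out <- lapply(.RESIDUE_FORMULAS, parse_formula)
  out$water <- elem_comp(H = 2, O = 1)
  out$ammonia <- elem_comp(N = 1, H = 3)
  out$co <- elem_comp(C = 1, O = 1)
  out$carbamidomethyl <- elem_comp(C = 2, H = 3, N = 1, O = 1)
  out
}

.RT <- NULL     # populated on load
.RMASS <- NULL  # monoisotopic mass per residue-table entry

.residues <- function() {
  if (is.null(.RT)) residue_table() else .RT
}

.residue_masses_tab <- function() {
  if (is.null(.RMASS)) vapply(.residues(), monoisotopic_mass, numeric(1)) else .RMASS
}

.onLoad <- function(libname, pkgname) {
  rt <- residue_table()
  ns <- topenv(environment())
  assign(".RT", rt, envir = ns)
  masses <- vapply(rt, monoisotopic_mass, numeric(1))
  assign(".RMASS", masses, envir = ns)
}

#' Elemental composition of a peptide
#'
#' Sum of residue compositions plus one water, with positioned variable
#' modifications applied: deamidation at N/Q contributes \code{-H -N +O}
#' (+0.984 Da), oxidation at M contributes \code{+O}.
#'
#' @param sequence residue string (standard one-letter codes).
#' @param deamidation integer vector of 1-based positions (must be N or Q).
#' @param oxidation integer vector of 1-based positions (must be M).
#' @param carbamidomethyl logical; alkylate all cysteines (+C2H3NO).
#'   Off by default (the workflow uses unalkylated cysteine).
#' @return an \code{elem_comp}.
#' @examples
#' format_formula(peptide_composition("QKR"))  # "C17H34N8O5"
#' @export
peptide_composition <- function(sequence, deamidation = integer(0),
                                oxidation = integer(0),
                                carbamidomethyl = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  rt <- .residues()
  counts <- table(factor(res, levels = names(.RESIDUE_FORMULAS)))
  total <- rt$water
  for (aa in names(counts)[counts > 0L]) {
    total <- total + elem_comp(unclass(rt[[aa]]) * as.integer(counts[[aa]]))
  }
  .check_mod_pos <- function(pos, allowed, what) {
    pos <- as.integer(pos)
    if (any(pos < 1L | pos > length(res)))
      stop(what, " position out of range: ", paste(pos[pos < 1L | pos > length(res)], collapse = ", "))
    off <- which(!res[pos] %in% allowed)
    if (length(off))
      stop(what, " not allowed on residue '", res[pos[off[1]]], "' at position ", pos[off[1]])
    if (anyDuplicated(pos)) stop("duplicate ", what, " positions")
    pos
  }
  if (length(deamidation)) {
    .check_mod_pos(deamidation, c("N", "Q"), "deamidation")
    total <- total + elem_comp(H = -1L, N = -1L, O = 1L) * length(deamidation)
  }
  if (length(oxidation)) {
    .check_mod_pos(oxidation, "M", "oxidation")
    total <- total + elem_comp(O = 1L) * length(oxidation)
  }
  if (isTRUE(carbamidomethyl)) {
    ncys <- sum(res == "C")
    if (ncys > 0L) total <- total + rt$carbamidomethyl * ncys
  }
  total
}

#' Crosslink "modification" composition of a TG2 donor peptide
#'
#' The isopeptide bond forms with loss of NH3, so using a lysine-containing
#' peptide as a modification on the partner peptide requires a formal NH3
#' subtraction from its elemental composition.
#'
#' @param beta_sequence the lysine-containing (acyl acceptor) peptide.
#' @return an \code{elem_comp}: \code{peptide_composition(beta_sequence) - NH3}.
#' @examples
#' format_formula(xlink_modification_composition("FLKNAGR"))  # "C36H57N11O9"
#' @export
xlink_modification_composition <- function(beta_sequence) {
  if (!grepl("K", beta_sequence, fixed = TRUE))
    stop("peptide contains no lysine; cannot form an epsilon-amine crosslink: ",
         beta_sequence)
  out <- peptide_composition(beta_sequence) - .residues()$ammonia
  if (any(out < 0L)) stop("internal error: negative counts in crosslink modification")
  out
}

#' Monoisotopic mass of a composition
#'
#' @param comp an \code{elem_comp} (possibly a signed delta).
#' @return mass in Da, \code{sum(count * monoisotopic atomic mass)}.
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_elem_comp(comp)
  if (length(comp) == 0L) return(0)
  missing <- setdiff(names(comp), names(.ELEMENTS))
  if (length(missing)) stop("no mass entry for element(s): ", paste(missing, collapse = ", "))
  sum(vapply(names(comp), function(e) .ELEMENTS[[e]]$mono, numeric(1)) * as.numeric(comp))
}

#' Average mass of a composition
#'
#' Provided for completeness; never used in matching.
#' @param comp an \code{elem_comp}.
#' @return abundance-weighted mass in Da.
#' @export
average_mass <- function(comp) {
  comp <- .as_elem_comp(comp)
  if (length(comp) == 0L) return(0)
  sum(vapply(names(comp), function(e) {
    el <- .ELEMENTS[[e]]
    if (is.null(el)) stop("no mass entry for element: ", e)
    sum(el$masses * el$abund) / sum(el$abund)
  }, numeric(1)) * as.numeric(comp))
}

#' Monoisotopic mass of a peptide
#' @inheritParams peptide_composition
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, deamidation = integer(0), oxidation = integer(0)) {
  monoisotopic_mass(peptide_composition(sequence, deamidation, oxidation))
}

#' Convert neutral mass to m/z and back
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param z positive integer charge (protonation only).
#' @return \code{mass_to_mz}: m/z; \code{mz_to_mass}: neutral mass.
#' @export
mass_to_mz <- function(mass, z) {
  stopifnot(all(z >= 1))
  (mass + z * PROTON_MASS) / z
}

#' @rdname mass_to_mz
#' @param mz observed m/z.
#' @export
mz_to_mass <- function(mz, z) {
  mz * z - z * PROTON_MASS
}

# Convolve two aggregated isotope distributions given as lists with
# $p (abundance) and $pm (abundance * mean mass) indexed by neutron offset 0..k.
.iso_convolve <- function(a, b, nmax) {
  la <- length(a$p); lb <- length(b$p)
  n <- min(la + lb - 1L, nmax)
  p <- numeric(n); pm <- numeric(n)
  for (i in seq_len(la)) {
    jmax <- min(lb, n - i + 1L)
    if (jmax < 1L) next
    j <- seq_len(jmax)
    k <- i + j - 1L
    p[k] <- p[k] + a$p[i] * b$p[j]
    # E[mass] adds: weight * (mA + mB) where m* are per-bin mean masses
    mA <- if (a$p[i] > 0) a$pm[i] / a$p[i] else 0
    mB <- ifelse(b$p[j] > 0, b$pm[j] / b$p[j], 0)
    pm[k] <- pm[k] + a$p[i] * b$p[j] * (mA + mB)
  }
  list(p = p, pm = pm)
}

.iso_element <- function(symbol, nmax) {
  el <- .ELEMENTS[[symbol]]
  n <- min(max(el$offsets) + 1L, nmax)
  p <- numeric(n); pm <- numeric(n)
  keep <- el$offsets < n
  idx <- el$offsets[keep] + 1L
  p[idx] <- el$abund[keep]
  pm[idx] <- el$abund[keep] * el$masses[keep]
  list(p = p, pm = pm)
}

#' Aggregated isotope distribution of a composition
#'
#' Computes the isotopologue envelope by per-element binomial/multinomial
#' convolution (exponentiation by squaring over offset polynomials), with
#' peaks aggregated by nominal neutron offset (A, A+1, ...) — the form on
#' which expected-vs-observed precursor comparisons (idotp) operate.
#'
#' @param comp a physical composition (all counts >= 0).
#' @param n_peaks number of aggregated peaks to return (>= 1).
#' @return data.frame with columns \code{mass} (abundance-weighted mean mass
#'   of each nominal bin) and \code{abundance}, normalized to sum to 1 over
#'   the returned peaks.
#' @export
isotope_distribution <- function(comp, n_peaks = 5L) {
  comp <- .as_elem_comp(comp)
  if (any(comp < 0L)) stop("isotope distribution requires a physical composition (counts >= 0)")
  n_peaks <- as.integer(n_peaks)
  stopifnot(n_peaks >= 1L)
  acc <- list(p = 1, pm = 0)
  for (e in names(comp)) {
    if (!e %in% names(.ELEMENTS)) stop("no isotope table for element: ", e)
    base <- .iso_element(e, n_peaks)
    k <- comp[[e]]
    # exponentiation by squaring
    pow <- base
    first <- TRUE
    part <- NULL
    while (k > 0L) {
      if (k %% 2L == 1L) {
        part <- if (is.null(part)) pow else .iso_convolve(part, pow, n_peaks)
      }
      k <- k %/% 2L
      if (k > 0L) pow <- .iso_convolve(pow, pow, n_peaks)
    }
    if (!is.null(part)) acc <- .iso_convolve(acc, part, n_peaks)
  }
  p <- acc$p
  if (length(p) < n_peaks) {
    p <- c(p, numeric(n_peaks - length(p)))
    acc$pm <- c(acc$pm, numeric(n_peaks - length(acc$pm)))
  }
  mass <- ifelse(p > 0, acc$pm / p, monoisotopic_mass(comp) + (seq_len(n_peaks) - 1L) * 1.0033548378)
  data.frame(mass = mass, abundance = p / sum(p))
}
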