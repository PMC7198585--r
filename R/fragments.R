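# The crosslinked-species data model and theoretical fragment enumeration.
#
# An isopeptide joins a gluten peptide (alpha side, acyl-donor Q) and a TG2
# peptide (beta side, acyl-acceptor K) through an amide bond formed with loss
# of NH3. Fragments of one side that contain the crosslink residue carry the
# full partner-peptide mass minus NH3.

#' Construct an isopeptide
#'
#' @param alpha gluten-side peptide sequence.
#' @param beta TG2-side peptide sequence.
#' @param alpha_q_pos 1-based position of the crosslinked glutamine on alpha.
#' @param beta_k_pos 1-based position of the crosslinked lysine on beta
#'   (default: the single K of beta).
#' @param deamidation 1-based deamidated positions on alpha (N/Q, never the
#'   crosslinked Q).
#' @param oxidation 1-based oxidized positions on alpha (M).
#' @param charges admissible precursor charges (within 1..5).
#' @param id optional identifier.
#' @param max_mods cap on total variable modifications per searched peptide,
#'   counting the crosslink (default 5).
#' @return an object of class \code{isopeptide}.
#' @examples
#' iso <- isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2)
#' precursor_mass(iso)
#' @export
isopeptide <- function(alpha, beta, alpha_q_pos, beta_k_pos = NULL,
                       deamidation = integer(0), oxidation = integer(0),
                       charges = 2:5, id = NULL, max_mods = 5L) {
  a <- strsplit(alpha, "")[[1]]
  b <- strsplit(beta, "")[[1]]
  alpha_q_pos <- as.integer(alpha_q_pos)
  if (alpha_q_pos < 1L || alpha_q_pos > length(a) || a[alpha_q_pos] != "Q")
    stop("alpha_q_pos must index a Q in alpha (got position ", alpha_q_pos, ")")
  if (is.null(beta_k_pos)) {
    kp <- which(b == "K")
    if (length(kp) != 1L)
      stop("beta_k_pos must be given when beta does not contain exactly one K")
    beta_k_pos <- kp
  }
  beta_k_pos <- as.integer(beta_k_pos)
  if (beta_k_pos < 1L || beta_k_pos > length(b) || b[beta_k_pos] != "K")
    stop("beta_k_pos must index a K in beta (got position ", beta_k_pos, ")")
  deamidation <- sort(as.integer(deamidation))
  oxidation <- sort(as.integer(oxidation))
  if (alpha_q_pos %in% deamidation)
    stop("deamidation cannot be placed on the crosslinked Q (position ",
         alpha_q_pos, ")")
  if (1L + length(deamidation) + length(oxidation) > max_mods)
    stop("more than ", max_mods, " variable modifications (including the crosslink)")
  charges <- sort(unique(as.integer(charges)))
  stopifnot(all(charges >= 1L), all(charges <= 5L))
  # validates residue compatibility of the modification positions
  peptide_composition(alpha, deamidation = deamidation, oxidation = oxidation)
  structure(list(alpha = alpha, beta = beta,
                 alpha_q_pos = alpha_q_pos, beta_k_pos = beta_k_pos,
                 deamidation = deamidation, oxidation = oxidation,
                 charges = charges, id = id),
            class = "isopeptide")
}

#' @export
print.isopeptide <- function(x, ...) {
  a <- strsplit(x$alpha, "")[[1]]
  a[x$alpha_q_pos] <- paste0("[", a[x$alpha_q_pos], "]")
  if (length(x$deamidation)) a[x$deamidation] <- paste0(tolower(strsplit(x$alpha, "")[[1]][x$deamidation]), "(de)")
  b <- strsplit(x$beta, "")[[1]]
  b[x$beta_k_pos] <- paste0("[", b[x$beta_k_pos], "]")
  cat("<isopeptide", if (!is.null(x$id)) paste0(" ", x$id), ">\n", sep = "")
  cat("  alpha:", paste(a, collapse = ""), "\n")
  cat("  beta: ", paste(b, collapse = ""), "\n")
  cat(sprintf("  M = %.4f Da; charges %s\n", precursor_mass(x),
              paste(x$charges, collapse = ",")))
  invisible(x)
}

#' Neutral monoisotopic precursor mass of an isopeptide
#'
#' \code{mass(alpha with modifications) + mass(beta) - mass(NH3)}; symmetric
#' in which side is treated as the base.
#'
#' @param iso an \code{\link{isopeptide}}.
#' @return neutral monoisotopic mass in Da.
#' @export
precursor_mass <- function(iso) {
  stopifnot(inherits(iso, "isopeptide"))
  peptide_mass(iso$alpha, deamidation = iso$deamidation, oxidation = iso$oxidation) +
    monoisotopic_mass(xlink_modification_composition(iso$beta))
}

#' Precursor m/z values of an isopeptide
#' @param iso an \code{\link{isopeptide}}.
#' @param charges charges to report (default: the isopeptide's own).
#' @return named numeric vector of m/z per charge.
#' @export
precursor_mz <- function(iso, charges = iso$charges) {
  m <- precursor_mass(iso)
  stats::setNames(mass_to_mz(m, charges), paste0("z", charges))
}

#' Fragment enumeration configuration
#'
#' @param ion_types subset of \code{c("b", "y", "a")} (a = b - CO).
#' @param losses neutral losses to generate: subset of \code{c("H2O", "NH3")}.
#' @param loss_mode \code{"residue"}: H2O loss only from fragments containing
#'   S/T/E/D and NH3 loss only from fragments containing R/K/N/Q (the partner
#'   peptide counts when carried); \code{"always"}: generate all losses.
#' @param max_charge maximum fragment charge (default 3).
#' @param internal generate interior b-type internal ions.
#' @param internal_length length bounds for internal ions (default 2-12).
#' @param truncated_partner additionally generate spanning ions in which the
#'   carried partner peptide is itself truncated to a b/y sub-fragment still
#'   containing its crosslink residue.
#' @return a config list for \code{\link{enumerate_fragments}}.
#' @export
fragment_config <- function(ion_types = c("b", "y", "a"),
                            losses = c("H2O", "NH3"),
                            loss_mode = c("residue", "always"),
                            max_charge = 3L,
                            internal = TRUE,
                            internal_length = c(2L, 12L),
                            truncated_partner = FALSE) {
  bad <- setdiff(ion_types, c("b", "y", "a"))
  if (length(bad)) stop("unsupported ion type(s): ", paste(bad, collapse = ", "))
  stopifnot(all(losses %in% c("H2O", "NH3")), max_charge >= 1L, max_charge <= 3L,
            length(internal_length) == 2L, internal_length[1] >= 2L)
  list(ion_types = ion_types, losses = losses, loss_mode = match.arg(loss_mode),
       max_charge = as.integer(max_charge), internal = isTRUE(internal),
       internal_length = as.integer(internal_length),
       truncated_partner = isTRUE(truncated_partner))
}

# Per-residue monoisotopic masses of a side, with modification deltas applied.
.side_residue_masses <- function(sequence, deamidation = integer(0),
                                 oxidation = integer(0)) {
  res <- strsplit(sequence, "")[[1]]
  rm <- .residue_masses_tab()[res]
  dd <- monoisotopic_mass(elem_comp(H = -1L, N = -1L, O = 1L))
  if (length(deamidation)) rm[deamidation] <- rm[deamidation] + dd
  if (length(oxidation)) rm[oxidation] <- rm[oxidation] + .ELEMENTS$O$mono
  unname(rm)
}

# Partner contribution masses for spanning ions: full partner minus NH3, plus
# (optionally) truncated partner b/y sub-fragments containing the crosslink
# residue. Returns named numeric vector; names label the partner form.
.partner_masses <- function(sequence, xpos, deamidation = integer(0),
                            oxidation = integer(0), truncated = FALSE) {
  rm <- .side_residue_masses(sequence, deamidation, oxidation)
  n <- length(rm)
  h2o <- monoisotopic_mass(elem_comp(H = 2L, O = 1L))
  nh3 <- monoisotopic_mass(elem_comp(N = 1L, H = 3L))
  out <- c(full = sum(rm) + h2o - nh3)
  if (truncated && n > 1L) {
    cs <- cumsum(rm)
    for (k in seq(xpos, n - 1L)) out[paste0("b", k)] <- cs[k] - nh3
    for (k in seq(n - xpos + 1L, n - 1L)) out[paste0("y", k)] <- (cs[n] - cs[n - k]) + h2o - nh3
  }
  out
}

# computed from the atomic-mass table: 2H+O and N+3H
.loss_masses <- c(H2O = 2 * 1.00782503207 + 15.99491461956,
                  NH3 = 14.0030740048 + 3 * 1.00782503207)

#' Enumerate theoretical fragments of an isopeptide
#'
#' For each side, b/y ions of every prefix/suffix (and a = b - CO), with
#' interior b-type internal ions; ions whose residue range contains the
#' crosslink position carry the partner peptide's mass minus NH3
#' (\code{carries_partner}). Water/ammonia-loss variants and charges
#' 1..max are applied; duplicates on (side, type, bounds, loss, charge,
#' partner form) are removed.
#'
#' @param iso an \code{\link{isopeptide}}.
#' @param config a \code{\link{fragment_config}}.
#' @return data.frame with columns \code{side} ("alpha"/"beta"), \code{type}
#'   ("a"/"b"/"y"/"internal"), \code{start}, \code{end} (1-based bounds on the
#'   side), \code{index} (ladder index for a/b/y ions), \code{loss},
#'   \code{charge}, \code{mz}, \code{carries_partner}, \code{partner_form}.
#' @export
enumerate_fragments <- function(iso, config = fragment_config()) {
  stopifnot(inherits(iso, "isopeptide"))
  h2o <- .loss_masses[["H2O"]]
  co <- 12 + 15.99491461956  # CO, for a = b - CO
  sides <- list(
    alpha = list(seq = iso$alpha, xpos = iso$alpha_q_pos,
                 dea = iso$deamidation, ox = iso$oxidation,
                 partner = iso$beta, partner_xpos = iso$beta_k_pos,
                 partner_dea = integer(0), partner_ox = integer(0)),
    beta = list(seq = iso$beta, xpos = iso$beta_k_pos,
                dea = integer(0), ox = integer(0),
                partner = iso$alpha, partner_xpos = iso$alpha_q_pos,
                partner_dea = iso$deamidation, partner_ox = iso$oxidation)
  )
  per_side <- lapply(names(sides), function(sname) {
    s <- sides[[sname]]
    res <- strsplit(s$seq, "")[[1]]
    rm <- .side_residue_masses(s$seq, s$dea, s$ox)
    n <- length(rm)
    cs <- c(0, cumsum(rm))
    # cumulative counts of loss-triggering residues, for O(1) range queries
    ch2o <- c(0L, cumsum(res %in% c("S", "T", "E", "D")))
    cnh3 <- c(0L, cumsum(res %in% c("R", "K", "N", "Q")))
    pres <- strsplit(s$partner, "")[[1]]
    p_h2o <- any(pres %in% c("S", "T", "E", "D"))
    p_nh3 <- any(pres %in% c("R", "K", "N", "Q"))
    pmass <- .partner_masses(s$partner, s$partner_xpos, s$partner_dea, s$partner_ox,
                             truncated = config$truncated_partner)
    type <- character(0); start <- integer(0); end <- integer(0)
    neutral <- numeric(0)
    if (n >= 2L) {
      i <- seq_len(n - 1L)
      if ("b" %in% config$ion_types) {
        type <- c(type, rep("b", n - 1L)); start <- c(start, rep(1L, n - 1L))
        end <- c(end, i); neutral <- c(neutral, cs[i + 1L])
      }
      if ("a" %in% config$ion_types) {
        type <- c(type, rep("a", n - 1L)); start <- c(start, rep(1L, n - 1L))
        end <- c(end, i); neutral <- c(neutral, cs[i + 1L] - co)
      }
      if ("y" %in% config$ion_types) {
        type <- c(type, rep("y", n - 1L)); start <- c(start, n - i + 1L)
        end <- c(end, rep(n, n - 1L))
        neutral <- c(neutral, cs[n + 1L] - cs[n - i + 1L] + h2o)
      }
    }
    if (config$internal && n >= 4L) {
      st <- rep(2:(n - 1L), each = config$internal_length[2] - config$internal_length[1] + 1L)
      en <- st + rep(seq(config$internal_length[1], config$internal_length[2]) - 1L,
                     times = n - 2L)
      ok <- en <= n - 1L
      st <- st[ok]; en <- en[ok]
      if (length(st)) {
        type <- c(type, rep("internal", length(st)))
        start <- c(start, st); end <- c(end, en)
        neutral <- c(neutral, cs[en + 1L] - cs[st])
      }
    }
    if (!length(type)) return(NULL)
    covers <- start <= s$xpos & s$xpos <= end
    # expand covering fragments over the partner forms
    pf_names <- names(pmass)
    base <- data.frame(type = type, start = start, end = end,
                       neutral = neutral, stringsAsFactors = FALSE)
    cols <- c("type", "start", "end", "neutral", "carries_partner", "partner_form")
    plain <- base[!covers, , drop = FALSE]
    plain$carries_partner <- logical(nrow(plain))
    plain$partner_form <- character(nrow(plain))
    xl <- base[covers, , drop = FALSE]
    k <- length(pf_names)
    xl <- xl[rep(seq_len(nrow(xl)), each = k), , drop = FALSE]
    xl$partner_form <- rep(pf_names, times = sum(covers))
    xl$neutral <- xl$neutral + unname(pmass[xl$partner_form])
    xl$carries_partner <- rep(TRUE, nrow(xl))
    df <- rbind(plain[, cols, drop = FALSE], xl[, cols, drop = FALSE])
    df$side <- sname
    df$index <- ifelse(df$type %in% c("a", "b"), df$end,
                       ifelse(df$type == "y", n - df$start + 1L, NA_integer_))
    # loss eligibility per fragment
    always <- config$loss_mode == "always"
    df$can_h2o <- "H2O" %in% config$losses &
      (always | (ch2o[df$end + 1L] - ch2o[df$start] > 0L) |
         (df$carries_partner & p_h2o))
    df$can_nh3 <- "NH3" %in% config$losses &
      (always | (cnh3[df$end + 1L] - cnh3[df$start] > 0L) |
         (df$carries_partner & p_nh3))
    df
  })
  df <- do.call(rbind, per_side[!vapply(per_side, is.null, logical(1))])
  if (is.null(df) || !nrow(df)) {
    return(data.frame(side = character(0), type = character(0),
                      start = integer(0), end = integer(0), index = integer(0),
                      loss = character(0), charge = integer(0), mz = numeric(0),
                      carries_partner = logical(0), partner_form = character(0),
                      stringsAsFactors = FALSE))
  }
  # expand loss variants
  loss_tab <- list(none = rep(TRUE, nrow(df)), H2O = df$can_h2o, NH3 = df$can_nh3)
  pieces <- lapply(names(loss_tab), function(l) {
    sub <- df[loss_tab[[l]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub$loss <- l
    sub$neutral <- sub$neutral - if (l == "none") 0 else .loss_masses[[l]]
    sub
  })
  df <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  # expand charges
  zmax <- config$max_charge
  df <- df[rep(seq_len(nrow(df)), each = zmax), , drop = FALSE]
  df$charge <- rep(seq_len(zmax), times = nrow(df) / zmax)
  df$mz <- (df$neutral + df$charge * PROTON_MASS) / df$charge
  df <- df[, c("side", "type", "start", "end", "index", "loss", "charge",
               "mz", "carries_partner", "partner_form")]
  df <- unique(df)
  df <- df[order(df$mz, df$side, df$type, df$start, df$end, df$loss, df$charge), ]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match observed peaks to theoretical fragments
#'
#' Deterministic one-to-one matching within an absolute m/z tolerance: for
#' each theoretical fragment (processed in ascending m/z), the nearest
#' unassigned peak within tolerance is taken; ties are broken toward higher
#' intensity, then lower peak index.
#'
#' @param spectrum a spectrum list with numeric \code{mz} (sorted ascending)
#'   and \code{intensity}.
#' @param fragments data.frame from \code{\link{enumerate_fragments}}.
#' @param tol absolute fragment tolerance in Da (default 0.5).
#' @return \code{fragments} subset with extra columns \code{peak} (index into
#'   the spectrum), \code{obs_mz}, \code{obs_intensity}, \code{error}.
#' @export
match_fragments <- function(spectrum, fragments, tol = 0.5) {
  stopifnot(tol > 0, !is.unsorted(spectrum$mz))
  if (nrow(fragments) == 0L || length(spectrum$mz) == 0L) {
    out <- fragments[integer(0), , drop = FALSE]
    out$peak <- integer(0); out$obs_mz <- numeric(0)
    out$obs_intensity <- numeric(0); out$error <- numeric(0)
    return(out)
  }
  ord <- order(fragments$mz, fragments$side, fragments$type,
               fragments$start, fragments$end, fragments$loss, fragments$charge)
  frag <- fragments[ord, , drop = FALSE]
  taken <- logical(length(spectrum$mz))
  hit <- integer(nrow(frag))
  for (i in seq_len(nrow(frag))) {
    lo <- findInterval(frag$mz[i] - tol, spectrum$mz) + 1L
    hi <- findInterval(frag$mz[i] + tol, spectrum$mz)
    if (hi < lo) { hit[i] <- NA_integer_; next }
    cand <- seq(lo, hi)
    cand <- cand[!taken[cand]]
    if (!length(cand)) { hit[i] <- NA_integer_; next }
    d <- abs(spectrum$mz[cand] - frag$mz[i])
    best <- cand[d == min(d)]
    if (length(best) > 1L) {
      best <- best[spectrum$intensity[best] == max(spectrum$intensity[best])]
      best <- best[1L]
    }
    taken[best] <- TRUE
    hit[i] <- best
  }
  keep <- !is.na(hit)
  out <- frag[keep, , drop = FALSE]
  out$peak <- hit[keep]
  out$obs_mz <- spectrum$mz[out$peak]
  out$obs_intensity <- spectrum$intensity[out$peak]
  out$error <- out$obs_mz - out$mz
  rownames(out) <- NULL
  out
}

#' Write a fragment (or annotation) table as TSV
#' @param fragments data.frame from \code{\link{enumerate_fragments}} or
#'   \code{\link{match_fragments}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
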