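# In-silico digestion of gluten proteins (pepsin + trypsin + chymotrypsin)
# and of TG2 (trypsin), plus selection of single-lysine TG2 donor peptides.

#' The seven single-lysine TG2 tryptic peptides used as crosslink donors
#'
#' Tryptic TG2 peptides each containing exactly one lysine (K205, K265, K429,
#' K468, K590, K600, K677 of the TG2 sequence), used reciprocally as the
#' beta-side of searched isopeptides.
#' @export
TG2_DONOR_PEPTIDES <- c(
  K205 = "FLKNAGR",
  K265 = "WKNHGCQR",
  K429 = "ISTKSVGR",
  K468 = "LAEKEETGMAMR",
  K590 = "DLYLENPEIKIR",
  K600 = "QKR",
  K677 = "AVKGFR"
)

.BUILTIN_RULES <- list(
  trypsin      = list(enzyme = "trypsin",      p1 = c("K", "R"),      p1prime_exclude = "P"),
  chymotrypsin = list(enzyme = "chymotrypsin", p1 = c("F", "Y", "W"), p1prime_exclude = "P"),
  pepsin       = list(enzyme = "pepsin",       p1 = c("F", "L"),      p1prime_exclude = "P")
)

#' Cleavage rules
#'
#' A cleavage rule is a pure function of the local sequence context: cleavage
#' occurs after a P1 residue unless the following (P1') residue is excluded.
#' Built-ins: \code{trypsin} (after K/R, not before P), \code{chymotrypsin}
#' (high specificity: after F/Y/W, not before P) and \code{pepsin}
#' (pH 1.3-2 convention: after F/L, not before P). Custom rules can be
#' supplied to \code{\link{digest}} in the same list form.
#'
#' @param enzyme name of a built-in rule, or a list with fields
#'   \code{enzyme}, \code{p1} (character vector of P1 residues) and
#'   \code{p1prime_exclude} (residues blocking cleavage when at P1').
#' @return a cleavage-rule list.
#' @export
cleavage_rule <- function(enzyme) {
  if (is.list(enzyme)) {
    stopifnot(all(c("enzyme", "p1") %in% names(enzyme)))
    if (is.null(enzyme$p1prime_exclude)) enzyme$p1prime_exclude <- character(0)
    return(enzyme)
  }
  rule <- .BUILTIN_RULES[[match.arg(enzyme, names(.BUILTIN_RULES))]]
  rule
}

#' Cleavage sites of one or more enzymes
#'
#' @param sequence protein sequence.
#' @param enzymes character vector of built-in enzyme names and/or list rules.
#' @return sorted integer positions \code{i}: cleavage between residues
#'   \code{i} and \code{i + 1} (never 0 or \code{nchar(sequence)}).
#' @export
cleavage_sites <- function(sequence, enzymes) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  sites <- integer(0)
  rules <- lapply(if (is.list(enzymes) && !is.null(enzymes$p1)) list(enzymes) else enzymes,
                  cleavage_rule)
  for (rule in rules) {
    i <- which(res[-n] %in% rule$p1)
    i <- i[!res[i + 1L] %in% rule$p1prime_exclude]
    sites <- union(sites, i)
  }
  sort(sites)
}

#' Digest a protein in silico
#'
#' Multi-enzyme digestion against the union of all active enzymes' cleavage
#' sites ("specific" single-pass search semantics); missed cleavages are
#' counted against that union. In \code{semi} mode, peptides specific at only
#' one terminus are additionally produced (flagged via the specificity
#' columns), which covers unspecific cleavage at one end.
#'
#' @param protein protein sequence (non-empty).
#' @param enzymes enzymes, as in \code{\link{cleavage_sites}}; must be non-empty.
#' @param max_missed maximum internal (missed) cleavage sites, >= 0.
#' @param specificity \code{"full"} or \code{"semi"}.
#' @param min_length,max_length peptide length bounds (defaults 1 and Inf;
#'   search candidate generation uses 5-30).
#' @param protein_id identifier recorded in the output.
#' @return data.frame with columns \code{sequence}, \code{protein},
#'   \code{start}, \code{end} (1-based inclusive), \code{missed},
#'   \code{nterm_specific}, \code{cterm_specific}.
#' @examples
#' digest("AKPRGK", "trypsin", max_missed = 0)$sequence  # "AKPR" "GK"
#' @export
digest <- function(protein, enzymes, max_missed = 2L, specificity = c("full", "semi"),
                   min_length = 1L, max_length = Inf, protein_id = "protein") {
  specificity <- match.arg(specificity)
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein),
            max_missed >= 0L)
  if (length(enzymes) == 0L) stop("at least one cleavage rule is required")
  n <- nchar(protein)
  sites <- cleavage_sites(protein, enzymes)
  bounds <- c(0L, sites, n)          # peptide (i, j): residues bounds[i]+1 .. bounds[j]
  nb <- length(bounds)
  out <- list()
  k <- 1L
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in seq(i + 1L, jmax)) {
      len <- bounds[j] - bounds[i]
      if (len < min_length || len > max_length) next
      out[[k]] <- c(bounds[i] + 1L, bounds[j], j - i - 1L, 1L, 1L)
      k <- k + 1L
    }
  }
  if (specificity == "semi") {
    site_set <- c(0L, sites, n)
    for (i in seq_len(nb - 1L)) {
      # specific N-terminus, ragged C-terminus (and vice versa)
      s <- bounds[i] + 1L
      emax <- if (is.finite(max_length)) min(n, s + max_length - 1L) else n
      for (e in seq(s + min_length - 1L, emax)) {
        if (e < s || e > n) next
        internal <- sum(sites >= s & sites < e)
        if (internal > max_missed) next
        if (e %in% site_set) next   # fully specific, already emitted
        out[[k]] <- c(s, e, internal, 1L, 0L)
        k <- k + 1L
      }
    }
    for (j in seq(2L, nb)) {
      e <- bounds[j]
      smin <- if (is.finite(max_length)) max(1L, e - max_length + 1L) else 1L
      for (s in seq(smin, e - min_length + 1L)) {
        if (s < 1L) next
        if ((s - 1L) %in% site_set) next
        internal <- sum(sites >= s & sites < e)
        if (internal > max_missed) next
        out[[k]] <- c(s, e, internal, 0L, 1L)
        k <- k + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence = character(0), protein = character(0),
                      start = integer(0), end = integer(0), missed = integer(0),
                      nterm_specific = logical(0), cterm_specific = logical(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(
    sequence = substring(protein, m[, 1], m[, 2]),
    protein = protein_id,
    start = m[, 1], end = m[, 2], missed = m[, 3],
    nterm_specific = as.logical(m[, 4]), cterm_specific = as.logical(m[, 5]),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Digest every record of a protein database
#'
#' @param proteins named character vector of protein sequences (names are ids),
#'   e.g. from \code{\link{read_fasta}}.
#' @param ... passed to \code{\link{digest}}.
#' @return row-bound peptide data.frame, deduplicated on
#'   (sequence, protein, start, end).
#' @export
digest_database <- function(proteins, ...) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  do.call(rbind, lapply(names(proteins), function(id) {
    digest(proteins[[id]], protein_id = id, ...)
  }))
}

#' Single-lysine tryptic TG2 donor peptides
#'
#' Tryptic peptides of the TG2 sequence containing exactly one lysine,
#' chosen as crosslink donors to avoid ambiguity on the TG2 side. The seven
#' selected peptides (\code{\link{TG2_DONOR_PEPTIDES}}) form a named subset
#' selectable via \code{donors_only}.
#'
#' @param tg2_sequence TG2 protein sequence (e.g. from the packaged fixture,
#'   \code{\link{load_tg2_sequence}}).
#' @param max_missed maximum missed tryptic cleavages (default 2).
#' @param donors_only if TRUE, restrict to the seven selected donor peptides.
#' @return peptide data.frame as from \code{\link{digest}}, plus a
#'   \code{k_pos} column (1-based lysine position within the peptide).
#' @export
tg2_donor_peptides <- function(tg2_sequence, max_missed = 2L, donors_only = FALSE) {
  if (!nzchar(tg2_sequence)) {
    return(data.frame(sequence = character(0), protein = character(0),
                      start = integer(0), end = integer(0), missed = integer(0),
                      nterm_specific = logical(0), cterm_specific = logical(0),
                      k_pos = integer(0), stringsAsFactors = FALSE))
  }
  pep <- digest(tg2_sequence, "trypsin", max_missed = max_missed, protein_id = "TG2")
  nk <- vapply(strsplit(pep$sequence, ""), function(r) sum(r == "K"), integer(1))
  pep <- pep[nk == 1L, , drop = FALSE]
  pep$k_pos <- vapply(pep$sequence, function(s) as.integer(regexpr("K", s, fixed = TRUE)),
                      integer(1), USE.NAMES = FALSE)
  if (donors_only) pep <- pep[pep$sequence %in% TG2_DONOR_PEPTIDES, , drop = FALSE]
  rownames(pep) <- NULL
  pep
}

#' Read a protein FASTA file
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
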