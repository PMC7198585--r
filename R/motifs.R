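# TG2 sequence-specificity bookkeeping: classification of glutamine contexts
# into the deamidation/crosslinking specificity motifs and summary counts.
#
# Preferred TG2 targets are Q in QXP, QXXF(Y/W/M/L/I/V) or QXPF(Y/W/M/L/I/V)
# (X = any residue except P); QP and QXXP are poor or non-targets.

.FSTAR <- c("F", "Y", "W", "M", "L", "I", "V")

#' Classify the sequence context of a glutamine
#'
#' Deterministic label with fixed precedence QP > QXPF* > QXP > QXXF* > QXXP >
#' other (QP and QXP cannot overlap since X excludes P; precedence only
#' resolves QXPF* toward the more specific label). F* denotes
#' \{F, Y, W, M, L, I, V\}. When residues needed to decide are missing at the
#' peptide C-terminus the label is \code{insufficient-context}. Context is
#' evaluated within the peptide as given, not the parent protein.
#'
#' @param sequence peptide sequence.
#' @param q_pos 1-based position; must hold a Q.
#' @return one of \code{"QP"}, \code{"QXPF*"}, \code{"QXP"}, \code{"QXXF*"},
#'   \code{"QXXP"}, \code{"other"}, \code{"insufficient-context"}.
#' @examples
#' classify_glutamine_context("WQIPEQSR", 2)  # "QXP"
#' classify_glutamine_context("PYSQPQPF", 4)  # "QP"
#' @export
classify_glutamine_context <- function(sequence, q_pos) {
  res <- strsplit(sequence, "")[[1]]
  q_pos <- as.integer(q_pos)
  if (q_pos < 1L || q_pos > length(res) || res[q_pos] != "Q")
    stop("position ", q_pos, " of ", sequence, " is not a glutamine")
  at <- function(k) if (q_pos + k <= length(res)) res[q_pos + k] else NA_character_
  r1 <- at(1L); r2 <- at(2L); r3 <- at(3L)
  if (is.na(r1)) return("insufficient-context")
  if (r1 == "P") return("QP")
  if (is.na(r2)) return("insufficient-context")
  if (r2 == "P") {
    if (!is.na(r3) && r3 %in% .FSTAR) return("QXPF*")
    return("QXP")
  }
  if (is.na(r3)) return("insufficient-context")
  if (r3 %in% .FSTAR) return("QXXF*")
  if (r3 == "P") return("QXXP")
  "other"
}

.MOTIF_LEVELS <- c("QP", "QXPF*", "QXP", "QXXF*", "QXXP", "other",
                   "insufficient-context")

# split a comma-separated position string into integers
.pos_vec <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Motif summary of crosslink and deamidation sites
#'
#' Contingency of motif label by site kind over the unambiguously localized
#' sites of a set of isopeptide records; ambiguous sites are reported
#' separately in \code{attr(, "ambiguous")}.
#'
#' @param records data.frame in the packaged fixture layout (see
#'   \code{\link{load_isopeptide_records}}): columns \code{id},
#'   \code{gluten_peptide}, \code{q_pos}, \code{q_ambiguous},
#'   \code{deamidation}, \code{deamidation_ambiguous}.
#' @param collapse_qxpf fold \code{QXPF*} sites into the \code{QXP} row
#'   (default TRUE): QXPF* is the sub-motif of QXP with an F-class residue
#'   at +3, and summary counts are conventionally reported at the QXP level.
#' @return data.frame with columns \code{motif}, \code{crosslink},
#'   \code{deamidation} (site counts; all motif levels present, zero-filled).
#' @export
motif_summary <- function(records, collapse_qxpf = TRUE) {
  xl <- character(0); de <- character(0)
  amb <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!is.na(r$q_pos)) {
      xl <- c(xl, classify_glutamine_context(r$gluten_peptide, r$q_pos))
    }
    qa <- .pos_vec(r$q_ambiguous)
    if (length(qa))
      amb[[length(amb) + 1L]] <- data.frame(id = r$id, kind = "crosslink",
                                            positions = r$q_ambiguous,
                                            stringsAsFactors = FALSE)
    for (d in .pos_vec(r$deamidation))
      de <- c(de, classify_glutamine_context(r$gluten_peptide, d))
    da <- .pos_vec(r$deamidation_ambiguous)
    if (length(da))
      amb[[length(amb) + 1L]] <- data.frame(id = r$id, kind = "deamidation",
                                            positions = r$deamidation_ambiguous,
                                            stringsAsFactors = FALSE)
  }
  if (collapse_qxpf) {
    xl[xl == "QXPF*"] <- "QXP"
    de[de == "QXPF*"] <- "QXP"
  }
  out <- data.frame(
    motif = .MOTIF_LEVELS,
    crosslink = as.integer(table(factor(xl, levels = .MOTIF_LEVELS))),
    deamidation = as.integer(table(factor(de, levels = .MOTIF_LEVELS))),
    stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- if (length(amb)) do.call(rbind, amb) else
    data.frame(id = character(0), kind = character(0), positions = character(0))
  out
}

#' Exact epitope substring lookup
#'
#' Convenience bookkeeping: which user-supplied epitope core sequences (e.g.
#' 9-mers) occur verbatim within each peptide. No alignment or partial
#' matching is attempted.
#'
#' @param peptides character vector of peptide sequences.
#' @param epitopes named or unnamed character vector of epitope sequences
#'   (default empty).
#' @return data.frame with columns \code{peptide}, \code{epitope} (one row
#'   per hit).
#' @export
find_epitopes <- function(peptides, epitopes = character(0)) {
  hits <- list()
  for (p in peptides) for (e in epitopes) {
    if (grepl(e, p, fixed = TRUE))
      hits[[length(hits) + 1L]] <- data.frame(peptide = p, epitope = e,
                                              stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(peptide = character(0), epitope = character(0))
}
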