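# Packaged transcription of the published isopeptide tables and the
# reference sequence fixtures.
#
# The TG2 and gluten FASTA files are synthetic scaffolds (labelled so in
# their filenames and headers): they embed the real peptide sequences of
# interest — the seven single-lysine TG2 tryptic donor peptides at their
# true lysine positions, and the identified gluten peptides — inside
# artificial filler, so that no network access is ever needed.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "glutenxl")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p)) stop("fixture not found: ", file)
  p
}

#' Load the transcribed isopeptide records
#'
#' The 29 isopeptides identified between TG2 and wheat (W1-W13), rye (R1-R6)
#' and barley (B1-B10) gluten peptides, with TG2 lysine, gluten peptide,
#' crosslinked glutamine position (NA with candidates in \code{q_ambiguous}
#' when not unambiguously localized), deamidation positions, and flags.
#' The fixture is validated on load; corruption fails hard with field-level
#' diagnostics.
#'
#' @param path optional path to a fixture TSV in the packaged layout
#'   (defaults to the packaged transcription).
#' @return data.frame of 29 records.
#' @export
load_isopeptide_records <- function(path = .fixture_path("tg2_gluten_isopeptides.tsv")) {
  df <- utils::read.delim(path,
                          stringsAsFactors = FALSE,
                          colClasses = list(q_ambiguous = "character",
                                            deamidation = "character",
                                            deamidation_ambiguous = "character",
                                            note = "character"))
  for (cc in c("q_ambiguous", "deamidation", "deamidation_ambiguous", "note"))
    df[[cc]][is.na(df[[cc]])] <- ""
  fail <- function(...) stop("isopeptide fixture corrupt: ", ...)
  if (nrow(df) != 29L) fail("expected 29 records, found ", nrow(df))
  if (anyDuplicated(df$id)) fail("duplicate ids: ",
                                 paste(df$id[duplicated(df$id)], collapse = ", "))
  if (!all(df$tg2_peptide %in% TG2_DONOR_PEPTIDES))
    fail("unknown TG2 peptide in record(s) ",
         paste(df$id[!df$tg2_peptide %in% TG2_DONOR_PEPTIDES], collapse = ", "))
  if (!identical(unname(TG2_DONOR_PEPTIDES[df$tg2_lysine]), df$tg2_peptide))
    fail("tg2_lysine / tg2_peptide mismatch")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    res <- strsplit(r$gluten_peptide, "")[[1]]
    sites <- c(r$q_pos, .pos_vec(r$q_ambiguous), .pos_vec(r$deamidation),
               .pos_vec(r$deamidation_ambiguous))
    sites <- sites[!is.na(sites)]
    if (any(sites < 1L | sites > length(res)))
      fail(r$id, ": site position outside the peptide")
    if (any(res[sites] != "Q"))
      fail(r$id, ": annotated site is not a glutamine (positions ",
           paste(sites[res[sites] != "Q"], collapse = ","), ")")
    if (is.na(r$q_pos) && !nzchar(r$q_ambiguous))
      fail(r$id, ": no crosslink site and no ambiguity candidates")
  }
  kpos <- regexpr("K", df$tg2_peptide, fixed = TRUE)
  if (any(kpos < 1L)) fail("TG2 peptide without lysine")
  df
}

#' Load the synthetic TG2 scaffold sequence
#'
#' A 687-residue synthetic scaffold placing the seven single-lysine tryptic
#' donor peptides at the true TG2 lysine positions (K205, K265, K429, K468,
#' K590, K600, K677); the filler between them is artificial. Suitable for
#' digestion and donor-peptide selection, not for whole-protein analyses.
#'
#' @return a single-element named character vector.
#' @export
load_tg2_sequence <- function() {
  read_fasta(.fixture_path("tg2_p21980_synthetic.fasta"))
}

#' Load the synthetic gluten protein scaffolds
#'
#' Three synthetic gluten-like records (wheat/rye/barley) embedding the
#' identified gluten peptides with enzyme-compatible context.
#'
#' @return named character vector of protein sequences.
#' @export
load_gluten_proteins <- function() {
  read_fasta(.fixture_path("gluten_synthetic.fasta"))
}

#' Convert fixture records to isopeptide objects
#'
#' Records without an unambiguous crosslink site are skipped unless
#' \code{ambiguous = "first"}, which takes the first candidate site (and
#' drops ambiguous deamidations).
#'
#' @param records data.frame from \code{\link{load_isopeptide_records}}
#'   (default) or a compatible subset.
#' @param ambiguous \code{"skip"} or \code{"first"}.
#' @return named list of \code{\link{isopeptide}} objects.
#' @export
fixture_isopeptides <- function(records = load_isopeptide_records(),
                                ambiguous = c("skip", "first")) {
  ambiguous <- match.arg(ambiguous)
  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    q <- r$q_pos
    if (is.na(q)) {
      if (ambiguous == "skip") next
      q <- .pos_vec(r$q_ambiguous)[1]
    }
    out[[r$id]] <- isopeptide(alpha = r$gluten_peptide, beta = r$tg2_peptide,
                              alpha_q_pos = q,
                              deamidation = .pos_vec(r$deamidation),
                              id = r$id)
  }
  out
}
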