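# Spectrum containers and I/O (MGF, minimal mzML).
#
# A spectrum is a plain list: id, ms_level, mz, intensity, precursor_mz,
# precursor_charge, rt (minutes), iso_mz / iso_width (isolation window,
# used by PRM scan-to-target assignment). A run is a list of spectra.

#' Construct an MS2 spectrum record
#'
#' @param mz,intensity peak arrays (will be sorted by m/z).
#' @param precursor_mz precursor m/z.
#' @param precursor_charge precursor charge (integer, may be NA).
#' @param rt retention time in minutes.
#' @param id spectrum identifier.
#' @param iso_mz,iso_width isolation window center and full width in Th
#'   (defaults: precursor m/z and 1.7).
#' @return a spectrum list.
#' @export
ms2_spectrum <- function(mz, intensity, precursor_mz, precursor_charge = NA_integer_,
                         rt = NA_real_, id = NULL, iso_mz = precursor_mz,
                         iso_width = 1.7) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  list(id = id, ms_level = 2L, mz = as.numeric(mz[ord]),
       intensity = as.numeric(intensity[ord]),
       precursor_mz = as.numeric(precursor_mz),
       precursor_charge = as.integer(precursor_charge),
       rt = as.numeric(rt), iso_mz = as.numeric(iso_mz),
       iso_width = as.numeric(iso_width))
}

#' Write spectra to an MGF file
#'
#' @param spectra list of spectra (see \code{\link{ms2_spectrum}}).
#' @param path output path.
#' @param header optional comment lines written at the top (prefixed \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", if (is.null(sp$id)) "spectrum" else sp$id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$precursor_charge))
      writeLines(paste0("CHARGE=", sp$precursor_charge, "+"), con)
    if (!is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$rt * 60), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file.
#' @return list of spectrum lists. Malformed blocks are skipped with a warning.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    meta <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[meta], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    pm <- suppressWarnings(as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1]))
    if (is.na(pm)) { warning("skipping MGF block ", k, ": missing/invalid PEPMASS"); next }
    ch <- NA_integer_
    if ("CHARGE" %in% keys)
      ch <- suppressWarnings(as.integer(sub("\\+$", "", vals[match("CHARGE", keys)])))
    rt <- NA_real_
    if ("RTINSECONDS" %in% keys)
      rt <- suppressWarnings(as.numeric(vals[match("RTINSECONDS", keys)])) / 60
    peaks <- block[!meta & nzchar(trimws(block))]
    pm2 <- do.call(rbind, lapply(strsplit(trimws(peaks), "\\s+"), function(x)
      suppressWarnings(as.numeric(x[1:2]))))
    if (is.null(pm2)) pm2 <- matrix(numeric(0), ncol = 2)
    if (anyNA(pm2)) { warning("skipping MGF block ", k, ": unparseable peak line"); next }
    out[[k]] <- ms2_spectrum(pm2[, 1], pm2[, 2], precursor_mz = pm,
                             precursor_charge = ch, rt = rt,
                             id = if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("scan_", k))
    keep[k] <- TRUE
  }
  out[keep]
}

.b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
}

.b64_decode_doubles <- function(s) {
  readBin(jsonlite::base64_dec(s), numeric(), n = 1e7, size = 8, endian = "little")
}

#' Write spectra as minimal mzML
#'
#' Emits a small, uncompressed, 64-bit little-endian mzML document carrying
#' ms level, retention time, precursor and isolation-window information —
#' enough for downstream PRM chromatogram extraction and for third-party
#' readers.
#'
#' @inheritParams write_mgf
#' @return \code{path}, invisibly.
#' @export
write_mzml <- function(spectra, path, header = NULL) {
  n <- length(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  if (!is.null(header)) w('  <!-- ', header, ' -->')
  w('  <cvList count="1">')
  w('    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  w('  </cvList>')
  w('  <fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>')
  w('  <run id="run">')
  w('    <spectrumList count="', n, '">')
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    id <- if (is.null(sp$id)) paste0("scan=", i) else sp$id
    mzb <- .b64_doubles(sp$mz)
    inb <- .b64_doubles(sp$intensity)
    w('      <spectrum index="', i - 1L, '" id="', id, '" defaultArrayLength="', length(sp$mz), '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="', sp$ms_level, '"/>')
    if (!is.na(sp$rt)) {
      w('        <scanList count="1"><scan>',
        '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
        sprintf("%.6f", sp$rt), '" unitName="minute"/>',
        '</scan></scanList>')
    }
    if (sp$ms_level >= 2L && !is.na(sp$precursor_mz)) {
      w('        <precursorList count="1"><precursor>')
      w('          <isolationWindow>')
      w('            <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="',
        sprintf("%.6f", sp$iso_mz), '"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="',
        sprintf("%.4f", sp$iso_width / 2), '"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="',
        sprintf("%.4f", sp$iso_width / 2), '"/>')
      w('          </isolationWindow>')
      w('          <selectedIonList count="1"><selectedIon>')
      w('            <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="',
        sprintf("%.6f", sp$precursor_mz), '"/>')
      if (!is.na(sp$precursor_charge))
        w('            <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="',
          sp$precursor_charge, '"/>')
      w('          </selectedIon></selectedIonList>')
      w('        </precursor></precursorList>')
    }
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="', nchar(mzb), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>')
    w('            <binary>', mzb, '</binary>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="', nchar(inb), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>')
    w('            <binary>', inb, '</binary>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

#' Read spectra from a minimal mzML file
#'
#' Parses the subset of mzML emitted by \code{\link{write_mzml}} (uncompressed
#' 64-bit arrays) via xml2.
#'
#' @param path mzML file.
#' @return list of spectrum lists.
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  lapply(specs, function(node) {
    cv <- function(scope, acc) {
      n <- xml2::xml_find_first(node, paste0(".//", scope, "cvParam[@accession='", acc, "']"))
      if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
    }
    ms_level <- as.integer(cv("", "MS:1000511"))
    rt <- suppressWarnings(as.numeric(cv("", "MS:1000016")))
    pre <- suppressWarnings(as.numeric(cv("", "MS:1000744")))
    ch <- suppressWarnings(as.integer(cv("", "MS:1000041")))
    iso <- suppressWarnings(as.numeric(cv("", "MS:1000827")))
    lo <- suppressWarnings(as.numeric(cv("", "MS:1000828")))
    hi <- suppressWarnings(as.numeric(cv("", "MS:1000829")))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    mz <- numeric(0); intensity <- numeric(0)
    for (a in arrays) {
      is_mz <- length(xml2::xml_find_all(a, ".//cvParam[@accession='MS:1000514']")) > 0
      raw64 <- xml2::xml_text(xml2::xml_find_first(a, ".//binary"))
      vals <- if (nzchar(raw64)) .b64_decode_doubles(raw64) else numeric(0)
      if (is_mz) mz <- vals else intensity <- vals
    }
    sp <- ms2_spectrum(mz, intensity,
                       precursor_mz = if (is.na(pre)) NA_real_ else pre,
                       precursor_charge = ch, rt = rt,
                       id = xml2::xml_attr(node, "id"),
                       iso_mz = if (is.na(iso)) pre else iso,
                       iso_width = if (is.na(lo) || is.na(hi)) 1.7 else lo + hi)
    sp$ms_level <- ms_level
    sp
  })
}

#' Read spectra from MGF or mzML, dispatching on file extension
#' @param path spectrum file (\code{.mgf}, \code{.mzml}/\code{.mzML}).
#' @return list of spectrum lists.
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mgf = read_mgf(path),
         mzml = read_mzml(path),
         stop("unsupported spectrum file extension: .", ext))
}
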