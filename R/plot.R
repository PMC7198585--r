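#' Plot an annotated MS/MS spectrum
#'
#' Base-graphics peak plot with matched fragments highlighted and labelled
#' by ion (alpha-side b/y in blue/red, beta-side in violet, other matches in
#' orange, unmatched peaks grey).
#'
#' @param spectrum a spectrum list.
#' @param matched data.frame from \code{\link{match_fragments}}.
#' @param main plot title.
#' @return invisibly, the matched table.
#' @export
plot_annotated_spectrum <- function(spectrum, matched, main = "") {
  graphics::plot(spectrum$mz, spectrum$intensity, type = "h", col = "grey70",
                 xlab = "m/z", ylab = "intensity", main = main)
  if (nrow(matched)) {
    col <- ifelse(matched$type %in% c("b", "a") & matched$side == "alpha", "blue",
           ifelse(matched$type == "y" & matched$side == "alpha", "red",
           ifelse(matched$side == "beta", "darkviolet", "orange")))
    graphics::segments(matched$obs_mz, 0, matched$obs_mz, matched$obs_intensity, col = col)
    lab <- paste0(matched$type, ifelse(is.na(matched$index), "", matched$index),
                  ifelse(matched$charge > 1, paste0("^", matched$charge, "+"), ""))
    graphics::text(matched$obs_mz, matched$obs_intensity, lab, pos = 3, cex = 0.6, col = col)
  }
  invisible(matched)
}

#' Plot PRM chromatograms of one target
#'
#' @param chrom list from \code{\link{extract_chromatograms}}.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plot_chromatograms <- function(chrom, main = "") {
  if (!length(chrom$rt)) { graphics::plot.new(); return(invisible(NULL)) }
  graphics::matplot(chrom$rt, chrom$intensity, type = "l", lty = 1,
                    xlab = "retention time (min)", ylab = "intensity", main = main)
  invisible(NULL)
}
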