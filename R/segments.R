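#' Map 8-state DSSP secondary-structure codes to 3 states
#'
#' Uses the standard reduction: H, G, I (helices) to H; E, B (extended /
#' bridge) to E; everything else (T, S, blank, '-') to C.  Unknown codes
#' are mapped to C with a warning.
#'
#' @param dssp8 character string of 8-state codes (may be empty).
#' @return character string over \code{H, E, C} of the same length.
#' @examples
#' map8to3("HGIEBTS ")   # "HHHEECCC"
#' @export
map8to3 <- function(dssp8) {
    stopifnot(is.character(dssp8), length(dssp8) == 1L)
    if (nchar(dssp8) == 0L) return("")
    ch <- strsplit(dssp8, "")[[1]]
    out <- rep("C", length(ch))
    out[ch %in% c("H", "G", "I")] <- "H"
    out[ch %in% c("E", "B")] <- "E"
    known <- c("H", "G", "I", "E", "B", "T", "S", " ", "-")
    if (any(!ch %in% known))
        warning("unknown DSSP code(s) mapped to C: ",
                paste(unique(ch[!ch %in% known]), collapse = ", "))
    paste(out, collapse = "")
}

#' Convert a 3-state secondary-structure string to segments
#'
#' Maximal runs of equal characters become segments; re-expanding the
#' segmentation reproduces the input string exactly.
#'
#' @param ss non-empty string over \code{H, E, C}.
#' @return an \linkS4class{SSSegmentation}.
#' @examples
#' as.data.frame(ssToSegments("CCHHHHHCC"))
#' @export
ssToSegments <- function(ss) {
    stopifnot(is.character(ss), length(ss) == 1L)
    if (nchar(ss) == 0L) stop("empty secondary-structure string")
    ch <- strsplit(ss, "")[[1]]
    if (!all(ch %in% c("H", "E", "C")))
        stop("secondary-structure string may only contain H, E, C")
    r <- rle(ch)
    end <- cumsum(r$lengths)
    new("SSSegmentation", type = r$values,
        start = as.integer(end - r$lengths + 1L), end = as.integer(end))
}

#' Expand a segmentation back to its 3-state string
#'
#' @param seg an \linkS4class{SSSegmentation}.
#' @return the H/E/C string the segmentation encodes.
#' @export
segmentsToSS <- function(seg) {
    stopifnot(is(seg, "SSSegmentation"))
    paste(rep(seg@type, seg@end - seg@start + 1L), collapse = "")
}
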