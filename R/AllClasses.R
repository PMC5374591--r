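#' Secondary-structure segmentation of a protein chain
#'
#' An ordered, gap-free partition of positions \code{1..L} into typed
#' segments.  Segment \code{j} has type \code{H} (helix), \code{E} (strand)
#' or \code{C} (coil), start \code{s(j)} and inclusive end \code{t(j)};
#' \code{s(1) == 1} and \code{s(j+1) == t(j) + 1}.
#'
#' @slot type character vector of segment types, values in \code{H,E,C}.
#' @slot start,end integer vectors of 1-based inclusive bounds.
#'
#' @exportClass SSSegmentation
setClass("SSSegmentation",
         representation(type = "character", start = "integer",
                        end = "integer"))

setValidity("SSSegmentation", function(object) {
    n <- length(object@type)
    if (length(object@start) != n || length(object@end) != n)
        return("type, start and end must have equal length")
    if (n == 0L) return("segmentation must contain at least one segment")
    if (!all(object@type %in% c("H", "E", "C")))
        return("segment types must be H, E or C")
    if (object@start[1L] != 1L)
        return("first segment must start at position 1")
    if (any(object@end < object@start))
        return("segment end before start")
    if (n > 1L && !all(object@start[-1L] == object@end[-n] + 1L))
        return("segments must tile 1..L without gaps or overlaps")
    TRUE
})

#' @describeIn SSSegmentation number of residues covered.
#' @param x,object an \code{SSSegmentation}.
#' @export
setMethod("length", "SSSegmentation",
          function(x) as.integer(x@end[length(x@end)]))

setMethod("show", "SSSegmentation", function(object) {
    cat(sprintf("SSSegmentation: %d segment(s), %d residues\n",
                length(object@type), length(object)))
    cat(" ", paste0(object@type, "[", object@start, "-", object@end, "]",
                    collapse = " "), "\n")
})

#' @describeIn SSSegmentation segments as a data.frame with columns
#'   \code{type}, \code{start}, \code{end}.
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.SSSegmentation <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(type = x@type, start = x@start, end = x@end,
               stringsAsFactors = FALSE)
}

#' One protein chain with features and (optionally) burial labels
#'
#' Bundles the amino-acid sequence, the 3-state secondary-structure string
#' and its segmentation, the singlet feature matrix (one row per residue),
#' the doublet feature matrices at separations 2/3/4, and, for training
#' data, the observed burial labels (buried = 1, exposed = 0).
#'
#' @slot id chain identifier.
#' @slot sequence amino-acid string over the 20 standard letters plus X.
#' @slot ss 3-state secondary-structure string (H/E/C) of the same length.
#' @slot segmentation an \linkS4class{SSSegmentation} covering the chain.
#' @slot singletFeatures numeric matrix, L x D, finite entries.
#' @slot doubletFeatures named list with elements \code{sep2}, \code{sep3},
#'   \code{sep4}; each an L x K numeric matrix whose row i holds the
#'   doublet observations between positions i-d and i (rows with i <= d
#'   are zero-filled).  May be empty for coil-only models.
#' @slot labels integer vector of 0/1 labels, or \code{integer(0)} when
#'   unlabeled.
#'
#' @exportClass ProteinRecord
setClass("ProteinRecord",
         representation(id = "character", sequence = "character",
                        ss = "character", segmentation = "SSSegmentation",
                        singletFeatures = "matrix",
                        doubletFeatures = "list", labels = "integer"))

setValidity("ProteinRecord", function(object) {
    L <- nchar(object@sequence)
    if (L < 1L) return("empty sequence")
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", object@sequence))
        return("sequence letters must be the 20 standard amino acids or X")
    if (nchar(object@ss) != L) return("ss string length != sequence length")
    if (length(object@segmentation) != L)
        return("segmentation does not cover the sequence")
    if (nrow(object@singletFeatures) != L)
        return("singletFeatures must have one row per residue")
    if (!all(is.finite(object@singletFeatures)))
        return("singletFeatures must be finite")
    for (nm in names(object@doubletFeatures)) {
        if (!nm %in% c("sep2", "sep3", "sep4"))
            return("doubletFeatures names must be sep2, sep3, sep4")
        m <- object@doubletFeatures[[nm]]
        if (!is.matrix(m) || nrow(m) != L || !all(is.finite(m)))
            return(sprintf("doubletFeatures$%s must be a finite L-row matrix", nm))
    }
    if (length(object@labels) &&
        (length(object@labels) != L || !all(object@labels %in% c(0L, 1L))))
        return("labels must be 0/1 and match the sequence length")
    TRUE
})

setMethod("show", "ProteinRecord", function(object) {
    cat(sprintf("ProteinRecord '%s': %d residues, %d segments, %d singlet features%s\n",
                object@id, nchar(object@sequence),
                length(object@segmentation@type),
                ncol(object@singletFeatures),
                if (length(object@labels)) ", labeled" else ""))
})

#' @describeIn ProteinRecord chain length (number of residues).
#' @param x,object a \code{ProteinRecord}.
#' @export
setMethod("length", "ProteinRecord", function(x) nchar(x@sequence))

#' Segment-conditioned high-order CRF parameters
#'
#' The weight vector Lambda = (theta, lambda, mu, gamma, tau) of the model.
#' \code{theta} weighs singlet features (one weight per feature column and
#' label); \code{lambda}, \code{mu}, \code{gamma}, \code{tau} weigh the
#' order-1/2/3/4 doublet terms.  Each doublet block is a 4 x P matrix: one
#' row per ordered label pair (\code{"00","01","10","11"}, previous label
#' first), a leading bias column, and one column per conjoined observation
#' feature.
#'
#' @slot theta D x 2 matrix; columns \code{exposed} (y = 0), \code{buried}
#'   (y = 1); rownames are the singlet feature names.
#' @slot lambda,mu,gamma,tau 4 x P numeric matrices (first column = bias).
#' @slot featureNames list with elements \code{singlet}, \code{order1},
#'   \code{order2}, \code{order3}, \code{order4}; the orderN entries name
#'   the observation columns conjoined with the label-pair indicators
#'   (excluding the bias).
#' @slot normalization list with per-column \code{center} and \code{scale}
#'   for the singlet matrix, or an empty list for no normalization.
#'
#' @exportClass BurialCRF
setClass("BurialCRF",
         representation(theta = "matrix", lambda = "matrix", mu = "matrix",
                        gamma = "matrix", tau = "matrix",
                        featureNames = "list", normalization = "list"))

setValidity("BurialCRF", function(object) {
    fn <- object@featureNames
    need <- c("singlet", "order1", "order2", "order3", "order4")
    if (!all(need %in% names(fn)))
        return("featureNames must contain singlet and order1..order4")
    if (nrow(object@theta) != length(fn$singlet) || ncol(object@theta) != 2L)
        return("theta must be |singlet| x 2")
    blocks <- list(lambda = object@lambda, mu = object@mu,
                   gamma = object@gamma, tau = object@tau)
    orders <- c("order1", "order2", "order3", "order4")
    for (b in seq_along(blocks)) {
        m <- blocks[[b]]
        if (nrow(m) != 4L || ncol(m) != length(fn[[orders[b]]]) + 1L)
            return(sprintf("%s must be 4 x (1 + |%s|)",
                           names(blocks)[b], orders[b]))
    }
    for (m in c(list(object@theta), blocks))
        if (!all(is.finite(m))) return("all weights must be finite")
    if (length(object@normalization) &&
        !all(c("center", "scale") %in% names(object@normalization)))
        return("normalization must have center and scale")
    TRUE
})

setMethod("show", "BurialCRF", function(object) {
    cat(sprintf(paste0("BurialCRF model: %d singlet features, doublet blocks ",
                       "4x%d (order1) 4x%d (order2) 4x%d (order3) 4x%d (order4), ",
                       "%d parameters%s\n"),
                nrow(object@theta), ncol(object@lambda), ncol(object@mu),
                ncol(object@gamma), ncol(object@tau), nParameters(object),
                if (length(object@normalization)) ", normalized inputs" else ""))
})

#' Per-position profile of absolute and relative solvent accessibility
#'
#' @slot asa per-residue absolute accessible surface area in square
#'   Angstrom.
#' @slot maxAsa per-residue maximum ASA for the residue type.
#' @slot rsa the ratio \code{asa / maxAsa} (not clipped at 1 by default).
#'
#' @exportClass RSAProfile
setClass("RSAProfile",
         representation(asa = "numeric", maxAsa = "numeric",
                        rsa = "numeric"))

setValidity("RSAProfile", function(object) {
    n <- length(object@asa)
    if (length(object@maxAsa) != n || length(object@rsa) != n)
        return("asa, maxAsa and rsa must have equal length")
    if (any(object@asa < 0)) return("asa must be non-negative")
    ok <- object@maxAsa > 0
    ratio <- object@asa[ok] / object@maxAsa[ok]
    clipped <- object@rsa[ok] == 1 & ratio >= 1   # clip mode
    if (any(abs(object@rsa[ok] - ratio)[!clipped] > 1e-9))
        return("rsa must equal asa / maxAsa")
    TRUE
})

setMethod("show", "RSAProfile", function(object) {
    cat(sprintf("RSAProfile: %d residues, mean RSA %.3f\n",
                length(object@asa), mean(object@rsa)))
})

#' Position-specific sequence profile
#'
#' Frequency (and optionally log-odds) view of a PSI-BLAST style profile,
#' plus the background amino-acid distribution used for conservation.
#'
#' @slot freq L x 20 matrix of per-position amino-acid frequencies (rows
#'   sum to 1); columns ordered as \code{A R N D C Q E G H I L K M F P S T
#'   W Y V} (the PSSM column order).
#' @slot logOdds L x 20 integer-valued log-odds matrix, or a 0 x 0 matrix
#'   when unavailable (e.g. one-hot pseudo-profiles).
#' @slot background length-20 positive vector summing to 1.
#'
#' @exportClass SequenceProfile
setClass("SequenceProfile",
         representation(freq = "matrix", logOdds = "matrix",
                        background = "numeric"))

setValidity("SequenceProfile", function(object) {
    if (ncol(object@freq) != 20L) return("freq must have 20 columns")
    if (any(object@freq < 0)) return("frequencies must be non-negative")
    if (nrow(object@freq) > 0L &&
        any(abs(rowSums(object@freq) - 1) > 1e-6))
        return("frequency rows must sum to 1")
    if (length(object@background) != 20L || any(object@background <= 0) ||
        abs(sum(object@background) - 1) > 1e-6)
        return("background must be 20 positive values summing to 1")
    if (nrow(object@logOdds) > 0L &&
        nrow(object@logOdds) != nrow(object@freq))
        return("logOdds row count must match freq")
    TRUE
})

setMethod("show", "SequenceProfile", function(object) {
    cat(sprintf("SequenceProfile: %d positions%s\n", nrow(object@freq),
                if (nrow(object@logOdds)) " (log-odds available)" else ""))
})
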