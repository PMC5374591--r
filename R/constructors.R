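#' Construct a ProteinRecord
#'
#' @param id chain identifier.
#' @param sequence amino-acid string (20 standard letters plus X).
#' @param ss 3-state secondary-structure string; 8-state DSSP strings are
#'   reduced with \code{\link{map8to3}} first if they contain other codes.
#' @param singletFeatures numeric L x D matrix (default: a single bias
#'   column of ones).  Column names are kept as the feature registry.
#' @param doubletFeatures named list of L x K matrices (\code{sep2},
#'   \code{sep3}, \code{sep4}); rows i <= d must be zero-filled.
#' @param labels optional 0/1 burial labels (buried = 1).
#' @return a validated \linkS4class{ProteinRecord}.
#' @examples
#' rec <- ProteinRecord("toy", "ACDEF", "CCHHH")
#' length(rec)
#' @export
ProteinRecord <- function(id, sequence, ss,
                          singletFeatures = NULL,
                          doubletFeatures = list(), labels = NULL) {
    sequence <- toupper(sequence)
    L <- nchar(sequence)
    if (!grepl("^[HEC]*$", ss)) ss <- map8to3(ss)
    if (is.null(singletFeatures))
        singletFeatures <- matrix(1, L, 1L, dimnames = list(NULL, "bias"))
    if (is.null(colnames(singletFeatures)))
        colnames(singletFeatures) <- paste0("f", seq_len(ncol(singletFeatures)))
    new("ProteinRecord", id = as.character(id), sequence = sequence,
        ss = ss, segmentation = ssToSegments(ss),
        singletFeatures = singletFeatures,
        doubletFeatures = doubletFeatures,
        labels = if (is.null(labels)) integer(0) else as.integer(labels))
}

#' Construct a (zero-initialized) BurialCRF model
#'
#' @param singletNames names of the singlet feature columns.
#' @param order1Names names of observation features conjoined with the
#'   adjacent-pair indicators (besides the always-present bias); default
#'   none, i.e. plain transition weights.
#' @param order2Names,order3Names,order4Names observation feature names for
#'   the separation-2/3/4 doublet terms; defaults are the three
#'   profile-derived doublet features.
#' @param normalization optional list with \code{center} and \code{scale}
#'   vectors for the singlet columns.
#' @return a \linkS4class{BurialCRF} with all weights zero.
#' @examples
#' m <- burialCRF(c("bias", "hydrophobicity"))
#' nParameters(m)
#' @export
burialCRF <- function(singletNames,
                      order1Names = character(0),
                      order2Names = c("mi", "cosine", "cmap"),
                      order3Names = c("mi", "cosine", "cmap"),
                      order4Names = c("mi", "cosine", "cmap"),
                      normalization = list()) {
    blk <- function(obs) matrix(0, 4L, 1L + length(obs),
                                dimnames = list(.PAIRS, c("(bias)", obs)))
    new("BurialCRF",
        theta = matrix(0, length(singletNames), 2L,
                       dimnames = list(singletNames,
                                       c("exposed", "buried"))),
        lambda = blk(order1Names), mu = blk(order2Names),
        gamma = blk(order3Names), tau = blk(order4Names),
        featureNames = list(singlet = singletNames, order1 = order1Names,
                            order2 = order2Names, order3 = order3Names,
                            order4 = order4Names),
        normalization = normalization)
}

#' Model template matching a record's feature layout
#'
#' Builds a zero-initialized \linkS4class{BurialCRF} whose blocks match
#' the singlet and doublet feature columns of \code{record}.  Records
#' without doublet matrices get bias-only doublet blocks.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param order1Features optional singlet column names to conjoin with the
#'   adjacent-pair indicators.
#' @return a \linkS4class{BurialCRF}.
#' @export
modelTemplate <- function(record, order1Features = character(0)) {
    dn <- function(sep) {
        m <- record@doubletFeatures[[sep]]
        if (is.null(m)) character(0)
        else colnames(m) %||% paste0("d", seq_len(ncol(m)))
    }
    burialCRF(colnames(record@singletFeatures),
              order1Names = order1Features,
              order2Names = dn("sep2"), order3Names = dn("sep3"),
              order4Names = dn("sep4"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
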