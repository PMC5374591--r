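#' Total number of free parameters of a model
#'
#' @param object a \linkS4class{BurialCRF} model.
#' @return integer count of weights across theta, lambda, mu, gamma, tau.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
setMethod("nParameters", "BurialCRF", function(object) {
    length(object@theta) + length(object@lambda) + length(object@mu) +
        length(object@gamma) + length(object@tau)
})

#' Accessors for protein records
#'
#' \code{burialLabels} returns the 0/1 label vector (or \code{NULL});
#' \code{segmentation} the \linkS4class{SSSegmentation};
#' \code{singletFeatures} / \code{doubletFeatures} the feature containers.
#'
#' @param object a \linkS4class{ProteinRecord}.
#' @name record-accessors
NULL

#' @rdname record-accessors
#' @export
setGeneric("burialLabels", function(object) standardGeneric("burialLabels"))

#' @rdname record-accessors
setMethod("burialLabels", "ProteinRecord", function(object)
    if (length(object@labels)) object@labels else NULL)

#' @rdname record-accessors
#' @export
setGeneric("segmentation", function(object) standardGeneric("segmentation"))

#' @rdname record-accessors
setMethod("segmentation", "ProteinRecord", function(object)
    object@segmentation)

#' @rdname record-accessors
#' @export
setGeneric("singletFeatures",
           function(object) standardGeneric("singletFeatures"))

#' @rdname record-accessors
setMethod("singletFeatures", "ProteinRecord", function(object)
    object@singletFeatures)

#' @rdname record-accessors
#' @export
setGeneric("doubletFeatures",
           function(object) standardGeneric("doubletFeatures"))

#' @rdname record-accessors
setMethod("doubletFeatures", "ProteinRecord", function(object)
    object@doubletFeatures)

#' @rdname record-accessors
#' @export
setGeneric("chainId", function(object) standardGeneric("chainId"))

#' @rdname record-accessors
setMethod("chainId", "ProteinRecord", function(object) object@id)

#' Relative solvent accessibility values of an RSAProfile
#'
#' @param object an \linkS4class{RSAProfile}.
#' @export
setGeneric("rsa", function(object) standardGeneric("rsa"))

#' @rdname rsa
setMethod("rsa", "RSAProfile", function(object) object@rsa)

#' Frequency view of a sequence profile
#'
#' @param object a \linkS4class{SequenceProfile}.
#' @export
setGeneric("profileFrequencies",
           function(object) standardGeneric("profileFrequencies"))

#' @rdname profileFrequencies
setMethod("profileFrequencies", "SequenceProfile",
          function(object) object@freq)
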