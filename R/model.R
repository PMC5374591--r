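# Log-potential assembly.
#
# Every position contributes its singlet term; inside a segment each
# doublet order applies from the first position where both of its label
# endpoints lie inside the segment (position s+1 gets the adjacent-pair
# term, s+2 the separation-2 term on strands, s+3 / s+4 the separation-3/4
# terms on helices).  Doublet terms never span two segments, so the model
# factorises over segments and all inference is exact per segment.

.normalizeSinglets <- function(F, model) {
    nz <- model@normalization
    if (!length(nz)) return(F)
    sweep(sweep(F, 2L, nz$center, "-"), 2L, nz$scale, "/")
}

.blockForSep <- function(model, d) {
    switch(as.character(d), "1" = model@lambda, "2" = model@mu,
           "3" = model@gamma, "4" = model@tau)
}

.order1Obs <- function(F, model) {
    nm <- model@featureNames$order1
    cbind(1, F[, nm, drop = FALSE])
}

# Per-segment potential tables: node (M x 2) and one M x 4 matrix per
# active separation (columns in .PAIRS order, matching the C++ core).
.recordTables <- function(record, model) {
    F <- .normalizeSinglets(record@singletFeatures, model)
    if (nrow(model@theta) != ncol(F) ||
        !identical(rownames(model@theta), colnames(F)))
        stop("record singlet features do not match the model registry")
    nodeAll <- F %*% model@theta
    obsAll <- list()
    seg <- record@segmentation
    out <- vector("list", length(seg@type))
    for (j in seq_along(seg@type)) {
        s <- seg@start[j]; t <- seg@end[j]
        type <- seg@type[j]
        seps <- .SEG_SEPS[[type]]
        rows <- s:t
        pairPots <- lapply(seps, function(d) {
            W <- .blockForSep(model, d)
            obs <- if (d == 1L) .order1Obs(F, model)[rows, , drop = FALSE]
                   else {
                       m <- record@doubletFeatures[[paste0("sep", d)]]
                       if (is.null(m)) {
                           if (ncol(W) != 1L)
                               stop(sprintf(
                                   "model expects separation-%d doublet features the record lacks", d))
                           matrix(1, length(rows), 1L)
                       } else cbind(1, m[rows, , drop = FALSE])
                   }
            unname(obs %*% t(W))
        })
        out[[j]] <- list(type = type, start = s, end = t, seps = seps,
                         k = .SEG_ORDER[[type]],
                         node = unname(nodeAll[rows, , drop = FALSE]),
                         pairPots = pairPots)
    }
    out
}

#' Coil log-potential
#'
#' \code{phiC(yPrev, y, i, ...)} is the per-position log-potential used on
#' coil segments: the singlet term of label \code{y} at position \code{i}
#' plus the adjacent-pair term for \code{(yPrev, y)}.  \code{phiE} adds
#' the separation-2 term used on strands; \code{phiH} adds the
#' separation-3 and separation-4 terms used on helices (helices carry no
#' separation-2 term).
#'
#' @param yPrev,y,y1,y2,y3,y4 labels in \code{0} (exposed) / \code{1}
#'   (buried); \code{yK} is the label at position \code{i - K}.
#' @param i 1-based position.
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @return scalar log-potential.
#' @export
phiC <- function(yPrev, y, i, record, model) {
    F <- .normalizeSinglets(record@singletFeatures, model)
    sum(F[i, ] * model@theta[, y + 1L]) +
        sum(.order1Obs(F, model)[i, ] * model@lambda[.pairRow(yPrev, y), ])
}

#' @rdname phiC
#' @export
phiE <- function(y2, y1, y, i, record, model) {
    phiC(y1, y, i, record, model) +
        sum(.doubletObs(record, 2L, i) * model@mu[.pairRow(y2, y), ])
}

#' @rdname phiC
#' @export
phiH <- function(y4, y3, y2, y1, y, i, record, model) {
    phiC(y1, y, i, record, model) +
        sum(.doubletObs(record, 3L, i) * model@gamma[.pairRow(y3, y), ]) +
        sum(.doubletObs(record, 4L, i) * model@tau[.pairRow(y4, y), ])
}

.pairRow <- function(yPrev, y) 2L * yPrev + y + 1L

.doubletObs <- function(record, d, i) {
    m <- record@doubletFeatures[[paste0("sep", d)]]
    if (is.null(m)) 1 else c(1, m[i, ])
}

#' Unnormalized log-score of a label sequence
#'
#' Sums, over every segment and position, the active potential terms for
#' the labeling \code{labels}: \code{log p(Y | X) = sequenceLogScore(Y) -
#' log Z(X)}.
#'
#' @param labels 0/1 vector of length \code{length(record)}.
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @return scalar log-score.
#' @export
sequenceLogScore <- function(labels, record, model) {
    L <- length(record)
    if (length(labels) != L) stop("labels length must equal record length")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    tabs <- .recordTables(record, model)
    score <- 0
    for (tb in tabs) {
        rows <- tb$start:tb$end
        y <- labels[rows]
        M <- length(rows)
        score <- score + sum(tb$node[cbind(seq_len(M), y + 1L)])
        for (t in seq_along(tb$seps)) {
            d <- tb$seps[t]
            if (M >= d + 1L) {
                j <- (d + 1L):M
                pair <- 2L * y[j - d] + y[j] + 1L
                score <- score + sum(tb$pairPots[[t]][cbind(j, pair)])
            }
        }
    }
    score
}

#' Flatten / restore the model weight vector
#'
#' \code{flattenModel} concatenates (theta, lambda, mu, gamma, tau) into
#' one named numeric vector; \code{unflattenModel} inverts it given a
#' template with the same layout.
#'
#' @param model,template \linkS4class{BurialCRF} objects.
#' @param x numeric vector from \code{flattenModel}.
#' @return a numeric vector, resp. a \linkS4class{BurialCRF}.
#' @export
flattenModel <- function(model) {
    c(theta = as.numeric(model@theta), lambda = as.numeric(model@lambda),
      mu = as.numeric(model@mu), gamma = as.numeric(model@gamma),
      tau = as.numeric(model@tau))
}

#' @rdname flattenModel
#' @export
unflattenModel <- function(x, template) {
    sizes <- c(length(template@theta), length(template@lambda),
               length(template@mu), length(template@gamma),
               length(template@tau))
    stopifnot(length(x) == sum(sizes))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    take <- function(b, proto) {
        m <- matrix(x[starts[b]:ends[b]], nrow(proto), ncol(proto))
        dimnames(m) <- dimnames(proto)
        m
    }
    new("BurialCRF", theta = take(1L, template@theta),
        lambda = take(2L, template@lambda), mu = take(3L, template@mu),
        gamma = take(4L, template@gamma), tau = take(5L, template@tau),
        featureNames = template@featureNames,
        normalization = template@normalization)
}

#' Save / load a model as a versioned JSON archive
#'
#' The archive stores the feature registry, the normalization statistics
#' and all weights at full IEEE precision, so a save/load round trip
#' reproduces the model bit-exactly.
#'
#' @param model a \linkS4class{BurialCRF}.
#' @param path file path.
#' @return \code{readBurialCRF} returns the restored model.
#' @export
writeBurialCRF <- function(model, path) {
    obj <- list(format = "burialCRF-model", version = 1L,
                featureNames = model@featureNames,
                registryHash = rlang::hash(model@featureNames),
                theta = as.numeric(model@theta),
                lambda = as.numeric(model@lambda),
                mu = as.numeric(model@mu),
                gamma = as.numeric(model@gamma),
                tau = as.numeric(model@tau),
                normalization = model@normalization)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeBurialCRF
#' @export
readBurialCRF <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "burialCRF-model"))
        stop("not a burialCRF model archive: ", path)
    fn <- lapply(obj$featureNames, function(x)
        if (length(x)) as.character(x) else character(0))
    template <- burialCRF(fn$singlet, fn$order1, fn$order2, fn$order3,
                          fn$order4)
    nz <- obj$normalization
    if (length(nz)) nz <- list(center = as.numeric(nz$center),
                               scale = as.numeric(nz$scale))
    else nz <- list()
    asMat <- function(x, proto)
        matrix(as.numeric(x), nrow(proto), ncol(proto),
               dimnames = dimnames(proto))
    new("BurialCRF", theta = asMat(obj$theta, template@theta),
        lambda = asMat(obj$lambda, template@lambda),
        mu = asMat(obj$mu, template@mu),
        gamma = asMat(obj$gamma, template@gamma),
        tau = asMat(obj$tau, template@tau),
        featureNames = fn, normalization = nz)
}
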