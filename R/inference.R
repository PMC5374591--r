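#' Exact forward-backward inference
#'
#' Runs the variable-order forward-backward recursions over every
#' secondary-structure segment (order 4 inside helices, 2 inside strands,
#' 1 on coils), entirely in log-space.  Because doublet potentials never
#' span segments, the partition function is the product of per-segment
#' partition functions and all quantities are exact.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @param marginals if \code{TRUE} (default) also compute per-position and
#'   label-pair marginals (needed by training).
#' @return a list with \code{logZ}, \code{logZBackward} (a numerical
#'   cross-check of the same quantity from the reverse recursion), and per
#'   segment the node marginals (M x 2, columns exposed/buried) and the
#'   transition pair marginals for each active separation.
#' @export
forwardBackward <- function(record, model, marginals = TRUE) {
    tabs <- .recordTables(record, model)
    segOut <- vector("list", length(tabs))
    logZ <- 0; logZb <- 0
    for (j in seq_along(tabs)) {
        tb <- tabs[[j]]
        if (!all(is.finite(tb$node)) ||
            !all(vapply(tb$pairPots, function(m) all(is.finite(m)), TRUE)))
            stop(sprintf("non-finite potential in segment %d (%s %d-%d)",
                         j, tb$type, tb$start, tb$end))
        fb <- cpp_segment_fb(tb$node, tb$pairPots, tb$seps, tb$k, marginals)
        logZ <- logZ + fb$logZ
        logZb <- logZb + fb$logZ_backward
        segOut[[j]] <- c(tb[c("type", "start", "end", "seps", "k")],
                         fb[intersect(names(fb),
                                      c("logZ", "nodeMarginals",
                                        "pairMarginals"))])
    }
    list(logZ = logZ, logZBackward = logZb, segments = segOut)
}

#' Per-position burial marginals
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @param fb optional result of \code{\link{forwardBackward}} to reuse.
#' @return L x 2 matrix of \code{p(Y_i = y | X)}; columns
#'   \code{exposed}, \code{buried}; each row sums to 1.
#' @export
positionMarginals <- function(record, model, fb = NULL) {
    if (is.null(fb)) fb <- forwardBackward(record, model, marginals = TRUE)
    L <- length(record)
    out <- matrix(NA_real_, L, 2L,
                  dimnames = list(NULL, c("exposed", "buried")))
    for (sg in fb$segments)
        out[sg$start:sg$end, ] <- sg$nodeMarginals
    out
}

#' Decode labels from marginals
#'
#' Per-position argmax of the marginal probability; exact ties go to
#' buried.
#'
#' @param marginals L x 2 matrix with columns \code{exposed},
#'   \code{buried}.
#' @return integer 0/1 label vector (buried = 1).
#' @export
decodeLabels <- function(marginals) {
    as.integer(marginals[, "buried"] >= marginals[, "exposed"])
}

#' Brute-force enumeration reference
#'
#' Computes the partition function and per-position marginals by explicit
#' summation over all \code{2^L} labelings of
#' \code{exp(sequenceLogScore)}.  Exponential in L (capped at 20); this is
#' the normative definition the dynamic program is tested against.
#'
#' @param record a \linkS4class{ProteinRecord} with \code{length <= 20}.
#' @param model a \linkS4class{BurialCRF}.
#' @return list with \code{logZ}, \code{marginals} (L x 2) and
#'   \code{decoded}.
#' @export
bruteForceReference <- function(record, model) {
    L <- length(record)
    if (L > 20L) stop("enumeration reference is limited to L <= 20")
    labs <- as.matrix(expand.grid(rep(list(0:1), L)))[, , drop = FALSE]
    tabs <- .recordTables(record, model)
    scoreOne <- function(y) {
        score <- 0
        for (tb in tabs) {
            rows <- tb$start:tb$end
            ySeg <- y[rows]
            M <- length(rows)
            score <- score + sum(tb$node[cbind(seq_len(M), ySeg + 1L)])
            for (t in seq_along(tb$seps)) {
                d <- tb$seps[t]
                if (M >= d + 1L) {
                    j <- (d + 1L):M
                    pair <- 2L * ySeg[j - d] + ySeg[j] + 1L
                    score <- score + sum(tb$pairPots[[t]][cbind(j, pair)])
                }
            }
        }
        score
    }
    scores <- apply(labs, 1L, scoreOne)
    m <- max(scores)
    w <- exp(scores - m)
    logZ <- m + log(sum(w))
    p <- w / sum(w)
    marg <- matrix(0, L, 2L, dimnames = list(NULL, c("exposed", "buried")))
    marg[, "buried"] <- as.numeric(t(labs) %*% p)
    marg[, "exposed"] <- 1 - marg[, "buried"]
    list(logZ = logZ, marginals = marg, decoded = decodeLabels(marg),
         probabilities = p, labelings = labs)
}

#' Predict burial states for one chain
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @return data.frame with 1-based \code{position}, \code{residue},
#'   \code{ss}, \code{p_buried}, \code{p_exposed} and the decoded 0/1
#'   \code{label} -- the package's standard prediction table.
#' @export
predictBurial <- function(record, model) {
    marg <- positionMarginals(record, model)
    data.frame(position = seq_len(length(record)),
               residue = strsplit(record@sequence, "")[[1]],
               ss = strsplit(record@ss, "")[[1]],
               p_buried = marg[, "buried"], p_exposed = marg[, "exposed"],
               label = decodeLabels(marg), stringsAsFactors = FALSE)
}

#' Trellis state counts per position
#'
#' The number of distinct dynamic-programming states carried at each
#' position: \code{2^min(j, k)} with \code{j} the within-segment index and
#' \code{k} the segment order (4 helix, 2 strand, 1 coil).  The audit
#' bound is 16 states (32 transitions) per position.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @return integer vector of length \code{length(record)}.
#' @export
trellisStateCounts <- function(record) {
    seg <- record@segmentation
    unlist(lapply(seq_along(seg@type), function(j) {
        M <- seg@end[j] - seg@start[j] + 1L
        k <- .SEG_ORDER[[seg@type[j]]]
        2L^pmin(seq_len(M), k)
    }), use.names = FALSE)
}
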