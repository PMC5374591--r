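#' Pooled two-state (Q2) accuracy
#'
#' Fraction of residues whose predicted burial state matches the truth,
#' pooled over all residues of all chains.
#'
#' @param pred,truth 0/1 vectors, or lists of such vectors (one per
#'   chain, matched lengths).
#' @return accuracy in [0, 1].
#' @export
q2Accuracy <- function(pred, truth) {
    if (is.list(pred)) pred <- unlist(pred)
    if (is.list(truth)) truth <- unlist(truth)
    if (length(pred) != length(truth))
        stop("prediction and truth lengths differ")
    mean(pred == truth)
}

#' Stratified evaluation report
#'
#' Overall Q2 accuracy plus accuracies stratified by secondary-structure
#' type, residue type, per-chain, and by quantile bins of any extra
#' per-residue covariates (e.g. conservation or contact number).
#'
#' @param records list of labeled \linkS4class{ProteinRecord}s (truth).
#' @param predictions list of 0/1 vectors (or prediction data.frames from
#'   \code{\link{predictBurial}}).
#' @param covariates optional named list; each element is a list of
#'   per-chain numeric vectors to stratify by quantile bins.
#' @param nbins number of quantile bins for covariates.
#' @return list of class \code{burialEvalReport}: \code{overall},
#'   \code{confusion}, \code{bySS}, \code{byResidue}, \code{perProtein},
#'   \code{byCovariate}, \code{n}.
#' @export
evaluationReport <- function(records, predictions, covariates = NULL,
                             nbins = 10L) {
    pred <- unlist(lapply(predictions, function(p)
        if (is.data.frame(p)) p$label else p))
    truth <- unlist(lapply(records, function(r) r@labels))
    if (length(pred) != length(truth))
        stop("predictions do not match records")
    ss <- unlist(lapply(records, function(r) strsplit(r@ss, "")[[1]]))
    res <- unlist(lapply(records, function(r)
        strsplit(r@sequence, "")[[1]]))
    accBy <- function(f) {
        t <- tapply(pred == truth, f, mean)
        n <- tapply(truth, f, length)
        data.frame(stratum = names(t), accuracy = as.numeric(t),
                   n = as.integer(n), row.names = NULL)
    }
    perProt <- vapply(seq_along(records), function(i) {
        p <- predictions[[i]]
        if (is.data.frame(p)) p <- p$label
        mean(p == records[[i]]@labels)
    }, 1)
    byCov <- NULL
    if (!is.null(covariates))
        byCov <- lapply(covariates, function(v) {
            x <- unlist(v)
            br <- unique(stats::quantile(x, seq(0, 1,
                                                length.out = nbins + 1L)))
            accBy(cut(x, br, include.lowest = TRUE))
        })
    structure(list(overall = mean(pred == truth),
                   confusion = table(truth = truth, pred = pred),
                   bySS = accBy(ss), byResidue = accBy(res),
                   perProtein = perProt, byCovariate = byCov,
                   n = length(truth)),
              class = "burialEvalReport")
}

#' @export
print.burialEvalReport <- function(x, ...) {
    cat(sprintf("Burial-state evaluation: Q2 = %.4f over %d residues (%d chains)\n",
                x$overall, x$n, length(x$perProtein)))
    cat("By secondary structure:\n")
    print(x$bySS, row.names = FALSE)
    invisible(x)
}

.plugInMI <- function(a, b) {
    j <- table(factor(a, 0:1), factor(b, 0:1)) / length(a)
    pr <- rowSums(j); pc <- colSums(j)
    term <- j * log2(j / outer(pr, pc))
    term[j == 0] <- 0
    max(0, sum(term))
}

#' Mutual information of burial states by sequence separation
#'
#' Plug-in MI (bits) of the empirical joint of (Y_i, Y_{i+d}) pooled over
#' qualifying pairs, the diagnostic behind the helix 3/4-periodicity and
#' strand 2-periodicity of burial states.  When stratified, both residues
#' of a pair must fall in the same segment of the given type.
#'
#' @param labelsList list of 0/1 label vectors.
#' @param segList list of matching \linkS4class{SSSegmentation}s (needed
#'   when \code{stratifyBySS}).
#' @param maxSep largest separation to report.
#' @param stratifyBySS stratify pairs by segment type.
#' @return data.frame with \code{separation}, \code{ss} (H/E/C or
#'   \code{all}), \code{mi} (NA when no qualifying pairs) and
#'   \code{nPairs}.
#' @export
miVsSeparation <- function(labelsList, segList = NULL, maxSep = 6L,
                           stratifyBySS = !is.null(segList)) {
    if (!is.list(labelsList)) labelsList <- list(labelsList)
    if (stratifyBySS && is.null(segList))
        stop("segmentations required for stratified MI")
    strata <- if (stratifyBySS) c("H", "E", "C") else "all"
    out <- expand.grid(separation = seq_len(maxSep), ss = strata,
                       stringsAsFactors = FALSE)
    out$mi <- NA_real_; out$nPairs <- 0L
    for (r in seq_len(nrow(out))) {
        d <- out$separation[r]
        a <- integer(0); b <- integer(0)
        for (m in seq_along(labelsList)) {
            y <- labelsList[[m]]
            if (out$ss[r] == "all") {
                if (length(y) > d) {
                    i <- seq_len(length(y) - d)
                    a <- c(a, y[i]); b <- c(b, y[i + d])
                }
            } else {
                seg <- segList[[m]]
                for (j in which(seg@type == out$ss[r])) {
                    s <- seg@start[j]; t <- seg@end[j]
                    if (t - s >= d) {
                        i <- s:(t - d)
                        a <- c(a, y[i]); b <- c(b, y[i + d])
                    }
                }
            }
        }
        out$nPairs[r] <- length(a)
        if (length(a)) out$mi[r] <- .plugInMI(a, b)
    }
    out
}

#' Logistic-regression baseline
#'
#' Per-residue binary logistic regression on the singlet features, with
#' no label coupling; evaluated through the same pipeline as the CRF.
#'
#' @param train,test lists of labeled \linkS4class{ProteinRecord}s.
#' @return list with \code{report} (\code{\link{evaluationReport}} on the
#'   test set), \code{accuracy}, \code{predictions} (per-chain 0/1
#'   vectors) and the fitted \code{glm}.
#' @export
baselineLogistic <- function(train, test) {
    pool <- function(recs) do.call(rbind, lapply(recs, singletFeatures))
    Ftr <- pool(train)
    keep <- apply(Ftr, 2L, function(x) stats::sd(x) > 1e-12)
    ytr <- unlist(lapply(train, function(r) r@labels))
    if (length(unique(ytr)) < 2L)
        stop("training labels are single-class")
    df <- as.data.frame(Ftr[, keep, drop = FALSE])
    df$.y <- ytr
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    predictions <- lapply(test, function(r) {
        nd <- as.data.frame(singletFeatures(r)[, keep, drop = FALSE])
        p <- predict(fit, newdata = nd, type = "response")
        as.integer(p >= 0.5)
    })
    rep <- evaluationReport(test, predictions)
    list(report = rep, accuracy = rep$overall,
         predictions = predictions, fit = fit)
}

#' Replace segmentations with a single coil segment
#'
#' Used by the chain-CRF baseline: every chain is treated as one coil
#' segment, so only the singlet and adjacent-pair (order-1) terms are
#' active.
#'
#' @param records list of \linkS4class{ProteinRecord}s.
#' @return list of converted records.
#' @export
asChainRecords <- function(records) {
    lapply(records, function(r) {
        L <- length(r)
        new("ProteinRecord", id = r@id, sequence = r@sequence,
            ss = strrep("C", L),
            segmentation = new("SSSegmentation", type = "C",
                               start = 1L, end = L),
            singletFeatures = r@singletFeatures,
            doubletFeatures = r@doubletFeatures, labels = r@labels)
    })
}

#' First-order chain-CRF baseline
#'
#' The same engine restricted to adjacent-pair structure: all segments
#' are treated with the coil potential (separation-2/3/4 weights are
#' never active, hence effectively frozen at zero).
#'
#' @param train,test lists of labeled \linkS4class{ProteinRecord}s.
#' @param config a \code{\link{trainingConfig}}.
#' @return list with \code{report}, \code{accuracy}, \code{predictions}
#'   and the fitted \code{model}.
#' @export
baselineChainCRF <- function(train, test, config = trainingConfig()) {
    fit <- fitBurialCRF(asChainRecords(train), config)
    chainTest <- asChainRecords(test)
    predictions <- lapply(chainTest, function(r)
        decodeLabels(positionMarginals(r, fit$model)))
    rep <- evaluationReport(test, predictions)
    list(report = rep, accuracy = rep$overall,
         predictions = predictions, model = fit$model)
}
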