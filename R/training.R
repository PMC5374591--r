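#' Training configuration
#'
#' @param learningRate initial step size for gradient ascent (adapted by
#'   the backtracking line search).
#' @param l2 L2 penalty strength; the penalized objective is the
#'   conditional log-likelihood minus \code{l2 * sum(weights^2)}.  A
#'   positive value makes the objective strictly concave.
#' @param maxIter maximum number of iterations.
#' @param tol convergence tolerance on the relative change of the
#'   penalized log-likelihood.
#' @param optimizer \code{"gd"} (full-batch gradient ascent with
#'   backtracking line search; the default) or \code{"lbfgs"}
#'   (quasi-Newton via \code{\link[stats]{optim}}).
#' @param seed integer seed recorded with the run (used only when
#'   \code{miniBatch > 0}).
#' @param miniBatch 0 for full batch (default); a positive value draws
#'   that many proteins per iteration with a fixed step size.
#' @return a validated list of class \code{trainingConfig}.
#' @export
trainingConfig <- function(learningRate = 0.5, l2 = 1, maxIter = 200L,
                           tol = 1e-6, optimizer = c("gd", "lbfgs"),
                           seed = 1L, miniBatch = 0L) {
    optimizer <- match.arg(optimizer)
    stopifnot(learningRate > 0, l2 >= 0, maxIter >= 1, tol > 0,
              miniBatch >= 0)
    structure(list(learningRate = learningRate, l2 = l2,
                   maxIter = as.integer(maxIter), tol = tol,
                   optimizer = optimizer, seed = as.integer(seed),
                   miniBatch = as.integer(miniBatch)),
              class = "trainingConfig")
}

# log-likelihood and gradient in one pass (tables and forward-backward are
# shared between the score and the expected feature counts)
.llAndGrad <- function(records, model, l2 = 0, wantGrad = TRUE) {
    ll <- 0
    if (wantGrad) {
        gTheta <- model@theta * 0
        gBlocks <- list(`1` = model@lambda * 0, `2` = model@mu * 0,
                        `3` = model@gamma * 0, `4` = model@tau * 0)
    }
    for (record in records) {
        y <- record@labels
        if (!length(y)) stop("all records must carry burial labels")
        F <- .normalizeSinglets(record@singletFeatures, model)
        tabs <- .recordTables(record, model)
        for (tb in tabs) {
            rows <- tb$start:tb$end
            M <- length(rows)
            ySeg <- y[rows]
            fb <- cpp_segment_fb(tb$node, tb$pairPots, tb$seps, tb$k,
                                 wantGrad)
            # observed score
            sc <- sum(tb$node[cbind(seq_len(M), ySeg + 1L)])
            empPair <- vector("list", length(tb$seps))
            for (t in seq_along(tb$seps)) {
                d <- tb$seps[t]
                emp <- matrix(0, M, 4L)
                if (M >= d + 1L) {
                    j <- (d + 1L):M
                    pair <- 2L * ySeg[j - d] + ySeg[j] + 1L
                    emp[cbind(j, pair)] <- 1
                    sc <- sc + sum(tb$pairPots[[t]][cbind(j, pair)])
                }
                empPair[[t]] <- emp
            }
            ll <- ll + sc - fb$logZ
            if (wantGrad) {
                empNode <- matrix(0, M, 2L)
                empNode[cbind(seq_len(M), ySeg + 1L)] <- 1
                gTheta <- gTheta + crossprod(F[rows, , drop = FALSE],
                                             empNode - fb$nodeMarginals)
                for (t in seq_along(tb$seps)) {
                    d <- tb$seps[t]
                    obs <- if (d == 1L)
                        .order1Obs(F, model)[rows, , drop = FALSE]
                    else {
                        m <- record@doubletFeatures[[paste0("sep", d)]]
                        if (is.null(m)) matrix(1, M, 1L)
                        else cbind(1, m[rows, , drop = FALSE])
                    }
                    gBlocks[[as.character(d)]] <-
                        gBlocks[[as.character(d)]] +
                        crossprod(empPair[[t]] - fb$pairMarginals[[t]], obs)
                }
            }
        }
    }
    w <- flattenModel(model)
    ll <- ll - l2 * sum(w^2)
    out <- list(loglik = ll)
    if (wantGrad) {
        grad <- c(theta = as.numeric(gTheta),
                  lambda = as.numeric(gBlocks[["1"]]),
                  mu = as.numeric(gBlocks[["2"]]),
                  gamma = as.numeric(gBlocks[["3"]]),
                  tau = as.numeric(gBlocks[["4"]]))
        out$gradient <- grad - 2 * l2 * unname(w)
    }
    out
}

#' Conditional log-likelihood of labeled records
#'
#' Sum over proteins of \code{sequenceLogScore(Y) - log Z(X)}, minus the
#' L2 penalty when \code{l2 > 0}.
#'
#' @param records list of labeled \linkS4class{ProteinRecord}s.
#' @param model a \linkS4class{BurialCRF}.
#' @param l2 L2 penalty strength.
#' @return scalar (penalized) log-likelihood.
#' @export
logLikelihood <- function(records, model, l2 = 0) {
    if (is(records, "ProteinRecord")) records <- list(records)
    .llAndGrad(records, model, l2, wantGrad = FALSE)$loglik
}

#' Analytic gradient of the (penalized) log-likelihood
#'
#' Per weight: empirical feature count minus model-expected count, the
#' expectations coming from forward-backward node and label-pair
#' marginals, minus the L2 term.  The layout matches
#' \code{\link{flattenModel}}.
#'
#' @inheritParams logLikelihood
#' @return numeric vector conformal to \code{flattenModel(model)}.
#' @export
modelGradient <- function(records, model, l2 = 0) {
    if (is(records, "ProteinRecord")) records <- list(records)
    .llAndGrad(records, model, l2, wantGrad = TRUE)$gradient
}

#' Fit a burial CRF by maximum likelihood
#'
#' Full-batch gradient ascent with a backtracking line search (default):
#' the step is halved until the penalized log-likelihood does not
#' decrease, and doubled after every accepted step, so the recorded trace
#' is monotone non-decreasing.  A quasi-Newton mode
#' (\code{optimizer = "lbfgs"}) is available in the configuration.
#' Weights start at zero; with \code{l2 > 0} the objective is strictly
#' concave, so the optimum does not depend on the initialization.
#'
#' @param records list of labeled \linkS4class{ProteinRecord}s.
#' @param config a \code{\link{trainingConfig}}.
#' @param template optional \linkS4class{BurialCRF} defining the feature
#'   layout (default: derived from the first record).
#' @param order1Features singlet columns to conjoin with the
#'   adjacent-pair indicators (used only when \code{template} is NULL).
#' @param normalize z-score real-valued singlet columns using
#'   training-set statistics stored in the model (constant columns are
#'   left untouched).
#' @return list with \code{model} (the fitted \linkS4class{BurialCRF}),
#'   \code{trace} (data.frame of iteration, penalized log-likelihood,
#'   gradient norm, step size) and \code{converged}.
#' @export
fitBurialCRF <- function(records, config = trainingConfig(),
                         template = NULL,
                         order1Features = character(0),
                         normalize = TRUE) {
    if (is(records, "ProteinRecord")) records <- list(records)
    if (!length(records)) stop("empty training set")
    if (is.null(template))
        template <- modelTemplate(records[[1]], order1Features)
    if (normalize && !length(template@normalization)) {
        Fall <- do.call(rbind, lapply(records, singletFeatures))
        ctr <- colMeans(Fall)
        scl <- apply(Fall, 2L, sd)
        const <- !is.finite(scl) | scl < 1e-12
        ctr[const] <- 0; scl[const] <- 1
        template@normalization <- list(center = unname(ctr),
                                       scale = unname(scl))
    }
    par <- unname(flattenModel(template))
    l2 <- config$l2

    if (config$optimizer == "lbfgs") {
        fn <- function(p) -.llAndGrad(records,
                                      unflattenModel(p, template), l2,
                                      wantGrad = FALSE)$loglik
        gr <- function(p) -.llAndGrad(records,
                                      unflattenModel(p, template), l2,
                                      wantGrad = TRUE)$gradient
        opt <- optim(par, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = config$maxIter,
                                    factr = config$tol / 1e-15))
        model <- unflattenModel(opt$par, template)
        ev <- .llAndGrad(records, model, l2)
        trace <- data.frame(iteration = opt$counts[["function"]],
                            loglik = -opt$value,
                            gradNorm = sqrt(sum(ev$gradient^2)),
                            step = NA_real_)
        return(list(model = model, trace = trace,
                    converged = opt$convergence == 0L))
    }

    if (config$miniBatch > 0L) set.seed(config$seed)
    step <- config$learningRate
    ev <- .llAndGrad(records, unflattenModel(par, template), l2)
    trace <- vector("list", config$maxIter)
    converged <- FALSE
    for (it in seq_len(config$maxIter)) {
        batch <- records
        if (config$miniBatch > 0L && config$miniBatch < length(records)) {
            batch <- records[sample.int(length(records),
                                        config$miniBatch)]
            ev <- .llAndGrad(batch, unflattenModel(par, template), l2)
        }
        g <- ev$gradient
        gnorm <- sqrt(sum(g^2))
        if (!is.finite(ev$loglik))
            stop("objective diverged (non-finite log-likelihood)")
        if (config$miniBatch > 0L) {
            par <- par + step * g / max(1, gnorm)
            evNew <- .llAndGrad(records, unflattenModel(par, template), l2)
        } else {
            repeat {     # backtracking: accept only non-decreasing steps
                cand <- par + step * g
                evNew <- .llAndGrad(records,
                                    unflattenModel(cand, template), l2)
                if (is.finite(evNew$loglik) &&
                    evNew$loglik >= ev$loglik) {
                    par <- cand
                    step <- min(step * 2, 1e3)
                    break
                }
                step <- step / 2
                if (step < 1e-14) { converged <- TRUE; break }
            }
        }
        trace[[it]] <- data.frame(iteration = it, loglik = evNew$loglik,
                                  gradNorm = gnorm, step = step)
        relChange <- abs(evNew$loglik - ev$loglik) /
            (abs(ev$loglik) + 1)
        ev <- evNew
        if (converged || relChange < config$tol) {
            converged <- TRUE
            break
        }
    }
    list(model = unflattenModel(par, template),
         trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
         converged = converged)
}

#' Seedable k-fold splitter
#'
#' Randomly divides protein indices into \code{k} folds of (near-)equal
#' size, the layout used for five-fold cross-validation.
#'
#' @param n number of proteins (or a list of records).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments in \code{1..k}.
#' @export
kFoldSplit <- function(n, k = 5L, seed = 1L) {
    if (is.list(n)) n <- length(n)
    stopifnot(n >= k)
    set.seed(seed)
    sample(rep(seq_len(k), length.out = n))
}
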