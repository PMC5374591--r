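# Synthetic-data generator.
#
# Labels are drawn first from the coupling-only prior process (the same
# segment-conditioned trellis with constant pair potentials), then
# features are drawn class-conditionally: singlet columns as Gaussians
# around a label-dependent mean, doublet observation columns as Gaussians
# around a label-pair-dependent mean at the positions where that order is
# active.  With shared unit variance this joint distribution implies that
# p(Y | X) is EXACTLY the segment-conditioned CRF returned by
# generatingModel(): the Gaussian class means become the theta weights,
# the pair means become the doublet observation weights, the prior
# couplings become the doublet biases, and the quadratic mean terms cancel
# between labels by symmetry.

.PAIR_SIGN <- c(1, -1, -1, 1)   # equal label pairs (00, 11) vs unequal

#' Synthetic-data generator configuration
#'
#' Defaults describe a mixed-composition benchmark of chains of 50-150
#' residues (mean 100): geometric segment lengths (helix mean 10, strand
#' 5, coil 6, alternating types), four label-informative singlet columns
#' with class-conditional mean separation \code{effectSize}, four pure
#' noise columns, and three doublet observation columns per separation
#' whose means depend on whether the flanking labels agree.
#'
#' @param nProteins number of chains.
#' @param lengthRange integer min/max chain length (uniform).
#' @param typeProbs named probabilities of segment types \code{H, E, C}
#'   (successive segments never repeat a type; transition probabilities
#'   are these, renormalized without the current type).
#' @param meanSegLen named mean segment lengths per type (geometric).
#' @param nInformative,nNoise numbers of label-informative and pure-noise
#'   singlet columns.
#' @param effectSize class-conditional mean separation of informative
#'   singlet columns (means at +/- effectSize/2, unit variance).
#' @param doubletEffect named magnitudes of the label-pair-conditional
#'   means of the three doublet observation columns.
#' @param couplings named prior label-pair couplings per doublet order
#'   (log-potential +J for equal pairs, -J for unequal).
#' @param classBias prior log-potential of the buried label.
#' @param seed mandatory integer seed.
#' @return list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(nProteins = 100L, lengthRange = c(50L, 150L),
                            typeProbs = c(H = 0.4, E = 0.25, C = 0.35),
                            meanSegLen = c(H = 10, E = 5, C = 6),
                            nInformative = 4L, nNoise = 4L,
                            effectSize = 1,
                            doubletEffect = c(mi = 0.5, cosine = 0.3,
                                              cmap = 0.2),
                            couplings = c(order1 = 0.2, order2 = 0.2,
                                          order3 = 0.3, order4 = 0.3),
                            classBias = 0, seed = 1L) {
    stopifnot(nProteins >= 1, length(lengthRange) == 2L,
              lengthRange[1] >= 1, lengthRange[2] >= lengthRange[1],
              all(c("H", "E", "C") %in% names(typeProbs)),
              all(typeProbs >= 0), sum(typeProbs) > 0,
              all(meanSegLen[c("H", "E", "C")] >= 1),
              nInformative >= 0, nNoise >= 0, effectSize >= 0,
              all(names(couplings) == paste0("order", 1:4)),
              is.numeric(seed), length(seed) == 1L)
    typeProbs <- typeProbs[c("H", "E", "C")] / sum(typeProbs)
    structure(list(nProteins = as.integer(nProteins),
                   lengthRange = as.integer(lengthRange),
                   typeProbs = typeProbs,
                   meanSegLen = meanSegLen[c("H", "E", "C")],
                   nInformative = as.integer(nInformative),
                   nNoise = as.integer(nNoise), effectSize = effectSize,
                   doubletEffect = doubletEffect, couplings = couplings,
                   classBias = classBias, seed = as.integer(seed)),
              class = "generatorConfig")
}

#' Benchmark presets named after the four structural-composition classes
#'
#' \code{"alpha"}: helix-rich chains with strong separation-3/4
#' couplings; \code{"beta"}: strand-rich with a strong separation-2
#' coupling; \code{"alpha/beta"} and \code{"alpha+beta"}: mixed
#' compositions with moderate couplings.
#'
#' @param name preset name.
#' @param ... overrides passed to \code{\link{generatorConfig}}.
#' @return a \code{generatorConfig}.
#' @export
generatorPreset <- function(name = c("alpha", "beta", "alpha/beta",
                                     "alpha+beta"), ...) {
    name <- match.arg(name)
    base <- switch(name,
        "alpha" = list(typeProbs = c(H = 0.65, E = 0.05, C = 0.30),
                       couplings = c(order1 = 0.2, order2 = 0.2,
                                     order3 = 0.8, order4 = 0.8)),
        "beta" = list(typeProbs = c(H = 0.05, E = 0.55, C = 0.40),
                      couplings = c(order1 = 0.2, order2 = 0.8,
                                    order3 = 0.3, order4 = 0.3)),
        "alpha/beta" = list(typeProbs = c(H = 0.40, E = 0.30, C = 0.30)),
        "alpha+beta" = list(typeProbs = c(H = 0.35, E = 0.35, C = 0.30)))
    do.call(generatorConfig, utils::modifyList(base, list(...)))
}

#' The CRF a generated dataset is exactly distributed under
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return the implied \linkS4class{BurialCRF} (Lambda*).
#' @export
generatingModel <- function(config) {
    singlet <- c("bias",
                 if (config$nInformative)
                     paste0("inf", seq_len(config$nInformative)),
                 if (config$nNoise)
                     paste0("noise", seq_len(config$nNoise)))
    dn <- names(config$doubletEffect)
    model <- burialCRF(singlet, order2Names = dn, order3Names = dn,
                       order4Names = dn)
    model@theta["bias", ] <- c(0, config$classBias)
    if (config$nInformative) {
        inf <- paste0("inf", seq_len(config$nInformative))
        model@theta[inf, "exposed"] <- -config$effectSize / 2
        model@theta[inf, "buried"] <- +config$effectSize / 2
    }
    model@lambda[, 1L] <- config$couplings["order1"] * .PAIR_SIGN
    for (d in 2:4) {
        W <- .blockForSep(model, d)
        W[, 1L] <- config$couplings[paste0("order", d)] * .PAIR_SIGN
        for (k in seq_along(dn))
            W[, k + 1L] <- config$doubletEffect[k] * .PAIR_SIGN
        slot(model, switch(d - 1L, "mu", "gamma", "tau")) <- W
    }
    validObject(model)
    model
}

#' Sample a secondary-structure segmentation
#'
#' Alternating-type segments with geometric lengths (mean per type from
#' the configuration), truncated to fit the chain.
#'
#' @param L chain length.
#' @param config a \code{\link{generatorConfig}}.
#' @return an \linkS4class{SSSegmentation}.  Uses the current RNG state.
#' @export
sampleSegmentation <- function(L, config = generatorConfig()) {
    stopifnot(L >= 1)
    types <- character(0); starts <- integer(0); ends <- integer(0)
    pos <- 1L
    cur <- sample(names(config$typeProbs), 1L, prob = config$typeProbs)
    while (pos <= L) {
        len <- 1L + rgeom(1L, 1 / config$meanSegLen[[cur]])
        len <- min(len, L - pos + 1L)
        types <- c(types, cur)
        starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
        pos <- pos + len
        if (pos > L) break
        p <- config$typeProbs
        p[cur] <- 0
        if (sum(p) == 0) p <- config$typeProbs  # single-type config
        cur <- sample(names(p), 1L, prob = p / sum(p))
    }
    new("SSSegmentation", type = types, start = starts,
        end = as.integer(ends))
}

# positions (global indices) where the separation-d doublet term is active
.activePositions <- function(seg, d) {
    use <- vapply(seg@type, function(tp) d %in% .SEG_SEPS[[tp]], TRUE)
    unlist(lapply(which(use), function(j) {
        s <- seg@start[j]; t <- seg@end[j]
        if (t - s >= d) (s + d):t else integer(0)
    }), use.names = FALSE)
}

# prior potential tables (no feature dependence) for one segment
.priorTables <- function(seg, j, config) {
    M <- seg@end[j] - seg@start[j] + 1L
    type <- seg@type[j]
    seps <- .SEG_SEPS[[type]]
    node <- matrix(c(0, config$classBias), M, 2L, byrow = TRUE)
    pairPots <- lapply(seps, function(d)
        matrix(config$couplings[[paste0("order", d)]] * .PAIR_SIGN,
               M, 4L, byrow = TRUE))
    list(node = node, pairPots = pairPots, seps = seps,
         k = .SEG_ORDER[[type]])
}

.samplePriorLabels <- function(seg, config) {
    y <- integer(0)
    for (j in seq_along(seg@type)) {
        tb <- .priorTables(seg, j, config)
        y <- c(y, as.integer(cpp_segment_sample(tb$node, tb$pairPots,
                                                tb$seps, tb$k, 1L)[1L, ]))
    }
    y
}

#' Sample feature matrices given labels and a segmentation
#'
#' Singlet columns: a bias column of ones, label-informative columns as
#' class-conditional Gaussians (unit variance, means +/- effectSize/2),
#' and pure-noise columns.  Doublet observation columns at separation d:
#' Gaussians whose mean is +effect when the labels at i-d and i agree and
#' -effect when they differ, at positions where that order is active;
#' standard normal noise elsewhere (zero in rows i <= d).
#'
#' @param labels 0/1 label vector.
#' @param seg the chain's \linkS4class{SSSegmentation}.
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{singlet} (L x D matrix) and \code{doublet}
#'   (list sep2/sep3/sep4).  Uses the current RNG state.
#' @export
sampleFeatureMatrices <- function(labels, seg, config = generatorConfig()) {
    L <- length(labels)
    cols <- list(bias = rep(1, L))
    for (k in seq_len(config$nInformative))
        cols[[paste0("inf", k)]] <-
            rnorm(L, mean = ifelse(labels == 1L, 1, -1) *
                          config$effectSize / 2)
    for (k in seq_len(config$nNoise))
        cols[[paste0("noise", k)]] <- rnorm(L)
    singlet <- do.call(cbind, cols)
    doublet <- list()
    for (d in 2:4) {
        m <- matrix(0, L, length(config$doubletEffect),
                    dimnames = list(NULL, names(config$doubletEffect)))
        if (L > d) {
            rows <- (d + 1L):L
            m[rows, ] <- rnorm(length(rows) * ncol(m))
            act <- .activePositions(seg, d)
            if (length(act)) {
                sign <- ifelse(labels[act - d] == labels[act], 1, -1)
                for (k in seq_len(ncol(m)))
                    m[act, k] <- rnorm(length(act),
                                       mean = sign * config$doubletEffect[k])
            }
        }
        doublet[[paste0("sep", d)]] <- m
    }
    list(singlet = singlet, doublet = doublet)
}

#' Draw exact label samples from a model given features
#'
#' Forward-filtering backward-sampling on the same per-segment trellis
#' used for inference, so draws follow \code{p(Y | X; model)} exactly.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param model a \linkS4class{BurialCRF}.
#' @param nsamples number of independent draws.
#' @return integer matrix, \code{nsamples} x L.  Uses the current RNG
#'   state (seed with \code{set.seed}).
#' @export
sampleLabels <- function(record, model, nsamples = 1L) {
    tabs <- .recordTables(record, model)
    out <- matrix(NA_integer_, nsamples, length(record))
    for (tb in tabs)
        out[, tb$start:tb$end] <-
            cpp_segment_sample(tb$node, tb$pairPots, tb$seps, tb$k,
                               as.integer(nsamples))
    out
}

#' Simulate a fully labeled synthetic dataset
#'
#' Draws segmentations, labels and features for
#' \code{config$nProteins} chains.  The returned records are exact draws
#' from the joint distribution whose conditional \code{p(Y | X)} is
#' \code{generatingModel(config)}.
#'
#' @param config a \code{\link{generatorConfig}}; its seed determines the
#'   whole dataset.
#' @return list with \code{records} (list of labeled
#'   \linkS4class{ProteinRecord}s), \code{model} (the generating
#'   \linkS4class{BurialCRF}) and \code{config}.
#' @export
simulateProteins <- function(config = generatorConfig()) {
    set.seed(config$seed)
    model <- generatingModel(config)
    records <- vector("list", config$nProteins)
    for (i in seq_len(config$nProteins)) {
        L <- if (config$lengthRange[1] == config$lengthRange[2])
            config$lengthRange[1]
        else sample(config$lengthRange[1]:config$lengthRange[2], 1L)
        seg <- sampleSegmentation(L, config)
        y <- .samplePriorLabels(seg, config)
        feats <- sampleFeatureMatrices(y, seg, config)
        records[[i]] <- new("ProteinRecord",
                            id = sprintf("syn%04d", i),
                            sequence = paste(sample(.AA20, L,
                                                    replace = TRUE),
                                             collapse = ""),
                            ss = segmentsToSS(seg), segmentation = seg,
                            singletFeatures = feats$singlet,
                            doubletFeatures = feats$doublet,
                            labels = y)
    }
    list(records = records, model = model, config = config)
}

#' Write a benchmark to disk as train/validation/test folds
#'
#' Simulates a dataset and writes it in the same plain-text formats the
#' real pipeline reads (FASTA sequences; per-chain TSVs for secondary
#' structure, singlet features, doublet features and labels), plus a
#' manifest recording the configuration hash and the seedable fold
#' assignment.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param dir output directory (created if needed).
#' @param folds number of cross-validation folds.
#' @return the manifest, invisibly.
#' @export
makeBenchmark <- function(config, dir, folds = 5L) {
    sim <- simulateProteins(config)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ids <- vapply(sim$records, chainId, "")
    fold <- kFoldSplit(length(ids), folds, seed = config$seed)
    writeFasta(sim$records, file.path(dir, "sequences.fasta"))
    for (rec in sim$records) {
        base <- file.path(dir, rec@id)
        .writeTSV(data.frame(position = seq_len(length(rec)),
                             ss = strsplit(rec@ss, "")[[1]]),
                  paste0(base, "_ss.tsv"))
        .writeTSV(cbind(data.frame(position = seq_len(length(rec))),
                        as.data.frame(rec@singletFeatures)),
                  paste0(base, "_singlet.tsv"))
        for (nm in names(rec@doubletFeatures))
            .writeTSV(cbind(data.frame(position = seq_len(length(rec))),
                            as.data.frame(rec@doubletFeatures[[nm]])),
                      paste0(base, "_", nm, ".tsv"))
        writeLabelsTSV(rec@labels, paste0(base, "_labels.tsv"))
    }
    manifest <- list(format = "burialCRF-benchmark", version = 1L,
                     configHash = rlang::hash(unclass(config)),
                     seed = config$seed, nProteins = length(ids),
                     folds = as.list(stats::setNames(fold, ids)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeBurialCRF(sim$model, file.path(dir, "generating_model.json"))
    invisible(manifest)
}

#' Read a benchmark directory back into records
#'
#' @param dir directory written by \code{\link{makeBenchmark}}.
#' @return list with \code{records}, \code{folds} (named integer vector)
#'   and \code{manifest}.
#' @export
readBenchmark <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    seqs <- readFastaSequences(file.path(dir, "sequences.fasta"))
    ids <- names(manifest$folds)
    records <- lapply(ids, function(id) {
        base <- file.path(dir, id)
        ss <- paste(read.table(paste0(base, "_ss.tsv"), header = TRUE,
                               colClasses = c("integer", "character"))$ss,
                    collapse = "")
        sm <- as.matrix(read.table(paste0(base, "_singlet.tsv"),
                                   header = TRUE)[, -1L, drop = FALSE])
        dbl <- list()
        for (nm in c("sep2", "sep3", "sep4")) {
            f <- paste0(base, "_", nm, ".tsv")
            if (file.exists(f))
                dbl[[nm]] <- as.matrix(read.table(f, header = TRUE)[
                    , -1L, drop = FALSE])
        }
        ProteinRecord(id, seqs[[id]], ss, sm, dbl,
                      labels = readLabelsTSV(paste0(base, "_labels.tsv")))
    })
    list(records = records,
         folds = unlist(manifest$folds), manifest = manifest)
}
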