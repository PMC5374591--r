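test_that("zero weights give zero potentials and zero scores", {
    set.seed(31)
    rec <- randomRecord(9)
    mod <- modelTemplate(rec)
    expect_equal(phiC(0, 1, 2, rec, mod), 0)
    expect_equal(phiE(1, 0, 1, 3, rec, mod), 0)
    expect_equal(phiH(1, 1, 0, 0, 1, 5, rec, mod), 0)
    for (i in 1:5)
        expect_equal(sequenceLogScore(sample(0:1, 9, replace = TRUE),
                                      rec, mod), 0)
})

test_that("potential term structure decouples as printed", {
    set.seed(32)
    rec <- randomRecord(10)
    mod <- modelTemplate(rec)
    # theta-only: phiC is independent of the previous label
    mod@theta[] <- rnorm(length(mod@theta))
    f0 <- sum(singletFeatures(rec)[4, ] * mod@theta[, 2])
    expect_equal(phiC(0, 1, 4, rec, mod), f0)
    expect_equal(phiC(1, 1, 4, rec, mod), f0)
    # mu-only: phiE varies with (y2, y) but not with y1
    mod2 <- modelTemplate(rec)
    mod2@mu[] <- rnorm(length(mod2@mu))
    expect_equal(phiE(1, 0, 1, 5, rec, mod2), phiE(1, 1, 1, 5, rec, mod2))
    expect_false(isTRUE(all.equal(phiE(0, 0, 1, 5, rec, mod2),
                                  phiE(1, 0, 1, 5, rec, mod2))))
    # tau-only: phiH depends on (y4, y) only
    mod3 <- modelTemplate(rec)
    mod3@tau[] <- rnorm(length(mod3@tau))
    expect_equal(phiH(1, 0, 1, 0, 1, 6, rec, mod3),
                 phiH(1, 1, 0, 1, 1, 6, rec, mod3))
    expect_false(isTRUE(all.equal(phiH(0, 0, 1, 0, 1, 6, rec, mod3),
                                  phiH(1, 0, 1, 0, 1, 6, rec, mod3))))
})

test_that("the sequence log-score matches the naive potential oracle", {
    set.seed(33)
    for (i in 1:20) {
        rec <- randomRecord(sample(1:14, 1))
        mod <- randomModel(rec, order1Features = "f1")
        y <- sample(0:1, length(rec), replace = TRUE)
        expect_equal(sequenceLogScore(y, rec, mod),
                     naiveLogScore(y, rec, mod), tolerance = 1e-12)
    }
})

test_that("every position contributes its singlet term exactly once", {
    set.seed(34)
    for (ss in c("HHHHHHH", "EEEE", "CCC", "HEC", "CCHHHHHEE", "H")) {
        L <- nchar(ss)
        rec <- randomRecord(L)
        rec@ss <- ss
        rec@segmentation <- ssToSegments(ss)
        mod <- modelTemplate(rec)
        mod@theta["bias", ] <- c(1, 1)   # each position adds exactly 1
        y <- sample(0:1, L, replace = TRUE)
        expect_equal(sequenceLogScore(y, rec, mod), L)
    }
})

test_that("a label-constant theta shift is a gauge transformation", {
    set.seed(35)
    rec <- randomRecord(12)
    mod <- randomModel(rec)
    shift <- mod
    shift@theta["bias", ] <- shift@theta["bias", ] + 2.5
    y <- sample(0:1, 12, replace = TRUE)
    expect_equal(sequenceLogScore(y, rec, shift),
                 sequenceLogScore(y, rec, mod) + 2.5 * 12)
    expect_equal(positionMarginals(rec, shift),
                 positionMarginals(rec, mod), tolerance = 1e-12)
    expect_equal(forwardBackward(rec, shift)$logZ,
                 forwardBackward(rec, mod)$logZ + 2.5 * 12)
})

test_that("the segment selector decomposes the score over segments", {
    set.seed(36)
    rec <- randomRecord(15)
    mod <- randomModel(rec)
    y <- sample(0:1, 15, replace = TRUE)
    seg <- as.data.frame(segmentation(rec))
    parts <- sum(sapply(seq_len(nrow(seg)), function(j) {
        idx <- seg$start[j]:seg$end[j]
        sub <- new("ProteinRecord", id = "part",
                   sequence = substr(rec@sequence, idx[1],
                                     idx[length(idx)]),
                   ss = strrep(seg$type[j], length(idx)),
                   segmentation = new("SSSegmentation",
                                      type = seg$type[j], start = 1L,
                                      end = length(idx)),
                   singletFeatures = singletFeatures(rec)[idx, ,
                                                          drop = FALSE],
                   doubletFeatures = lapply(doubletFeatures(rec),
                       function(m) m[idx, , drop = FALSE]),
                   labels = integer(0))
        # zero-fill doublet rows that would reach before the sub-record
        for (nm in names(sub@doubletFeatures)) {
            d <- as.integer(sub("sep", "", nm))
            zr <- seq_len(min(d, nrow(sub@doubletFeatures[[nm]])))
            sub@doubletFeatures[[nm]][zr, ] <- 0
        }
        sequenceLogScore(y[idx], sub, mod)
    }))
    expect_equal(sequenceLogScore(y, rec, mod), parts, tolerance = 1e-10)
})

test_that("model weights flatten and restore losslessly", {
    set.seed(37)
    rec <- randomRecord(6)
    mod <- randomModel(rec)
    v <- flattenModel(mod)
    expect_length(v, nParameters(mod))
    back <- unflattenModel(unname(v), mod)
    expect_identical(flattenModel(back), v)
    expect_identical(back@theta, mod@theta)
    expect_identical(back@tau, mod@tau)
})

test_that("the model archive round-trips bit-exactly", {
    set.seed(38)
    rec <- randomRecord(6)
    mod <- randomModel(rec)
    mod@normalization <- list(center = rnorm(ncol(singletFeatures(rec))),
                              scale = abs(rnorm(ncol(singletFeatures(rec)))) + 0.5)
    f <- withr::local_tempfile(fileext = ".json")
    writeBurialCRF(mod, f)
    back <- readBurialCRF(f)
    expect_identical(back@theta, mod@theta)
    expect_identical(back@lambda, mod@lambda)
    expect_identical(back@mu, mod@mu)
    expect_identical(back@gamma, mod@gamma)
    expect_identical(back@tau, mod@tau)
    expect_identical(back@normalization, mod@normalization)
    expect_identical(back@featureNames, mod@featureNames)
    other <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(format = "something-else"), other,
                         auto_unbox = TRUE)
    expect_error(readBurialCRF(other), "not a burialCRF model")
})
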