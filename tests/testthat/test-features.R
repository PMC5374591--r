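test_that("PSI-BLAST ASCII PSSMs are parsed into both views", {
    set.seed(7)
    lo <- matrix(sample(-5:8, 60, replace = TRUE), 3, 20)
    pct <- matrix(5L, 3, 20)
    f <- writePssmFixture(lo, pct, c("M", "A", "D"),
                          withr::local_tempfile())
    prof <- readPSSM(f, sequence = "MAD")
    expect_equal(nrow(profileFrequencies(prof)), 3L)
    expect_equal(unname(prof@logOdds), lo)
    expect_equal(unname(profileFrequencies(prof)[1, ]), rep(0.05, 20))
    expect_equal(rowSums(profileFrequencies(prof)), rep(1, 3))
    expect_error(readPSSM(f, sequence = "MADE"), "3 rows")
})

test_that("missing-profile mode builds a one-hot pseudo-profile", {
    prof <- onehotProfile("ACX")
    fr <- profileFrequencies(prof)
    expect_equal(unname(fr[1, "A"]), 1)
    expect_equal(unname(fr[2, "C"]), 1)
    expect_equal(unname(fr[3, ]), unname(aaBackground()))
    expect_equal(nrow(prof@logOdds), 0L)
})

test_that("conservation is relative entropy against the background", {
    bg <- aaBackground("uniform")
    prof <- new("SequenceProfile",
                freq = matrix(bg, 2, 20, byrow = TRUE,
                              dimnames = list(NULL, names(bg))),
                logOdds = matrix(0, 0, 0), background = unname(bg))
    expect_equal(sequenceConservation(prof), c(0, 0))
    # point mass on one residue, uniform background: log2(20)
    pm <- onehotProfile("A", background = bg)
    expect_equal(sequenceConservation(pm), log2(20))
    # random columns against a direct summation oracle
    set.seed(21)
    p <- matrix(rexp(80), 4, 20); p <- p / rowSums(p)
    q <- rexp(20); q <- q / sum(q)
    colnames(p) <- names(bg)
    prof2 <- new("SequenceProfile", freq = p, logOdds = matrix(0, 0, 0),
                 background = q)
    oracle <- sapply(1:4, function(i)
        sum(ifelse(p[i, ] > 0, p[i, ] * log2(p[i, ] / q), 0)))
    expect_equal(sequenceConservation(prof2), oracle, tolerance = 1e-12)
    expect_true(all(sequenceConservation(prof2) >= 0))
})

test_that("contact numbers use strict 8-Angstrom / >=5-separation rules", {
    co <- matrix(0, 6, 3)
    co[6, ] <- c(7.9, 0, 0)            # |1-6| = 5, d = 7.9 < 8
    expect_equal(contactNumber(co)[c(1, 6)], c(1L, 1L))
    co[6, 1] <- 8.0                    # boundary is excluded
    expect_equal(contactNumber(co)[c(1, 6)], c(0L, 0L))
    expect_equal(contactNumber(matrix(rnorm(9), 3, 3)), rep(0L, 3))
    # random coordinates against an all-pairs brute force
    set.seed(9)
    co <- matrix(rnorm(90, sd = 6), 30, 3)
    cn <- contactNumber(co)
    brute <- sapply(1:30, function(i)
        sum(sapply(1:30, function(j)
            abs(i - j) >= 5 && sqrt(sum((co[i, ] - co[j, ])^2)) < 8)))
    expect_equal(cn, as.integer(brute))
    # rigid-body invariance
    th <- 0.7
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
               c(0, 0, 1))
    expect_equal(contactNumber(co %*% R + 3), cn)
    # missing coordinates are flagged
    co[4, 2] <- NA
    expect_true(is.na(contactNumber(co)[4]))
})

test_that("doublet MI and cosine follow their closed forms", {
    prof <- onehotProfile("AAAC")
    # outer-product joint: independence, exactly zero
    expect_identical(mutualInformationDoublet(prof, 3, 2), 0)
    # perfectly correlated 2-letter joint: 1 bit
    expect_equal(mutualInformationDoublet(prof, 3, 2,
                                          joint = diag(c(0.5, 0.5))), 1)
    # random joint against direct summation
    set.seed(4)
    J <- matrix(rexp(16), 4, 4); J <- J / sum(J)
    mi <- mutualInformationDoublet(prof, 3, 2, joint = J)
    pr <- rowSums(J); pc <- colSums(J)
    expect_equal(mi, sum(J * log2(J / outer(pr, pc))), tolerance = 1e-12)
    expect_equal(mi, mutualInformationDoublet(prof, 3, 2, joint = t(J)),
                 tolerance = 1e-12)
    expect_error(mutualInformationDoublet(prof, 2, 2), "out of range")

    expect_equal(cosineDoublet(prof, 3, 2), 1)     # identical columns
    expect_equal(cosineDoublet(prof, 4, 2), 0)     # orthogonal one-hots
    set.seed(5)
    p <- matrix(rexp(40), 2, 20); p <- p / rowSums(p)
    colnames(p) <- colnames(profileFrequencies(prof))
    pr2 <- new("SequenceProfile", freq = p, logOdds = matrix(0, 0, 0),
               background = unname(aaBackground()))
    expect_equal(cosineDoublet(pr2, 2, 1),
                 sum(p[1, ] * p[2, ]) /
                     (sqrt(sum(p[1, ]^2)) * sqrt(sum(p[2, ]^2))),
                 tolerance = 1e-12)
})

test_that("doublet feature matrices are assembled per separation", {
    prof <- onehotProfile("AAAAA")
    cm <- matrix(seq_len(25) / 25, 5, 5)
    d <- doubletFeatureSet(prof, contactMap = cm)
    expect_named(d, c("sep2", "sep3", "sep4"))
    expect_equal(d$sep2[1:2, ], matrix(0, 2, 3,
                 dimnames = list(NULL, c("mi", "cosine", "cmap"))))
    expect_equal(unname(d$sep2[3, "cosine"]), 1)
    expect_equal(unname(d$sep3[4, "cmap"]), cm[1, 4])
})

test_that("singlet assembly is deterministic and registry-driven", {
    m <- assembleSingletFeatures("ACD", groups = "residue")
    expect_equal(dim(m), c(3L, 21L))
    expect_equal(rowSums(m), rep(1, 3))
    expect_equal(which(m[2, ] == 1), c(resC = 5L))

    prof <- onehotProfile("ACD")
    full <- assembleSingletFeatures("ACD", profile = prof,
                                    ssProbs = matrix(1 / 3, 3, 3),
                                    contactNumbers = c(0, 2, 1))
    reg <- attr(full, "registry")
    expect_equal(ncol(full), sum(reg$width))
    expect_true(all(reg$supplied))
    # profile group equals the frequency rows
    expect_equal(unname(full[, paste0("prof", colnames(prof@freq))]),
                 unname(profileFrequencies(prof)))
    # purity: identical inputs give identical matrices
    expect_identical(full, assembleSingletFeatures("ACD", profile = prof,
                                                   ssProbs = matrix(1 / 3, 3, 3),
                                                   contactNumbers = c(0, 2, 1)))
    # requested-but-missing groups are zero-filled and flagged
    miss <- assembleSingletFeatures("ACD", groups = c("bias", "cn"))
    regm <- attr(miss, "registry")
    expect_false(regm$supplied[regm$group == "cn"])
    expect_equal(unname(miss[, "cn1"]), rep(0, 3))
    expect_error(assembleSingletFeatures("ACD", contactNumbers = 1:2),
                 "length")
})
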