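test_that("generation is bit-reproducible from (config, seed)", {
    cfg <- generatorConfig(nProteins = 5, lengthRange = c(10L, 30L),
                           seed = 61)
    a <- simulateProteins(cfg)
    b <- simulateProteins(cfg)
    expect_identical(lapply(a$records, singletFeatures),
                     lapply(b$records, singletFeatures))
    expect_identical(lapply(a$records, burialLabels),
                     lapply(b$records, burialLabels))
    expect_identical(vapply(a$records, function(r) r@ss, ""),
                     vapply(b$records, function(r) r@ss, ""))
    expect_identical(flattenModel(a$model), flattenModel(b$model))
})

test_that("segment lengths follow the configured geometric means", {
    cfg <- generatorConfig(seed = 62,
                           meanSegLen = c(H = 10, E = 5, C = 6))
    set.seed(62)
    # long chains keep truncation negligible
    lens <- list(H = numeric(0), E = numeric(0), C = numeric(0))
    for (r in 1:60) {
        seg <- sampleSegmentation(3000L, cfg)
        df <- as.data.frame(seg)
        df <- df[-nrow(df), , drop = FALSE]      # drop truncated tail
        for (tp in c("H", "E", "C"))
            lens[[tp]] <- c(lens[[tp]],
                            df$end[df$type == tp] - df$start[df$type == tp] + 1)
    }
    expect_gt(min(lengths(lens)), 2000)          # ~1e4 segments total
    expect_lt(abs(mean(lens$H) - 10) / 10, 0.05)
    expect_lt(abs(mean(lens$E) - 5) / 5, 0.05)
    expect_lt(abs(mean(lens$C) - 6) / 6, 0.05)
    # degenerate cases
    expect_equal(nrow(as.data.frame(sampleSegmentation(1L, cfg))), 1L)
    allC <- generatorConfig(typeProbs = c(H = 0, E = 0, C = 1),
                            meanSegLen = c(H = 5, E = 5, C = 1e6),
                            seed = 1)
    seg <- sampleSegmentation(50L, allC)
    expect_equal(as.data.frame(seg),
                 data.frame(type = "C", start = 1L, end = 50L))
})

test_that("informative singlet columns separate classes as configured", {
    cfg <- generatorConfig(nProteins = 120, lengthRange = c(80L, 120L),
                           effectSize = 1, seed = 63)
    sim <- simulateProteins(cfg)
    y <- unlist(lapply(sim$records, burialLabels))
    F <- do.call(rbind, lapply(sim$records, singletFeatures))
    expect_gt(length(y), 1e4)
    for (cn in c("inf1", "inf2")) {
        diffMean <- mean(F[y == 1, cn]) - mean(F[y == 0, cn])
        se <- sqrt(1 / sum(y == 1) + 1 / sum(y == 0))
        expect_lt(abs(diffMean - 1), 3 * se)
    }
    # noise columns carry no signal
    dn <- mean(F[y == 1, "noise1"]) - mean(F[y == 0, "noise1"])
    expect_lt(abs(dn), 4 * sqrt(1 / sum(y == 1) + 1 / sum(y == 0)))
})

test_that("zero effect size leaves held-out accuracy at chance", {
    cfg <- generatorConfig(nProteins = 80, lengthRange = c(60L, 80L),
                           effectSize = 0,
                           doubletEffect = c(mi = 0, cosine = 0, cmap = 0),
                           couplings = c(order1 = 0, order2 = 0,
                                         order3 = 0, order4 = 0),
                           seed = 64)
    sim <- simulateProteins(cfg)
    lr <- baselineLogistic(sim$records[1:40], sim$records[41:80])
    # ~2800 test residues: 0.04 is > 4 binomial standard errors
    expect_lt(abs(lr$accuracy - 0.5), 0.04)
})

test_that("zero-weight models sample fair independent coins", {
    set.seed(65)
    rec <- randomRecord(20, withLabels = FALSE)
    mod <- modelTemplate(rec)
    draws <- sampleLabels(rec, mod, 500)
    counts <- table(factor(as.vector(draws), 0:1))
    expect_gt(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value, 0.01)
    # no serial correlation at zero coupling
    expect_lt(abs(cor(as.vector(draws[, -1]), as.vector(draws[, -20]))),
              0.03)
})

test_that("exact sampling matches enumeration frequencies", {
    cfg <- generatorConfig(nProteins = 1, lengthRange = c(5L, 5L),
                           seed = 66)
    sim <- simulateProteins(cfg)
    rec <- sim$records[[1]]
    ref <- naiveEnumeration(rec, sim$model)
    set.seed(660)
    draws <- sampleLabels(rec, sim$model, 20000)
    code <- as.vector(draws %*% 2^(0:4))
    emp <- tabulate(code + 1, nbins = 32) / length(code)
    pexp <- numeric(32)
    pexp[ref$labelings %*% 2^(0:4) + 1] <- ref$probabilities
    expect_lt(0.5 * sum(abs(emp - pexp)), 0.03)
})

test_that("strong helix couplings reproduce the periodic correlation", {
    cfg <- generatorPreset("alpha", nProteins = 150,
                           lengthRange = c(60L, 100L), seed = 67)
    sim <- simulateProteins(cfg)
    mi <- miVsSeparation(lapply(sim$records, burialLabels),
                         lapply(sim$records, segmentation), maxSep = 4)
    h <- function(d) mi$mi[mi$ss == "H" & mi$separation == d]
    expect_gt(h(4), h(2))
    expect_gt(h(3), h(2))
})

test_that("benchmarks are written deterministically and read back", {
    cfg <- generatorConfig(nProteins = 10, lengthRange = c(15L, 25L),
                           seed = 68)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    m1 <- makeBenchmark(cfg, d1, folds = 5)
    m2 <- makeBenchmark(cfg, d2, folds = 5)
    expect_identical(m1, m2)
    expect_equal(unname(table(unlist(m1$folds))), rep(2L, 5),
                 ignore_attr = TRUE)
    expect_equal(length(unique(names(m1$folds))), 10L)  # disjoint folds
    back <- readBenchmark(d1)
    expect_equal(length(back$records), 10L)
    sim <- simulateProteins(cfg)
    expect_identical(back$records[[3]]@ss, sim$records[[3]]@ss)
    expect_identical(burialLabels(back$records[[3]]),
                     burialLabels(sim$records[[3]]))
    expect_equal(singletFeatures(back$records[[3]]),
                 singletFeatures(sim$records[[3]]), tolerance = 1e-15)
    gm <- readBurialCRF(file.path(d1, "generating_model.json"))
    expect_identical(flattenModel(gm), flattenModel(sim$model))
})
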