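test_that("log-likelihood closed forms at zero weights", {
    rec1 <- ProteinRecord("one", "A", "C", labels = 1L)
    mod1 <- modelTemplate(rec1)
    expect_equal(logLikelihood(rec1, mod1), log(1 / 2))
    # M proteins, any segmentation: uniform model gives -sum(L_m) log 2
    set.seed(51)
    recs <- lapply(c(4, 7, 10), randomRecord)
    mod <- modelTemplate(recs[[1]])
    expect_equal(logLikelihood(recs, mod), -sum(c(4, 7, 10)) * log(2))
    # random weights agree with the enumeration oracle
    modr <- randomModel(recs[[2]])
    oracle <- sum(sapply(recs, function(r) {
        ref <- naiveEnumeration(r, modr)
        naiveLogScore(r@labels, r, modr) - ref$logZ
    }))
    expect_equal(logLikelihood(recs, modr), oracle, tolerance = 1e-9)
    unl <- recs[[1]]; unl@labels <- integer(0)
    expect_error(logLikelihood(list(unl), mod), "labels")
})

test_that("the analytic gradient matches central finite differences", {
    set.seed(52)
    for (i in 1:6) {
        recs <- lapply(sample(3:9, 2), randomRecord)
        tmpl <- modelTemplate(recs[[1]], order1Features = "f1")
        par <- rnorm(length(flattenModel(tmpl)), sd = 0.5)
        mod <- unflattenModel(par, tmpl)
        l2 <- if (i %% 2) 0 else 0.7
        g <- modelGradient(recs, mod, l2)
        h <- 1e-5
        fd <- vapply(seq_along(par), function(k) {
            up <- par; up[k] <- up[k] + h
            dn <- par; dn[k] <- dn[k] - h
            (logLikelihood(recs, unflattenModel(up, tmpl), l2) -
             logLikelihood(recs, unflattenModel(dn, tmpl), l2)) / (2 * h)
        }, 1)
        expect_lt(max(abs(g - fd) / (abs(fd) + 1e-6)), 1e-5)
    }
})

test_that("bias-weight gradients vanish at zero for balanced labels", {
    set.seed(53)
    rec <- randomRecord(12)
    rec@labels <- c(rep(0L, 6), rep(1L, 6))[sample(12)]
    mod <- modelTemplate(rec)
    g <- unflattenModel(modelGradient(rec, mod), mod)
    # theta bias gradient: empirical count (6) minus expected (L/2 = 6)
    expect_equal(unname(g@theta["bias", ]), c(0, 0), tolerance = 1e-9)
})

test_that("fitting is monotone, convergent and deterministic", {
    set.seed(54)
    cfg <- generatorConfig(nProteins = 8, lengthRange = c(20L, 30L),
                           seed = 54)
    sim <- simulateProteins(cfg)
    f1 <- fitBurialCRF(sim$records, trainingConfig(maxIter = 40))
    expect_true(all(diff(f1$trace$loglik) >= -1e-9))
    expect_true(all(is.finite(f1$trace$gradNorm)))
    # stationarity at the (penalized) optimum
    f2 <- fitBurialCRF(sim$records,
                       trainingConfig(optimizer = "lbfgs",
                                      maxIter = 500, tol = 1e-9))
    gpen <- modelGradient(sim$records, f2$model, 1)
    expect_lt(sqrt(sum(gpen^2)) / length(gpen), 0.05)
    # determinism: identical runs give bit-identical traces and models
    f3 <- fitBurialCRF(sim$records, trainingConfig(maxIter = 40))
    expect_identical(f1$trace, f3$trace)
    expect_identical(flattenModel(f1$model), flattenModel(f3$model))
})

test_that("a capacity-sufficient model memorizes a single protein", {
    set.seed(55)
    cfg <- generatorConfig(nProteins = 1, lengthRange = c(25L, 25L),
                           effectSize = 2, seed = 55)
    sim <- simulateProteins(cfg)
    fit <- fitBurialCRF(sim$records,
                        trainingConfig(l2 = 0, optimizer = "lbfgs",
                                       maxIter = 200))
    pred <- decodeLabels(positionMarginals(sim$records[[1]], fit$model))
    expect_equal(pred, sim$records[[1]]@labels)
})

test_that("the concave objective makes the optimum initialization-free", {
    set.seed(56)
    cfg <- generatorConfig(nProteins = 6, lengthRange = c(15L, 25L),
                           seed = 56)
    sim <- simulateProteins(cfg)
    tmpl <- modelTemplate(sim$records[[1]])
    warm <- unflattenModel(rnorm(length(flattenModel(tmpl)), sd = 0.8),
                           tmpl)
    cold <- fitBurialCRF(sim$records,
                         trainingConfig(optimizer = "lbfgs",
                                        maxIter = 500, tol = 1e-9))
    hot <- fitBurialCRF(sim$records,
                        trainingConfig(optimizer = "lbfgs",
                                       maxIter = 500, tol = 1e-9),
                        template = warm, normalize = FALSE)
    coldN <- fitBurialCRF(sim$records,
                          trainingConfig(optimizer = "lbfgs",
                                         maxIter = 500, tol = 1e-9),
                          normalize = FALSE)
    mc <- positionMarginals(sim$records[[1]], coldN$model)
    mh <- positionMarginals(sim$records[[1]], hot$model)
    expect_lt(max(abs(mc - mh)), 1e-4)
    expect_true(cold$converged)
})

test_that("the k-fold splitter is seeded, balanced and exhaustive", {
    f <- kFoldSplit(100, 5, seed = 9)
    expect_equal(sort(unique(f)), 1:5)
    expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
    expect_identical(f, kFoldSplit(100, 5, seed = 9))
    expect_false(identical(f, kFoldSplit(100, 5, seed = 10)))
})
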