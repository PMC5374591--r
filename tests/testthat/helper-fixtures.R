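# Fixtures built in code: random instances, a hand-rolled potential
# oracle, and writers for crafted DSSP / PSSM files.

randomSS <- function(L) paste(sample(c("H", "E", "C"), L, replace = TRUE),
                              collapse = "")

# random labeled record with bias + 2 singlet columns and 3-column doublet
# matrices (rows i <= d zero-filled)
randomRecord <- function(L, withLabels = TRUE) {
    singlet <- cbind(bias = rep(1, L),
                     f1 = rnorm(L), f2 = rnorm(L))
    dbl <- lapply(c(2, 3, 4), function(d) {
        m <- matrix(0, L, 3,
                    dimnames = list(NULL, c("mi", "cosine", "cmap")))
        if (L > d) m[(d + 1):L, ] <- rnorm((L - d) * 3)
        m
    })
    names(dbl) <- paste0("sep", c(2, 3, 4))
    ProteinRecord(id = "rnd",
                  sequence = paste(sample(c("A", "C", "D", "E"), L,
                                          replace = TRUE), collapse = ""),
                  ss = randomSS(L), singletFeatures = singlet,
                  doubletFeatures = dbl,
                  labels = if (withLabels) sample(0:1, L, replace = TRUE))
}

randomModel <- function(record, sd = 0.6, order1Features = character(0)) {
    tmpl <- modelTemplate(record, order1Features)
    unflattenModel(rnorm(length(flattenModel(tmpl)), sd = sd), tmpl)
}

# independent potential oracle: recomputes the log-score position by
# position straight from the model slots and the stated term structure
naiveLogScore <- function(y, rec, mod) {
    F <- singletFeatures(rec)
    nz <- mod@normalization
    if (length(nz))
        F <- sweep(sweep(F, 2, nz$center, "-"), 2, nz$scale, "/")
    seg <- as.data.frame(segmentation(rec))
    dbl <- doubletFeatures(rec)
    total <- 0
    for (si in seq_len(nrow(seg))) {
        s <- seg$start[si]; t <- seg$end[si]; tp <- seg$type[si]
        for (i in s:t) {
            total <- total + sum(F[i, ] * mod@theta[, y[i] + 1])
            pr <- function(d) 2 * y[i - d] + y[i] + 1
            if (i >= s + 1) {
                obs1 <- c(1, F[i, mod@featureNames$order1])
                total <- total + sum(obs1 * mod@lambda[pr(1), ])
            }
            if (tp == "E" && i >= s + 2)
                total <- total +
                    sum(c(1, dbl$sep2[i, ]) * mod@mu[pr(2), ])
            if (tp == "H" && i >= s + 3)
                total <- total +
                    sum(c(1, dbl$sep3[i, ]) * mod@gamma[pr(3), ])
            if (tp == "H" && i >= s + 4)
                total <- total +
                    sum(c(1, dbl$sep4[i, ]) * mod@tau[pr(4), ])
        }
    }
    total
}

# enumeration over all labelings through the naive oracle only
naiveEnumeration <- function(rec, mod) {
    L <- length(rec)
    labs <- as.matrix(expand.grid(rep(list(0:1), L)))
    scores <- apply(labs, 1, naiveLogScore, rec = rec, mod = mod)
    m <- max(scores)
    w <- exp(scores - m)
    p <- w / sum(w)
    marg <- cbind(exposed = 1 - as.numeric(t(labs) %*% p),
                  buried = as.numeric(t(labs) %*% p))
    list(logZ = m + log(sum(w)), marginals = marg, probabilities = p,
         labelings = labs)
}

# crafted classic-layout DSSP file; df columns: aa, ss8, acc; breakAfter
# gives residue counts after which a '!' row is inserted
writeDsspFixture <- function(df, path, breakAfter = integer(0),
                             chain = "A", header = TRUE) {
    lines <- c("==== Secondary Structure Definition, synthetic fixture ====",
               "REFERENCE   none")
    if (header)
        lines <- c(lines, paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
                                 "     N-H-->O    O-->H-N    TCO KAPPA"))
    n <- 0L
    for (r in seq_len(nrow(df))) {
        n <- n + 1L
        lines <- c(lines, sprintf("%5d%5d %s %s  %s%17s%4d",
                                  r, r, chain, df$aa[r], df$ss8[r], "",
                                  as.integer(df$acc[r])))
        if (n %in% breakAfter)
            lines <- c(lines, sprintf("%5d      %s %s  %s%17s%4d",
                                      r, " ", "!", " ", "", 0L))
    }
    writeLines(lines, path)
    path
}

# crafted PSI-BLAST ASCII PSSM; logOdds and pct are L x 20 matrices
writePssmFixture <- function(logOdds, pct, aa, path) {
    alph <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    lines <- c("", "Last position-specific scoring matrix computed",
               paste0("           ",
                      paste(sprintf("%3s", c(alph, alph)), collapse = "")))
    for (i in seq_len(nrow(logOdds)))
        lines <- c(lines, paste0(sprintf("%5d %s ", i, aa[i]),
                                 paste(sprintf("%3d", logOdds[i, ]),
                                       collapse = ""),
                                 paste(sprintf("%4d", pct[i, ]),
                                       collapse = ""),
                                 sprintf("  %4.2f %8.2f", 0.5, 1)))
    lines <- c(lines, "", "                      K         Lambda")
    writeLines(lines, path)
    path
}
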