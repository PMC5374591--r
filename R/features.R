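#' Contact numbers from C-alpha coordinates
#'
#' The contact number of a residue is the count of residues at spatial
#' distance strictly below \code{radius} (default 8 Angstrom) and
#' sequence separation of at least \code{minSep} (default 5) positions.
#' Rows with missing coordinates yield \code{NA}.
#'
#' @param coords numeric L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param radius distance cutoff (strict \code{<}).
#' @param minSep minimum sequence separation (\code{|i - j| >= minSep}).
#' @return integer vector of contact numbers (all zero when fewer than
#'   \code{minSep + 1} residues).
#' @export
contactNumber <- function(coords, radius = 8, minSep = 5L) {
    coords <- as.matrix(coords)
    stopifnot(ncol(coords) == 3L)
    L <- nrow(coords)
    if (L < minSep + 1L) return(rep(0L, L))
    miss <- !stats::complete.cases(coords)
    d <- as.matrix(dist(coords))
    sep <- abs(outer(seq_len(L), seq_len(L), "-"))
    hit <- d < radius & sep >= minSep
    cn <- as.integer(rowSums(hit, na.rm = TRUE))
    cn[miss] <- NA_integer_
    cn
}

#' Mutual information between two profile columns
#'
#' Columns of a single profile are marginals, not a joint; by default the
#' joint is their outer product, whose mutual information is exactly 0.
#' A pair-count joint (e.g. from alignment columns) can be supplied to
#' obtain a non-trivial value: \code{sum p log2(p / (p_row p_col))} in
#' bits.
#'
#' @param profile a \linkS4class{SequenceProfile}.
#' @param i 1-based position; the pair is (i - d, i).
#' @param d separation, \code{i - d >= 1}.
#' @param joint optional joint distribution matrix (normalized
#'   internally).
#' @return mutual information in bits (non-negative).
#' @export
mutualInformationDoublet <- function(profile, i, d, joint = NULL) {
    if (i - d < 1L || i > nrow(profile@freq))
        stop("position out of range for separation ", d)
    if (is.null(joint)) return(0)
    joint <- joint / sum(joint)
    pr <- rowSums(joint); pc <- colSums(joint)
    ind <- outer(pr, pc)
    term <- joint * log2(joint / ind)
    term[joint == 0] <- 0
    max(0, sum(term))
}

#' Cosine similarity between two profile columns
#'
#' Standard cosine of the 20-dimensional frequency columns at positions
#' \code{i - d} and \code{i}; zero-norm columns give 0.
#'
#' @inheritParams mutualInformationDoublet
#' @return value in [-1, 1].
#' @export
cosineDoublet <- function(profile, i, d) {
    if (i - d < 1L || i > nrow(profile@freq))
        stop("position out of range for separation ", d)
    a <- profile@freq[i - d, ]; b <- profile@freq[i, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

#' Doublet feature matrices at separations 2, 3, 4
#'
#' For each separation d, an L x 3 matrix of (mutual information, cosine
#' similarity, contact-map score) between positions i - d and i.  MI is 0
#' unless per-pair joints are supplied; the contact-map score comes from
#' a precomputed per-pair score matrix (its formula is not derived here)
#' and is 0 when absent.  Rows with \code{i <= d} are zero-filled.
#'
#' @param profile a \linkS4class{SequenceProfile}.
#' @param contactMap optional L x L numeric matrix of per-pair scores.
#' @param joints optional function \code{(i, d)} returning a joint
#'   distribution matrix for the pair, or \code{NULL}.
#' @return named list \code{sep2}, \code{sep3}, \code{sep4} of L x 3
#'   matrices with columns \code{mi}, \code{cosine}, \code{cmap}.
#' @export
doubletFeatureSet <- function(profile, contactMap = NULL, joints = NULL) {
    L <- nrow(profile@freq)
    out <- list()
    for (d in 2:4) {
        m <- matrix(0, L, 3L,
                    dimnames = list(NULL, c("mi", "cosine", "cmap")))
        if (L > d) for (i in (d + 1L):L) {
            j <- if (is.null(joints)) NULL else joints(i, d)
            m[i, "mi"] <- mutualInformationDoublet(profile, i, d, j)
            m[i, "cosine"] <- cosineDoublet(profile, i, d)
            if (!is.null(contactMap)) m[i, "cmap"] <- contactMap[i - d, i]
        }
        out[[paste0("sep", d)]] <- m
    }
    out
}

#' Assemble the singlet feature matrix
#'
#' Builds the per-residue feature matrix from its registered groups in a
#' fixed, deterministic order: \code{bias} (1), \code{residue} (21-way
#' one-hot incl. X), \code{terminal} (N/C-terminal flags, 2),
#' \code{profile} (20 frequency columns, optionally windowed),
#' \code{conservation} (1), \code{ss} (3 predicted class probabilities),
#' \code{cn} (1 contact-number column), \code{extra} (any precomputed
#' per-residue columns, e.g. disorder or binding-site probabilities,
#' physicochemical tendencies, secondary-structure end tendencies, I-site
#' scores or contact potentials).  Groups that are requested but not
#' supplied are zero-filled and flagged in the registry.  The total
#' column count is asserted from the registry, never hardcoded.
#'
#' @param sequence amino-acid string.
#' @param profile optional \linkS4class{SequenceProfile}.
#' @param ssProbs optional L x 3 matrix of H/E/C probabilities.
#' @param conservation optional numeric vector (computed from the profile
#'   when absent but requested).
#' @param contactNumbers optional numeric vector.
#' @param extra optional numeric matrix of additional columns.
#' @param groups which groups to include, in registry order; default: the
#'   always-available groups plus every supplied input.
#' @param windowRadius include profile columns of flanking positions up
#'   to this offset (0 = no context window).
#' @return L x D numeric matrix with a \code{"registry"} attribute
#'   (data.frame: group, width, supplied).
#' @export
assembleSingletFeatures <- function(sequence, profile = NULL,
                                    ssProbs = NULL, conservation = NULL,
                                    contactNumbers = NULL, extra = NULL,
                                    groups = NULL, windowRadius = 0L) {
    ch <- strsplit(toupper(sequence), "")[[1]]
    L <- length(ch)
    if (is.null(groups))
        groups <- c("bias", "residue", "terminal",
                    if (!is.null(profile)) c("profile", "conservation"),
                    if (!is.null(ssProbs)) "ss",
                    if (!is.null(contactNumbers)) "cn",
                    if (!is.null(extra)) "extra")
    known <- c("bias", "residue", "terminal", "profile", "conservation",
               "ss", "cn", "extra")
    if (!all(groups %in% known))
        stop("unknown feature group(s): ",
             paste(setdiff(groups, known), collapse = ", "))
    groups <- known[known %in% groups]
    chk <- function(x, what) {
        if (NROW(x) != L)
            stop(what, " length does not match the sequence")
        x
    }
    build <- list()
    supplied <- logical(0)
    for (g in groups) {
        m <- switch(g,
            bias = matrix(1, L, 1L, dimnames = list(NULL, "bias")),
            residue = {
                alph <- c(.AA20, "X")
                m <- matrix(0, L, 21L, dimnames = list(NULL,
                            paste0("res", alph)))
                m[cbind(seq_len(L), match(ch, alph))] <- 1
                m
            },
            terminal = cbind(nterm = as.numeric(seq_len(L) == 1L),
                             cterm = as.numeric(seq_len(L) == L)),
            profile = if (is.null(profile)) NULL else {
                p <- chk(profile@freq, "profile")
                offs <- (-windowRadius):windowRadius
                do.call(cbind, lapply(offs, function(o) {
                    sh <- matrix(0, L, 20L)
                    src <- seq_len(L) + o
                    ok <- src >= 1L & src <= L
                    sh[ok, ] <- p[src[ok], ]
                    colnames(sh) <- paste0("prof", .PSSM_AA,
                                           if (o != 0) sprintf("%+d", o)
                                           else "")
                    sh
                }))
            },
            conservation = {
                v <- conservation
                if (is.null(v) && !is.null(profile))
                    v <- sequenceConservation(profile)
                if (is.null(v)) NULL
                else matrix(chk(v, "conservation"),
                            dimnames = list(NULL, "conservation"))
            },
            ss = if (is.null(ssProbs)) NULL else {
                m <- as.matrix(chk(ssProbs, "ssProbs"))
                colnames(m) <- c("pH", "pE", "pC")
                m
            },
            cn = if (is.null(contactNumbers)) NULL
                 else matrix(chk(as.numeric(contactNumbers), "cn"),
                             dimnames = list(NULL, "cn")),
            extra = if (is.null(extra)) NULL else {
                m <- as.matrix(chk(extra, "extra"))
                if (is.null(colnames(m)))
                    colnames(m) <- paste0("extra", seq_len(ncol(m)))
                m
            })
        sup <- !is.null(m)
        if (!sup) {    # requested but unavailable: zero-filled, flagged
            w <- switch(g, profile = 20L * (2L * windowRadius + 1L),
                        conservation = 1L, ss = 3L, cn = 1L, extra = 1L)
            m <- matrix(0, L, w,
                        dimnames = list(NULL, paste0(g, seq_len(w))))
        }
        build[[g]] <- m
        supplied[g] <- sup
    }
    out <- do.call(cbind, build)
    registry <- data.frame(group = groups,
                           width = vapply(build, ncol, 1L),
                           supplied = supplied, row.names = NULL)
    stopifnot(ncol(out) == sum(registry$width))
    attr(out, "registry") <- registry
    out
}
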