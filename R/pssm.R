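# PSI-BLAST ASCII PSSM column order (the profile alphabet used throughout)
.PSSM_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson (1991) amino-acid background frequencies
.RR_BACKGROUND <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536,
                    C = 0.0192, Q = 0.0426, E = 0.0624, G = 0.0738,
                    H = 0.0226, I = 0.0514, L = 0.0901, K = 0.0574,
                    M = 0.0224, F = 0.0385, P = 0.0520, S = 0.0711,
                    T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)

#' Amino-acid background distribution
#'
#' @param name \code{"robinson"} (Robinson-Robinson 1991 frequencies) or
#'   \code{"uniform"}.
#' @return length-20 vector summing to 1, in PSSM column order.
#' @export
aaBackground <- function(name = c("robinson", "uniform")) {
    name <- match.arg(name)
    b <- if (name == "uniform") stats::setNames(rep(1 / 20, 20), .PSSM_AA)
         else .RR_BACKGROUND / sum(.RR_BACKGROUND)
    b[.PSSM_AA]
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the \code{-out_ascii_pssm} layout: per-position rows with 20
#' integer log-odds columns followed by 20 weighted-percentage columns.
#' Both views are kept; the percentage columns divided by 100 give the
#' frequency view (all-zero rows fall back to the background).
#'
#' @param path PSSM file.
#' @param sequence optional amino-acid string cross-checked against the
#'   file (length and letters).
#' @param background background distribution for conservation.
#' @return a \linkS4class{SequenceProfile}.
#' @export
readPSSM <- function(path, sequence = NULL,
                     background = aaBackground()) {
    lines <- readLines(path)
    toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
    hdr <- which(vapply(toks, function(t)
        length(t) >= 40L && identical(t[1:20], .PSSM_AA) &&
            identical(t[21:40], .PSSM_AA), TRUE))
    if (!length(hdr)) stop("not a PSI-BLAST ASCII PSSM: ", path)
    rows <- list()
    aa <- character(0)
    for (i in (hdr[1] + 1L):length(toks)) {
        t <- toks[[i]]
        if (length(t) < 42L) break
        v <- suppressWarnings(as.numeric(t[3:42]))
        if (anyNA(v)) break
        rows[[length(rows) + 1L]] <- v
        aa <- c(aa, t[2])
    }
    if (!length(rows)) stop("truncated PSSM (no data rows): ", path)
    m <- do.call(rbind, rows)
    logOdds <- m[, 1:20, drop = FALSE]
    freq <- m[, 21:40, drop = FALSE] / 100
    zero <- rowSums(freq) == 0
    if (any(zero))
        freq[zero, ] <- matrix(background, sum(zero), 20L, byrow = TRUE)
    freq <- freq / rowSums(freq)
    colnames(logOdds) <- colnames(freq) <- .PSSM_AA
    if (!is.null(sequence)) {
        if (nchar(sequence) != nrow(freq))
            stop(sprintf("PSSM has %d rows but sequence has %d residues",
                         nrow(freq), nchar(sequence)))
        sch <- strsplit(toupper(sequence), "")[[1]]
        if (any(aa != sch & sch != "X"))
            warning("PSSM residue letters differ from the sequence")
    }
    new("SequenceProfile", freq = freq, logOdds = logOdds,
        background = unname(background))
}

#' One-hot pseudo-profile from a bare sequence
#'
#' Missing-profile fallback: each row puts all mass on the residue's own
#' letter (\code{X} rows are the background distribution).
#'
#' @param sequence amino-acid string.
#' @param background background distribution.
#' @return a \linkS4class{SequenceProfile} without a log-odds view.
#' @export
onehotProfile <- function(sequence, background = aaBackground()) {
    ch <- strsplit(toupper(sequence), "")[[1]]
    freq <- matrix(0, length(ch), 20L,
                   dimnames = list(NULL, .PSSM_AA))
    for (i in seq_along(ch)) {
        if (ch[i] %in% .PSSM_AA) freq[i, ch[i]] <- 1
        else freq[i, ] <- background
    }
    new("SequenceProfile", freq = freq,
        logOdds = matrix(0, 0L, 0L), background = unname(background))
}

#' Per-position sequence conservation
#'
#' Relative entropy (bits) of the profile column against the background:
#' \code{sum_a p_i(a) log2(p_i(a) / q(a))}, with \code{0 log 0 = 0}.
#' Zero iff the column equals the background.
#'
#' @param profile a \linkS4class{SequenceProfile}.
#' @return non-negative numeric vector, one value per position.
#' @export
sequenceConservation <- function(profile) {
    p <- profile@freq
    q <- matrix(profile@background, nrow(p), 20L, byrow = TRUE)
    term <- p * log2(p / q)
    term[p == 0] <- 0
    rowSums(term)
}
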