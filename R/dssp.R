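#' Parse a classic DSSP output file
#'
#' Reads the fixed-width residue records of DSSP text output (the
#' \code{"  #  RESIDUE AA STRUCTURE ..."} layout): residue letter, 8-state
#' secondary-structure code and absolute accessible surface area.
#' Chain-break rows (\code{'!'} in the AA column) are recorded as breaks,
#' not residues.  Lowercase letters (disulfide-bridge cysteines) are
#' mapped to \code{C}; letters outside the 20-letter alphabet are mapped
#' to \code{X} with a warning.
#'
#' @param path DSSP output file.
#' @return list with \code{residues} (data.frame: \code{aa}, \code{ss8},
#'   \code{asa}, \code{chain}) and \code{breaks} (integer vector: a value
#'   b means a chain break falls between residues b and b+1).
#' @export
parseDSSP <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^  #  RESIDUE", lines)
    if (!length(hdr))
        stop("malformed DSSP file (no '  #  RESIDUE' header): ", path)
    body <- lines[(hdr[1] + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    aa <- substr(body, 14L, 14L)
    isBreak <- aa == "!"
    breaks <- integer(0)
    count <- cumsum(!isBreak)
    if (any(isBreak)) breaks <- count[isBreak]
    body <- body[!isBreak]
    aa <- aa[!isBreak]
    lower <- aa %in% letters
    aa[lower] <- "C"
    bad <- !aa %in% c(.AA20, "X")
    if (any(bad)) {
        warning("unknown residue letter(s) mapped to X: ",
                paste(unique(aa[bad]), collapse = ", "))
        aa[bad] <- "X"
    }
    asa <- suppressWarnings(as.numeric(substr(body, 35L, 38L)))
    if (anyNA(asa))
        stop("malformed DSSP accessibility field in: ", path)
    list(residues = data.frame(aa = aa,
                               ss8 = substr(body, 17L, 17L),
                               asa = asa,
                               chain = substr(body, 12L, 12L),
                               stringsAsFactors = FALSE),
         breaks = breaks)
}

#' Per-residue maximum accessible surface area table
#'
#' Ships the Tien et al. (2013) theoretical maximum ASA values as a
#' plain-text data file; other tables can be supplied as a named numeric
#' vector wherever a table argument is accepted.
#'
#' @param name table name (currently \code{"tien2013"}).
#' @return named numeric vector (square Angstrom) over the 20 residues.
#' @export
maxASATable <- function(name = "tien2013") {
    path <- system.file("extdata", paste0("max_asa_", name, ".tsv"),
                        package = "burialCRF", mustWork = TRUE)
    df <- read.table(path, header = TRUE,
                     colClasses = c("character", "numeric"))
    stats::setNames(df$max_asa, df$residue)
}

#' Relative solvent accessibility from absolute ASA
#'
#' \code{rsa[i] = asa[i] / maxAsa[type_i]}.  Values above 1 are retained
#' unless \code{clip = TRUE}.  Residue type \code{X} uses the mean of the
#' table.
#'
#' @param asa numeric vector of absolute ASA values (square Angstrom).
#' @param residues residue letters (character vector or single string).
#' @param table named max-ASA vector (default the shipped Tien table).
#' @param clip clip RSA at 1.
#' @return an \linkS4class{RSAProfile}.
#' @export
computeRSA <- function(asa, residues, table = maxASATable(),
                       clip = FALSE) {
    if (length(residues) == 1L && nchar(residues) > 1L)
        residues <- strsplit(residues, "")[[1]]
    if (length(asa) != length(residues))
        stop("asa and residues must have equal length")
    if (any(asa < 0)) stop("negative ASA value")
    table <- c(table, X = mean(table))
    if (any(!residues %in% names(table)))
        stop("residue type without a max-ASA entry: ",
             paste(setdiff(residues, names(table)), collapse = ", "))
    ma <- unname(table[residues])
    r <- asa / ma
    if (clip) r <- pmin(r, 1)
    new("RSAProfile", asa = as.numeric(asa), maxAsa = ma, rsa = r)
}

#' Binarize RSA into burial labels
#'
#' The exposure threshold is read as the minimum exposure: residues with
#' \code{rsa < threshold} are buried (1), residues with \code{rsa >=
#' threshold} -- including exactly the threshold -- are exposed (0).
#'
#' @param x an \linkS4class{RSAProfile} or a numeric RSA vector.
#' @param threshold exposure threshold in (0, 1); default 0.25.
#' @return integer 0/1 label vector (buried = 1).
#' @export
binarizeRSA <- function(x, threshold = 0.25) {
    if (is(x, "RSAProfile")) x <- rsa(x)
    stopifnot(threshold > 0, threshold < 1)
    as.integer(x < threshold)
}

#' Derive sequences, secondary structure and burial labels from DSSP
#'
#' Convenience wrapper: parses a DSSP file, computes RSA and binary
#' labels, reduces the secondary structure to 3 states, and splits the
#' chain at chain breaks (each part can be used for prediction; chains
#' with breaks are conventionally excluded from training).
#'
#' @param path DSSP output file.
#' @param threshold exposure threshold passed to
#'   \code{\link{binarizeRSA}}.
#' @param table max-ASA table for \code{\link{computeRSA}}.
#' @return list with \code{parts} (each: \code{sequence}, \code{ss},
#'   \code{labels}, \code{rsa}) and \code{hasBreaks}.
#' @export
dsspLabels <- function(path, threshold = 0.25, table = maxASATable()) {
    p <- parseDSSP(path)
    prof <- computeRSA(p$residues$asa, p$residues$aa, table)
    labels <- binarizeRSA(prof, threshold)
    ss3 <- map8to3(paste(p$residues$ss8, collapse = ""))
    n <- nrow(p$residues)
    bounds <- sort(unique(c(0L, p$breaks, n)))
    parts <- lapply(seq_len(length(bounds) - 1L), function(k) {
        idx <- (bounds[k] + 1L):bounds[k + 1L]
        list(sequence = paste(p$residues$aa[idx], collapse = ""),
             ss = substr(ss3, idx[1], idx[length(idx)]),
             labels = labels[idx], rsa = rsa(prof)[idx])
    })
    list(parts = parts, hasBreaks = length(p$breaks) > 0L)
}
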