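# Plain-text readers/writers for the pipeline's external formats.
# Sequences go through Biostrings; tables are headered TSV with 1-based
# positions, the convention used by DSSP/PDB-facing tools.

.writeTSV <- function(df, path) {
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid strings.
#' @export
readFastaSequences <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(x), names(x))
}

#' Write record sequences as FASTA
#'
#' @param records list of \linkS4class{ProteinRecord}s (or a named
#'   character vector of sequences).
#' @param path output file.
#' @export
writeFasta <- function(records, path) {
    if (is.list(records)) {
        seqs <- vapply(records, function(r) r@sequence, "")
        names(seqs) <- vapply(records, chainId, "")
    } else seqs <- records
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
    invisible(path)
}

#' Read/write burial labels as two-column TSV
#'
#' Columns: 1-based \code{position} and 0/1 \code{label} (buried = 1).
#'
#' @param labels integer 0/1 vector.
#' @param path file path.
#' @return \code{readLabelsTSV} returns the integer label vector.
#' @export
writeLabelsTSV <- function(labels, path) {
    write.table(data.frame(position = seq_along(labels),
                           label = as.integer(labels)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLabelsTSV
#' @export
readLabelsTSV <- function(path) {
    df <- read.table(path, header = TRUE)
    if (!all(c("position", "label") %in% names(df)))
        stop("label TSV must have columns position, label")
    df <- df[order(df$position), ]
    as.integer(df$label)
}

#' Write a prediction table
#'
#' The standard per-residue output: 1-based position, residue, secondary
#' structure, marginal probabilities of both states, decoded label.
#'
#' @param pred data.frame from \code{\link{predictBurial}}.
#' @param path output TSV.
#' @export
writePredictionTSV <- function(pred, path) {
    .writeTSV(pred, path)
}

#' Read per-residue auxiliary feature columns
#'
#' Headered TSV whose first column is the 1-based position; remaining
#' numeric columns are returned as a matrix (used for precomputed
#' features such as disorder or binding-site probabilities, secondary
#' structure probabilities or contact numbers).
#'
#' @param path TSV file.
#' @param length expected number of residues (checked when given).
#' @return numeric matrix with the file's column names.
#' @export
readResidueTSV <- function(path, length = NULL) {
    df <- read.table(path, header = TRUE)
    df <- df[order(df[[1L]]), , drop = FALSE]
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.null(length) && nrow(m) != length)
        stop(sprintf("%s has %d rows, expected %d", path, nrow(m), length))
    m
}
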