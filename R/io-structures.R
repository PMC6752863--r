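#' Read and write dot-bracket structure files
#'
#' Vienna dialect: one structure per line. Lines starting with `>` (FASTA
#' style headers) and lines consisting of sequence characters are skipped on
#' read, so `RNAsubopt`-style output files can be read directly.
#'
#' @param path File path.
#' @return `readDotBracketFile`: character vector of dot-bracket strings.
#' @examples
#' f <- tempfile()
#' writeDotBracketFile(c("(((...)))", "........."), f)
#' readDotBracketFile(f)
#' @export
readDotBracketFile <- function(path) {
    lines <- readLines(path)
    # strip trailing free-energy annotations like "(((...))) -3.00"
    lines <- sub("\\s.*$", "", lines)
    db <- grep("^[.()]+$", lines, value = TRUE)
    if (!length(db)) stop("no dot-bracket lines found in ", path)
    invisible(lapply(db, parseDotBracket))  # validate nesting
    db
}

#' @param db Character vector of dot-bracket strings.
#' @rdname readDotBracketFile
#' @export
writeDotBracketFile <- function(db, path) {
    invisible(lapply(db, parseDotBracket))
    writeLines(db, path)
    invisible(path)
}
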