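#' Canonicalize an RNA sequence
#'
#' Uppercases, maps DNA-style \code{T} to \code{U}, and validates that every
#' residue is one of \code{A}, \code{C}, \code{G}, \code{U}.
#'
#' @param x Character vector of sequences (or a `Biostrings::XStringSet`,
#'   which is coerced via `as.character`).
#' @return Character vector of canonical RNA sequences.
#' @examples
#' canonicalizeRna("acgt")  # "ACGU"
#' @export
canonicalizeRna <- function(x) {
    if (!is.character(x)) x <- as.character(x)
    if (length(x) == 0L) stop("no sequences supplied")
    out <- chartr("acgutT", "ACGUUU", x)
    bad <- grepl("[^ACGU]", out)
    if (any(bad)) {
        stop("invalid residue(s) in sequence ", which(bad)[1L],
             ": only A/C/G/U (or T) are allowed")
    }
    if (any(!nzchar(out))) stop("empty sequence not allowed")
    out
}

# A=0, C=1, G=2, U=3 (0-based, for the C++ sampler)
.seqToInts <- function(seq) {
    match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "U")) - 1L
}

#' Read RNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] with canonicalization
#' (T is mapped to U, case is normalized).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of canonical RNA sequences.
#' @export
readRnaFasta <- function(path) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- canonicalizeRna(as.character(ss))
    names(seqs) <- names(ss)
    seqs
}
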