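#' k-mer vocabulary
#'
#' The 4^k k-mers over A, C, G, U in lexicographic order, plus one reserved
#' padding id for k-mers that overhang the 3' end of the sequence. Ids are
#' 1-based: k-mer ids run 1..4^k and the padding id is 4^k + 1. The
#' lexicographic order is part of the on-disk model contract, so saved models
#' are portable.
#'
#' @param k k-mer length (nt).
#' @return List with elements `k`, `size` (4^k), `padId` (4^k + 1), and
#'   `kmers` (the lexicographic k-mer strings).
#' @examples
#' kmerVocabulary(1)$kmers  # "A" "C" "G" "U"
#' @export
kmerVocabulary <- function(k) {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    alph <- c("A", "C", "G", "U")
    grid <- do.call(expand.grid,
                    c(rep(list(alph), k), list(stringsAsFactors = FALSE)))
    # expand.grid varies the first factor fastest; lexicographic order needs
    # the last character fastest, so feed columns reversed
    kmers <- do.call(paste0, rev(grid))
    kmers <- sort(kmers, method = "radix")
    list(k = k, size = as.integer(4^k), padId = as.integer(4^k + 1),
         kmers = kmers)
}

#' Extract positional k-mer ids from a sequence
#'
#' Position i receives the vocabulary id of the k-mer starting at i; positions
#' whose k-mer would overhang the sequence end receive the padding id. The
#' output always has one id per sequence position.
#'
#' @param seq RNA sequence (character scalar).
#' @param k k-mer length.
#' @return Integer vector of length `nchar(seq)` with values in
#'   `1..4^k + 1` (`4^k + 1` = padding).
#' @examples
#' extractKmerIds("ACGU", 2)  # ids of AC, CG, GU, then the pad id
#' @export
extractKmerIds <- function(seq, k) {
    seq <- canonicalizeRna(seq)
    k <- as.integer(k)
    l <- nchar(seq)
    s <- .seqToInts(seq)  # 0..3, lexicographic base-4 digits
    padId <- as.integer(4^k + 1)
    ids <- rep(padId, l)
    if (k <= l) {
        nfull <- l - k + 1L
        # base-4 value of s[i..i+k-1], first character most significant
        v <- integer(nfull)
        for (off in 0:(k - 1L)) {
            v <- v * 4L + s[(1L + off):(nfull + off)]
        }
        ids[seq_len(nfull)] <- v + 1L
    }
    ids
}

#' Create an embedding table for one k-mer length
#'
#' A `(4^k + 1) x d` matrix of learnable weights; row `4^k + 1` is the
#' padding row, frozen at zero (it receives no gradient updates). Non-pad
#' rows are Xavier-initialized by default.
#'
#' @param k k-mer length.
#' @param d Embedding dimension.
#' @param init `"xavier"` (uniform on ±sqrt(6/(4^k + d))) or `"zero"`.
#' @return Numeric matrix of weights.
#' @export
newEmbeddingTable <- function(k, d, init = c("xavier", "zero")) {
    init <- match.arg(init)
    rows <- 4L^k + 1L
    w <- matrix(0, rows, d)
    if (init == "xavier") {
        lim <- sqrt(6 / (4^k + d))
        w[seq_len(rows - 1L), ] <- runif((rows - 1L) * d, -lim, lim)
    }
    w
}

#' Look up embeddings for a vector of k-mer ids
#'
#' @param ids Integer ids from [extractKmerIds()].
#' @param table Embedding table from [newEmbeddingTable()].
#' @return `length(ids) x d` matrix; padding ids map to zero rows.
#' @export
embedIds <- function(ids, table) {
    if (any(ids < 1L | ids > nrow(table)))
        stop("k-mer id out of range for this embedding table")
    table[ids, , drop = FALSE]
}

#' Build the stacked multi-length k-mer sequence representation
#'
#' Horizontally concatenates the per-k embedded sequences for k = 1..k_m,
#' giving the `l x k_m*d` sequence representation matrix E. Column block k
#' holds the embeddings of the k-mers starting at each position.
#'
#' @param seq RNA sequence.
#' @param tables List of embedding tables, element k for k-mer length k; all
#'   must share the embedding dimension d.
#' @return `l x (k_m * d)` numeric matrix.
#' @export
buildSequenceRepresentation <- function(seq, tables) {
    d <- unique(vapply(tables, ncol, 1L))
    if (length(d) != 1L)
        stop("embedding tables disagree on dimension d: ",
             paste(vapply(tables, ncol, 1L), collapse = ", "))
    blocks <- lapply(seq_along(tables), function(k)
        embedIds(extractKmerIds(seq, k), tables[[k]]))
    do.call(cbind, blocks)
}

#' One-hot encode an RNA sequence
#'
#' @param seq RNA sequence.
#' @return `l x 4` 0/1 matrix with columns `A, C, G, U`.
#' @examples
#' oneHotSequence("ACGU")
#' @export
oneHotSequence <- function(seq) {
    seq <- canonicalizeRna(seq)
    s <- .seqToInts(seq) + 1L
    m <- matrix(0, length(s), 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
    m[cbind(seq_along(s), s)] <- 1
    m
}
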