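#' @title Tally of a sampled structure ensemble
#'
#' @description Collapses the N sampled structures of one RNA to its U unique
#' structures with descending frequencies m_1 >= ... >= m_U. Ties in
#' frequency are ordered lexicographically by dot-bracket string so that the
#' selection of the top-T high-probability structures is deterministic.
#'
#' @slot structures Character vector of U unique dot-bracket strings.
#' @slot counts Integer vector of U frequencies, summing to `nsamples`.
#' @slot nsamples Total number of samples N.
#' @name EnsembleTally-class
#' @rdname EnsembleTally
#' @exportClass EnsembleTally
setClass("EnsembleTally",
    representation(structures = "character", counts = "integer",
                   nsamples = "integer"),
    validity = function(object) {
        msg <- character(0)
        if (length(object@structures) != length(object@counts))
            msg <- c(msg, "structures and counts differ in length")
        if (sum(object@counts) != object@nsamples)
            msg <- c(msg, "counts must sum to nsamples")
        if (length(unique(nchar(object@structures))) > 1L)
            msg <- c(msg, "structures must share one length")
        if (is.unsorted(rev(object@counts)))
            msg <- c(msg, "counts must be non-increasing")
        if (anyDuplicated(object@structures))
            msg <- c(msg, "structures must be unique")
        if (length(msg)) msg else TRUE
    })

#' @describeIn EnsembleTally Unique dot-bracket structures, most frequent first.
#' @param object,x An `EnsembleTally`.
#' @export
uniqueStructures <- function(x) x@structures

#' @describeIn EnsembleTally Frequencies m_i (descending).
#' @export
structureCounts <- function(x) x@counts

#' @describeIn EnsembleTally Total sample count N.
#' @export
sampleSize <- function(x) x@nsamples

#' @describeIn EnsembleTally Number of unique structures U.
#' @export
nUnique <- function(x) length(x@structures)

setMethod("show", "EnsembleTally", function(object) {
    cat(sprintf("EnsembleTally: N=%d samples, U=%d unique, l=%d nt\n",
                object@nsamples, nUnique(object),
                if (nUnique(object)) nchar(object@structures[1L]) else 0L))
    k <- min(5L, nUnique(object))
    for (i in seq_len(k))
        cat(sprintf("  m_%d=%3d  %s\n", i, object@counts[i],
                    object@structures[i]))
    if (nUnique(object) > k) cat("  ...\n")
})

#' Tally unique structures of a sample
#'
#' @param samples Character vector of dot-bracket strings of equal length.
#' @return An [EnsembleTally-class], sorted by descending frequency with
#'   lexicographic tie-break; invariant under permutation of the input.
#' @examples
#' tallyUnique(c("....", "....", "(..)"))
#' @export
tallyUnique <- function(samples) {
    if (!length(samples)) stop("empty sample list")
    if (length(unique(nchar(samples))) > 1L)
        stop("sampled structures have mixed lengths")
    tab <- table(samples)
    structures <- names(tab)
    counts <- as.integer(tab)
    # descending count; ties broken by dot-bracket string (C collation)
    o <- order(-counts, structures, method = "radix")
    new("EnsembleTally", structures = structures[o], counts = counts[o],
        nsamples = length(samples))
}

#' Full inside partition-function matrix under the bundled energy model
#'
#' Z(i, j) sums the Boltzmann factors exp(-E/kT) of all nested structures of
#' the subsequence i..j; `Z[1, l]` is the partition function of the whole
#' sequence.
#'
#' @param seq RNA sequence.
#' @param em An [EnergyModel-class].
#' @return `l x l` numeric matrix (1-based; entries below the diagonal are
#'   unused).
#' @export
partitionMatrix <- function(seq, em = energyModel()) {
    seq <- canonicalizeRna(seq)
    .partitionMatrixCpp(.seqToInts(seq), .energyMatrix(em), em@kT,
                        em@minHairpin)
}

#' Sample a Boltzmann ensemble of secondary structures
#'
#' Draws `n` structures (with replacement, i.e. repeats are expected and
#' meaningful) from the Boltzmann distribution of the sequence. The bundled
#' engine computes the inside partition function under a simple pair-energy
#' model and samples by stochastic traceback, exactly and reproducibly. The
#' external engine shells out to an RNAsubopt-compatible executable
#' (`RNAsubopt -p n`), which uses the full nearest-neighbor energy model of
#' the ViennaRNA package.
#'
#' @param seq RNA sequence (character scalar).
#' @param n Number of samples (default 100).
#' @param engine `"bundled"` or `"external"`.
#' @param em Energy model for the bundled engine.
#' @param seed Integer seed for the bundled engine; if `NULL`, one is drawn
#'   from the R random stream (so `set.seed()` governs it).
#' @param path Executable for the external engine (default `"RNAsubopt"`).
#' @param args Extra command-line arguments passed through to the external
#'   executable (e.g. temperature flags).
#' @return Character vector of `n` dot-bracket strings of length `nchar(seq)`.
#' @examples
#' sampleEnsemble("GGGAAACCC", n = 10, seed = 1)
#' @export
sampleEnsemble <- function(seq, n = 100L, engine = c("bundled", "external"),
                           em = energyModel(), seed = NULL,
                           path = "RNAsubopt", args = character(0)) {
    engine <- match.arg(engine)
    seq <- canonicalizeRna(seq)
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1")
    if (engine == "bundled") {
        if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
        return(.sampleStructuresCpp(.seqToInts(seq), .energyMatrix(em),
                                    em@kT, em@minHairpin, n, as.double(seed)))
    }
    if (!nzchar(Sys.which(path)))
        stop("external sampler executable '", path, "' not found; ",
             "use engine = \"bundled\" for the self-contained sampler")
    out <- tryCatch(
        suppressWarnings(system2(path, args = c("-p", n, args),
                                 input = seq, stdout = TRUE, stderr = FALSE)),
        error = function(e) character(0))
    db <- grep(sprintf("^[.()]{%d}$", nchar(seq)), out, value = TRUE)
    if (length(db) < n)
        stop("external sampler '", path, "' returned ", length(db),
             " structures instead of ", n,
             "; check the executable or use engine = \"bundled\"")
    db[seq_len(n)]
}

#' Average structure profile of the low-frequency remainder
#'
#' Frequency-weighted mean of the one-hot context matrices of the unique
#' structures ranked below the top `T`:
#' \deqn{R_{T+1} = \sum_{i=T+1}^{U} \frac{m_i}{\sum_{j=T+1}^{U} m_j} R_i}
#' Each row is a convex combination of one-hot rows, hence sums to 1.
#'
#' @param tally An [EnsembleTally-class].
#' @param T Number of top-ranked structures to exclude (default 5). `T = 0`
#'   averages over the whole ensemble.
#' @return An `l x 5` row-stochastic matrix with columns `P,H,I,M,E`, or
#'   `NULL` when `U <= T` (empty remainder; its combination weight is then
#'   exactly zero).
#' @export
averageProfile <- function(tally, T = 5L) {
    stopifnot(is(tally, "EnsembleTally"))
    U <- nUnique(tally)
    if (U <= T) return(NULL)
    idx <- (T + 1L):U
    m <- tally@counts[idx]
    w <- m / sum(m)
    l <- nchar(tally@structures[1L])
    R <- matrix(0, l, 5L, dimnames = list(NULL, c("P", "H", "I", "M", "E")))
    ctxs <- annotateContexts(tally@structures[idx])
    for (a in seq_along(idx)) {
        R <- R + w[a] * structureOneHot(ctxs[a])
    }
    R
}

# One-hot context matrices of the top min(T, U) structures, as a list.
.topStructureMatrices <- function(tally, T) {
    k <- min(T, nUnique(tally))
    lapply(seq_len(k), function(i)
        structureOneHot(annotateContexts(tally@structures[i])))
}
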