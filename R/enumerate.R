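#' Exhaustively enumerate all nested secondary structures
#'
#' Lists every properly nested structure of a short RNA under the bundled
#' pair-energy model (pairable combinations and the minimum-hairpin
#' constraint), together with its energy (the sum of its pair energies).
#' Intended as an exact reference for the partition function and sampler on
#' small sequences; the number of structures grows exponentially, so the
#' length is capped.
#'
#' @param seq RNA sequence (character scalar).
#' @param em An [EnergyModel-class]; defaults to [energyModel()].
#' @param maxLen Refuse sequences longer than this (default 16).
#' @return A `data.frame` with columns `structure` (dot-bracket) and
#'   `energy`, one row per structure, each structure exactly once.
#' @examples
#' enumerateStructures("GAAAC")
#' @export
enumerateStructures <- function(seq, em = energyModel(), maxLen = 16L) {
    seq <- canonicalizeRna(seq)
    n <- nchar(seq)
    if (n > maxLen)
        stop("sequence length ", n, " exceeds enumeration cap ", maxLen)
    s <- .seqToInts(seq) + 1L
    emat <- .energyMatrix(em)
    m <- em@minHairpin
    memo <- new.env(parent = emptyenv())

    rec <- function(i, j) {
        if (j < i) return(list(structure = "", energy = 0))
        key <- paste0(i, "_", j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        # branch on the status of position j: unpaired, or paired to some k
        sub <- rec(i, j - 1L)
        structs <- paste0(sub$structure, ".")
        energies <- sub$energy
        for (k in i:j) {
            if (k > j - m - 1L) break
            e <- emat[s[k], s[j]]
            if (e == 0) next
            left <- rec(i, k - 1L)
            inner <- rec(k + 1L, j - 1L)
            combo <- expand.grid(L = seq_along(left$structure),
                                 I = seq_along(inner$structure))
            structs <- c(structs, paste0(left$structure[combo$L], "(",
                                         inner$structure[combo$I], ")"))
            energies <- c(energies,
                          left$energy[combo$L] + inner$energy[combo$I] + e)
        }
        res <- list(structure = structs, energy = energies)
        memo[[key]] <- res
        res
    }

    out <- rec(1L, n)
    data.frame(structure = out$structure, energy = out$energy,
               stringsAsFactors = FALSE)
}

#' Boltzmann distribution over all structures of a short RNA
#'
#' @inheritParams enumerateStructures
#' @return `data.frame` with columns `structure`, `energy`, `probability`;
#'   probabilities are exp(-E/kT) normalized by the total.
#' @export
boltzmannDistribution <- function(seq, em = energyModel(), maxLen = 16L) {
    d <- enumerateStructures(seq, em, maxLen)
    w <- exp(-d$energy / em@kT)
    d$probability <- w / sum(w)
    d
}
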