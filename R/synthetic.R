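#' Define a planted-signal synthetic binding task
#'
#' Desk-scale stand-in for RNAcompete-style (41 nt) and CLIP-seq-style
#' (101 nt) binding data. Sequences are uniform random RNA; a motif is
#' planted at a random position in half the records. The target is either a
#' pure sequence signal (`sequence_only`: effect size times motif presence
#' plus Gaussian noise) or a structure-dependent signal (`hairpin_context`:
#' effect size times the probability that the motif sits entirely in a
#' hairpin loop, measured over the bundled sampler's Boltzmann ensemble,
#' plus noise).
#'
#' @param motif Planted motif. The default 6-mer `CAACAA` cannot form a base
#'   pair with itself under the minimum-hairpin rule, so its hairpin-loop
#'   probability spans the full dynamic range; self-pairing motifs (e.g. the
#'   FOX-family `UGCAUG`, whose U1/G6 wobble pair competes with the clean
#'   loop) cap `p_H` well below 1 and weaken the planted structure signal.
#' @param effectSize Signal amplitude a (default 2).
#' @param noiseSd Gaussian noise standard deviation (default 0.3).
#' @param mode `"sequence_only"` or `"hairpin_context"`.
#' @param n Number of records (default 2000).
#' @param l Sequence length in nt (default 41; use 101 for CLIP-seq-like
#'   geometry).
#' @param seed Integer seed.
#' @return Validated list of class `PlantedTask`.
#' @export
plantedTask <- function(motif = "CAACAA", effectSize = 2, noiseSd = 0.3,
                        mode = c("sequence_only", "hairpin_context"),
                        n = 2000L, l = 41L, seed = 1L) {
    mode <- match.arg(mode)
    motif <- canonicalizeRna(motif)
    stopifnot(nchar(motif) < l, noiseSd >= 0, n >= 2)
    structure(list(motif = motif, effectSize = effectSize,
                   noiseSd = noiseSd, mode = mode, n = as.integer(n),
                   l = as.integer(l), seed = as.integer(seed)),
              class = "PlantedTask")
}

# Embed a motif as the loop of a stem-loop of given stem length (0 = bare
# motif), random stem composition and imperfect complementarity (each
# closing-arm base is mutated with probability `mismatchProb`, so stem
# stability cannot be read off base composition alone), A/U flanks, and a
# random flank split (hence a random motif position).
.plantStemLoop <- function(motif, stemLen, l, mismatchProb = 0.2) {
    mlen <- nchar(motif)
    nflank <- l - 2L * stemLen - mlen
    nL <- sample.int(nflank + 1L, 1L) - 1L
    nR <- nflank - nL
    stem <- if (stemLen) sample(c("A", "C", "G", "U"), stemLen, TRUE)
            else character(0)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    rc <- rev(unname(comp[stem]))
    if (stemLen) {
        for (i in seq_len(stemLen)) {
            if (runif(1) < mismatchProb)
                rc[i] <- sample(setdiff(c("A", "C", "G", "U"), rc[i]), 1L)
        }
    }
    fl <- function(k) if (k) paste(sample(c("A", "U"), k, TRUE),
                                   collapse = "") else ""
    list(seq = paste0(fl(nL), paste(stem, collapse = ""), motif,
                      paste(rc, collapse = ""), fl(nR)),
         motifStart = nL + stemLen + 1L)
}

# P(motif entirely in hairpin-loop context) under the sampled ensemble.
.hairpinContextProb <- function(seq, pos, motifLen, em, nsamples, seed) {
    sam <- sampleEnsemble(seq, n = nsamples, em = em, seed = seed)
    tal <- tallyUnique(sam)
    span <- pos:(pos + motifLen - 1L)
    ctxs <- annotateContexts(uniqueStructures(tal))
    inH <- vapply(ctxs, function(ctx) {
        all(strsplit(ctx, "", fixed = TRUE)[[1L]][span] == "H")
    }, TRUE, USE.NAMES = FALSE)
    sum(structureCounts(tal)[inH]) / sampleSize(tal)
}

#' Generate a synthetic intensity dataset with a planted signal
#'
#' Half the records carry the motif; the noiseless target is 0 for
#' motif-free records. In `sequence_only` mode all backgrounds are uniform
#' random RNA, the motif sits at a uniformly random position, and
#' motif-carrying records score `a * 1`. In `hairpin_context` mode
#' motif-carrying records embed the motif as the loop of a designed
#' stem-loop of randomly drawn stem length (0-12 bp), random composition
#' and imperfect complementarity (20% per-base mismatch in the closing
#' arm), with A/U flanks, so that the probability `p_H` of the motif lying
#' entirely in hairpin-loop context varies over a wide range without being
#' readable from base composition alone; the target is `a * p_H`,
#' with `p_H` measured over the record's sampled Boltzmann ensemble (uniform
#' backgrounds leave `p_H` degenerate at ~0 under the bundled energy model,
#' which would plant no learnable structure signal). Ground truth (motif
#' presence, position, `p_H`) is attached as `attr(, "truth")`.
#'
#' @param task A [plantedTask()].
#' @param em Energy model used both here (ground truth) and by default in
#'   the trained model, so tests need no external folding executable; the
#'   ground-truth ensembles use their own seeds, independent of any model
#'   run.
#' @param nsamples Ensemble size for the ground-truth `p_H` (default 100).
#' @return `data.frame` with columns `id`, `seq`, `intensity` and a
#'   `truth` attribute.
#' @export
generateDataset <- function(task, em = energyModel(), nsamples = 100L) {
    set.seed(task$seed)
    n <- task$n; l <- task$l
    mlen <- nchar(task$motif)
    alph <- c("A", "C", "G", "U")
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(alph, l, replace = TRUE), collapse = ""), "")
    present <- rep(c(TRUE, FALSE), length.out = n)
    present <- sample(present)
    position <- rep(NA_integer_, n)
    if (task$mode == "sequence_only") {
        position[present] <- sample.int(l - mlen + 1L, sum(present),
                                        replace = TRUE)
        for (i in which(present)) {
            substr(seqs[i], position[i], position[i] + mlen - 1L) <-
                task$motif
        }
    } else {
        maxStem <- min(12L, (l - mlen) %/% 2L)
        for (i in which(present)) {
            hp <- .plantStemLoop(task$motif, sample(0:maxStem, 1L), l)
            seqs[i] <- hp$seq
            position[i] <- hp$motifStart
        }
    }
    pH <- rep(NA_real_, n)
    signal <- numeric(n)
    if (task$mode == "sequence_only") {
        signal[present] <- task$effectSize
    } else {
        gtSeeds <- sample.int(.Machine$integer.max, n)
        for (i in which(present)) {
            pH[i] <- .hairpinContextProb(seqs[i], position[i], mlen, em,
                                         nsamples, gtSeeds[i])
        }
        signal[present] <- task$effectSize * pH[present]
    }
    y <- signal + rnorm(n, 0, task$noiseSd)
    out <- data.frame(id = sprintf("synth_%05d", seq_len(n)), seq = seqs,
                      intensity = y, stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(present = present, position = position,
                                     pH = pH, signal = signal)
    out
}

#' Generate a synthetic binary-label dataset (CLIP-seq-like)
#'
#' Same planted signals as [generateDataset()], binarized by a median split
#' of the continuous target, giving balanced classes (exactly n/2 positives
#' for even n).
#'
#' @inheritParams generateDataset
#' @return `data.frame` with columns `id`, `seq`, `label` (0/1) and the same
#'   `truth` attribute.
#' @export
generateBinaryDataset <- function(task, em = energyModel(),
                                  nsamples = 100L) {
    d <- generateDataset(task, em, nsamples)
    lab <- as.integer(d$intensity > median(d$intensity))
    out <- data.frame(id = d$id, seq = d$seq, label = lab,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- attr(d, "truth")
    out
}

#' Construct a GC-clamped hairpin placing a motif in its loop
#'
#' Builds `flank + stem + motif + reverse-complement(stem) + flank`, with a
#' random G/C stem, so that under the bundled energy model the motif sits in
#' a hairpin loop with high probability. Used to verify that the
#' hairpin-context signal responds to designed structure.
#'
#' @param motif Loop motif (also the hairpin loop itself).
#' @param stemLen Stem length in bp (default 8).
#' @param l Total sequence length; flanks are random A/U fill.
#' @return List with `seq` and `motifStart`.
#' @export
designHairpin <- function(motif, stemLen = 8L, l = 41L) {
    motif <- canonicalizeRna(motif)
    core <- 2L * stemLen + nchar(motif)
    if (core > l) stop("stem and motif do not fit in l = ", l)
    stem <- sample(c("G", "C"), stemLen, replace = TRUE)
    rc <- rev(ifelse(stem == "G", "C", "G"))
    nflank <- l - core
    nL <- nflank %/% 2L
    nR <- nflank - nL
    fl <- function(k) if (k) paste(sample(c("A", "U"), k, TRUE),
                                   collapse = "") else ""
    list(seq = paste0(fl(nL), paste(stem, collapse = ""), motif,
                      paste(rc, collapse = ""), fl(nR)),
         motifStart = nL + stemLen + 1L)
}
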