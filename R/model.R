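#' Network/ensemble configuration
#'
#' @param l Input sequence length in nt (41 for RNAcompete-style probes, 101
#'   for CLIP-seq-style windows). Shorter sequences are right-padded.
#' @param nLayers Number of stacked convolutional layers (default 5).
#' @param kernelWidth 1-D convolution kernel width (grid-searched over
#'   7, 12, 16 in the reference setting).
#' @param nKernels Kernels per layer (16 or 64).
#' @param d k-mer embedding dimension (10, 20 or 30).
#' @param km Maximum k-mer length, k = 1..km (2..5).
#' @param T Number of top-ranked high-probability structures given their own
#'   rank-specific network (default 5). `T = 0` collapses the model to a
#'   single network over the average structure profile.
#' @param N Ensemble sample count per sequence (default 100).
#' @param useStructure When `FALSE`, the five structure input columns are
#'   zeroed (sequence-only ablation variant).
#' @return Validated list of class `NetworkConfig`.
#' @export
networkConfig <- function(l, nLayers = 5L, kernelWidth = 7L, nKernels = 16L,
                          d = 10L, km = 3L, T = 5L, N = 100L,
                          useStructure = TRUE) {
    stopifnot(l >= 1, nLayers >= 1, kernelWidth >= 1, nKernels >= 1,
              d >= 1, km >= 1, T >= 0, N >= 1)
    structure(list(l = as.integer(l), nLayers = as.integer(nLayers),
                   kernelWidth = as.integer(kernelWidth),
                   nKernels = as.integer(nKernels), d = as.integer(d),
                   km = as.integer(km), T = as.integer(T), N = as.integer(N),
                   useStructure = isTRUE(useStructure)),
              class = "NetworkConfig")
}

#' @title Trained thermodynamic ensemble model
#'
#' @description Holds the T rank-specific base networks plus the
#' average-profile network, the configuration, and the sampler settings used
#' to build structure ensembles at prediction time. Networks that received no
#' training data (e.g. a rank never reached because every training RNA had
#' fewer unique structures) are `NULL` and contribute weight 0.
#'
#' @slot networks List of length `T + 1`; element i is the rank-i
#'   `BaseNetwork`, the last element is the average-profile network.
#' @slot config The [networkConfig()] list.
#' @slot trainCfg The [trainConfig()] list.
#' @slot sampler List: `engine`, energy-model parameters, `N`.
#' @slot trainLog Per-network, per-epoch training records.
#' @name ThermoNetModel-class
#' @rdname ThermoNetModel
#' @exportClass ThermoNetModel
setClass("ThermoNetModel",
    representation(networks = "list", config = "list", trainCfg = "list",
                   sampler = "list", trainLog = "data.frame"),
    validity = function(object) {
        if (length(object@networks) != object@config$T + 1L)
            return("networks list must have length T + 1")
        TRUE
    })

setMethod("show", "ThermoNetModel", function(object) {
    cfg <- object@config
    ntrained <- sum(!vapply(object@networks, is.null, TRUE))
    cat(sprintf(paste0("ThermoNetModel: T=%d rank networks + average-profile",
                       " network (%d trained)\n"), cfg$T, ntrained))
    cat(sprintf("  l=%d nt, k_m=%d, d=%d, %d conv layers x %d kernels (width %d)\n",
                cfg$l, cfg$km, cfg$d, cfg$nLayers, cfg$nKernels,
                cfg$kernelWidth))
    cat(sprintf("  ensemble: N=%d samples, engine=%s\n", cfg$N,
                object@sampler$engine))
})

# Sample, tally and annotate the structure ensemble of each sequence once;
# reused across the T+1 networks. Returns per sequence: the tally, the top
# min(T, U) one-hot matrices, and the average profile of the remainder.
.prepareStructures <- function(seqs, config, em, engine, samples = NULL) {
    lapply(seq_along(seqs), function(i) {
        s <- seqs[[i]]
        if (is.null(samples)) {
            sam <- sampleEnsemble(s, n = config$N, engine = engine, em = em)
        } else {
            sam <- samples[[i]]
        }
        tally <- tallyUnique(sam)
        list(tally = tally,
             Rtop = .topStructureMatrices(tally, config$T),
             Ravg = averageProfile(tally, config$T))
    })
}

.getY <- function(data) {
    for (nm in c("y", "intensity", "label")) {
        if (nm %in% names(data)) return(as.numeric(data[[nm]]))
    }
    stop("data must have a 'y', 'intensity' or 'label' column")
}

#' Train the full thermodynamic ensemble model
#'
#' Samples the structure ensemble of every training RNA once, tallies its
#' unique structures, and trains the T rank-specific networks plus the
#' average-profile network individually: the rank-i network sees exactly the
#' sequences whose ensemble has at least i unique structures (the sequences
#' whose rank-i combination weight m_i/N is positive), and the
#' average-profile network sees the sequences with a non-empty remainder
#' (U > T). Each network owns its own embedding tables.
#'
#' @param data `data.frame` with columns `seq` and `y` (or `intensity` /
#'   `label`).
#' @param config A [networkConfig()].
#' @param tc A [trainConfig()]; `tc$seed` drives all randomness.
#' @param em Energy model for the bundled sampler.
#' @param engine Structure sampling engine, `"bundled"` or `"external"`.
#' @param structures Optional pre-sampled structures: a list (one element per
#'   row of `data`) of character vectors of dot-bracket strings.
#' @return A [ThermoNetModel-class].
#' @export
trainThermoNet <- function(data, config, tc = trainConfig(),
                           em = energyModel(), engine = "bundled",
                           structures = NULL) {
    seqs <- canonicalizeRna(as.character(data$seq))
    y <- .getY(data)
    n <- length(seqs)
    if (any(nchar(seqs) > config$l))
        stop("sequence longer than config$l = ", config$l)
    set.seed(tc$seed)
    prep <- .prepareStructures(seqs, config, em, engine, samples = structures)
    U <- vapply(prep, function(p) nUnique(p$tally), 1L)
    ids <- .makeIdMatrices(seqs, config$km, config$l)
    # one shared validation split for early stopping across all networks
    valIdx <- integer(0)
    if (tc$valFraction > 0)
        valIdx <- sample.int(n, max(2L, floor(tc$valFraction * n)))
    isVal <- seq_len(n) %in% valIdx

    trainOne <- function(elig, Rfor) {
        trIdx <- which(elig & !isVal)
        vaIdx <- which(elig & isVal)
        if (!length(trIdx)) return(NULL)
        Rtr <- .stackStructureRows(lapply(trIdx, Rfor), config$l)
        btr <- list(ids = lapply(ids, function(m) m[trIdx, , drop = FALSE]),
                    R = Rtr)
        vb <- NULL; vy <- NULL
        if (length(vaIdx) >= 2L) {
            vb <- list(ids = lapply(ids, function(m) m[vaIdx, , drop = FALSE]),
                       R = .stackStructureRows(lapply(vaIdx, Rfor), config$l))
            vy <- y[vaIdx]
        }
        net <- initBaseNetwork(list(l = config$l, km = config$km,
                                    d = config$d,
                                    nKernels = config$nKernels,
                                    kernelWidth = config$kernelWidth,
                                    nLayers = config$nLayers,
                                    useStructure = config$useStructure))
        trainBaseNetwork(net, btr, y[trIdx], tc, vb, vy)
    }

    networks <- vector("list", config$T + 1L)
    logs <- list()
    for (i in seq_len(config$T)) {
        networks[i] <- list(trainOne(U >= i, function(j) prep[[j]]$Rtop[[i]]))
        if (!is.null(networks[[i]])) {
            lg <- networks[[i]]$log
            lg$network <- paste0("rank", i)
            logs[[length(logs) + 1L]] <- lg
        }
    }
    networks[config$T + 1L] <-
        list(trainOne(U > config$T, function(j) prep[[j]]$Ravg))
    if (!is.null(networks[[config$T + 1L]])) {
        lg <- networks[[config$T + 1L]]$log
        lg$network <- "average"
        logs[[length(logs) + 1L]] <- lg
    }
    new("ThermoNetModel", networks = networks, config = unclass(config),
        trainCfg = unclass(tc),
        sampler = list(engine = engine,
                       pairEnergies = as.list(em@pairEnergies),
                       kT = em@kT, minHairpin = em@minHairpin,
                       N = config$N),
        trainLog = if (length(logs)) do.call(rbind, logs) else data.frame())
}

#' Combine structure-specific predictions by Boltzmann-frequency weights
#'
#' The final prediction for a sequence is the frequency-weighted average of
#' the rank-specific predictions plus the remainder-weighted average-profile
#' prediction:
#' \deqn{f(s) = \sum_{i=1}^{\min(T,U)} \frac{m_i}{N} f_i +
#'   \Big(1 - \sum_{i=1}^{\min(T,U)} \frac{m_i}{N}\Big) f_{avg}}
#' Weights are formed in integer arithmetic over N before division, so they
#' sum to 1 exactly; when `U <= T` the average-profile coefficient is exactly
#' 0 and `fAvg` is ignored.
#'
#' @param preds Numeric vector of rank-specific predictions f_1..f_T (only
#'   the first `min(T, U)` are used).
#' @param fAvg Average-profile prediction (may be `NA` when the remainder is
#'   empty).
#' @param tally The sequence's [EnsembleTally-class].
#' @param T Number of rank-specific networks.
#' @return The combined scalar prediction.
#' @examples
#' tal <- tallyUnique(c(rep("(((...)))", 5), rep(".........", 3),
#'                      rep("((.....))", 2)))
#' combinePredictions(c(1, 0.5), fAvg = 0, tally = tal, T = 2)  # 0.65
#' @export
combinePredictions <- function(preds, fAvg, tally, T = length(preds)) {
    stopifnot(is(tally, "EnsembleTally"))
    N <- sampleSize(tally)
    k <- min(T, nUnique(tally))
    mTop <- if (k > 0L) structureCounts(tally)[seq_len(k)] else integer(0)
    remN <- N - sum(mTop)
    out <- if (k > 0L) sum(mTop * preds[seq_len(k)]) / N else 0
    if (remN > 0L) out <- out + (remN / N) * fAvg
    out
}

#' Predict binding intensities with a trained ensemble model
#'
#' For each sequence: sample the structure ensemble, tally unique structures,
#' run each relevant base network on its assembled input (inference-mode
#' batch normalization), and combine the structure-specific predictions with
#' Boltzmann-frequency weights. If a needed network is untrained (`NULL`),
#' its weight is dropped and the remaining weights renormalized.
#'
#' @param model A [ThermoNetModel-class].
#' @param seqs Character vector of RNA sequences.
#' @param seed Integer seed for the structure sampler (fixing it makes
#'   prediction bit-reproducible).
#' @param structures Optional pre-sampled structures, as in
#'   [trainThermoNet()].
#' @return Numeric vector of predicted intensities.
#' @export
predictIntensity <- function(model, seqs, seed = NULL, structures = NULL) {
    seqs <- canonicalizeRna(seqs)
    config <- model@config
    if (!is.null(seed)) set.seed(seed)
    em <- energyModel(unlist(model@sampler$pairEnergies),
                      model@sampler$kT, model@sampler$minHairpin)
    prep <- .prepareStructures(seqs, config, em, model@sampler$engine,
                               samples = structures)
    n <- length(seqs)
    Tn <- config$T
    U <- vapply(prep, function(p) nUnique(p$tally), 1L)
    ids <- .makeIdMatrices(seqs, config$km, config$l)
    netPreds <- matrix(NA_real_, n, Tn + 1L)
    runNet <- function(net, idxs, Rfor) {
        b <- list(ids = lapply(ids, function(m) m[idxs, , drop = FALSE]),
                  R = .stackStructureRows(lapply(idxs, Rfor), config$l))
        .networkPredict(net, b)
    }
    for (i in seq_len(Tn)) {
        idxs <- which(U >= i)
        if (!length(idxs) || is.null(model@networks[[i]])) next
        netPreds[idxs, i] <- runNet(model@networks[[i]], idxs,
                                    function(j) prep[[j]]$Rtop[[i]])
    }
    idxs <- which(U > Tn)
    if (length(idxs) && !is.null(model@networks[[Tn + 1L]]))
        netPreds[idxs, Tn + 1L] <- runNet(model@networks[[Tn + 1L]], idxs,
                                          function(j) prep[[j]]$Ravg)
    out <- numeric(n)
    for (s in seq_len(n)) {
        tally <- prep[[s]]$tally
        N <- sampleSize(tally)
        k <- min(Tn, nUnique(tally))
        w <- if (k > 0L) structureCounts(tally)[seq_len(k)] / N else numeric(0)
        v <- if (k > 0L) netPreds[s, seq_len(k)] else numeric(0)
        remW <- 1 - sum(w)
        if (remW > 1e-12) {
            w <- c(w, remW)
            v <- c(v, netPreds[s, Tn + 1L])
        }
        keep <- !is.na(v)
        if (!any(keep))
            stop("untrained ensemble: no trained network applies to ",
                 "sequence ", s)
        out[s] <- sum(w[keep] * v[keep]) / sum(w[keep])
    }
    out
}

#' @describeIn ThermoNetModel `predict` method delegating to
#'   [predictIntensity()].
#' @param object A `ThermoNetModel`.
#' @param ... Passed to [predictIntensity()] (`seqs`, `seed`, `structures`).
#' @export
setMethod("predict", "ThermoNetModel", function(object, ...) {
    predictIntensity(object, ...)
})
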