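#' Ablation comparison of model variants
#'
#' Trains and evaluates the four model variants on the same data with shared
#' seeds: `1-struc` (1-mers + average structure profile only), `k-no-struc`
#' (multi-length k-mer embeddings, structure input zeroed), `k-struc`
#' (k-mer embeddings + average structure profile, a single network), and
#' `k-struc-sampling` (the full model: rank-specific networks over the
#' high-probability structures plus the average-profile network).
#'
#' @param trainData,testData `data.frame`s with `seq` and `intensity` (or
#'   `label`; binary labels are scored by AUROC, intensities by Pearson
#'   correlation).
#' @param config A [networkConfig()] describing the full model; variants
#'   derive from it.
#' @param tc A [trainConfig()].
#' @param variants Subset of the four variant names.
#' @param seeds Integer vector; each variant is trained once per seed.
#' @return `data.frame` with columns `variant`, `seed`, `metric`, `value`.
#' @export
runAblation <- function(trainData, testData, config, tc = trainConfig(),
                        variants = c("1-struc", "k-no-struc", "k-struc",
                                     "k-struc-sampling"),
                        seeds = 1L) {
    known <- c("1-struc", "k-no-struc", "k-struc", "k-struc-sampling")
    bad <- setdiff(variants, known)
    if (length(bad)) stop("unknown ablation variant: ", bad[1L])
    binary <- "label" %in% names(testData)
    metric <- if (binary) "auroc" else "pearson"
    res <- list()
    for (sd in seeds) {
        for (v in variants) {
            cfg <- config
            if (v == "1-struc") { cfg$km <- 1L; cfg$T <- 0L }
            if (v == "k-no-struc") { cfg$T <- 0L; cfg$useStructure <- FALSE }
            if (v == "k-struc") cfg$T <- 0L
            tcv <- tc; tcv$seed <- as.integer(sd)
            fit <- trainThermoNet(trainData, cfg, tcv)
            pred <- predictIntensity(fit, testData$seq, seed = sd + 10000L)
            truth <- .getY(testData)
            value <- if (binary) auroc(pred, truth) else pearson(pred, truth)
            res[[length(res) + 1L]] <- data.frame(variant = v, seed = sd,
                                                  metric = metric,
                                                  value = value)
        }
    }
    do.call(rbind, res)
}
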