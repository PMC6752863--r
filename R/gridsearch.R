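#' Grid-search model selection by two-fold cross-validation
#'
#' Evaluates every combination of the supplied hyperparameter grids by mean
#' validation Huber loss over `folds` cross-validation folds and returns the
#' argmin. Ties are broken by first-in-grid order, so the result is
#' deterministic given the seed. The reference search space is learning rate
#' {1e-3, 1e-4, 1e-5}, kernel width {7, 12, 16}, kernels {16, 64}, L2
#' {1e-3, 1e-4, 1e-5}, embedding dimension {10, 20, 30} and k_m {2..5} (648
#' combinations); desk-scale runs should pass much smaller grids.
#'
#' @param data Training `data.frame` (`seq`, `y`).
#' @param grid Named list of vectors; names may be any [networkConfig()] or
#'   [trainConfig()] field (e.g. `learningRate`, `kernelWidth`, `nKernels`,
#'   `l2`, `d`, `km`).
#' @param config,tc Base configurations whose fields the grid overrides.
#' @param folds Number of cross-validation folds (default 2).
#' @param seed Seed for the fold assignment and training.
#' @param evalFun Optional replacement scorer `function(params)` returning a
#'   validation loss for one grid point (used for selection-correctness
#'   testing and custom objectives); when `NULL`, a model is trained and
#'   scored per fold.
#' @param em,engine Sampler settings, as in [trainThermoNet()].
#' @return List with `best` (named list of the winning parameter values),
#'   `scores` (a `data.frame` of all grid points and their mean validation
#'   losses).
#' @export
gridSearch <- function(data, grid, config, tc = trainConfig(), folds = 2L,
                       seed = tc$seed, evalFun = NULL, em = energyModel(),
                       engine = "bundled") {
    if (!length(grid) || any(!lengths(grid)))
        stop("empty hyperparameter grid")
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    n <- nrow(data)
    set.seed(seed)
    foldId <- sample(rep(seq_len(folds), length.out = n))
    scores <- numeric(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
        params <- as.list(combos[ci, , drop = FALSE])
        if (!is.null(evalFun)) {
            scores[ci] <- evalFun(params)
            next
        }
        cfg <- config; tcc <- tc
        for (nm in names(params)) {
            if (nm %in% names(cfg)) cfg[[nm]] <- params[[nm]]
            else if (nm %in% names(tcc)) tcc[[nm]] <- params[[nm]]
            else stop("unknown grid parameter: ", nm)
        }
        foldLoss <- numeric(folds)
        for (f in seq_len(folds)) {
            tr <- data[foldId != f, , drop = FALSE]
            va <- data[foldId == f, , drop = FALSE]
            tcc$seed <- seed + f
            fit <- trainThermoNet(tr, cfg, tcc, em = em, engine = engine)
            pred <- predictIntensity(fit, va$seq, seed = seed + 100L + f)
            foldLoss[f] <- mean(huberLoss(.getY(va), pred))
        }
        scores[ci] <- mean(foldLoss)
    }
    best <- which.min(scores)  # first minimum = first-in-grid tie-break
    list(best = as.list(combos[best, , drop = FALSE]),
         scores = cbind(combos, valLoss = scores))
}
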