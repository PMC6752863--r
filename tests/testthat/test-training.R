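test_that("Huber loss matches its closed forms and quadratic bound", {
    expect_equal(huberLoss(1.3, 1.3), 0)
    expect_equal(huberLoss(1, 0), 0.5)   # knee from the quadratic branch
    expect_equal(huberLoss(0, 1), 0.5)   # and from the linear branch
    expect_equal(huberLoss(3, 0), 2.5)
    expect_equal(huberLoss(0.5, 0), 0.125)
    r <- seq(-4, 4, by = 0.001)
    L <- huberLoss(r, 0)
    expect_true(all(L >= 0))
    expect_equal(L, huberLoss(0, r))                 # symmetric in sign
    expect_true(all(L <= r^2 / 2 + 1e-12))           # bounded by L2/2
    expect_lt(max(abs(diff(L))), 1.1e-3)             # continuous (Lipschitz 1)
})

test_that("learning rate drops to one tenth after the drop epoch", {
    set.seed(20)
    l <- 10L
    net <- initBaseNetwork(smallNetConfig(l))
    seqs <- replicate(12, randomRna(l))
    batch <- makeTestBatch(seqs, l, 2L)
    tc <- trainConfig(learningRate = 0.001, epochs = 7, lrDropEpoch = 5,
                      batchSize = 6, valFraction = 0, seed = 20)
    fit <- trainBaseNetwork(net, batch, rnorm(12), tc)
    expect_equal(fit$log$lr[1:5], rep(0.001, 5))
    expect_equal(fit$log$lr[6:7], rep(0.0001, 2))
})

test_that("training fits a constant target to within 0.05", {
    set.seed(21)
    l <- 15L
    net <- initBaseNetwork(smallNetConfig(l))
    seqs <- replicate(40, randomRna(l))
    batch <- makeTestBatch(seqs, l, 2L)
    y <- rep(1.3, 40)
    # generous epochs: inference-mode batch-norm running statistics converge
    # slowly on tiny data
    tc <- trainConfig(learningRate = 0.02, epochs = 80, batchSize = 8,
                      lrDropEpoch = 70, valFraction = 0, seed = 21)
    fit <- trainBaseNetwork(net, batch, y, tc)
    pred <- thermonet:::.networkPredict(fit, batch)
    expect_true(all(abs(pred - 1.3) < 0.05))
})

test_that("training descends on a 200-example linear-signal toy set", {
    set.seed(22)
    l <- 15L
    net <- initBaseNetwork(smallNetConfig(l, nKernels = 4L))
    seqs <- replicate(200, randomRna(l))
    batch <- makeTestBatch(seqs, l, 2L)
    # linear signal: target proportional to the G content
    y <- vapply(seqs, function(s)
        sum(strsplit(s, "")[[1]] == "G") / 5, 1, USE.NAMES = FALSE)
    tc <- trainConfig(epochs = 10, batchSize = 32, valFraction = 0,
                      seed = 22)
    fit <- trainBaseNetwork(net, batch, y, tc)
    expect_lt(fit$log$trainLoss[nrow(fit$log)], fit$log$trainLoss[1])
})

test_that("T=0 collapses the ensemble to the average-profile network", {
    set.seed(23)
    seqs <- replicate(30, randomRna(20))
    data <- data.frame(seq = seqs, y = rnorm(30))
    cfg <- networkConfig(l = 20, km = 2, d = 4, nKernels = 2, nLayers = 2,
                         T = 0, N = 20)
    tc <- trainConfig(epochs = 2, batchSize = 8, valFraction = 0, seed = 23)
    fit <- trainThermoNet(data, cfg, tc)
    expect_length(fit@networks, 1)
    p1 <- predictIntensity(fit, seqs[1:5], seed = 99)
    p2 <- predictIntensity(fit, seqs[1:5], seed = 99)
    expect_identical(p1, p2)  # fixed seed -> bit-identical predictions
})

test_that("unstructured sequences degenerate to the rank-1 network", {
    # poly-A cannot pair: U = 1, open structure, prediction = f_1 on all-E
    set.seed(24)
    seqs <- replicate(20, paste(rep("A", 15), collapse = ""))
    data <- data.frame(seq = seqs, y = rnorm(20))
    cfg <- networkConfig(l = 15, km = 2, d = 4, nKernels = 2, nLayers = 2,
                         T = 3, N = 10)
    tc <- trainConfig(epochs = 2, batchSize = 8, valFraction = 0, seed = 24)
    fit <- trainThermoNet(data, cfg, tc)
    expect_false(is.null(fit@networks[[1]]))
    expect_null(fit@networks[[2]])   # rank 2 never has data
    p <- predictIntensity(fit, seqs[1], seed = 5)
    batch <- makeTestBatch(seqs[1], 15L, 2L)
    expect_equal(p, thermonet:::.networkPredict(fit@networks[[1]], batch))
})

test_that("prediction is a convex combination of the per-network outputs", {
    set.seed(25)
    seqs <- replicate(25, randomRna(18))
    data <- data.frame(seq = seqs, y = rnorm(25))
    cfg <- networkConfig(l = 18, km = 2, d = 4, nKernels = 2, nLayers = 2,
                         T = 2, N = 30)
    tc <- trainConfig(epochs = 2, batchSize = 8, valFraction = 0, seed = 25)
    fit <- trainThermoNet(data, cfg, tc)
    newSeqs <- replicate(8, randomRna(18))
    set.seed(77)
    prep <- thermonet:::.prepareStructures(newSeqs, fit@config,
                                           energyModel(), "bundled")
    set.seed(77)
    p <- predictIntensity(fit, newSeqs)
    for (i in seq_along(newSeqs)) {
        vals <- c()
        batchFor <- function(R) list(
            ids = lapply(thermonet:::.makeIdMatrices(newSeqs[i], 2L, 18L),
                         identity),
            R = thermonet:::.stackStructureRows(list(R), 18L))
        for (rk in seq_len(min(2, nUnique(prep[[i]]$tally)))) {
            if (is.null(fit@networks[[rk]])) next
            vals <- c(vals, thermonet:::.networkPredict(
                fit@networks[[rk]], batchFor(prep[[i]]$Rtop[[rk]])))
        }
        if (!is.null(prep[[i]]$Ravg) && !is.null(fit@networks[[3]]))
            vals <- c(vals, thermonet:::.networkPredict(
                fit@networks[[3]], batchFor(prep[[i]]$Ravg)))
        expect_gte(p[i], min(vals) - 1e-9)
        expect_lte(p[i], max(vals) + 1e-9)
    }
})

test_that("grid search selects the planted best configuration", {
    data <- data.frame(seq = replicate(10, randomRna(10)), y = rnorm(10))
    grid <- list(learningRate = c(1e-3, 1e-4), km = c(2, 3))
    # rigged scorer: km = 3 with lr = 1e-4 is strictly best
    scorer <- function(params)
        ifelse(params$km == 3 && params$learningRate == 1e-4, 0.1, 0.5)
    res <- gridSearch(data, grid, networkConfig(l = 10), trainConfig(),
                      evalFun = scorer, seed = 1)
    expect_equal(res$best$km, 3)
    expect_equal(res$best$learningRate, 1e-4)
    # tie -> first-in-grid order wins
    res2 <- gridSearch(data, grid, networkConfig(l = 10), trainConfig(),
                       evalFun = function(p) 0.5, seed = 1)
    expect_equal(res2$best$learningRate, 1e-3)
    expect_equal(res2$best$km, 2)
    # single-point grid returns that point
    res3 <- gridSearch(data, list(km = 4), networkConfig(l = 10),
                       trainConfig(), evalFun = function(p) 1, seed = 1)
    expect_equal(res3$best$km, 4)
    expect_error(gridSearch(data, list(), networkConfig(l = 10)),
                 "empty")
})

test_that("grid search trains and scores real folds on a tiny problem", {
    set.seed(26)
    seqs <- replicate(24, randomRna(12))
    data <- data.frame(seq = seqs, y = rnorm(24))
    grid <- list(km = c(1, 2))
    cfg <- networkConfig(l = 12, km = 1, d = 3, nKernels = 2, nLayers = 1,
                         T = 1, N = 10)
    tc <- trainConfig(epochs = 1, batchSize = 12, valFraction = 0, seed = 26)
    res <- gridSearch(data, grid, cfg, tc, seed = 26)
    expect_equal(nrow(res$scores), 2)
    expect_true(all(is.finite(res$scores$valLoss)))
    expect_true(res$best$km %in% c(1, 2))
})

test_that("model checkpoints round-trip and reject manifest mismatches", {
    set.seed(27)
    seqs <- replicate(15, randomRna(12))
    data <- data.frame(seq = seqs, y = rnorm(15))
    cfg <- networkConfig(l = 12, km = 2, d = 3, nKernels = 2, nLayers = 2,
                         T = 1, N = 10)
    tc <- trainConfig(epochs = 1, batchSize = 8, valFraction = 0, seed = 27)
    fit <- trainThermoNet(data, cfg, tc)
    dir <- file.path(tempdir(), "ckpt-test")
    saveThermoNet(fit, dir)
    back <- loadThermoNet(dir)
    expect_equal(predictIntensity(back, seqs[1:3], seed = 4),
                 predictIntensity(fit, seqs[1:3], seed = 4))
    # corrupt the manifest config: must fail loudly
    mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
    mf$config$km <- 5
    jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    expect_error(loadThermoNet(dir), "mismatch")
})
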