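#' Huber loss
#'
#' Robust regression loss: quadratic for residuals up to 1, linear beyond,
#' continuous at the knee:
#' \deqn{L(y, f) = \frac12 (y-f)^2 \textrm{ if } |y-f| \le 1, \quad
#'       |y-f| - \frac12 \textrm{ otherwise.}}
#'
#' @param y Observed (normalized) intensities.
#' @param f Predicted intensities.
#' @return Elementwise loss, same length as the inputs.
#' @examples
#' huberLoss(3, 0)    # 2.5
#' huberLoss(0.5, 0)  # 0.125
#' @export
huberLoss <- function(y, f) {
    r <- y - f
    ifelse(abs(r) <= 1, 0.5 * r * r, abs(r) - 0.5)
}

#' Training configuration
#'
#' @param learningRate Initial Adam learning rate.
#' @param l2 L2 weight-decay coefficient (applied to conv, FC and embedding
#'   weights; never to biases or batch-norm affine terms).
#' @param epochs Maximum epochs.
#' @param batchSize Minibatch size.
#' @param lrDropEpoch Epoch after which the learning rate is multiplied once
#'   by `lrDropFactor` (default: one-tenth after the 5th epoch).
#' @param lrDropFactor Multiplicative drop, in (0, 1).
#' @param valFraction Fraction of examples held out for early stopping; 0
#'   disables early stopping.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling every random choice of the run.
#' @return Validated list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.001, l2 = 1e-4, epochs = 20L,
                        batchSize = 64L, lrDropEpoch = 5L,
                        lrDropFactor = 0.1, valFraction = 0.1,
                        patience = 5L, seed = 1L) {
    stopifnot(learningRate > 0, l2 >= 0, epochs >= 1, batchSize >= 1,
              lrDropFactor > 0, lrDropFactor < 1,
              valFraction >= 0, valFraction < 1)
    structure(list(learningRate = learningRate, l2 = l2,
                   epochs = as.integer(epochs),
                   batchSize = as.integer(batchSize),
                   lrDropEpoch = as.integer(lrDropEpoch),
                   lrDropFactor = lrDropFactor,
                   valFraction = valFraction,
                   patience = as.integer(patience),
                   seed = as.integer(seed)),
              class = "TrainConfig")
}

# Batch container: per-k id matrices (B x l) plus stacked structure rows
# ((B*l) x 5, example-major). Sequences shorter than l are right-padded with
# the k-mer padding id (zero embedding) and all-E structure rows.
.makeIdMatrices <- function(seqs, km, l) {
    lapply(seq_len(km), function(k) {
        padId <- as.integer(4^k + 1)
        t(vapply(seqs, function(s) {
            ids <- extractKmerIds(s, k)
            c(ids, rep(padId, l - length(ids)))
        }, integer(l), USE.NAMES = FALSE))
    })
}

.stackStructureRows <- function(Rlist, l) {
    eRow <- c(0, 0, 0, 0, 1)
    padded <- lapply(Rlist, function(R) {
        if (nrow(R) < l)
            R <- rbind(R, matrix(eRow, l - nrow(R), 5L, byrow = TRUE))
        R
    })
    do.call(rbind, padded)
}

.subsetBatch <- function(batch, idx, l) {
    rows <- as.vector(outer(seq_len(l), (idx - 1L) * l, `+`))
    list(ids = lapply(batch$ids, function(m) m[idx, , drop = FALSE]),
         R = batch$R[rows, , drop = FALSE])
}

#' Train one base network by Adam on the Huber loss
#'
#' Minimizes mean Huber loss plus L2 weight decay with Adam from Xavier
#' initialization. The learning rate is multiplied once by
#' `tc$lrDropFactor` after epoch `tc$lrDropEpoch`. If validation data is
#' given, training stops early after `tc$patience` epochs without
#' improvement and the best-validation parameters are kept.
#'
#' @param net A `BaseNetwork` from [initBaseNetwork()].
#' @param batch Training inputs (internal batch format: `ids`, `R`).
#' @param y Training targets.
#' @param tc A [trainConfig()].
#' @param valBatch,valY Optional validation split for early stopping.
#' @return The trained network, with a per-epoch log (`epoch`, `lr`,
#'   `trainLoss`, `valLoss`) attached as `net$log`.
#' @export
trainBaseNetwork <- function(net, batch, y, tc, valBatch = NULL,
                             valY = NULL) {
    n <- length(y)
    l <- net$config$l
    state <- .adamInit(net$params)
    bestLoss <- Inf
    bestParams <- NULL
    bestRunning <- NULL
    wait <- 0L
    log <- data.frame(epoch = integer(0), lr = numeric(0),
                      trainLoss = numeric(0), valLoss = numeric(0))
    for (epoch in seq_len(tc$epochs)) {
        lr <- tc$learningRate *
            if (epoch > tc$lrDropEpoch) tc$lrDropFactor else 1
        perm <- sample.int(n)
        starts <- seq(1L, n, by = tc$batchSize)
        epochLoss <- 0
        for (s in starts) {
            idx <- perm[s:min(s + tc$batchSize - 1L, n)]
            mb <- .subsetBatch(batch, idx, l)
            lg <- .networkLossGrad(net, mb, y[idx], l2 = tc$l2)
            net$running <- lg$running
            upd <- .adamStep(net$params, lg$grads, state, lr)
            net$params <- upd$params
            state <- upd$state
            epochLoss <- epochLoss + lg$loss * length(idx)
        }
        trainLoss <- epochLoss / n
        valLoss <- NA_real_
        if (!is.null(valBatch)) {
            vp <- .networkPredict(net, valBatch)
            valLoss <- mean(huberLoss(valY, vp))
            if (valLoss < bestLoss - 1e-9) {
                bestLoss <- valLoss
                bestParams <- net$params
                bestRunning <- net$running
                wait <- 0L
            } else {
                wait <- wait + 1L
            }
        }
        log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                     trainLoss = trainLoss,
                                     valLoss = valLoss))
        if (!is.null(valBatch) && wait >= tc$patience) break
    }
    if (!is.null(bestParams)) {
        net$params <- bestParams
        net$running <- bestRunning
    }
    net$trained <- TRUE
    net$log <- log
    net
}
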