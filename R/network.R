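#' Assemble the network input from sequence and structure representations
#'
#' Column-wise concatenation of the sequence embedding E (`l x k_m*d`) and a
#' structure matrix R (`l x 5`, one-hot or average profile), structure
#' columns last in the fixed order P, H, I, M, E.
#'
#' @param E Sequence representation matrix from
#'   [buildSequenceRepresentation()].
#' @param R Structure matrix from [structureOneHot()] or [averageProfile()].
#' @return `l x (ncol(E) + 5)` matrix.
#' @export
assembleInput <- function(E, R) {
    if (nrow(E) != nrow(R))
        stop("sequence representation (", nrow(E), " rows) and structure ",
             "matrix (", nrow(R), " rows) differ in length")
    if (ncol(R) != 5L) stop("structure matrix must have 5 columns (P,H,I,M,E)")
    cbind(E, R)
}

# ---------------------------------------------------------------------------
# Base convolutional predictor.
#
# Architecture: nLayers blocks of (same-length 1-D convolution -> batch
# normalization -> ReLU), then a fully-connected map from the flattened
# final feature map to one scalar. All matrices are stored row-grouped by
# example: row = pos + (b-1)*l for example b, position pos; this keeps every
# heavy operation a single BLAS matrix product.
# ---------------------------------------------------------------------------

.xavier <- function(nr, nc, fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Create an untrained base network. Uses the current R random stream for
# Xavier initialization of conv, FC and embedding weights.
#' Create an untrained base convolutional predictor
#'
#' @param config List with elements `l` (input length, nt), `km` (maximum
#'   k-mer length), `d` (embedding dimension), `nKernels`, `kernelWidth`,
#'   `nLayers`, and `useStructure` (logical; when `FALSE` the five structure
#'   input columns are zeroed, the sequence-only ablation).
#' @return A `BaseNetwork` list: parameters (embedding tables, conv kernels,
#'   batch-norm affine terms, FC head), batch-norm running statistics, and
#'   the config.
#' @export
initBaseNetwork <- function(config) {
    km <- config$km; d <- config$d; K <- config$nKernels
    w <- config$kernelWidth; L <- config$nLayers
    c0 <- km * d + 5L
    params <- list()
    for (k in seq_len(km))
        params[[paste0("emb", k)]] <- newEmbeddingTable(k, d)
    cin <- c0
    for (ly in seq_len(L)) {
        params[[paste0("conv", ly, "_W")]] <-
            .xavier(w * cin, K, fanIn = w * cin, fanOut = w * K)
        params[[paste0("conv", ly, "_b")]] <- rep(0, K)
        params[[paste0("conv", ly, "_gamma")]] <- rep(1, K)
        params[[paste0("conv", ly, "_beta")]] <- rep(0, K)
        cin <- K
    }
    params$fc_W <- .xavier(config$l * K, 1L, fanIn = config$l * K, fanOut = 1)
    params$fc_b <- 0
    running <- lapply(seq_len(L), function(ly)
        list(mean = rep(0, K), var = rep(1, K)))
    structure(list(config = config, params = params, running = running,
                   trained = FALSE),
              class = "BaseNetwork")
}

# Which parameters carry L2 weight decay (conv/FC/embedding weights only;
# never batch-norm affine terms or biases).
.l2Names <- function(net) {
    nm <- names(net$params)
    nm[grepl("^emb[0-9]+$|_W$", nm)]
}

# im2col gather indices: column w holds the 1-based source row feeding each
# output row at kernel offset w, with 0 for the implicit zero padding
# outside the sequence (same-length convolution).
.convIdx <- function(B, l, width) {
    hw <- (width - 1L) %/% 2L
    pos <- rep(seq_len(l), B)
    base <- rep((seq_len(B) - 1L) * l, each = l)
    idx <- matrix(0L, B * l, width)
    for (w in seq_len(width)) {
        p2 <- pos + (w - 1L - hw)
        ok <- p2 >= 1L & p2 <= l
        idx[, w] <- ifelse(ok, p2 + base, 0L)
    }
    idx
}

# Batch-normalization constants shared with the compiled kernel: biased
# batch variance, eps 1e-5, running-statistic momentum 0.1.

# Assemble the (B*l) x (km*d + 5) input matrix: embedded k-mer blocks plus
# the five structure-context columns (zeroed for the sequence-only variant).
.networkInput <- function(net, batch) {
    cfg <- net$config
    B <- nrow(batch$ids[[1L]])
    blocks <- lapply(seq_len(cfg$km), function(k) {
        ids <- as.vector(t(batch$ids[[k]]))
        net$params[[paste0("emb", k)]][ids, , drop = FALSE]
    })
    Rmat <- if (isTRUE(cfg$useStructure)) batch$R else
        matrix(0, B * cfg$l, 5L)
    cbind(do.call(cbind, blocks), Rmat)
}

.layerParams <- function(net, what) {
    lapply(seq_len(net$config$nLayers), function(ly)
        net$params[[paste0("conv", ly, "_", what)]])
}

.cnnCall <- function(net, batch, training, y, computeGrads) {
    cfg <- net$config
    B <- nrow(batch$ids[[1L]])
    X0 <- .networkInput(net, batch)
    idx <- .convIdx(B, cfg$l, cfg$kernelWidth)
    .cnnLossGradCpp(X0, idx,
                    .layerParams(net, "W"), .layerParams(net, "b"),
                    .layerParams(net, "gamma"), .layerParams(net, "beta"),
                    lapply(net$running, `[[`, "mean"),
                    lapply(net$running, `[[`, "var"),
                    as.numeric(net$params$fc_W), net$params$fc_b,
                    B, cfg$l, training,
                    if (is.null(y)) numeric(B) else y, computeGrads)
}

# Training-mode loss (mean Huber + L2 on weights) and its gradients on one
# batch; the single entry point shared by the optimizer and the
# finite-difference gradient check.
.networkLossGrad <- function(net, batch, y, l2 = 0, withGrads = TRUE) {
    cfg <- net$config
    res <- .cnnCall(net, batch, training = TRUE, y = y,
                    computeGrads = withGrads)
    loss <- res$loss
    if (l2 > 0) {
        for (nm in .l2Names(net))
            loss <- loss + l2 * sum(net$params[[nm]]^2)
    }
    running <- lapply(seq_len(cfg$nLayers), function(ly)
        list(mean = as.numeric(res$runMean[[ly]]),
             var = as.numeric(res$runVar[[ly]])))
    if (!withGrads) return(list(loss = loss, running = running))
    grads <- list()
    for (ly in seq_len(cfg$nLayers)) {
        grads[[paste0("conv", ly, "_W")]] <- res$gConvW[[ly]]
        grads[[paste0("conv", ly, "_b")]] <- as.numeric(res$gConvB[[ly]])
        grads[[paste0("conv", ly, "_gamma")]] <- as.numeric(res$gGamma[[ly]])
        grads[[paste0("conv", ly, "_beta")]] <- as.numeric(res$gBeta[[ly]])
    }
    grads$fc_W <- matrix(res$gFcW, ncol = 1L)
    grads$fc_b <- res$gFcb
    d <- cfg$d
    for (k in seq_len(cfg$km)) {
        colsel <- ((k - 1L) * d + 1L):(k * d)
        dE <- res$dX0[, colsel, drop = FALSE]
        ids <- as.vector(t(batch$ids[[k]]))
        tab <- net$params[[paste0("emb", k)]]
        g <- matrix(0, nrow(tab), d)
        rs <- rowsum(dE, group = ids)
        g[as.integer(rownames(rs)), ] <- rs
        grads[[paste0("emb", k)]] <- g
    }
    if (l2 > 0) {
        for (nm in .l2Names(net))
            grads[[nm]] <- grads[[nm]] + 2 * l2 * net$params[[nm]]
    }
    # keep the embedding padding rows frozen even under weight decay
    for (k in seq_len(cfg$km)) {
        nm <- paste0("emb", k)
        grads[[nm]][nrow(grads[[nm]]), ] <- 0
    }
    list(loss = loss, grads = grads, running = running)
}

# --- Adam ------------------------------------------------------------------

.adamInit <- function(params) {
    list(t = 0L,
         m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0))
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
        mhat <- state$m[[nm]] / bc1
        vhat <- state$v[[nm]] / bc2
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
}

# Inference-mode predictions (running batch-norm statistics), so a single
# sequence gets the same answer regardless of what it is batched with.
.networkPredict <- function(net, batch) {
    as.numeric(.cnnCall(net, batch, training = FALSE, y = NULL,
                        computeGrads = FALSE)$pred)
}
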