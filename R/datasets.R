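#' Read and write binding-data tables
#'
#' Tab-separated records, one per line, RNAcompete-style for intensities
#' (`id`, `seq`, `intensity`) and CLIP-seq-style for binary labels (`id`,
#' `seq`, `label`). A header line is detected and skipped when its third
#' field is not numeric. Sequences are canonicalized (T mapped to U).
#'
#' @param path File path.
#' @return `data.frame` with columns `id`, `seq` and `intensity` (or
#'   `label`).
#' @export
readIntensityTable <- function(path) {
    .readTable3(path, "intensity")
}

#' @rdname readIntensityTable
#' @export
readBinaryTable <- function(path) {
    d <- .readTable3(path, "label")
    if (!all(d$label %in% c(0, 1)))
        stop("labels must be 0 or 1 in ", path)
    d$label <- as.integer(d$label)
    d
}

.readTable3 <- function(path, valueName) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty table: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) start <- 2L
    if (start > length(lines)) stop("no records in ", path)
    n <- length(lines) - start + 1L
    id <- character(n); seq <- character(n); val <- numeric(n)
    for (i in seq_len(n)) {
        f <- fields[[start + i - 1L]]
        if (length(f) != 3L)
            stop("malformed line ", start + i - 1L, " in ", path,
                 ": expected 3 tab-separated fields, got ", length(f))
        v <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(v) || !is.finite(v))
            stop("malformed line ", start + i - 1L, " in ", path,
                 ": non-numeric value '", f[3L], "'")
        id[i] <- f[1L]; seq[i] <- f[2L]; val[i] <- v
    }
    out <- data.frame(id = id, seq = canonicalizeRna(seq),
                      stringsAsFactors = FALSE)
    out[[valueName]] <- val
    out
}

#' @param data `data.frame` with columns `id`, `seq` and a value column
#'   (`intensity`, `label` or `y`).
#' @param header Write a header line (default `TRUE`).
#' @rdname readIntensityTable
#' @export
writeIntensityTable <- function(data, path, header = TRUE) {
    valueName <- intersect(c("intensity", "label", "y"), names(data))[1L]
    lines <- sprintf("%s\t%s\t%.10g", data$id, data$seq, data[[valueName]])
    if (header) lines <- c(paste("id", "seq", valueName, sep = "\t"), lines)
    writeLines(lines, path)
    invisible(path)
}

#' Write predictions as a tab-separated (id, prediction) table
#'
#' Fixed `%.10g` formatting, so identical predictions give byte-identical
#' files.
#'
#' @param id Identifiers.
#' @param pred Predicted intensities.
#' @param path Output path.
#' @export
writePredictions <- function(id, pred, path) {
    writeLines(sprintf("%s\t%.10g", id, pred), path)
    invisible(path)
}

#' Intensity preprocessing: percentile clamp then z-normalization
#'
#' `fitPreprocess` computes, on the training intensities only, the 99.5th
#' percentile (linear interpolation between closest ranks, the type-7
#' quantile), and the mean and standard deviation of the clamped values.
#' `applyPreprocess` clamps at that value and z-scores with the training
#' statistics, so applying the training stats to a test split introduces no
#' leakage.
#'
#' @param x Numeric intensities (training split for `fitPreprocess`).
#' @param clampQuantile Clamp percentile (default 0.995).
#' @return `fitPreprocess`: list with `clamp`, `mean`, `sd`.
#'   `applyPreprocess`: normalized values.
#' @export
fitPreprocess <- function(x, clampQuantile = 0.995) {
    if (length(x) < 2L) stop("need at least 2 training values")
    if (!all(is.finite(x))) stop("intensities must be finite")
    clamp <- unname(quantile(x, clampQuantile, type = 7))
    xc <- pmin(x, clamp)
    s <- sd(xc)
    if (!is.finite(s) || s == 0)
        stop("zero variance after clamping; cannot z-normalize")
    structure(list(clamp = clamp, mean = mean(xc), sd = s),
              class = "PreprocessStats")
}

#' @param stats A `PreprocessStats` from `fitPreprocess`.
#' @rdname fitPreprocess
#' @export
applyPreprocess <- function(x, stats) {
    (pmin(x, stats$clamp) - stats$mean) / stats$sd
}

#' Pearson correlation between predicted and measured intensities
#'
#' @param pred,meas Equal-length numeric vectors with nonzero variance.
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson <- function(pred, meas) {
    if (length(pred) != length(meas)) stop("length mismatch")
    if (length(pred) < 2L) stop("need at least 2 observations")
    if (sd(pred) == 0 || sd(meas) == 0)
        stop("degenerate (zero-variance) input to Pearson correlation")
    cor(pred, meas)
}

#' Area under the ROC curve
#'
#' Computed by rank summation, which equals the Mann-Whitney statistic
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Real-valued prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
    if (length(scores) != length(labels)) stop("length mismatch")
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to compute AUROC")
    r <- rank(scores)  # average ranks handle ties
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
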