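#' Save / load a trained model checkpoint
#'
#' A checkpoint is a directory holding one parameter file per base network
#' plus `manifest.json` recording the network configuration, the k-mer
#' vocabulary convention, and the sampler settings. Loading verifies the
#' manifest against the parameter files and fails loudly on any mismatch.
#'
#' @param model A [ThermoNetModel-class].
#' @param dir Checkpoint directory (created if missing).
#' @return `saveThermoNet`: `dir`, invisibly. `loadThermoNet`: the restored
#'   [ThermoNetModel-class].
#' @export
saveThermoNet <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (i in seq_along(model@networks)) {
        if (is.null(model@networks[[i]])) next
        f <- sprintf("network_%02d.rds", i)
        saveRDS(model@networks[[i]], file.path(dir, f))
        files[as.character(i)] <- f
    }
    manifest <- list(
        format = "thermonet-checkpoint-1",
        config = model@config,
        trainCfg = model@trainCfg,
        sampler = model@sampler,
        vocabulary = "k-mers in lexicographic order over A<C<G<U; pad id 4^k+1",
        networks = as.list(files))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' @rdname saveThermoNet
#' @export
loadThermoNet <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    if (!file.exists(mf)) stop("no manifest.json in ", dir)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!identical(manifest$format, "thermonet-checkpoint-1"))
        stop("unrecognized checkpoint format: ", manifest$format)
    config <- manifest$config
    networks <- vector("list", config$T + 1L)
    for (nm in names(manifest$networks)) {
        i <- as.integer(nm)
        f <- file.path(dir, manifest$networks[[nm]])
        if (!file.exists(f))
            stop("manifest lists missing parameter file: ", f)
        net <- readRDS(f)
        for (fld in c("l", "km", "d", "nKernels", "kernelWidth", "nLayers"))
            if (!identical(as.integer(net$config[[fld]]),
                           as.integer(config[[fld]])))
                stop("checkpoint mismatch: network ", i, " has ", fld, " = ",
                     net$config[[fld]], " but manifest says ", config[[fld]])
        networks[[i]] <- net
    }
    new("ThermoNetModel", networks = networks, config = as.list(config),
        trainCfg = as.list(manifest$trainCfg),
        sampler = as.list(manifest$sampler),
        trainLog = data.frame())
}
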