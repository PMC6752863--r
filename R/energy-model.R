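#' @title Simple pair-energy model for the bundled Boltzmann sampler
#'
#' @description The bundled sampler scores a nested secondary structure as the
#' sum of the energies of its base pairs, with a minimum hairpin constraint.
#' Defaults follow the usual stability ordering GC < AU < GU (more negative =
#' more stable) with kT = 1, so Boltzmann factors are exp(-E/kT).
#'
#' @slot pairEnergies Named numeric: energies for "GC", "AU", "GU" (applied
#'   symmetrically to the reversed pairs). All must be negative.
#' @slot kT Positive temperature factor, same units as the energies.
#' @slot minHairpin Minimum number of unpaired bases enclosed by a pair.
#' @name EnergyModel-class
#' @rdname EnergyModel
#' @exportClass EnergyModel
setClass("EnergyModel",
    representation(pairEnergies = "numeric", kT = "numeric",
                   minHairpin = "integer"),
    validity = function(object) {
        msg <- character(0)
        need <- c("GC", "AU", "GU")
        if (!all(need %in% names(object@pairEnergies)))
            msg <- c(msg, "pairEnergies must name GC, AU and GU")
        if (any(object@pairEnergies >= 0))
            msg <- c(msg, "pair energies must be negative (stabilizing)")
        if (length(object@kT) != 1L || object@kT <= 0)
            msg <- c(msg, "kT must be a single positive number")
        if (object@minHairpin < 3L)
            msg <- c(msg, "minHairpin must be >= 3")
        if (length(msg)) msg else TRUE
    })

#' Construct a pair-energy model
#'
#' @param pairEnergies Named numeric vector with elements "GC", "AU", "GU";
#'   negative energies in arbitrary units.
#' @param kT Temperature factor (same units); Boltzmann weight is exp(-E/kT).
#' @param minHairpin Minimum unpaired span enclosed by any pair (nt).
#' @return An [EnergyModel-class] object.
#' @examples
#' em <- energyModel()
#' em
#' @rdname EnergyModel
#' @export
energyModel <- function(pairEnergies = c(GC = -3, AU = -2, GU = -1),
                        kT = 1, minHairpin = 3L) {
    new("EnergyModel", pairEnergies = pairEnergies, kT = as.numeric(kT),
        minHairpin = as.integer(minHairpin))
}

# 4x4 matrix over (A,C,G,U) x (A,C,G,U); 0 marks a non-pairable combination
.energyMatrix <- function(em) {
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
    pe <- em@pairEnergies
    m["G", "C"] <- m["C", "G"] <- pe[["GC"]]
    m["A", "U"] <- m["U", "A"] <- pe[["AU"]]
    m["G", "U"] <- m["U", "G"] <- pe[["GU"]]
    m
}

setMethod("show", "EnergyModel", function(object) {
    cat("EnergyModel: ",
        paste(names(object@pairEnergies), object@pairEnergies,
              sep = "=", collapse = ", "),
        sprintf("; kT=%g; minHairpin=%d\n", object@kT, object@minHairpin),
        sep = "")
})
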