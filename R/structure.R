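#' Parse a dot-bracket structure into a pair table
#'
#' Stack-based matching of a Vienna dot-bracket string. Pseudoknots cannot be
#' expressed in this dialect, so the result is always a properly nested set of
#' pairs.
#'
#' @param db A single dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector of length `nchar(db)`; element `i` holds the 1-based
#'   index of the partner of position `i`, or `NA` if unpaired.
#' @examples
#' parseDotBracket("(((...)))")
#' @export
parseDotBracket <- function(db) {
    stopifnot(is.character(db), length(db) == 1L)
    ch <- strsplit(db, "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% c(".", "(", ")"))
    if (length(bad))
        stop("invalid dot-bracket character at position ", bad[1L])
    n <- length(ch)
    partner <- rep(NA_integer_, n)
    stack <- integer(0)
    for (i in seq_len(n)) {
        if (ch[i] == "(") {
            stack <- c(stack, i)
        } else if (ch[i] == ")") {
            if (!length(stack))
                stop("unbalanced dot-bracket: unmatched ')' at position ", i)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            partner[i] <- j
            partner[j] <- i
        }
    }
    if (length(stack))
        stop("unbalanced dot-bracket: unmatched '(' at position ",
             stack[length(stack)])
    partner
}

# pair table -> dot-bracket string
.pairTableToDb <- function(partner) {
    ch <- rep(".", length(partner))
    paired <- which(!is.na(partner))
    ch[paired] <- ifelse(partner[paired] > paired, "(", ")")
    paste(ch, collapse = "")
}

#' Annotate per-position structural contexts
#'
#' Classifies every position of a nested secondary structure into one of the
#' five structural contexts used throughout the package: paired (P), hairpin
#' loop (H), internal loop (I, including bulges), multiloop (M), or external
#' region (E). An unpaired position takes the class of the loop it lies in:
#' the loop closed by its innermost enclosing pair has 0 directly enclosed
#' child pairs for a hairpin, exactly 1 for an internal loop / bulge, and 2 or
#' more for a multiloop; positions enclosed by no pair are external.
#'
#' @param x A dot-bracket string (vectorized over several strings) or a pair
#'   table from [parseDotBracket()].
#' @return String(s) over `P`, `H`, `I`, `M`, `E` of the same length.
#' @examples
#' annotateContexts("(((...)))")        # "PPPHHHPPP"
#' annotateContexts("((...).(...))")    # multiloop spacer -> M
#' @export
annotateContexts <- function(x) {
    db <- if (is.character(x)) x else .pairTableToDb(as.integer(x))
    as.character(.annotateContextsCpp(db))
}

#' One-hot encode a structural-context annotation
#'
#' @param ca Context string over `P`, `H`, `I`, `M`, `E` (from
#'   [annotateContexts()]).
#' @return An `l x 5` 0/1 matrix with columns in the fixed order
#'   `P, H, I, M, E`; every row sums to 1.
#' @examples
#' structureOneHot("PHE")
#' @export
structureOneHot <- function(ca) {
    lev <- c("P", "H", "I", "M", "E")
    ch <- strsplit(ca, "", fixed = TRUE)[[1L]]
    idx <- match(ch, lev)
    if (anyNA(idx)) stop("invalid context character: ", ch[which(is.na(idx))[1L]])
    m <- matrix(0, length(ch), 5L, dimnames = list(NULL, lev))
    m[cbind(seq_along(idx), idx)] <- 1
    m
}
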