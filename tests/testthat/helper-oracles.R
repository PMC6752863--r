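# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code they check.

# Depth-counting dot-bracket matcher (no stack): the partner of '(' at i is
# the first j > i where the bracket depth returns to depth(i) - 1.
oracleParse <- function(db) {
    ch <- strsplit(db, "", fixed = TRUE)[[1L]]
    delta <- ifelse(ch == "(", 1L, ifelse(ch == ")", -1L, 0L))
    depth <- cumsum(delta)
    stopifnot(all(depth >= 0), depth[length(depth)] == 0)
    partner <- rep(NA_integer_, length(ch))
    for (i in which(ch == "(")) {
        j <- which(seq_along(ch) > i & ch == ")" & depth == depth[i] - 1L)[1L]
        partner[i] <- j
        partner[j] <- i
    }
    partner
}

# Brute-force context annotator: classify each unpaired base by explicitly
# enumerating enclosing pairs and the children of its innermost one.
oracleAnnotate <- function(db) {
    partner <- oracleParse(db)
    n <- length(partner)
    opens <- which(!is.na(partner) & partner > seq_len(n))
    pairs <- cbind(opens, partner[opens])
    innermostEnclosing <- function(u) {
        encl <- pairs[pairs[, 1] < u & pairs[, 2] > u, , drop = FALSE]
        if (!nrow(encl)) return(NULL)
        encl[which.max(encl[, 1]), ]   # nested => max opening = innermost
    }
    ctx <- character(n)
    for (u in seq_len(n)) {
        if (!is.na(partner[u])) { ctx[u] <- "P"; next }
        inner <- innermostEnclosing(u)
        if (is.null(inner)) { ctx[u] <- "E"; next }
        # children: pairs directly enclosed by `inner`
        nchild <- 0L
        for (p in seq_len(nrow(pairs))) {
            a <- pairs[p, 1]; b <- pairs[p, 2]
            if (a <= inner[1] || b >= inner[2]) next
            enclOfChild <- innermostEnclosing(a)
            if (!is.null(enclOfChild) && all(enclOfChild == inner))
                nchild <- nchild + 1L
        }
        ctx[u] <- if (nchild == 0L) "H" else if (nchild == 1L) "I" else "M"
    }
    paste(ctx, collapse = "")
}

# Recursive-backtracking structure enumeration branching on the FIRST base
# of each interval (the package version branches on the last base).
oracleEnumerate <- function(seq, em = energyModel()) {
    s <- strsplit(seq, "", fixed = TRUE)[[1L]]
    pe <- em@pairEnergies
    pairEnergy <- function(a, b) {
        key <- paste0(a, b)
        if (key %in% c("GC", "CG")) return(pe[["GC"]])
        if (key %in% c("AU", "UA")) return(pe[["AU"]])
        if (key %in% c("GU", "UG")) return(pe[["GU"]])
        NA_real_
    }
    m <- em@minHairpin
    rec <- function(i, j) {
        if (i > j) return(data.frame(db = "", energy = 0))
        out <- rec(i + 1L, j)
        out$db <- paste0(".", out$db)
        for (k in (i + m + 1L):j) {
            if (k > j) break
            e <- pairEnergy(s[i], s[k])
            if (is.na(e)) next
            ins <- rec(i + 1L, k - 1L)
            rest <- rec(k + 1L, j)
            combo <- expand.grid(a = seq_len(nrow(ins)), b = seq_len(nrow(rest)))
            out <- rbind(out, data.frame(
                db = paste0("(", ins$db[combo$a], ")", rest$db[combo$b]),
                energy = e + ins$energy[combo$a] + rest$energy[combo$b]))
        }
        out
    }
    rec(1L, nchar(seq))
}

# Fixed panel of RNA sequences for exhaustive small-scale checks.
oracleSeqPanel <- function() {
    c("GAAAC", "GGAAAC", "GCAAAGC", "GGAAACC", "AUGAAACAU", "GCGAAACGCA",
      "GGCAAAGGCAAAGCC", "ACGUACGUACGU", "GGGAAAUCCC", "UGCAUGAAAGCA",
      "CCGAAACGGAAA", "GAAACGAAAC")
}

randomRna <- function(l) paste(sample(c("A", "C", "G", "U"), l, TRUE),
                               collapse = "")

# Curated dot-bracket suite covering hairpins, bulges on both sides,
# internal loops, multiloops (2-4 children, nested), and external spacers.
curatedStructures <- function() {
    c("(((...)))", "(.((...)).)", "((...).(...))", ".....",
      "(((...)))...", "...(((...)))", "((((...))))",
      "((.(...)))",            # 5' bulge
      "(((...).))",            # 3' bulge
      "((..(...)..))",         # symmetric internal loop
      "((.(...)...))",         # asymmetric internal loop
      "((...)(...))",          # multiloop, adjacent children
      "((...)..(...).)",       # multiloop with spacers
      "((...)(...)(...))",     # 3-child multiloop
      "(.(...).(...).)",       # multiloop, spacer before each child
      "((((...)))(...))",      # deep helix child + sibling
      "((.((...))..(...).))",  # nested bulge inside multiloop child
      "(...).(...)",           # two external helices, spacer
      "(...)(...)",            # adjacent external helices
      ".(...).",               # dangling external bases
      "((.((...)).((...)).))", # multiloop of internal-loop children
      "(((...))).((.(...)))",  # mixed external composition
      "((..((...))((...))..))",
      "(..(..(..(...)..)..)..)",   # onion of internal loops
      "((...)((...)(...)))",       # multiloop nested in multiloop
      "....(((....)))....",
      "((((....)).((....))))",
      "(.(.(.(...).).).)",
      "((...)...(...)...(...))",   # 3 children with spacers
      "(((..((....))..)))",
      "..((((...)).(...)))..",
      "(....)",
      "((......))",
      "(((((...)))))",
      "((..((...))..))",
      "((...)....)",               # single child, long 3' side
      "(....(...))",               # single child, 5' side
      "((((...))).((...)))",
      ".((...)).((...)).",
      "((.(..(...)..).))",
      "((...))(((...)))",
      ".....((((...)))).....",
      "((((...))((...))))",
      "(.((...))((...)).)",
      "((..(...)(...)..))",
      "(((...).(...)))",
      "(..((...))..)",
      "((....))",
      "(((....).))",
      "(((.(....)))).."
    )
}

# Build the internal batch format from sequences and optional dot-brackets.
makeTestBatch <- function(seqs, l, km, dbs = NULL) {
    Rl <- if (is.null(dbs)) {
        lapply(seqs, function(s) structureOneHot(strrep("E", nchar(s))))
    } else {
        lapply(dbs, function(db) structureOneHot(annotateContexts(db)))
    }
    list(ids = thermonet:::.makeIdMatrices(seqs, km, l),
         R = thermonet:::.stackStructureRows(Rl, l))
}

smallNetConfig <- function(l, km = 2L, d = 3L, nKernels = 2L,
                           kernelWidth = 3L, nLayers = 2L,
                           useStructure = TRUE) {
    list(l = l, km = km, d = d, nKernels = nKernels,
         kernelWidth = kernelWidth, nLayers = nLayers,
         useStructure = useStructure)
}
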