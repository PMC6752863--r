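test_that("intensity tables round-trip and canonicalize DNA alphabets", {
    f <- tempfile()
    d <- data.frame(id = c("r1", "r2", "r3"),
                    seq = c("ACGUACGU", "GGGTTTCC", "AUAUAUAU"),
                    intensity = c(0.5, -1.25, 3.75))
    writeIntensityTable(d, f)
    back <- readIntensityTable(f)
    expect_equal(nrow(back), 3)
    expect_equal(back$seq[2], "GGGUUUCC")  # T -> U on read (already on write)
    expect_equal(back$intensity, d$intensity)
    # headerless files parse too
    writeIntensityTable(d, f, header = FALSE)
    expect_equal(readIntensityTable(f)$id, d$id)
    # malformed line reported with its line number
    writeLines(c("id\tseq\tintensity", "a\tACGU\t1.0", "b\tACGU"), f)
    expect_error(readIntensityTable(f), "line 3")
    writeLines(c("a\tACGU\t1.0", "b\tACGU\tnot_a_number"), f)
    expect_error(readIntensityTable(f), "line 2")
})

test_that("binary tables enforce 0/1 labels", {
    f <- tempfile()
    writeLines(c("a\tACGU\t1", "b\tGGCC\t0"), f)
    d <- readBinaryTable(f)
    expect_identical(d$label, c(1L, 0L))
    writeLines(c("a\tACGU\t2", "b\tGGCC\t0"), f)
    expect_error(readBinaryTable(f), "0 or 1")
})

test_that("preprocessing clamps at the 99.5th percentile then z-scores", {
    x <- as.numeric(1:1000)
    st <- fitPreprocess(x)
    expect_equal(st$clamp, quantile(x, 0.995, type = 7), ignore_attr = TRUE)
    z <- applyPreprocess(x, st)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(var(z), 1, tolerance = 1e-6)
    # everything above the percentile maps to the clamp value
    top <- which(x > st$clamp)
    expect_gte(length(top), 4)
    expect_equal(length(unique(z[top])), 1)
    expect_equal(max(z), z[top][1])
    expect_error(fitPreprocess(rep(2, 50)), "variance")
    expect_error(fitPreprocess(3), "at least 2")
})

test_that("preprocessing is monotone and reuses training statistics on test data", {
    set.seed(30)
    train <- rlnorm(500)
    test <- rlnorm(200)
    st <- fitPreprocess(train)
    zTest <- applyPreprocess(test, st)
    o <- order(test)
    expect_true(all(diff(zTest[o]) >= 0))
    # test stats come from the training split, so the test mean is NOT 0
    expect_gt(abs(mean(zTest)), 1e-6)
    expect_equal(applyPreprocess(train, st),
                 (pmin(train, st$clamp) - st$mean) / st$sd)
})

test_that("pearson matches a direct covariance computation", {
    expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(pearson(c(1, 2, 3), c(-1, -2, -3)), -1)
    a <- c(1, 2, 3); b <- c(2, 4, 7)
    byHand <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson(a, b), byHand)
    expect_equal(pearson(a, b), 0.9933993, tolerance = 1e-6)
    # invariance to positive affine rescaling
    set.seed(31)
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(pearson(2.5 * x + 1, y), pearson(x, y))
    expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "degenerate")
    expect_error(pearson(1:3, 1:4), "length")
})

test_that("auroc equals brute-force pair counting, including ties", {
    expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
    expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
    # 4-point set with one inversion: pairs (pos > neg): 3 of 4
    expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
    bruteAuc <- function(s, l) {
        pos <- s[l == 1]; neg <- s[l == 0]
        g <- outer(pos, neg, `>`); t <- outer(pos, neg, `==`)
        (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
    }
    set.seed(32)
    for (i in 1:40) {
        n <- sample(4:12, 1)
        l <- c(0, 1, sample(0:1, n - 2, TRUE))
        s <- sample(seq(0, 2, by = 0.5), n, TRUE)  # forces ties
        expect_equal(auroc(s, l), bruteAuc(s, l))
    }
    # null behaviour: independent scores give about one half
    set.seed(33)
    l <- rep(0:1, each = 2000)
    expect_equal(auroc(rnorm(4000), l), 0.5, tolerance = 0.03)
    expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auroc agrees with the pROC reference implementation", {
    skip_if_not_installed("pROC")
    set.seed(34)
    s <- rnorm(150)
    l <- as.integer(runif(150) < plogis(s))
    if (length(unique(l)) == 2) {
        ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<")))
        expect_equal(auroc(s, l), ref, tolerance = 1e-12)
    }
})

test_that("FASTA sequences are read and canonicalized", {
    f <- tempfile(fileext = ".fa")
    writeLines(c(">probe1", "ACGTACGT", ">probe2", "gggaaaccc"), f)
    seqs <- readRnaFasta(f)
    expect_equal(unname(seqs), c("ACGUACGU", "GGGAAACCC"))
    expect_equal(names(seqs), c("probe1", "probe2"))
})
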