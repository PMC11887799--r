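test_that("relative abundance normalizes with and without pseudocount", {
    expect_equal(relativeAbundance(c(2, 3, 5), eps = 0), c(0.2, 0.3, 0.5))
    expect_equal(relativeAbundance(c(0, 0), eps = 1), c(0.5, 0.5))
    expect_equal(relativeAbundance(c(9, 1), eps = 1), c(10, 2) / 12)
    expect_error(relativeAbundance(c(0, 0), eps = 0),
        class = "wildIg_all_zero")
    expect_error(relativeAbundance(c(-1, 2)), class = "wildIg_bad_counts")
})

test_that("ig scores are log2 bound/unbound ratios", {
    expect_equal(igScore(c(0.5, 0.5), c(0.5, 0.5)), c(0, 0))
    expect_equal(igScore(0.2, 0.1), 1)
    expect_equal(igScore(c(0.9, 0.1), c(0.5, 0.5)),
        c(log2(1.8), log2(0.2)))
    expect_error(igScore(c(0.5, 0), c(0.5, 0.5)),
        class = "wildIg_zero_abundance")
})

test_that("score tables apply the pipeline sample-wise with filtering", {
    m <- matrix(c(10L, 5L, 0L, 3L, 8L, 0L), 3,
        dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
    grp <- c("laboratory", "rewilded")
    bound <- fractionCountTable(m, grp, "bound", "IgG")
    unboundSame <- fractionCountTable(m, grp, "unbound", "IgG")
    st <- scoreTable(bound, unboundSame, minPrevalence = 1)
    expect_true(all(scores(st) == 0))  # identical fractions score 0

    # a taxon detected in a single sample is dropped and listed
    m2 <- m; m2["t3", 1] <- 4L
    bound2 <- fractionCountTable(m2, grp, "bound", "IgG")
    st2 <- scoreTable(bound2, unboundSame, minPrevalence = 2)
    expect_false("t3" %in% taxa(st2))
    expect_identical(S4Vectors::metadata(st2)$dropped, "t3")

    # sample mismatch is a labelled error
    colnames(m2) <- c("s1", "sX")
    expect_error(scoreTable(fractionCountTable(m2, grp, "bound", "IgG"),
        unboundSame), class = "wildIg_sample_mismatch")
})

test_that("swapping bound and unbound negates every score", {
    sim <- presetIgseq()
    st <- scoreTable(sim$IgM$bound, sim$IgM$unbound)
    rev <- scoreTable(sim$IgM$unbound, sim$IgM$bound)
    expect_equal(scores(st), -scores(rev))
})

test_that("scores are nearly invariant to sequencing depth rescaling", {
    m <- matrix(c(4000L, 1000L, 5000L, 2000L, 3000L, 5000L), 3,
        dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
    grp <- c("laboratory", "rewilded")
    um <- matrix(c(2000L, 3000L, 5000L, 4000L, 1000L, 5000L), 3,
        dimnames = dimnames(m))
    st1 <- scoreTable(fractionCountTable(m, grp, "bound", "IgG"),
        fractionCountTable(um, grp, "unbound", "IgG"), minPrevalence = 1)
    st10 <- scoreTable(fractionCountTable(m * 10L, grp, "bound", "IgG"),
        fractionCountTable(um, grp, "unbound", "IgG"), minPrevalence = 1)
    expect_lt(max(abs(scores(st1) - scores(st10))), 0.01)
})

test_that("Mann-Whitney U enumerates the exact two-sided null", {
    r <- mannWhitneyU(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)
    expect_equal(r$P, 1 / 3)
    # complete separation with ties: C(8,4) = 70 assignments, 2 extreme
    r2 <- mannWhitneyU(c(0, 0, 0, 0), c(1, 1, 1, 1))
    expect_equal(r2$P, 2 / 70)
    # matches wilcox.test exactly in the tie-free case
    set.seed(4)
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(mannWhitneyU(x, y)$P,
        wilcox.test(x, y, exact = TRUE)$p.value)
    # large samples fall back to the tie-corrected normal approximation
    r3 <- mannWhitneyU(rnorm(10), rnorm(10))
    expect_identical(r3$method, "normal_approximation")
})

test_that("taxon tests report group fold differences and exact P values", {
    m <- rbind(tA = c(1, 2, 3, 4), tB = c(5, 5, 5, 5))
    colnames(m) <- paste0("s", 1:4)
    grp <- c("laboratory", "laboratory", "rewilded", "rewilded")
    tt <- taxonTests(m, grp)
    expect_equal(tt$meanFoldDifference[tt$taxon == "tA"], 2)
    expect_equal(tt$U[tt$taxon == "tA"], 0)       # laboratory always lower
    expect_equal(tt$P[tt$taxon == "tA"], 1 / 3)
    expect_equal(tt$meanFoldDifference[tt$taxon == "tB"], 0)
    expect_equal(tt$P[tt$taxon == "tB"], 1)
    expect_error(taxonTests(m, c("laboratory", rep("rewilded", 3))),
        class = "wildIg_small_group")
})

test_that("abundance/score pairs line up per taxon and group", {
    m <- matrix(c(3L, 7L, 3L, 7L), 2,
        dimnames = list(c("t1", "t2"), c("s1", "s2")))
    grp <- c("laboratory", "rewilded")
    input <- fractionCountTable(m, grp, "input", "none")
    bound <- fractionCountTable(m, grp, "bound", "IgG")
    st <- scoreTable(bound, fractionCountTable(m, grp, "unbound", "IgG"),
        minPrevalence = 1)
    pairs <- abundanceScorePairs(input, st, eps = 0)
    expect_equal(nrow(pairs), 4L)
    expect_equal(pairs$meanAbundance[pairs$taxon == "t1"], c(0.3, 0.3))
    expect_true(all(pairs$meanScore == 0))

    # simulated preset: taxa with raised rewilded IgM binding score higher
    sim <- presetIgseq()
    stM <- scoreTable(sim$IgM$bound, sim$IgM$unbound)
    pp <- abundanceScorePairs(sim$input, stM)
    raised <- rownames(sim$truth$bindingProb$IgM)[
        sim$truth$bindingProb$IgM[, "rewilded"] >
            sim$truth$bindingProb$IgM[, "laboratory"]]
    raised <- intersect(raised, pp$taxon)
    dScore <- sapply(raised, function(t)
        pp$meanScore[pp$taxon == t & pp$group == "rewilded"] -
        pp$meanScore[pp$taxon == t & pp$group == "laboratory"])
    expect_true(all(dScore > 0))

    # disjoint taxa warn and return empty
    rownames(m) <- c("x1", "x2")
    other <- fractionCountTable(m, grp, "input", "none")
    expect_warning(out <- abundanceScorePairs(other, st),
        class = "wildIg_empty_intersection")
    expect_equal(nrow(out), 0L)
})
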