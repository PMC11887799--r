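test_that("mutation frequencies count informative mismatches only", {
    germ <- strrep("A", 300)
    seq3 <- germ
    for (p in c(10, 20, 30)) substr(seq3, p, p) <- "G"
    df <- makeRecords("TGTGCA", sequence_alignment = seq3,
        germline_alignment = germ)
    prof <- mutationProfile(rearrangementSet(df))
    expect_equal(prof$frequency, 0.01)           # 3 / 300

    # identical sequences have zero frequency
    df0 <- makeRecords("TGTGCA", sequence_alignment = germ,
        germline_alignment = germ)
    expect_equal(mutationProfile(rearrangementSet(df0))$frequency, 0)

    # gaps and N positions are non-informative: 3 / 300 despite length 310
    germ310 <- paste0(strrep("A", 300), strrep(".", 10))
    seq310 <- paste0(seq3, strrep(".", 10))
    substr(seq310, 5, 5) <- "N"; substr(germ310, 5, 5) <- "N"
    # one more informative position lost at 5 -> 3 mutations / 299
    df310 <- makeRecords("TGTGCA", sequence_alignment = seq310,
        germline_alignment = germ310)
    p310 <- mutationProfile(rearrangementSet(df310))
    expect_equal(p310$informative, 299)
    expect_equal(p310$mutations, 3)

    allN <- makeRecords("TGTGCA", sequence_alignment = strrep("N", 10),
        germline_alignment = strrep("N", 10))
    expect_error(mutationProfile(rearrangementSet(allN)),
        class = "wildIg_no_informative")
})

test_that("clone median frequency is the member median", {
    prof <- data.frame(sequence_id = paste0("s", 1:5),
        frequency = c(0.01, 0.03, 0.05, 0.2, 0.4))
    clones <- setNames(c("k1", "k1", "k1", "k2", "k2"), paste0("s", 1:5))
    med <- cloneMedianFrequency(prof, clones)
    expect_equal(med$medianFrequency[med$clone_id == "k1"], 0.03)
    expect_equal(med$medianFrequency[med$clone_id == "k2"], 0.3)
    expect_equal(med$n, c(3L, 2L))
})

test_that("KS statistic follows the ECDF supremum", {
    expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$D, 0)
    expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$P, 1)
    expect_equal(ksCompare(c(1, 2, 3), c(4, 5, 6))$D, 1)
    expect_equal(ksCompare(c(1, 3), c(2, 4))$D, 0.5)
    expect_error(ksCompare(1, c(1, 2)), class = "wildIg_small_sample")
    # exact small-sample P agrees with full enumeration
    a <- c(0.1, 0.9, 1.7); b <- c(0.4, 2.2, 3.1)
    expect_equal(ksCompare(a, b, exact = TRUE)$P, bruteKS(a, b)$P)
})

test_that("Simpson index follows the closed form and bounds richness", {
    expect_equal(simpsonIndex(c(1, 1, 1, 1)), 4)
    expect_equal(simpsonIndex(c(2, 1, 1)), 8 / 3)
    expect_equal(simpsonIndex(c(2, 1, 1), form = "gini"), 1 - 0.375)
    skip_if_not_installed("vegan")
    set.seed(8)
    for (i in 1:10) {
        sizes <- sample(1:40, sample(2:15, 1), replace = TRUE)
        expect_equal(simpsonIndex(sizes),
            unname(vegan::diversity(sizes, index = "invsimpson")))
        # inverse Simpson never exceeds richness; equality iff uniform
        expect_lte(simpsonIndex(sizes), length(sizes) + 1e-12)
    }
    expect_lt(simpsonIndex(c(5, 1)), 2)
})

test_that("bootstrap diversity deltas are symmetric for identical groups", {
    set.seed(6)
    clones <- sample(sprintf("k%02d", 1:30), 400, replace = TRUE)
    group <- rep(c("laboratory", "rewilded"), each = 200)
    # same clone pool in both groups: delta distribution centered at 0
    dp <- cloneDiversity(clones, group, nBoot = 300, seed = 17)
    ci <- dp@deltaCI
    expect_lt(ci[1, "invSimpson"], 0)
    expect_gt(ci[2, "invSimpson"], 0)
    expect_lt(abs(mean(dp@delta[, "richness"])), 2)
    # replicates reproduce bit-exactly under the same seed
    dp2 <- cloneDiversity(clones, group, nBoot = 300, seed = 17)
    expect_identical(dp@replicates, dp2@replicates)
    expect_warning(cloneDiversity(clones, group, nBoot = 50, seed = 1),
        class = "wildIg_few_bootstrap")
})

test_that("constant-region usage is per-group frequency among called", {
    df <- makeRecords(rep("TGTGCA", 4),
        c_call = c("IGHM", "IGHM", "IGHD", "IGHG1"),
        sequence_id = paste0("s", 1:4))
    u <- constantRegionUsage(rearrangementSet(df))
    expect_equal(u$usage$frequency[u$usage$isotype == "IGHM"], 0.5)
    expect_equal(u$usage$frequency[u$usage$isotype == "IGHD"], 0.25)
    expect_equal(sum(u$uncalled), 0)

    dfNA <- makeRecords(rep("TGTGCA", 3), c_call = "",
        sequence_id = paste0("n", 1:3))
    u2 <- constantRegionUsage(rearrangementSet(dfNA))
    expect_equal(nrow(u2$usage), 0L)
    expect_equal(unname(u2$uncalled["laboratory"]), 3)

    # simulator preset raises IGHD in the rewilded group
    x <- presetRepertoire()
    u3 <- constantRegionUsage(x)$usage
    fD <- function(g) u3$frequency[u3$group == g & u3$isotype == "IGHD"]
    expect_gt(fD("rewilded"), fD("laboratory"))
    expect_lt(abs(fD("rewilded") - 0.25), 0.05)   # preset weights
    expect_lt(abs(fD("laboratory") - 0.12), 0.05)
})

test_that("network edges join same-clone cells within the threshold", {
    base <- strrep("A", 50)
    b <- base; substr(b, 1, 1) <- "T"
    df <- makeRecords(c(base, base, b, strrep("G", 50)),
        sequence_id = sprintf("s%d", 1:4))
    df$clone_id <- c("k1", "k1", "k1", "k2")
    net <- buildNetwork(rearrangementSet(df), threshold = 0.03)
    expect_equal(nrow(net@nodes), 4L)
    expect_equal(nrow(net@edges), 3L)  # triangle within k1, k2 isolated
    expect_true(all(net@edges$node1 < net@edges$node2))

    # theta = 0 with identical junctions: complete within-clone graph
    df0 <- makeRecords(rep(base, 4), sequence_id = sprintf("t%d", 1:4))
    df0$clone_id <- "k1"
    net0 <- buildNetwork(rearrangementSet(df0), threshold = 0)
    expect_equal(nrow(net0@edges), 6L)

    # all-singleton clones give an edgeless graph over all cells
    df1 <- makeRecords(c("AAAA", "CCCC", "GGGG"),
        sequence_id = sprintf("u%d", 1:3))
    df1$clone_id <- sprintf("k%d", 1:3)
    net1 <- buildNetwork(rearrangementSet(df1), threshold = 0.5)
    expect_equal(nrow(net1@edges), 0L)
    expect_equal(nrow(net1@nodes), 3L)

    # edge count equals the brute-force within-clone pair count
    x <- simulateRepertoire(repertoireConfig(nCells = c(laboratory = 60L),
        mu = 0.02, corruptionRate = 0, duplicateRate = 0), seed = 9)
    ca <- assignClones(x, 0.1)
    netS <- buildNetwork(x, ca, threshold = 0.1)
    df6 <- as.data.frame(rearrangements(x))
    df6$clone_id <- unname(cloneIds(ca)[df6$sequence_id])
    want <- 0L
    for (k in unique(df6$clone_id)) {
        idx <- which(df6$clone_id == k)
        if (length(idx) < 2) next
        for (i in seq_len(length(idx) - 1)) for (j in seq.int(i + 1,
            length(idx)))
            if (junctionDistance(df6$junction[idx[i]],
                                 df6$junction[idx[j]]) <= 0.1)
                want <- want + 1L
    }
    expect_equal(nrow(netS@edges), want)
    # igraph view matches
    g <- asIgraph(netS)
    expect_equal(igraph::gsize(g), want)
})
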