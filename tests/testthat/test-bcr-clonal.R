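test_that("qc filter applies the six-rule cascade", {
    aln270 <- strrep("ACG", 90)
    good <- makeRecords("TGTGCAGCAGCT", sequence_alignment = aln270)
    tooN <- good
    tooN$sequence_alignment <- paste0(strrep("N", 12),
        substr(aln270, 13, 270))
    len13 <- makeRecords("TGTGCAGCAGCTA"[1],
        sequence_alignment = aln270)  # length 13, not divisible by 3
    chain <- good; chain$j_call <- "IGKJ1*01"
    noV <- good; noV$v_call <- ""
    withN <- good; withN$junction <- "TGTGCAGCANCT"
    nonprod <- good; nonprod$productive <- FALSE
    df <- rbind(good, tooN, len13, chain, noV, withN, nonprod)
    df$sequence_id <- sprintf("s%02d", seq_len(nrow(df)))
    df$cell_id <- paste0("c", df$sequence_id)
    res <- qcFilter(rearrangementSet(df))
    rep <- as.data.frame(res$report@perRecord)
    expect_identical(rep$pass,
        c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
    expect_identical(rep$reasons[2], "too_many_N")
    expect_identical(rep$reasons[3], "cdr3_len_not_div3")
    expect_identical(rep$reasons[4], "chain_inconsistent")
    expect_identical(rep$reasons[5], "missing_vj")
    expect_identical(rep$reasons[6], "cdr3_has_N")
    expect_identical(rep$reasons[7], "nonproductive")
    expect_length(res$set, 1L)

    # exactly 9 N positions still passes (rule is "fewer than 10")
    nineN <- good
    nineN$sequence_alignment <- paste0(strrep("N", 9),
        substr(aln270, 10, 270))
    expect_true(as.data.frame(qcFilter(
        rearrangementSet(nineN))$report@perRecord)$pass)
})

test_that("qc pass-set is the intersection of the individual rules", {
    x <- presetRepertoire()
    res <- qcFilter(x)
    rep <- as.data.frame(res$report@perRecord)
    fails <- strsplit(rep$reasons, ",", fixed = TRUE)
    expect_identical(rep$pass, lengths(fails) == 0L |
        vapply(fails, function(f) all(f == ""), logical(1)))
    expect_identical(sum(rep$pass), length(res$set))
})

test_that("partitions key on allele-stripped genes and junction length", {
    df <- rbind(
        makeRecords("TGTGCAGCAGCT", v_call = "IGHV1-26*01",
            sequence_id = "a"),
        makeRecords("TGTGCAGCAGCA", v_call = "IGHV1-26*02",
            sequence_id = "b"),
        makeRecords("TGTGCAGCAGCTGCA", v_call = "IGHV1-26*01",
            sequence_id = "c"),
        makeRecords("TGTGCAGCAGCG", v_call = "IGHV1-26*01,IGHV1-2*01",
            sequence_id = "d"))
    parts <- partitionRearrangements(rearrangementSet(df))
    expect_length(parts, 2L)                    # lengths 12 and 15
    expect_length(parts[["IGHV1-26|IGHJ1|12"]], 3L)  # alleles + first gene
    expect_length(parts[["IGHV1-26|IGHJ1|15"]], 1L)
    expect_identical(partitionRearrangements(
        rearrangementSet(df[0, ])), list())
})

test_that("junction distance is normalized Hamming with N exclusion", {
    expect_equal(junctionDistance("AAAA", "AAAT"), 0.25)
    expect_equal(junctionDistance("AAAA", "AAAA"), 0)
    expect_equal(junctionDistance("AANA", "AATA"), 0)   # 0 over 3 positions
    expect_equal(junctionDistance("AANT", "AATA"), 1 / 3)
    expect_error(junctionDistance("AAA", "AAAA"),
        class = "wildIg_length_mismatch")
})

test_that("nearest-neighbor distances take partition-wise minima", {
    df <- rbind(
        makeRecords(c("AAAAAAAAAA", "AAAAAAAAAT"),
            sequence_id = c("p1", "p2")))
    nn <- nearestNeighborDistances(rearrangementSet(df))
    expect_equal(sort(distances(nn)), c(0.1, 0.1))

    # {A,B,C}: d(A,B)=0.02 (1/50), d(A,C)=d(B,C)=0.3 -> minima (.02,.02,.3)
    base <- strrep("A", 50)
    b <- base; substr(b, 1, 1) <- "T"
    c3 <- base
    for (i in 1:15) substr(c3, i + 10, i + 10) <- "G"
    df2 <- makeRecords(c(base, b, c3), sequence_id = c("A", "B", "C"))
    nn2 <- nearestNeighborDistances(rearrangementSet(df2))
    expect_equal(sort(distances(nn2)), c(0.02, 0.02, 0.3))

    # all singletons: empty distribution with a warning
    df3 <- makeRecords(c("AAAA", "AAAAAAA"), sequence_id = c("x", "y"))
    expect_warning(nn3 <- nearestNeighborDistances(rearrangementSet(df3)),
        class = "wildIg_no_neighbors")
    expect_length(distances(nn3), 0L)
})

test_that("threshold estimation finds the between-mode crossing", {
    set.seed(17)
    d <- c(pmin(pmax(rnorm(500, 0.01, 0.005), 0), 1),
           rnorm(500, 0.20, 0.05))
    est <- estimateThreshold(d, seed = 17)
    expect_gt(threshold(est), 0.03)
    expect_lt(threshold(est), 0.10)
    # scaling both modes scales the threshold accordingly
    est2 <- estimateThreshold(d * 2, seed = 17)
    expect_gt(threshold(est2), threshold(est))
    expect_equal(threshold(est2) / threshold(est), 2, tolerance = 0.25)
    # a single tight mode is rejected with advice
    set.seed(17)
    expect_error(estimateThreshold(rnorm(300, 0.25, 0.02), seed = 17),
        class = "wildIg_unimodal")
    expect_error(estimateThreshold(runif(10)),
        class = "wildIg_too_few_distances")
})

test_that("single linkage at the cut equals threshold-graph components", {
    # chaining: d(A,B)=d(B,C)=0.02, d(A,C)=0.04, cut 0.03 -> one clone
    base <- strrep("A", 100)
    b <- base; substr(b, 1, 2) <- "TT"
    c3 <- base; substr(c3, 3, 4) <- "GG"
    # A-B 0.02, A-C 0.02? need d(A,B)=0.02, d(B,C)=0.02, d(A,C)=0.04
    b2 <- base; substr(b2, 1, 2) <- "TT"          # A vs b2: 2 diffs
    c2 <- base; substr(c2, 1, 4) <- "TTGG"        # A vs c2: 4; b2 vs c2: 2
    df <- makeRecords(c(base, b2, c2), sequence_id = c("A", "B", "C"))
    ca <- assignClones(rearrangementSet(df), threshold = 0.03)
    expect_length(unique(cloneIds(ca)), 1L)

    # far pair stays apart
    far <- makeRecords(c(strrep("A", 8), strrep("T", 8)),
        sequence_id = c("A", "B"))
    ca2 <- assignClones(rearrangementSet(far), threshold = 0.03)
    expect_length(unique(cloneIds(ca2)), 2L)

    # clone membership never depends on record order
    x <- simulateRepertoire(repertoireConfig(nCells = c(laboratory = 80L),
        mu = 0.02, corruptionRate = 0, duplicateRate = 0), seed = 5)
    df5 <- as.data.frame(rearrangements(x))
    shuffled <- rearrangementSet(df5[rev(seq_len(nrow(df5))), ])
    expect_identical(
        cloneIds(assignClones(x, 0.1))[sort(df5$sequence_id)],
        cloneIds(assignClones(shuffled, 0.1))[sort(df5$sequence_id)])

    # raising the threshold never increases the number of clones
    nClones <- vapply(c(0.02, 0.1, 0.3, 0.6), function(th)
        length(unique(cloneIds(assignClones(x, th)))), numeric(1))
    expect_true(all(diff(nClones) <= 0))
})

test_that("clones equal brute-force connected components on random sets", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(5:30, 1)
        len <- 12L
        seeds <- vapply(1:3, function(i) paste(sample(c("A", "C", "G", "T"),
            len, replace = TRUE), collapse = ""), character(1))
        juncs <- vapply(seq_len(n), function(i) {
            s <- sample(seeds, 1)
            nMut <- sample(0:4, 1)
            if (nMut > 0) for (p in sample(len, nMut))
                substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
            s
        }, character(1))
        x <- rearrangementSet(makeRecords(juncs,
            sequence_id = sprintf("s%02d", seq_len(n))))
        th <- runif(1, 0.05, 0.4)
        got <- cloneIds(assignClones(x, th))
        D <- outer(juncs, juncs, Vectorize(junctionDistance))
        want <- bruteComponents(D, th)
        expect_equal(ariIndex(got[sprintf("s%02d", seq_len(n))], want), 1)
    }
})

test_that("duplicate collapse respects compartment and isotype boundaries", {
    aln <- strrep("ACGT", 25)
    df <- rbind(
        makeRecords(c("TGTGCA", "TGTGCA"), sequence_alignment = aln,
            c_call = "IGHM", compartment = "naive",
            sequence_id = c("s1", "s2")),
        makeRecords(c("TGTGCA", "TGTGCA"), sequence_alignment = aln,
            c_call = c("IGHM", "IGHG1"), compartment = "naive",
            sequence_id = c("s3", "s4")))
    df$clone_id <- "clone1"
    x <- rearrangementSet(df)
    out <- rearrangements(collapseDuplicates(x))
    # s1+s2+s3 merge (same clone/alignment/compartment/isotype); s4 kept
    expect_equal(nrow(out), 2L)
    expect_identical(out$sequence_id, c("s1", "s4"))
    expect_identical(out$duplicate_count, c(3L, 1L))

    # no duplicates: set unchanged apart from the added count column
    df2 <- makeRecords(c("AAACCC", "GGGTTT"), sequence_id = c("u1", "u2"))
    df2$clone_id <- c("k1", "k2")
    out2 <- rearrangements(collapseDuplicates(rearrangementSet(df2)))
    expect_equal(nrow(out2), 2L)
    expect_true(all(out2$duplicate_count == 1L))
})
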