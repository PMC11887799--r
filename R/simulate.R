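#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

## ---------------------------------------------------------------------------
## Ig-seq sorting simulator
## ---------------------------------------------------------------------------

#' Configuration for the Ig-seq sorting simulator
#'
#' Describes a two-group (laboratory vs rewilded) antibody-sorting experiment:
#' per-group community composition, per-taxon antibody binding probabilities
#' for each antibody class, sequencing depth per fraction and per-sample
#' compositional overdispersion. The sorting model splits each community into
#' exactly complementary bound/unbound partitions in expectation: for binding
#' probability \eqn{b_t} and abundance \eqn{a_t}, bound-fraction proportions
#' are proportional to \eqn{a_t b_t} and unbound to \eqn{a_t (1 - b_t)}.
#'
#' @param nPerGroup samples per group.
#' @param baseAbundance taxa x group matrix of proportions (columns sum to 1).
#' @param bindingProb named list, one taxa x group matrix per antibody class
#'   (\code{IgG}, \code{IgM}); entries strictly inside (0, 1).
#' @param readsPerFraction sequencing depth N per fraction per sample.
#' @param dirichletConcentration per-sample compositions are drawn from a
#'   Dirichlet with this total concentration around the group base; larger
#'   means less sample-to-sample variation.
#' @param lineage semicolon-delimited taxonomy strings, one per taxon.
#' @return a validated config (class \code{IgseqSimConfig}).
#' @seealso [igseqPreset()] for the default community, [simulateIgSeq()].
#' @export
igseqConfig <- function(nPerGroup, baseAbundance, bindingProb,
                        readsPerFraction = 50000L,
                        dirichletConcentration = 200,
                        lineage = NULL) {
    nPerGroup <- .checkCount(nPerGroup, "nPerGroup")
    readsPerFraction <- .checkCount(readsPerFraction, "readsPerFraction")
    baseAbundance <- as.matrix(baseAbundance)
    if (is.null(colnames(baseAbundance)))
        colnames(baseAbundance) <- .GROUPS[seq_len(ncol(baseAbundance))]
    if (any(baseAbundance < 0) ||
        any(abs(colSums(baseAbundance) - 1) > 1e-8))
        .wildStop("bad_abundance",
            "abundances must be non-negative and sum to 1 per group")
    for (cls in names(bindingProb)) {
        b <- bindingProb[[cls]]
        if (any(b <= 0) || any(b >= 1))
            .wildStop("degenerate_config", "binding probabilities for ", cls,
                " must lie strictly inside (0, 1)")
    }
    if (is.null(lineage))
        lineage <- rownames(baseAbundance)
    structure(list(nPerGroup = nPerGroup, baseAbundance = baseAbundance,
        bindingProb = bindingProb, readsPerFraction = readsPerFraction,
        dirichletConcentration = dirichletConcentration, lineage = lineage),
        class = "IgseqSimConfig")
}

#' Default Ig-seq community preset
#'
#' A 30-taxon mouse gut community across six orders. The rewilded group
#' enriches the Clostridiales block (abundance doubled) and depletes
#' Erysipelotrichales (abundance x 0.4); IgM binding odds of the
#' Clostridiales block are raised threefold in rewilded animals, IgG binding
#' odds of Lactobacillaceae are raised and of Akkermansia lowered. Laboratory
#' abundances follow a Zipf-like 1/i^0.7 profile; binding probabilities are
#' spread over logit(-2.2 .. 2.2) in a fixed scrambled order so that binding
#' and abundance are unrelated.
#'
#' @param nPerGroup samples per group (default 8, the study design).
#' @param readsPerFraction reads per fraction per sample (default 50000).
#' @return an \code{IgseqSimConfig}.
#' @export
igseqPreset <- function(nPerGroup = 8L, readsPerFraction = 50000L) {
    fam <- c(rep("Lachnospiraceae", 6), rep("Ruminococcaceae", 5),
        rep("Clostridiaceae", 3), rep("Erysipelotrichaceae", 4),
        rep("Bacteroidaceae", 3), rep("Muribaculaceae", 3),
        rep("Lactobacillaceae", 3), "Akkermansiaceae",
        rep("Enterobacteriaceae", 2))
    genus <- c("Blautia", "Roseburia", "Dorea", "Coprococcus", "Anaerostipes",
        "Lachnoclostridium", "Ruminococcus", "Faecalibacterium",
        "Oscillibacter", "Ruminiclostridium", "Flavonifractor", "Clostridium",
        "Butyricicoccus", "Hungatella", "Turicibacter", "Allobaculum",
        "Faecalibaculum", "Dubosiella", "Bacteroides", "Phocaeicola",
        "Prevotella", "Muribaculum", "Duncaniella", "Paramuribaculum",
        "Lactobacillus", "Ligilactobacillus", "Limosilactobacillus",
        "Akkermansia", "Escherichia", "Klebsiella")
    higher <- c(
        Lachnospiraceae = "Bacteria;Firmicutes;Clostridia;Clostridiales",
        Ruminococcaceae = "Bacteria;Firmicutes;Clostridia;Clostridiales",
        Clostridiaceae = "Bacteria;Firmicutes;Clostridia;Clostridiales",
        Erysipelotrichaceae =
            "Bacteria;Firmicutes;Erysipelotrichia;Erysipelotrichales",
        Bacteroidaceae = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales",
        Muribaculaceae = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales",
        Lactobacillaceae = "Bacteria;Firmicutes;Bacilli;Lactobacillales",
        Akkermansiaceae =
            "Bacteria;Verrucomicrobiota;Verrucomicrobiae;Verrucomicrobiales",
        Enterobacteriaceae =
            "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales")
    lineage <- paste(higher[fam], fam, genus, sep = ";")
    n <- length(genus)
    clostridiales <- grepl("Clostridiales", lineage)
    erysipelo <- grepl("Erysipelotrichales", lineage)

    lab <- (1 / seq_len(n)^0.7)
    lab <- lab / sum(lab)
    rw <- lab * ifelse(clostridiales, 2, ifelse(erysipelo, 0.4, 1))
    rw <- rw / sum(rw)
    base <- cbind(laboratory = lab, rewilded = rw)
    rownames(base) <- genus

    ## fixed scrambles (multiplicative bijections mod 31) decorrelate binding
    ## rank from abundance rank
    spread <- stats::plogis(seq(-2.2, 2.2, length.out = n))
    permG <- order((7L * seq_len(n)) %% 31L)
    permM <- order((11L * seq_len(n)) %% 31L)
    oddsMul <- function(b, f) stats::plogis(stats::qlogis(b) + log(f))
    bG <- spread[permG]
    bGrw <- oddsMul(bG, ifelse(fam == "Lactobacillaceae", 2.5,
        ifelse(genus == "Akkermansia", 0.35, 1)))
    bM <- spread[permM]
    bMrw <- oddsMul(bM, ifelse(clostridiales, 3, 1))
    binding <- list(
        IgG = cbind(laboratory = bG, rewilded = bGrw),
        IgM = cbind(laboratory = bM, rewilded = bMrw))
    for (i in seq_along(binding)) rownames(binding[[i]]) <- genus

    igseqConfig(nPerGroup = nPerGroup, baseAbundance = base,
        bindingProb = binding, readsPerFraction = readsPerFraction,
        lineage = lineage)
}

#' Simulate an Ig-seq sorting experiment
#'
#' For every sample, a community composition is drawn from a Dirichlet around
#' its group base; the pre-sort \code{input} fraction is a multinomial of
#' depth N from that composition, and for each antibody class the \code{bound}
#' and \code{unbound} fractions are multinomials from the complementary
#' sorted compositions \eqn{a_t b_t} and \eqn{a_t (1-b_t)} (normalized).
#' Ground truth (group bases, per-sample compositions, binding probabilities)
#' is returned alongside.
#'
#' @param config an \code{IgseqSimConfig}, default [igseqPreset()].
#' @param seed integer seed; fixed seed gives identical tables.
#' @return a list with elements \code{input} (a
#'   [FractionCountTable-class]), one element per antibody class (each a list
#'   of \code{bound} and \code{unbound} tables), and \code{truth}.
#' @examples
#' sim <- simulateIgSeq(igseqPreset(nPerGroup = 2, readsPerFraction = 1000),
#'     seed = 17)
#' sim$IgG$bound
#' @export
simulateIgSeq <- function(config = igseqPreset(), seed = 17L) {
    stopifnot(inherits(config, "IgseqSimConfig"))
    set.seed(as.integer(seed))
    base <- config$baseAbundance
    groups <- colnames(base)
    nTaxa <- nrow(base)
    npg <- config$nPerGroup
    N <- config$readsPerFraction
    sampleNames <- unlist(lapply(seq_along(groups), function(g)
        sprintf("%s%02d", substr(groups[g], 1L, 3L), seq_len(npg))))
    sampleGroup <- rep(groups, each = npg)

    sampleAb <- matrix(0, nTaxa, length(sampleNames),
        dimnames = list(rownames(base), sampleNames))
    for (j in seq_along(sampleNames))
        sampleAb[, j] <- .rdirichlet(1L,
            config$dirichletConcentration * base[, sampleGroup[j]])[1L, ]

    drawFraction <- function(probFun) {
        m <- vapply(seq_along(sampleNames), function(j)
            stats::rmultinom(1L, N, probFun(j))[, 1L], integer(nTaxa))
        dimnames(m) <- dimnames(sampleAb)
        m
    }
    mk <- function(m, fraction, cls) fractionCountTable(m,
        group = sampleGroup, fraction = fraction, antibodyClass = cls,
        lineage = config$lineage)

    out <- list(input = mk(drawFraction(function(j) sampleAb[, j]),
        "input", "none"))
    for (cls in names(config$bindingProb)) {
        b <- config$bindingProb[[cls]]
        bj <- function(j) b[, sampleGroup[j]]
        bound <- drawFraction(function(j) {
            p <- sampleAb[, j] * bj(j); p / sum(p)
        })
        unbound <- drawFraction(function(j) {
            p <- sampleAb[, j] * (1 - bj(j)); p / sum(p)
        })
        out[[cls]] <- list(bound = mk(bound, "bound", cls),
                           unbound = mk(unbound, "unbound", cls))
    }
    out$truth <- list(baseAbundance = base, sampleAbundance = sampleAb,
        bindingProb = config$bindingProb,
        group = stats::setNames(sampleGroup, sampleNames))
    out
}

## ---------------------------------------------------------------------------
## BCR repertoire simulator
## ---------------------------------------------------------------------------

#' Configuration for the BCR repertoire simulator
#'
#' Clones are drawn with sizes from a truncated power law; each clone carries
#' one unexposed germline (V/J calls, junction embedded in a full-length
#' alignment) and its members accumulate independent per-site Bernoulli
#' substitutions at the group's hypermutation rate over the whole alignment.
#' Junctions of distinct clones sharing a V/J/length partition are kept at
#' least \code{minJunctionSeparation} apart, so true clones are unambiguous.
#' A small fraction of records is corrupted to exercise quality control, and
#' a small fraction is duplicated verbatim to exercise duplicate collapse.
#'
#' @param nCells named integer vector of cells per group.
#' @param mu named per-site hypermutation rate per group, each in [0, 0.2].
#' @param vGenes,jGenes named usage weights (normalized internally).
#' @param junctionLengths named weights over junction nucleotide lengths
#'   (names must be multiples of 3).
#' @param cloneSizeExponent power-law exponent of the clone-size law.
#' @param maxCloneSize truncation of the clone-size law.
#' @param isotypeProb isotype x group matrix of constant-region usage weights.
#' @param compartmentProb named weights over B cell compartments.
#' @param alignmentLength length of the simulated gapless V(D)J alignment.
#' @param corruptionRate fraction of records given a QC defect.
#' @param duplicateRate fraction of records duplicated verbatim.
#' @param nSubjectsPerGroup subjects per group (clones nest in subjects).
#' @param minJunctionSeparation minimum normalized Hamming distance between
#'   germline junctions of distinct clones in the same partition.
#' @return a validated config (class \code{RepertoireSimConfig}).
#' @seealso [repertoirePreset()], [simulateRepertoire()]
#' @export
repertoireConfig <- function(nCells, mu,
        vGenes = NULL, jGenes = NULL, junctionLengths = NULL,
        cloneSizeExponent = 2.5, maxCloneSize = 100L,
        isotypeProb = NULL, compartmentProb = NULL,
        alignmentLength = 300L, corruptionRate = 0.02,
        duplicateRate = 0.02, nSubjectsPerGroup = 4L,
        minJunctionSeparation = 0.3) {
    if (is.null(names(nCells)))
        names(nCells) <- .GROUPS[seq_along(nCells)]
    groups <- names(nCells)
    mu <- rep_len(mu, length(groups))
    names(mu) <- groups
    if (any(mu < 0) || any(mu > 0.2))
        .wildStop("bad_mu", "hypermutation rate must lie in [0, 0.2]")
    norm <- function(w) w / sum(w)
    if (is.null(vGenes)) {
        v <- paste0("IGHV", c("1-11", "1-26", "1-53", "1-72", "1-81", "2-2",
            "3-6", "5-17", "6-6", "8-8", "9-3", "10-1", "11-2", "12-3",
            "14-2"))
        vGenes <- stats::setNames(1 / seq_along(v)^0.5, v)
    }
    if (is.null(jGenes))
        jGenes <- c(IGHJ1 = 0.15, IGHJ2 = 0.3, IGHJ3 = 0.3, IGHJ4 = 0.25)
    if (is.null(junctionLengths)) {
        L <- seq(30L, 60L, by = 3L)
        junctionLengths <- stats::setNames(stats::dnorm(L, 45, 7), L)
    }
    if (any(as.integer(names(junctionLengths)) %% 3L != 0L))
        .wildStop("bad_argument", "junction lengths must be multiples of 3")
    if (is.null(isotypeProb)) {
        iso <- c("IGHM", "IGHD", "IGHG1", "IGHG2B", "IGHG2C", "IGHG3",
                 "IGHA")
        baseIso <- cbind(
            laboratory = c(0.55, 0.12, 0.08, 0.07, 0.06, 0.05, 0.07),
            rewilded = c(0.45, 0.25, 0.07, 0.06, 0.05, 0.04, 0.08))
        rownames(baseIso) <- iso
        isotypeProb <- vapply(groups, function(g)
            if (g %in% colnames(baseIso)) baseIso[, g]
            else baseIso[, "laboratory"], numeric(nrow(baseIso)))
        rownames(isotypeProb) <- iso
    }
    isotypeProb <- as.matrix(isotypeProb)
    if (is.null(compartmentProb))
        compartmentProb <- c(naive = 0.5, memory = 0.2,
                             germinal_center = 0.15, plasma = 0.15)
    structure(list(nCells = as.integer(nCells) |> stats::setNames(groups),
        mu = mu, vGenes = norm(vGenes), jGenes = norm(jGenes),
        junctionLengths = norm(junctionLengths),
        cloneSizeExponent = cloneSizeExponent,
        maxCloneSize = as.integer(maxCloneSize),
        isotypeProb = apply(isotypeProb, 2L, norm),
        compartmentProb = norm(compartmentProb),
        alignmentLength = .checkCount(alignmentLength, "alignmentLength"),
        corruptionRate = corruptionRate, duplicateRate = duplicateRate,
        nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
        minJunctionSeparation = minJunctionSeparation),
        class = "RepertoireSimConfig")
}

#' Default repertoire preset
#'
#' Two groups sized to the captured productive heavy chains of the study
#' design (1381 laboratory, 1178 rewilded cells), per-site hypermutation rate
#' 0.010 (laboratory) vs 0.013 (rewilded), and a raised IGHD constant-region
#' weight in the rewilded group.
#'
#' @param ... overrides passed to [repertoireConfig()].
#' @return a \code{RepertoireSimConfig}.
#' @export
repertoirePreset <- function(...) {
    args <- list(...)
    defaults <- list(nCells = c(laboratory = 1381L, rewilded = 1178L),
        mu = c(laboratory = 0.010, rewilded = 0.013))
    do.call(repertoireConfig, utils::modifyList(defaults, args))
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

.mutateSeq <- function(seq, mu) {
    if (mu <= 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(chars)) < mu)
    for (i in hit)
        chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
    paste(chars, collapse = "")
}

.hamming <- function(a, b) {
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    sum(av != bv) / length(av)
}

#' Simulate a clonally expanded BCR repertoire
#'
#' See [repertoireConfig()] for the generative model. The returned set carries
#' the usual AIRR columns plus \code{compartment}, \code{subject},
#' \code{group}, the generator's \code{true_clone_id}, and \code{qc_defect}
#' (empty for clean records; one of the six QC failure labels for corrupted
#' ones).
#'
#' @param config a \code{RepertoireSimConfig}, default [repertoirePreset()].
#' @param seed integer seed.
#' @return a [RearrangementSet-class].
#' @examples
#' rep0 <- simulateRepertoire(repertoireConfig(
#'     nCells = c(laboratory = 50), mu = 0), seed = 17)
#' rep0
#' @export
simulateRepertoire <- function(config = repertoirePreset(), seed = 17L) {
    stopifnot(inherits(config, "RepertoireSimConfig"))
    set.seed(as.integer(seed))
    alignLen <- config$alignmentLength
    maxL <- max(as.integer(names(config$junctionLengths)))
    jStart <- alignLen - maxL - 10L
    if (jStart < 1L)
        .wildStop("bad_argument",
            "alignmentLength too short for the junction length distribution")
    rows <- list()
    seqCounter <- 0L
    for (g in names(config$nCells)) {
        nCells <- config$nCells[[g]]
        mu <- config$mu[[g]]
        sizes <- integer(0)
        szSupport <- seq_len(config$maxCloneSize)
        szProb <- szSupport^(-config$cloneSizeExponent)
        while (sum(sizes) < nCells)
            sizes <- c(sizes, sample(szSupport, 1L, prob = szProb))
        sizes[length(sizes)] <- nCells - sum(sizes[-length(sizes)])
        sizes <- sizes[sizes > 0L]
        partitions <- new.env(parent = emptyenv())
        for (k in seq_along(sizes)) {
            v <- sample(names(config$vGenes), 1L, prob = config$vGenes)
            j <- sample(names(config$jGenes), 1L, prob = config$jGenes)
            L <- as.integer(sample(names(config$junctionLengths), 1L,
                prob = config$junctionLengths))
            key <- paste(v, j, L, sep = "|")
            germ <- .randSeq(alignLen)
            for (try in seq_len(100L)) {
                junc <- substr(germ, jStart, jStart + L - 1L)
                others <- if (is.null(partitions[[key]])) character(0)
                          else partitions[[key]]
                if (!length(others) ||
                    min(vapply(others, .hamming, numeric(1), a = junc)) >=
                        config$minJunctionSeparation)
                    break
                substr(germ, jStart, jStart + L - 1L) <- .randSeq(L)
            }
            junc <- substr(germ, jStart, jStart + L - 1L)
            partitions[[key]] <- c(partitions[[key]], junc)
            cloneId <- sprintf("%s_clone%04d", g, k)
            subject <- sprintf("%s_subj%d", g,
                1L + (k - 1L) %% config$nSubjectsPerGroup)
            iso <- sample(rownames(config$isotypeProb), sizes[k],
                replace = TRUE, prob = config$isotypeProb[, g])
            comp <- sample(names(config$compartmentProb), sizes[k],
                replace = TRUE, prob = config$compartmentProb)
            for (m in seq_len(sizes[k])) {
                seqCounter <- seqCounter + 1L
                mutated <- .mutateSeq(germ, mu)
                rows[[seqCounter]] <- list(
                    sequence_id = sprintf("seq%06d", seqCounter),
                    cell_id = sprintf("cell%06d", seqCounter),
                    locus = "IGH",
                    v_call = paste0(v, "*01"),
                    j_call = paste0(j, "*01"),
                    junction = substr(mutated, jStart, jStart + L - 1L),
                    junction_length = L,
                    c_call = iso[m],
                    productive = TRUE,
                    sequence_alignment = mutated,
                    germline_alignment = germ,
                    compartment = comp[m],
                    subject = subject,
                    group = g,
                    true_clone_id = cloneId,
                    qc_defect = "")
            }
        }
    }
    df <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))

    ## verbatim duplicates (same compartment and isotype -> collapsible)
    nDup <- round(config$duplicateRate * nrow(df))
    if (nDup > 0L) {
        src <- sample(nrow(df), nDup, replace = FALSE)
        dup <- df[src, , drop = FALSE]
        dup$sequence_id <- sprintf("seq%06d", nrow(df) + seq_len(nDup))
        dup$cell_id <- sprintf("cell%06d", nrow(df) + seq_len(nDup))
        df <- rbind(df, dup)
    }

    ## QC defects, cycling through the six failure modes
    nBad <- round(config$corruptionRate * nrow(df))
    if (nBad > 0L) {
        bad <- sample(nrow(df), nBad, replace = FALSE)
        modes <- rep_len(c("nonproductive", "too_many_N", "cdr3_has_N",
            "cdr3_len_not_div3", "missing_vj", "chain_inconsistent"), nBad)
        for (i in seq_len(nBad)) {
            r <- bad[i]
            df$qc_defect[r] <- modes[i]
            switch(modes[i],
                nonproductive = { df$productive[r] <- FALSE },
                too_many_N = {
                    sa <- df$sequence_alignment[r]
                    pos <- sample(nchar(sa) - maxL - 10L, 12L)  # outside CDR3
                    for (p in pos) substr(sa, p, p) <- "N"
                    df$sequence_alignment[r] <- sa
                },
                cdr3_has_N = {
                    jn <- df$junction[r]
                    p <- sample(nchar(jn), 1L)
                    substr(jn, p, p) <- "N"
                    df$junction[r] <- jn
                },
                cdr3_len_not_div3 = {
                    df$junction[r] <- paste0(df$junction[r], "A")
                    df$junction_length[r] <- df$junction_length[r] + 1L
                },
                missing_vj = { df$v_call[r] <- "" },
                chain_inconsistent = { df$j_call[r] <- "IGKJ1*01" })
        }
    }
    rownames(df) <- NULL
    rearrangementSet(df)
}
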