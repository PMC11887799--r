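#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

#' Relative abundance with pseudocount
#'
#' Returns \code{(counts + eps) / sum(counts + eps)}; with \code{eps = 0} an
#' all-zero vector is an error.
#'
#' @param counts non-negative count vector.
#' @param eps pseudocount added to every count (default 1).
#' @return proportion vector summing to 1.
#' @examples
#' relativeAbundance(c(2, 3, 5), eps = 0)  # 0.2 0.3 0.5
#' @export
relativeAbundance <- function(counts, eps = 1) {
    if (any(counts < 0) || eps < 0)
        .wildStop("bad_counts", "counts and pseudocount must be non-negative")
    tot <- sum(counts + eps)
    if (tot == 0)
        .wildStop("all_zero",
            "all-zero counts with eps = 0; use a positive pseudocount")
    (counts + eps) / tot
}

#' Per-taxon antibody enrichment score
#'
#' The Ig score of a taxon is the log2 ratio of its relative abundance in the
#' antibody-bound fraction over the unbound fraction; positive scores mean
#' preferential antibody targeting.
#'
#' @param boundRel,unboundRel strictly positive proportion vectors over the
#'   same taxa.
#' @return per-taxon score vector, log2 units.
#' @examples
#' igScore(c(0.9, 0.1), c(0.5, 0.5))  # log2(1.8), log2(0.2)
#' @export
igScore <- function(boundRel, unboundRel) {
    if (length(boundRel) != length(unboundRel))
        .wildStop("taxon_mismatch", "vectors must cover the same taxa")
    if (any(boundRel <= 0) || any(unboundRel <= 0))
        .wildStop("zero_abundance",
            "zero relative abundance; renormalize with a positive pseudocount")
    log2(boundRel / unboundRel)
}

#' Score a bound/unbound fraction pair
#'
#' Applies [relativeAbundance()] then [igScore()] sample-wise to a matched
#' pair of bound/unbound count tables. Taxa detected (combined bound +
#' unbound count > 0) in fewer than \code{minPrevalence} samples are dropped
#' from the output and listed in \code{metadata(result)$dropped}.
#'
#' @param bound,unbound [FractionCountTable-class]s with identical taxa and
#'   samples.
#' @param eps pseudocount (default 1, Laplace smoothing).
#' @param minPrevalence minimum number of samples a taxon must be detected in
#'   (default 2).
#' @return an [IgScoreTable-class].
#' @export
scoreTable <- function(bound, unbound, eps = 1, minPrevalence = 2L) {
    if (!identical(colnames(bound), colnames(unbound)))
        .wildStop("sample_mismatch",
            "bound and unbound fractions must share samples")
    if (!identical(rownames(bound), rownames(unbound)))
        .wildStop("taxon_mismatch",
            "bound and unbound fractions must share taxa")
    if (eps <= 0)
        .wildStop("bad_argument", "scoreTable needs a positive pseudocount")
    bm <- assay(bound, "counts")
    um <- assay(unbound, "counts")
    detected <- rowSums(bm + um > 0)
    keep <- detected >= minPrevalence
    dropped <- rownames(bm)[!keep]
    if (length(dropped))
        .log("info", length(dropped), " taxa dropped by prevalence rule")
    s <- vapply(seq_len(ncol(bm)), function(j)
        igScore(relativeAbundance(bm[, j], eps),
                relativeAbundance(um[, j], eps)),
        numeric(nrow(bm)))
    dimnames(s) <- dimnames(bm)
    s <- s[keep, , drop = FALSE]
    se <- SummarizedExperiment(assays = list(scores = s),
        rowData = rowData(bound)[keep, , drop = FALSE],
        colData = colData(bound))
    out <- new("IgScoreTable", se, antibodyClass = antibodyClass(bound),
        pseudocount = eps, logBase = 2)
    metadata(out)$dropped <- dropped
    out
}

#' Exact and approximate two-sided Mann-Whitney U test
#'
#' U counts pairs where an \code{x} value exceeds a \code{y} value (ties
#' count one half). When \code{n1 * n2 <= exactMax} the two-sided P value is
#' computed by full enumeration of the \code{choose(n1 + n2, n1)} group
#' assignments of the pooled values (exact even under ties); otherwise the
#' normal approximation with tie correction is used.
#'
#' @param x,y numeric samples for the two groups.
#' @param exactMax largest \code{n1 * n2} for which the null is enumerated
#'   (default 64).
#' @return list with \code{U}, \code{P} and \code{method}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact P = 1/3
#' @export
mannWhitneyU <- function(x, y, exactMax = 64L) {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L)
        .wildStop("small_group", "each group needs at least 2 values")
    uStat <- function(a, b) {
        cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
        sum(cmp)
    }
    U <- uStat(x, y)
    if (n1 * n2 <= exactMax) {
        pool <- c(x, y)
        n <- n1 + n2
        idx <- utils::combn(n, n1)
        mid <- n1 * n2 / 2
        dObs <- abs(U - mid)
        Us <- vapply(seq_len(ncol(idx)), function(k) {
            a <- pool[idx[, k]]
            b <- pool[-idx[, k]]
            uStat(a, b)
        }, numeric(1))
        P <- mean(abs(Us - mid) >= dObs - 1e-12)
        list(U = U, P = P, method = "exact_enumeration")
    } else {
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
            correct = TRUE))
        list(U = U, P = wt$p.value, method = "normal_approximation")
    }
}

#' Per-taxon group tests on scores or abundances
#'
#' For every taxon (row), computes the mean fold difference between groups on
#' the log2 scale (mean of rewilded values minus mean of laboratory values)
#' and a two-sided Mann-Whitney U test, exact by null enumeration for small
#' designs (see [mannWhitneyU()]). Applied to Ig scores this contrasts
#' antibody targeting between environments; applied to log-scale input
#' relative abundances it contrasts community composition.
#'
#' @param values an [IgScoreTable-class], or a taxa x sample numeric matrix.
#' @param group per-sample labels (taken from the score table when omitted);
#'   exactly two levels, each with at least 2 samples.
#' @param reference the group subtracted in the fold difference (default
#'   \code{"laboratory"} when present, else the first level).
#' @param exactMax passed to [mannWhitneyU()].
#' @param adjust add a Benjamini-Hochberg adjusted column (default TRUE).
#' @param family optional per-taxon family annotation (taken from the score
#'   table's rowData when available).
#' @return data.frame: taxon, family, meanFoldDifference, U, P (and q).
#' @export
taxonTests <- function(values, group = NULL, reference = NULL,
                       exactMax = 64L, adjust = TRUE, family = NULL) {
    if (is(values, "SummarizedExperiment")) {
        if (is.null(group))
            group <- as.character(colData(values)$group)
        if (is.null(family) && "family" %in% colnames(rowData(values)))
            family <- rowData(values)$family
        values <- if (is(values, "IgScoreTable")) assay(values, "scores")
                  else assay(values, 1L)
    }
    group <- .checkGroups(group)
    lev <- unique(group)
    if (length(lev) != 2L)
        .wildStop("bad_argument", "exactly two groups are required")
    if (any(table(group) < 2L))
        .wildStop("small_group", "each group needs at least 2 samples")
    if (is.null(reference))
        reference <- if ("laboratory" %in% lev) "laboratory" else lev[1L]
    other <- setdiff(lev, reference)
    if (is.null(family))
        family <- rep(NA_character_, nrow(values))
    res <- lapply(seq_len(nrow(values)), function(i) {
        a <- values[i, group == other]       # e.g. rewilded
        b <- values[i, group == reference]   # e.g. laboratory
        ## U counts pairs where a reference value exceeds the other group
        mw <- mannWhitneyU(b, a, exactMax = exactMax)
        data.frame(taxon = rownames(values)[i], family = family[i],
            meanFoldDifference = mean(a) - mean(b),
            U = mw$U, P = mw$P, method = mw$method,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (adjust)
        out$q <- stats::p.adjust(out$P, method = "BH")
    out
}

#' Pair input-fraction abundance with antibody scores
#'
#' For every taxon present in both tables, returns the per-group mean input
#' relative abundance and mean Ig score, ready for scatter plotting (no
#' statistics are computed).
#'
#' @param input an input-fraction [FractionCountTable-class].
#' @param scores an [IgScoreTable-class].
#' @param eps pseudocount for the input relative abundances.
#' @return data.frame: taxon, group, meanAbundance, meanScore.
#' @export
abundanceScorePairs <- function(input, scores, eps = 1) {
    shared <- intersect(rownames(input), rownames(scores))
    if (!length(shared)) {
        .wildWarn("empty_intersection",
            "no taxa shared between input table and score table")
        return(data.frame(taxon = character(), group = character(),
            meanAbundance = numeric(), meanScore = numeric()))
    }
    cm <- assay(input, "counts")
    rel <- apply(cm, 2L, relativeAbundance, eps = eps)
    rownames(rel) <- rownames(cm)
    sm <- assay(scores, "scores")
    gIn <- as.character(colData(input)$group)
    gSc <- as.character(colData(scores)$group)
    out <- lapply(unique(gSc), function(g) data.frame(
        taxon = shared, group = g,
        meanAbundance = rowMeans(rel[shared, gIn == g, drop = FALSE]),
        meanScore = rowMeans(sm[shared, gSc == g, drop = FALSE]),
        stringsAsFactors = FALSE))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
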