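#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Correlation-based distance between sample profiles
#'
#' Computes pairwise Pearson correlations \eqn{r_{ij}} between sample score
#' (or abundance) vectors and converts them to distances. The default
#' conversion \eqn{d = \sqrt{2 (1 - r)}} is Euclidean-embeddable (it equals
#' the Euclidean distance between the z-scored vectors divided by
#' \eqn{\sqrt{m}}), which guarantees a positive semi-definite Gram matrix for
#' PCoA; the plain \eqn{d = 1 - r} conversion is available by flag.
#'
#' @param profiles samples x taxa numeric matrix, or an
#'   [IgScoreTable-class] / [FractionCountTable-class] (taxa x samples;
#'   transposed internally, counts are converted to relative abundances).
#' @param conversion \code{"sqrt"} (default) or \code{"linear"}.
#' @return a \code{dist} object with a \code{"conversion"} attribute.
#' @export
correlationDistance <- function(profiles, conversion = c("sqrt", "linear")) {
    conversion <- match.arg(conversion)
    if (is(profiles, "IgScoreTable"))
        profiles <- t(assay(profiles, "scores"))
    else if (is(profiles, "FractionCountTable"))
        profiles <- t(apply(assay(profiles, "counts"), 2L,
                            relativeAbundance, eps = 1))
    profiles <- as.matrix(profiles)
    if (ncol(profiles) < 2L)
        .wildStop("bad_argument", "need at least 2 taxa per profile")
    sds <- apply(profiles, 1L, stats::sd)
    if (any(sds == 0))
        .wildStop("constant_profile", "constant profile for sample(s): ",
            paste(rownames(profiles)[sds == 0], collapse = ", "))
    r <- stats::cor(t(profiles))
    d <- if (conversion == "sqrt") sqrt(pmax(2 * (1 - r), 0)) else 1 - r
    out <- stats::as.dist(d)
    attr(out, "conversion") <- conversion
    out
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and returns sample
#' coordinates \eqn{v_k \sqrt{\lambda_k}} on the axes with positive
#' eigenvalues. Negative eigenvalues are reported in the result but their
#' axes are dropped (a warning is logged).
#'
#' @param d a \code{dist} object or a symmetric non-negative matrix with zero
#'   diagonal.
#' @return an [Ordination-class].
#' @export
pcoa <- function(d) {
    if (!inherits(d, "dist")) {
        d <- as.matrix(d)
        if (!isSymmetric(unname(d), tol = 1e-8))
            .wildStop("not_symmetric", "distance matrix must be symmetric")
        d <- stats::as.dist(d)
    }
    n <- attr(d, "Size")
    fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
    ev <- sort(fit$eig, decreasing = TRUE)
    tol <- max(abs(ev), 1e-12) * 1e-8
    nPos <- sum(ev > tol)
    if (any(ev < -tol))
        .log("warning", sum(ev < -tol),
             " negative eigenvalue(s); their axes are dropped")
    coords <- fit$points[, seq_len(nPos), drop = FALSE]
    if (is.null(rownames(coords)))
        rownames(coords) <- attr(d, "Labels")
    colnames(coords) <- paste0("axis", seq_len(nPos))
    new("Ordination", coordinates = coords, eigenvalues = ev,
        proportionExplained = ev[seq_len(nPos)] / sum(ev[seq_len(nPos)]))
}

## All distinct assignments of group labels (1..k, with the given counts) to
## n positions; used for exact PERMANOVA enumeration.
.enumerateLabelings <- function(counts) {
    n <- sum(counts)
    res <- vector("list", 0L)
    recur <- function(avail, gi, acc) {
        if (gi == length(counts)) {
            acc[avail] <- gi
            res[[length(res) + 1L]] <<- acc
            return(invisible(NULL))
        }
        cmb <- utils::combn(length(avail), counts[gi])
        for (k in seq_len(ncol(cmb))) {
            sel <- avail[cmb[, k]]
            acc2 <- acc
            acc2[sel] <- gi
            recur(setdiff(avail, sel), gi + 1L, acc2)
        }
    }
    recur(seq_len(n), 1L, integer(n))
    res
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix. With squared distances
#' \eqn{d_{ij}^2}: \eqn{SS_{total} = \frac1n \sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac1{n_g} \sum_{i<j \in g} d_{ij}^2},
#' \eqn{SS_{between} = SS_{total} - SS_{within}}, and pseudo-F is
#' \eqn{(SS_{between}/(g-1)) / (SS_{within}/(n-g))}. Significance comes from
#' label permutation: when the number of distinct relabelings is at most
#' \code{enumerateMax}, all of them are evaluated and P is exact; otherwise P
#' uses \code{nPerm} random permutations with the identity included,
#' \eqn{P = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}. Ties in F
#' count as greater-or-equal.
#'
#' @param d \code{dist} object or symmetric matrix.
#' @param group per-sample labels; at least two groups of size at least 2.
#' @param nPerm random permutations (default 999; at least 99).
#' @param seed integer seed for the random scheme.
#' @param enumerateMax full-enumeration cap on distinct relabelings
#'   (default 10000).
#' @return a [PermanovaResult-class]. All distances zero gives a degenerate
#'   result with \code{F = NA} (a warning is logged).
#' @export
permanova <- function(d, group, nPerm = 999L, seed = 17L,
                      enumerateMax = 10000L) {
    D2 <- as.matrix(d)^2
    n <- nrow(D2)
    group <- .checkGroups(group)
    if (length(group) != n)
        .wildStop("bad_argument", "one group label per sample is required")
    counts <- table(group)
    g <- length(counts)
    if (g < 2L)
        .wildStop("bad_argument", "at least two groups are required")
    if (any(counts < 2L))
        .wildStop("small_group", "every group needs at least 2 samples")
    if (nPerm < 99L)
        .wildStop("bad_argument", "nPerm must be at least 99")
    gi <- match(group, names(counts))
    ssWithin <- function(assignment) {
        s <- 0
        for (k in seq_len(g)) {
            idx <- which(assignment == k)
            s <- s + sum(D2[idx, idx]) / (2 * length(idx))
        }
        s
    }
    ssTotal <- sum(D2) / (2 * n)
    fStat <- function(assignment) {
        ssw <- ssWithin(assignment)
        ((ssTotal - ssw) / (g - 1)) / (ssw / (n - g))
    }
    sswObs <- ssWithin(gi)
    if (sswObs <= 0 || ssTotal <= 0) {
        .log("warning", "degenerate distances: pseudo-F undefined")
        return(new("PermanovaResult", F = NA_real_, P = NA_real_,
            nPermutations = 0L, exact = FALSE, seed = as.integer(seed),
            groupSizes = stats::setNames(as.integer(counts),
                                         names(counts))))
    }
    fObs <- fStat(gi)
    eps <- 1e-12 * max(1, abs(fObs))
    nDistinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
    if (nDistinct <= enumerateMax) {
        labelings <- .enumerateLabelings(as.integer(counts))
        fAll <- vapply(labelings, fStat, numeric(1))
        P <- mean(fAll >= fObs - eps)
        res <- new("PermanovaResult", F = fObs, P = P,
            nPermutations = length(fAll), exact = TRUE,
            seed = NA_integer_,
            groupSizes = stats::setNames(as.integer(counts), names(counts)))
    } else {
        set.seed(as.integer(seed))
        nPerm <- as.integer(nPerm)
        hits <- 0L
        for (p in seq_len(nPerm)) {
            fp <- fStat(gi[sample.int(n)])
            if (fp >= fObs - eps) hits <- hits + 1L
        }
        P <- (1 + hits) / (1 + nPerm)
        res <- new("PermanovaResult", F = fObs, P = P,
            nPermutations = nPerm, exact = FALSE, seed = as.integer(seed),
            groupSizes = stats::setNames(as.integer(counts), names(counts)))
    }
    res
}
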