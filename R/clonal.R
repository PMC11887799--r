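#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

.QC_REASONS <- c("missing_vj", "chain_inconsistent", "too_many_N",
    "cdr3_has_N", "cdr3_len_not_div3", "nonproductive")

## Noninformative positions of an alignment: anything outside A/C/G/T,
## IMGT gap characters ('.', '-') excluded from the count.
.countN <- function(seqs) {
    nchar(gsub("[ACGT.-]", "", toupper(seqs)))
}

#' Quality-control filter for rearrangement records
#'
#' Retains records satisfying all six requirements: non-empty V and J gene
#' annotations; chain (locus) consistency among the v/j/constant-region
#' calls; fewer than 10 noninformative \code{N} positions (non-A/C/G/T,
#' alignment gap characters excluded) in the full sequence alignment; a CDR3
#' junction devoid of \code{N}; a junction nucleotide length divisible by 3;
#' and a productive rearrangement. Filtering never fails: records that break
#' a rule are reported, not errors.
#'
#' @param x a [RearrangementSet-class].
#' @param maxN maximum tolerated noninformative positions minus one; records
#'   with \code{>= maxN} fail (default 10, i.e. fewer than 10 pass).
#' @return list with \code{set} (the passing records) and \code{report}
#'   (a [QcReport-class]).
#' @export
qcFilter <- function(x, maxN = 10L) {
    df <- rearrangements(x)
    n <- nrow(df)
    empty <- function(v) is.na(v) | v == ""
    fail <- list(
        missing_vj = empty(df$v_call) | empty(df$j_call),
        chain_inconsistent = vapply(seq_len(n), function(i) {
            loci <- .locusOf(c(df$v_call[i], df$j_call[i], df$c_call[i]))
            loci <- loci[loci != ""]
            length(unique(loci)) > 1L
        }, logical(1)),
        too_many_N = .countN(df$sequence_alignment) >= maxN,
        cdr3_has_N = grepl("[^ACGT]", toupper(df$junction)),
        cdr3_len_not_div3 = df$junction_length %% 3L != 0L,
        nonproductive = !df$productive)
    failMat <- do.call(cbind, fail)
    reasons <- apply(failMat, 1L, function(r)
        paste(.QC_REASONS[r], collapse = ","))
    pass <- !apply(failMat, 1L, any)
    report <- new("QcReport",
        perRecord = DataFrame(sequence_id = df$sequence_id, pass = pass,
                              reasons = reasons),
        reasonCounts = stats::setNames(colSums(failMat), .QC_REASONS) |>
            as.integer() |> stats::setNames(.QC_REASONS))
    .log("info", sum(pass), "/", n, " records pass QC")
    list(set = x[pass], report = report)
}

#' Partition rearrangements by V gene, J gene and junction length
#'
#' Records sharing the allele-stripped V gene (text before \code{"*"};
#' ambiguous comma-separated multi-gene calls resolve to the first listed
#' gene), the allele-stripped J gene and the junction nucleotide length form
#' one partition; clonal clustering never crosses partitions.
#'
#' @param x a QC-filtered [RearrangementSet-class].
#' @return named list of integer row indices into \code{rearrangements(x)},
#'   keys \code{"V|J|length"}.
#' @export
partitionRearrangements <- function(x) {
    df <- rearrangements(x)
    if (!nrow(df)) return(list())
    key <- paste(.geneOf(df$v_call), .geneOf(df$j_call), df$junction_length,
                 sep = "|")
    split(seq_len(nrow(df)), key)
}

#' Normalized Hamming distance between two junction sequences
#'
#' Mismatching positions divided by sequence length; positions where either
#' sequence has a non-A/C/G/T character (e.g. \code{N}) are excluded from
#' both numerator and denominator. \code{NA} when no informative position
#' remains.
#'
#' @param a,b equal-length nucleotide strings.
#' @return normalized distance in [0, 1].
#' @examples
#' junctionDistance("AAAA", "AAAT")  # 0.25
#' junctionDistance("AANA", "AATA")  # 0 (N position excluded)
#' @export
junctionDistance <- function(a, b) {
    if (nchar(a) != nchar(b))
        .wildStop("length_mismatch",
            "junctions have different lengths (", nchar(a), " vs ",
            nchar(b), ")")
    av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
    bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
    ok <- av %in% .BASES & bv %in% .BASES
    if (!any(ok)) return(NA_real_)
    sum(av[ok] != bv[ok]) / sum(ok)
}

## Pairwise junction distance matrix for one partition (equal lengths).
.junctionDistMatrix <- function(juncs) {
    m <- do.call(rbind, strsplit(toupper(juncs), "", fixed = TRUE))
    code <- matrix(match(m, .BASES, nomatch = 0L), nrow = nrow(m))
    k <- length(juncs)
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
            ok <- code[i, ] > 0L & code[j, ] > 0L
            D[i, j] <- D[j, i] <-
                if (any(ok)) sum(code[i, ok] != code[j, ok]) / sum(ok)
                else NA_real_
        }
    }
    D
}

#' Nearest-neighbor junction distance distribution
#'
#' For every sequence with at least one partition mate, the minimum
#' normalized Hamming junction distance to any mate; singleton partitions
#' contribute nothing. The distribution is typically bimodal: a near-zero
#' clonal mode and a background mode of unrelated sequences, whose valley
#' locates the clonal threshold (see [estimateThreshold()]).
#'
#' @param x a [RearrangementSet-class] or the partition list from
#'   [partitionRearrangements()] together with \code{set}.
#' @param set the rearrangement set when \code{x} is a partition list.
#' @param by optional per-record labels (e.g. environment group); distances
#'   are then computed within label only, mirroring per-environment
#'   estimation.
#' @return a [NearestNeighborDistribution-class] (threshold not yet
#'   estimated).
#' @export
nearestNeighborDistances <- function(x, set = NULL, by = NULL) {
    if (is(x, "RearrangementSet")) {
        set <- x
        parts <- partitionRearrangements(set)
    } else parts <- x
    df <- rearrangements(set)
    if (!is.null(by)) {
        by <- as.character(by)
        parts <- unlist(lapply(parts, function(idx)
            split(idx, by[idx])), recursive = FALSE)
    }
    dists <- numeric(0)
    for (idx in parts) {
        if (length(idx) < 2L) next
        D <- .junctionDistMatrix(df$junction[idx])
        diag(D) <- NA_real_
        dists <- c(dists, apply(D, 1L, min, na.rm = TRUE))
    }
    dists <- dists[is.finite(dists)]
    if (!length(dists))
        .wildWarn("no_neighbors",
            "all partitions are singletons; empty distance distribution")
    new("NearestNeighborDistribution", distances = unname(dists),
        fit = list(), threshold = NA_real_, method = "none")
}

#' Estimate the clonal distance threshold
#'
#' Fits a two-component univariate Gaussian mixture (EM) to the
#' nearest-neighbor distance distribution and places the threshold at the
#' point between the component means where the posterior responsibilities are
#' equal (the weighted-density crossing). When the EM fit degenerates, the
#' threshold falls back to the minimum of a kernel density estimate between
#' the two dominant modes. Component means closer than one standard
#' deviation mean the distribution is effectively unimodal: a labelled error
#' advises a manual threshold.
#'
#' @param x a [NearestNeighborDistribution-class] or numeric distance vector.
#' @param seed integer seed (EM initialization reproducibility).
#' @return a [NearestNeighborDistribution-class] with \code{threshold},
#'   \code{fit} and \code{method} filled in; read the value with
#'   [threshold()].
#' @export
estimateThreshold <- function(x, seed = 17L) {
    d <- if (is(x, "NearestNeighborDistribution")) x@distances else
        as.numeric(x)
    if (length(d) < 50L)
        .wildStop("too_few_distances", "need at least 50 nearest-neighbor ",
            "distances spanning both modes; set the threshold manually")
    set.seed(as.integer(seed))
    if (.kdeModes(d) < 2L)
        .wildStop("unimodal", "nearest-neighbor distance distribution has a ",
            "single mode; set the threshold manually")
    fit <- NULL
    th <- NA_real_
    method <- "gmm"
    gmm <- .fitGmm2(d, maxRestarts = 100L)
    if (!is.null(gmm)) {
        mu <- gmm$mean; sd2 <- gmm$sd; pro <- gmm$pro
        if (abs(mu[2L] - mu[1L]) < max(sd2))
            .wildStop("unimodal", "mixture component means lie within one ",
                "standard deviation; the distribution looks unimodal - set ",
                "the threshold manually")
        fit <- gmm
        f <- function(z) pro[1L] * stats::dnorm(z, mu[1L], sd2[1L]) -
            pro[2L] * stats::dnorm(z, mu[2L], sd2[2L])
        th <- tryCatch(
            stats::uniroot(f, lower = mu[1L], upper = mu[2L])$root,
            error = function(e) NA_real_)
    }
    if (is.na(th)) {
        method <- "kde"
        th <- .kdeValley(d)
    }
    if (is.na(th))
        .wildStop("unimodal", "no valley between modes; the distribution ",
            "looks unimodal - set the threshold manually")
    th <- min(max(th, 1e-6), 1 - 1e-6)
    new("NearestNeighborDistribution", distances = unname(d),
        fit = fit %||% list(), threshold = th, method = method)
}

## Two-component univariate Gaussian mixture via EM (mclust model "V"),
## k-means initialization, restart cap; components returned sorted by mean.
.fitGmm2 <- function(d, maxRestarts = 100L) {
    for (r in seq_len(maxRestarts)) {
        km <- tryCatch(stats::kmeans(d, centers = 2L), error = function(e)
            NULL)
        if (is.null(km)) next
        fit <- tryCatch(
            suppressWarnings(mclust::meV(data = d, z = mclust::unmap(
                km$cluster))),
            error = function(e) NULL)
        if (is.null(fit) || anyNA(fit$parameters$mean)) next
        mu <- as.numeric(fit$parameters$mean)
        sd2 <- rep_len(sqrt(as.numeric(fit$parameters$variance$sigmasq)), 2L)
        pro <- as.numeric(fit$parameters$pro)
        if (any(!is.finite(c(mu, sd2, pro))) || any(sd2 <= 0)) next
        o <- order(mu)
        return(list(mean = mu[o], sd = sd2[o], pro = pro[o]))
    }
    NULL
}

## Number of kernel-density modes with height at least 5% of the peak.
.kdeModes <- function(d) {
    dens <- stats::density(d, n = 512L)
    y <- dens$y
    locmax <- which(diff(sign(diff(y))) == -2L) + 1L
    sum(y[locmax] >= 0.05 * max(y))
}

## Valley of a kernel density estimate between its two dominant modes.
.kdeValley <- function(d) {
    dens <- stats::density(d, n = 512L, from = min(d), to = max(d))
    y <- dens$y
    locmax <- which(diff(sign(diff(y))) == -2L) + 1L
    if (length(locmax) < 2L) return(NA_real_)
    top2 <- locmax[order(y[locmax], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    between <- seq.int(lo, hi)
    dens$x[between[which.min(y[between])]]
}

#' Assign clones by single-linkage clustering within partitions
#'
#' Within each V/J/junction-length partition, sequences are clustered by
#' single linkage on the normalized Hamming junction distance and the tree is
#' cut at the threshold; single-linkage clusters at a cut equal the connected
#' components of the graph joining pairs at distance at most the threshold.
#' Clone identifiers are globally unique and deterministic: partitions are
#' visited in sorted key order and records processed sorted by
#' \code{sequence_id}, so the result does not depend on input record order.
#'
#' @param x a QC-filtered [RearrangementSet-class].
#' @param threshold normalized junction distance cutoff in (0, 1); the
#'   default 0.03 matches the fitted value typical of these data, use
#'   [estimateThreshold()] to refit.
#' @return a [CloneAssignment-class].
#' @export
assignClones <- function(x, threshold = 0.03) {
    if (threshold <= 0 || threshold >= 1)
        .wildStop("bad_argument", "threshold must lie in (0, 1)")
    df <- rearrangements(x)
    parts <- partitionRearrangements(x)
    parts <- parts[order(names(parts))]
    rows <- vector("list", length(parts))
    cloneCounter <- 0L
    for (p in seq_along(parts)) {
        idx <- parts[[p]]
        idx <- idx[order(df$sequence_id[idx])]
        key <- strsplit(names(parts)[p], "|", fixed = TRUE)[[1L]]
        if (length(idx) == 1L) {
            member <- 1L
        } else {
            D <- .junctionDistMatrix(df$junction[idx])
            D[is.na(D)] <- 1
            hc <- stats::hclust(stats::as.dist(D), method = "single")
            member <- stats::cutree(hc, h = threshold)
            ## renumber clusters by first (smallest sequence_id) appearance
            member <- match(member, unique(member))
        }
        rows[[p]] <- DataFrame(sequence_id = df$sequence_id[idx],
            clone_id = sprintf("clone%05d", cloneCounter + member),
            v_gene = key[1L], j_gene = key[2L],
            junction_length = as.integer(key[3L]))
        cloneCounter <- cloneCounter + max(member)
    }
    assignments <- do.call(rbind, rows)
    new("CloneAssignment", assignments = assignments,
        threshold = threshold)
}

#' Collapse duplicate aligned sequences within clones
#'
#' Within a clone, records with identical aligned V(D)J sequences are merged
#' into one record unless they come from different B cell compartments or
#' carry different constant-region calls. The merged record keeps the
#' lexicographically smallest \code{sequence_id} and gains a
#' \code{duplicate_count} column.
#'
#' @param x a [RearrangementSet-class].
#' @param clones a [CloneAssignment-class] for \code{x} (or omitted when the
#'   records already carry a \code{clone_id} column).
#' @return a collapsed [RearrangementSet-class] with \code{clone_id} and
#'   \code{duplicate_count} columns.
#' @export
collapseDuplicates <- function(x, clones = NULL) {
    df <- rearrangements(x)
    if (!is.null(clones)) {
        ids <- cloneIds(clones)
        df$clone_id <- unname(ids[df$sequence_id])
    }
    if (!"clone_id" %in% colnames(df))
        .wildStop("bad_argument", "records carry no clone assignment")
    comp <- if ("compartment" %in% colnames(df)) df$compartment else ""
    key <- paste(df$clone_id, df$sequence_alignment, comp, df$c_call,
                 sep = "\r")
    groupsOf <- split(seq_len(nrow(df)), key)
    keep <- integer(length(groupsOf))
    dupCount <- integer(length(groupsOf))
    for (k in seq_along(groupsOf)) {
        idx <- groupsOf[[k]]
        keep[k] <- idx[order(df$sequence_id[idx])[1L]]
        dupCount[k] <- length(idx)
    }
    o <- order(keep)
    out <- df[keep[o], , drop = FALSE]
    out$duplicate_count <- dupCount[o]
    new("RearrangementSet", rearrangements = out)
}
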