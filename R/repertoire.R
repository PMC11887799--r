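#' @include AllClasses.R AllGenerics.R utils.R io.R clonal.R
NULL

#' Somatic hypermutation profile
#'
#' Counts mutations of each record against its germline over the entire
#' aligned sequence (replacement and silent changes pooled): positions where
#' both the observed and the germline alignment carry an unambiguous A/C/G/T
#' base are informative, and a mutation is an informative position where they
#' differ. The per-record frequency is mutations over informative length.
#'
#' @param x a [RearrangementSet-class].
#' @return data.frame: sequence_id, mutations, informative, frequency.
#' @export
mutationProfile <- function(x) {
    df <- rearrangements(x)
    res <- vapply(seq_len(nrow(df)), function(i) {
        s <- strsplit(toupper(df$sequence_alignment[i]), "",
                      fixed = TRUE)[[1L]]
        g <- strsplit(toupper(df$germline_alignment[i]), "",
                      fixed = TRUE)[[1L]]
        ok <- s %in% .BASES & g %in% .BASES
        if (!any(ok))
            .wildStop("no_informative", "record ", df$sequence_id[i],
                " has no informative alignment position")
        c(sum(s[ok] != g[ok]), sum(ok))
    }, numeric(2))
    data.frame(sequence_id = df$sequence_id, mutations = res[1L, ],
        informative = res[2L, ], frequency = res[1L, ] / res[2L, ],
        stringsAsFactors = FALSE)
}

#' Median mutation frequency within clones
#'
#' @param profile per-record output of [mutationProfile()].
#' @param clones a [CloneAssignment-class], or a named clone-id vector
#'   indexed by sequence_id.
#' @return data.frame: clone_id, n, medianFrequency.
#' @export
cloneMedianFrequency <- function(profile, clones) {
    ids <- if (is(clones, "CloneAssignment")) cloneIds(clones) else clones
    cl <- unname(ids[profile$sequence_id])
    keep <- !is.na(cl)
    freqs <- split(profile$frequency[keep], cl[keep])
    data.frame(clone_id = names(freqs),
        n = lengths(freqs),
        medianFrequency = vapply(freqs, stats::median, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided \eqn{D = \sup |ECDF_a - ECDF_b|} with P value from the
#' asymptotic Kolmogorov distribution by default (\code{exact = TRUE} for the
#' exact small-sample null).
#'
#' @param a,b numeric samples, each of size at least 2.
#' @param exact logical, exact null distribution (tie-free samples only).
#' @return list with \code{D} and \code{P}.
#' @examples
#' ksCompare(c(1, 3), c(2, 4))$D  # 0.5
#' @export
ksCompare <- function(a, b, exact = FALSE) {
    if (length(a) < 2L || length(b) < 2L)
        .wildStop("small_sample", "each sample needs at least 2 values")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    list(D = unname(kt$statistic), P = kt$p.value)
}

#' Simpson's diversity index over clone sizes
#'
#' Inverse form (Hill order 2) by default: \eqn{1 / \sum p_i^2} over clone
#' proportions, the effective number of equally sized clones; the
#' Gini-Simpson form \eqn{1 - \sum p_i^2} is available by flag.
#'
#' @param sizes positive clone sizes (cells per clone).
#' @param form \code{"inverse"} (default) or \code{"gini"}.
#' @return the index value.
#' @examples
#' simpsonIndex(c(2, 1, 1))  # 8/3
#' @export
simpsonIndex <- function(sizes, form = c("inverse", "gini")) {
    form <- match.arg(form)
    sizes <- sizes[sizes > 0]
    if (!length(sizes))
        .wildStop("bad_argument", "no clones")
    p <- sizes / sum(sizes)
    s2 <- sum(p^2)
    if (form == "inverse") 1 / s2 else 1 - s2
}

#' Clone diversity with bootstrap group deltas
#'
#' Richness (Hill order 0: number of distinct clones) and inverse Simpson
#' index (Hill order 2) per group, computed over clone relative sizes (cells
#' per clone / total cells). Uncertainty comes from bootstrapping cells:
#' each replicate resamples cells with replacement to the common size
#' \code{n = min} group cell count and recomputes both indices; the delta
#' distribution is the replicate-wise difference (second group minus first,
#' in the order of \code{levels}) with a 95 percent percentile interval.
#'
#' @param clones per-cell clone identifiers (character vector), or a
#'   [CloneAssignment-class].
#' @param group per-cell group labels, exactly two levels.
#' @param nBoot bootstrap replicates (default 1000; below 100 warns).
#' @param seed integer seed; fixed seed reproduces replicates bit-exactly.
#' @param levels optional explicit group order (delta = second - first).
#' @return a [DiversityProfile-class].
#' @export
cloneDiversity <- function(clones, group, nBoot = 1000L, seed = 17L,
                           levels = NULL) {
    if (is(clones, "CloneAssignment"))
        clones <- unname(cloneIds(clones))
    clones <- as.character(clones)
    group <- .checkGroups(group)
    if (length(clones) != length(group))
        .wildStop("bad_argument", "clones and group must be parallel")
    if (!length(clones))
        .wildStop("bad_argument", "no clones")
    if (nBoot < 100L)
        .wildWarn("few_bootstrap", "fewer than 100 bootstrap replicates")
    lev <- levels %||% unique(group)
    if (length(lev) != 2L)
        .wildStop("bad_argument", "exactly two groups are required")
    byGroup <- split(clones, factor(group, levels = lev))
    indices <- function(cells) {
        sizes <- table(cells)
        c(richness = length(sizes), invSimpson = simpsonIndex(sizes))
    }
    observed <- data.frame(group = lev,
        t(vapply(byGroup, indices, numeric(2))), row.names = NULL)
    nCommon <- min(lengths(byGroup))
    set.seed(as.integer(seed))
    replicates <- lapply(byGroup, function(cells) {
        t(vapply(seq_len(nBoot), function(r)
            indices(sample(cells, nCommon, replace = TRUE)),
            numeric(2)))
    })
    delta <- replicates[[2L]] - replicates[[1L]]
    ci <- apply(delta, 2L, stats::quantile, probs = c(0.025, 0.975))
    new("DiversityProfile", observed = observed, replicates = replicates,
        delta = delta, deltaCI = ci, nBoot = as.integer(nBoot),
        seed = as.integer(seed))
}

#' Constant-region (isotype) usage per group
#'
#' Frequency of each allele-stripped constant-region gene among records with
#' a call, per group; records lacking a call are counted separately.
#'
#' @param x a [RearrangementSet-class].
#' @param group per-record group labels; defaults to the records'
#'   \code{group} column.
#' @return list with \code{usage} (data.frame: group, isotype, count,
#'   frequency) and \code{uncalled} (named count of records without a call).
#' @export
constantRegionUsage <- function(x, group = NULL) {
    df <- rearrangements(x)
    if (is.null(group)) {
        if (!"group" %in% colnames(df))
            .wildStop("missing_group", "records carry no 'group' column")
        group <- df$group
    }
    group <- as.character(group)
    called <- !(is.na(df$c_call) | df$c_call == "")
    uncalled <- vapply(split(!called, group), sum, numeric(1))
    iso <- .geneOf(df$c_call[called])
    g <- group[called]
    usage <- do.call(rbind, lapply(unique(group), function(gl) {
        tab <- table(iso[g == gl])
        if (!length(tab))
            return(NULL)
        data.frame(group = gl, isotype = names(tab),
            count = as.integer(tab),
            frequency = as.numeric(tab) / sum(tab),
            stringsAsFactors = FALSE)
    }))
    if (is.null(usage))
        usage <- data.frame(group = character(), isotype = character(),
            count = integer(), frequency = numeric())
    rownames(usage) <- NULL
    list(usage = usage, uncalled = uncalled)
}

#' Build the clonal repertoire network
#'
#' Nodes are BCR-containing cells; an edge joins two cells of the same clone
#' whose junction distance is at most the threshold. The edge list is
#' deterministic: endpoints sorted lexicographically within an edge and edges
#' sorted by endpoints.
#'
#' @param x a [RearrangementSet-class].
#' @param clones a [CloneAssignment-class] (or omitted when the records carry
#'   a \code{clone_id} column).
#' @param threshold junction distance cutoff for edges.
#' @return a [RepertoireNetwork-class].
#' @export
buildNetwork <- function(x, clones = NULL, threshold = 0.03) {
    df <- rearrangements(x)
    if (!is.null(clones)) {
        ids <- cloneIds(clones)
        df$clone_id <- unname(ids[df$sequence_id])
    }
    if (!"clone_id" %in% colnames(df))
        .wildStop("bad_argument", "records carry no clone assignment")
    df <- df[!is.na(df$clone_id), , drop = FALSE]
    nodes <- data.frame(cell_id = df$cell_id, clone_id = df$clone_id,
        isotype = .geneOf(df$c_call), stringsAsFactors = FALSE)
    nodes <- nodes[!duplicated(nodes$cell_id), , drop = FALSE]
    nodes <- nodes[order(nodes$cell_id), , drop = FALSE]
    rownames(nodes) <- NULL
    edges <- list()
    for (idx in split(seq_len(nrow(df)), df$clone_id)) {
        if (length(idx) < 2L) next
        D <- .junctionDistMatrix(df$junction[idx])
        for (i in seq_len(length(idx) - 1L)) {
            for (j in seq.int(i + 1L, length(idx))) {
                ci <- df$cell_id[idx[i]]; cj <- df$cell_id[idx[j]]
                if (ci == cj || is.na(D[i, j]) || D[i, j] > threshold)
                    next
                edges[[length(edges) + 1L]] <- data.frame(
                    node1 = min(ci, cj), node2 = max(ci, cj),
                    clone_id = df$clone_id[idx[i]], distance = D[i, j],
                    stringsAsFactors = FALSE)
            }
        }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
        data.frame(node1 = character(), node2 = character(),
            clone_id = character(), distance = numeric())
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
    rownames(edges) <- NULL
    new("RepertoireNetwork", nodes = nodes, edges = edges,
        threshold = threshold)
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "RepertoireNetwork", function(x) {
    igraph::graph_from_data_frame(x@edges, directed = FALSE,
        vertices = x@nodes)
})
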