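#' @include AllClasses.R AllGenerics.R utils.R
NULL

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct a FractionCountTable
#'
#' @param counts integer matrix, taxa as rows, samples as columns (set
#'   \code{taxaAsRows = FALSE} for the transposed orientation).
#' @param group per-sample group labels, recycled names from \code{counts}
#'   columns; either a named vector or one value per sample.
#' @param fraction one of \code{"input"}, \code{"bound"}, \code{"unbound"}.
#' @param antibodyClass \code{"IgG"}, \code{"IgM"} or \code{"none"}.
#' @param lineage optional semicolon-delimited taxonomy strings, one per
#'   taxon; defaults to the taxon identifier itself when that contains
#'   semicolons.
#' @param taxaAsRows logical; \code{FALSE} transposes \code{counts} first.
#' @return a [FractionCountTable-class].
#' @examples
#' m <- matrix(c(2L, 3L, 5L, 0L), 2, dimnames = list(c("t1", "t2"),
#'     c("s1", "s2")))
#' fractionCountTable(m, group = c("laboratory", "rewilded"),
#'     fraction = "bound", antibodyClass = "IgG")
#' @export
fractionCountTable <- function(counts, group, fraction, antibodyClass = "none",
                               lineage = NULL, taxaAsRows = TRUE) {
    if (!taxaAsRows)
        counts <- t(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    group <- .checkGroups(group)
    if (!is.null(names(group)))
        group <- group[colnames(counts)]
    group <- rep_len(group, ncol(counts))
    if (is.null(lineage))
        lineage <- ifelse(grepl(";", rownames(counts), fixed = TRUE),
                          rownames(counts), NA_character_)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(lineage = lineage,
                            family = taxonFamily(lineage),
                            row.names = rownames(counts)),
        colData = DataFrame(group = group, row.names = colnames(counts)))
    new("FractionCountTable", se, fractionLabel = fraction,
        antibodyClass = antibodyClass)
}

#' Extract the family rank from semicolon-delimited lineage strings
#'
#' The family is read as the 5th semicolon-delimited rank
#' (kingdom;phylum;class;order;family;...) when present.
#'
#' @param lineage character vector of lineage strings (NAs pass through).
#' @return character vector of family names (NA when absent).
#' @export
taxonFamily <- function(lineage) {
    vapply(strsplit(as.character(lineage), ";", fixed = TRUE),
        function(p) if (length(p) >= 5L) trimws(p[5L]) else NA_character_,
        character(1))
}

#' Construct a RearrangementSet from a record table
#'
#' @param records a \code{data.frame} or \code{DataFrame} with the mandatory
#'   AIRR columns (see [RearrangementSet-class]); extra columns are preserved.
#' @return a [RearrangementSet-class].
#' @export
rearrangementSet <- function(records) {
    df <- as(records, "DataFrame")
    missing <- setdiff(.AIRR_REQUIRED, colnames(df))
    if (length(missing))
        .wildStop("missing_column", "missing mandatory column(s): ",
                  paste(missing, collapse = ", "))
    df$junction_length <- as.integer(df$junction_length)
    if (is.character(df$productive))
        df$productive <- toupper(df$productive) %in% c("T", "TRUE")
    new("RearrangementSet", rearrangements = df)
}

## ---------------------------------------------------------------------------
## Accessor and show methods
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("fractionLabel", "FractionCountTable", function(x) x@fractionLabel)

#' @rdname accessors
#' @export
setMethod("antibodyClass", "FractionCountTable", function(x) x@antibodyClass)

#' @rdname accessors
#' @export
setMethod("antibodyClass", "IgScoreTable", function(x) x@antibodyClass)

#' @rdname accessors
#' @export
setMethod("groupLabels", "SummarizedExperiment",
    function(x) stats::setNames(colData(x)$group, colnames(x)))

#' @rdname accessors
#' @export
setMethod("groupLabels", "RearrangementSet",
    function(x) {
        df <- x@rearrangements
        if (!"group" %in% colnames(df))
            .wildStop("missing_group", "records carry no 'group' column")
        stats::setNames(df$group, df$sequence_id)
    })

#' @rdname accessors
#' @export
setMethod("taxa", "SummarizedExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("scores", "IgScoreTable", function(x) assay(x, "scores"))

#' @rdname accessors
#' @export
setMethod("rearrangements", "RearrangementSet",
    function(x) x@rearrangements)

#' @rdname accessors
#' @export
setMethod("cloneIds", "CloneAssignment",
    function(x) stats::setNames(x@assignments$clone_id,
                                x@assignments$sequence_id))

#' @rdname accessors
#' @export
setMethod("threshold", "CloneAssignment", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("threshold", "NearestNeighborDistribution", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("distances", "NearestNeighborDistribution", function(x) x@distances)

#' @describeIn RearrangementSet-class number of records.
#' @param x a RearrangementSet.
#' @export
setMethod("length", "RearrangementSet",
    function(x) nrow(x@rearrangements))

#' @describeIn RearrangementSet-class subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RearrangementSet", function(x, i, j, ..., drop = FALSE)
    new("RearrangementSet", rearrangements = x@rearrangements[i, ,
        drop = FALSE]))

setMethod("show", "FractionCountTable", function(object) {
    cat(sprintf("FractionCountTable: %d taxa x %d samples (%s fraction, %s)\n",
        nrow(object), ncol(object), object@fractionLabel,
        object@antibodyClass))
    cat("groups:", paste(sprintf("%s=%d",
        names(table(colData(object)$group)),
        table(colData(object)$group)), collapse = ", "), "\n")
})

setMethod("show", "IgScoreTable", function(object) {
    cat(sprintf(
        "IgScoreTable: %d taxa x %d samples (%s, log%g, pseudocount %g)\n",
        nrow(object), ncol(object), object@antibodyClass, object@logBase,
        object@pseudocount))
    dropped <- metadata(object)$dropped
    if (length(dropped))
        cat("dropped (prevalence rule):", length(dropped), "taxa\n")
})

setMethod("show", "RearrangementSet", function(object) {
    df <- object@rearrangements
    cat(sprintf("RearrangementSet: %d records, %d cells\n",
        nrow(df), length(unique(df$cell_id))))
    extra <- setdiff(colnames(df), .AIRR_REQUIRED)
    if (length(extra))
        cat("extra annotations:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "QcReport", function(object) {
    cat(sprintf("QcReport: %d/%d records pass\n",
        sum(object@perRecord$pass), nrow(object@perRecord)))
    rc <- object@reasonCounts
    for (r in names(rc))
        cat(sprintf("  %-20s %d\n", r, rc[[r]]))
})

setMethod("show", "CloneAssignment", function(object) {
    cat(sprintf("CloneAssignment: %d sequences in %d clones (threshold %g)\n",
        nrow(object@assignments),
        length(unique(object@assignments$clone_id)), object@threshold))
})

setMethod("show", "NearestNeighborDistribution", function(object) {
    cat(sprintf(
        "NearestNeighborDistribution: %d distances, threshold %s (%s)\n",
        length(object@distances),
        ifelse(is.na(object@threshold), "not estimated",
               .formatNum(object@threshold, 4L)), object@method))
})

setMethod("show", "PermanovaResult", function(object) {
    cat(sprintf("PERMANOVA: pseudo-F = %s, P = %s (%s, %d permutations)\n",
        .formatNum(object@F, 6L), .formatNum(object@P, 6L),
        if (object@exact) "exact enumeration" else "random permutations",
        object@nPermutations))
})

setMethod("show", "Ordination", function(object) {
    k <- ncol(object@coordinates)
    cat(sprintf("Ordination (PCoA): %d samples, %d retained axes\n",
        nrow(object@coordinates), k))
    if (k)
        cat("proportion explained:",
            paste(.formatNum(object@proportionExplained[seq_len(min(k, 3L))],
                             4L), collapse = ", "), "...\n")
})

setMethod("show", "DiversityProfile", function(object) {
    print(object@observed)
    cat(sprintf("bootstrap: %d replicates; 95%% CI of deltas:\n",
        object@nBoot))
    print(object@deltaCI)
})

setMethod("show", "RepertoireNetwork", function(object) {
    cat(sprintf("RepertoireNetwork: %d nodes, %d edges (threshold %g)\n",
        nrow(object@nodes), nrow(object@edges), object@threshold))
})

## ---------------------------------------------------------------------------
## Readers
## ---------------------------------------------------------------------------

#' Read a taxon-by-sample count table from a tab-separated file
#'
#' The file has a header row, taxon identifiers in the first column and one
#' column per sample (set \code{taxaAsRows = FALSE} when samples are the
#' rows). Cells must be non-negative integers.
#'
#' @param path file path.
#' @param fraction,antibodyClass see [fractionCountTable()].
#' @param metadata sample-to-group map: a named character vector, a
#'   data.frame with columns \code{sample} and \code{group}, or the path of a
#'   two-column tab-separated file.
#' @param taxaAsRows orientation flag (default taxa are rows).
#' @return a [FractionCountTable-class].
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, fraction, antibodyClass = "none",
                           metadata = NULL, taxaAsRows = TRUE) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
        check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids))
        .wildStop("duplicate_taxon", "duplicated taxon identifier(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
        .wildStop("bad_counts",
            "counts must be non-negative integers in ", path)
    rownames(m) <- ids
    group <- .resolveMetadata(metadata,
        if (taxaAsRows) colnames(m) else ids)
    fractionCountTable(m, group = group, fraction = fraction,
        antibodyClass = antibodyClass, taxaAsRows = taxaAsRows)
}

.resolveMetadata <- function(metadata, samples) {
    if (is.null(metadata))
        .wildStop("missing_group", "a sample-to-group map is required")
    if (is.character(metadata) && length(metadata) == 1L &&
        file.exists(metadata))
        metadata <- utils::read.delim(metadata, header = TRUE, sep = "\t",
            stringsAsFactors = FALSE)
    if (is.data.frame(metadata))
        metadata <- stats::setNames(as.character(metadata$group),
                                    metadata$sample)
    absent <- setdiff(samples, names(metadata))
    if (length(absent))
        .wildStop("missing_group", "no group label for sample(s): ",
            paste(absent, collapse = ", "))
    metadata[samples]
}

#' Read AIRR rearrangement records from a tab-separated file
#'
#' Expects the AIRR Rearrangement column names (see
#' [RearrangementSet-class]); unknown extra columns are preserved as opaque
#' annotations. \code{productive} is parsed from \code{T}/\code{F} or
#' \code{TRUE}/\code{FALSE}.
#'
#' @param path file path.
#' @return a [RearrangementSet-class].
#' @seealso [writeRearrangements()]
#' @export
readRearrangements <- function(path) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
        colClasses = "character", check.names = FALSE,
        stringsAsFactors = FALSE)
    rearrangementSet(raw)
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write a count or score table to a tab-separated file
#'
#' Taxa are rows, samples columns, taxon identifier in the first column
#' (\code{taxon_id}); deterministic output.
#'
#' @param x a [FractionCountTable-class] or [IgScoreTable-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCountTable <- function(x, path) {
    m <- if (is(x, "IgScoreTable")) assay(x, "scores") else assay(x, "counts")
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(df, path)
    invisible(path)
}

#' Write AIRR rearrangement records to a tab-separated file
#'
#' @param x a [RearrangementSet-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRearrangements <- function(x, path) {
    df <- as.data.frame(rearrangements(x))
    df$productive <- ifelse(df$productive, "T", "F")
    .writeTSV(df, path)
    invisible(path)
}

.outPath <- function(dir, prefix, suffix) {
    if (!dir.exists(dir)) {
        ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        if (!ok || !dir.exists(dir))
            .wildStop("unwritable_path", "cannot create directory ", dir)
    }
    file.path(dir, paste0(prefix, suffix))
}

#' @rdname writeResults
#' @export
setMethod("writeResults", "IgScoreTable", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% paste0(tolower(x@antibodyClass), "_scores")
    p1 <- .outPath(dir, prefix, ".tsv")
    writeCountTable(x, p1)
    paths <- p1
    dropped <- metadata(x)$dropped
    p2 <- .outPath(dir, prefix, "_dropped.tsv")
    .writeTSV(data.frame(taxon_id = as.character(dropped)), p2)
    invisible(c(paths, p2))
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "PermanovaResult", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "permanova"
    p <- .outPath(dir, prefix, ".tsv")
    df <- data.frame(
        key = c("F", "P", "n_permutations", "exact", "seed",
                paste0("n_", names(x@groupSizes))),
        value = c(.formatNum(x@F, 12L), .formatNum(x@P, 12L),
                  x@nPermutations, x@exact, x@seed, x@groupSizes))
    .writeTSV(df, p)
    invisible(p)
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "CloneAssignment", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "clones"
    p <- .outPath(dir, prefix, ".tsv")
    .writeTSV(as.data.frame(x@assignments), p)
    invisible(p)
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "QcReport", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "qc_report"
    p1 <- .outPath(dir, prefix, ".tsv")
    .writeTSV(as.data.frame(x@perRecord), p1)
    p2 <- .outPath(dir, prefix, "_counts.tsv")
    .writeTSV(data.frame(reason = names(x@reasonCounts),
                         n_failed = x@reasonCounts), p2)
    invisible(c(p1, p2))
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "Ordination", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "pcoa"
    p <- .outPath(dir, prefix, ".tsv")
    con <- file(p, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# eigenvalues\t",
        paste(.formatNum(x@eigenvalues, 12L), collapse = "\t")), con)
    writeLines(paste0("# proportion_explained\t",
        paste(.formatNum(x@proportionExplained, 12L), collapse = "\t")), con)
    k <- ncol(x@coordinates)
    df <- data.frame(sample = rownames(x@coordinates), x@coordinates,
                     check.names = FALSE)
    colnames(df) <- c("sample", paste0("axis", seq_len(k)))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(p)
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "NearestNeighborDistribution",
    function(x, dir, prefix = NULL) {
        prefix <- prefix %||% "nn_distances"
        p1 <- .outPath(dir, prefix, ".tsv")
        .writeTSV(data.frame(distance = .formatNum(x@distances, 12L)), p1)
        p2 <- .outPath(dir, prefix, "_threshold.tsv")
        .writeTSV(data.frame(key = c("threshold", "method"),
            value = c(.formatNum(x@threshold, 12L), x@method)), p2)
        invisible(c(p1, p2))
    })

#' @rdname writeResults
#' @export
setMethod("writeResults", "DiversityProfile", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "diversity"
    p1 <- .outPath(dir, prefix, ".tsv")
    obs <- x@observed
    obs$richness <- .formatNum(obs$richness, 12L)
    obs$invSimpson <- .formatNum(obs$invSimpson, 12L)
    .writeTSV(obs, p1)
    p2 <- .outPath(dir, prefix, "_bootstrap.tsv")
    reps <- do.call(rbind, lapply(names(x@replicates), function(g) {
        data.frame(group = g, replicate = seq_len(nrow(x@replicates[[g]])),
            richness = .formatNum(x@replicates[[g]][, "richness"], 12L),
            invSimpson = .formatNum(x@replicates[[g]][, "invSimpson"], 12L))
    }))
    .writeTSV(reps, p2)
    p3 <- .outPath(dir, prefix, "_delta_ci.tsv")
    ci <- data.frame(index = colnames(x@delta),
        lower = .formatNum(x@deltaCI[1L, ], 12L),
        upper = .formatNum(x@deltaCI[2L, ], 12L))
    .writeTSV(ci, p3)
    invisible(c(p1, p2, p3))
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "RepertoireNetwork", function(x, dir, prefix = NULL) {
    prefix <- prefix %||% "network"
    p1 <- .outPath(dir, prefix, "_edges.tsv")
    e <- x@edges
    e$distance <- .formatNum(e$distance, 12L)
    .writeTSV(e, p1)
    p2 <- .outPath(dir, prefix, "_nodes.tsv")
    .writeTSV(x@nodes, p2)
    invisible(c(p1, p2))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
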