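#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

.FRACTIONS <- c("input", "bound", "unbound")
.AB_CLASSES <- c("IgG", "IgM", "none")
.GROUPS <- c("laboratory", "rewilded")

#' Taxon-by-sample counts for one sorted fraction
#'
#' A \code{FractionCountTable} holds the 16S count matrix of one fraction of a
#' sorting experiment (\code{input}, antibody-\code{bound} or \code{unbound})
#' for one antibody class, as a \linkS4class{SummarizedExperiment}: the
#' \code{"counts"} assay is a non-negative integer matrix with taxa as rows and
#' samples as columns, \code{rowData} carries the semicolon-delimited taxonomy
#' \code{lineage}, and \code{colData} carries the per-sample \code{group} label
#' (\code{laboratory} or \code{rewilded}).
#'
#' @slot fractionLabel one of \code{"input"}, \code{"bound"}, \code{"unbound"}.
#' @slot antibodyClass one of \code{"IgG"}, \code{"IgM"}, or \code{"none"}
#'   (pre-sort input material is not class-specific).
#'
#' @seealso [fractionCountTable()] to construct one, [readCountTable()] to read
#'   one from a tab-separated file, [simulateIgSeq()] to simulate a full
#'   experiment.
#' @exportClass FractionCountTable
setClass("FractionCountTable",
    contains = "SummarizedExperiment",
    slots = c(fractionLabel = "character", antibodyClass = "character"))

setValidity("FractionCountTable", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (any(is.na(m)))
            msg <- c(msg, "counts contain NA")
        else if (any(m < 0))
            msg <- c(msg, "counts must be non-negative")
        else if (any(m != round(m)))
            msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "taxon identifiers (rownames) must be unique")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (any(is.na(colData(object)$group)))
        msg <- c(msg, "every sample needs a group label")
    if (length(object@fractionLabel) != 1L ||
        !object@fractionLabel %in% .FRACTIONS)
        msg <- c(msg, "fractionLabel must be one of input/bound/unbound")
    if (length(object@antibodyClass) != 1L ||
        !object@antibodyClass %in% .AB_CLASSES)
        msg <- c(msg, "antibodyClass must be one of IgG/IgM/none")
    if (length(msg)) msg else TRUE
})

#' Per-taxon antibody enrichment scores
#'
#' An \code{IgScoreTable} holds log2 enrichment scores (the Ig score: log2 of
#' taxon relative abundance in the antibody-bound fraction over the unbound
#' fraction) as a \linkS4class{SummarizedExperiment} with assay
#' \code{"scores"}, taxa as rows and samples as columns. Sample \code{group}
#' labels live in \code{colData}; taxa dropped by the prevalence rule are
#' listed in \code{metadata(x)$dropped}.
#'
#' @slot antibodyClass \code{"IgG"} or \code{"IgM"}.
#' @slot pseudocount the pseudocount added to every count before
#'   normalization.
#' @slot logBase base of the logarithm (2).
#'
#' @seealso [scoreTable()]
#' @exportClass IgScoreTable
setClass("IgScoreTable",
    contains = "SummarizedExperiment",
    slots = c(antibodyClass = "character", pseudocount = "numeric",
              logBase = "numeric"))

setValidity("IgScoreTable", function(object) {
    msg <- character()
    if (!"scores" %in% names(assays(object)))
        msg <- c(msg, "assay 'scores' is required")
    else if (any(!is.finite(assay(object, "scores"))))
        msg <- c(msg, "scores must be finite (use a positive pseudocount)")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
        msg <- c(msg, "pseudocount must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

.AIRR_REQUIRED <- c("sequence_id", "cell_id", "locus", "v_call", "j_call",
    "junction", "junction_length", "c_call", "productive",
    "sequence_alignment", "germline_alignment")

#' Annotated B cell receptor rearrangements
#'
#' A \code{RearrangementSet} wraps a \linkS4class{DataFrame} of annotated
#' single-cell BCR rearrangement records in the AIRR Rearrangement layout.
#' Mandatory columns are \code{sequence_id}, \code{cell_id}, \code{locus},
#' \code{v_call}, \code{j_call}, \code{junction}, \code{junction_length},
#' \code{c_call}, \code{productive}, \code{sequence_alignment} and
#' \code{germline_alignment}; any extra columns (e.g. \code{compartment},
#' \code{group}, a simulator's \code{true_clone_id}) are carried along
#' untouched.
#'
#' Invariants enforced: unique \code{sequence_id}; \code{junction_length}
#' equals the junction string length; \code{sequence_alignment} and
#' \code{germline_alignment} have equal lengths record-wise.
#'
#' @slot rearrangements the underlying \code{DataFrame}, one row per record.
#'
#' @seealso [readRearrangements()], [qcFilter()], [assignClones()]
#' @exportClass RearrangementSet
setClass("RearrangementSet", slots = c(rearrangements = "DataFrame"))

setValidity("RearrangementSet", function(object) {
    df <- object@rearrangements
    msg <- character()
    missing <- setdiff(.AIRR_REQUIRED, colnames(df))
    if (length(missing))
        return(paste0("missing mandatory column(s): ",
                      paste(missing, collapse = ", ")))
    if (anyDuplicated(df$sequence_id))
        msg <- c(msg, "sequence_id values must be unique")
    if (!is.logical(df$productive))
        msg <- c(msg, "productive must be logical")
    bad <- which(df$junction_length != nchar(df$junction))
    if (length(bad))
        msg <- c(msg, paste0("junction_length disagrees with junction for: ",
            paste(utils::head(df$sequence_id[bad], 3L), collapse = ", ")))
    bad <- which(nchar(df$sequence_alignment) != nchar(df$germline_alignment))
    if (length(bad))
        msg <- c(msg, paste0("alignment length mismatch for: ",
            paste(utils::head(df$sequence_id[bad], 3L), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Quality-control report for a rearrangement set
#'
#' Produced by [qcFilter()]. Records pass/fail per record together with the
#' failure reasons drawn from \code{missing_vj}, \code{chain_inconsistent},
#' \code{too_many_N}, \code{cdr3_has_N}, \code{cdr3_len_not_div3} and
#' \code{nonproductive}; a record fails iff at least one reason is recorded.
#'
#' @slot perRecord \code{DataFrame} with \code{sequence_id}, logical
#'   \code{pass}, and \code{reasons} (comma-separated, empty when passing).
#' @slot reasonCounts named integer vector of failure counts per reason.
#' @exportClass QcReport
setClass("QcReport",
    slots = c(perRecord = "DataFrame", reasonCounts = "integer"))

setValidity("QcReport", function(object) {
    df <- object@perRecord
    if (!all(c("sequence_id", "pass", "reasons") %in% colnames(df)))
        return("perRecord needs sequence_id, pass, reasons")
    if (any(df$pass != (df$reasons == "")))
        return("a record fails iff at least one reason is recorded")
    TRUE
})

#' Nearest-neighbor junction distance distribution and fitted threshold
#'
#' Produced by [nearestNeighborDistances()] and [estimateThreshold()]. Holds
#' the per-sequence nearest-neighbor normalized Hamming distances computed
#' within V/J/junction-length partitions, the fitted two-component Gaussian
#' mixture parameters, and the selected clonal distance threshold.
#'
#' @slot distances numeric vector in [0, 1], one entry per sequence with at
#'   least one partition mate.
#' @slot fit list of mixture parameters (\code{mean}, \code{sd}, \code{pro})
#'   or an empty list before fitting / after a KDE fallback.
#' @slot threshold the selected threshold, or \code{NA_real_} before
#'   estimation.
#' @slot method \code{"none"}, \code{"gmm"} or \code{"kde"}.
#' @exportClass NearestNeighborDistribution
setClass("NearestNeighborDistribution",
    slots = c(distances = "numeric", fit = "list", threshold = "numeric",
              method = "character"))

setValidity("NearestNeighborDistribution", function(object) {
    d <- object@distances
    if (length(d) && (any(d < 0) || any(d > 1)))
        return("distances must lie in [0, 1]")
    th <- object@threshold
    if (!is.na(th) && (th <= 0 || th >= 1))
        return("threshold must lie in (0, 1)")
    TRUE
})

#' Clone membership of a rearrangement set
#'
#' Produced by [assignClones()]: the mapping from \code{sequence_id} to a
#' globally unique \code{clone_id}, together with the V/J/junction-length
#' partition key of each clone and the distance threshold that produced the
#' clustering. Clones never span partitions.
#'
#' @slot assignments \code{DataFrame} with \code{sequence_id},
#'   \code{clone_id}, \code{v_gene}, \code{j_gene}, \code{junction_length}.
#' @slot threshold normalized Hamming distance threshold used.
#' @exportClass CloneAssignment
setClass("CloneAssignment",
    slots = c(assignments = "DataFrame", threshold = "numeric"))

setValidity("CloneAssignment", function(object) {
    df <- object@assignments
    need <- c("sequence_id", "clone_id", "v_gene", "j_gene",
              "junction_length")
    if (!all(need %in% colnames(df)))
        return(paste("assignments needs columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(df$sequence_id))
        return("every retained sequence has exactly one clone")
    key <- paste(df$v_gene, df$j_gene, df$junction_length)
    if (any(vapply(split(key, df$clone_id),
                   function(k) length(unique(k)) > 1L, logical(1))))
        return("clones must not span V/J/length partitions")
    TRUE
})

#' PERMANOVA result
#'
#' Pseudo-F and permutation P value for a grouping factor on a distance
#' matrix, plus the permutation scheme that produced them. \code{exact = TRUE}
#' means all distinct relabelings were enumerated and P is exact.
#'
#' @slot F pseudo-F statistic (NA when degenerate, e.g. all distances zero).
#' @slot P permutation or enumeration P value.
#' @slot nPermutations number of permutations evaluated (excluding the
#'   observed labeling for the random scheme; total enumerated for exact).
#' @slot exact logical, full enumeration used.
#' @slot seed integer seed used for random permutations (NA when exact).
#' @slot groupSizes named integer vector.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
    slots = c(F = "numeric", P = "numeric", nPermutations = "integer",
              exact = "logical", seed = "integer", groupSizes = "integer"))

#' Principal coordinates ordination
#'
#' Classical metric scaling of a distance matrix: sample coordinates on the
#' axes with positive eigenvalues, all eigenvalues (non-increasing; negative
#' ones are reported but their axes dropped), and the proportion of positive
#' eigenvalue mass explained per retained axis.
#'
#' @slot coordinates samples x axes matrix.
#' @slot eigenvalues all eigenvalues, non-increasing.
#' @slot proportionExplained per retained axis.
#' @exportClass Ordination
setClass("Ordination",
    slots = c(coordinates = "matrix", eigenvalues = "numeric",
              proportionExplained = "numeric"))

setValidity("Ordination", function(object) {
    ev <- object@eigenvalues
    if (length(ev) > 1L && any(diff(ev) > 1e-8 * max(abs(ev), 1)))
        return("eigenvalues must be non-increasing")
    TRUE
})

#' Clone diversity profile with bootstrap group deltas
#'
#' Richness (Hill order 0, number of distinct clones) and inverse Simpson
#' index (Hill order 2, 1 / sum p_i^2 over clone proportions) per group, with
#' bootstrap replicate values obtained by resampling cells with replacement to
#' the minimum group cell count, the replicate-wise delta distribution between
#' groups, and its 95 percent percentile confidence interval.
#'
#' @slot observed data.frame: group, richness, invSimpson.
#' @slot replicates list of per-group matrices (replicate x index).
#' @slot delta matrix of replicate-wise differences (group2 - group1).
#' @slot deltaCI matrix of 2.5/97.5 percentiles per index.
#' @slot nBoot number of replicates.
#' @slot seed integer seed.
#' @exportClass DiversityProfile
setClass("DiversityProfile",
    slots = c(observed = "data.frame", replicates = "list", delta = "matrix",
              deltaCI = "matrix", nBoot = "integer", seed = "integer"))

#' Clonal repertoire network
#'
#' Nodes are BCR-containing cells; edges connect same-clone pairs whose
#' junction distance is at most the threshold. Edge list is deterministic
#' (endpoints sorted lexicographically).
#'
#' @slot nodes data.frame: cell_id, clone_id, isotype.
#' @slot edges data.frame: node1, node2, clone_id, distance.
#' @slot threshold junction distance cutoff used for edges.
#' @seealso [buildNetwork()], [asIgraph()]
#' @exportClass RepertoireNetwork
setClass("RepertoireNetwork",
    slots = c(nodes = "data.frame", edges = "data.frame",
              threshold = "numeric"))

setValidity("RepertoireNetwork", function(object) {
    e <- object@edges
    if (nrow(e) && any(e$node1 == e$node2))
        return("no self-edges allowed")
    TRUE
})
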