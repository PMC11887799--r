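#' @include AllClasses.R
NULL

#' Accessors for wildIg classes
#'
#' Small accessor generics: \code{fractionLabel} and \code{antibodyClass}
#' return the fraction / antibody class of a [FractionCountTable-class] or
#' [IgScoreTable-class]; \code{groupLabels} returns the named per-sample (or
#' per-record) group factor; \code{taxa} the taxon identifiers; \code{scores}
#' the score matrix; \code{rearrangements} the underlying record
#' \code{DataFrame}; \code{cloneIds} the named \code{sequence_id ->
#' clone_id} vector; \code{threshold} the distance threshold; and
#' \code{distances} the nearest-neighbor distance vector.
#'
#' @param x a wildIg object.
#' @return the accessed component; see Details.
#' @name accessors
#' @aliases fractionLabel antibodyClass groupLabels taxa scores
#'   rearrangements cloneIds threshold distances
NULL

#' @rdname accessors
#' @export
setGeneric("fractionLabel", function(x) standardGeneric("fractionLabel"))

#' @rdname accessors
#' @export
setGeneric("antibodyClass", function(x) standardGeneric("antibodyClass"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("rearrangements", function(x) standardGeneric("rearrangements"))

#' @rdname accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' Write results to deterministic tab-separated files
#'
#' Every result class can be serialized to one or more plain-text files with
#' headers; identical inputs produce byte-identical outputs. Returns the paths
#' written, invisibly.
#'
#' @param x a wildIg object.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix; defaults to a class-specific stem.
#' @return character vector of file paths, invisibly.
#' @export
setGeneric("writeResults",
    function(x, dir, prefix = NULL) standardGeneric("writeResults"))

#' Convert a repertoire network to an igraph object
#'
#' @param x a [RepertoireNetwork-class].
#' @return an \code{igraph} graph with per-node \code{clone_id} and
#'   \code{isotype} attributes.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
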