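#' @include AllClasses.R
NULL

## Labelled conditions: every user-facing failure carries a condition class
## "wildIg_<label>" so callers (and tests) can match on the label rather than
## on message wording.
.wildStop <- function(label, ...) {
    msg <- paste0(...)
    stop(structure(class = c(paste0("wildIg_", label), "error", "condition"),
        list(message = msg, call = sys.call(-1))))
}

.wildWarn <- function(label, ...) {
    msg <- paste0(...)
    warning(structure(
        class = c(paste0("wildIg_", label), "warning", "condition"),
        list(message = msg, call = sys.call(-1))))
}

.LOG_LEVELS <- c(debug = 1L, info = 2L, warning = 3L, error = 4L, quiet = 5L)

#' Set or query the logging level
#'
#' Log lines go to standard error only; results never do. Levels, from most to
#' least verbose: \code{debug}, \code{info}, \code{warning}, \code{error},
#' \code{quiet}. Default \code{info}.
#'
#' @param level one of the level names, or \code{NULL} to query.
#' @return the current level, invisibly when setting.
#' @export
logLevel <- function(level = NULL) {
    if (is.null(level))
        return(getOption("wildIg.logLevel", "info"))
    level <- match.arg(level, names(.LOG_LEVELS))
    options(wildIg.logLevel = level)
    invisible(level)
}

.log <- function(level, ...) {
    cur <- .LOG_LEVELS[[getOption("wildIg.logLevel", "info")]]
    if (.LOG_LEVELS[[level]] >= cur)
        message(sprintf("[%s] %s", level, paste0(...)))
}

## Dirichlet draws through independent gammas.
.rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                nrow = n, byrow = TRUE)
    g / rowSums(g)
}

## Gene name of an allele-level call: text before "*"; ambiguous multi-gene
## calls ("IGHV1-2*01,IGHV1-3*01") resolve to the first listed gene.
.geneOf <- function(call) {
    first <- sub(",.*$", "", call)
    sub("\\*.*$", "", first)
}

## Locus prefix (IGH/IGK/IGL) of a call; "" stays "".
.locusOf <- function(call) {
    ifelse(is.na(call) | call == "", "", substr(call, 1L, 3L))
}

.checkCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min || x != round(x))
        .wildStop("bad_argument",
                  name, " must be a single integer >= ", min)
    as.integer(x)
}

.checkGroups <- function(group) {
    group <- as.character(group)
    if (any(is.na(group) | group == ""))
        .wildStop("missing_group", "every sample needs a group label")
    group
}

## Deterministic TSV writer: fixed options so outputs are byte-stable.
.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    path
}

.formatNum <- function(x, digits = 10L) {
    formatC(x, digits = digits, format = "g")
}
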