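# Independent oracles and fixture builders shared across the suite.

# Minimal AIRR-style record table; vectors recycle to the longest.
makeRecords <- function(junction,
                        v_call = "IGHV1-1*01", j_call = "IGHJ1*01",
                        c_call = "IGHM", productive = TRUE,
                        sequence_alignment = NULL,
                        germline_alignment = NULL,
                        compartment = "naive", group = "laboratory",
                        sequence_id = NULL) {
    n <- length(junction)
    if (is.null(sequence_alignment))
        sequence_alignment <- junction
    if (is.null(germline_alignment))
        germline_alignment <- sequence_alignment
    if (is.null(sequence_id))
        sequence_id <- sprintf("s%03d", seq_len(n))
    data.frame(
        sequence_id = sequence_id,
        cell_id = paste0("c", sequence_id),
        locus = "IGH",
        v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
        junction = junction, junction_length = nchar(junction),
        c_call = rep_len(c_call, n),
        productive = rep_len(productive, n),
        sequence_alignment = rep_len(sequence_alignment, n),
        germline_alignment = rep_len(germline_alignment, n),
        compartment = rep_len(compartment, n),
        group = rep_len(group, n),
        stringsAsFactors = FALSE)
}

# Midrank-formula null distribution of U over all group assignments;
# independent of the package's direct pair-counting route.
bruteMWU <- function(x, y) {
    pool <- c(x, y)
    n1 <- length(x); n <- length(pool)
    idx <- utils::combn(n, n1)
    uOf <- function(sel) {
        r <- rank(pool)  # midranks
        sum(r[sel]) - n1 * (n1 + 1) / 2
    }
    uObs <- uOf(seq_len(n1))
    mid <- n1 * (n - n1) / 2
    uAll <- apply(idx, 2L, function(sel) {
        # recompute midranks of the same pool: U depends only on selection
        r <- rank(pool)
        sum(r[sel]) - n1 * (n1 + 1) / 2
    })
    list(U = uObs, P = mean(abs(uAll - mid) >= abs(uObs - mid) - 1e-12))
}

# Exact two-sample KS by enumeration of all group assignments.
bruteKS <- function(a, b) {
    pool <- c(a, b)
    na <- length(a); n <- length(pool)
    dOf <- function(xa, xb) {
        pts <- sort(unique(pool))
        max(abs(vapply(pts, function(t) mean(xa <= t) - mean(xb <= t),
                       numeric(1))))
    }
    dObs <- dOf(a, b)
    idx <- utils::combn(n, na)
    dAll <- apply(idx, 2L, function(sel) dOf(pool[sel], pool[-sel]))
    list(D = dObs, P = mean(dAll >= dObs - 1e-12))
}

# Connected components of the threshold graph (union-find).
bruteComponents <- function(D, th) {
    n <- nrow(D)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
        if (!is.na(D[i, j]) && D[i, j] <= th) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    vapply(seq_len(n), find, integer(1))
}

# Adjusted Rand index from the contingency table.
ariIndex <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    nPairs <- comb2(sum(tab))
    expected <- sumI * sumJ / nPairs
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}

# Memoized preset simulations shared by several tests.
presetIgseq <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- simulateIgSeq(igseqPreset(), seed = 17)
        cache
    }
})

presetRepertoire <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateRepertoire(repertoirePreset(), seed = 17)
        cache
    }
})
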