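# Evaluation metrics: adjusted Rand index for stratification, per-SNP label
# mapping against references, percentage of incorrect local ancestry, and
# SNP-wise inferred population counts.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' under the permutation model: 1 for identical partitions (up to label
#' permutation), 0 in expectation for random labellings. Valid when the two
#' partitions have different numbers of clusters.
#'
#' @param p1,p2 cluster label vectors over the same items.
#' @return the adjusted Rand index.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjustedRandIndex <- function(p1, p2) {
    if (length(p1) != length(p2))
        stop("partitions must label the same items")
    n <- length(p1)
    tab <- table(p1, p2)
    sumIJ <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expected <- sumI * sumJ / choose(n, 2)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
    (sumIJ - expected) / (maxIdx - expected)
}

# best one-to-one mapping (inferred label -> true label) maximizing
# agreement counts in the contingency matrix; exhaustive over the smaller
# side's injections (fine for the handful of populations considered here)
.bestAssignment <- function(cont) {
    infLabs <- as.integer(rownames(cont))
    truLabs <- as.integer(colnames(cont))
    nI <- length(infLabs); nT <- length(truLabs)
    best <- NULL; bestScore <- -1L
    if (nI <= nT) {
        # assign each inferred label a distinct true label (or none)
        perms <- .permutations(nT, nI)
        for (k in seq_len(nrow(perms))) {
            sc <- sum(cont[cbind(seq_len(nI), perms[k, ])])
            if (sc > bestScore) { bestScore <- sc; best <- perms[k, ] }
        }
        map <- setNames(truLabs[best], infLabs)
    } else {
        perms <- .permutations(nI, nT)
        for (k in seq_len(nrow(perms))) {
            sc <- sum(cont[cbind(perms[k, ], seq_len(nT))])
            if (sc > bestScore) { bestScore <- sc; best <- perms[k, ] }
        }
        map <- setNames(rep(NA_integer_, nI), infLabs)
        map[as.character(infLabs[best])] <- truLabs
    }
    map
}

# all ordered selections of k items from 1..n, rows in lexicographic order
# (memoized: the mapping step calls this at every SNP)
.permCache <- new.env(parent = emptyenv())
.permutations <- function(n, k) {
    key <- paste(n, k)
    if (!is.null(.permCache[[key]])) return(.permCache[[key]])
    out <- if (k == 0L) matrix(integer(), 1L, 0L) else {
        acc <- matrix(seq_len(n), ncol = 1L)
        for (d in seq_len(k - 1L)) {
            acc <- do.call(rbind, lapply(seq_len(nrow(acc)), function(rr) {
                rest <- setdiff(seq_len(n), acc[rr, ])
                cbind(matrix(acc[rr, ], length(rest), d, byrow = TRUE), rest)
            }))
        }
        unname(acc)
    }
    .permCache[[key]] <- out
    out
}

#' Map inferred population labels to true labels at each SNP
#'
#' At each SNP independently, finds the one-to-one mapping between inferred
#' and true population labels that maximizes agreement on the reference
#' haplotypes, and relabels all haplotypes accordingly. Inferred labels with
#' no reference support map to 0 ("unmatched"). This is the label-mapping
#' step used to score de novo fits, where inferred label codes are
#' arbitrary.
#'
#' @param inferred 2N x L matrix of inferred labels including the reference
#'   individuals' chains.
#' @param refTruth length-2N vector of true labels for the reference
#'   chains, `NA` for sample chains (at least one reference per true
#'   population).
#' @return 2N x L matrix of mapped labels (0 = unmatched).
#' @export
mapLabelsPerSnp <- function(inferred, refTruth) {
    refChains <- which(!is.na(refTruth))
    if (!length(refChains)) stop("no reference haplotypes given")
    if (length(refTruth) != nrow(inferred))
        stop("refTruth must have one entry per chain")
    L <- ncol(inferred)
    truLabs <- sort(unique(refTruth[refChains]))
    refTru <- match(refTruth[refChains], truLabs)
    out <- matrix(0L, nrow(inferred), L)
    for (j in seq_len(L)) {
        col <- inferred[, j]
        infLabs <- sort(unique(col))
        infRef <- match(col[refChains], infLabs)
        cont <- matrix(0L, length(infLabs), length(truLabs),
                       dimnames = list(infLabs, truLabs))
        for (k in seq_along(refChains))
            cont[infRef[k], refTru[k]] <- cont[infRef[k], refTru[k]] + 1L
        map <- .bestAssignment(cont)
        mapped <- map[match(col, infLabs)]
        mapped[is.na(mapped)] <- 0L
        out[, j] <- mapped
    }
    out
}

#' Percentage of incorrect local ancestry
#'
#' The per-SNP error is the fraction of mismatched labels after optimal
#' within-individual pairing of the two inferred labels with the two true
#' labels (phase-agnostic: the unordered pair is compared, consistent with
#' the switch-error-tolerant model). The overall error is the mean over
#' SNPs, with its standard error across SNPs.
#'
#' @param inferred,truth 2N x L label matrices (chains of individual i on
#'   rows 2i-1 and 2i). Unmatched labels (0) always count as errors.
#' @param chains optional chain indices to score (default all), e.g. to
#'   exclude reference individuals.
#' @return list with `error` (mean fraction in [0, 1]), `se` (standard
#'   error over SNPs) and `perSnp` (per-SNP fractions).
#' @export
localAncestryError <- function(inferred, truth, chains = NULL) {
    if (!all(dim(inferred) == dim(truth)))
        stop("inferred and truth must have identical dimensions")
    if (!is.null(chains)) {
        inferred <- inferred[chains, , drop = FALSE]
        truth <- truth[chains, , drop = FALSE]
    }
    C <- nrow(inferred)
    if (C %% 2L != 0L) stop("chains must come in within-individual pairs")
    o1 <- seq(1L, C, 2L); o2 <- seq(2L, C, 2L)
    a1 <- inferred[o1, , drop = FALSE]; a2 <- inferred[o2, , drop = FALSE]
    t1 <- truth[o1, , drop = FALSE]; t2 <- truth[o2, , drop = FALSE]
    direct <- (a1 != t1) + (a2 != t2)
    crossed <- (a1 != t2) + (a2 != t1)
    mism <- pmin(direct, crossed)
    perSnp <- colSums(mism) / C
    list(error = mean(perSnp),
         se = if (length(perSnp) > 1) sd(perSnp) / sqrt(length(perSnp)) else 0,
         perSnp = perSnp)
}

#' Per-SNP number of inferred populations
#'
#' The maximum a posteriori count of distinct occupied population labels at
#' each SNP across all haplotypes.
#'
#' @param x an [AncestryFit-class] (uses the sampled per-SNP counts), a
#'   single 2N x L label matrix, or a 2N x L x nSamples array of sampled
#'   labels.
#' @return integer vector of per-SNP population counts.
#' @export
populationsPerSnp <- function(x) {
    if (is(x, "AncestryFit"))
        return(as.integer(max.col(t(x@kCounts), ties.method = "first")))
    if (is.matrix(x))
        return(cpp_distinct_per_column(matrix(as.integer(x), nrow(x))))
    if (length(dim(x)) == 3L) {
        L <- dim(x)[2L]
        counts <- sapply(seq_len(dim(x)[3L]), function(s)
            cpp_distinct_per_column(matrix(as.integer(x[, , s]), dim(x)[1L])))
        return(as.integer(apply(counts, 1L, function(v)
            which.max(tabulate(v)))))
    }
    stop("unsupported input for populationsPerSnp")
}
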