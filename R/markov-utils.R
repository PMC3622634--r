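# Shared internals of the two Markov layers (haplotype states and
# population origins): new-label bookkeeping, stick counts, split moves.

# Replace runs of the collapsed super label (qstar + 1 in the sampled path)
# by freshly drawn concrete labels. Runs are delimited by the transition
# indicator: consecutive super SNPs with no event between them share one new
# label; separately entered super stretches draw independently.
.relabelNewRuns <- function(path, events, stick) {
    qstar <- length(stick@v)
    super <- qstar + 1L
    idx <- which(path >= super)
    if (length(idx)) {
        brk <- c(TRUE, diff(idx) > 1L | events[idx[-1L]] == 1L)
        runId <- cumsum(brk)
        for (rr in seq_len(max(runId))) {
            draw <- sampleNewLabel(stick)
            stick <- draw$stick
            path[idx[runId == rr]] <- draw$label
        }
    }
    list(path = path, stick = stick)
}

# c_q: occurrences of label q at event sites (indicator = 1) or chain starts
.stickCounts <- function(Q, events, qstar) {
    sel <- events == 1L
    sel[, 1L] <- TRUE
    tabulate(Q[sel], qstar)
}

# Split move on a label matrix: pick an occupied label, move a random subset
# of its event-delimited occupancy blocks to the fresh label qstar + 1 (at
# least one block moves). Event boundaries are preserved, so the indicator
# matrix stays valid. The target's stick mass is halved between old and new.
.splitPops <- function(Q, events, stick) {
    occ <- sort(unique(as.vector(Q)))
    target <- if (length(occ) == 1L) occ else occ[sample.int(length(occ), 1L)]
    qstar <- length(stick@v)
    newLab <- qstar + 1L
    C <- nrow(Q); L <- ncol(Q)
    blocks <- list()
    for (cc in seq_len(C)) {
        starts <- which(events[cc, ] == 1L)
        starts <- sort(unique(c(1L, starts)))
        ends <- c(starts[-1L] - 1L, L)
        keep <- Q[cc, starts] == target
        for (b in which(keep))
            blocks[[length(blocks) + 1L]] <- c(cc, starts[b], ends[b])
    }
    if (!length(blocks)) return(list(Q = Q, events = events, stick = stick))
    move <- runif(length(blocks)) < 0.5
    if (!any(move)) move[sample.int(length(move), 1L)] <- TRUE
    for (b in which(move)) {
        bl <- blocks[[b]]
        Q[bl[1L], bl[2L]:bl[3L]] <- newLab
    }
    v <- stick@v
    v[target] <- v[target] / 2
    v <- c(v, v[target])
    stick <- new("StickWeights", v = v, superMass = stick@superMass)
    list(Q = Q, events = events, stick = stick)
}

# iterations (within burn-in) at which split moves are applied
.splitIterations <- function(nBurnin, nSplits) {
    if (nSplits <= 0L) return(integer())
    unique(pmax(1L, round(seq(1L, max(1L, floor(nBurnin / 2)),
                              length.out = nSplits))))
}

# relabel a label matrix to dense 1..K by first appearance in column-major
# order (SNP 1 chains first); returns list(labels, perm) where
# perm[old] = new for labels that occur
.denseRelabel <- function(Q) {
    first <- unique(as.vector(Q))
    perm <- integer(max(Q))
    perm[first] <- seq_along(first)
    list(labels = matrix(perm[Q], nrow(Q)), perm = perm)
}
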