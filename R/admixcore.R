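# Probability model of the admixture layer: stick-breaking prior over
# populations, segment emission with switch-error summation, and the
# Dirichlet-marginalized admixture chain with its parameter updates.

#' Stick-breaking weights from Beta draws
#'
#' Computes \eqn{v_q = V_q \prod_{t<q}(1 - V_t)} and the residual "super"
#' mass \eqn{1 - \sum_q v_q} that collapses all labels beyond the truncation.
#'
#' @param V numeric vector of stick proportions in (0, 1].
#' @return A [StickWeights-class].
#' @examples
#' stickWeights(c(0.5, 0.5, 0.5))  # v = .5, .25, .125; super = .125
#' @export
stickWeights <- function(V) {
    if (any(V <= 0 | V > 1)) stop("stick proportions V must lie in (0, 1]")
    v <- V * cumprod(c(1, 1 - V))[seq_along(V)]
    new("StickWeights", v = v, superMass = max(0, prod(1 - V)))
}

# internal: weights + super mass as one numeric vector (super last)
.stickVec <- function(sw) c(sw@v, sw@superMass)

#' Per-SNP segment weights
#'
#' Weights that discount the redundant information of SNPs within one
#' haplotype segment. The default scheme gives every SNP in segment
#' \eqn{[a, b]} the weight
#' \eqn{w = (1 + \sum_{j'=a+1}^{b} r_{j'}) / (b - a + 1)}: the numerator is
#' the expected number of haplotype recombination events within the segment,
#' so the weighted product of emissions equals the geometric mean of the
#' per-SNP probabilities raised to that expectation. The alternative scheme
#' puts weight 1 on the first SNP of the segment and \eqn{r_j} elsewhere.
#'
#' @param a,b 1-based inclusive segment bounds, `a <= b`.
#' @param r per-SNP haplotype recombination probabilities (full-length
#'   vector, indexed by SNP).
#' @param scheme `"mean"` (default) or `"first"`.
#' @return numeric vector of weights for SNPs `a..b`.
#' @examples
#' segmentWeights(1, 4, rep(0, 4))  # 0.25 at each SNP
#' @export
segmentWeights <- function(a, b, r, scheme = c("mean", "first")) {
    scheme <- match.arg(scheme)
    if (b < a) stop("segment bounds must satisfy a <= b")
    if (scheme == "mean") {
        inner <- if (b > a) sum(r[(a + 1):b]) else 0
        rep((1 + inner) / (b - a + 1), b - a + 1)
    } else {
        c(1, r[seq.int(a + 1, length.out = b - a)])
    }
}

#' Population-specific haplotype-state emission table
#'
#' Estimates \eqn{\Pr(s | q)} per SNP with add-one smoothing:
#' \eqn{(y + 1) / (n + K_j)}, where y counts co-occurrences of state s and
#' population q across the 2N chains at SNP j, n counts chains assigned to
#' q at j, and \eqn{K_j} is the number of distinct haplotype states at j.
#' Unoccupied populations (and the super state) receive the uniform row
#' \eqn{1 / K_j}, the prior predictive for a brand-new population.
#'
#' @param S,Q 2N x L integer matrices of haplotype states and population
#'   labels.
#' @param nPops number of population slots (default `max(Q)`).
#' @return list of class `emissionTable` with elements `logProb`
#'   (maxS x (nPops + 1) x L; the last population column is the super row),
#'   `Kj`, `present` (maxS x L logical: state observed at SNP), `nPops`.
#' @export
updateEmissionTable <- function(S, Q, nPops = max(Q)) {
    stopifnot(all(dim(S) == dim(Q)))
    S <- matrix(as.integer(S), nrow(S))
    Q <- matrix(as.integer(Q), nrow(Q))
    tab <- cpp_admix_table(S, Q, as.integer(nPops))
    maxS <- dim(tab$logT)[1]
    L <- ncol(S)
    present <- matrix(FALSE, maxS, L)
    for (j in seq_len(L)) present[unique(S[, j]), j] <- TRUE
    structure(list(logProb = tab$logT, Kj = tab$Kj, present = present,
                   nPops = as.integer(nPops)),
              class = "emissionTable")
}

# internal: look up log Pr(s | q) at SNP j with contract checking
.tabLookup <- function(table, s, q, j) {
    if (!table$present[s, j])
        stop("haplotype state absent from the emission table at this SNP")
    table$logProb[s, q, j]
}

#' Block emission log-probability
#'
#' Sums the weighted log emission of all segments of one
#' double-recombination block for a fixed switch-error indicator: for
#' `delta = 0` each strand l emits its own state with weight
#' \eqn{w_{ijl}}; for `delta = 1` strand l emits the other strand's state
#' \eqn{s_{ij(3-l)}} with the strand-swapped weight \eqn{w_{ij(3-l)}}.
#'
#' @param jRange SNP indices of the block (the segments it contains).
#' @param S2,Q2,W2 2 x L matrices of states, population labels and weights
#'   for the two strands of the individual.
#' @param table an `emissionTable` built from the same S
#'   (see [updateEmissionTable()]).
#' @param delta 0 or 1, the block's switch-error indicator.
#' @return log-probability (log of the emission product over the block).
#' @export
blockEmissionLogProb <- function(jRange, S2, Q2, table, delta) {
    W2 <- attr(S2, "weights")
    stopifnot(nrow(S2) == 2L, nrow(Q2) == 2L, delta %in% c(0, 1))
    if (is.null(W2)) stop("S2 must carry a 'weights' attribute (2 x L)")
    tot <- 0
    for (j in jRange) {
        for (l in 1:2) {
            ls <- if (delta == 0) l else 3L - l
            tot <- tot + W2[ls, j] * .tabLookup(table, S2[ls, j], Q2[l, j], j)
        }
    }
    tot
}

#' Individual emission log-probability, summed over switch-error chains
#'
#' Computes \eqn{\log \sum_{\delta} \prod_m \epsilon^{|\delta_m -
#' \delta_{m-1}|} (1-\epsilon)^{1 - |\delta_m - \delta_{m-1}|} \prod_{blocks}
#' \Pr(X | \delta)} by a 2-state forward recursion over the switch-error
#' indicator along the double-recombination blocks (never by enumeration).
#' The chain is anchored at \eqn{\delta = 0} before the first site; with the
#' default \eqn{\epsilon = 0.5} the anchor choice is immaterial. The value
#' carries the same proportionality constant as the block emissions (the
#' constant cancels in sampling).
#'
#' @param S2,Q2 2 x L state / label matrices for the individual; `S2` must
#'   carry a `weights` attribute (2 x L), see [blockEmissionLogProb()].
#' @param sites double-recombination SNP indices of the individual,
#'   including SNP 1 and SNP L.
#' @param table an `emissionTable`.
#' @param eps switch-error probability in (0, 0.5].
#' @return log-probability.
#' @export
individualEmissionLogProb <- function(S2, Q2, sites, table, eps = 0.5) {
    L <- ncol(S2)
    blocks <- .blocksFromSites(sites, L)
    # forward over delta in {0, 1}
    lf <- c(0, -Inf)  # anchor delta = 0 before the first block
    ltrans <- log(matrix(c(1 - eps, eps, eps, 1 - eps), 2))
    for (m in seq_along(blocks)) {
        le <- c(blockEmissionLogProb(blocks[[m]], S2, Q2, table, 0),
                blockEmissionLogProb(blocks[[m]], S2, Q2, table, 1))
        lf <- sapply(1:2, function(d)
            .logSumExp(lf + ltrans[, d]) + le[d])
    }
    .logSumExp(lf)
}

# blocks of SNP indices between consecutive double-recombination sites;
# SNP L is appended as a closing site and does not open a new block
.blocksFromSites <- function(sites, L) {
    bs <- sort(unique(c(1L, sites, L)))
    M <- length(bs)
    if (M == 1L) return(list(1L))
    starts <- bs[-M]
    ends <- c(bs[-c(1L, M)] - 1L, L)
    lapply(seq_along(starts), function(m) seq.int(starts[m], ends[m]))
}

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Marginalized chain prior log-probability
#'
#' The prior of population origins Q and admix indicators I with the per-SNP
#' admix probabilities \eqn{\gamma_j} integrated out under their
#' \eqn{Dir(\alpha r_j, 1 - \alpha r_j)} prior:
#' \deqn{\sum_i \sum_l \big[\log v_{q_{i1l}} + \sum_j I_{ijl} \log
#'   v_{q_{ijl}}\big] + \sum_j \log \frac{\Gamma(\xi_j + \alpha r_j)
#'   \Gamma(2N - \xi_j + 1 - \alpha r_j)}{\Gamma(2N + 1) \Gamma(\alpha r_j)
#'   \Gamma(1 - \alpha r_j)}}
#' with \eqn{\xi_j = \sum_i \sum_l I_{ijl}} the total number of admix events
#' at SNP j.
#'
#' @param Q,I 2N x L matrices of labels and admix indicators
#'   (`I[, 1]` must be 0; a label change at j requires `I[, j] == 1`).
#' @param v a [StickWeights-class].
#' @param alpha small prior constant (default 0.2).
#' @param r per-SNP haplotype recombination probabilities.
#' @return log-probability.
#' @export
chainPriorLogProb <- function(Q, I, v, alpha = 0.2, r) {
    stopifnot(all(dim(Q) == dim(I)), is(v, "StickWeights"))
    C <- nrow(Q); L <- ncol(Q)
    if (any(I[, 1] != 0)) stop("I at the chain start must be 0")
    if (L >= 2) {
        chg <- Q[, -1L, drop = FALSE] != Q[, -L, drop = FALSE]
        if (any(chg & I[, -1L, drop = FALSE] == 0))
            stop("a label change requires I = 1 (AncestryState invariant)")
    }
    if (max(Q) > length(v@v)) stop("labels exceed the stick truncation")
    lv <- log(v@v)
    tot <- sum(lv[Q[, 1L]])
    if (L >= 2) {
        ev <- I[, -1L, drop = FALSE] == 1L
        tot <- tot + sum(lv[Q[, -1L, drop = FALSE][ev]])
        xi <- colSums(I[, -1L, drop = FALSE])
        if (any(xi > C)) stop("xi_j cannot exceed the number of chains")
        ar <- alpha * r[-1L]
        if (any(ar <= 0 | ar >= 1)) stop("alpha * r_j must lie in (0, 1)")
        tot <- tot + sum(lgamma(xi + ar) + lgamma(C - xi + 1 - ar) -
                         lgamma(C + 1) - lgamma(ar) - lgamma(1 - ar))
    }
    tot
}

#' Beta-binomial factor of the marginalized chain prior
#'
#' The per-SNP factor of [chainPriorLogProb()] as a function of the event
#' total \eqn{\xi}, useful for checking against numerical quadrature of
#' \eqn{\int \gamma^{\xi} (1-\gamma)^{2N-\xi} Beta(\gamma; \alpha r, 1 -
#' \alpha r) d\gamma}.
#'
#' @param xi number of admix events at the SNP (0..nChains).
#' @param ar the product \eqn{\alpha r_j \in (0, 1)}.
#' @param nChains total number of chains 2N.
#' @return the factor on the natural scale.
#' @export
chainPriorFactor <- function(xi, ar, nChains) {
    if (any(xi < 0 | xi > nChains)) stop("xi must lie in 0..nChains")
    if (ar <= 0 || ar >= 1) stop("alpha * r must lie in (0, 1)")
    exp(lgamma(xi + ar) + lgamma(nChains - xi + 1 - ar) -
        lgamma(nChains + 1) - lgamma(ar) - lgamma(1 - ar))
}

#' One row of the heterogeneous transition matrix
#'
#' The admixture chain stays with probability \eqn{(1 - \gamma_j) + \gamma_j
#' v_{cur}} (an admix event may redraw the current population) and moves to
#' population q with probability \eqn{\gamma_j v_q}; the super state
#' receives \eqn{\gamma_j} times the residual stick mass.
#'
#' @param gamma admix probability at the SNP, in [0, 1].
#' @param v a [StickWeights-class].
#' @param current current population label.
#' @return named numeric vector over labels `1..q*` and `"super"`, summing
#'   to 1.
#' @export
transitionRow <- function(gamma, v, current) {
    stopifnot(is(v, "StickWeights"), gamma >= 0, gamma <= 1)
    row <- gamma * c(v@v, v@superMass)
    row[current] <- row[current] + (1 - gamma)
    names(row) <- c(seq_along(v@v), "super")
    row
}

#' Sample the stick posterior
#'
#' Draws \eqn{V_q \sim Beta(c_q + 1, \sum_{t>q} c_t + 2)} from the posterior
#' given per-population event counts and recomputes the weights.
#'
#' @param counts per-population counts \eqn{c_q}: occurrences of population
#'   q at admix sites (I = 1) or at chain starts.
#' @return A [StickWeights-class].
#' @export
updateStickPosterior <- function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    tail <- rev(cumsum(rev(counts)))  # sum_{t >= q} c_t
    after <- c(tail[-1L], 0)          # sum_{t > q} c_t
    V <- rbeta(length(counts), counts + 1, after + 2)
    V <- pmin(pmax(V, 1e-12), 1 - 1e-12)
    stickWeights(V)
}

#' Draw the label of a new population from the residual stick
#'
#' When the backward pass selects the super state, the concrete label of the
#' new population is drawn from the residual stick-breaking prior: sequential
#' `Beta(1, 1)` sticks within the super mass, so the first unoccupied index
#' is the most probable (size-biased ordering). The stick weights are
#' extended accordingly and the super mass reduced.
#'
#' @param sw a [StickWeights-class].
#' @param Vdraws optional numeric vector of stick proportions to use instead
#'   of fresh `Beta(1, 1)` draws (for deterministic replay).
#' @return list with `label` (the new label, `> q*`) and `stick` (the
#'   updated [StickWeights-class]).
#' @export
sampleNewLabel <- function(sw, Vdraws = NULL) {
    stopifnot(is(sw, "StickWeights"))
    qstar <- length(sw@v)
    v <- sw@v
    rem <- if (qstar == 0L) 1 else sw@superMass
    if (rem <= 0) stop("no residual mass to draw from")
    k <- 0L
    repeat {
        k <- k + 1L
        V <- if (!is.null(Vdraws)) Vdraws[min(k, length(Vdraws))] else runif(1)
        piece <- rem * V
        rem <- rem - piece
        v <- c(v, piece)
        # accept index q* + k with probability V (sequential stick choice)
        if (V >= 1 || runif(1) < V || k > 1000L) break
    }
    list(label = qstar + k,
         stick = new("StickWeights", v = v, superMass = max(0, rem)))
}
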