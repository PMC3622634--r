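# Model fitting: per-individual forward-summation / backward-sampling over
# the joint diploid + switch-error state, super-state collapsing, random
# splits during burn-in, stick/emission updates, per-SNP MAP summaries and
# the fixed-K / reference mode.

#' Forward-summation and backward pass for one individual
#'
#' Runs the admixture-layer sweep for a single individual over the joint
#' state (q1, q2, delta): forward messages are computed recursively over
#' SNPs with all labels above the truncation collapsed into a super state,
#' admix transitions restricted to segment boundaries, and the switch-error
#' indicator evolving only at double-recombination sites; the backward pass
#' then samples (or maximizes) population origins, admix indicators and
#' switch errors in descending SNP order.
#'
#' This is the collapsed per-individual conditional: the admix probability
#' `gammaHat` is the Beta-Bernoulli predictive given the other individuals'
#' event counts, \eqn{(\xi_j^{(-i)} + \alpha r_j) / (2N - 1)}.
#'
#' @param emis1,emis2 (P'+1) x L weighted log-emission matrices for the two
#'   strands (rows = population labels, last row = the uniform row used for
#'   the super state and any label newer than the emission table).
#' @param boundary1,boundary2 logical length-L: `TRUE` where the strand may
#'   admix (segment starts at j >= 2).
#' @param gammaHat length-L collapsed admix probability (entry 1 unused).
#' @param stick a [StickWeights-class] (its super mass may be 0 for
#'   fixed-K fitting).
#' @param dsites logical length-L: interior double-recombination sites at
#'   which the switch-error indicator may flip.
#' @param eps switch-error probability.
#' @param mode `"sample"` or `"maximize"`.
#' @param returnForward also return the per-SNP normalized forward
#'   marginals (a P x P x 2 x L array over (q1, q2, delta)).
#' @return list with `q1`, `q2` (labels; `length(stick@v) + 1` denotes the
#'   super state), `I1`, `I2`, `delta`, `loglik`, and optionally `forward`.
#' @export
admixForwardBackward <- function(emis1, emis2, boundary1, boundary2,
                                 gammaHat, stick, dsites, eps = 0.5,
                                 mode = c("sample", "maximize"),
                                 returnForward = FALSE) {
    mode <- match.arg(mode)
    stopifnot(is(stick, "StickWeights"))
    cpp_admix_fb(emis1, emis2, as.logical(boundary1), as.logical(boundary2),
                 gammaHat, .stickVec(stick), as.logical(dsites), eps,
                 if (mode == "sample") 0L else 1L, returnForward)
}

#' Randomly split a population during burn-in
#'
#' Picks an occupied population and moves a random subset of its
#' event-delimited occupancy blocks to the fresh label `q* + 1`, giving the
#' sampler a chance to discover subtler structure; admix-indicator
#' invariants are preserved because whole blocks move. The target
#' population's stick mass is halved between the old and new label.
#'
#' @param Q,I 2N x L label and admix-indicator matrices.
#' @param stick a [StickWeights-class].
#' @return list with perturbed `Q`, `I` and extended `stick`.
#' @export
randomSplit <- function(Q, I, stick) {
    stopifnot(all(dim(Q) == dim(I)), is(stick, "StickWeights"))
    out <- .splitPops(Q, I, stick)
    list(Q = out$Q, I = out$events, stick = out$stick)
}

# strand weights and admix-boundary masks from a segment set
.segmentMatrices <- function(segs, r, scheme) {
    L <- segs@nSnps
    C <- 2L * segs@nIndividuals
    W <- matrix(0, C, L)
    A <- matrix(FALSE, C, L)
    sg <- segs@segments
    chain <- 2L * sg$individual - 2L + sg$haplotype
    for (k in seq_len(nrow(sg))) {
        idx <- sg$a[k]:sg$b[k]
        W[chain[k], idx] <- segmentWeights(sg$a[k], sg$b[k], r, scheme)
        if (sg$a[k] > 1L) A[chain[k], sg$a[k]] <- TRUE
    }
    list(W = W, A = A)
}

# grow the first dimension of a (nLab x C x L) integer count array
.growCounts <- function(acc, nLab) {
    d <- dim(acc)
    if (d[1L] >= nLab) return(acc)
    out <- array(0L, c(nLab, d[2L], d[3L]))
    out[seq_len(d[1L]), , ] <- acc
    out
}

#' Fit the admixture model
#'
#' Iterates \{emission-table update, per-individual forward-summation /
#' backward-sampling sweeps, stick (or Dirichlet) posterior update\} over
#' burn-in and sampling phases, then summarizes the posterior per SNP by
#' maximum a posteriori. Three modes:
#' \describe{
#'   \item{de novo}{no references, unknown number of populations: the
#'     stick-breaking prior with super-state collapsing determines the
#'     number of populations; burn-in applies random splits (one forced
#'     split precedes the first sweep).}
#'   \item{fixed K}{`fixedK = C` set, no reference labels: a heterogeneous
#'     finite Markov model with `C` states and a symmetric
#'     `Dirichlet(1, ..., 1)` prior on the population weights.}
#'   \item{reference}{`refLabels` given: as fixed K, but the labelled
#'     individuals' origins are pinned to their known population at every
#'     SNP; sample and reference individuals are fitted together.}
#' }
#'
#' @param hapstruct a [HaplotypeStructure-class].
#' @param segments optional [SegmentSet-class] (computed from `hapstruct`
#'   when `NULL`).
#' @param refLabels optional integer vector of length N: known population
#'   (1..C) per individual, `NA` for sample individuals.
#' @param config a [FitConfig-class].
#' @return An [AncestryFit-class]. In de novo and fixed-K mode the MAP
#'   labels are relabelled to dense 1..K by first appearance along the
#'   genome; in reference mode labels keep the reference coding.
#' @export
fitAncestry <- function(hapstruct, segments = NULL, refLabels = NULL,
                        config = FitConfig()) {
    stopifnot(is(hapstruct, "HaplotypeStructure"), is(config, "FitConfig"))
    if (!is.na(config@seed)) set.seed(config@seed)
    S <- hapstruct@S
    r <- hapstruct@r
    C <- nrow(S); N <- C %/% 2L; L <- ncol(S)
    if (is.null(segments)) segments <- segmentsFromStructure(hapstruct)
    sm <- .segmentMatrices(segments, r, config@weightScheme)
    dsiteM <- hapstruct@Phi[seq(1L, C, 2L), , drop = FALSE] == 1L &
              hapstruct@Phi[seq(2L, C, 2L), , drop = FALSE] == 1L
    dsiteM[, 1L] <- FALSE

    # exact computation grid per individual: the population state can only
    # change at segment starts (admix) or double-recombination sites (switch
    # error), so the sweep runs on those SNPs with run-summed emissions
    grids <- lapply(seq_len(N), function(i) {
        c1 <- 2L * i - 1L; c2 <- 2L * i
        mask <- sm$A[c1, ] | sm$A[c2, ] | dsiteM[i, ]
        mask[1L] <- TRUE
        g <- which(mask)
        runId <- cumsum(mask)
        list(g = g, runId = as.integer(runId), G = length(g),
             runLen = as.integer(diff(c(g, L + 1L))))
    })

    refMode <- !is.null(refLabels) && any(!is.na(refLabels))
    if (refMode && is.na(config@fixedK))
        config@fixedK <- max(refLabels, na.rm = TRUE)
    denovo <- !refMode && is.na(config@fixedK)
    if (refMode && max(refLabels, na.rm = TRUE) > config@fixedK)
        stop("reference labels exceed the fixed number of populations")
    refInd <- if (refMode) which(!is.na(refLabels)) else integer()
    refChainIdx <- as.integer(c(rbind(2L * refInd - 1L, 2L * refInd)))
    sampleInd <- setdiff(seq_len(N), refInd)
    modeInt <- if (config@mode == "sample") 0L else 1L
    eps <- config@eps
    alphaR <- config@alpha * r
    alphaR[1L] <- config@alpha * 1e-6

    # initialization: deterministic, label-stable
    I <- matrix(0L, C, L)
    if (denovo) {
        Q <- matrix(1L, C, L)
        stick <- updateStickPosterior(.stickCounts(Q, I, 1L))
        sp <- .splitPops(Q, I, stick)       # forced split before first sweep
        Q <- sp$Q; stick <- sp$stick
    } else {
        K <- config@fixedK
        Q <- matrix(rep(sample.int(K, N, replace = TRUE), each = 2L), C, L)
        if (refMode)
            Q[rep(2L * refInd, each = 2L) - c(1L, 0L), ] <-
                rep(refLabels[refInd], each = 2L)
        vK <- rgamma(K, 1 + tabulate(Q[, 1L], K))
        stick <- new("StickWeights", v = vK / sum(vK), superMass = 0)
    }
    splitIters <- if (denovo) .splitIterations(config@nBurnin,
                                               config@nRandomSplits)
                  else integer()

    xi <- colSums(I)
    nSlots <- 8L
    labCounts <- array(0L, c(nSlots, C, L))
    kCounts <- matrix(0L, nSlots, L)
    xiAcc <- numeric(L)
    # sampled switch-error indicator per individual: labels q refer to the
    # latent chains, so the emission table must pair q with the state of the
    # delta-corrected strand, and summaries report observed-strand labels
    D <- matrix(0L, N, L)
    swapRows <- function(M, D) {
        out <- M
        for (i in seq_len(N)) {
            sw <- D[i, ] == 1L
            if (any(sw)) {
                c1 <- 2L * i - 1L; c2 <- 2L * i
                out[c1, sw] <- M[c2, sw]
                out[c2, sw] <- M[c1, sw]
            }
        }
        out
    }

    for (iter in seq_len(config@nBurnin + config@nSamples)) {
        qstar <- length(stick@v)
        Stil <- swapRows(S, D)  # delta-corrected: state emitted by chain
        if (refMode && iter == 1L) {
            # anchor the label coding to the references on the first sweep:
            # with randomly initialized sample labels the table would be
            # dominated by the (much more numerous) sample chains, and a
            # regionally anti-reference coding can lock in
            Qanchor <- Q
            Qanchor[-refChainIdx, ] <- 0L
            cnt <- cpp_admix_counts(Stil, Qanchor, qstar)
        } else {
            cnt <- cpp_admix_counts(Stil, Q, qstar)
        }
        for (i in sampleInd) {
            c1 <- 2L * i - 1L; c2 <- 2L * i
            gr <- grids[[i]]
            gam <- (xi - I[c1, ] - I[c2, ] + alphaR) / ((C - 2) + 1)
            # leave-one-out emissions: exclude this individual's own
            # previous (state, label) contributions from the table (the
            # reference-anchored first table contains no sample chains,
            # so there is nothing to exclude then)
            sOwn <- Stil[c(c1, c2), , drop = FALSE]
            qOwn <- if (refMode && iter == 1L)
                matrix(0L, 2L, L) else Q[c(c1, c2), , drop = FALSE]
            M1 <- cpp_strand_emission_loo(cnt$y, cnt$n, cnt$Kj, S[c1, ],
                                          sOwn, qOwn, sm$W[c1, ], qstar,
                                          gr$runId, gr$G)
            M2 <- cpp_strand_emission_loo(cnt$y, cnt$n, cnt$Kj, S[c2, ],
                                          sOwn, qOwn, sm$W[c2, ], qstar,
                                          gr$runId, gr$G)
            res <- cpp_admix_fb(M1, M2, sm$A[c1, gr$g], sm$A[c2, gr$g],
                                gam[gr$g], .stickVec(stick),
                                dsiteM[i, gr$g], eps, modeInt)
            if (denovo) {
                rel1 <- .relabelNewRuns(res$q1, res$I1, stick)
                stick <- rel1$stick
                rel2 <- .relabelNewRuns(res$q2, res$I2, stick)
                stick <- rel2$stick
                res$q1 <- rel1$path; res$q2 <- rel2$path
            }
            q1 <- rep.int(res$q1, gr$runLen)
            q2 <- rep.int(res$q2, gr$runLen)
            I1 <- I2 <- integer(L)
            I1[gr$g] <- res$I1; I2[gr$g] <- res$I2
            xi <- xi - I[c1, ] - I[c2, ] + I1 + I2
            Q[c1, ] <- q1; Q[c2, ] <- q2
            I[c1, ] <- I1; I[c2, ] <- I2
            D[i, ] <- rep.int(res$delta, gr$runLen)
        }
        if (iter %in% splitIters) {
            sp <- .splitPops(Q, I, stick)
            Q <- sp$Q; stick <- sp$stick
        }
        if (denovo) {
            qstar <- max(Q)
            stick <- updateStickPosterior(.stickCounts(Q, I, qstar))
        } else {
            cK <- .stickCounts(Q, I, config@fixedK)
            vK <- rgamma(config@fixedK, 1 + cK)
            stick <- new("StickWeights", v = vK / sum(vK), superMass = 0)
        }
        if (iter > config@nBurnin) {
            mx <- max(Q)
            if (mx > nSlots) {
                nSlots <- mx
                labCounts <- .growCounts(labCounts, nSlots)
                kCounts <- rbind(kCounts,
                                 matrix(0L, nSlots - nrow(kCounts), L))
            }
            Qobs <- swapRows(Q, D)  # observed-strand-aligned labels
            cpp_accumulate_labels(Qobs, labCounts, nSlots)
            kj <- cpp_distinct_per_column(Q)
            kCounts[cbind(kj, seq_len(L))] <- kCounts[cbind(kj,
                                                            seq_len(L))] + 1L
            xiAcc <- xiAcc + xi
        }
    }

    # per-SNP maximum a posteriori (ties: lowest label)
    mapLab <- matrix(0L, C, L)
    for (cc in seq_len(C))
        mapLab[cc, ] <- max.col(t(labCounts[, cc, , drop = TRUE]),
                                ties.method = "first")
    kPerSnp <- max.col(t(kCounts), ties.method = "first")
    if (!refMode) {
        rel <- .denseRelabel(mapLab)
        mapLab <- rel$labels
        keep <- which(rel$perm > 0L)
        ord <- keep[order(rel$perm[keep])]
        ord <- c(ord, setdiff(seq_len(nSlots), ord))
        labCounts <- labCounts[ord, , , drop = FALSE]
    }
    new("AncestryFit", mapLabels = mapLab, labelCounts = labCounts,
        kCounts = kCounts, kPerSnp = as.integer(kPerSnp),
        admixRate = xiAcc / config@nSamples / C,
        nPops = max(mapLab), nSamples = config@nSamples,
        refChains = as.integer(c(rbind(2L * refInd - 1L, 2L * refInd))),
        positions = hapstruct@positions)
}

#' Individual-level stratification labels from a fit
#'
#' Majority label per individual over all SNPs and both chains of the MAP
#' labelling — the partition used to score stratification recovery.
#'
#' @param fit an [AncestryFit-class].
#' @return integer vector of length N.
#' @export
stratificationLabels <- function(fit) {
    stopifnot(is(fit, "AncestryFit"))
    M <- fit@mapLabels
    N <- nrow(M) %/% 2L
    vapply(seq_len(N), function(i) {
        tab <- tabulate(M[c(2L * i - 1L, 2L * i), ])
        which.max(tab)
    }, integer(1))
}

#' @describeIn fitAncestry MAP per-SNP per-chain labels of a fit.
#' @param fit an [AncestryFit-class].
#' @export
ancestryLabels <- function(fit) fit@mapLabels

#' @describeIn fitAncestry per-SNP posterior mean admix-event rate.
#' @export
admixRate <- function(fit) fit@admixRate
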