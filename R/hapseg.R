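# Haplotype segmentation layer: infer haplotype states S, transition
# indicators Phi and per-SNP recombination probabilities r from phased
# haplotypes, genotypes or sequencing read counts.

#' Poisson read-count log-likelihood given a genotype
#'
#' Models the two allele counts at a site by independent Poisson draws with
#' means `coverage * dosage / 2` (minor allele) and
#' `coverage * (2 - dosage) / 2` (major allele). Each mean is floored at
#' `errFloor` so the support stays valid when a dosage puts zero expectation
#' on an allele.
#'
#' @param d count pair `c(major, minor)`, or a 2-column matrix of pairs.
#' @param g genotype dosage in \{0, 1, 2\} (number of minor alleles).
#' @param coverage mean total depth.
#' @param errFloor floor on each Poisson mean (default 1e-3).
#' @return log-likelihood (vector if `d` is a matrix).
#' @examples
#' readLikelihood(c(3, 5), 1, 8)  # log Pois(3; 4) + log Pois(5; 4)
#' @export
readLikelihood <- function(d, g, coverage, errFloor = 1e-3) {
    if (is.null(dim(d))) d <- matrix(d, ncol = 2L)
    if (any(d < 0)) stop("read counts must be non-negative")
    mMinor <- pmax(coverage * g / 2, errFloor)
    mMajor <- pmax(coverage * (2 - g) / 2, errFloor)
    dpois(d[, 2L], mMinor, log = TRUE) + dpois(d[, 1L], mMajor, log = TRUE)
}

# 3 x L genotype log-likelihood matrix for one individual's read counts
.readLogPg <- function(ref, alt, coverage, errFloor = 1e-3) {
    t(vapply(0:2, function(g)
        readLikelihood(cbind(ref, alt), g, coverage, errFloor),
        numeric(length(ref))))
}

#' Infer haplotype structure
#'
#' Fits the segmentation layer: an infinite-state Markov chain per haplotype
#' with per-SNP Bernoulli allele emissions per state, a stick-breaking prior
#' over states, and Dirichlet-marginalized per-SNP transition rates (the
#' same machinery the admixture layer uses on population origins). Chains
#' are updated one at a time by forward-summation / backward-sampling with
#' all unoccupied states collapsed into a "super" state; burn-in uses random
#' state splits to escape local modes. The output is the posterior-mode
#' state matrix `S`, the transition indicators `Phi`, the per-SNP
#' recombination probability `r` (posterior mean transition frequency
#' across chains, floored at 1e-6), and the haplotypes `H` (called from
#' reads/genotypes, or taken as given for phased input).
#'
#' With read-count or genotype input the two chains of an individual are
#' updated jointly over pairs of states, so the genotype likelihood factors
#' correctly; latent alleles are sampled alongside.
#'
#' @param data a 2N x L 0/1 haplotype matrix (phased input), an N x L
#'   dosage matrix in \{0,1,2\} (genotype input), or a [ReadCounts-class].
#' @param positions optional SNP bp positions (taken from `data` when it is
#'   a [ReadCounts-class]).
#' @param input `"auto"` (default), `"haplotypes"`, `"genotypes"` or
#'   `"reads"`.
#' @param nBurnin,nSamples burn-in / posterior sampling iterations.
#' @param nRandomSplits random state splits during burn-in (default 10; the
#'   state layer must discover many more states than the population layer,
#'   so it splits more often).
#' @param recombRate prior haplotype recombinations per bp (default
#'   1/200000, one per 200 kb): sets the prior per-interval transition level
#'   `rho0_j = min(0.5, recombRate * bp gap)`.
#' @param priorStrength pseudo-count weight `kappa` of the transition-rate
#'   prior `Beta(kappa * rho0_j, kappa * (1 - rho0_j))`; the collapsed
#'   predictive for one chain is `(count + kappa * rho0_j) / (2N - 1 +
#'   kappa)`, so `kappa` balances the prior recombination level against the
#'   transition counts of the other chains (default 10).
#' @param coverage mean depth for read input (default: estimated from the
#'   data).
#' @param errFloor floor on Poisson means, see [readLikelihood()].
#' @param seed optional RNG seed.
#' @return A [HaplotypeStructure-class].
#' @export
inferHaplotypeStructure <- function(data, positions = NULL, input = "auto",
                                    nBurnin = 20L, nSamples = 30L,
                                    nRandomSplits = 10L,
                                    recombRate = 1 / 200000,
                                    priorStrength = 10, coverage = NULL,
                                    errFloor = 1e-3, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    input <- match.arg(input, c("auto", "haplotypes", "genotypes", "reads"))
    if (is(data, "ReadCounts")) {
        input <- "reads"
        if (is.null(positions)) positions <- data@positions
    } else if (input == "auto") {
        input <- if (all(data %in% c(0L, 1L))) "haplotypes" else "genotypes"
    }
    if (input == "reads") {
        L <- ncol(data@refCount); N <- nrow(data@refCount)
    } else {
        L <- ncol(data); N <- if (input == "haplotypes") nrow(data) / 2L
                              else nrow(data)
    }
    if (L < 2L) stop("need at least 2 SNPs")
    if (is.null(positions)) positions <- seq_len(L)
    C <- 2L * N

    # per-individual 3 x L genotype log-likelihoods (diploid modes)
    logPg <- NULL
    if (input == "reads") {
        if (is.null(coverage))
            coverage <- mean(data@refCount + data@altCount)
        logPg <- lapply(seq_len(N), function(i)
            .readLogPg(data@refCount[i, ], data@altCount[i, ], coverage,
                       errFloor))
    } else if (input == "genotypes") {
        if (!all(data %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
        logPg <- lapply(seq_len(N), function(i) {
            m <- matrix(-Inf, 3L, L)
            m[cbind(data[i, ] + 1L, seq_len(L))] <- 0
            m
        })
    }

    # initial haplotypes
    if (input == "haplotypes") {
        H <- matrix(as.integer(data), C, L)
    } else {
        H <- matrix(0L, C, L)
        for (i in seq_len(N)) {
            ghat <- max.col(t(logPg[[i]]), ties.method = "first") - 1L
            H[2L * i - 1L, ] <- as.integer(ghat >= 1L)  # het minor to strand 1
            H[2L * i, ] <- as.integer(ghat == 2L)
        }
    }

    S <- matrix(1L, C, L)
    Phi <- matrix(0L, C, L)
    stick <- updateStickPosterior(.stickCounts(S, Phi, 1L))
    sp <- .splitPops(S, Phi, stick)   # forced initial split
    S <- sp$Q; stick <- sp$stick
    splitIters <- .splitIterations(nBurnin, nRandomSplits)
    rAcc <- numeric(L)
    rho0 <- pmin(0.5, recombRate * c(0, diff(positions)))
    rprior <- priorStrength * rho0

    sweep <- function(S, Phi, stick, mode) {
        qstar <- length(stick@v)
        cnt <- cpp_hap_counts(S, H, qstar)
        phiTot <- colSums(Phi)
        if (input == "haplotypes") {
            for (cc in seq_len(C)) {
                rho <- (phiTot - Phi[cc, ] + rprior) /
                    ((C - 1) + priorStrength)
                th <- cpp_hap_theta_loo(cnt$y1, cnt$n,
                                        S[cc, , drop = FALSE],
                                        H[cc, , drop = FALSE])
                res <- cpp_chain_fb(th$lth1, th$lth0, H[cc, ], rho,
                                    .stickVec(stick), mode)
                rel <- .relabelNewRuns(res$path, res$phi, stick)
                stick <- rel$stick
                phiTot <- phiTot - Phi[cc, ] + res$phi
                S[cc, ] <- rel$path
                Phi[cc, ] <- res$phi
            }
        } else {
            for (i in seq_len(N)) {
                c1 <- 2L * i - 1L; c2 <- 2L * i
                rho <- (phiTot - Phi[c1, ] - Phi[c2, ] + rprior) /
                    ((C - 2) + priorStrength)
                th <- cpp_hap_theta_loo(cnt$y1, cnt$n,
                                        S[c(c1, c2), , drop = FALSE],
                                        H[c(c1, c2), , drop = FALSE])
                res <- cpp_pair_fb(logPg[[i]], th$lth1, th$lth0, rho,
                                   .stickVec(stick), mode)
                rel1 <- .relabelNewRuns(res$s1, res$phi1, stick)
                stick <- rel1$stick
                rel2 <- .relabelNewRuns(res$s2, res$phi2, stick)
                stick <- rel2$stick
                phiTot <- phiTot - Phi[c1, ] - Phi[c2, ] + res$phi1 + res$phi2
                S[c1, ] <- rel1$path; S[c2, ] <- rel2$path
                Phi[c1, ] <- res$phi1; Phi[c2, ] <- res$phi2
                H[c1, ] <- res$h1; H[c2, ] <- res$h2
            }
        }
        list(S = S, Phi = Phi, stick = stick, H = H)
    }

    for (iter in seq_len(nBurnin + nSamples)) {
        sw <- sweep(S, Phi, stick, 0L)
        S <- sw$S; Phi <- sw$Phi; stick <- sw$stick; H <- sw$H
        if (iter %in% splitIters) {
            sp <- .splitPops(S, Phi, stick)
            S <- sp$Q; stick <- sp$stick
        }
        qstar <- max(S)
        stick <- updateStickPosterior(.stickCounts(S, Phi, qstar))
        if (iter > nBurnin) rAcc <- rAcc + colSums(Phi) / C
    }

    # posterior-mode structure: one maximization sweep at the final parameters
    sw <- sweep(S, Phi, stick, 1L)
    S <- sw$S; Phi <- sw$Phi; H <- sw$H
    S <- .denseRelabel(S)$labels
    r <- pmax(rAcc / nSamples, 1e-6)
    r[1L] <- 1e-6
    new("HaplotypeStructure", S = S, Phi = Phi, r = r,
        H = matrix(as.integer(H), C, L), positions = as.numeric(positions))
}

#' Haplotype segments and double-recombination sites from a structure
#'
#' Segments are the maximal runs of constant haplotype state per chain;
#' double-recombination sites of an individual are the SNPs at which both
#' of its chains transition (`Phi == 1` on both), with SNP 1 and SNP L
#' always included. Blocks of segments between consecutive sites are the
#' units over which the switch-error indicator is constant.
#'
#' @param hs a [HaplotypeStructure-class].
#' @return A [SegmentSet-class].
#' @examples
#' # a chain with states (1,1,2,2,2) yields segments [1,2] and [3,5]
#' @export
segmentsFromStructure <- function(hs) {
    stopifnot(is(hs, "HaplotypeStructure"))
    S <- hs@S; Phi <- hs@Phi
    C <- nrow(S); L <- ncol(S); N <- C %/% 2L
    segs <- vector("list", C)
    for (cc in seq_len(C)) {
        rl <- rle(S[cc, ])
        b <- cumsum(rl$lengths)
        a <- c(1L, head(b, -1L) + 1L)
        segs[[cc]] <- data.frame(
            individual = (cc + 1L) %/% 2L,
            haplotype = 2L - (cc %% 2L),
            a = a, b = b, state = rl$values)
    }
    sites <- lapply(seq_len(N), function(i) {
        both <- which(Phi[2L * i - 1L, ] == 1L & Phi[2L * i, ] == 1L)
        sort(unique(c(1L, both, L)))
    })
    new("SegmentSet", segments = do.call(rbind, segs), sites = sites,
        nSnps = L, nIndividuals = N)
}

#' Apply strand flips (switch errors) to a haplotype structure
#'
#' Swaps the two strands of the given individuals from the given SNP
#' onwards, in `S`, `Phi` and `H` — the operation a phasing switch error
#' performs. Useful for probing the model's robustness to mis-phased input.
#'
#' @param hs a [HaplotypeStructure-class].
#' @param flips data.frame with columns `individual` and `snp`.
#' @return the modified [HaplotypeStructure-class].
#' @export
applyStrandFlips <- function(hs, flips) {
    stopifnot(is(hs, "HaplotypeStructure"))
    L <- ncol(hs@S)
    S <- hs@S; Phi <- hs@Phi; H <- hs@H
    for (k in seq_len(nrow(flips))) {
        i <- flips$individual[k]; j <- flips$snp[k]
        c1 <- 2L * i - 1L; c2 <- 2L * i
        cols <- j:L
        for (m in c("S", "Phi", "H")) {
            M <- get(m)
            tmp <- M[c1, cols]
            M[c1, cols] <- M[c2, cols]
            M[c2, cols] <- tmp
            assign(m, M)
        }
        if (j > 1L) for (cc in c(c1, c2))   # a flip is itself a transition
            if (S[cc, j] != S[cc, j - 1L]) Phi[cc, j] <- 1L
    }
    new("HaplotypeStructure", S = S, Phi = Phi, r = hs@r, H = H,
        positions = hs@positions)
}
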