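# Admixture simulator: ancestral panels, mosaic haplotypes under a genetic
# map, Poisson sequencing reads, and ground-truth ancestry tracks.

#' Interpolate per-SNP crossover probabilities from a genetic map
#'
#' Cumulative centimorgan positions at the SNPs are obtained by linear
#' interpolation of the map anchors; positions beyond the anchors are
#' extrapolated at the nearest interval's rate. The per-SNP crossover
#' probability per generation is \eqn{d_j = (cM_j - cM_{j-1}) / 100}
#' (1 cM = 1\% recombination per generation); \eqn{d_1} is undefined (the
#' chain start) and returned as `NA`.
#'
#' @param map a [GeneticMap-class] object.
#' @param snpPositions sorted bp positions of the SNPs.
#' @return numeric vector of length `length(snpPositions)`; element 1 is
#'   `NA`, elements j >= 2 are `d_j >= 0`.
#' @examples
#' gm <- GeneticMap(c(0, 1e6), c(0, 1))
#' interpolateMap(gm, c(0, 5e5))  # NA, 0.005
#' @export
interpolateMap <- function(map, snpPositions) {
    stopifnot(is(map, "GeneticMap"))
    if (is.unsorted(snpPositions))
        stop("snpPositions must be sorted in increasing order")
    cm <- .mapCm(map, snpPositions)
    c(NA_real_, diff(cm) / 100)
}

# cumulative cM at arbitrary positions, with rate-preserving extrapolation
.mapCm <- function(map, x) {
    p <- map@positions
    cm <- map@cM
    out <- approx(p, cm, xout = x, rule = 2)$y
    n <- length(p)
    lo <- x < p[1]
    hi <- x > p[n]
    if (any(lo)) {
        rate <- (cm[2] - cm[1]) / (p[2] - p[1])
        out[lo] <- cm[1] + (x[lo] - p[1]) * rate
    }
    if (any(hi)) {
        rate <- (cm[n] - cm[n - 1]) / (p[n] - p[n - 1])
        out[hi] <- cm[n] + (x[hi] - p[n]) * rate
    }
    out
}

#' Uniform-rate genetic map
#'
#' Convenience constructor for a constant-rate map over one chromosome, used
#' by the simulator when no empirical map is supplied.
#'
#' @param chromLength chromosome length in bp.
#' @param cMperMb map rate in centimorgan per megabase (default 1, the
#'   genome-wide human average).
#' @return A [GeneticMap-class].
#' @export
uniformGeneticMap <- function(chromLength, cMperMb = 1) {
    GeneticMap(c(0, chromLength), c(0, chromLength / 1e6 * cMperMb))
}

#' Per-SNP admixture probability
#'
#' The probability of an admix event between SNPs j-1 and j after
#' `lambda` generations of admixture is \eqn{1 - \exp(-\lambda d_j)}.
#' `lambda = 0` gives 0 everywhere: the pure-stratification special case.
#'
#' @param lambda generations of admixture (>= 0).
#' @param d per-SNP crossover probability (>= 0); `NA` entries (the chain
#'   start) propagate.
#' @return probabilities in [0, 1).
#' @examples
#' admixProbability(24, 0.01)  # 1 - exp(-0.24)
#' @export
admixProbability <- function(lambda, d) {
    if (lambda < 0) stop("lambda must be >= 0")
    if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
    1 - exp(-lambda * d)
}

#' Simulate divergent ancestral panels
#'
#' Draws per-population allele frequencies from a Balding-Nichols-style
#' divergence model: an ancestral frequency \eqn{p \sim U(0.05, 0.95)} per
#' SNP, then population frequencies
#' \eqn{p_k \sim Beta(p(1-F)/F, (1-p)(1-F)/F)} with fixation index `F`.
#' A pool of template haplotypes per population is then sampled from the
#' population frequencies; mosaic individuals are later copied from these
#' templates, which induces the haplotype sharing (LD) the segmentation
#' layer exploits.
#'
#' @param K number of populations.
#' @param L number of SNPs.
#' @param chromLength chromosome length in bp (SNP positions are uniform).
#' @param F fixation index controlling divergence (default 0.2).
#' @param nHapPool template haplotypes per population (default 8); set to 0
#'   for a frequency-only panel.
#' @param ancestralRange range of the ancestral frequency draw.
#' @param seed optional RNG seed.
#' @return An [AncestralPanel-class].
#' @export
simulatePanel <- function(K, L, chromLength = L * 6000, F = 0.2, nHapPool = 8,
                          ancestralRange = c(0.05, 0.95), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    positions <- sort(sample.int(chromLength, L))
    p0 <- runif(L, ancestralRange[1], ancestralRange[2])
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    freqs <- matrix(rbeta(K * L, rep(a, each = K), rep(b, each = K)),
                    nrow = K, ncol = L)
    haps <- list()
    if (nHapPool > 0) {
        haps <- lapply(seq_len(K), function(k) {
            matrix(rbinom(nHapPool * L, 1L, rep(freqs[k, ], each = nHapPool)),
                   nrow = nHapPool, ncol = L)
        })
    }
    new("AncestralPanel", freqs = freqs, haplotypes = haps,
        positions = as.numeric(positions))
}

#' Simulate mosaic admixed individuals under a genetic map
#'
#' Each haplotype is generated as a mosaic: at each SNP j >= 2, with
#' probability \eqn{1 - \exp(-\lambda d_j)} the ancestral population is
#' redrawn from the admixture proportions (an admix event; it may land on
#' the current population, so visible ancestry switches are a subset of
#' events) and a new template haplotype is drawn from the new population's
#' pool. Otherwise, within the current population the template switches
#' with probability `min(1, rate x bp gap)` (one recombination per 200 kb in
#' expectation by default). Alleles are copied from the template, or drawn
#' `Bernoulli(freq)` for a frequency-only panel. The truth track records
#' the population of every chain at every SNP.
#'
#' @param panel an [AncestralPanel-class].
#' @param cfg an [AdmixtureConfig-class].
#' @param map a [GeneticMap-class] (defaults to a uniform 1 cM/Mb map over
#'   the panel's positions).
#' @param nIndividuals number of diploid individuals to simulate.
#' @param seed optional RNG seed (identical seeds give identical output).
#' @return An [AdmixedSample-class].
#' @export
simulateAdmixedSample <- function(panel, cfg, map = NULL, nIndividuals, seed = NULL) {
    stopifnot(is(panel, "AncestralPanel"), is(cfg, "AdmixtureConfig"))
    if (!is.null(seed)) set.seed(seed)
    K <- nrow(panel@freqs)
    if (K == 0L) stop("empty ancestral panel")
    if (length(cfg@proportions) != K)
        stop("proportions must have one entry per panel population")
    pos <- panel@positions
    L <- length(pos)
    if (is.null(map)) map <- uniformGeneticMap(max(pos) + 1)
    d <- interpolateMap(map, pos)
    pAdmix <- admixProbability(cfg@lambda, d)
    pAdmix[1] <- 0
    gaps <- c(0, diff(pos))
    pRecomb <- pmin(1, cfg@withinPopRecombRate * gaps)
    hasPool <- length(panel@haplotypes) > 0L
    nChains <- 2L * nIndividuals
    H <- matrix(0L, nChains, L)
    truth <- matrix(0L, nChains, L)
    props <- cfg@proportions
    # lambda = 0 is the stratification special case: an individual belongs to
    # one population, so both of its chains share the founding draw; with
    # admixture (lambda > 0) each haplotype is an independent mosaic
    indPop <- if (cfg@lambda == 0)
        rep(vapply(seq_len(nIndividuals), function(i)
            sample.int(K, 1L, prob = props), integer(1)), each = 2L)
    else integer()
    for (cc in seq_len(nChains)) {
        pop <- if (cfg@lambda == 0) indPop[cc]
               else sample.int(K, 1L, prob = props)
        tpl <- if (hasPool) sample.int(nrow(panel@haplotypes[[pop]]), 1L) else 0L
        for (j in seq_len(L)) {
            if (j > 1L) {
                if (runif(1) < pAdmix[j]) {
                    pop <- sample.int(K, 1L, prob = props)
                    tpl <- if (hasPool)
                        sample.int(nrow(panel@haplotypes[[pop]]), 1L) else 0L
                } else if (hasPool && runif(1) < pRecomb[j]) {
                    tpl <- sample.int(nrow(panel@haplotypes[[pop]]), 1L)
                }
            }
            truth[cc, j] <- pop
            H[cc, j] <- if (hasPool) panel@haplotypes[[pop]][tpl, j]
                        else rbinom(1L, 1L, panel@freqs[pop, j])
        }
    }
    new("AdmixedSample", haplotypes = H, truth = truth,
        positions = pos, d = d)
}

#' Simulate Poisson sequencing reads from genotype dosages
#'
#' For each site, minor-allele reads are drawn
#' `Poisson(coverage x dosage / 2)` and major-allele reads
#' `Poisson(coverage x (2 - dosage) / 2)`, so the total depth has mean
#' `coverage`. An optional per-read flip probability models base errors
#' (default 0: the Poisson read model has no base-error term).
#'
#' @param genotypes N x L matrix of minor-allele dosages in \{0, 1, 2\}.
#' @param coverage mean total depth (> 0).
#' @param seed optional RNG seed.
#' @param errorRate per-read allele flip probability.
#' @param positions optional SNP bp positions (default 1..L).
#' @return A [ReadCounts-class].
#' @export
simulateReads <- function(genotypes, coverage, seed = NULL, errorRate = 0,
                          positions = NULL) {
    if (coverage <= 0) stop("coverage must be > 0")
    if (!all(genotypes %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
    if (!is.null(seed)) set.seed(seed)
    n <- length(genotypes)
    alt <- matrix(rpois(n, coverage * genotypes / 2), nrow(genotypes))
    ref <- matrix(rpois(n, coverage * (2 - genotypes) / 2), nrow(genotypes))
    if (errorRate > 0) {
        altFlip <- matrix(rbinom(n, alt, errorRate), nrow(genotypes))
        refFlip <- matrix(rbinom(n, ref, errorRate), nrow(genotypes))
        alt <- alt - altFlip + refFlip
        ref <- ref - refFlip + altFlip
    }
    if (is.null(positions)) positions <- seq_len(ncol(genotypes))
    new("ReadCounts", refCount = ref, altCount = alt,
        positions = as.numeric(positions))
}

#' Drop non-polymorphic SNPs
#'
#' Removes SNPs at which all called alleles (or genotypes) are identical and
#' returns the mapping from kept columns back to the original indices.
#'
#' @param calls matrix of called alleles/genotypes (rows = chains or
#'   individuals, columns = SNPs).
#' @return list with `data` (the reduced matrix) and `kept` (original column
#'   indices of the retained SNPs).
#' @export
filterNonpolymorphic <- function(calls) {
    if (!is.matrix(calls)) stop("calls must be a matrix")
    poly <- apply(calls, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
    list(data = calls[, poly, drop = FALSE], kept = which(poly))
}

#' Simulate an admixture benchmark: admixed individuals plus references
#'
#' Draws an ancestral panel, simulates `nAdmixed` admixed diploids under
#' `lambda` generations of admixture with equal proportions, and appends
#' `nRefPerPop` pure individuals per population (candidate references).
#' All individuals share one panel and genetic map; the references are
#' simulated as the `lambda = 0` special case of their own population.
#'
#' @param K number of ancestral populations.
#' @param L number of SNPs.
#' @param lambda generations of admixture for the admixed individuals.
#' @param nAdmixed number of admixed diploids.
#' @param nRefPerPop pure reference diploids per population (0 for none).
#' @param F fixation index of the panel divergence model.
#' @param nHapPool template haplotypes per population.
#' @param chromLength chromosome length in bp.
#' @param cMperMb genetic map rate.
#' @param seed optional RNG seed.
#' @return list with `sample` (an [AdmixedSample-class]; admixed
#'   individuals first, then references), `refLabels` (length-N integer
#'   vector: `NA` for admixed individuals, the true population for
#'   references) and `refTruth` (the same per chain, length 2N).
#' @export
simulateAdmixtureBenchmark <- function(K = 2, L = 5000, lambda = 8,
                                       nAdmixed = 20, nRefPerPop = 2,
                                       F = 0.2, nHapPool = 8,
                                       chromLength = 3e7, cMperMb = 1,
                                       seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    panel <- simulatePanel(K, L, chromLength, F, nHapPool)
    map <- uniformGeneticMap(chromLength + 1, cMperMb)
    adm <- simulateAdmixedSample(panel, AdmixtureConfig(lambda, rep(1, K) / K),
                                 map, nAdmixed)
    H <- adm@haplotypes
    truth <- adm@truth
    if (nRefPerPop > 0) {
        for (k in seq_len(K)) {
            props <- as.numeric(seq_len(K) == k)
            ref <- simulateAdmixedSample(panel, AdmixtureConfig(0, props),
                                         map, nRefPerPop)
            H <- rbind(H, ref@haplotypes)
            truth <- rbind(truth, ref@truth)
        }
    }
    sample <- new("AdmixedSample", haplotypes = H, truth = truth,
                  positions = adm@positions, d = adm@d)
    refLabels <- c(rep(NA_integer_, nAdmixed),
                   rep(seq_len(K), each = nRefPerPop))
    list(sample = sample, refLabels = refLabels,
         refTruth = rep(refLabels, each = 2L))
}

#' Genotype dosages of an admixed sample
#'
#' @param sample an [AdmixedSample-class].
#' @return N x L matrix of minor-allele dosages.
#' @export
genotypeDosages <- function(sample) {
    stopifnot(is(sample, "AdmixedSample"))
    H <- sample@haplotypes
    H[seq(1, nrow(H), 2), , drop = FALSE] + H[seq(2, nrow(H), 2), , drop = FALSE]
}

#' Per-SNP number of true populations in a truth track
#'
#' @param sample an [AdmixedSample-class] (or a 2N x L truth label matrix).
#' @return integer vector: distinct true populations present at each SNP.
#' @export
truePopulationsPerSnp <- function(sample) {
    truth <- if (is(sample, "AdmixedSample")) sample@truth else sample
    cpp_distinct_per_column(matrix(as.integer(truth), nrow(truth)))
}

#' Count visible ancestry switches per chain
#'
#' @param sample an [AdmixedSample-class].
#' @return integer vector (length 2N) of label changes along each chain.
#' @export
ancestrySwitchCounts <- function(sample) {
    truth <- sample@truth
    as.integer(rowSums(truth[, -1L, drop = FALSE] !=
                       truth[, -ncol(truth), drop = FALSE]))
}
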