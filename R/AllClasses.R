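#' @import methods
#' @importFrom stats approx rpois rbinom runif rbeta rgamma dpois setNames sd
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib mosaicAncestry, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# GeneticMap

#' Genetic map in cumulative centimorgan
#'
#' A genetic map anchors physical positions (bp) to cumulative map positions
#' in centimorgan (1 cM = 1\% crossover probability per generation). Per-SNP
#' crossover probabilities \eqn{d_j} between consecutive SNPs are obtained by
#' linear interpolation of the anchors (see [interpolateMap()]).
#'
#' @slot positions numeric, physical bp coordinates, strictly increasing.
#' @slot cM numeric, cumulative centimorgan at each anchor, non-decreasing.
#' @export
setClass("GeneticMap",
         representation(positions = "numeric", cM = "numeric"))

setValidity("GeneticMap", function(object) {
    if (length(object@positions) != length(object@cM))
        return("positions and cM must have equal length")
    if (length(object@positions) < 2L)
        return("a genetic map needs at least two anchors")
    if (any(diff(object@positions) <= 0))
        return("positions must be strictly increasing")
    if (any(diff(object@cM) < 0))
        return("cM must be non-decreasing")
    TRUE
})

#' @param positions,cM map anchors (bp; cumulative centimorgan).
#' @return A `GeneticMap` object.
#' @rdname GeneticMap-class
#' @examples
#' gm <- GeneticMap(c(0, 1e6), c(0, 1))
#' @export
GeneticMap <- function(positions, cM) {
    new("GeneticMap", positions = as.numeric(positions), cM = as.numeric(cM))
}

setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap with", length(object@positions), "anchors,",
        sprintf("%.3g", max(object@cM) - min(object@cM)), "cM over",
        sprintf("%.4g", diff(range(object@positions)) / 1e6), "Mb\n")
})

# ---------------------------------------------------------------------------
# AncestralPanel

#' Ancestral population panel
#'
#' Per-population minor-allele frequencies at each SNP, optionally with a
#' pool of phased template haplotypes per population from which mosaic
#' individuals are copied.
#'
#' @slot freqs K x L numeric matrix of minor-allele frequencies in [0, 1].
#' @slot haplotypes list of length K; each element a 0/1 matrix
#'   (pool haplotypes x L), or an empty list for a frequency-only panel.
#' @slot positions numeric, SNP bp positions (length L).
#' @export
setClass("AncestralPanel",
         representation(freqs = "matrix", haplotypes = "list",
                        positions = "numeric"))

setValidity("AncestralPanel", function(object) {
    if (any(object@freqs < 0 | object@freqs > 1))
        return("freqs must lie in [0, 1]")
    if (ncol(object@freqs) != length(object@positions))
        return("freqs and positions disagree on the number of SNPs")
    if (length(object@haplotypes)) {
        if (length(object@haplotypes) != nrow(object@freqs))
            return("need one haplotype pool per population")
        for (hm in object@haplotypes) {
            if (nrow(hm) < 2L)
                return("each haplotype pool needs at least 2 haplotypes")
            if (ncol(hm) != length(object@positions))
                return("haplotype pools and positions disagree on SNP count")
        }
    }
    TRUE
})

setMethod("show", "AncestralPanel", function(object) {
    cat("AncestralPanel:", nrow(object@freqs), "populations,",
        ncol(object@freqs), "SNPs,",
        if (length(object@haplotypes))
            paste0(nrow(object@haplotypes[[1]]), " pool haplotypes/population")
        else "frequency-only", "\n")
})

# ---------------------------------------------------------------------------
# AdmixtureConfig

#' Admixture simulation parameters
#'
#' @slot lambda generations of admixture (>= 0); `lambda = 0` simulates pure
#'   stratification.
#' @slot proportions per-population admixture proportions, summing to 1.
#' @slot withinPopRecombRate within-population template recombinations per bp
#'   (default 1/200000, i.e. one per 200 kb).
#' @slot coverage mean sequencing depth for read simulation (default 8).
#' @slot readErrorRate per-read allele flip probability (default 0).
#' @export
setClass("AdmixtureConfig",
         representation(lambda = "numeric", proportions = "numeric",
                        withinPopRecombRate = "numeric", coverage = "numeric",
                        readErrorRate = "numeric"))

setValidity("AdmixtureConfig", function(object) {
    if (object@lambda < 0) return("lambda must be >= 0")
    if (abs(sum(object@proportions) - 1) > 1e-9)
        return("proportions must sum to 1")
    if (any(object@proportions < 0)) return("proportions must be >= 0")
    if (object@coverage <= 0) return("coverage must be > 0")
    if (object@withinPopRecombRate < 0) return("recombination rate must be >= 0")
    if (object@readErrorRate < 0 || object@readErrorRate > 1)
        return("readErrorRate must be in [0, 1]")
    TRUE
})

#' @param lambda,proportions,withinPopRecombRate,coverage,readErrorRate see
#'   slot documentation.
#' @return An `AdmixtureConfig` object.
#' @rdname AdmixtureConfig-class
#' @export
AdmixtureConfig <- function(lambda, proportions,
                            withinPopRecombRate = 1 / 200000,
                            coverage = 8, readErrorRate = 0) {
    new("AdmixtureConfig", lambda = lambda,
        proportions = proportions / sum(proportions) * sum(proportions),
        withinPopRecombRate = withinPopRecombRate, coverage = coverage,
        readErrorRate = readErrorRate)
}

setMethod("show", "AdmixtureConfig", function(object) {
    cat("AdmixtureConfig: lambda =", object@lambda, "| proportions =",
        paste(signif(object@proportions, 3), collapse = "/"),
        "| within-pop recomb =", sprintf("1/%g bp", 1 / object@withinPopRecombRate),
        "| coverage =", object@coverage, "\n")
})

# ---------------------------------------------------------------------------
# AdmixedSample

#' Simulated admixed sample with ground truth
#'
#' Haplotypes are stored as a 2N x L binary matrix whose rows are the chains
#' (individual i's strands occupy rows 2i-1 and 2i). The truth track records
#' the ancestral population of every chain at every SNP.
#'
#' @slot haplotypes 2N x L 0/1 matrix (1 = minor allele).
#' @slot truth 2N x L integer matrix of true population labels.
#' @slot positions SNP bp positions.
#' @slot d per-SNP crossover probabilities used during simulation
#'   (`d[1]` is `NA`, the chain start).
#' @export
setClass("AdmixedSample",
         representation(haplotypes = "matrix", truth = "matrix",
                        positions = "numeric", d = "numeric"))

setValidity("AdmixedSample", function(object) {
    if (!all(dim(object@haplotypes) == dim(object@truth)))
        return("haplotypes and truth must have identical dimensions")
    if (nrow(object@haplotypes) %% 2L != 0L)
        return("haplotype rows must come in chain pairs (2 per individual)")
    if (ncol(object@haplotypes) != length(object@positions))
        return("positions must match the number of SNPs")
    if (!all(object@haplotypes %in% c(0L, 1L)))
        return("haplotypes must be 0/1")
    TRUE
})

setMethod("show", "AdmixedSample", function(object) {
    cat("AdmixedSample:", nrow(object@haplotypes) / 2, "diploids,",
        ncol(object@haplotypes), "SNPs,",
        length(unique(as.vector(object@truth))), "ancestral populations\n")
})

# ---------------------------------------------------------------------------
# ReadCounts

#' Per-individual per-SNP biallelic read counts
#'
#' @slot refCount N x L matrix of major-allele read counts.
#' @slot altCount N x L matrix of minor-allele read counts.
#' @slot positions SNP bp positions.
#' @export
setClass("ReadCounts",
         representation(refCount = "matrix", altCount = "matrix",
                        positions = "numeric"))

setValidity("ReadCounts", function(object) {
    if (!all(dim(object@refCount) == dim(object@altCount)))
        return("refCount and altCount must have identical dimensions")
    if (any(object@refCount < 0) || any(object@altCount < 0))
        return("read counts must be non-negative")
    if (ncol(object@refCount) != length(object@positions))
        return("positions must match the number of SNPs")
    TRUE
})

setMethod("show", "ReadCounts", function(object) {
    cat("ReadCounts:", nrow(object@refCount), "individuals,",
        ncol(object@refCount), "SNPs, mean depth",
        sprintf("%.2f", mean(object@refCount + object@altCount)), "\n")
})

# ---------------------------------------------------------------------------
# HaplotypeStructure

#' Inferred haplotype structure
#'
#' The segmentation-layer output consumed by the admixture model: haplotype
#' states S, transition indicators Phi, per-SNP recombination probabilities
#' r, and the (called or given) haplotypes H. All chain matrices are 2N x L
#' with individual i on rows 2i-1 and 2i.
#'
#' @slot S integer matrix of haplotype-state indices (contiguous 1..max).
#' @slot Phi 0/1 integer matrix of state-transition indicators
#'   (`Phi[, 1] == 0`, the chain start).
#' @slot r per-SNP recombination probability (posterior mean transition
#'   frequency across chains, floored at 1e-6; `r[1]` is the floor).
#' @slot H 0/1 haplotype matrix.
#' @slot positions SNP bp positions.
#' @export
setClass("HaplotypeStructure",
         representation(S = "matrix", Phi = "matrix", r = "numeric",
                        H = "matrix", positions = "numeric"))

setValidity("HaplotypeStructure", function(object) {
    if (!all(dim(object@S) == dim(object@Phi)))
        return("S and Phi must have identical dimensions")
    if (!all(dim(object@S) == dim(object@H)))
        return("S and H must have identical dimensions")
    if (length(object@r) != ncol(object@S))
        return("r must have one entry per SNP")
    if (any(object@r < 0 | object@r > 1)) return("r must lie in [0, 1]")
    L <- ncol(object@S)
    if (L >= 2) {
        changed <- object@S[, -1L, drop = FALSE] != object@S[, -L, drop = FALSE]
        if (any(changed & object@Phi[, -1L, drop = FALSE] == 0L))
            return("Phi must be 1 wherever the state changes")
    }
    if (any(object@Phi[, 1L] != 0L)) return("Phi[, 1] must be 0 (chain start)")
    TRUE
})

setMethod("show", "HaplotypeStructure", function(object) {
    cat("HaplotypeStructure:", nrow(object@S) / 2, "diploids,",
        ncol(object@S), "SNPs,", max(object@S), "haplotype states,",
        sum(object@Phi), "transitions\n")
})

# ---------------------------------------------------------------------------
# SegmentSet

#' Haplotype segments and double-recombination sites
#'
#' @slot segments data.frame with columns `individual`, `haplotype` (1/2),
#'   `a`, `b` (1-based inclusive SNP bounds) and `state`; segments of one
#'   chain are consecutive and tile 1..L.
#' @slot sites list (one per individual) of double-recombination SNP indices,
#'   always including SNP 1 and SNP L.
#' @slot nSnps,nIndividuals dimensions.
#' @export
setClass("SegmentSet",
         representation(segments = "data.frame", sites = "list",
                        nSnps = "integer", nIndividuals = "integer"))

setValidity("SegmentSet", function(object) {
    sg <- object@segments
    if (!all(c("individual", "haplotype", "a", "b", "state") %in% names(sg)))
        return("segments must have individual/haplotype/a/b/state columns")
    if (any(sg$a > sg$b)) return("segment bounds must satisfy a <= b")
    if (any(sg$a < 1L) || any(sg$b > object@nSnps))
        return("segment bounds must lie in 1..L")
    cov <- tapply(sg$b - sg$a + 1L, interaction(sg$individual, sg$haplotype,
                                                drop = TRUE), sum)
    if (any(cov != object@nSnps))
        return("segments of each haplotype must cover 1..L exactly once")
    if (length(object@sites) != object@nIndividuals)
        return("need one double-recombination site vector per individual")
    for (s in object@sites)
        if (s[1] != 1L || s[length(s)] != object@nSnps)
            return("double-recombination sites must include SNP 1 and SNP L")
    TRUE
})

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet:", nrow(object@segments), "segments over",
        object@nIndividuals, "individuals x", object@nSnps, "SNPs\n")
})

# ---------------------------------------------------------------------------
# StickWeights

#' Truncated stick-breaking weights
#'
#' \eqn{v_q = V_q \prod_{t<q}(1 - V_t)} truncated at the maximum occupied
#' label, with the residual mass of all unoccupied labels collapsed into a
#' "super" state.
#'
#' @slot v numeric vector of population weights (labels 1..q*).
#' @slot superMass residual mass \eqn{1 - \sum_q v_q}.
#' @export
setClass("StickWeights",
         representation(v = "numeric", superMass = "numeric"))

setValidity("StickWeights", function(object) {
    if (any(object@v < 0)) return("v must be non-negative")
    if (object@superMass < -1e-12) return("super mass must be non-negative")
    if (abs(sum(object@v) + object@superMass - 1) > 1e-12)
        return("v and super mass must sum to 1")
    TRUE
})

setMethod("show", "StickWeights", function(object) {
    cat("StickWeights: q* =", length(object@v), "| v =",
        paste(signif(object@v, 4), collapse = ", "),
        "| super =", signif(object@superMass, 4), "\n")
})

# ---------------------------------------------------------------------------
# FitConfig

#' Admixture model fitting configuration
#'
#' @slot nBurnin burn-in iterations (default 20).
#' @slot nSamples posterior sampling iterations (default 30).
#' @slot nRandomSplits random population splits during burn-in (default 3).
#' @slot mode `"sample"` (default) or `"maximize"` for the backward pass.
#' @slot fixedK fixed number of populations C (NA = de novo stick-breaking).
#' @slot eps switch-error probability (default 0.5).
#' @slot alpha admix-rate prior constant (default 0.2).
#' @slot weightScheme `"mean"` (geometric-mean weights, default) or
#'   `"first"` (weight 1 at the segment start, r_j elsewhere).
#' @slot seed integer RNG seed (NA = leave the RNG state alone).
#' @export
setClass("FitConfig",
         representation(nBurnin = "integer", nSamples = "integer",
                        nRandomSplits = "integer", mode = "character",
                        fixedK = "integer", eps = "numeric", alpha = "numeric",
                        weightScheme = "character", seed = "integer"))

setValidity("FitConfig", function(object) {
    if (object@nBurnin < 1L || object@nSamples < 1L)
        return("iteration counts must be >= 1")
    if (!object@mode %in% c("sample", "maximize"))
        return("mode must be 'sample' or 'maximize'")
    if (!is.na(object@fixedK) && object@fixedK < 1L)
        return("fixedK must be >= 1 when set")
    if (object@eps <= 0 || object@eps > 0.5)
        return("eps must be in (0, 0.5]")
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must be in (0, 1)")
    if (!object@weightScheme %in% c("mean", "first"))
        return("weightScheme must be 'mean' or 'first'")
    TRUE
})

#' @param nBurnin,nSamples,nRandomSplits,mode,fixedK,eps,alpha,weightScheme,seed
#'   see slot documentation.
#' @return A `FitConfig` object.
#' @rdname FitConfig-class
#' @export
FitConfig <- function(nBurnin = 20L, nSamples = 30L, nRandomSplits = 3L,
                      mode = "sample", fixedK = NA_integer_, eps = 0.5,
                      alpha = 0.2, weightScheme = "mean", seed = NA_integer_) {
    new("FitConfig", nBurnin = as.integer(nBurnin),
        nSamples = as.integer(nSamples),
        nRandomSplits = as.integer(nRandomSplits), mode = mode,
        fixedK = as.integer(fixedK), eps = eps, alpha = alpha,
        weightScheme = weightScheme, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# AncestryFit

#' Posterior summary of an admixture fit
#'
#' @slot mapLabels 2N x L integer matrix of per-SNP maximum a posteriori
#'   population labels per chain.
#' @slot labelCounts nLabels x 2N x L integer array of posterior label
#'   occupancies across sampling iterations.
#' @slot kCounts maxK x L integer matrix of sampled per-SNP distinct
#'   population counts.
#' @slot kPerSnp per-SNP MAP number of distinct populations.
#' @slot admixRate per-SNP posterior mean admix-event rate
#'   \eqn{\xi_j / 2N}.
#' @slot nPops number of populations in the MAP labelling.
#' @slot nSamples number of posterior samples summarized.
#' @slot refChains integer indices of chains whose labels were fixed
#'   (reference mode), possibly empty.
#' @slot positions SNP bp positions.
#' @export
setClass("AncestryFit",
         representation(mapLabels = "matrix", labelCounts = "array",
                        kCounts = "matrix", kPerSnp = "integer",
                        admixRate = "numeric", nPops = "integer",
                        nSamples = "integer", refChains = "integer",
                        positions = "numeric"))

setValidity("AncestryFit", function(object) {
    if (length(object@kPerSnp) != ncol(object@mapLabels))
        return("kPerSnp must have one entry per SNP")
    if (any(object@kPerSnp < 1L)) return("per-SNP K must be >= 1")
    TRUE
})

setMethod("show", "AncestryFit", function(object) {
    cat("AncestryFit:", nrow(object@mapLabels) / 2, "diploids,",
        ncol(object@mapLabels), "SNPs |", object@nPops, "populations |",
        "median per-SNP K =", stats::median(object@kPerSnp),
        "| mean admix rate =", signif(mean(object@admixRate), 3), "\n")
})
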