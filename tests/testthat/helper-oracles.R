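# Independent oracles used across test files. These recompute quantities by
# enumeration / direct evaluation and never call the code paths they check.

# ---------------------------------------------------------------------------
# Exhaustive enumeration of the per-individual admixture conditional over
# (q1 path, q2 path, delta path), for toy sizes. Inputs mirror the sweep:
# emis1/emis2 (P+1) x L weighted log emissions, boundary masks, gammaHat,
# weights v (super last), dsites, eps. Returns the log marginal likelihood,
# the filtered forward marginals per SNP over (q1, q2, delta), and the
# joint MAP path.
enumAdmixOracle <- function(emis1, emis2, A1, A2, gam, v, dsites, eps) {
    P <- nrow(emis1)          # states incl super
    L <- ncol(emis1)
    # all per-chain label paths consistent with the boundary restriction
    paths <- as.matrix(expand.grid(rep(list(seq_len(P)), L)))
    okPath <- function(path, A) all(A[-1] | path[-1] == path[-L])
    if (L > 1) {
        keep1 <- apply(paths, 1L, okPath, A = A1)
        keep2 <- apply(paths, 1L, okPath, A = A2)
    } else keep1 <- keep2 <- rep(TRUE, nrow(paths))
    # chain prior: start v[q1]; at boundaries (1-g) + g v[t] if stay else g v[t]
    priorOf <- function(path, A) {
        p <- v[path[1L]]
        for (j in seq_len(L)[-1L]) {
            if (A[j]) {
                p <- p * (gam[j] * v[path[j]] +
                          (path[j] == path[j - 1L]) * (1 - gam[j]))
            } else if (path[j] != path[j - 1L]) p <- 0
        }
        p
    }
    # delta paths: flip allowed only at dsites; delta[1] free w.p. (1-eps, eps)
    dpaths <- as.matrix(expand.grid(rep(list(0:1), L)))
    dkeep <- apply(dpaths, 1L, function(d)
        L == 1 || all(dsites[-1] | d[-1] == d[-L]))
    dpaths <- dpaths[dkeep, , drop = FALSE]
    dprior <- apply(dpaths, 1L, function(d) {
        p <- if (d[1L] == 1) eps else 1 - eps
        for (j in seq_len(L)[-1L])
            if (dsites[j]) p <- p * (if (d[j] != d[j - 1L]) eps else 1 - eps)
        p
    })
    emisOf <- function(p1, p2, d) {
        tot <- 0
        for (j in seq_len(L)) {
            tot <- tot + if (d[j] == 0) emis1[p1[j], j] + emis2[p2[j], j]
                         else emis2[p1[j], j] + emis1[p2[j], j]
        }
        tot
    }
    idx1 <- which(keep1)
    idx2 <- which(keep2)
    total <- 0
    fw <- array(0, c(P, P, 2, L))     # joint prob of prefix ending in state
    best <- -Inf
    bestPath <- NULL
    for (a in idx1) {
        pr1 <- priorOf(paths[a, ], A1)
        if (pr1 == 0) next
        for (b in idx2) {
            pr2 <- priorOf(paths[b, ], A2)
            if (pr2 == 0) next
            for (k in seq_len(nrow(dpaths))) {
                lp <- log(pr1) + log(pr2) + log(dprior[k]) +
                    emisOf(paths[a, ], paths[b, ], dpaths[k, ])
                pr <- exp(lp)
                total <- total + pr
                if (lp > best) {
                    best <- lp
                    bestPath <- list(q1 = paths[a, ], q2 = paths[b, ],
                                     delta = dpaths[k, ])
                }
            }
        }
    }
    # filtered marginals: for each j, enumerate prefixes 1..j
    for (j in seq_len(L)) {
        pj <- as.matrix(expand.grid(rep(list(seq_len(P)), j)))
        dj <- as.matrix(expand.grid(rep(list(0:1), j)))
        accum <- array(0, c(P, P, 2))
        subPrior <- function(path, A) {
            p <- v[path[1L]]
            for (jj in seq_len(j)[-1L]) {
                if (A[jj]) p <- p * (gam[jj] * v[path[jj]] +
                               (path[jj] == path[jj - 1L]) * (1 - gam[jj]))
                else if (path[jj] != path[jj - 1L]) p <- 0
            }
            p
        }
        dPrior <- function(d) {
            p <- if (d[1L] == 1) eps else 1 - eps
            for (jj in seq_len(j)[-1L]) {
                if (dsites[jj]) p <- p * (if (d[jj] != d[jj - 1L]) eps
                                          else 1 - eps)
                else if (d[jj] != d[jj - 1L]) p <- 0
            }
            p
        }
        for (a in seq_len(nrow(pj))) {
            pr1 <- subPrior(pj[a, ], A1)
            if (pr1 == 0) next
            for (b in seq_len(nrow(pj))) {
                pr2 <- subPrior(pj[b, ], A2)
                if (pr2 == 0) next
                for (k in seq_len(nrow(dj))) {
                    pd <- dPrior(dj[k, ])
                    if (pd == 0) next
                    le <- 0
                    for (jj in seq_len(j))
                        le <- le + if (dj[k, jj] == 0)
                            emis1[pj[a, jj], jj] + emis2[pj[b, jj], jj]
                        else emis2[pj[a, jj], jj] + emis1[pj[b, jj], jj]
                    accum[pj[a, j], pj[b, j], dj[k, j] + 1L] <-
                        accum[pj[a, j], pj[b, j], dj[k, j] + 1L] +
                        pr1 * pr2 * pd * exp(le)
                }
            }
        }
        fw[, , , j] <- accum / sum(accum)
    }
    list(loglik = unname(log(total)), forward = fw, map = bestPath,
         mapLogProb = unname(best))
}

# log joint probability of one configuration under the toy's conditional
# (used for tie-aware MAP comparisons: with eps = 0.5 the mirror
# configuration has identical probability)
scoreAdmixConfig <- function(q1, q2, delta, emis1, emis2, A1, A2, gam, v,
                             dsites, eps) {
    L <- length(q1)
    priorOf <- function(path, A) {
        p <- log(v[path[1L]])
        for (j in seq_len(L)[-1L]) {
            if (A[j]) {
                p <- p + log(gam[j] * v[path[j]] +
                             (path[j] == path[j - 1L]) * (1 - gam[j]))
            } else if (path[j] != path[j - 1L]) p <- -Inf
        }
        p
    }
    dp <- if (delta[1L] == 1) log(eps) else log(1 - eps)
    for (j in seq_len(L)[-1L]) {
        if (dsites[j]) dp <- dp + (if (delta[j] != delta[j - 1L]) log(eps)
                                   else log(1 - eps))
        else if (delta[j] != delta[j - 1L]) dp <- -Inf
    }
    le <- 0
    for (j in seq_len(L))
        le <- le + if (delta[j] == 0) emis1[q1[j], j] + emis2[q2[j], j]
                   else emis2[q1[j], j] + emis1[q2[j], j]
    unname(priorOf(q1, A1) + priorOf(q2, A2) + dp + le)
}

# random toy instance for the oracle comparisons
randomAdmixToy <- function(L = 4, P = 3) {
    emis1 <- matrix(log(runif(P * L, 0.05, 1)), P, L)
    emis2 <- matrix(log(runif(P * L, 0.05, 1)), P, L)
    A1 <- c(FALSE, runif(L - 1) < 0.7)
    A2 <- c(FALSE, runif(L - 1) < 0.7)
    gam <- c(0, runif(L - 1, 0.05, 0.6))
    v <- runif(P, 0.1, 1)
    v <- v / sum(v)
    dsites <- c(FALSE, runif(L - 1) < 0.4)
    eps <- 0.5
    stick <- new("StickWeights", v = v[-P] * (1 - 1e-12),
                 superMass = v[P] + sum(v[-P]) * 1e-12)
    list(emis1 = emis1, emis2 = emis2, A1 = A1, A2 = A2, gam = gam,
         v = .stickOf(stick), stick = stick, dsites = dsites, eps = eps)
}

.stickOf <- function(sw) c(sw@v, sw@superMass)

# brute-force switch-error likelihood: enumerate all delta vectors over
# blocks and sum block emissions directly (oracle for
# individualEmissionLogProb)
enumSwitchLikelihood <- function(S2, Q2, sites, table, eps) {
    L <- ncol(S2)
    W2 <- attr(S2, "weights")
    bs <- sort(unique(c(1L, sites, L)))
    M <- length(bs)
    starts <- bs[-M]
    ends <- c(bs[-c(1L, M)] - 1L, L)
    nb <- length(starts)
    total <- 0
    for (mask in seq_len(2^nb) - 1L) {
        d <- as.integer(intToBits(mask))[seq_len(nb)]
        pr <- if (d[1L] == 1) eps else 1 - eps
        if (nb > 1) for (m in 2:nb)
            pr <- pr * (if (d[m] != d[m - 1L]) eps else 1 - eps)
        le <- 0
        for (m in seq_len(nb)) {
            for (j in starts[m]:ends[m]) for (l in 1:2) {
                ls <- if (d[m] == 0) l else 3L - l
                le <- le + W2[ls, j] *
                    log(exp(table$logProb[S2[ls, j], Q2[l, j], j]))
            }
        }
        total <- total + pr * exp(le)
    }
    log(total)
}

# small helper: simulated stratified dataset through the full pipeline
quickStratFit <- function(K = 2, L = 600, nPerPop = 6, seed = 1,
                          fitSeed = seed + 1000) {
    panel <- simulatePanel(K = K, L = L, F = 0.2, nHapPool = 6,
                           seed = seed)
    cfg <- AdmixtureConfig(lambda = 0, proportions = rep(1, K) / K)
    sam <- simulateAdmixedSample(panel, cfg, nIndividuals = K * nPerPop,
                                 seed = seed + 500)
    hs <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                                  nBurnin = 10, nSamples = 10,
                                  seed = seed + 900)
    fit <- fitAncestry(hs, config = FitConfig(nBurnin = 10, nSamples = 15,
                                              seed = fitSeed))
    list(sample = sam, hs = hs, fit = fit)
}
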