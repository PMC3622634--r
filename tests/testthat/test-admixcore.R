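# Probability model of the admixture layer: stick-breaking, segment
# weights, emission with switch-error summation, marginalized chain prior,
# parameter updates.

test_that("stick-breaking weights telescope to one", {
    sw <- stickWeights(c(0.5, 0.5, 0.5))
    expect_equal(sw@v, c(0.5, 0.25, 0.125))
    expect_equal(sw@superMass, 0.125)
    sw1 <- stickWeights(c(1, 0.3))
    expect_equal(sw1@v[1], 1)
    expect_equal(sw1@superMass, 0)
    for (k in 1:10) {
        V <- runif(sample(1:6, 1))
        sw <- stickWeights(V)
        expect_equal(sum(sw@v) + sw@superMass, 1, tolerance = 1e-12)
    }
    expect_error(stickWeights(c(0.5, 1.2)), "lie in")
    expect_error(stickWeights(c(0, 0.5)), "lie in")
})

test_that("segment weights implement both schemes", {
    expect_equal(segmentWeights(2, 2, rep(0.3, 5)), 1)
    expect_equal(segmentWeights(1, 4, rep(0, 4)), rep(0.25, 4))
    r <- c(0, 0.1, 0.3)
    expect_equal(segmentWeights(1, 3, r), rep(1.4 / 3, 3))
    expect_equal(segmentWeights(1, 3, r, scheme = "first"), c(1, 0.1, 0.3))
    expect_error(segmentWeights(3, 2, r), "a <= b")
})

test_that("weighted product over a segment is the geometric mean when r = 0", {
    # one effective observation per segment
    p <- runif(6, 0.2, 0.9)
    w <- segmentWeights(1, 6, rep(0, 6))
    expect_equal(prod(p^w), exp(mean(log(p))), tolerance = 1e-12)
})

test_that("emission table uses (y+1)/(n+K_j) with uniform unoccupied rows", {
    S <- rbind(c(1, 1), c(2, 1), c(2, 2))    # K_1 = 2, K_2 = 2
    Q <- rbind(c(1, 1), c(1, 1), c(1, 2))
    tab <- updateEmissionTable(S, Q, nPops = 3)
    # SNP 1, pop 1: y(state1) = 1, y(state2) = 2, n = 3, K = 2
    expect_equal(exp(tab$logProb[1, 1, 1]), 2 / 5)
    expect_equal(exp(tab$logProb[2, 1, 1]), 3 / 5)
    # unoccupied population and super row: uniform 1/K
    expect_equal(exp(tab$logProb[1, 3, 1]), 0.5)
    expect_equal(exp(tab$logProb[1, 4, 1]), 0.5)
    # rows sum to 1 over present states
    for (j in 1:2) for (q in 1:4) {
        pres <- which(tab$present[, j])
        expect_equal(sum(exp(tab$logProb[pres, q, j])), 1, tolerance = 1e-12)
    }
    # y = 3, n = 9, K_j = 3 arithmetic
    expect_equal((3 + 1) / (9 + 3), 1 / 3)
})

test_that("block emission swaps strands and weights under delta = 1", {
    L <- 4
    S2 <- rbind(c(1, 1, 2, 2), c(2, 2, 1, 1))
    Q2 <- rbind(rep(1L, 4), rep(2L, 4))
    W2 <- rbind(rep(0.5, 4), rep(0.25, 4))
    attr(S2, "weights") <- W2
    allS <- rbind(S2, c(1, 2, 1, 2), c(2, 1, 2, 1))
    allQ <- rbind(Q2, rep(1L, 4), rep(2L, 4))
    tab <- updateEmissionTable(allS, allQ, nPops = 2)
    # scalar oracle: explicit double loop over strands and SNPs
    oracle <- function(delta) {
        tot <- 0
        for (j in 1:4) for (l in 1:2) {
            ls <- if (delta == 0) l else 3 - l
            tot <- tot + W2[ls, j] * tab$logProb[S2[ls, j], Q2[l, j], j]
        }
        tot
    }
    expect_equal(blockEmissionLogProb(1:4, S2, Q2, tab, 0), oracle(0),
                 tolerance = 1e-12)
    expect_equal(blockEmissionLogProb(1:4, S2, Q2, tab, 1), oracle(1),
                 tolerance = 1e-12)
    # a uniform table is symmetric in Q and delta
    uni <- tab
    uni$logProb[] <- log(0.5)
    expect_equal(blockEmissionLogProb(1:4, S2, Q2, uni, 0),
                 blockEmissionLogProb(1:4, S2, Q2, uni, 1))
    expect_error(blockEmissionLogProb(1:4, S2, matrix(9L, 2, 4), tab, 0))
})

test_that("switch-error summation matches delta enumeration", {
    set.seed(8)
    for (rep in 1:5) {
        L <- 7
        C <- 6
        S <- matrix(sample(1:3, C * L, replace = TRUE), C, L)
        Q <- matrix(sample(1:2, C * L, replace = TRUE), C, L)
        tab <- updateEmissionTable(S, Q, nPops = 2)
        S2 <- S[1:2, ]
        Q2 <- Q[1:2, ]
        attr(S2, "weights") <- matrix(runif(2 * L, 0.1, 1), 2, L)
        sites <- sort(unique(c(1L, sample(2:(L - 1), 2), L)))
        for (eps in c(0.5, 0.3)) {
            got <- individualEmissionLogProb(S2, Q2, sites, tab, eps)
            want <- enumSwitchLikelihood(S2, Q2, sites, tab, eps)
            expect_equal(got, want, tolerance = 1e-10)
        }
        # eps = 0.5: swapping the two strands entirely leaves the value
        S2s <- S2[2:1, ]
        attr(S2s, "weights") <- attr(S2, "weights")[2:1, ]
        expect_equal(individualEmissionLogProb(S2s, Q2, sites, tab, 0.5),
                     individualEmissionLogProb(S2, Q2, sites, tab, 0.5),
                     tolerance = 1e-10)
    }
    # one block: mixture of delta = 0 and delta = 1 by the anchor convention
    S2 <- rbind(c(1L, 2L), c(2L, 1L))
    Q2 <- rbind(c(1L, 1L), c(1L, 1L))
    attr(S2, "weights") <- matrix(1, 2, 2)
    S <- rbind(S2, c(1L, 1L), c(2L, 2L))
    Q <- rbind(Q2, c(1L, 1L), c(1L, 1L))
    tab <- updateEmissionTable(S, Q, nPops = 1)
    b0 <- blockEmissionLogProb(1:2, S2, Q2, tab, 0)
    b1 <- blockEmissionLogProb(1:2, S2, Q2, tab, 1)
    expect_equal(individualEmissionLogProb(S2, Q2, c(1L, 2L), tab, 0.5),
                 log(0.5 * exp(b0) + 0.5 * exp(b1)), tolerance = 1e-12)
})

test_that("marginalized chain prior factor matches numerical quadrature", {
    set.seed(9)
    for (k in 1:20) {
        n2 <- 2L * sample(1:6, 1)
        xi <- sample(0:n2, 1)
        ar <- runif(1, 0.05, 0.95)
        got <- chainPriorFactor(xi, ar, n2)
        # quadrature of the Beta integral, with the endpoint singularities
        # absorbed by the substitutions t = g^ar and t = (1-g)^(1-ar)
        f <- function(g) g^xi * (1 - g)^(n2 - xi)
        left <- integrate(function(t) {
            g <- t^(1 / ar)
            f(g) * (1 - g)^(-ar) / ar
        }, 0, 0.5^ar, rel.tol = 1e-12)$value
        right <- integrate(function(t) {
            g <- 1 - t^(1 / (1 - ar))
            f(g) * g^(ar - 1) / (1 - ar)
        }, 0, 0.5^(1 - ar), rel.tol = 1e-12)$value
        want <- (left + right) / beta(ar, 1 - ar)
        expect_lt(abs(got - want) / want, 1e-8)
    }
    # normalization: sum over xi of C(2N, xi) * factor = 1
    for (k in 1:5) {
        n2 <- 2L * sample(1:8, 1)
        ar <- runif(1, 0.05, 0.95)
        tot <- sum(choose(n2, 0:n2) *
                   vapply(0:n2, chainPriorFactor, 0, ar = ar, nChains = n2))
        expect_equal(tot, 1, tolerance = 1e-10)
    }
    # spot value: 2N = 2, xi = 0, ar = 0.1
    expect_equal(chainPriorFactor(0, 0.1, 2),
                 gamma(0.1) * gamma(2.9) / (gamma(3) * gamma(0.1) * gamma(0.9)),
                 tolerance = 1e-12)
})

test_that("chain prior is exchangeable and handles degenerate cases", {
    set.seed(10)
    C <- 6; L <- 5
    r <- runif(L, 0.01, 0.5)
    sw <- stickWeights(c(0.6, 0.5, 0.5))
    Q <- matrix(1L, C, L)
    I <- matrix(0L, C, L)
    Q[2, 3:5] <- 2L; I[2, 3] <- 1L
    Q[5, 2:5] <- 3L; I[5, 2] <- 1L; I[3, 4] <- 1L
    base <- chainPriorLogProb(Q, I, sw, 0.2, r)
    # permuting individuals (chain pairs) leaves the value unchanged
    perm <- c(3, 4, 1, 2, 5, 6)
    expect_equal(chainPriorLogProb(Q[perm, ], I[perm, ], sw, 0.2, r), base,
                 tolerance = 1e-12)
    # no events and v_1 = 1: chain-start product contributes 0 in log
    swOne <- new("StickWeights", v = 1, superMass = 0)
    lp <- chainPriorLogProb(matrix(1L, 2, 3), matrix(0L, 2, 3), swOne, 0.2,
                            rep(0.1, 3))
    xiPart <- sum(vapply(2:3, function(j)
        log(chainPriorFactor(0, 0.02, 2)), 0))
    expect_equal(lp, xiPart, tolerance = 1e-12)
    expect_error(chainPriorLogProb(Q, matrix(0L, C, L), sw, 0.2, r),
                 "requires I = 1")
})

test_that("transition rows mix identity and the stick distribution", {
    sw <- stickWeights(c(0.5, 0.6))
    row0 <- transitionRow(0, sw, 2)
    expect_equal(unname(row0), c(0, 1, 0))
    row1 <- transitionRow(1, sw, 1)
    expect_equal(unname(row1), c(sw@v, sw@superMass))
    for (g in c(0.2, 0.7)) {
        row <- transitionRow(g, sw, 1)
        expect_equal(sum(row), 1, tolerance = 1e-12)
        expect_equal(unname(row[1]), (1 - g) + g * sw@v[1])
    }
})

test_that("stick posterior follows Beta(c+1, tail+2) and stays normalized", {
    set.seed(12)
    draws <- replicate(4000, updateStickPosterior(c(100, 0))@v[1])
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - 101 / 103), 3 * se)
    # prior-dominated case: E[V] = 1/3
    draws0 <- replicate(4000, updateStickPosterior(c(0, 0))@v[1])
    expect_lt(abs(mean(draws0) - 1 / 3), 3 * sd(draws0) / sqrt(4000))
    for (k in 1:10) {
        sw <- updateStickPosterior(sample(0:5, 3, replace = TRUE))
        expect_equal(sum(sw@v) + sw@superMass, 1, tolerance = 1e-12)
    }
})

test_that("new labels follow the size-biased residual stick", {
    sw <- stickWeights(c(0.5, 0.5))
    # residual sticks fixed at V = 1: always the first unoccupied label
    out <- sampleNewLabel(sw, Vdraws = 1)
    expect_equal(out$label, 3L)
    expect_equal(out$stick@superMass, 0)
    # empty stick: first assignment gets label 1
    empty <- new("StickWeights", v = numeric(), superMass = 1)
    expect_equal(sampleNewLabel(empty, Vdraws = 1)$label, 1L)
    # Monte-Carlo: P(first) = 1/2, P(second) = 1/4 under Beta(1,1) sticks
    set.seed(13)
    labs <- replicate(4000, sampleNewLabel(sw)$label)
    p1 <- mean(labs == 3)
    p2 <- mean(labs == 4)
    expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 4000))
    expect_lt(abs(p2 - 0.25), 3 * sqrt(0.1875 / 4000))
    expect_gt(p1, p2)
})
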