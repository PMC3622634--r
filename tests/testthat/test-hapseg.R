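# Haplotype segmentation layer: read likelihood, structure inference,
# segments and double-recombination sites, genotype-calling accuracy.

test_that("read likelihood equals the product of the two Poisson pmfs", {
    # direct dpois evaluation as oracle
    expect_equal(readLikelihood(c(3, 5), 1, 8),
                 dpois(3, 4, log = TRUE) + dpois(5, 4, log = TRUE))
    # strict ordering: 8 major / 0 minor reads favour g = 0 over g = 2
    expect_gt(readLikelihood(c(8, 0), 0, 8), readLikelihood(c(8, 0), 2, 8))
    # zero-coverage limit: empty counts carry no information
    expect_equal(readLikelihood(c(0, 0), 1, 1e-12, errFloor = 1e-12), 0,
                 tolerance = 1e-9)
    expect_error(readLikelihood(c(-1, 0), 1, 8), "non-negative")
})

test_that("identical haplotypes collapse to one state without transitions", {
    H <- matrix(rep(rbinom(30, 1, 0.5), each = 4), 4, 30, byrow = FALSE)
    H <- matrix(rep(rbinom(30, 1, 0.5), 4), 4, 30, byrow = TRUE)
    hs <- inferHaplotypeStructure(H, positions = (1:30) * 1e4,
                                  nBurnin = 8, nSamples = 8, seed = 1)
    expect_equal(max(hs@S), 1L)
    expect_equal(sum(hs@Phi), 0L)
    expect_identical(hs@H, H)
})

test_that("complementary haplotypes yield two states and no transitions", {
    set.seed(3)
    base <- rbinom(40, 1, 0.5)
    H <- rbind(matrix(rep(base, 3), 3, byrow = TRUE),
               matrix(rep(1 - base, 3), 3, byrow = TRUE))
    hs <- inferHaplotypeStructure(H, positions = (1:40) * 1e4,
                                  nBurnin = 10, nSamples = 10, seed = 2)
    expect_equal(max(hs@S), 2L)
    expect_equal(sum(hs@Phi), 0L)
    # the two groups occupy different states at every SNP
    expect_true(all(hs@S[1, ] != hs@S[4, ]))
})

test_that("a recombinant haplotype transitions where its template changes", {
    set.seed(4)
    L <- 60
    a <- rbinom(L, 1, 0.5)
    b <- 1 - a                       # maximally distinct backgrounds
    H <- rbind(matrix(rep(a, 6), 6, byrow = TRUE),
               matrix(rep(b, 5), 5, byrow = TRUE),
               c(a[1:30], b[31:60]))  # switches template at j = 31
    hs <- inferHaplotypeStructure(H, positions = (1:L) * 1e4,
                                  nBurnin = 10, nSamples = 10, seed = 5)
    # the recombinant chain transitions at SNP 31 (forced by emissions)
    expect_true(31L %in% which(hs@Phi[12, ] == 1L))
    # and shares its state locally with the matching background group
    # (state labels are per-SNP; twin labels over disjoint ranges are
    # equivalent, so compare per SNP rather than globally)
    expect_equal(hs@S[12, 1:30], hs@S[1, 1:30])
    expect_equal(hs@S[12, 31:60], hs@S[7, 31:60])
    # the two backgrounds never share a state at any SNP
    expect_true(all(hs@S[1, ] != hs@S[7, ]))
})

test_that("segments are maximal constant-state runs with proper sites", {
    S <- rbind(c(1, 1, 2, 2, 2),
               c(3, 3, 3, 3, 3))
    Phi <- rbind(c(0, 0, 1, 0, 0),
                 c(0, 0, 0, 0, 0))
    hs <- new("HaplotypeStructure", S = S, Phi = Phi,
              r = rep(0.01, 5), H = matrix(0L, 2, 5), positions = 1:5)
    segs <- segmentsFromStructure(hs)
    sg1 <- segs@segments[segs@segments$haplotype == 1, ]
    expect_equal(sg1$a, c(1L, 3L))
    expect_equal(sg1$b, c(2L, 5L))
    sg2 <- segs@segments[segs@segments$haplotype == 2, ]
    expect_equal(c(sg2$a, sg2$b), c(1L, 5L))
    # no SNP where both chains transition: sites are just the ends
    expect_equal(segs@sites[[1]], c(1L, 5L))

    # both chains transitioning at j = 4 only: sites {1, 4, L}
    S2 <- rbind(c(1, 1, 1, 2, 2), c(1, 1, 1, 2, 2))
    Phi2 <- rbind(c(0, 0, 0, 1, 0), c(0, 0, 0, 1, 0))
    hs2 <- new("HaplotypeStructure", S = S2, Phi = Phi2,
               r = rep(0.01, 5), H = matrix(0L, 2, 5), positions = 1:5)
    segs2 <- segmentsFromStructure(hs2)
    expect_equal(segs2@sites[[1]], c(1L, 4L, 5L))
    # two blocks between consecutive sites
    blocks <- mosaicAncestry:::.blocksFromSites(segs2@sites[[1]], 5L)
    expect_equal(blocks, list(1:3, 4:5))
})

test_that("segment cover and Phi consistency hold on pipeline output", {
    panel <- simulatePanel(K = 2, L = 300, seed = 11)
    sam <- simulateAdmixedSample(panel, AdmixtureConfig(8, c(0.5, 0.5)),
                                 nIndividuals = 6, seed = 12)
    hs <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                                  nBurnin = 8, nSamples = 8, seed = 13)
    segs <- segmentsFromStructure(hs)
    cov <- tapply(segs@segments$b - segs@segments$a + 1L,
                  interaction(segs@segments$individual,
                              segs@segments$haplotype), sum)
    expect_true(all(cov == 300L))
    # consecutive: b_(k-1) + 1 = a_k within each chain
    for (cc in unique(paste(segs@segments$individual,
                            segs@segments$haplotype))) {
        sg <- segs@segments[paste(segs@segments$individual,
                                  segs@segments$haplotype) == cc, ]
        if (nrow(sg) > 1)
            expect_equal(sg$a[-1], head(sg$b, -1) + 1L)
    }
    # Phi = 1 wherever the state changes (validity already enforces it)
    chg <- hs@S[, -1] != hs@S[, -300]
    expect_true(all(hs@Phi[, -1][chg] == 1L))
    # r is floored and within [0, 1]
    expect_true(all(hs@r >= 1e-6 & hs@r <= 1))
})

test_that("genotypes re-called from 8x reads are over 99% accurate", {
    # mirrors the operating point at which downstream analyses run
    set.seed(21)
    panel <- simulatePanel(K = 2, L = 2000, nHapPool = 6, seed = 21)
    sam <- simulateAdmixedSample(panel, AdmixtureConfig(0, c(0.5, 0.5)),
                                 nIndividuals = 10, seed = 22)
    truthG <- genotypeDosages(sam)
    rc <- simulateReads(truthG, coverage = 8, seed = 23,
                        positions = sam@positions)
    hs <- inferHaplotypeStructure(rc, nBurnin = 8, nSamples = 8, seed = 24)
    called <- hs@H[seq(1, 19, 2), ] + hs@H[seq(2, 20, 2), ]
    acc <- mean(called == truthG)   # 20,000 genotype calls
    se <- sqrt(0.01 * 0.99 / length(truthG))
    expect_gt(acc, 0.99 - 3 * se)
})

test_that("strand flips swap the remainder of both chains", {
    S <- rbind(c(1, 1, 2, 2), c(3, 3, 3, 3))
    Phi <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 0))
    H <- rbind(c(0, 0, 1, 1), c(1, 1, 1, 0))
    hs <- new("HaplotypeStructure", S = S, Phi = Phi, r = rep(0.01, 4),
              H = H, positions = 1:4)
    fl <- applyStrandFlips(hs, data.frame(individual = 1L, snp = 3L))
    expect_equal(fl@S[1, ], c(1L, 1L, 3L, 3L))
    expect_equal(fl@S[2, ], c(3L, 3L, 2L, 2L))
    expect_equal(fl@H[1, ], c(0L, 0L, 1L, 0L))
    # transition indicators repaired where the flip created a state change
    expect_true(validObject(fl))
})

test_that("structure inference is deterministic given a seed", {
    panel <- simulatePanel(K = 2, L = 150, seed = 31)
    sam <- simulateAdmixedSample(panel, AdmixtureConfig(0, c(0.5, 0.5)),
                                 nIndividuals = 4, seed = 32)
    a <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                                 nBurnin = 6, nSamples = 6, seed = 33)
    b <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                                 nBurnin = 6, nSamples = 6, seed = 33)
    expect_identical(a@S, b@S)
    expect_identical(a@r, b@r)
    expect_error(inferHaplotypeStructure(matrix(0L, 2, 1)), "2 SNPs")
})
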