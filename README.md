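# mosaicAncestry

De novo inference of population stratification and SNP-resolution local
ancestry from sequencing read counts, genotypes, or phased haplotypes —
without reference ancestry information.

## Who this is for

Population and disease geneticists working with dense SNP data from
species (or cohorts) for which no reference panel of known-ancestry
individuals exists. Methods that require independent markers or large
reference panels cannot do de novo structure detection on sequencing data,
because linkage disequilibrium (LD) between SNPs breaks their calibration.
`mosaicAncestry` handles all SNPs jointly and infers the number of
populations itself.

## The model

Two layers of infinite-state Bayesian Markov chains:

1. **Haplotype segmentation.** Each of the 2N haplotype chains follows a
   Markov chain over haplotype states with per-SNP Bernoulli allele
   emissions; read counts enter through Poisson likelihoods
   (`Pois(cov·g/2)` / `Pois(cov·(2−g)/2)` for dosage g). Runs of constant
   state are haplotype segments bounded by recombination events; the layer
   outputs states S, transition indicators Φ, per-SNP recombination
   probabilities r_j, and called haplotypes H.
2. **Population admixture.** Population origins Q form a second family of
   Markov chains over an unbounded label set with a stick-breaking prior
   `v_q = V_q ∏_{t<q}(1−V_t)`, `V_q ~ Beta(1,1)`; unoccupied labels are
   collapsed into a "super" state. Admix events are restricted to segment
   boundaries; the per-SNP admix rate γ_j carries a
   `Dir(α r_j, 1−α r_j)` prior (α = 0.2) and is integrated out to a
   Beta-binomial factor. Populations emit haplotype states via per-SNP
   tables `Pr(s|q) = (y+1)/(n+K_j)`, with geometric-mean segment weights,
   and phasing switch errors are summed out at double-recombination sites
   with ε = 0.5.

Fitting is iterative: emission-table update, per-individual
forward-summation/backward-sampling over the joint diploid + switch state
(collapsed predictives for both the admix rate and the emissions), and a
stick posterior update `V_q ~ Beta(c_q+1, Σ_{t>q}c_t+2)`; burn-in uses
random population splits. Reference individuals, when available, are
pinned to their labels and fitted together with the sample. See the
vignette `vignettes/model-and-methods.Rmd` for the full account.

## Worked example

```r
library(mosaicAncestry)

# two divergent populations (F = 0.2), 40 stratified diploids, 2,000 SNPs
panel <- simulatePanel(K = 2, L = 2000, F = 0.2, nHapPool = 8, seed = 1)
sam <- simulateAdmixedSample(panel,
                             AdmixtureConfig(lambda = 0,
                                             proportions = c(0.5, 0.5)),
                             nIndividuals = 40, seed = 2)

hs  <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                               seed = 3)
fit <- fitAncestry(hs, config = FitConfig(seed = 4))

fit
#> AncestryFit: 40 diploids, 2000 SNPs | 2 populations | median per-SNP K = 2
#> | mean admix rate = 4.79e-06

adjustedRandIndex(stratificationLabels(fit), sam@truth[seq(1, 79, 2), 1])
#> [1] 1
table(populationsPerSnp(fit))
#>    2
#> 2000
```

The fit recovers both individual origins (adjusted Rand index 1 against
the simulated truth) and the number of populations (K = 2 at every SNP).
For admixed samples (`lambda > 0`), `fitAncestry()` with `refLabels`
and/or `fixedK` runs the reference / fixed-K modes, and
`localAncestryError()` with `mapLabelsPerSnp()` scores SNP-resolution
ancestry against a truth track.

A command-line interface over the same functions is installed at
`inst/cli/mosaic-ancestry.R`, with subcommands `simulate`, `segment`,
`infer`, `evaluate` and `pipeline`.

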