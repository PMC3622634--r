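---
title: "A two-layer Bayesian Markov model for de novo stratification and local ancestry"
author: "mosaicAncestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer Bayesian Markov model for de novo stratification and local ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicAncestry)
```

## The problem

Given dense SNP data for N unrelated diploid individuals — sequencing read
counts, genotypes, or phased haplotypes — we want to know (i) whether the
sample is stratified into distinct populations, (ii) how many populations
there are, and (iii) for admixed individuals, which ancestral population
each genomic interval of each haplotype descends from, at SNP resolution.
Crucially, we want this *de novo*: without a reference panel of individuals
of known ancestry, which for most non-human species does not exist.

The obstacle to de novo inference on dense SNPs is linkage disequilibrium:
nearby SNPs are strongly dependent, so methods that assume independent
markers cannot calibrate how much evidence the data really carry and
over- or under-estimate the number of populations. The approach taken here
first *learns* the dependence structure as a haplotype segmentation, then
clusters the segments into populations.

## Layer 1: haplotype segmentation

Each of the 2N haplotype chains is modelled as a Markov chain over an
unbounded set of *haplotype states*; haplotypes in the same state at a SNP
share a Bernoulli allele frequency. Runs of constant state are *haplotype
segments* — stretches co-inherited from an ancestral haplotype — and
state transitions mark recombination events. The layer outputs the state
matrix S, the transition indicators Phi, the per-SNP recombination
probability r_j (posterior mean transition frequency across chains,
floored at 1e-6 so downstream Beta priors stay proper), and the called
haplotypes H.

With sequencing input, read counts at a site are modelled as two
independent Poissons with means `coverage * g/2` and `coverage * (2-g)/2`
for minor-allele dosage g (each mean floored at `errFloor = 1e-3` to keep
the support valid); the two chains of an individual are updated jointly
over pairs of states so that the genotype likelihood factors correctly,
and the latent alleles are sampled alongside. With phased input the read
layer is skipped and H is taken as given.

Two hyper-parameters matter here:

* `recombRate` (default 1/200000 per bp, i.e. one recombination per
  200 kb): sets the prior per-interval transition level
  `rho0_j = min(0.5, recombRate * gap_j)`.
* `priorStrength` (default 10): the pseudo-count weight kappa of the
  transition-rate prior `Beta(kappa * rho0_j, kappa * (1 - rho0_j))`. The
  collapsed predictive for one chain is
  `(count among other chains + kappa * rho0_j) / (2N - 1 + kappa)`.
  A near-point-mass prior here (kappa → 0 with a fixed mean) cannot
  bootstrap segmentation: transitions are individually rare per SNP, so
  the predictive would stay pinned near zero and the sampler would never
  propose the first recombination. kappa = 10 lets the prior level carry
  real weight against up to a few dozen chains while the empirical
  transition counts still dominate once discovered.

## Layer 2: population origins with a stick-breaking prior

Population origins Q form a second family of 2N Markov chains over an
unbounded label set. The prior over labels is stick-breaking:
`v_q = V_q * prod_{t<q} (1 - V_t)` with `V_q ~ Beta(1, 1)`, so arbitrarily
many populations are allowed but the weights decay, which regularizes the
inferred number of populations. All unoccupied labels are collapsed into a
single *super state* carrying the residual mass, making computation
finite.

Transitions (admix events, indicator I) are allowed **only at haplotype
segment boundaries** — the model's way of exploiting the learned LD
structure: an ancestry switch inside a segment would contradict the
segment's single ancestral origin. The per-SNP admix probability gamma_j
has a `Dir(alpha * r_j, 1 - alpha * r_j)` prior (alpha = 0.2 by default)
and is integrated out, producing a Beta-binomial factor per SNP in the
marginalized chain prior (`chainPriorLogProb()`, with the per-SNP factor
exposed as `chainPriorFactor()`).

A population emits haplotype states through a per-SNP table
`Pr(s | q) = (y + 1) / (n + K_j)` where y counts chains with state s and
label q at the SNP, n counts chains with label q, and K_j is the number of
distinct states at the SNP; unoccupied populations get the uniform row
`1/K_j`, the prior predictive for a brand-new population. SNPs inside a
segment are redundant, so each SNP enters with a weight: by default
`w = (1 + sum of r_j inside the segment) / segment length`, which makes a
segment contribute its geometric-mean emission raised to the expected
number of recombination events it contains — roughly "one observation per
segment plus one per expected recombination". The alternative scheme
(weight 1 at the segment start, r_j elsewhere) is available via
`weightScheme = "first"`.

### Phasing switch errors

Computationally phased haplotypes contain switch errors: the two parental
strands are exchanged from some point onward. Such errors look exactly
like paired ancestry switches and would otherwise corrupt local-ancestry
calls. Switches can only occur at *double-recombination sites* — SNPs
where both of an individual's chains transition. The model sums over a
per-block switch indicator delta with error probability eps = 0.5: a flat
prior that makes the likelihood invariant to strand relabelling within
any block (asserted in the tests). delta is anchored at 0 before SNP 1;
with eps = 0.5 the anchor choice is immaterial.

One bookkeeping subtlety follows from delta: population labels refer to
the *latent* chains, while states are stored per *observed* strand. The
sampled delta of each individual is therefore carried across iterations,
the emission table is built from delta-corrected (state, label) pairs, and
posterior summaries report observed-strand labels. The admissible admix
sites of a chain are taken from its observed strand's segmentation in
either phase — the two strands share boundaries at exactly the sites
where delta can change, so this is a notational simplification rather
than an approximation worth the extra state space.

## Model fitting

Fitting iterates three steps, with `nBurnin = 20` burn-in and
`nSamples = 30` sampling iterations by default:

1. **Emission-table update** from the current (S, Q, delta).
2. **Per-individual forward-summation / backward-sampling** over the joint
   diploid + switch state (q1, q2, delta), conditioning on all other
   individuals. The admix probability used is the collapsed Beta-Bernoulli
   predictive `(xi_j^(-i) + alpha * r_j) / (2N - 1)` where xi_j^(-i)
   counts the other individuals' events at the SNP. Emission lookups for
   the individual being updated are **leave-one-out**: its own two chains
   are removed from y and n. This is the exact analogue of the collapsed
   predictive used for gamma, and it matters: with self-counting, a chain
   that founds a singleton population makes that population its own best
   fit ((0+1+1)/(1+K_j) beats the shared population's ratio), and junk
   populations never die.
3. **Stick posterior update**: with c_q the occurrences of label q at
   event sites or chain starts, `V_q ~ Beta(c_q + 1, sum_{t>q} c_t + 2)`.

When the backward pass selects the super state, the concrete new label is
drawn from the residual stick (sequential Beta(1,1) sticks, size-biased
ordering; `sampleNewLabel()`). During burn-in, `nRandomSplits = 3` random
splits move a random subset of one population's event-delimited occupancy
blocks to a fresh label, letting the sampler escape merged local modes;
one forced split precedes the first sweep from the deterministic all-in-
one-population initialization. Sampling (rather than maximization) is the
default backward mode for the same local-mode reason. Individuals are
swept once per iteration in index order.

Summaries are per-SNP maximum a posteriori: MAP label per chain per SNP,
MAP count of distinct occupied labels per SNP, and the posterior mean
admix-event rate. Ties break to the lowest label, and output labels are
relabelled to dense 1..K by first appearance along the genome (except in
reference mode, where the reference coding is kept).

### Reference and fixed-K modes

With reference individuals of known origin (or just a known population
count C), the model becomes a heterogeneous finite Markov chain with C
states: reference chains are pinned to their labels at every SNP and fitted
*together* with the sample, and the population weights get a symmetric
`Dirichlet(1, ..., 1)` prior in place of the stick (the stick's size-biased
ordering is meaningless when labels are externally fixed). Sample
individuals are initialized at a random whole-genome label in this mode.

### Exact computation grid

Between segment starts and double-recombination sites the population state
cannot change, so the forward recursion runs on the union grid of
event-admissible SNPs with run-summed emissions. This is an exact
algebraic reduction (the skipped steps are identity kernels), and turns
the per-sweep cost from O(L) to O(#segments) per individual.

## The simulator

`simulatePanel()` draws divergent ancestral populations from a
Balding–Nichols-style model: ancestral frequency `p ~ U(0.05, 0.95)` per
SNP, population frequency `~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with fixation
index F = 0.2 by default — strongly separated populations, comparable to
continental-scale human divergence. A pool of `nHapPool = 8` template
haplotypes per population is sampled from those frequencies; mosaic
individuals copy from the pool, which induces the haplotype sharing the
segmentation layer exploits. Eight templates keep the state space at desk
scale while leaving each population with realistic haplotype diversity.

`simulateAdmixedSample()` builds each haplotype left to right: at SNP j
an admix event occurs with probability `1 - exp(-lambda * d_j)` (lambda =
generations of admixture; d_j = per-interval crossover probability from
linear interpolation of the genetic map, 1 cM = 1% recombination), and the
population is redrawn from the admixture proportions — possibly landing on
the same population, matching the inference layer's redraw convention, so
visible ancestry switches are a subset of events. Within a population the
template switches at rate one per 200 kb. `lambda = 0` is the
stratification special case; there both chains of an individual share the
founding population, since a stratified individual belongs to one
population. Reads are Poisson at 8x by default with no base-error term (an
optional per-read flip probability exists, default 0).

What the simulator does **not** emulate: coalescent genealogies (no
population-size histories, bottlenecks, or drift beyond the fixed F),
mutation after admixture, allele-frequency spectra conditioned on
ascertainment, base-calling errors, or multi-chromosome structure (run
chromosomes independently). Passing tests therefore demonstrate
correctness of the inference machinery under the model's own generative
assumptions and realistic marker densities — not performance on any
particular organism's data.

## Numerical choices

* All sweep computations are in linear space per SNP with per-step
  normalization and accumulated log-normalizers; emission shifts by the
  per-SNP maximum prevent underflow.
* `r_j` floored at 1e-6; `alpha * r_j` therefore always in (0, 1).
* Poisson means floored at `errFloor = 1e-3`.
* Ties in MAP summaries and Viterbi: lowest label index wins; stay beats
  move at equal score.
* Degenerate inputs: L = 1 reduces to emission-only clustering; a chain
  whose segmentation is one segment can only choose its ancestry at the
  chain start (admixture restricted to boundaries makes within-chain
  events impossible by construction — documented, not an error).
* Truly information-free input (a single individual with flat emissions)
  yields a prior-driven population count; the stick prior with the
  prescribed `Beta(c_q + 1, tail + 2)` posterior does not concentrate on
  K = 1 for two exchangeable chains, so the honest guarantee is a
  genome-wide *constant* count, not a specific value.
* Label identity across Gibbs iterations is maintained (no per-iteration
  relabelling), so per-SNP posterior label frequencies are meaningful;
  "twin states" occupying disjoint SNP ranges can appear in the
  segmentation layer and are inferentially equivalent because all emission
  tables are per-SNP.

## Problem sizes in the test suite

The packaged checks run, by choice, at desk scale: stratification recovery
uses 2,000 SNPs and 20 diploids per population for K = 2 and 3 over 10
seeds; the reference-mode ordering benchmark uses 20 admixed diploids plus
2 references per population at 5,000 SNPs over ~30 Mb for lambda = 8 and
216, 10 seeds; genotype-calling accuracy uses 20,000 calls at 8x. At these
densities an ancestry tract at lambda = 216 spans only ~75 SNPs, so
absolute error rates are intrinsically higher than at biobank densities;
the suite therefore asserts orderings (more references never hurt; older
admixture is harder; larger samples help) and exact oracle equivalences
rather than absolute error levels.

## Known limitations

* The segmentation layer is a simplified reimplementation of the sketch
  above; numerical equivalence with any other haplotype-segmentation
  program is not claimed.
* The sampler has split moves but no merge moves; merging relies on the
  likelihood pulling chains across, which the leave-one-out predictive
  makes reliable in informative data but which can be slow on the edge of
  identifiability (very old admixture, very similar populations).
* Admixture proportions are global constants of the simulator; the
  inference layer estimates per-SNP structure and does not report global
  ancestry fractions directly (they are a byproduct of the MAP labels).
* One chromosome at a time; no sex chromosomes; biallelic SNPs only.

## A worked example

```{r example, eval = FALSE}
panel <- simulatePanel(K = 2, L = 2000, F = 0.2, nHapPool = 8, seed = 1)
sam <- simulateAdmixedSample(panel, AdmixtureConfig(lambda = 0,
                                                    proportions = c(.5, .5)),
                             nIndividuals = 40, seed = 2)
hs <- inferHaplotypeStructure(sam@haplotypes, positions = sam@positions,
                              seed = 3)
fit <- fitAncestry(hs, config = FitConfig(seed = 4))
adjustedRandIndex(stratificationLabels(fit),
                  sam@truth[seq(1, 79, 2), 1])   # 1 on this seed
table(populationsPerSnp(fit))                    # K = 2 at every SNP
```

One consequence of the small default template pool deserves emphasis: with
samples much larger than the pool (roughly 2N >> K × nHapPool), chains
genuinely cluster by template usage, and the de novo fit correctly reports
those clusters as sub-populations — the error–sample-size curve then turns
back up. This is a property of the desk-scale generator, not of the
method; panels drawn from real cohorts carry haplotype diversity well
beyond the sample size.
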