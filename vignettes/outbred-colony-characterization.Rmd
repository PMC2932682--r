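---
title: "Characterizing outbred mouse colonies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing outbred mouse colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Commercial breeders maintain large closed colonies of outbred mice. Whether
such a colony is usable for genome-wide association mapping depends on a
handful of population-genetic properties: allele frequencies high enough to
give power, heterozygosity high enough to indicate segregating variation,
linkage disequilibrium (LD) short-ranged enough to give resolution, and an
absence of population structure that would generate false associations.
`outbredtools` computes this battery from diploid biallelic SNP genotypes,
reconstructs each genome as a probabilistic mosaic of inbred founder
haplotypes, maps quantitative trait loci (QTLs) within and across colonies
under the shared-founder assumption, and estimates how many variants in a
colony are absent from an inbred-strain catalogue. A forward-in-time
simulator generates every input, so the whole pipeline runs and is tested
without any external data.

## The colony metric battery

For each marker with genotype codes counting copies of one allele,
the minor allele frequency is `min(p, 1 - p)` over non-missing calls.
Observed heterozygosity is the fraction of heterozygous calls per marker,
averaged over markers. Hardy–Weinberg equilibrium is assessed by the exact
conditional test: given the allele counts and sample size, the p-value sums
the probabilities of all heterozygote counts whose conditional probability
does not exceed that of the observed count. The per-individual inbreeding
coefficient is the moment estimator

$$F = \frac{O_{hom} - E_{hom}}{L - E_{hom}},$$

with $E_{hom} = \sum_j (1 - 2 p_j q_j)$ over the individual's non-missing
polymorphic markers and plug-in colony allele frequencies; the colony
summary is the mean over individuals, reported ×100 so that a fully
homozygous panel scores exactly 100 and excess heterozygosity gives
negative values.

Choices worth noting:

* The HWE failure percentage uses α = 0.05 by default (configurable); its
  denominator excludes monomorphic markers, which cannot fail HWE.
* Monomorphic markers contribute 0 to the mean MAF but stay in that mean:
  a panel's MAF should reflect fixed sites.
* Suitability cut-offs: heterozygosity below 5% marks an almost-inbred
  colony; 5–10% is too low to be useful; mean F×100 above 20 disqualifies
  and 10–20 is flagged as elevated. A colony is "usable for mapping" when
  none of the disqualifying flags applies.

## Linkage disequilibrium

Colony genotypes are unphased, so pairwise LD uses the genotypic
(composite) r²: the squared Pearson correlation of dosages over
pairwise-complete samples. It is deterministic and phase-free. The decay
radius is the distance at which the distance-binned mean r² first drops
below 0.5: pairs are binned (100 Kb default, at least 10 pairs per bin),
the binned means are smoothed by a weighted non-increasing isotonic fit
(raw binned means are noisy and "first drops below" is otherwise
ill-defined), and the crossing is located by linear interpolation between
bin midpoints. Curves that never reach 0.5 report "greater than span";
curves starting below 0.5 report "below the first bin".

Haplotype blocks use the confidence-interval rule from human LD studies:
per pair, two-locus haplotype frequencies are estimated by EM (only the
double heterozygote is phase-ambiguous; 50 iterations or Δlog-likelihood
< 1e-8, initialized at linkage equilibrium), |D′| is profiled on a
101-point grid with allele frequencies and the sign of D held at their
MLEs, and the CI endpoints are the 5th/95th percentiles of the normalized
likelihood mass. A pair is in strong LD when CI low ≥ 0.70 and CI high ≥
0.98, and shows strong recombination when CI high < 0.90. Maximal runs in
which ≥95% of informative pairs are strong LD form candidate blocks,
accepted greedily longest-first without overlap.

## Population structure

Identity-by-state distances (1 minus the shared-allele fraction over
pairwise-complete markers) feed classical metric MDS. Because the original
survey judged cluster plots by eye, the package makes the judgement
explicit: k-means with k in 2–4 (fixed seed, 10 restarts) on the MDS
coordinates, flagged as structured when the best mean silhouette width
exceeds 0.50. The cut-off follows the usual silhouette reading of a
"reasonable" partition; we measured best silhouettes of 0.37–0.47 on
simulated panmictic colonies (k-means will happily split a Gaussian
cloud), while planted two-population mixtures score above 0.7, so 0.40
would flag noise and 0.50 separates the two regimes cleanly.

Between-colony differentiation uses the Weir–Cockerham θ with the a/b/c
variance components per locus, combined across loci as a ratio of sums
(mean-of-ratios is biased at small counts). θ of a colony against a copy
of itself is slightly negative (about −1/(2n)), a known small-sample
property of the estimator, not a defect. Colony trees are average-linkage
agglomerative clusterings of the Fst matrix (negatives clamped to zero),
serialized as Newick via `ape`. Admixture proportions come from the
binomial-likelihood EM over K ancestral populations (default up to 10,000
iterations, Δlog-likelihood 1e-6, best of 5 restarts); the log-likelihood
is non-decreasing by construction and is asserted in tests. No LD thinning
is applied by default — with markers in LD the ancestry estimates are
biased, as is well known; thin to one marker per block when that matters.

## The founder-mosaic hidden Markov model

Each individual's genome is modelled as a mosaic of S homozygous founder
haplotypes. The hidden state at a marker is the unordered founder pair
(S(S+1)/2 states — genotypes are unphased, so ordered pairs are
unidentifiable). Along a chromosome each haplotype switches ancestry
independently across an interval with probability $1 - e^{-G d / 100}$
($d$ in cM on a uniform map, default 0.5 cM/Mb; no hotspot information is
used), and a switch lands on any founder uniformly. Emissions use a
per-allele error ε: each transmitted allele matches its founder's allele
with probability 1 − ε; missing calls emit 1 in every state. Posteriors
come from a scaled forward–backward pass whose transitions factorize per
haplotype, so the work per marker is two small matrix operations rather
than a full S²×S² transition.

States are anchored at markers and a marker's posterior represents the
surrounding interval; founder contributions weight each marker by half its
flanking inter-marker gaps (midpoint rule), average the posterior founder
dosages over individuals, divide by two, and normalize. Defaults: G = 30
generations since founding, ε = 0.01. Both are exposed; G mainly controls
how quickly the posterior is allowed to switch ancestry, and the
contribution profiles are insensitive to factor-of-two changes in it.

Tests verify the implementation against an exhaustive path-sum oracle
(every ordered-pair path enumerated, emissions expanded allele-by-allele)
to 1e-10 on small instances, and against pedigree truth on simulated
colonies (argmax accuracy ≥ 90%; contribution error ≤ 0.05 at S = 8,
G = 30).

## QTL mapping

Traits are rank-inverse-normal transformed within colony (ties by average
rank) and re-standardized; candidate covariates are screened by one-way
ANOVA and retained at p < 0.01. The single-marker scan is the partial F
test of the genotype factor added to the covariate-only model, computed by
Frisch–Waugh residualization (exact, and it lets a thousand permutation
traits be scanned as one matrix operation); logP = −log10 p, capped at
300; variance explained is the partial R². The conditional scan adds the
conditioning marker's genotype factor to the covariates — testing the
conditioning marker against itself leaves an exactly collinear term, which
the scan reports as a rank-deficiency note rather than a fabricated zero.
The founder-dosage (haplotype) scan regresses the trait on the posterior
founder dosages (one column dropped; dosages sum to 2), again as a partial
F against the covariate model, skipping rank-deficient intervals with a
note.

Region-wide significance uses permutation: the transformed trait is
permuted across samples — within colony when several colonies are
analysed together, preserving colony-level differences; covariates stay
attached to their samples — and the threshold is the 95th percentile of
the per-permutation region-wide maximum logP (1,000 permutations by
convention).

The shared-effect test asks whether one set of founder effects common to
all colonies fits as well as colony-specific effects: at the peak interval
of the pooled scan, a partial F compares covariates + colony + shared
dosages against covariates + colony + per-colony dosages. Non-rejection
supports mapping on the shared-ancestor assumption. Calibration is tested:
type-I error within [0.02, 0.09] at α = 0.05 across 200 shared-effect
simulations.

## Variant novelty

The novelty stage consumes an already-called variant table with read-level
metadata and applies three conjunctive filters: calls within 3 bases of a
read end are discarded, calls not mapping within 32 bases of a known
restriction site are discarded (calls with no known site distance count as
failing), and read depth must exceed 10×. The raw novelty rate is the
fraction of filtered calls whose position and alternate allele are absent
from the inbred-strain catalogue; because reduced-representation calling
carries a known false-discovery rate, the adjusted rate subtracts the FDR
(floored at zero) — 11.7% raw with an 8% FDR gives about 4%.

## The synthetic-colony simulator

`simulate_founders()` draws homozygous founder haplotypes whose per-marker
allele frequencies follow a symmetric Beta tuned so the expected mean
pairwise difference equals the divergence target. `breed_colony()` runs
forward-in-time breeding: random pair mating, circular (ring-neighbour)
mating, group rotation (an idealization of the rotational/Poiley/Robertson
schemes breeders report), or an IGS-style scheme in which a small
reservoir population is bred in parallel and periodically supplies a
fraction of the parents. Meiosis places Poisson crossovers on the same
uniform map the HMM assumes (no interference), so recovery tests are
internally consistent. Genotypes are emitted with per-allele error
(matching the HMM emission model) and per-call missingness; founder-label
mosaics, the final-generation pedigree, the heterozygosity trajectory and
offspring-number variance (for Ne estimation via Crow's
$N_e = (4N-2)/(V_k+2)$) are recorded as ground truth.

Defaults describe a desk-scale colony: 8 founders, 351 markers in 5 Mb
(the sparse survey panel density), 30 generations at census 100, 1%
per-allele genotype error, 2% missing calls. Phenotypes are planted as an
additive marker effect or per-founder allele effects scaled to a target
variance fraction, plus optional covariate effects and Gaussian noise.

What the simulator does **not** emulate: sex chromosomes, crossover
interference and recombination hotspots, litter structure and selection,
age/batch phenotype artefacts beyond simple covariates, and genotyping
platform artefacts beyond symmetric allele flips. Passing recovery tests
therefore show the methods are correct under their own assumptions, not
that real colonies satisfy those assumptions.

## Numerical choices and degenerate inputs

* HWE p-values are computed with a log-gamma closed form and normalized
  within the reachable heterozygote set; ties at the observed probability
  are included with a 1e-12 relative tolerance. Monomorphic markers return
  p = 1.
* The scan core zeroes residualized design columns whose norm falls below
  1e-8 of the raw column norm, so covariate-absorbed or constant terms
  register as rank-deficient instead of numerically tiny F denominators.
* The decay-radius isotonic fit is a small weighted
  pool-adjacent-violators pass (bin pair counts as weights).
* Forward–backward scales at every marker and errors out, naming the
  marker, if a scaling constant underflows; forward and backward
  log-likelihoods are compared to 1e-8 in tests.
* Strand-ambiguous A/T and C/G markers with MAF in (0.4, 0.6) are dropped
  during founder alignment; they cannot be oriented reliably.

## Problem sizes used in the shipped checks

The test suite exercises the statistical claims at sizes a laptop handles
comfortably: the all-homozygous panel limit at 94 lines × 351 SNPs; HWE
oracle equivalence for every genotype configuration up to N = 30; HMM
path-sum equivalence up to 3 founders × 6 markers; founder-contribution
recovery at S = 8, G = 30, 400 markers; QTL power at n = 200 with
1,000-permutation thresholds over 25 replicates; shared-effect and
permutation calibration over 200 replicates each; and the LD-decay laws on
two-founder colonies over a 50 Mb region (few founder haplotypes are
needed for short-range r² to approach 1, as in stocks descended from a
couple of founders; with 8 equifrequent founders even perfectly linked
markers average r² near 1/8).

## Known limitations

* The block detector is the CI rule only; four-gamete and solid-spine
  definitions are out of scope.
* No kinship/mixed-model correction in the scans — appropriate for closed
  colonies without strong structure, which is exactly what the suitability
  battery screens for.
* Admixture K is user-chosen; no cross-validation is provided.
* The IBS/Fst/HMM code paths assume autosomal biallelic SNPs throughout.
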