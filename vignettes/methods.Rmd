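---
title: "Methods: simulating optimized mate selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating optimized mate selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices behind the solvers, and the limits of
what a green test establishes. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The simulated world

**Genome.** `build_genome_spec()` lays out biallelic SNPs on an evenly
spaced grid per chromosome (midpoint grid: a chromosome of genetic length
$L$ Morgans with $m$ SNPs has spacing $L/m$) and places QTL uniformly at
random as *separate* loci. SNP statistics (GBLUP, kinship, $H_O$) use SNPs
only; trait machinery uses QTL only. The full-scale map is 29 chromosomes
$\times$ 2.33 Morgans, 100 000 SNPs, 750 QTL of which 125 carry dominance.
"2.33 M" is read as Morgans: meiosis needs a genetic map, and no
recombination rate is available for a physical reading.

**Meiosis** (`gamete()`, Rcpp): per chromosome, a Poisson($L$) crossover
count, uniform crossover positions, alternating strands from a random
start; then symmetric allele-flip mutation at $10^{-5}$ per locus per
transmitted gamete. At realistic rates the mutation count is drawn
binomially and assigned to random loci (repeat hits are $O(10^{-9})$ per
gamete); at artificial rates $\ge 0.01$, used only by tests, each locus is
flipped by an exact Bernoulli draw.

**Founders.** The base population starts at allele frequency 0.5
everywhere; a 1000-generation random-mating burn-in at $N = 1000$ (1:1 sex
ratio, non-overlapping generations) establishes the frequency spectrum,
LD, and mutation–drift balance. The population then expands linearly to
1400 (male count 500 $\to$ 200) over five generations and is split evenly,
stratified by sex, into founder populations FP1 and FP2 of 700 (100 M /
600 F). Only the endpoints of the expansion are prescribed; the linear
interpolation of size and male count is this package's choice, and it
makes the male fraction monotonically non-increasing.

**Traits.** Five genetically independent traits with heritabilities
0.44/0.48/0.45/0.30/0.22. Additive QTL effects are i.i.d. standard normal;
dominance effects, at the 125 flagged QTL only, are normal at half the
additive scale (the relative magnitude is not prescribed anywhere; half
scale is a conventional moderate-dominance choice). Effects are rescaled
so the true-genetic-value variance in the founder generation equals 1 —
all gains are therefore in founder genetic-SD units — and the residual
variance is $(1-h^2)/h^2$, giving phenotypic variance $\approx 1/h^2$.

## 2. Evaluation and selection machinery

**GBLUP.** The genomic relationship matrix is VanRaden method 1,
$K = ZZ'/(2\sum p_k(1-p_k))$, frequencies from the evaluated panel,
monomorphic SNPs dropped, $10^{-6}$ added to the diagonal before solving.
Variance components are plugged in from the known simulation
heritabilities ($\lambda = h^2/(1-h^2)$) rather than re-estimated by REML
each generation: the truth is available in simulation and the plug-in is
deterministic. GEBVs are $\hat g = \lambda K(\lambda K + I)^{-1}(y-\bar y)$.

Because a single-generation GBLUP is mean-centered, cross-generation gain
would be meaningless on raw solves. Each generation is therefore evaluated
*jointly with the founder population* carried as phenotyped reference
animals in the GRM; gain is the mean GEBV difference between the current
and founder individuals within that joint solve. The true-genetic-value
gain is recorded alongside as a scale-free cross-check.

**LP mate allocation.** Candidates are the WSG top 10% of males and top
50% of females (ties broken by id, deterministically). The pair index is
$I_{ij} = \tfrac{w_i + w_j}{2} - \gamma f_{ij}\,\mathrm{sd}(WSG)$: the
midparent WSG is the expectation of the offspring's breeding value, and
$f_{ij}$ is the parents' genomic kinship, which equals expected progeny
inbreeding. The published formula's scale symbol is called a variance but
defined as a standard deviation; the standard deviation is used, and
$\gamma$ (default 1.0, configurable) multiplies it. The assignment problem
— row sums $\le 10$, column sums $\le 1$, total matings fixed — is a
transportation LP whose optimum is integral; it is solved exactly by
successive-shortest-path min-cost flow (Bellman–Ford, handles the negative
costs). The mating-count equality is imposed because a pure maximization
could leave dams unmated whenever $I_{ij} < 0$ and under-produce
offspring; it defaults to `min(a * male_cap, b)`. Offspring are spread as
evenly as possible over selected pairs, remainder to the highest-index
pairs.

**OCS.** Males are preselected to the GEBV top 10% (the source text's
"highest genetic contributions" is not operationalized; GEBV ranking is
the stand-in), all females remain candidates. Contributions satisfy
$\sum_{males} c_i = \sum_{females} c_i = 1/2$, $c \ge 0$.

* *minKin*: minimize $c'Kc$ subject to a gain floor
  $c'g - \bar g \ge \Delta$ ($\Delta \in \{0.05, 0.07, 0.10, 0.20\}$
  genetic-SD units against the current population mean). The floor is
  first tested inactive; otherwise it is imposed as an equality (the
  optimum of the convex problem sits on the boundary), with a feasible
  start interpolated between the unconstrained minimum and the max-gain
  vertex.
* *maxBVE*: maximize $c'g$ subject to
  $c'Kc \le$ (current population average kinship) $+\ \Delta K$
  ($\Delta K = 0.01$/generation). Solved by bisecting the penalty
  multiplier $\mu$ of $\min_c\, \mu\,c'Kc - c'g$ until the kinship
  constraint is met with $\mu_{hi}/\mu_{lo} < 1+10^{-8}$; each
  sub-problem is scaled as $\min c'Kc - (g/\mu)'c$ so the Hessian stays
  well-conditioned for small $\mu$.

Both reduce to a primal active-set QP on the nonnegative orthant with
equality constraints. The KKT ridge is applied to the Hessian block only,
so the sex-sum constraints hold to $\sim 10^{-10}$; $K$ gets a $10^{-8}$
diagonal ridge (the IIS kinship matrix is PSD only on the fixed-sum
manifold, which is exactly where the QP lives). Unreachable bounds fall
back: minKin to the unconstrained kinship minimum, maxBVE likewise, both
recorded in the solver status. Realization samples each offspring's sire
with probability $2c_{sire}$ and dam with probability $2c_{dam}$; no
per-dam litter cap applies (600 dams cannot each be capped at one while
producing 700 offspring).

## 3. Tracked genetic parameters, and a standardization subtlety

Pairwise kinship is the identity-in-state statistic
$(f_{IIS} - p^2 - q^2)/(2pq)$ averaged over polymorphic loci, with
$f_{IIS} \in \{0, \tfrac12, 1\}$; the population value averages distinct
pairs only. A consequence worth knowing: **with the current generation's
own frequencies, the distinct-pair average is algebraically pinned near
$-(1+\bar F)/(2(n-1))$** — summing $f_{IIS}$ over all ordered pairs
(self-pairs included) recovers the gene-pool homozygosity exactly, so the
standardized mean over all pairs is identically zero. A kinship level that
*accumulates* over generations, as reported trajectories do, requires
anchoring the standardizing frequencies at a reference generation. The
package therefore anchors the tracked kinship (and the kinship fed to the
LP index and the OCS constraint) at the founder generation's frequencies,
dropping loci monomorphic in the founders; the metric functions implement
the literal current-frequency form by default and accept anchoring
frequencies as an argument. A unit test pins down the identity above.

QTL effect variance is $\sigma^2 = \frac1n\sum 2p_i(1-p_i)a_i^2$ over the
(anchored-effect) QTL; observed heterozygosity is the mean per-individual
heterozygous-call fraction over all SNPs, monomorphic included, matching
the conventional per-sample het report of genotype-QC tools.

## 4. The desk-scale preset and what green tests establish

`desk_small` preserves the study's structure at roughly 1/50 compute: 5
chromosomes $\times$ 2.33 M, 2000 SNPs, 150 QTL (25 dominant), burn-in 100
generations at $N = 300$ (burn-in size is unprescribed at this scale;
300 $\to$ 400 mirrors the full-scale 1000 $\to$ 1400 expansion shape with
150 $\to$ 60 males), founder populations of 200 (30 M / 170 F), 200
offspring per generation, 15 selection generations.

The acceptance suite checks *orderings*, not endpoint values: LP $\ge$
TS−I on final kinship, every OCS variant $\le$ TS−II, TS−II's Trait-5 gain
$\ge$ each OCS variant, heterozygosity ranking inversely to kinship, and a
positive within-replicate trend of final kinship across the minKin gain
bounds — each as a one-sided paired test over 10 replicates at
$\alpha = 0.1$. A green run establishes that the implemented strategies
reproduce the qualitative structure of the full-scale study at reduced
scale; it does not establish the full-scale endpoint numbers (0.19–0.36
kinship, gains of 2.35–6.51), which would need the multi-hour
configuration (`preset = "paper_full"`). Two desk-scale caveats: with only
$\sim$3 preselected males the minKin gain floors bind intermittently (the
unconstrained minimum-kinship solution already gains $\sim$0.25
SD/generation through male preselection), so the kinship gradient across
the four bounds is weak; and replicate noise at $N = 200$ is large
relative to between-variant differences.

What the generator does *not* emulate: real linkage maps and recombination
hotspots, sequence-level mutation, genetic correlations between traits
(deliberately absent), overlapping generations, sex chromosomes, genotyping
error, and selective genotyping. Conclusions about those features cannot
be drawn from these simulations.

## 5. Numerical choices, degenerate inputs, determinism

* Ties in truncation selection break by ascending id; remainder offspring
  go to the highest-index pairs — both deterministic.
* Monomorphic loci: excluded from the GRM and from kinship averages;
  included in $H_O$ (they dilute, as a real per-sample het report would).
* Degenerate inputs error early with named conditions: all-monomorphic
  panels, empty candidate sets, same-sex matings, infeasible mating
  counts, odd sex classes at the founder split.
* Every stochastic step draws from R's global RNG; `run_experiment()`
  derives per-replicate, per-strategy seeds from the root seed (kept below
  $2^{31}$), so a run is bit-reproducible and strategies within a
  replicate start from identical founder snapshots.
* The min-cost-flow solution is integral by construction, so no LP
  rounding step exists to go wrong; the brute-force equivalence tests
  would catch a non-optimal augmentation.

## 6. Known limitations

* Variance components are plugged in, not REML-estimated; with estimated
  components the GEBV dispersion (and thus realized selection intensity)
  would differ somewhat.
* The joint founder-reference evaluation grows the GRM linearly in
  generation size; at full scale this is the dominant cost per generation.
* The OCS realization is multinomial, so realized contributions match the
  optimized ones only in expectation; at 200–700 offspring the binomial
  noise on a 0.5/3 male contribution is a few percent.
* `OCS_maxBVE`'s bound references the current population's average
  kinship, an interpretation choice (see the decisions record in the
  repository notes for the alternatives considered); with few preselected
  males the bound is occasionally infeasible and the fallback engages.
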