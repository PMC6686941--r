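---
title: "Bit-level breeding simulation: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-level breeding simulation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitqg)
```

## The representation

A diploid genome is stored per chromosome as two packed bit vectors, the
alpha and beta strands, with one bit per mapped locus. Bit index 1 is the
locus with the smallest map position; positions are genetic coordinates in
Morgans. A biallelic locus needs a single bit; several loci assigned to the
same position act as one multi-bit factor (a multiallelic locus), because
recombination depends on positions only and therefore can never separate
them. The allele convention is fixed: bit 1 is the allele carried by the
`"AA"` founder, bit 0 the allele of `"aa"`. The convention is arbitrary —
the two founders are exact bitwise complements (`mirror()`), so every result
has a mirrored twin — but fixing it makes phased output well defined.

Packing matters for capacity as well as speed: a locus costs one bit per
strand, and `check_capacity()` verifies that an encoding fits the 2^32 - 1
single-bitset limit. The largest human chromosome at two bits per nucleotide
needs 497,912,844 bits, comfortably inside it.

## Meiosis as mask algebra

A gamete strand is a mosaic `delta` of the two parental strands, controlled
by a crossover mask `gamma`:

    delta <- (gamma & alpha) | (~gamma & beta)

one bitwise statement over the packed words, evaluated by `recombine()`.
The mask is built from chiasma coordinates by `crossover_mask()`:

1. start from the all-zero mask;
2. for each chiasma, find the first locus at or beyond it
   (`upper_bound()`, a "greater than or equal to" rule, so a chiasma exactly
   at a locus position includes that locus in the flipped tail);
3. the event mask is a replete (all-one) bit set right-shifted by that
   index — zeros up to the boundary locus, ones from it onward;
4. XOR the event into the mask.

XOR chaining makes the construction order-free and self-cancelling: bit `j`
of the mask is the parity of the number of chiasmata at or below locus `j`'s
position, which the tests use as an independent oracle. Point mutation and
gene editing reuse the same machinery: `toggle_loci()` XORs a strand with an
event mask assembled from single-bit events.

Independent assortment is realized by flipping the whole mask with
probability one half (`orient_mask()`), once per chromosome per meiosis.
The flip is applied unconditionally — also when there are no chiasmata —
otherwise a chiasma-free chromosome would always transmit the alpha strand
and unlinked loci would fail to assort independently. With the flip, a
mask and its complement are equally likely, so each parental strand is
transmitted with probability one half at every locus, and chromosomes
assort independently (both properties are tested empirically at 10^4–10^5
gametes).

## Recombination models and the plugin contract

Chiasma sampling is pluggable. A model is a function of the chromosome
length (Morgans) and the locus positions returning chiasma coordinates for
one meiosis; anything satisfying that contract composes unchanged with the
mask construction, and can be registered by name
(`register_meiosis_model()`). Three models ship with the package:

* **Count-location** (default): the chiasma count is Poisson with mean equal
  to the chromosome length in Morgans, locations are independent uniform.
  This is the classical no-interference reading of the count-location
  process — the citation chain for the process does not pin its
  parameterization, so we adopt the standard one and verify the observable
  consequence: the recombination fraction between loci `d` Morgans apart
  follows Haldane's map function `r(d) = (1 - exp(-2d))/2`, checked at
  `d` in {0.05, 0.1, 0.2, 0.5} over 10^5 gametes.
* **Independent segregation**: one chiasma at the midpoint of each adjacent
  pair of distinct positions with probability one half. All `2^k` masks of a
  `k`-locus chromosome become equally likely, so markers segregate
  independently regardless of spacing — a useful null model, and the
  contrast case for the plugin mechanism.
* **Hotspots**: count-location counts with locations drawn from a
  normalized mixture of a uniform background and Gaussian kernels truncated
  to the chromosome (by rejection; kernels are required to have their
  centers inside the chromosome, so acceptance is at least one half per
  draw).

Crossover interference is deliberately out of core: an interference model
(chi-square / gamma renewal) is expressible through the same plugin contract.

## Randomness and reproducibility

Each specie owns a private seeded Mersenne-Twister stream. Batch operations
(`gametes()`, `cross()`, `selfcross()`, `dh()`) swap the stream in for their
whole duration and swap the caller's state back afterwards, so package
randomness never perturbs the session RNG. Within a meiosis, chromosomes are
processed in map order; per chromosome the chiasmata are drawn first, then
the single orientation flip. Per offspring of a cross, the maternal gamete
is drawn before the paternal one. This documented call order makes every
simulation bit-reproducible from the specie seed, which the command-line
layer exposes as `--seed` and records in every output header.

## Breeding operations

`cross(n, mother, father)` gives each offspring its alpha strands from a
fresh maternal gamete and beta strands from a fresh paternal gamete; the
strand-order convention (first parent to alpha) fixes the semantics of
phased output (`"A|a"` for the F1 of AA x aa). `selfcross()` draws two
independent gametes from the same individual — required for the 1:2:1 F2
ratios. `dh()` consumes exactly one meiosis per doubled-haploid line and
copies the gamete into both strands, so DH lines are homozygous everywhere
and their recombinant fractions reflect a single meiosis. Parents are never
modified; every individual's parents are recorded in the specie's pedigree
registry.

## Quantitative genetics layer

Genotypic values use the Falconer parameterization: a locus contributes
`+a` when homozygous for the bit-1 allele, `d` when heterozygous, `-a`
otherwise, around an intercept `m`. The trait constructor broadcasts scalar
effects over all loci, so `trait_infty(spp, m = 0, a = 1, d = 0)` is the
classical additive infinitesimal trait. Phenotypes are simulated as
`alpha_std + e` with `e ~ N(0, (1 - h2)/h2)` after standardizing the genetic
values to unit variance, so the realized heritability targets `h2`
(`h2 = 1` is exact, noise-free).

Two relationship matrices are provided. `kinship_vanraden()` computes the
realized genomic relationship `G = Z'Z / (2 * sum p(1-p))` with per-locus
centering by twice the allele frequency; frequencies default to the observed
ones (the common behavior of realized-relationship software), with an option
to fix a known base frequency such as 0.5 for an F2 from contrasting
inbreds. Monomorphic loci carry no information and are dropped with a
notice; an all-monomorphic matrix is an error rather than a silent zero.
`kinship_pedigree()` builds the expected additive relationship A by the
tabular method (`A_ii = 1 + A_mf/2`, `A_ij = (A_jm + A_jf)/2`), requiring
parents to precede offspring.

`fit_variance_components()` is a deliberately minimal single-kernel REML
solver for `y = 1 mu + g + e`, `g ~ N(0, vA K)`, `e ~ N(0, vE I)`: K is
spectrally decomposed once, the restricted likelihood is profiled down to
the ratio `lambda = vA/vE`, and `log(lambda)` is maximized by Brent search
on `[-10, 10]` (natural log; tolerance 1e-8, fully deterministic).
Eigenvalues below -1e-8 are rejected as non-PSD; values in `[-1e-8, 0]` are
clipped to zero. A solution at a search boundary (for instance noise-free
phenotypes driving `vE` to zero) is returned with `converged = FALSE`.
With `K = I` the two components are not separately identifiable and the
profiled likelihood is flat; the fit then recovers the total variance, which
the tests document. The solver was cross-checked against a brute-force
evaluation of the exact REML likelihood on a (vA, vE) grid.

## The F2:3 study and what it honestly shows

`run_f23_study()` chains everything: two contrasting founders, their F1,
an F2 of size `N`, `P` selfed progeny per F2 plant, standardized true
breeding values under the additive infinitesimal trait, phenotypes at target
`h2`, then REML fits with both A (pedigree) and G (realized). The default
map is the five-chromosome, 1000-loci-per-chromosome, two-Morgan grid; each
replicate runs on a fresh specie with a derived seed, and phenotype noise
uses a second derived seed so the meiosis and noise streams are decoupled.

One empirical property of this design deserves emphasis. The ratio
`vA/(vA + vE)` estimated under G does *not* recover the target heritability,
and the shortfall is structural, not numerical:

* the true breeding values are standardized to unit variance, while the
  diagonal of G in an F2:3 population is about 1.5 (selfing raises
  homozygosity relative to the Hardy-Weinberg denominator), capping the
  ratio near 0.4 even for a perfectly G-aligned signal;
* the uniform effect vector (`a = 1` at every locus of a dense map)
  concentrates the genetic signal in a few leading eigendirections of G,
  which the isotropic REML model penalizes increasingly with sample size.

In our runs (N = 50, P = 10, h2 = 0.5, 20 replicates), the mean ratio under
G is about 0.26–0.28 while the pedigree-A fit lands near 0.64. Both numbers
are reproduced by `scripts/acceptance.R`; the package asserts the solver's
correctness separately, by parameter recovery under the correctly specified
model (`g` drawn from `N(0, vA K)`), where the mean estimated ratio is
within 0.05 of the target at n = 100 and within 0.1 for `h2` in
{0.2, 0.5, 0.8}.

## What the generator emulates — and what it does not

The synthetic maps (`fixture_map()`) are equally spaced grids; real maps
have irregular spacing, centromeric suppression and chromosome-specific
lengths. Count-location meiosis has no crossover interference and no sex
differences. Founders are fully inbred and maximally contrasting, the ideal
biparental design; real founder pairs share alleles, so realized diversity
is lower. Traits here have no epistasis, no GxE, and effects identical
across loci. Passing tests therefore demonstrate the correctness of the
bitwise genetic machinery and the statistical behavior of the idealized
design — not calibration against any real organism.

## Numerical choices and problem sizes

* Exhaustive oracles run at `k <= 10` loci (all 2^k masks); parity-oracle
  checks at 10^3 random configurations, strands up to 64 loci.
* Stochastic checks use 3-binomial-SE tolerances at fixed seeds; gamete
  counts are 10^4–10^5 depending on the statistic; chi-square
  goodness-of-fit tests run at alpha = 0.01.
* The replicated study is exercised at N = 50, P = 10 with 20 replicates
  on the full 5 x 1000 map (about one second per replicate), a scale chosen
  so the whole pipeline, including two 500 x 500 spectral decompositions per
  replicate, stays interactive. The property tests that only need the
  statistical shape of the study use smaller maps (for example 5 x 200).
* `check_capacity()` validates its operands to remain below 2^53, where
  double-precision integer arithmetic is exact, before multiplying.
* Heterozygous founders are intentionally not constructible from codes;
  cross contrasting founders instead, which keeps founder genomes
  unambiguous and phased output interpretable.

## Known limitations

* Map coordinates are Morgans only; physical coordinates can be carried as
  annotation but do not drive recombination. The VCF dialect therefore uses
  the within-chromosome locus rank as POS and stores centimorgans in
  INFO/cM.
* No four-strand chromatid bundle: meiosis is modeled at the two-strand
  mosaic level, which reproduces gamete-level statistics but not
  chromatid-level phenomena such as chromatid interference.
* No selection, no overlapping generations, and no gene-drop on external
  pedigrees; pedigrees are those the package itself records.
* The REML solver is single-kernel with an intercept-only fixed effect —
  exactly what the variance-partitioning study needs, and nothing more.
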