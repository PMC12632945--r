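---
title: "Degrading simulated genotypes with empirical missingness patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degrading simulated genotypes with empirical missingness patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genodegrade)
```

## Why degrade simulated data

Simulators emit genotypes that are complete, phased, and polarized.
Empirical callsets — ancient-DNA data most of all — are dominated by
missing genotypes whose *rate* and *position* both carry structure:
missingness clusters in regions of poor mappability and low coverage,
and its per-site distribution is rarely well described by a single
parametric family. A method benchmarked only on pristine simulations
may owe part of its apparent performance to exactly this gap.

`genodegrade` closes the gap in two steps: degradation operators that
strip the idealized properties (phase, polarization, diploid calls,
undamaged alleles), and a missingness engine that transfers an
empirical template's per-site missingness — its aggregate distribution
*and* its dispersal along the segment — onto the simulated target.

## The dispersal-replication model

The template contributes one number per site: `x_i`, the proportion of
samples whose genotype at site `i` is *fully* missing (both allele
calls absent, `./.`). Half-missing calls such as `./0` are deliberately
not counted — they are still partially informative and are tallied
separately by `summarize_missingness()`. The ordered vector
`x = (x_1, ..., x_N)` is the missingness profile; its order *is* the
dispersal information.

`replicate_dispersal(x, M)` maps the profile onto `M` target sites:

* **Downsampling (M ≤ N).** Template indices are cut into `M`
  contiguous blocks, block `j` covering `⌊(j−1)N/M⌋+1 .. ⌊jN/M⌋`, and
  `y_j` is a uniformly random element of block `j`. We use this
  proportional boundary rule rather than fixed blocks of `⌈N/M⌉` sites
  because the fixed rule produces fewer than `M` blocks whenever `M`
  does not divide `N`; the proportional rule coincides with it whenever
  `M | N` and always yields exactly `M` non-empty contiguous blocks.
  Each `y_j` is an actually observed template proportion, so the
  support of the empirical distribution is preserved exactly.
* **Upsampling (M > N).** Target indices are cut into `N` contiguous
  blocks by the same rule with the roles of `M` and `N` exchanged.
  Targets in block `j < N` draw independently from the uniform
  distribution on `[min(x_j, x_{j+1}), max(x_j, x_{j+1}))`; the last
  block reuses the interval spanned by `x_{N−1}` and `x_N`, i.e. the
  trend at the end of the template is assumed to continue. A
  single-site template broadcasts its value. The degenerate interval
  `U(a, a)` returns `a`, so constant templates are preserved for every
  `(N, M)`.
* `M = N` returns the profile verbatim, for any RNG state.

The stratification loses resolution when `M` and `N` are very
different — with `M ≫ N` each target block interpolates a single
template interval, and with `M ≪ N` each `y_j` summarizes a long
stretch by one draw. This is inherent to the block design.

### Realizing a plan

The model specifies target *proportions*; turning `y_j` into concrete
missing samples is underdetermined. `apply_plan()` defaults to
independent per-sample Bernoulli(`y_j`) knockouts — the simplest
exchangeable rule, and the one under which realized proportions
concentrate on the plan at binomial rates. `exact_count = TRUE`
instead masks `round(y_j * n)` randomly chosen samples, making the
realized profile deterministic up to `1/n` quantization; the synthetic
template generator uses this rule internally so that test templates
are exact oracles. Already-missing genotypes are never resurrected,
and only fully-missing genotypes are ever produced.

### The beta-model baseline

The conventional random alternative fits a beta distribution to the
mean and standard deviation of the `x_i` by the method of moments
(`alpha = mean(mean(1−mean)/sd² − 1)`, `beta` analogous; feasible only
when `sd² < mean(1−mean)`) and draws `y_j` i.i.d. It reproduces the
aggregate distribution's first two moments but is blind to position
and support. `beta_model_from_template()` uses the population
(divide-by-N) standard deviation; with thousands of sites the
difference from the sample estimator is negligible, but the choice is
fixed so results are reproducible.

## Degradation operators

All four operators act on biallelic sites where the operation is only
meaningful there; monomorphic and multiallelic records pass through
untouched with a reported skip count.

* `unphase()` — swaps left/right alleles with probability 1/2 per
  genotype and clears all phase flags. Allele values never change.
* `depolarize()` — with probability 1/2 per site, exchanges the
  REF/ALT labels and flips all allele indices; the site's carried
  nucleotides are unchanged (a pure relabeling). The ancestral-allele
  annotation is dropped unconditionally, because after this step index
  0 no longer means ancestral.
* `deaminate(p_transition, p_deaminate)` — each site is designated a
  transition site once, with probability `p_transition`, regardless of
  its actual nucleotides (the model is deliberately abstract: the
  parameters, not the sequence context, define the damage process). At
  transition sites every reference-allele *copy* independently
  converts to the alternative allele with probability `p_deaminate`;
  a heterozygote can lose one or both reference copies, which mirrors
  the per-molecule nature of real post-mortem damage. Only REF→ALT
  conversion is modeled; ALT alleles are never repaired, so per-site
  ALT counts are non-decreasing.
* `pseudohaploidize()` — each non-missing genotype is replaced by a
  homozygote for one of its own two allele calls, chosen with equal
  probability. For heterozygotes this is exactly the textbook "random
  allele" pseudohaploid call; homozygotes are fixed points, which
  keeps the operator information-preserving at monomorphic-in-sample
  sites (rewriting *all* genotypes as coin flips would destroy the
  genotype signal entirely). A half-missing genotype draws uniformly
  over its two slots and so becomes fully missing half the time.

When a pipeline requests several operators, `run_pipeline()` applies
them in a fixed order — depolarize, deaminate, pseudohaploidize,
unphase, missingness — chosen so that allele-level damage precedes
representation changes and missingness comes last (planned proportions
are then exact, not diluted by later operators). The order is fixed
purely for reproducibility; runs are fully determined by inputs plus
`--seed`.

## Evaluation: histograms and KL divergence

`missingness_histogram()` bins a profile into 50 equal-width bins on
`[0, 1]` (left-closed, last bin closed; a site with proportion exactly
1 lands in the final bin). Agreement between a template `p` and a
replicate `q` is `KL(p ‖ q) = Σ p_i ln(p_i / q_i)` in nats. KL is
undefined when `q` has an empty bin where `p` has mass; if either
histogram has an empty bin, both are regularized by adding half an
observation per bin before normalizing. Histograms with no empty bins
are compared exactly, and identical inputs give 0 in either regime.
Because the regularization and the log base rescale both sides of any
comparison equally, the *ordering* of KL values — the quantity of
scientific interest here — does not depend on these conventions.

## File formats and conventions

* **VCF** — reading uses `vcfR`; only the GT field is interpreted
  (separator `|`/`/` sets the phase flag; `.`, `./.` and `.|.` are
  fully missing; records without GT in FORMAT are read as fully
  missing with a warning). Non-diploid GT strings are an error: the
  whole model assumes diploid samples. The writer emits a minimal
  VCF 4.2 with GT only and tags records `AA=<REF>` while the matrix is
  still polarized, so polarization is observable downstream.
* **ms-style text** — multi-replicate input is split into one output
  per replicate (`_rep1`, `_rep2`, ...). Fractional positions map to
  integers as `floor(fraction × L) + 1` with ties bumped to the next
  free integer — deterministic and order-preserving; `L` defaults to
  1 Mb and is user-settable. ms output is refused whenever missing
  data, unphased genotypes, or non-biallelic sites are present, since
  the format cannot represent them.
* **EIGENSTRAT** — `.geno` digits count reference-allele copies
  (0/1/2, 9 = missing); conversion emits unphased genotypes because
  the format carries no phase.

## The synthetic template generator

`make_template()` emulates the one property of an empirical template
that the missingness engine consumes: a per-site missingness profile
with controllable spatial structure (constant, linear ramp, sinusoid,
mappability-like blocks, or i.i.d. beta draws), realized by exact
counts so the generated profile is a deterministic oracle.
`make_clean_segment()` emulates idealized simulator output with
derived-allele counts drawn from the neutral `1/i` site-frequency
spectrum. Neither generator models linkage disequilibrium, correlated
missingness across nearby samples, ascertainment bias, or genotype
errors other than those introduced by the operators — so passing tests
demonstrate that the machinery reproduces prescribed missingness
structure, not that any particular empirical dataset is matched.

## Problem sizes and numerical choices

The test suite exercises the dispersal algorithm exhaustively for all
`(N, M)` with `N, M ≤ 12` against an independently coded
block-boundary oracle, checks moment recovery at 50,000 beta draws,
and runs the template-versus-beta comparison on a 2,000-site,
100-sample ramp template across 100 seeded repetitions, requiring the
dispersal method to win (lower KL) in at least 80. The reference
coalescent simulation (10 Mb, 200 diploids, `Ne = 10,000`,
`mu = 1.29e-8`, `rho = 1e-8`) is run once per suite invocation through
msprime and is expected to produce a segregating-site count within 10%
of Watterson's `θ Σ 1/i ≈ 3.4 × 10⁴` — these sizes give comfortable
statistical resolution while keeping a full run in tens of seconds.

Degenerate inputs are handled explicitly: empty matrices cannot yield
profiles or summaries (error), a zero-variance profile cannot
parameterize a beta model (error), `U(a, a) = a`, empty replicates
write `segsites: 0`, and position-collision bumping fails loudly if
the segment is too short to hold distinct integer positions.

## Known limitations

* Missingness is independent across samples within a site; real data
  show sample-level covariance (bad libraries are bad everywhere).
* The block scheme cannot invent structure finer than the template
  resolution when upsampling, and compresses aggressively when
  downsampling.
* Deamination is strand-agnostic and ignores actual nucleotides; no
  contamination or sequencing-error model is included.
* Homozygosity and ascertainment characteristics of empirical data are
  not replicated.
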