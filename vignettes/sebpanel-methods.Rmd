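---
title: "Diagnostic SNP panels for redfish species identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic SNP panels for redfish species identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebpanel)
library(dplyr)
```

North-east Atlantic redfish (*Sebastes mentella*, *S. norvegicus* and
*S. viviparus*, with two cryptic types inside *S. norvegicus*) are
morphologically hard to tell apart but reproductively isolated. A small
panel of SNPs at which two taxa are *reciprocally fixed* for alternative
alleles lets a single genotype identify the taxon. `sebpanel` implements
the complete analysis chain around such panels: discovering candidate
diagnostic SNPs from genotype + depth data, summarising per-locus
diversity, assigning individuals to species from multilocus genotype
rules, and quantifying between-group divergence. A synthetic cohort
generator with planted diagnostic loci makes every stage testable without
sequencing data.

## The discovery model

A locus is *diagnostic* for a group pair (G1, G2) when every typed
individual of G1 is homozygous for one allele and every typed individual
of G2 is homozygous for a different allele. Discovery is a three-stage
filter, with the thresholds exposed in `discovery_config()`:

* **Quality**: only loci with Phred-scaled quality strictly greater than
  `min_qual` (default 500) are eligible. The inequality is strict because
  the protocol this follows is phrased as "greater than".
* **Coverage**: mean read depth over typed calls must be strictly greater
  than `min_depth` (default 20×) *in each group of the pair*. The
  protocol's coverage criterion refers to its comparison units, which are
  species groups; we therefore read coverage as the group mean. A
  stricter per-individual mode (`depth_mode = "per_individual"`) is
  provided because the alternative reading (each representative sample
  exceeds 20×) cannot be excluded.
* **Linkage thinning**: only contigs strictly longer than
  `min_contig_length` (default 20 kb) are eligible, and at most one SNP
  is retained per such contig — the highest quality, ties broken by the
  smallest position. The stated motive is minimising linkage
  disequilibrium between panel SNPs, which is why short contigs are
  excluded entirely rather than exempted from thinning.

Fixation is assessed among *typed* individuals only; `max_group_missing`
(default 0, i.e. complete typing required) controls how much missing data
a group may carry before the locus is disqualified. The source protocol
does not state how missing calls were handled, so the strict default is
ours, with the tolerance exposed.

`discover_panel()` unions the pairwise candidates over all unordered
group pairs before filtering, so a locus diagnostic for several pairs
appears once with all pairs annotated.

## Per-locus statistics

`locus_summary()` and `summary_table()` compute, per locus: the typed
count N, allele count Na, observed heterozygosity
$H_O = \#\text{het}/N$, expected heterozygosity (gene diversity)
$H_E = 1 - \sum_i p_i^2$, inbreeding coefficient
$F = (H_E - H_O)/H_E$ (undefined when $H_E = 0$), and the minor allele
frequency. $H_E$ uses the plain gene-diversity form with no small-sample
correction, matching the GenAlEx convention of the reference panel
report: MAF 0.485 gives $H_E = 0.500$ at 3 d.p., as published. The
unbiased $2N/(2N-1)$ variant sits behind `unbiased = TRUE`. $F$ is
computed from unrounded $H_O$/$H_E$; printed tables round to 3 d.p.
afterwards, which is why recomputing $F$ from already-rounded table
values can differ in the third decimal.

The Hardy–Weinberg test is the biallelic exact test: conditional on the
observed allele counts, every heterozygote count of compatible parity is
enumerated, and the p-value is the sum of the probabilities of all
configurations no more probable than the observed one (two-sided). Full
enumeration is exact and cheap at panel-scale sample sizes, so no Monte
Carlo approximation is used. Monomorphic loci return p = 1 by
convention. Significance stars in `summary_table()` follow `**` for
p < 0.01 and `***` for p < 0.001; the reference report's footnote is
typographically ambiguous between these two bands and this is the
reading we adopt.

When reproductively isolated groups are pooled, every diagnostic locus
shows a heterozygote deficiency (the Wahlund effect): pooling two groups
fixed for alternative alleles gives $H_O = 0$, $F = 1$, and an exact-test
rejection far below the 0.001 level for group sizes of 20. This is the
testable form of the published observation that all 47 panel loci
deviate from HWE with heterozygote deficiencies.

The genotypic linkage-disequilibrium test
(`ld_permutation_test()`) is this package's own choice, since the
reference analysis reports no LD numbers: the statistic is the
likelihood-ratio G on the genotype × genotype contingency table of
individuals typed at both loci, and the null is built by permuting one
locus's individual assignment, with
$p = (1 + \#\{G^* \ge G\})/(n_{\mathrm{perm}} + 1)$.

## Species assignment

`assign_by_rules()` scores each species rule by exact genotype matches
over non-missing rule loci and assigns the unique best rule whose
conflicts and missing counts are within tolerance (defaults 0 and 0 — the
strict panel). Heterozygous observations at a rule locus count as
conflicts, never half-matches: the one anomalous *S. viviparus*
heterozygote at SEB39 in the reference data is exactly the kind of
observation that should surface as a diagnostic rather than be averaged
away. Unknown signatures return `UNASSIGNED` with per-locus diagnostics
instead of a forced call. The shipped `sebastes_rules()` encode the
published three-SNP signatures (SEB29 separates *S. viviparus*, SEB39
*S. mentella*, SEB25 the two *S. norvegicus* types).

`assign_by_likelihood()` is the many-locus fallback: per group, the
log-likelihood is the sum over typed loci of the log Hardy–Weinberg
genotype probability under that group's allele frequencies. Frequencies
are floored at $\varepsilon = 1/(2N+1)$ (an add-one-style guard scaled to
the typed sample size) so an allele unseen in the reference group keeps
the likelihood finite. Assignment requires a natural-log margin of at
least `min_margin` (default 2, about a 7.4-fold likelihood ratio) over
the runner-up; identical groups therefore yield `UNASSIGNED`, not an
arbitrary pick.

## Divergence: chord distance, NJ, bootstrap, PCA

The Cavalli-Sforza–Edwards chord distance between groups x and y is,
per locus $l$ with frequencies $x_{lj}, y_{lj}$:

$$f_l = \sum_j \sqrt{x_{lj} y_{lj}}, \qquad
  d_l = \frac{2}{\pi}\sqrt{2\,(1 - f_l)},$$

aggregated over $L$ loci as the arithmetic mean $D_{CE} = \frac1L \sum_l
d_l$. Published implementations disagree on whether the average is taken
over per-locus distances or inside the square root over per-locus
similarities; we default to the former and expose the latter as
`aggregate = "mean_similarity"`. Because the variant used by the legacy
Populations program is not documented, printed branch lengths of the
reference tree are not treated as reproducible targets; the topology and
support behaviour are.

Neighbor-joining follows the canonical Saitou–Nei agglomeration with
$Q(i,j) = (n-2)d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$. Ties in $Q$ are
broken by the lexicographically smallest label pair, making the tree
fully deterministic; on additive matrices the input path lengths are
recovered to machine precision. Negative branch lengths are floored at 0
for display (`floor_negative = FALSE` disables this for exact-recovery
checks). Node support comes from resampling **loci** with replacement
(the published protocol runs 1000 such bootstraps), rebuilding
frequencies → chord distances → NJ per replicate, and scoring each
internal edge by the percentage of replicates containing the same leaf
bipartition.

PCA uses centred allele-dosage coding: the count (0/1/2) of the
lexicographically first allele per locus, missing dosages replaced by the
locus mean, columns mean-centred without variance scaling — the common
default of SNP-clustering toolkits. Percent variance per axis is its
eigenvalue over the eigenvalue sum, and each axis's sign is fixed by
making its largest-magnitude loading positive, so coordinates are
reproducible across runs.

## The synthetic cohort generator

`simulate_cohort()` emulates the kind of cohort the panel protocol was
developed on: a handful of reproductively isolated groups genotyped at
tens of loci with per-call read depths, missing calls and rare errors.
Its defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| groups | 4 × 30 | four species units at MassArray-plate scale |
| diagnostic loci/pair | 3 | the deployed panel separates each pair with few SNPs |
| shared loci | 40 | the remainder of a ~50-SNP assay |
| shared-frequency concentration | 50 | moderate between-group drift; groups stay polymorphic |
| depth | NB(mean 40, size 5) | ddRAD coverage is overdispersed; a negative binomial, not a Poisson |
| missing rate | 0.02 | typical assay dropout |
| error rate | 0.002 | rare genotyping error; replacement by a uniform random genotype (possibly the same one) |
| contig lengths | 25–100 kb, one locus each | all contigs eligible for thinning |
| quality scores | uniform 600–3000 | post-filter, high-confidence variant calls |

Genotypes are two independent allele draws from the individual's group
frequencies, i.e. Hardy–Weinberg *within* groups — so departures from HWE
in pooled data are pure Wahlund signal. Diagnostic loci are fixed (freq
1) for alternative alleles in their pair and held at 0.5/0.5 in the other
groups, so each planted locus is diagnostic for exactly its pair. Shared
loci draw per-group frequencies from a Beta distribution centred on a
common ancestral frequency (uniform on 0.2–0.8) with the concentration
above.

What the generator does **not** emulate: linkage and recombination
(every locus is independent, one per contig), coalescent genealogy,
selection, allele-specific error structure, and depth-genotype coupling
(low-depth calls are not more error-prone). Passing tests therefore
demonstrate the correctness of the algorithms under clean HWE-with-
fixed-differences conditions, not robustness to every artefact of real
ddRAD data.

## Numerical and design choices

* HWE enumeration uses log-factorials normalised by the maximum term;
  probability ties in the two-sided tail use a 1e-10 relative guard.
* The chord similarity $f_l$ is clipped to [0, 1] before the square
  root to absorb floating-point overshoot.
* GENEPOP allele coding is fixed at A=01, C=02, G=03, T=04 and missing
  = 0000 so written files are byte-reproducible.
* Half-calls (`./1`) in VCF input are treated as missing: downstream
  statistics assume complete diploid calls. Genotypes are stored
  unphased as sorted allele pairs.
* Under the uniform-replacement error model, an error reproduces the
  true homozygote with probability 1/3; the expected strict-panel
  unassignment rate at three rule loci is therefore
  $1-(1-\tfrac{2}{3}e)^3$, which the assignment tests verify.
* Test and bootstrap problem sizes (cohorts of 120–1000 individuals,
  100–1000 replicates) were chosen as the smallest sizes at which the
  binomial/permutation tolerances in the test-suite are informative.

## Limitations

The package starts from called genotypes: read alignment, SNP calling
and assay chemistry are upstream and out of scope, as are Bayesian
clustering (STRUCTURE-style), outlier/selection scans and hybrid-index
estimation. The exact-test implementation is biallelic; loci with more
than two observed alleles get frequencies and diversity statistics but
no HWE p-value. Likelihood assignment assumes HWE within reference
groups and independent loci — exactly the simulator's generative model,
so its near-perfect accuracy there is an upper bound, not a field
estimate.
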