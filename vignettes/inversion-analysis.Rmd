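---
title: "Detecting and analyzing polymorphic inversions with invkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analyzing polymorphic inversions with invkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invkit)
```

## The analysis model

A polymorphic inversion partitions the haplotypes of the affected region into
two classes between which recombination is suppressed in heterokaryotypes.
Three signatures follow, and each module of invkit targets one of them.

**PC1 clustering.** Coding genotypes as 0/1/2 copies of the alternative
allele, the inversion contributes a rank-one component to the genotype
covariance: individuals separate along PC1 into homozygote–heterozygote–
homozygote clusters. `run_pca()` performs the SVD of the column-centered
dosage matrix without variance scaling (the convention of the standard
`prcomp` default), mean-imputes missing dosages per SNP, doubles hemizygous
(ploidy-1) dosages onto the diploid scale, and fixes each component's sign
by forcing its largest-magnitude loading positive, so results are fully
deterministic. `detect_clusters()` formalizes "discrete clusters": exact 1-D
k-means (dynamic programming over the sorted scores, which is optimal and
has no initialization ambiguity — a deliberate strengthening of Lloyd-style
iteration from quantile seeds) for k = 3 and 2, accepting a k when the
smallest between-cluster gap exceeds `gap_ratio` (default 2) times the
largest within-cluster range. The largest accepted k wins; otherwise the
chromosome is reported as having no inversion evidence. On smooth unimodal
scores this rule accepts k ≥ 2 only a few percent of the time, which is the
operating false-positive rate of the scan.

**Loading block.** SNPs in complete association with the karyotype carry the
largest absolute PC1 loadings, and gene flux (gene conversion and double
crossovers) erodes that association toward the inversion center, so the top
loadings form a block whose first and last SNP positions estimate the
breakpoints. `locate_breakpoint_block()` takes the top 0.5 % of |PC1|
loadings by default, falling back to the top 5 % (with a floor of five SNPs)
when the strict threshold holds fewer than two SNPs. The threshold is a
*value* threshold: SNPs tied with the n-th largest loading are all included,
because SNPs in complete LD with the karyotype have exactly equal loadings
and an arbitrary tie-break would truncate the block. A contiguity number
(fraction of SNPs inside the recovered interval that are themselves top
SNPs) flags non-block patterns.

**Karyotype assignment.** With three clusters the extremes are homozygotes
and the center is heterokaryotypic; with two clusters the cluster with the
higher heterozygosity at the top-loading SNPs is heterokaryotypic. The
heterozygosity comparison uses at least ten top SNPs: with few arrangement
carriers, a single high-variance polymorphic SNP can outrank the diagnostic
SNPs by chance, and a wider panel makes the comparison robust. Major/minor
arrangements are named by allele frequency computed from karyotype counts
(haploids contribute one allele); an exact tie is resolved toward the
lower-PC1 cluster. Hardy–Weinberg equilibrium is checked with the exact
conditional test (full enumeration of heterozygote counts given the allele
counts, summing probabilities of tables no more probable than the observed
one); monomorphic data give p = 1, haploid samples are excluded.
`project_samples()` centers new samples with the training means over shared
SNPs and projects onto the training PC1 loading restricted to those SNPs,
dividing by its squared norm so that full overlap reproduces the training
score exactly; karyotypes are assigned to the nearest trained cluster mean.

**Linked-read verification.** `filter_interactions()` applies four criteria
in a fixed order (so every rejected record is attributed to the first
criterion it fails): (i) span above 0.4 Mb on chromosomes smaller than 20 Mb
and above 3 Mb otherwise ("smaller than 20 Mb" is strict, so a 20 Mb
chromosome uses 3 Mb); (ii) quality at least 4; (iii) both endpoints at
least 10 kb from every assembly gap, measured to the nearest gap edge and
zero inside a gap; (iv) the locus pair supported by more than one sample,
where records are greedily clustered across samples with a 50 kb endpoint
merge radius — wide compared with the ~8 kb breakpoint resolution typical of
such calls, so true calls from different individuals always merge.
`relaxed_rescan()` disables (iii) or (iv), which is how nested inversions
with breakpoints near assembly gaps, or carried by a single sequenced
individual, are recovered.

**Ancestral state.** The derived arrangement descends from one founder
haplotype: it shows lower heterozygosity, shares less polymorphism with an
outgroup, and accumulates more fixed differences against it.
`diversity_stats()` counts all three per sample in a region, expressing
rates per base pair of region length (not per SNP, so rates are invariant to
SNP density elsewhere). `flank_regions()` supplies the regions: 10 % of the
inversion length inside each breakpoint (20 % combined), or a single
400 kb region adjacent to a chosen breakpoint for sequence export.
`classify_ancestral()` fits an OLS contrast per statistic and votes; the
verdict needs two of three statistics concordant, a 2–1 split is flagged
weak, exact ties are undetermined, and when both classes fall below half
(configurable) of the chromosome-background heterozygosity the verdict is
"both derived" — the pattern expected when all extant arrangements are
recent. The classification is label-symmetric by construction.
`strata_scan()` recomputes the three contrast signs in 50 kb windows
stepping by 25 kb and labels windows consistent or opposite to the global
verdict by majority of informative signs; contiguous opposite runs are
candidate evolutionary strata, with single-window interruptions closed
(`merge_gap = 1`) because an isolated flipped window at this window size is
sampling noise.

**Neutrality.** Under the neutral site-frequency spectrum the probability of
a derived allele at count i of 2N is proportional to 1/i; conditioning on
detectability truncates the support at `detect_min` and renormalizes. The
folded variant uses (1/i + 1/(2N−i)) over minor counts with the midpoint
counted once. `exceedance_test()` draws k frequencies per replicate and, in
the default `sorted_dominance` comparison, scores a success when after
sorting both vectors every draw strictly exceeds its paired observation —
equivalently, when a perfect matching of draws strictly above the
observations exists. Because "six frequencies higher than those observed"
can also be read as a threshold statement, an `all_exceed_min` mode (every
draw above the smallest observation) is provided; sorted dominance is the
default as the stricter and more natural reading. The default observed set
(`zebra_finch_derived_freqs()`) is the six derived-arrangement frequencies
in the 19-bird wild panel (0.395, 0.605, 0.605, 0.711, 0.421, 0.500). The
implementation avoids per-replicate sorting: after sorting the observations,
a replicate succeeds iff at least k−j+1 draws exceed the j-th smallest
observation for every j.

**Fitness effects.** Traits are Z-scaled (mean 0, SD 1, n−1 denominator) and
each genotype class is contrasted against the ancestral homozygote baseline
in a linear model (`fit_contrast()`), optionally with covariates and a
random intercept via lme4. When several grouping factors are supplied the
one with the most levels is used, with a message: single-grouping intercepts
capture the bulk of the pseudo-replication in these designs and keep the
estimator simple; fully crossed random effects are out of scope. Binary
traits are analyzed on the same Z-scaled linear scale as continuous ones —
effect sizes stay comparable across traits at the cost of
heteroscedasticity, which the meta-analytic weighting absorbs.
`meta_summarize()` pools the standardized estimates by weighted least
squares without intercept and weights 1/SE — the inverse standard error, not
the conventional inverse variance, which is available behind
`weights = "inv_var"`. The per-contrast solution is exactly
sum(w·b)/sum(w). Tag SNPs are ranked by squared Pearson correlation with the
karyotype dosage, then missing rate, then position; `tag_attenuation_sim()`
shows that a tag at r² < 1 attenuates the estimated effect roughly in
proportion, so effects estimated through tags are underestimates — the
direction of bias matters when interpreting weak heterosis.

## The synthetic-data generator

`simulate_inversion_population()` implements a parametric two-pool model
rather than a coalescent: the ancestral pool carries standing polymorphism,
the derived pool is founded from a single ancestral haplotype (the founder
bottleneck strength is exposed; the default is a strict single founder) and
the two pools are separated by fixed differences in proportion to `t_div`.
Each inversion-interior SNP is one of three types, with probabilities
proportional to `t_div` (fixed difference), `theta` (ancestral-pool
polymorphism) and `theta * derived_diversity` (derived-private
polymorphism, default 0.3 — the derived class has recovered some variation
since founding). This gives exactly the heterozygosity, shared-polymorphism
and fixed-difference signatures the ancestry module tests, at negligible
cost. With `t_div = 0` the class structure is disabled entirely and the
generator produces exchangeable genotypes — the null for false-detection
rates.

Gene flux is modeled as per-site homogenization: with probability
`gene_flux` times a weight that is zero within 10 % of the inversion length
of each breakpoint (recombination suppression is tightest at the
breakpoints) and ramps to one at the center, a site's alleles have spread
through both pools over the inversion's history and every haplotype draws
from the pooled frequency. An earlier per-haplotype, per-site allele-swap
implementation was rejected: independent small perturbations across
haplotypes blur the PC1 clusters without producing the observed bimodal
loading pattern, whereas historical flux events propagate through the pools
and either leave a site diagnostic or homogenize it. The homogenization
model reproduces both observations — discrete clusters and |PC1| loadings
declining toward the center — at the stated panel sizes. The default
`gene_flux = 0.4` erodes roughly one in five interior sites, consistent
with strong LD loss at the centers of old inversions.

The outgroup (`simulate_outgroup()`) diverged from the ancestral-pool root:
it is homozygous ancestral at fixed differences (so derived homozygotes
accumulate fixed differences against it), retains a fraction `p_share`
(default 0.5) of ancestral polymorphisms as heterozygous sites, never
shares derived-private polymorphism, and adds substitutions at
`outgroup_div` plus private heterozygosity at `theta_outgroup`.
Reversed-polarity nested intervals swap the pool roles locally, creating a
younger stratum whose three contrasts flip sign — the truth model for
strata-scan tests. Barcode interactions are emitted by every carrier of a
non-reference arrangement at both breakpoints (jitter ≤ 5 kb, quality
4–60); spurious records fail at least one filter criterion by construction,
with singleton-mode records placed on start slots spaced beyond twice the
endpoint-merge radius so they cannot gain support by chance co-clustering.
Fitness traits are emitted on an approximately unit-variance scale with the
residual SD defaulting to whatever fills the variance left by the genetic,
covariate and group components.

Default study conditions: 20 individuals, 60 SNPs inside a 10 Mb inversion
on a 20 Mb chromosome, 60 SNPs outside (the same SNP density on both sides),
derived frequency 0.4, `theta = 0.005`, `t_div = 0.01`,
`outgroup_div = 0.03` (an outgroup roughly three times as divergent as the
arrangements are from each other). All randomness flows from a single
integer seed; a fixed seed reproduces the output bit for bit, and every
generator writes its truth (karyotypes, breakpoints, site metadata) for
recovery tests.

**What the generator does not emulate.** Sites are independent given the
class structure (no within-class LD), positions are uniform, there is no
genotyping error or missingness unless injected, no coalescent variance in
class divergence, and no sequencing reads. Passing recovery tests therefore
demonstrates that the estimators extract the planted signal at realistic
sizes and noise levels — not that they are robust to reference bias, calling
artifacts or population structure, which real data add.

## Test conditions and problem sizes

The recovery suites use: 20 samples and 60 inversion-interior SNPs per
replicate for detection power and karyotype/breakpoint recovery (70
replicates per derived frequency in {0.1, 0.25, 0.5}, 100 null replicates);
28 samples (20 training, 8 held out) for projection over 200 replicates;
600-SNP panels for ancestry classification (100 replicates); 8,000 SNPs
across a 2 Mb two-epoch inversion — one SNP per 250 bp, ordinary
whole-genome-sequencing density — for strata-boundary recovery (50
replicates); and 5,000 individuals for fitness contrasts (200 replicates).

Three choices in the power analysis deserve note. First, the detection
claim is evaluated by running PCA and cluster detection directly on the
simulated 60-SNP panel: the panel *is* the analysis set, as in a
selected-marker design. The default `filter_maf(0.1)` step would itself
remove the diagnostic SNPs of an inversion at frequency 0.1 (their expected
allele frequency sits exactly at the threshold), so detecting low-frequency
inversions in practice requires a filter below the target frequency — a
real operating constraint of the method, documented rather than hidden.
Second, breakpoint recovery is scored at SNP resolution: the recovered
block is compared against the span of SNPs in complete LD with the
arrangement (recorded in the truth sidecar), with tolerance one average SNP
spacing. With 60 SNPs over 10 Mb the nearest SNP to a breakpoint is often
more than one spacing away, so scoring against the base-pair breakpoints
would measure SNP-placement luck, not the estimator. Third, the projection
check scores per-sample karyotype correctness.

## Numerical conventions and degenerate inputs

All coordinates are 1-based inclusive; BED input is converted at the
boundary and back on write. Missing dosages are distinct from zero and are
mean-imputed only inside PCA, never in storage. Hemizygous dosages are
doubled only inside PCA. PCA reconstruction is validated to 1e-8;
meta-summary equals the closed-form weighted mean to 1e-12. Cluster-count
ties break toward smaller k (conservative). A MAF filter that removes all
SNPs warns "no informative SNPs" and the scan reports a cluster count of 1
rather than failing. An all-missing sample projects as unassigned. A window
larger than the inversion yields a single strata window and no strata. Tag
simulation resamples until the realized r² is within 0.05 of the target and
errors when the class counts make the target infeasible. Zero-variance
traits are an error naming the trait.

## Known limitations

The cluster rule compares gaps against within-cluster ranges and is
calibrated for panels of tens of individuals; with hundreds of samples a
density-based rule would be preferable. The paper-scale mixed-effect
designs (crossed random effects of mother, father, pair, clutch and season)
are approximated by a single grouping factor. The exceedance test treats
the observed frequencies as fixed; uncertainty in their estimation is not
propagated. Divergence-time estimation and tree building are out of scope —
`write_iupac_consensus()` exports per-sample consensus sequences for
external phylogenetic tools instead.
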