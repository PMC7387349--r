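---
title: "Models and methods behind gbspopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbspopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gbspopgen` analyses sparse diploid SNP panels of the kind produced by
genotyping-by-sequencing (GBS) of largely self-pollinating crop
collections — several hundred inbred-ish lines, a few thousand to tens of
thousands of biallelic SNPs spread over many chromosomes, variable
per-call depth, and a substantial fraction of missing calls. This
vignette explains the models the package implements, the defaults it
ships with, and the choices made where the design was genuinely open.

## The synthetic panel generator

Real GBS genotype panels of this kind are rarely redistributable, so the
package ships a calibrated generator (`simulate_panel()`) used throughout
the test suite.

**Model.** Ancestral allele frequencies are drawn uniformly on
(0.05, 0.95). Two subpopulations receive frequencies from the
Balding–Nichols Beta distribution around the ancestral value with
differentiation parameter $F$, i.e.
$p_{k\ell} \sim \mathrm{Beta}\!\big(p_\ell \tfrac{1-F}{F},\,
(1-p_\ell)\tfrac{1-F}{F}\big)$, so that the expected Weir–Cockerham
$F_{ST}$ between the subpopulations equals $F$ — a closed-form
calibration that needs no coalescent machinery and is verified by the
test suite (recovered within $\pm 0.02$ at $F = 0.15$ over 30 seeds).
Genotypes are binomial draws; inbreeding is modelled *phenomenologically*
by converting heterozygotes to homozygotes with probability
`selfing_rate` (a single parameter reproducing the high fixation indices
of selfing crops: at `selfing_rate = 0.82` the realized $F_{IS}$ is
$\approx 0.82$), rather than by explicit generational selfing.
Missing calls are Bernoulli per call; depths are zero-truncated Poisson,
with missing calls carrying depth 0.

**Defaults.** The default configuration mirrors a global Ethiopian
mustard (*Brassica carinata*) diversity collection: 549 + 41 diploid
lines in two unequal subpopulations, 17 chromosomes named B1–B8 and
C1–C9, 600 loci per chromosome (10,200 SNPs), differentiation 0.148,
selfing rate 0.82, 10% missing calls, mean depth 8. Chromosomes default
to 10 Mb — a desk-scale stand-in for ~75 Mb Brassica chromosomes chosen
so that 100-kb windows hold a workable handful of SNPs; analyses whose
geometry depends on absolute SNP spacing (see the sweep scan below)
scale their clustering gaps accordingly.

**Planted sweeps.** `plant_sweep()` copies a single founder gamete
(drawn from the target subpopulation's allele frequencies) homozygously
into a chosen fraction of the target-population samples across every
locus in an interval, leaving missing-call patterns untouched. This
depresses nucleotide diversity and Tajima's D locally in the target
population, raises windowed $F_{ST}$, and creates local LD.

**What the generator does *not* emulate.** Loci are statistically
independent given the subpopulation frequencies: there is *no background
linkage disequilibrium* from shared descent, no allele-frequency
correlation along chromosomes, and no isolation-by-distance. Real
selfing collections are mosaics of long shared haplotypes and show
genome-wide LD; here LD exists only where a sweep was planted or via the
(weak) mixture effect of pooling two populations. Consequently
Gabriel-style haplotype blocks — which require D′ confidence intervals
consistent with |D′| ≈ 1 — form only sporadically even inside planted
sweeps, because the unswept portion of the panel still supplies all four
two-locus haplotypes. Passing tests therefore demonstrate correctness of
the estimators and the sweep-evidence integration, not that real panels
would show equally clean block structure; on real data the block track
is expected to be far richer.

## SNP quality control

`filter_snps()` applies, in order: per-call masking at depth < 4
(calls with unknown depth are left alone), then per-locus removal at
MAF ≤ 0.05 (strict ">"), observed heterozygote fraction > 0.1, and
missing fraction > 30% ("up to 30%" read inclusively). All locus
statistics are recomputed after depth masking, and filtering is
idempotent. The heterozygosity rule is interpreted *per locus*: in a
polyploid-derived, highly inbred crop an excess of heterozygote calls at
one locus is the signature of collapsed paralogous loci, which is what
this filter exists to remove. A per-sample reading would be vacuous in a
panel whose observed sample-level heterozygosity is ~0.05.

`impute_missing()` replaces each missing call with a
Binomial(2, $\hat p_\ell$) draw at the locus' observed ALT frequency.
This is deliberately simple: it leaves allele frequencies unbiased in
expectation, which is all the downstream frequency-based statistics
need, and it cannot manufacture spurious LD. It does not borrow
haplotype information, so per-call imputation accuracy is bounded by the
genotype-frequency entropy (at $p = 0.5$ under Hardy–Weinberg the best
achievable concordance is 0.375); the hold-out test asserts exactly
that bound is beaten on mixed-frequency panels.

## Site annotation

`annotate_sites()` classifies sites as coding (inside any CDS), intron
(inside a gene but outside all exons), or intergenic, resolving
overlaps in that order of specificity. `classify_coding_effect()`
substitutes the ALT base into the codon — strand-aware, frame taken from
the CDS phase — and translates with the standard genetic code; premature
stops count as non-synonymous. A metamorphic test verifies that effects
are invariant under reverse-complementing the entire reference. Note
that under the random-substitution generator roughly one quarter of
coding changes are synonymous (the neutral expectation); real panels
shaped by purifying selection show much higher synonymous fractions.

## Diversity statistics

`windowed_diversity()` works on non-overlapping 100-kb windows
(half-open, tiling each chromosome). Per site, with $n_\ell$ observed
allele copies and ALT frequency $\hat p_\ell$, the unbiased mean
pairwise difference is $\frac{n_\ell}{n_\ell-1} 2\hat p_\ell \hat
q_\ell$; the window's $\hat k$ sums these and $\pi = \hat k / L_w$ with
$L_w$ the *full window length* — the per-site convention of windowed
scans over sparse GBS data, which makes $\pi$ magnitudes directly
comparable across windows regardless of SNP counts. Watterson's
$\theta_W = S / (a_1 L_w)$ and Tajima's D use the standard constants
evaluated at $n$ = the *median per-site allele count* of the window:
missing data make $n$ site-specific and some single choice is required;
the median is robust to a few low-coverage sites. At $n = 2$, D is the
0/0 identity and is reported as 0; windows with $S \le 1$ give NA.
A brute-force enumeration oracle (explicit pairwise differences over
expanded pseudo-haplotypes) pins the $\pi$ computation exactly.

`weir_cockerham_fst()` implements the 1984 variance-component estimator
from genotype counts (components $a$, $b$, $c$ with observed
heterozygosities), combining loci as the ratio of sums
$\sum a / \sum(a+b+c)$ — not the average of per-locus ratios, which is
biased for low-information loci. Windowed, per-locus, pairwise and
multilocus modes share the same per-locus components. $F_{IS}$ and
$F_{IT}$ are derived from the same components for internal consistency.

`amova()` partitions allelic variance (each diploid contributes its two
implied allele values per locus) into among-population /
among-individual / within-individual levels with the standard nested
expected-mean-square equations, truncating negative components to zero
before percentages — the convention of desktop AMOVA tools.
`kinship_matrix()` is the correlation-type estimator
$F_{ij} = \sum_\ell (x_i-\hat p)(x_j-\hat p) / \sum_\ell \hat p(1-\hat
p)$ on half-dosages, with negative values truncated to zero (less
related than random pairs carries no information for the downstream
uses); a pedigree oracle checks parent–offspring pairs land at ~0.25.

## Population structure

`ld_prune()` is the standard greedy left-to-right scan (drop any locus
with composite $r^2 > 0.1$ against a retained locus within 500 kb).
`run_pca()` centers at $2\hat p$ with optional Patterson scaling
$\sqrt{\hat p(1-\hat p)}$, drops monomorphic loci, and fixes component
signs (largest-magnitude loading positive) for reproducibility.

`admixture_em()` fits the classical admixture likelihood
$g_{i\ell} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{k\ell})$ by EM.
This is the same likelihood that Bayesian model-based clustering
programs explore by MCMC; the maximum-likelihood fit preserves the Q/P
output contract while running deterministically in seconds, so MCMC
burn-in settings map onto `max_iter`/`tol`. Monotonicity of the
log-likelihood is asserted at every iteration. The model assumes
Hardy–Weinberg within clusters, which the inbred panels violate;
empirically the violation costs a few points of membership sharpness
(mean absolute Q error ~0.03 at $F = 0.15$ with selfing 0.8) without
moving assignments. `select_k()` applies the Evanno second-difference
statistic over replicate restarts; a zero replicate standard deviation
yields an infinite sentinel and flags the selection, as does zero
curvature. Membership assignment uses the inclusive Q ≥ 0.70 rule on
the single best-likelihood run, everything below it labelled admixed.

`build_tree()` offers both UPGMA and neighbour joining on
identity-by-state distances — analyses of such panels are described
variously with either algorithm, so both sit behind one interface —
with locus-resampling bootstrap support (desk-scale default of a few
hundred replicates; raise for publication figures).

## Linkage disequilibrium

`pairwise_r2()` uses the composite (dosage-correlation, Rogers–Huff
style) $r^2$ on unphased genotypes within 500-kb windows — the
genotypic mode of standard LD software, orders of magnitude faster than
haplotype EM and accurate to within 0.05 of haplotypic $r^2$ in the
property tests. Significance is the $\chi^2_1$ statistic $N r^2$.
`ld_decay()` averages significant pairs in 25-kb left-closed bins from
zero and reports the left edge of the first bin whose mean falls below
the critical $r^2$ (0.1); panels in extreme LD never cross it and
return NA. Raising the critical value can only shorten the reported
decay distance — the monotonicity the property test asserts.

`dprime_ci()` estimates two-locus haplotype frequencies by EM from the
3×3 genotype table and profiles the data likelihood over a grid of
|D′| values (allele margins fixed), normalising to a posterior with a
flat prior whose 5th/95th percentiles form the confidence interval.
`gabriel_blocks()` applies the plain Gabriel classification — strong LD
when CI ∈ [0.70, 1] with upper bound ≥ 0.98, strong recombination when
the upper bound < 0.90 — and accepts intervals whose endpoint pair is
in strong LD with ≥ 95% of informative internal pairs strong.
Haploview's block-size-dependent refinements of the strong-LD fraction
are deliberately not implemented. Overlapping candidates are resolved
largest-span-first with a leftmost tie-break, a rule fixed here because
the original definition leaves overlap handling open; an exhaustive
enumeration oracle checks the implementation on small instances.

`min_markers_for_gwas()` is the genome-size-over-decay-distance rule of
thumb, rounded to the nearest marker.

## Sweep scanning

`sweep_scan()` integrates three evidence tracks: (i) clusters of ≥ 5
SNPs whose absolute PC-loading exceeds 0.02, single-linkage joined
within a gap; (ii) runs of windows with $F_{ST}$ at least three
standard deviations above the windowed mean; (iii) haplotype blocks of
at least 400 kb. Maximal connected overlap components carrying at least
two distinct evidence types become regions of interest, ranked by
evidence count and then by their peak windowed $F_{ST}$; each ROI is
verified by a regional PCA (variance explained by the top 2 and 5 PCs,
and the silhouette of the subpopulation labels on the first two PCs).

Two geometric points deserve care. The 0.02 loading threshold is an
absolute number on unit-norm loading vectors: it is meaningful for
panels of roughly 10⁴ loci (where the RMS loading is ~0.01) and
saturates on much smaller panels — the validation simulations therefore
use full 10,200-locus panels. Likewise the loading-cluster join gap is
about 5–6 times the mean SNP spacing in the source analysis (500 kb at
one SNP per 92 kb); on the denser desk-scale panels the same *relative*
gap (100 kb at one SNP per 17 kb) is used, otherwise background loci
chain into chromosome-length artefacts. The mean-plus-3-sd $F_{ST}$
rule was chosen because "localised high differentiation" is otherwise
unquantified; `z` is exposed as a parameter. Both thresholds were fixed
before the recovery experiments and are exercised by the acceptance
suite: a planted 1-Mb sweep (fraction 0.9, $F = 0.1$) is recovered as
the top-ranked ROI with ≥ 2 evidence types in ≥ 90% of 20 seeds, while
sweep-free panels average at most one ROI.

## Pipeline and reproducibility

`run_full()` chains simulate/read → filter → impute → annotate →
diversity → structure → LD → sweep scan from one configuration, writing
stable-column-order TSVs (windowed statistics in the classic
chromosome/start/end track layout; per-chromosome LD and block
summaries; an ROI table) plus a checksummed manifest. A single master
seed fans out to per-stage seeds via `derive_seed()`, so identical
configurations give byte-identical outputs and individual stages can be
re-run in isolation. Validation problem sizes throughout the package
(panels of 70–620 samples, 400–10,200 loci, 1–17 chromosomes of 5–20
Mb) were chosen as the smallest panels on which each statistic is
well-conditioned.

## Known limitations

* No background LD in the generator (see above); block-based results on
  real panels will be richer than on simulated ones.
* Frequency-draw imputation is unbiased but ignores haplotype
  information; panels destined for haplotype-sensitive analyses should
  be imputed with a dedicated haplotype-HMM tool before import.
* The admixture model assumes within-cluster Hardy–Weinberg; strongly
  inbred panels violate it, which mildly softens Q estimates.
* AMOVA significance testing (permutation p-values) and
  population-recombination-rate estimation are out of scope.
* Tajima's D in windows with very few SNPs is noisy; interpret the
  windowed tracks, not individual windows.
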