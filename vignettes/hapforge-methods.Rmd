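---
title: "Variant discovery and population-genetics QC for inbred panels: models and methods"
author: "hapforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant discovery and population-genetics QC for inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapforge)
```

# The problem

Calling variants in a large panel of inbred lines from low-coverage
whole-genome sequencing against a single reference faces two dominant error
sources that ordinary per-site callers handle poorly: reads from paralogous
or structurally divergent regions mapping to the wrong place (producing
false heterozygous sites and false rare alleles), and plain sequencing
error at very low depth. hapforge implements a pipeline that exploits the
*population structure* of an inbred panel to separate true variants from
these artifacts: a real variant segregates between lines, so (i) its minor
and major read depths concentrate in roughly disjoint subsets of taxa, (ii)
its genotypes are consistent between lines that are identical by descent
(IBD), and (iii) it is in strong *local* linkage disequilibrium (LD) with
trusted nearby markers. Each of these expectations becomes a filter.

Two filtering routes are provided. The **strict** route applies the
segregation test, the IBD filter and the LD filter, yielding a conservative
marker set annotated with confidence flags. The **permissive** route
replaces the LD filter with a minor-allele read-depth rule (">1, >2") and
then fills missing genotypes by LD-KNN imputation, trading some specificity
for far better coverage of rare alleles, which strict LD testing cannot
assess.

# Genotype calls and the six-allele space

Indels are collapsed to two symbolic alleles, `I` (insertion) and `D`
(deletion), regardless of length and sequence, giving the fixed allele
space {A, C, G, T, I, D}. Per taxon and site, the caller sees a vector of
six read depths and maximizes the multinomial likelihood over the 21
unordered genotypes. A read from homozygote $a/a$ shows allele $x$ with
probability $1-\varepsilon$ if $x=a$ and $\varepsilon/5$ otherwise; under
heterozygote $a/b$, each of $a$ and $b$ appears with probability
$(1-\varepsilon)/2+\varepsilon/10$. The error rate defaults to
$\varepsilon = 0.01$, a deliberately flat, sequencer-agnostic model: with
panel-level filters downstream, modelling base-quality structure buys
little. Ties are broken toward the homozygote of the deeper allele, then by
allele order, so calls are deterministic. A taxon with zero reads is
missing. A position becomes a *tentative site* only if at least 10 taxa
have coverage, a non-reference allele is present in the reads, and at least
one call is non-reference; at most the two most read-supported alternative
alleles are kept.

# The segregation test

For each pair of site alleles, the per-taxon depths of the two alleles form
a $2\times N$ contingency table. Under the null of no segregation
(errors scattered at random), the table should look proportional; a real
variant in inbreds concentrates the two rows in different taxa. Exact
Fisher testing of $2\times N$ tables is expensive, so a hybrid is used:
the Pearson chi-square P-value is computed first, and only when it falls
below 0.2 is a Monte-Carlo estimate of the exact P-value computed, by
sampling `B` tables with the observed margins (Patefield's algorithm via
`stats::r2dtable`) and scoring those whose log-probability does not exceed
the observed one:

$$\hat P = \frac{1 + \#\{\text{simulated} \le \text{observed}\}}{B + 1}.$$

The 0.2 gate rests on the empirical observation—reproduced in this
package's tests—that for insignificant tables the chi-square P-value is a
de facto *lower bound* on the exact one, so no site that would survive an
exact test is lost by reporting the chi-square value there. Ties between
simulated and observed statistics are counted as "at least as extreme"
(the convention of `fisher.test`), and the $+1$ correction keeps
$\hat P > 0$. An alternative allele is retained if *any* table involving it
has $P \le 0.01$; a consequence worth knowing is that at multiallelic
sites a scattered allele can survive through its table against a strongly
segregating allele. Per-site RNG streams are derived from the master seed
and the site coordinates, so results are independent of processing order
and worker count. The emitted `PV` annotation is the minimum P-value over
the site's allele-pair tables.

# The IBD filter

A trusted *anchor map* of SNP genotypes defines windows of 2000 anchor
sites (a trailing remainder is merged into the previous window rather than
left as an under-powered stub; a chromosome with fewer than 2000 anchors is
one window). Within each window, the identity-by-state distance between
two taxa is the mean over comparable sites (both nonmissing) of
$1-\text{shared alleles}/2$; at least 200 comparable sites are required,
and pairs at distance $\le 0.02$ are declared IBD there.

At a candidate site, every IBD pair with both genotypes present is a
*contrast*. For each allele, a pair where both genotypes carry it counts
as a match, and a pair where exactly one does as a mismatch; a
heterozygote carries both of its alleles, so het-vs-hom($a$) yields a
match for $a$ and a mismatch for the other allele. The site is confirmed
if at least two alleles reach match/mismatch $\ge 2$ (mismatch 0 with
positive matches counts as infinite). If confirmation fails but at most
one allele appears among the contrasts—including the case of no usable
contrasts at all—the site *passes weakly* and is flagged `IBD1`: it does
not violate IBD, but the variant is unconfirmed (typically low-MAF sites
whose carriers sit outside the IBD pairs). Everything else fails.
Candidate positions outside the anchored span are assigned to the first or
last window of their chromosome.

# The LD filter

Each strict-route candidate is tested for LD against every anchor site.
The LD measure is the two-sided Fisher exact P-value of the $2\times 2$
haplotype-count table, where each taxon contributes one haplotype:
heterozygotes are collapsed to minor-allele carriers, and at multiallelic
sites all non-major alleles count as minor. A pair of sites is testable
only when they are at least 2500 bp apart (different chromosomes always
qualify), at least 40 taxa are nonmissing at both, and at least 2 of those
carry the minor allele at each site. The up-to-20 best hits are kept; the
site is rejected when the best P-value exceeds $10^{-6}$, or when no
retained hit is *local* (same chromosome, within 1 Mb, with P within a
factor 10 of the best). Local sites pass with the `LLD` flag; sites with
no testable pair at all pass unflagged ("LD could not be assessed").
Two small conventions were left open by the published description and are
fixed here: the 1 Mb radius is measured between site positions, and the
best hit may itself serve as the local hit (the within-factor-10
comparison uses $\le$, so a best hit with P-value 0 still qualifies).

A desk-scale caveat: with exactly $n$ taxa the smallest achievable
two-sided Fisher P with $c$ minor carriers is $1/\binom{n}{c}$, so at
$n = 40$ a site needs roughly 6 carriers (MAF about 0.15) before the
$10^{-6}$ cutoff is reachable at all. The published threshold presumes a
panel an order of magnitude larger; validation cohorts here are built so
that most MAF $\ge 0.1$ sites carry at least 6 minor alleles.

# The ">1, >2" depth filter and imputation

The permissive route accepts a site when some minor allele has read
support greater than 1 in at least one taxon *and* greater than 2 summed
over all taxa; with two alternative alleles each is judged on its own
depths.

Missing genotypes are then filled by LD-KNN imputation. For a target site,
up to 70 surrounding sites within $\pm 600$ kb, with heterozygosity below
3% and more than 50% nonmissing taxa, are ranked by $r^2$ with the target
($r^2$ = squared Pearson correlation of minor-allele dosages 0/0.5/1 over
jointly nonmissing taxa; fewer than 2 informative taxa gives 0). For each
taxon, up to 30 neighbours are chosen by IBS distance over those LD sites,
excluding taxa that are missing at the target site, have more than 50%
missing data at the LD sites, fewer than 10 comparable sites, or distance
above 0.1. Each candidate genotype $g$ receives weight

$$w_g = \sum_i \frac{1}{1 + 70\, d_i}$$

over neighbours $i$ with genotype $g$, and the top genotype is imputed
only if its weight is at least 10 times the runner-up's; otherwise the
imputation is "unknown". Unknown imputations at sites with pre-imputation
MAF below 1% become major-allele homozygotes. The vote is over exact
genotype values (allele pairs), not dosages, and is fully deterministic
(ties by genotype code, neighbour ties by taxon order).

Every genotype—missing or not—is test-imputed with the target taxon
excluded from its own neighbour set. Known genotypes are never changed in
the output; the test-imputations feed the transition matrix (original
class × imputed class over major homozygote / heterozygote / minor
homozygote / indel-containing, plus an unimputable outcome) and the
per-site `ImpHomoAccuracy` and `ImpMinorAccuracy` statistics, which follow
the transition-matrix convention of computing accuracy among genotypes
that could be imputed.

# Annotations

Per site: `DP`, `NZ`, `AD`, `AC`, `AQ` (depth-weighted mean base
qualities), `GN` (genotype-class counts in VCF order, six classes at
2-ALT sites), `HT`,
`EF = het_frequency / (presence_frequency × MAF)` (missing, not zero,
when MAF or presence is zero), `PV`, `MAF` (summed over all alternative
alleles), `MAF0`, `FH` (heterozygote fraction within the high-coverage
subset: taxa with strictly more than 50% nonmissing genotypes on a
designated chromosome), and flags `FH2` (FH > 2%), `DUP` (heterozygote
frequency > 3%, judged on unimputed genotypes), `IBD1`, `LLD`, `NI5`
(indel, or within 5 bp of a putative indel—any retained site carrying an
I/D allele), and `INHMP311` (membership in the strict-route set). Per
taxon, the inbreeding coefficient is
$F = (O - E)/(N - E)$ with $E = \sum_k (1 - 2 p_k q_k)$ over the taxon's
genotyped sites, $p_k$ the site MAF from all nonmissing taxa. No
multiple-testing correction is applied anywhere: the pipeline uses fixed
per-filter thresholds by design.

# Depth stores and the one-byte codec

Allelic depths and mean base qualities are extracted once per taxon from
single-sample pileup text (bases need quality $\ge 10$; mapping quality
$\ge 30$ is imposed upstream at pileup generation) and persisted so that
genotyping can be re-run—e.g. after adding taxa—without touching the
alignments. Each store file covers one taxon and one chromosome and keeps
only sites with non-zero coverage. Every depth and quality occupies one
byte: values 0–182 are exact, and 73 negative codes form a geometric grid
$\mathrm{round}(183\,b^k)$, $k = 1..73$, with $b = (10000/183)^{1/73}
\approx 1.0563$, covering counts up to 10000 with at most 3.1% relative
error (saturating above). Encoding maps a count to the nearest
representable value, which keeps the encoder monotone and the round-trip
error minimal; in the byte itself, negative codes occupy 183–255 in two's
complement, so the 256 byte values are used exactly. The indel allele's
quality is the quality of the read base directly preceding the indel
event.

# The synthetic cohort simulator

`simulate_cohort()` generates the ground-truth world the tests and the
validation suite run against. Taxa are mosaics of a few founder
haplotypes (Poisson breakpoints, mean segment `founder_block_bp`), which
yields the two population features the filters rely on: IBD between taxa
sharing a founder across a window, and block-scale local LD. Site classes
are `true` variants (founders carry the minor allele at the site's MAF;
taxa are homozygous apart from planted residual heterozygosity; a
configurable fraction are indels), `error_only` (monomorphic; minor
alleles arise only from read errors), `paralog` (taxa whose founder
carries a hidden paralog allele emit a 50/50 read mixture—systematic
heterozygosity), and `translocated` (the carrier pattern of a distant,
segregating donor site is copied, mimicking a marker whose genetic
position contradicts its physical one; donors are restricted to carrier
fractions $\ge$ 10% because a pattern copied from a near-monomorphic site
is untestable by construction). Read depths are
Poisson(`coverage_mean`); each read reports a genotype allele, replaced
with probability `seq_error_rate` by one of the other five alleles
uniformly. The anchor map is a subsample of high-MAF (realized MAF
$\ge 0.05$) true SNP sites more than 5 bp from any indel, with genotypes
masked at `anchor_missing_rate`.

Defaults describe a realistic low-coverage inbred panel: 50 taxa from 5
founders, mean coverage ×4 (the panel-wide average of the data the
pipeline was designed for), per-read error 0.5%, residual heterozygosity
1% per genotype (inbred lines are expected to stay below 2–3%), MAF drawn
from a rare-skewed folded spectrum $0.5\,\mathrm{Beta}(1,3)$, founder
blocks of 4 Mb, and anchors at half the eligible sites with 5%
missingness. `founder_assignment = "balanced"` assigns the first founder
segment of each chromosome from a balanced permutation—the clone-group
design of a deliberately constructed validation panel—which the validation
cohorts use so that IBD confirmation counts (which grow quadratically with
group size) stay comfortably above the linear mismatch burden a single
residual-heterozygous taxon contributes; random assignment occasionally
produces a small founder group whose sites then fail confirmation in a
correlated block, a desk-scale artifact the real panel's thousands of IBD
contrasts never exhibit.

What the simulator does *not* emulate: read-level artifacts (mapping
quality structure, base-quality miscalibration, strand bias), realistic
recombination maps or demography, linked selection, copy-number variation
beyond the two-locus paralog collapse, and reference bias. Passing the
validation suite therefore demonstrates that the statistical machinery
behaves as specified under the population structure it assumes, not that
real-data error modes are fully covered.

# Validation problem sizes and numerical choices

The validation suite exercises: the codec exhaustively to 12000; the
Monte-Carlo segregation P against full enumeration on all 2×2 tables with
total $\le 12$ plus random 2×3 tables ($B = 10^4$; a correct Monte-Carlo
estimator lands within 3 standard errors about 99.7% of the time, so the
suite requires 99% within 3 SE and everything within 5 SE); the
chi-square lower-bound property on 1000 random 2×10 tables; IBD recovery
on a noiseless 20-taxon clone cohort with 2 windows and filter behaviour
on a noisy 80-taxon cohort (×4 coverage, 0.5% error); the LD filter on a
40-taxon cohort with ~5000 anchors and 150 translocated markers;
imputation on a 50-taxon × 5000-site cohort with 30% of genotypes masked;
and both pipeline routes end-to-end on a 20-taxon × 200-site cohort,
byte-identical across reruns. These sizes keep the full suite within a
few minutes on one core while leaving each check statistically
meaningful.

Numerical conventions: tie handling in the caller and the vote is
documented above; simulated-vs-observed statistic comparisons use the
`fisher.test` relative-tolerance convention; degenerate segregation
tables (a zero row, or fewer than two non-empty columns) give $P = 1$;
`EF` is missing in its degenerate cases; genotypes carrying alleles
pruned by a filter are set to missing rather than silently re-coded.

# Known limitations

* The LD filter's $10^{-6}$ best-hit cutoff is effectively unreachable
  for sites with fewer than ~6 minor carriers, so on small panels
  low-MAF true sites are rejected (on large panels they are mostly
  "unassessed" and pass); this mirrors the published design, which
  motivated the permissive route in the first place.
* The per-base error model is uniform; systematic errors that correlate
  across taxa at a site will defeat the segregation test.
* Heterozygote imputation accuracy is intrinsically poor (the published
  self-imputation accuracy for heterozygotes is ~11%); hapforge
  reproduces this behaviour rather than fixing it, since in an inbred
  panel most heterozygous calls are artifacts to be flagged (`DUP`), not
  rescued.
* Indel alleles are symbolic; no local realignment is attempted, and
  `NI5` marks the affected neighbourhoods as tentative.
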