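---
title: "Methods: windowed selection scans, DCMS compositing, and runs of homozygosity"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans, DCMS compositing, and runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why the
defaults are what they are.  It covers the statistical model behind
each stage, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## The problem

Given diploid genotypes for a handful of populations (a few dozen
animals re-sequenced per breed is the motivating design), we want to
locate genomic regions whose variation patterns are better explained by
recent positive selection than by drift: locally elevated
allele-frequency differentiation between populations, a site-frequency
spectrum (SFS) skewed toward high-frequency derived alleles, and
unusually long haplotypes around the selected site.  No single statistic
captures all three signals, so four are computed and composited:

* **within-population**: the SweepFinder-style composite likelihood
  ratio (CLR) against the genome-wide background SFS, and the
  integrated haplotype score (iHS);
* **cross-population**: the heterozygosity-partition fixation index
  F_ST for every population pair, and XP-EHH for every pair.

Each statistic is averaged in non-overlapping 50-kb windows
(haplotype statistics as absolute values, since both signs are
sweep-like), converted to an upper-tail empirical p-value under a
fitted skew-normal, and combined into the de-correlated composite of
multiple signals (DCMS).  The top 1% of windows by DCMS are the called
sweep regions.  In parallel, runs of homozygosity (ROH) give per-animal
inbreeding coefficients F_ROH and population ROH hotspots, which are
intersected with the sweep regions.

## Statistics

### F_ST

Per site, with `p_i` the (derived/alternate) allele frequency in
population i from non-missing calls, `c_i = n_i / sum_j n_j` the
population's share of non-missing alleles at that site, and
`pbar = sum c_i p_i`:

F_ST = (pbar(1 - pbar) - sum_i c_i p_i (1 - p_i)) / (pbar(1 - pbar)).

Concavity of x(1 - x) makes the numerator non-negative, so the value is
always in [0, 1]; sites monomorphic in the pool are undefined and are
excluded from window means.  The weighting term is interpreted as
relative sample contribution (chromosome counts); this is a documented
reading of an ambiguous printed phrase, flagged wherever weights
matter.

### EHH, iHH, iHS, XP-EHH

EHH at offset d from a focal site is the probability that two
haplotypes drawn from a carrier class are identical over the whole
interval from the focal site to d: `sum_h C(c_h, 2) / C(n, 2)`.  The
class starts as a single group at distance 0 (EHH(0) = 1 by
definition) and is refined site by site outward, which makes EHH
non-increasing — asserted on every computed profile.

iHH is the trapezoidal integral of EHH over *genetic* distance, using
the study's map convention 1 Mb ~ 1 cM.  Following selscan's defaults
(the tool the study ran "with default parameters"), integration stops
at the first point where EHH < 0.05 (that trapezoid is excluded),
physical gaps above 20 kb down-weight their trapezoid by 20 kb/gap,
gaps above 200 kb truncate the side, and a side that reaches the
chromosome end with EHH still at or above the cutoff leaves the site
unscored.  iHS raw = ln(iHH_ancestral / iHH_derived) at sites with
minor-allele frequency >= 0.05, standardized within 100 equal-width
derived-allele-frequency bins.  XP-EHH raw = ln(iHH_A / iHH_B) with EHH
over all haplotypes of each population, standardized in a single
genome-wide bin (the behaviour of selscan's `norm` for XP-EHH).  Where
the ancestral allele is unknown the reference allele stands in,
flagged; this is a documented fallback, not a claim about the original
analysis, whose handling of unpolarized sites is ambiguous.

The outward partition-refinement walk over every site is the pipeline's
hot path and is implemented in C++ (as the field's tools do); the R
functions `ehh()` and `ihh()` expose the same computation stepwise and
are tested for exact agreement with the compiled scans and with an
independent string-grouping oracle.

### CLR

The composite likelihood ratio follows the Nielsen 2005 skeleton rather
than byte-matching SweepFinder2.  The background SFS is the normalized
histogram of derived-allele counts over all polarized segregating
sites.  For a test position x and sweep intensity alpha, a site at
recombination distance d (Morgans) escapes the sweep with probability
`pe = 1 - exp(-alpha d)`; its likelihood is
`pe P_bg(j) + (1 - pe) P_forced(j)`, where the forced spectrum places
the background mass on derived counts n-1 (the swept lineage carried
the derived allele, probability `sum_k P_bg(k) k/n`) and 1 (it carried
the ancestral allele).  CLR(x) = 2(max_alpha log CL - log CL_bg),
floored at zero: the large-alpha end of the grid is the null, so the
statistic is a genuine likelihood-ratio and non-negative everywhere.

Numerical choices: test positions are 50-kb window centres; the alpha
grid is 40 log-spaced values spanning sweep footprints of roughly 1 kb
to 10 Mb; only sites within 1 Mb of a test position enter its composite
likelihood (farther sites have pe ~ 1 and cancel from the ratio; the
radius was fixed a priori as about five times the largest injected
core).

### Skew-normal empirical p-values

Each window column is fitted with a three-parameter skew-normal
(location xi, scale omega, shape alpha) by maximum likelihood over
(xi, log omega, alpha), initialized by the method of moments with the
sample skewness clamped inside the attainable range; if the optimizer
fails, the moment estimates are used and flagged.  The CDF uses Owen's
T function evaluated by 64-node Gauss-Legendre quadrature (with the
standard |a| > 1 reduction), cross-checked in the tests against
numerical integration of the density.  P-values are upper-tail for all
four statistic families — large CLR, |iHS|, F_ST and |XP-EHH| are all
sweep-like — and are floored at the smallest positive double.

A caution that shapes the tests: near alpha = 0 the shape parameter
itself is ill-determined (a sample skewness of +/- sqrt(6/n)
back-transforms through a cube root), so the nested-normal limit is
asserted on the skewness and CDF scales, not on alpha.  Recovery of a
genuinely skewed truth (0, 1, 5) at n = 5000 is within 10% (0.1
absolute for the location, whose relative error against 0 is
undefined).

### DCMS

With p_si the p-value of statistic s in window i and r the Pearson
correlation matrix of the -log10 p columns (pairwise complete),

weight_s = 1 / sum_t |r_st|  (diagonal included),
DCMS_i = sum_s weight_s (-log10 p_si).

Perfectly correlated duplicate columns split their weight (0.5 each);
independent columns contribute fully — both are asserted analytically
in the tests.  Windows missing some columns are scored from the
available ones with the weight total renormalized and flagged.  How the
original analysis stacked its columns is unstated; here the within-run
score stacks {CLR, |iHS|} for every population and the cross-run score
stacks {F_ST, |XP-EHH|} for every pair, because "combined separately in
a single score" implies one genome-wide score per class and DCMS's
weights are designed to absorb the induced correlation.  The top
`floor(0.01 n)` scored windows are selected (ties at the cut broken by
genomic order, with a warning), and bookended selected windows merge
into regions.

### Runs of homozygosity

"Non-overlapping sliding windows of 50 SNPs" is self-contradictory as
printed; since the study ran PLINK v1.90, the PLINK scanning-window
algorithm is implemented: every 50-SNP window with at most 3
heterozygous and 3 missing calls passes; a SNP enters a run when at
least 5% of the windows covering it pass; maximal runs of such SNPs are
kept when they span >= 500 kb and >= 50 SNPs.  PLINK's density and
inter-SNP-gap sub-thresholds are not mentioned in the study and default
to disabled.  The detector is verified segment-for-segment against an
exhaustive enumeration oracle.

F_ROH = S_ROH / L_GEN per animal; L_GEN defaults to the 2511.4-Mb
cattle autosome length and is overridden by the simulated genome length
on synthetic data.  Group means are compared by one-way ANOVA with
Tukey's HSD and a compact letter display.  Hotspots are maximal
intervals covered by ROH in strictly more than 50% of a population's
samples, computed from the coverage profile.

### PCA and AMOVA

PCA mean-imputes missing calls per site, drops monomorphic sites,
centres, scales by sqrt(p(1-p)) (both the LD-pruned input and the
scaling are switchable; defaults on, since the pruning rule is part of
the study's protocol), and eigendecomposes via SVD.  AMOVA partitions
pairwise squared Euclidean distances over raw 0/1/2 genotypes (the
default behaviour of `dist` on a genotype table; pairs with missing
calls use shared sites, rescaled) into among- and within-population
components, giving Phi_ST; significance is the add-one permutation
estimate over random relabelings with group sizes fixed, which can
never be zero.  Sums of squares are cross-checked against
vegan::adonis2 in the tests.

### Hard filters and LD pruning

The hard-filter thresholds are empirical quantiles of the data being
filtered (FS: upper 5%; the three rank sums and DP: 2.5% per tail),
with MQ using a fixed floor of 30, because the study's printed cut-offs
(14.44 and so on) are its own data's quantiles.  All comparisons are
strict — a site exactly at a threshold is kept, and a constant column
removes nothing — and the realized thresholds are reported, making the
filter idempotent when thresholds are frozen.  Quantiles are computed
after the biallelic/indel filter (the ordering is unstated in the
source protocol; this choice is logged).  Clustered SNPs (> 5 in any
20-bp span) are removed wholesale, verified against a brute-force
all-windows oracle.  LD pruning removes, greedily within 50-SNP windows
advanced by 5, the later-positioned SNP of any pair with genotype
r-squared > 0.1.

## The synthetic-data generator

The generator emulates the study design — a few populations of about a
dozen diploids, divergence of order F_ST 0.05, ~1 SNP per kb on a
1 Mb ~ 1 cM map — with three components:

* **Neutral baseline**: per-site ancestral frequencies uniform on
  (0.05, 0.95), population frequencies Balding-Nichols
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, alleles sampled independently per
  site.  The Hudson-style mean F_ST of the output matches F (tested at
  F = 0.001 and 0.2).
* **Hard sweeps**: at the nearest segregating site to the requested
  position, the derived-allele frequency is lifted to its target by
  converting random non-carriers, and a randomly chosen core haplotype
  is copied over every carrier across geometric (memoryless,
  recombination-like) extents with mean 200 kb per side.  This is
  deliberately phenomenological: it produces exactly the three signal
  classes the statistics respond to (differentiation, SFS skew, long
  shared haplotypes) without a forward or coalescent simulation.
* **Autozygosity**: per individual, non-overlapping exponential-length
  tracts (mean 2 Mb) are placed uniformly until the target genome
  fraction is reached (the last tract trimmed to land exactly), and the
  second haplotype is overwritten by the first inside each tract.

What the generator does **not** emulate: background linkage
disequilibrium (the neutral baseline is linkage equilibrium), mutation
processes, demographic history (bottlenecks, migration, admixture), or
sequencing error beyond the synthetic caller-annotation table.  Passing
tests therefore demonstrate that the statistics respond to the signal
classes they target and that the machinery is numerically correct —
not that power on real data, where neutral LD inflates haplotype
statistics' variance, equals the measured power here.

Study conditions used by the tests and the acceptance script (chosen
once, as the package's own design): the sweep-power design is two
populations of 24 diploids on one 10-Mb chromosome, one sweep to
frequency 0.95 with a 200-kb core placed at a 50-kb window *centre* (a
boundary placement splits the signal across two windows that then
compete for the floor(0.01 x 200) = 2 selection slots — the
window-level power question presumes the sweep has a window), 20
seeded replicates.  F_ROH recovery uses a 5 x 20-Mb genome.  The
null-calibration scans use ~12k sites so the standardized-iHS tail has
~10^4 observations.

## Known limitations

* The CLR neighbourhood radius (1 Mb) truncates a negligible but
  nonzero part of the composite likelihood for very weak (wide) sweep
  intensities.
* XP-EHH truncates each population's integral at its own EHH cutoff
  rather than at a pooled criterion; label-swap antisymmetry holds
  exactly either way.
* The ROH detector implements PLINK's scanning logic but not its
  density/gap sub-thresholds (disabled here, as unstated in the source
  protocol).
* With phased input the reader builds haplotypes only when every
  genotype is phased and non-missing; post-imputation VCFs satisfy
  this, raw ones may not.
* DCMS weights depend on the observed correlation matrix, so adding or
  removing a population changes all windows' scores; scores are
  comparable within a run, not across runs.
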