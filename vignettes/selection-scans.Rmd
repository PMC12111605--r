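---
title: "Selection-signature scans: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the parameter choices that matter, what the bundled
simulator does and does not emulate, and the known limitations. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Haplotype-homozygosity statistics

All three scan statistics are built from one primitive: partition a set
of haplotypes by their identity over the interval from a focal SNP *s*
out to a flanking SNP *t*, and measure the probability that two
haplotypes drawn at random fall in the same group,

$$EHH_{s,t} = \frac{\sum_k n_k (n_k-1)}{n (n-1)}.$$

For **EHH** the set is the carriers of one core allele (the curve starts
at 1); for **EHHS** it is all haplotypes at the site, and by default the
focal SNP's own alleles take part in the haplotype, so the curve starts
at the focal-site homozygosity (a switch, `include_focal`, reverts to a
single starting group — the definition is ambiguous in parts of the
literature, so both are available). Curves are non-increasing outward by
construction: refinement can only split groups.

The **integral** under each decay curve (iHH per allele, iES per
population) is a trapezoid sum in bp, anchored at the focal value. Three
numerical choices matter:

* **Stop threshold** (`stop_threshold`, default 0.05): the outward scan
  stops when the curve drops below it, and the final trapezoid is
  interpolated linearly down to the threshold crossing rather than to
  the sub-threshold marker, so the integral does not depend on where the
  next marker happens to sit.
* **Maximum extension** (`max_extension`, default 1 Mb per side): bounds
  the integration window, as in common practice on dense real data.
* **Gap cap** (`gap_cap_bp`, default 20 kb): an inter-marker interval
  contributes at most this much width, so sparse regions cannot
  dominate an integral. Set to `Inf` to disable (the exact-equivalence
  tests do, so the oracle stays a pure transcription of the formulas).

Focal SNPs whose scan runs off the chromosome end while still above the
threshold keep their truncated integral and are flagged `edge = TRUE`;
no correction is applied, and downstream consumers can drop flagged
SNPs when integrals must be comparable across loci.

**iHS** is `ln(iHH_A) - ln(iHH_D)` (computed as a difference of logs so
that exchanging the ancestral/derived labels flips the sign exactly),
standardized to mean 0 / sd 1 (population sd, denominator *n*) within
derived-allele-frequency bins of width 0.025. Bins with fewer than 10
scored SNPs are merged with the adjacent bin holding fewer values (ties
to the left) until every stratum is populated; the bin width, floor and
the standardization are all arguments. **XP-EHH** is
`ln(iES_1) - ln(iES_2)` standardized globally. **Rsb** first centres
each population's log iES on its own median (configurable to the mean),
which absorbs any population-wide multiplicative difference in
haplotype homozygosity — an invariance the tests assert directly.
Scores map to two-sided Gaussian tail probabilities
$-\log_{10}(1 - 2|\Phi(X) - 0.5|)$, computed in log space so large
scores do not underflow, clamped at 320.

Ancestral-allele polarity is a user decision (`ref`, `aa` INFO tag, or
`major`), default `ref`: the source data for such scans rarely states
how alleles were polarized, the choice only flips iHS signs per SNP,
and an explicit default is reproducible. Sites with any unphased or
missing genotype are dropped on input (with counts), because the
group-refinement definition assumes complete phased haplotypes.

## ROH, F_ROH and islands

ROH calling follows the PLINK sliding-window design: 50-SNP windows are
homozygous if they contain at most 1 heterozygous and 5 missing calls
(the two tolerances are the conventional defaults and are exposed as
arguments); a SNP is in a run when at least 5% of the windows covering
it are homozygous; runs split at inter-SNP gaps over 1000 kb and are
kept when they span at least 300 kb, 50 SNPs, and one SNP per 50 kb.
Segments begin and end at the outermost qualifying SNPs. The
"proportion of homozygous overlapping windows" parameter is read as the
per-SNP hit-proportion threshold, the same quantity PLINK's
window-threshold flag controls. Length classes use half-open intervals
(0–2], (2–4], (4–8], (8–16], >16 Mb, so an exactly-2 Mb run is "0–2 Mb".

`F_ROH` divides summed ROH length by the autosome length; by default
the denominator is the span actually covered by the variant table
(first to last SNP per chromosome, summed), since a scan knows nothing
about sequence beyond its markers, and a user-supplied assembly length
is accepted. Island tracks report the percentage of individuals whose
ROH covers each SNP; the significance threshold is the empirical
`1 - top_fraction` quantile (default top 0.1%), with ties at the
threshold flagged.

## LD, Ne, GRM and PCA

Pairwise r² is the squared Pearson correlation of dosage vectors
(missing values mean-imputed per site, monomorphic sites skipped),
with bp converted to Morgan at 100 Mb/Morgan (configurable).
`ne_trajectory()` applies $N_e = \frac{1}{4c}(\frac{1}{r^2}-1)$ at the
bin-midpoint distance, with time depth $t = 1/(2c)$ — the convention of
the LD-based Ne literature. The formula is applied literally by
default; an `adjust_n` argument subtracts the $1/n$ finite-sample
inflation first, for users who want the corrected variant. The GRM is
VanRaden's first form, $ZZ'/\sum 2p_j(1-p_j)$, and PCA scores are
eigenvectors scaled by the root eigenvalue with percent variance from
the trace.

## QC

Three per-site filters, applied as one pass with removal being the
union and each removed site counted once under the precedence
call rate → MAF → HWE: call rate ≥ 0.95, MAF ≥ 0.01 (computed on
non-missing alleles), exact Hardy–Weinberg p ≥ 1e-5. The HWE test is
the exact conditional test (two-sided by probability-mass ordering) —
the default of the standard genotype-QC tools — implemented directly
and verified against a full-enumeration oracle for every table with
n ≤ 25. With a population factor the HWE test runs within each
population and a site fails if it fails in any (pooling populations
with different allele frequencies manufactures Wahlund-driven
rejections); a `joint` switch pools anyway.

## Significance and regions

iHS uses a fixed threshold, strictly `-log10(p) > 4`. XP-EHH and Rsb
control FDR at 0.05 by Benjamini–Hochberg over all scored SNPs
genome-wide (the test universe is a choice; genome-wide is the most
conservative of the plausible readings). ROH islands take the top 0.1%
of coverage. "A 1 Mb window around a significant SNP" is read as
±500 kb (total 1 Mb); a `mode = "flank"` option gives ±1 Mb instead.
Windows are unioned per chromosome; each merged region records the SNP
with the largest |score| as its peak. Gene overlap is any intersection
in half-open coordinates (BED taken as 0-based half-open, GFF3
converted from 1-based closed), so a gene starting exactly at a
region's end is excluded.

## The simulator: what it emulates, and what it does not

`simulate_populations()` is a forward diploid Wright–Fisher model on
one chromosome: standing variation only (sites initialized at founder
frequencies drawn from U(0.05, 0.95); no new mutation), Poisson
crossovers at 1e-8 Morgan/bp, additive viability selection (1, 1+s,
1+2s) at one site, an optional population split copying the ancestral
pool, and per-generation frequency trajectories recorded as truth.
Conditioning (`not_lost`, `fixed`, `reach_target`) reruns from the same
seeded stream, aborting an attempt the moment the allele is lost, and
logs the attempt count. The sweep allele can be present from the
founding (a sweep from standing variation) or injected when selection
starts (a de novo hard sweep).

Default scale: two populations of 100 diploids, 2000 SNPs on 20 Mb
(10 kb spacing), 50 shared burn-in generations before the split. These
sizes keep a full scan-plus-simulation cycle in seconds while leaving
enough markers per ROH window and per EHH decay curve; the problem
sizes used by the validation suite (20 replicates per scenario,
300-generation LD equilibration for Ne, 150 post-split generations for
the PCA check) are stated in the tests and the acceptance script.

What the simulator deliberately does not emulate: new mutation (so
diversity only decays, and a swept region never recovers), gene
conversion, variable recombination maps, genotyping error and
missingness patterns, and real-data marker ascertainment. Passing
validation on this generator therefore demonstrates correctness of the
statistics and sensible behaviour under drift, linkage and selection —
not calibration of real-data error models.

Two desk-scale consequences deserve emphasis:

* **EHHS decay scale.** At N = 100, neutral EHHS falls below 0.05 only
  at roughly 0.05 Morgan (~5 Mb here). The 1 Mb default
  `max_extension`, sensible for dense real data from much larger
  populations, saturates iES in both populations and flattens the
  XP-EHH/Rsb contrast; the validation scans therefore use
  `max_extension = 5e6` for the between-population statistics.
* **Peak localization of completed sweeps is coarse.** The footprint of
  a completed sweep spans 1/(r·T) of physical distance (T the sweep's
  sojourn time) — megabases for any selection strength that still
  out-runs drift at N = 100 — and the integral of EHHS from any focal
  SNP inside the swept plateau is nearly position-invariant, so the
  single |score|-maximal SNP lands anywhere within the footprint, its
  exact position set by the other population's Mb-scale iES
  fluctuations. Detection of the swept region is robust; nominating the
  sweep site to sub-footprint precision from the peak SNP alone is not,
  at this scale. Real analyses face the same geometry, which is why
  candidate regions, not peak SNPs, are the reporting unit of
  `merge_regions()`.

## Validation design

Correctness rests on independent oracles rather than reference outputs:
a paste-based direct-enumeration implementation of the EHH/EHHS
formulas with its own trapezoid code (agreement to 1e-12 on hundreds of
random panels), a naive loop implementation of the ROH window rules, a
factorial-based enumeration of the exact HWE distribution, and a
textbook step-up loop for BH. Stochastic properties (sweep-detection
power, false-positive behaviour on neutral data, Ne recovery within a
factor of two, PC1 separation of diverged populations, heterozygosity
decay at 1/(2N) per generation, F_ST growth after a split, F_ROH
rising with inbreeding) run on freshly simulated replicates under fixed
seeds. Oracle-equivalence tests compare the raw statistics and use a
single standardization stratum, because reproducing the frequency-bin
merge tie-breaking inside an "independent" oracle would merely
duplicate the implementation; the binned standardization is covered by
its own unit tests and by the within-bin mean-0/sd-1 invariant.

## Known limitations

* Physical distance only (bp, with a global Mb-per-Morgan constant); no
  genetic-map integration.
* Biallelic SNPs only; multi-allelic records are dropped on input.
* EHH statistics require complete phased haplotypes; there is no
  unphased approximation.
* The exact HWE test enumerates the full conditional support per site;
  it is exact, not an approximation, but for very large samples a
  mid-p or chi-square variant (not provided) can be preferable.
* Completed-sweep peak localization at desk scale is coarse, as
  discussed above.
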