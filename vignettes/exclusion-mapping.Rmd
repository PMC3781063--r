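---
title: "Exclusion mapping of candidate variants in an IBD interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exclusion mapping of candidate variants in an IBD interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcoamap)
```

## The problem

Equine Multiple Congenital Ocular Anomalies (MCOA) is an eye-defect syndrome
inherited as an incompletely dominant trait: homozygotes for the disease
allele show the full MCOA phenotype, heterozygotes the milder "Cyst"
phenotype, and most affected horses also carry the Silver coat-colour
dilution, which maps to *PMEL*. Linkage work had confined the locus to a
~208 kb identity-by-descent (IBD) interval on chromosome 6
(chr6:73,640,494–73,848,154). When such an interval is deep-sequenced in a
small case/intermediate/control panel, the mapping problem becomes an
*exclusion* problem: enumerate every variant in the interval and discard
each one whose genotypes contradict the inheritance model, until only the
candidates compatible with causality remain.

`mcoamap` implements that workflow as a reusable, fully testable pipeline:

1. **Site filtering** — PHRED site quality strictly above 20 and total
   depth inside a 50–100,000× band (a varfilter-style band appropriate for
   very deep amplicon coverage).
2. **Annotation** — constraint-element membership (a BED track emulating a
   29-mammal constrained-element set) and codon-level consequence calling
   against a minimal gene model.
3. **Reference-only classification** — sites where every panel sample is
   homozygous for the non-reference allele differ from the reference
   genome, not between cases and controls, and are set aside.
4. **Concordance filtering** — the core exclusion step (below).
5. **IBD narrowing** — flanking haplotype-discordance clusters trim the
   interval.
6. **Cohort LD validation** — EM haplotype-frequency estimation and
   D/D′/r² for a two-locus genotyped cohort.
7. **Relative-coverage scan** — windowed case-vs-control read-depth
   comparison for deletions, duplications and larger insertions.

A seeded generator plants ground truth for every stage, so the pipeline is
exercised end to end without any external data.

## The concordance filter

For an incompletely dominant trait, the genotype–phenotype relationship is
exact: every MCOA case must be homozygous for the disease allele, every
Cyst (intermediate) sample heterozygous, and every control homozygous for
the other allele. A variant is a candidate iff one of the two allele
orientations satisfies all three constraints simultaneously — orientation
is free because either the reference or the alternate allele may travel
with the disease haplotype. No statistics are involved; this is exact
pattern matching, which is why it is so powerful at this panel size.

Under Hardy–Weinberg genotypes independent across samples, the probability
that a neutral site survives is

$$P_\text{pass}(p) = (2pq)^{n_I}\left(p^{2n_A}q^{2n_U} + q^{2n_A}p^{2n_U}\right),$$

with $n_A$, $n_I$, $n_U$ the case/intermediate/control counts. For the
default 5/1/4 panel at $p = 0.5$ this is $2^{-18} \approx 3.8\times10^{-6}$
— a few hundred background variants essentially never survive by chance.
`expected_background_pass_rate()` exposes the closed form; property tests
compare it against brute-force enumeration over all $3^{10}$ genotype
configurations and against the empirical rate at $10^5$ simulated sites.

Missing genotypes fail the variant by default (`fail_variant`): a candidate
must be positively confirmed in every sample. The `ignore_sample` policy
drops missing genotypes instead; it is appropriate when coverage is uneven,
at the cost of weaker confirmation.

## IBD narrowing and the boundary-marker definition

Sites that contradict a *shared ancestral haplotype* at the ends of the
interval bound the region that can contain the causal variant.
`narrow_interval()` places the new 5′ edge one base past the
largest-coordinate discordant marker that precedes the first concordant
marker (the discordant base itself cannot sit on the disease haplotype, so
it is excluded — a convention chosen to make exclusions well defined to the
base pair); the 3′ edge is symmetric, and a flank without discordant
markers leaves its edge untouched.

Which sites count as *discordant* deserves care. Merely failing the
candidate pattern is not evidence of a haplotype boundary: a neutral
polymorphic site fails the pattern almost surely, yet says nothing about
shared ancestry. `haplotype_boundary_markers()` therefore requires the
class-structured signature that haplotype-comparison panels actually show
at a boundary: controls homozygous for one allele and either (a) the cases
homozygous and unanimous *within breed* but split *between* breeds with the
intermediate heterozygous — the pattern produced when one breed's cases
carry a different flanking haplotype — or (b) all cases homozygous for the
putative disease allele while the obligate-carrier intermediate is
homozygous for the other allele — the pattern produced when the
intermediate's disease chromosome does not extend that far. Interior
contradictions are counted and reported but never move an edge.

The generator plants one such cluster inside each flank-exclusion zone
(defaults 7.2 kb + 7.2 kb, i.e. 14.4 kb in total over the 207,661 bp
interval, leaving a 193,261 bp ≈ 193.3 kb core; the split between flanks is
a package choice, and both sides are reported separately). The innermost
marker of each cluster is pinned to the zone edge so the planted truth is
exact. Because the boundary-marker signature can arise by chance in
independent HWE background genotypes (probability ~2×10⁻⁵ per site at
p = 0.5), the generator redraws the rare background site matching it:
background variation inside an IBD core does not mimic haplotype switches,
and this keeps the planted clusters the unique contradictions.
Chance *candidate* patterns are deliberately **not** redrawn — the
background pass-rate distribution stays untouched, and any such site is
recorded in `truth$expected_candidates`.

## Two-locus LD in the validation cohort

The cohort stage formalizes "the alleles were in complete LD" for a pair of
loci genotyped in a large panel (default 936 individuals: 24 heterozygous
and 4 homozygous carriers at both loci, 908 non-carriers; the het/hom split
among carriers is a free parameter because only the totals are known for
the modelled panel). Haplotype frequencies are estimated from unphased
genotype counts by EM, with the double-heterozygote class split by expected
phase at each iteration. Statistics follow the standard definitions
$D = p_{AB} - p_A p_B$, $D' = |D|/D_\max$ (0 when $D = 0$), and
$r^2 = D^2/(p_Aq_Ap_Bq_B)$.

Numerical choices: convergence when the largest haplotype-frequency change
falls below $10^{-10}$ (cap 1000 iterations), and the EM is run from three
starts — linkage equilibrium plus both phase-boundary corners — keeping the
best likelihood. The equilibrium start alone sits on a symmetry point of
the E-step (the double-heterozygote split is exactly even there) and the
two-locus likelihood can be multimodal, so the multi-start is a cheap
robustness guarantee; tests require the EM likelihood never to fall below
an exhaustive grid search along the feasible $p_{AB}$ ridge. Monomorphic
loci yield a flagged degenerate result (zero statistics, a warning, no
exception) so batch runs do not abort.

## Relative-coverage scan

Each sample's per-base depth is divided by its own mean (making the scan
invariant to library size), cases and controls are averaged per
non-overlapping window, and the statistic is the log2 ratio of the two.
Defaults: 500 bp windows and a $|{\log_2}| \ge 0.58$ (≈1.5-fold) call
threshold — sized to catch a single-copy loss (expected −1) or gain
(expected +0.585) while tolerating depth noise of a few percent. Bases with
zero depth in every sample emulate reference-genome gaps and are masked;
windows more than half masked are skipped. Note that a planted CNV shifts
its own sample mean slightly, so the observed log2 ratio of a single-copy
loss is −1 only up to the CNV's share of the interval; tests account for
this with a 0.05 tolerance.

## What the generator does and does not emulate

`simulate_panel()` reproduces the *structure* of the study inputs: the
ten-horse three-breed panel; 609 SNPs (547 background + 60 reference-only +
the causal pair), 129 indels; a causal SNP pair 760 bp apart with only the
lower-coordinate SNP conserved and coding; and a minus-strand toy *PMEL*
model built so that SNP falls on codon 625 (CGC→TGC on the transcript,
hence Arg625Cys; in plus-strand VCF orientation the planted alleles are
G>A, the transcript-oriented complement of the commonly quoted C>T —
protein-change numbering is model-relative, not genome-authoritative).
Site qualities and depths are drawn inside the default filter band, and
depth defaults to a desk-sized 100× rather than the study's ~11,000× —
nothing downstream depends on absolute depth except the thresholds, which
scale.

It does **not** emulate read-level errors, amplicon tiling, LD among
background sites (the concordance filter treats sites independently, so
background LD is irrelevant to its correctness), breed-level population
structure, or genotype-calling uncertainty. Passing tests therefore
demonstrate the correctness of the *decision logic* on structurally
faithful inputs, not robustness to upstream calling artefacts.

## Degenerate inputs and tie-breaks

* `apply_site_filters()`: missing quality or depth fails the corresponding
  criterion; "above 20" is strict by default (`quality_strict = FALSE`
  switches to ≥ for callers with inclusive conventions); indels may carry
  their own, typically laxer, quality threshold.
* `narrow_interval()`: discordant markers with no concordant marker at all
  raise "no IBD core remains"; a marker exactly at the region edge excludes
  exactly one base.
* `concordance_filter()` audit: for an excluded variant the reported
  violations are those of the closer orientation (fewest violating
  samples).
* Consequence calls are SNP-only; coding indels are tagged
  `coding_indel_unclassified` and never silently translated.

## Problem sizes used by the test suite

The suite runs the full default-scale interval (207,661 bp, 738 variant
records) once through the pipeline and uses a 40 kb / 82-variant
configuration for seed sweeps: 25 seeds for planted-truth recovery
(candidates, narrowed interval, CNV calls), 100,000 sites for the
pass-rate/closed-form comparison, and 30–45 random tables for the EM/grid
cross-checks. Everything is seeded and deterministic.

## Limitations

* The narrowing logic consumes per-site genotype patterns, not phased
  haplotypes; a true haplotype-sharing analysis could narrow further.
* The boundary-marker signature assumes breed labels are meaningful proxies
  for flanking-haplotype groups, as they were in the modelled panel.
* The coverage scan is a windowed mean-ratio method without segmentation or
  GC correction; it is designed for large, clean events in very deep data.
* Consequence calling handles one transcript, one substitution at a time;
  splice-site and regulatory effects are out of scope.
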