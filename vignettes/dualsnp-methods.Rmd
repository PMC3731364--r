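---
title: "Dual-evidence exome SNP discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-evidence exome SNP discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsnp)
```

`dualsnp` discovers and validates genotypable SNPs in the exome of a species
without a reference genome. The reference is a *de novo* transcriptome; two
independent read alignments to it — transcriptome reads (T2T, long reads at
modest depth) and genome reads (G2T, short reads at high depth) — provide
complementary evidence, and only sites supported by both are reported. This
vignette explains each model, the tunable parameters, and what the simulated
studies used in the tests do and do not demonstrate.

## Reference filtering

Two failure modes of a *de novo* transcriptome corrupt SNP calling, and each
has a detectable signature in the genome-read alignment:

* **Collapsed homologs and low-complexity contigs** attract far more genome
  reads than their length warrants. The filter flags contigs whose
  length-normalized primary-read count exceeds `median + k·MAD` (default
  `k = 5`). The MAD is robust and scale-free, but collapses to zero when
  most contigs have near-identical counts; the filter then falls back to a
  fold rule (above `5×` the median). Both constants are configurable; the
  default `k = 5` is deliberately permissive, since false removal discards
  every SNP on the contig.
* **Duplicated genome regions** reveal themselves through *multimap reads*:
  reads with a secondary alignment record (FLAG 0x100) under a
  report-two-alignments policy. Any contig touched by at least one multimap
  read — including a read multimapping within a single contig — is removed.
  One read is enough by design: with ~78× coverage, a genuine duplication
  produces hundreds of such reads, so the single-read rule costs little and
  buys a recall of 1.0 on simulated paralog pairs (the truth alignments
  guarantee the secondary record whenever a paralog exists).

The excess-depth rule runs first and the multimap rule on the remainder, so
the report's three sets partition the input. An `annotate_only` flag keeps
multimap contigs in the retained set for users who prefer annotation to
removal; removed contigs always stay in the similarity-screen database,
because an assay flank resembling *any* transcribed sequence — retained or
not — is a genotyping liability.

## Intron–exon boundary prediction

A genome read that crosses an exon junction cannot align contiguously to the
spliced contig: a local aligner reports the exonic portion and soft-clips
the rest. At a true boundary, many reads therefore *terminate their
alignment at the same internal position with sequence left over*. These are
the change points. Two asymmetries matter:

* Only **soft-clipped termini** count as support. A read whose alignment
  ends because the read itself ends is a natural end; natural ends occur at
  every position at a rate set by coverage and read length and carry no
  boundary information.
* Termini at the very ends of a contig are structural (the reference stops,
  so the alignment must), and are excluded both from candidate positions
  (change points are strictly internal) and from the background rate.

The test statistic is a one-sided binomial tail: with `s` clipped termini
among `d` reads overlapping the position and a background terminus rate
`p0`, the p-value is `P(X ≥ s)` for `X ~ Binomial(d, p0)`. `p0` is estimated
dataset-wide as clipped internal termini per aligned base, floored at 1e-6
so that clip-free data does not degenerate. This is an intentionally simple
null — termini are not strictly independent across overlapping reads — but
at the default `α = 1e-4` with a minimum support of 3 reads the procedure
recovers essentially all simulated boundaries at 80× with no false
positives, and an intron-free simulation yields a floored `p0` and zero
predictions.

Significant start-side and end-side points within 3 bp collapse into one
breakpoint at the maximum-support position: microhomology at a junction
lets the aligner shift a clip by a base or two, and the two sides of the
same intron legitimately produce support at the same coordinate.
Breakpoints partition the contig into putative exons; assay flanks never
cross them.

Parameters: `alpha` (1e-4), `min_support` (3 reads), `collapse_window`
(3 bp). All were fixed on simulated data before the acceptance suite was
written and are exposed on `detect_iebs()` and the CLI.

## The dual-evidence SNP filter cascade

Per-site evidence is a tally of **high-quality bases** (Phred strictly
greater than 20) from primary alignments after duplicate removal. A column
is a candidate only if it is cleanly biallelic: the observed HQ bases are
exactly the reference base plus one alternate, and no read carries an
insertion or deletion across it. Columns with three observed alleles are
dropped entirely rather than reduced to their top two — at an error rate of
1e-3 this occasionally sacrifices a true site that picked up one stray
error base, but the package's stance, like the pipeline it implements, is
that a complex column is not a trustworthy assay target.

The cascade, per side:

| side | min alt HQ count | min HQ depth | depth waived at count | max depth |
|------|-----------------:|-------------:|----------------------:|----------:|
| T2T  | 2 | 8  | ≥ 3 | 200 |
| G2T  | 2 | 20 | ≥ 3 | 200 |

The waiver reflects that three independent HQ observations of the same
alternate base are already unlikely under any realistic error model, while
two observations need depth to rule out coincidence. The 200× cap applies
to both sides: a site that deep in either stream is more plausibly a
collapsed duplication (PSV/MSV) than a deeply covered locus. The final set
is the intersection on (contig, position, unordered allele pair);
same-position sites with conflicting alleles are excluded and reported.

Duplicate removal keys on (contig, **unclipped** start, orientation),
keeping the highest-total-quality read per key. The unclipped start — the
alignment start minus any leading soft clip — identifies the template's
origin; keying on the clipped start would merge every read that enters an
exon from the same intron, which are distinct molecules, not PCR
duplicates.

## Assay flank construction and the similarity screen

A genotyping assay needs clean sequence around the target. The flank is the
putative-exon segment containing the SNP (so it never spans a predicted
IEB and is truncated at contig ends), with *every* other variant position —
including sites called by only one evidence stream — masked as `N`.
Rejection rules, applied in order: fewer than 30 usable bases on either
side (`short_flank`); any `N`, masked variant or ambiguity within ±5 bases
of the target (`nonconserved_core`); similarity to another contig
(`similarity_hit`). An independent validator in the test suite re-checks
every accepted candidate against these invariants from scratch.

The built-in similarity screen finds exact 11-mer seed matches between the
flank and every other contig (removed contigs included), extends them
without gaps under an X-drop of 20 with +1/−2 scoring, and converts the
best score to an E-value with the ungapped Karlin–Altschul approximation —
λ solved at run time from the score system under uniform base composition,
K fixed at 0.35. The default threshold of 1e-25 corresponds to roughly a
perfect 50–55 bp match at these database sizes; a perfect 100 bp match
scores around 1e-50. Users with a real search engine can supply tabular
hits and bypass the built-in screen entirely; the threshold semantics are
identical.

SNP categories for panel assembly come from pluggable protein-level hit
intervals per contig: no hits → `no_homology`; contig carrying both coding
and non-coding assignments → `tSNP` (the ambiguous class takes precedence
regardless of which hit covers the SNP — the conservative reading, flagged
here as a design choice); otherwise `cSNP` if a coding interval covers the
SNP, else `ncSNP`. The panel combines every accepted cSNP plus a seeded
random draw of tSNPs (up to half the panel by default) with the
highest-Fst remaining candidates.

Preliminary per-marker Fst is the Weir–Cockerham (1984) variance-components
estimator θ = a/(a+b+c) for biallelic loci, computed from per-individual
genotypes derived from each individual's G2T allele depths (homozygous at
≥ 90% of one allele with ≥ 4 HQ reads, heterozygous otherwise at ≥ 4,
missing below). At ~8 reads per individual these calls are imperfect —
hets are missed at depth 4–6 often enough to bias θ slightly upward — which
is acceptable for *ranking* candidates and is why the estimator is labelled
preliminary.

## Post-genotyping validation

Marker classes are assigned with a fixed precedence: `no_signal` (nothing
amplified) → `disperse` (under 80% of individuals assigned) → `psv_msv`
(≥ 99% of assigned individuals heterozygous) → `monomorphic` (MAF < 0.01) →
`polymorphic`. PSV/MSV is checked before the MAF rule deliberately: an
all-heterozygote column has MAF 0.5 and would otherwise class as a fine
polymorphic marker, when it is the classic signature of co-amplifying
paralogs. Conversion rate is the non-failed fraction; validation rate the
polymorphic fraction; both over the full assayed panel.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the probability of each admissible heterozygote count is computed
by a stable ratio recurrence from the mode, and the two-sided p-value sums
all configurations no more probable than the observed one. The test suite
verifies it against a direct log-factorial enumeration for every genotype
table up to 60 alleles (agreement within 1e-12 — double precision, as no
arbitrary-precision arithmetic is available) and confirms its conservative
calibration under simulated equilibrium sampling. Per-population p-values
are combined by taking the minimum; the failure threshold (default 0.001)
is applied to that minimum, and no additional multiplicity correction is
imposed by default since the cited threshold is conventionally already the
corrected one.

Linkage disequilibrium is tested genotypically — Fisher's exact test on the
pairwise genotype contingency table, Bonferroni-corrected over pairs —
avoiding haplotype inference entirely. Significant pairs join by transitive
closure; each group keeps one representative, giving the independent-marker
count `polymorphic − HWE failures − (linked − groups)`.

## What the simulator emulates, and what it does not

`sim_config()` defaults encode the study conditions the pipeline targets:
10 diploid individuals in 3 populations; pooled cDNA fragments at 15× per
contig with lengths 250–350 bp; per-individual 100 bp gDNA reads summing to
78× over the gene scaffolds; sequencing error 1e-3; constant Q40 base
qualities; planted biallelic SNPs at population frequencies drawn from
U(0.05, 0.5) with an SD-0.1 per-population perturbation; genotypes drawn
under within-population HWE. Genes carry 150 bp intergenic flanks so gDNA
coverage is flat across terminal exons, and cDNA fragments sample with
molecule-end overhang and exponentially jittered 5′/3′ molecule ends (mean
75 bp): real transcript ends are heterogeneous, and without that
heterogeneity every end-overhanging fragment would share alignment start 0
and be annihilated by position-based duplicate removal — an artifact of
treating the contig as a hard-walled molecule, not a property of real
libraries. Fragments are drawn until the target base yield, so realized
interior coverage matches the configured depth.

Alignments are written from known truth, not from an aligner: a gDNA read
is assigned to the exon it overlaps most (at least 20 bp), with the
remainder soft-clipped, and reads from a duplicated gene carry a secondary
record on the paralog contig. All reads are emitted forward-strand, so
orientation handling in duplicate removal is exercised by hand-built
alignments in the unit tests instead. The simulator does not model
platform-specific error structure (homopolymer indels, quality decay),
strand bias, alignment ambiguity in repeats, or assembly errors other than
the two failure modes the reference filter targets. Consequently, passing
simulated benchmarks demonstrates the *logic* of the pipeline — recovery
of planted structure under the stated depths and error rate — not its
robustness to the full pathology of real data.

Two calibration facts from the seeded benchmarks are worth stating plainly.
First, boundary prediction at 80× is essentially perfect (sensitivity and
precision 1.0 on the standard 20-contig study) because truth-placement
alignments clip exactly at junctions; real aligners add placement noise the
collapse window only partly absorbs. Second, SNP-caller sensitivity at the
default conditions is about 0.70–0.75, not higher, and the limit is
arithmetic, not implementation: with 10 individuals the realized pool
frequency of a SNP planted at 0.25 is Binomial(20, 0.25)/20, and sites
where the alternate allele landed on few haplotypes cannot produce two HQ
alternate bases at 15×. The false-discovery rate is ~0 under the same
conditions, which is the design priority of a dual-evidence intersection.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM/VCF/BED conversion
  happens only at I/O boundaries and is tested explicitly.
* `change_point_pvalue` returns 1 at depth 0; the binomial tail uses the
  stable `pbinom` upper tail and matches brute-force pmf summation to
  1e-12 through depth 50.
* The HWE recurrence normalizes unnormalized weights by their sum;
  probability-ordering ties use a 1 + 1e-12 relative guard so equal-probability
  configurations are included symmetrically.
* θ is reported as `NA` (not 0) when its denominator vanishes — a
  monomorphic marker carries no differentiation information.
* `segment_exons` silently deduplicates repeated breakpoints; duplicate
  marker columns in LD grouping join the same group by construction.
* MAD = 0 in the excess-depth filter triggers the fold rule; an all-zero
  median disables removal entirely rather than dividing by zero.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; identical configurations produce byte-identical files.

## Problem sizes used by the tests

The suites run on deliberately small studies: the shared unit fixture is 6
genes, the standard benchmark 20 contigs (2 boundaries each, 80× gDNA), the
end-to-end study 50 genes with a 40-marker panel genotyped in 90
individuals. The exhaustive oracles cover every HWE table to 60 alleles and
every 2-population genotype table to 4 individuals per population (plus a
seeded sample of 3-population tables). These sizes were chosen as the
smallest that exercise every code path and the planted-truth claims;
scaling the simulation up changes runtimes, not conclusions.

## Known limitations

* The binomial change-point null ignores read-overlap dependence; its
  α-level is honest only in the tail where it is actually used.
* The built-in similarity screen is an ungapped approximation; flanks
  similar through gapped alignment only are passed (supply external hits
  when this matters).
* G2T-derived genotypes at ~8 reads per individual miscall some
  heterozygotes; preliminary Fst rankings inherit that noise.
* The tSNP precedence rule means a SNP inside a coding interval on a
  contig that *also* has a non-coding hit is labelled ambiguous, never
  cSNP.
* Microsatellite "primer design" is approximated by flank purity
  (homopolymer/nanosatellite exclusion), not thermodynamics.
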