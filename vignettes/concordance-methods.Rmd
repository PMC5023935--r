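---
title: "Methods: Sanger/WES variant concordance, coverage QC, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sanger/WES variant concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wesconcord)
```

## The problem

Clinical Sanger sequencing of single genes is the historical gold standard
for diagnostic variant detection in rare genetic disease. Whole-exome
sequencing (WES) examines most protein-coding genes at once, but its coverage
is uneven: capture kits target exons, high-GC regions capture poorly, and
allelic dropout can distort genotype calls. Before relying on WES as a
screening test, a laboratory wants to know how often a variant reported by
Sanger sequencing is recovered by WES in the same patient — overall, by
region (coding vs intronic), and after removing genes the exome assay cannot
see properly.

`wesconcord` mechanizes that comparison. The inputs are a tabulated clinical
*truth table* of Sanger-reported variants (patient, gene, position, alleles,
zygosity), each patient's *unfiltered* WES VCF, per-base depth tracks, gene
models, a reference sequence, and optionally a table of confirmatory
re-sequencing results for the discordant sites. The output is a stratified
concordance table with error rates, plus per-variant verdicts from which
every reported number can be recomputed.

## Allele normalization: the matching engine

Sanger reports and VCFs frequently write the same indel differently
(different anchor position within a homopolymer, redundant padding bases).
Two records are treated as the same variant if and only if they have the same
*normalized* representation: shared suffix trimmed, shared prefix trimmed to
a single anchor base for indels, and indels left-aligned against the
reference by repeated left-shift while an equivalent representation exists.
Normalization is idempotent and collapses every equivalent representation of
an edit to one canonical `(chrom, pos, ref, alt)`. The test suite checks this
against a brute-force enumerator that generates *all* representations of a
fuzzed indel and asserts they normalize identically.

Matching is deliberately strict: a call is pulled in only at the truth
variant's normalized position. A call there with the same alleles is
`concordant` if zygosity also agrees and `discordant_zygosity` otherwise; a
call there with a different alternate allele is `discordant_base`; no call is
`missing`. There is no window search and no haplotype-aware rewriting of
nearby compound representations — normalization is the whole equivalence
relation. Zygosity is derived from the GT field alone (`0/1` het, `1/1` hom,
phased treated as unphased, `1/2` het for each alternate); hemizygous calls
are kept distinct from homozygous ones and therefore compare unequal to a
truth `hom`. The VCF FILTER column is ignored: the comparison is made
against the unfiltered call set on purpose, because filtering is exactly the
kind of pipeline behaviour the comparison is meant to audit.

## Region stratification

Gene models store exons as 0-based half-open intervals in genomic order (all
user-facing positions are 1-based, the VCF convention). A position is
`coding` (exonic, inside the CDS), `utr` (exonic, outside the CDS), intronic,
or outside the transcript. Distances follow the HGVS convention: the first
intronic base on either side of an exon has distance 1, and the reporting
strata bin noncoding positions as *near* (distance ≤ 20 bp, inclusive) or
*deep* (> 20 bp). Positions upstream or downstream of the transcript use the
distance from the transcript edge with the same binning; exonic UTR positions
have distance 0 and fall in the near bin. These conventions are design
choices of this package; the ≤/> boundary placement at 20 is configurable
(`near_max`).

HGVS c. positions (`c.76`, `c.76+9`, `c.77-3`, `c.-30`, `c.*12`) are resolved
by walking exonic positions in transcript orientation, strand-aware. Truth
rows that carry a c. position but no genomic coordinate are resolved against
the gene model at read time; unresolvable rows land in a rejects report, never
silently dropped. Two deliberate extensions: UTR numbering beyond the
transcribed UTR continues genomically past the transcript edge (so a site a
few hundred bases upstream of the first exon has a well-defined c. label),
and a `g.→c.` inverse is provided so the round trip can be tested
exhaustively on fuzzed transcripts of both strands. Full HGVS grammar (dup,
inv, protein level) is out of scope, as is more than one transcript per gene.

## Coverage QC and gene exclusion

The "sequence" of a gene, for coverage purposes, is its *footprint*: the
union of exons each widened by 20 bp flanks (`flank_pad`). This follows what
an exome assay actually targets; computing the rule over a whole genomic
locus would drown exon-level signal in intron size. A gene fails QC in one
patient when less than 75% (`min_fraction`) of footprint bases have depth
strictly greater than 20 (`depth_threshold`); both thresholds read as strict
inequalities. A gene is excluded cohort-wide when it fails in the *median*
carrier patient — an operationalization of "consistently poorly covered";
in the benchmark cohort the per-patient profiles are all-or-none, so the
aggregation rule is not load-bearing there. Variants of excluded genes are
reported only in a separate excluded-genes stratum.

Individual variants with site depth below 10 reads are flagged `low_depth`
(strict `< 10`, configurable). Site depth comes from the call's `DP` when
present, else from the depth track at the normalized position. Exceedance
summaries (fraction of a region set above 10x / 20x) are provided as an
operation; cohort-level coverage of real exomes is a property of external
data and is not asserted anywhere.

## The concordance table and error rates

Each stratum row counts `total`, `concordant`, `discordant_base`,
`discordant_zygosity`, `missing`, `indeterminate`, and reports
`rate = concordant / total` as a percentage. The table is defined by a
summation invariant: `noncoding_total` is the two intronic strata combined,
and `overall` is the sum of all included-gene strata; no row is computed any
other way, so the counts always reconcile. A `discordant_base` record whose
confirmatory re-sequencing shows the reference allele — both platforms wrong
— is displayed as *indeterminate*: it stays in its stratum's total but never
in the concordance numerator, being neither concordant nor discordant in the
usual sense.

Adjudication consumes a confirmatory table keyed by patient and normalized
position. A `missing` record whose confirmatory allele matches the truth
allele resolves `sanger_correct` (a WES false negative); one shown wild-type
resolves `wes_correct` (the original report was a Sanger false positive);
zygosity discordances resolve toward whichever zygosity the confirmatory
call shows. The WES false-negative rate is the number of coding `missing`
records resolved `sanger_correct`, divided by all included coding variants;
the Sanger false-positive rate is the analogous `wes_correct` count over the
same denominator. Both come with a standing caveat, printed in the reports:
these are rates over polymorphisms and variants of unknown significance, not
clinically relevant calls, so they are not false positives/negatives in the
traditional diagnostic sense. With no confirmatory table, every discordance
is `unresolved` and the error rates are reported as absent.

Percentages are rounded half-up to one decimal on the percent scale
(`rate_percent()`), so printed rates are stable and reproducible to the digit.

## The synthetic-study generator

No patient data ships with this package; every test input is generated.
The generator plants outcomes rather than sampling them downstream: each
truth variant's fate (concordant, missing, discordant base, zygosity flip)
is decided first, and the VCFs, depth tracks and confirmatory table are then
*constructed* to be exactly consistent with that fate. Self-consistency —
pipeline output equals the planted manifest record for record — is therefore
an exact assertion, not a statistical one.

Details worth knowing:

* **Geometry.** Each gene sits on its own synthetic chromosome (`chrS1`,
  `chrS2`, ...; names chosen so no coordinate can collide with a real genome
  build), with 4 exons of 300 bp and 400 bp introns by default, CDS bounds
  leaving 100 exonic UTR bases at each end, and strands alternating so both
  orientations are always exercised. Variant positions come from a
  deterministic slot allocator that spaces them widely enough that planted
  homopolymer contexts for indels can never interact.
* **Indels.** Planted indels get a dedicated homopolymer run; the truth table
  deliberately records the right-shifted representation while the VCF records
  the left-aligned one, so every cohort exercises normalization end to end.
* **Toy caller.** Emitted genotypes pass through a site-level caller that
  requires at least 3 reads to call a position and at least a 20% alternate
  read fraction to support a variant (the 20% floor is inclusive). The
  homozygous boundary — alternate fraction ≥ 0.80 — is this package's choice,
  symmetric to the 20% floor. No emitted VCF record violates these rules.
* **Coverage profiles.** Each gene carries a mean depth and a
  `low_cov_fraction`: the fraction of its footprint left at depth 6. A gene
  with more than 25% low fraction fails the 75% rule by construction. High
  `gc_target` genes are generated with depressed mean depth, qualitatively
  modeling GC-linked capture bias; the exact coupling form is a free choice
  and nothing quantitative is asserted about it.
* **Determinism.** A single seed fixes everything; identical seeds give
  byte-identical bundles on disk. The analysis path itself contains no
  randomness at all.

What the generator does **not** emulate: read-level artifacts (mapping
quality, strand bias, duplicates), capture-kit bait geometry, sequencing
error models, multi-transcript genes, structural variants, or the messiness
of clinical report parsing. A green test suite therefore demonstrates that
the *comparison machinery* is correct under controlled inputs — not that any
particular real-world exome assay achieves these concordance figures.

## The benchmark cohort

`build_paper_fixture()` constructs one deterministic cohort — 391 truth
variants in 26 patients across 51 genes — whose planted inventory pins down
every stratum of the output table: 9 genes (seven of them high-GC) fail
coverage QC carrying 131 variants of which 79 are identified (60.3%); the
adequately covered genes contribute 150 coding variants (146 concordant,
97.3%), 52 near-intronic (48 concordant, 92.3%) and 58 deep-intronic (44
concordant, 75.9%, including one indeterminate both-platforms-wrong base and
13 variants absent from WES). Four coding SNVs are missing from WES at
well-covered positions (30–60 reads); confirmatory re-sequencing resolves
three in favour of the original report (WES false-negative rate 3/150 = 2.0%)
and one against it (Sanger false-positive rate 1/150 = 0.7%). The four
zygosity discordances are placed as near-intronic variants, two resolving
each way; three coding and six intronic concordant variants sit under 10
reads. The indel spectrum is small (deletions of 1–5 bp, 1 bp insertions),
split across strata, and written right-shifted in the truth table. One
deep-stratum variant sits 176 bp upstream of its transcript, binned by
distance from the transcript edge like any other noncoding site — the
binning of outside-transcript positions is a documented package choice.
The benchmark also includes one tally reconciliation: the per-gene coding
counts and the stratum totals in the inventory disagreed by one, and the
fixture resolves it by adding one coding variant to a single-variant gene so
the stratum totals are exact; stratum totals are canonical throughout.

## Numerical and testing choices

* Rounding: half-up at one decimal on percentages; chosen so every printed
  rate is an exact function of its counts.
* Degenerate inputs: empty truth tables yield a zero-count table (rates
  absent, not 0/0); empty region sets and empty footprints are structural
  errors; all-N sequences are degenerate for GC content; reference-mismatch
  alleles fail loudly, since they signal a wrong genome build.
* Tie-breaks: an intronic position equidistant from both flanking exons
  anchors to the transcript-upstream exon's `+` side in HGVS output.
* Problem sizes: fuzz tests use transcripts of 2–5 exons and cohorts of a few
  hundred variants; the parameter-recovery property pools 200 seeded
  replicates per planted probability (p ∈ {0.01, 0.05, 0.2}) with independent
  seed streams per condition, and checks that the exact binomial 95% CI of
  the pooled estimate covers p. These sizes are the package's own choice —
  large enough that the CIs are a few tenths of a percentage point wide,
  small enough that the whole suite runs in a few minutes.

## Known limitations

Single transcript per gene; no liftover (one reference build per run); no
multi-sample VCF semantics beyond selecting one sample; no haplotype-aware
matching of compound representations; the confirmatory-table format is this
package's own dialect. The excluded-gene aggregation rule (median carrier)
and the outside-transcript binning are defensible but not the only possible
readings of "consistently poorly covered" and "noncoding"; both are
configurable or isolated in one function each.
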