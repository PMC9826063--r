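---
title: "Anchored phasing of de novo mutations: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored phasing of de novo mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorphase)
```

## The problem

A de novo mutation (DNM) is present in a proband but absent from both
parents. Two questions follow its discovery: on which parental haplotype
did it arise (parent-of-origin), and when (prezygotic, in a gamete, versus
postzygotic, after fertilisation — a mosaic)? Both require *phasing*: a
physical DNA molecule must be observed that carries the DNM position
together with at least one informative SNP (iSNP) — a proband-heterozygous
site whose two alleles are each uniquely attributable to one parent.
Short-read exomes rarely contain such a molecule (most iSNPs lie hundreds
of bases or more from the DNM), which motivates deep amplicon long-read
sequencing of a region around each DNM. Long reads, however, carry a few
percent per-base error, so naive variant calling on an amplicon produces a
large crop of false heterozygous candidates, and naive allele counting is
biased by error reads.

`anchorphase` implements the anchored solution: the DNM itself is already
*validated* (orthogonally confirmed, e.g. by Sanger sequencing), so its
alternate base can be treated as ground truth. Reads covering the DNM are
split into a wild-type group, a mutant group and an "other" group by their
base at that single position. A genuine iSNP must look effectively
homozygous inside the mutant group — it sits on one haplotype — while a
candidate created by sequencing noise is symmetric across the groups. One
iSNP is then selected, a two-locus allele table is built over reads
spanning both positions, known-false allele pairs are removed, and the
polished mutant allele fraction, parent-of-origin and zygosity follow.

## The quantities reported

With the validated alternate base $a$, reference base $r$, the iSNP base
$L$ linked to the mutant haplotype and the other parental base $O$:

* **raw DNM base fraction** — reads showing $a$ at the DNM over all
  DNM-covering reads. Under substitution error $e$ (uniform over the three
  wrong bases) a true 50% heterozygote is observed at
  $0.5(1-e) + 0.5\,e/3$, i.e. about 48.7% at $e = 0.04$ — the
  characteristic downward bias of raw long-read base frequencies.
* **raw mutant allele fraction** — count of the pair $(a, L)$ over all
  spanning reads.
* **polished mutant allele fraction** — $(a,L)$ over the credible pairs
  only: $(a,L)$, $(r,O)$, and $(r,L)$ iff a credible third allelic form is
  present. Removing the error pairs from the denominator restores a
  prezygotic target to ~50%.
* **third allelic form** — the pair $(r, L)$: the wild-type version of the
  mutant haplotype. It can only exist biologically if some cell lineages
  never acquired the mutation, so it is the signature of a postzygotic
  event; any other extra pair is error by construction and is never
  promoted.
* **error metrics** — at the iSNP, the fractions of bases outside
  $\{L, O\}$ (total and largest single); over the table, the fractions of
  pairs outside the credible set (total and largest single). The cohort
  mean of the largest single false base at the chosen iSNP is the
  background-noise summary.

## Pipeline stages and their thresholds

All thresholds live in `phase_control()`; comparisons are exactly as
stated (strict or inclusive).

| stage | rule | default |
|---|---|---|
| variant calling | depth strictly > `min_depth` | 20 |
| | allele fraction inside `af_window`, inclusive | 0.20–0.80 |
| | heterozygosity posterior ≥ `min_conf` | 0.96 |
| exome polishing | exome-covered means proband depth ≥ `wes_min_depth` | 10 |
| trio iSNP discovery | each parent's exome depth ≥ `isnp_min_parent_depth` | 5 |
| parental long-read typing | allele supported at fraction ≥ `parental_support_af`, depth ≥ `parental_min_depth` | 0.20 / 20 |
| linkage vetting | mutant-group majority over the allele pair ≥ `min_group_agreement` | 0.80 |
| phasing | spanning reads ≥ `min_spanning` | 20 |
| zygosity | prezygotic band for polished fraction | 0.40–0.60 |
| third allele | fraction > max(`third_allele_floor`, `third_allele_k` × max false allele) | 0.05 / 2 |
| exome-only control | reads per allele strictly > `wes_allele_min_reads` | 10 |
| read QC | end-trim below quality `qc_quality`; drop reads < `qc_min_len` | 10 / 30 bp |

Targets are grouped into three categories by the distance from the DNM to
the nearest exome-typed iSNP: within `short_read_span` (300 bp) paired
short reads may phase the target by themselves (category 1, used here as a
cross-validation control); within `long_window` (10 kb) proband long reads
suffice because the trio exomes already type the iSNP (category 2);
otherwise intronic iSNPs must be typed from parental long reads over a
±`trio_window` (5 kb) region (category 3).

### The heterozygosity confidence model

The original workflow took a "confidence" from its neural-network variant
caller and thresholded it at 0.96. The published material specifies the
threshold, not the caller's internals, so the package re-grounds the score
as a transparent posterior: at a column with counts over the four bases,
the error rate is estimated from the third- and fourth-ranked bases
(each wrong base receives $e/3$, so $\hat e = 1.5\,(c_3+c_4)/n$, floored at
`error_floor` and capped below 0.75), and a multinomial likelihood is
evaluated for hom-ref, het and hom-alt with a uniform prior. The
confidence is the posterior probability of the heterozygous genotype. This
is a deliberate stand-in: it reproduces the *role* of the filter (discard
columns whose minor base is explainable as noise) with an auditable model,
and the threshold is kept at 0.96.

### Linkage vetting: what "homozygous in the two groups" means here

Three operational choices deserve a note, because the qualitative
description ("homozygous variants are identified in the two groups")
admits several readings:

1. **Homozygosity is enforced only in the mutant (DNM-alt) group.** A
   postzygotic target legitimately carries *both* iSNP bases in its
   wild-type group — that mixture *is* the third allelic form — so
   requiring homozygosity on both sides would make every mosaic target
   unphaseable. Identical majorities in the two groups are treated as
   discordant only when the wild-type group is itself effectively
   homozygous for the same base.
2. **The majority is computed over the candidate's two alleles.** Reads
   showing a third/fourth base or a deletion at the candidate position are
   sequencing error by definition and are accounted in the error metrics;
   counting them against linkage would penalise small mutant groups. For
   a mosaic of fraction $m$ at coverage $c$, the mutant group holds about
   $cm/2$ reads plus roughly $c(1-m/2)\,e/3$ cross-contaminating wild-type
   reads (error at the DNM position); at $m = 0.2$, $c = 400$, $e = 0.04$
   the expected pair-restricted majority is ~0.92.
3. **The threshold is 0.80.** Given the contamination arithmetic above, a
   0.90 cutoff would reject a substantial share of genuinely linked iSNPs
   on mosaic targets purely by sampling noise, while a noise candidate
   sits near 0.50 in the mutant group. 0.80 keeps more than six standard
   deviations of separation from noise at the minimum spanning depth of
   20 and stays conservative for prezygotic targets (expected majority
   ~0.97 at $e = 0.04$).

The agreement score reported and used for ranking is the mean of the two
within-group majority fractions.

### iSNP selection

The published selection is "the greatest combination of split-read
agreement, coverage and supporting data" — a ranking concept without a
formula. The package fixes a lexicographic order: support category
(primary: exome trio typed > secondary: proband exome only > tertiary:
parental long reads > unvalidated), then agreement, then spanning
coverage, then smaller absolute distance to the DNM, then leftmost
position. The final tie-breaks make selection a pure function of its
inputs, invariant under read and candidate ordering (tested by
permutation). A weighted-sum alternative was considered and rejected: with
no published weights, any choice would be arbitrary, and lexicographic
order makes the dominance of orthogonal validation explicit.

### Zygosity

Classification combines the three evidence categories (exome DNM base
information, long-read DNM base information, long-read allele
information):

* credible third allelic form → **postzygotic**;
* polished fraction inside the prezygotic band (0.40–0.60, from "around
  50% ± 10%") and no credible third allele → **prezygotic**;
* polished fraction outside the band, no third allele, but the raw DNM
  base fraction also outside the band by more than the measured total
  base error → **postzygotic** (the low-m regime where the wild-type-group
  mixture is the main signal);
* polished fraction outside the band while base frequencies stay inside →
  **prezygotic with an `allelic_bias` flag** (the allelic-sequencing-bias
  adjudication);
* otherwise **ambiguous**.

Missing exome evidence at the DNM (the 1×-coverage situation) adds a
`low_confidence_wes` flag but does not block classification — deep
long-read data still resolves such targets.

The third-allele credibility rule — fraction above
max(0.05, 2 × largest single false-allele fraction) — is a declared
stand-in for an unpublished numeric rule. The 0.05 floor sits above the
~1–2% per-pair background observed at 4% substitution error and well below
the (1−m)/2 ≥ 0.3 signal of any detectable mosaic; the ×2 multiple
protects against heavy-noise tables. The candidate pair is excluded from
the false set when its own credibility bar is computed, otherwise the test
would be circular.

### Anchoring the DNM site itself

Two exemptions apply at the DNM position. It is exempt from the
20–80% allele-fraction window and the confidence filter (mosaic DNMs run
as low as single-digit percent and would otherwise be discarded), and
exome polishing never removes it (a low-coverage exome can miss a mosaic
allele entirely; the site is independently validated by definition). Only
the validated alternate base is admitted there — any other non-reference
base at the DNM position is counted as noise in the `other` split group.

## The simulator

`simulate_dnm_target()` generates the study conditions end to end: a
random amplicon reference (41% GC), Mendelian trio genotypes with
informative SNPs (one parent homozygous reference, the other homozygous
alternate, random orientation), a DNM placed on one parental haplotype
with mosaic fraction `m`, full-length amplicon long reads with
substitution error and homopolymer-biased indel error, and trio exome
evidence (error-free genotypes with Poisson depths, per-position coverage
table, proband allelic depths at the DNM). Reads are emitted already
aligned with correct CIGARs: basecalling and alignment are out of scope,
so the simulator doubles as the alignment oracle, which keeps every
downstream stage deterministic and testable at desk scale. Ground truth
(per-read haplotype and mutant status) is kept outside the SAM fields.

Default error preset: `e_sub = 0.04`, `e_indel = 0.01`, homopolymer
multiplier 5 on runs of ≥ 3 identical bases, chosen to reproduce the
~4%-scale substitution noise of the targeted platform; the platform's true
substitution/indel decomposition is not published, so the preset is a
stand-in and every rate is overridable. Substituted bases are uniform over
the three non-true bases; inserted bases duplicate the template base
(indel error in this chemistry is homopolymer-length confusion).
A seed is mandatory and a single RNG stream drives the dataset; identical
seeds give byte-identical outputs.

What the simulator does **not** emulate: PCR chimeras and polymerase
error, read-length distributions of real flow cells (amplicons are read
full length by default; a truncation sampler exists because read ends are
quality-trimmed in practice), position-dependent quality profiles,
mapping ambiguity and alignment artefacts, and strand effects. Passing
tests therefore demonstrate the correctness and calibration of the
*pipeline logic* under a realistic error budget — not robustness to every
artefact of real amplicon data.

## Problem sizes used by the test-suite and acceptance script

Simulated cohorts are scaled to desk size while keeping the statistical
regime of the study: 69 prezygotic targets at coverage 1,000× with 4%
substitution error for the cohort frequency summaries (the real study's
coverage is tens of thousands; at 1,000× the binomial standard error of a
per-target fraction is already below 1.6%, so the cohort mean is estimated
to ±0.2%); 200 targets at coverage 400× for parameter-recovery checks
(83% paternal, 10% postzygotic with m drawn from 0.1–0.4); and ≤ 50-read
instances for exact brute-force oracle comparisons. Amplicons are 0.9–1.5
kb with the iSNP a few hundred bases from the DNM — category-2 geometry,
which is the dominant case in practice.

## Known limitations

* Only SNV DNMs are anchored; indel DNMs would need their own split logic.
* A single iSNP is used per target, by design — no multi-iSNP haplotype
  graph or statistical phasing is attempted (deliberately so; the single
  validated anchor makes heavier machinery unnecessary at amplicon scale).
* Sites where both parents share a heterozygous genotype are never
  informative and are excluded at discovery rather than rescued by
  population phasing.
* The binomial heterozygosity confidence ignores base qualities; at
  amplicon depths the counts dominate and the published threshold
  operates on a comparable scale, but the two scores are not numerically
  identical.
* Demultiplexing assigns a read by containment of its alignment start;
  reads straddling a region boundary (not expected for non-overlapping
  amplicons) follow their start.
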