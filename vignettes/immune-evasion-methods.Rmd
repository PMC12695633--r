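---
title: "Models and methods behind neoEscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoEscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoEscape)
```

`neoEscape` quantifies immune evasion in multi-region colorectal tumour
cohorts sampled down to individual glands. This vignette explains the
models, the decision rules and their operating points, what the synthetic
cohort generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Data model

A `GlandCohort` holds patients (with mismatch-repair status and class-I
HLA genotypes), samples (tissue, region, assay, purity), mutations
(consequence, 192-class strand-resolved trinucleotide context, predicted
strong-binder count, immunogenicity tier), per-sample genotypes
(presence, VAF, depth), RNA allele counts, HLA allele states, expression
matrices on two scales (variance-stabilised for cross-sample comparison
of a gene; TPM-like for expression-level thresholds), a promoter-peak
ATAC fold-change matrix, and interval catalogues as `GRanges` (peaks,
promoter/TSS intervals, TF binding sites, immunopeptidome ON-target
regions). On disk, tables are headered TSV and intervals are BED; BED's
0-based half-open coordinates are converted by `rtracklayer`, while
mutation positions remain 1-based. Trinucleotide context is stored
strand-resolved (192 classes); collapsing to 96 would lose the
transcription-strand information the opportunity correction uses.

## Clonality and proportional neoantigen burden

A mutation present in every eligible deep-sequenced carcinoma biopsy of a
patient is clonal; in WGS mode any other mutation is subclonal, while in
panel mode absence from a single biopsy leaves the mutation unclassified
(absence from two or more makes it subclonal). Low-pass and normal
samples never count as eligible: clonality is defined on sequenced cancer
biopsies, and low-pass samples are genotyped after the fact.

Proportional burden per biopsy is the number of present mutations with at
least one strong-binding peptide divided by the number of present
protein-changing mutations. The headline stratum is SNV-only (frameshifts
removed from numerator and denominator alike); frameshift neoantigens are
a separate stratum. A zero denominator yields an absent value, never 0 —
a biopsy without protein-changing mutations carries no information about
burden. One genomic variant is one unit regardless of how many binding
peptides it yields.

Group comparisons with several biopsies per patient use a patient
random-intercept model: `value ~ group + (1 | patient)` against
`value ~ (1 | patient)`, both fitted by maximum likelihood, compared by a
likelihood-ratio test (lme4). A caveat the tests make explicit: when two
tissue groups carry tissue-private mutation pools (each lesion's glands
share one pool), glands are not conditionally independent given patient
and the LRT is anti-conservative under a "same rates" null. The
calibration tests therefore use within-patient label permutation — the
exact exchangeable null for this model contract — and the same caution
applies to real cohorts with few lesions per patient.

## Genetic immune escape

**HLA LOH.** Per allele and sample, allelic imbalance requires p < 0.01.
An imbalanced allele is LOH when the lost-allele copy number is below 0.5
with its confidence interval strictly below 0.7, the kept-allele copy
number is above 0.75, and more than 10 sites mismatch between the
alleles. Independently, a minor-allele copy number of 0 from the
allele-specific caller marks a candidate LOH. When both evidence sources
are present, agreement yields LOH; disagreement defers to a
`corroborated` flag representing manual copy-number inspection, which
cannot be automated. When the minor-allele column is absent the combined
criteria decide alone. The decision is monotone: worsening any single
criterion can only demote the call.

**HLA mutations.** Protein-changing mutations in HLA-A/B/C are classified
frameshift, stop-gain, or SNV-class (missense and splice). Sub-threshold
candidates are rescued only when the identical nucleotide change passes
filters in another biopsy of the same tumour, and then carry a
second-tier evidence flag.

**APG mutations.** The 35-gene antigen-presentation set (TAP1 … RFXAP) is
first filtered to genes clearly expressed (≥ 10 TPM) in at least 5% of
samples; genes absent from the matrix are retained with a warning since
there is no evidence to exclude them. High-impact alterations
(frameshift/stop-gain/splice) are sufficient for escape; missense
variants require at least moderate annotated impact and count as
SNV-class.

**Checkpoint expression.** PD-L1 (CD274) and CTLA-4 are compared to the
normal-sample pool on the variance-stabilised scale: high above
mean + 2 SD, moderate in (1, 2] SD. The rule is OR by default (either
gene suffices) and configurable to AND; the permissive reading matches
how overexpression of either checkpoint can blunt a T-cell response, and
no numeric threshold is published, so a z-score against the normal pool
is the simplest reproducible rule.

**Labels.** A sample is `escaped` with any of: HLA LOH, HLA frameshift,
HLA stop-gain, high-impact APG alteration, high checkpoint expression, or
at least two SNV-class mechanisms ("several SNVs" read minimally as ≥ 2,
consistent with a single SNV being only `potential_escape`). At the
cancer level, an escape-grade mechanism present in all deep-sequenced
carcinoma samples is clonal; in fewer than 25% of samples,
minor-subclonal; otherwise subclonal. Cancers without genetic escape but
with at least one APG promoter accessibility loss are flagged
epigenetic-only.

## Chromatin accessibility (SCAA) analysis

SCAAs are defined per cancer from the purity- and copy-number-corrected
peak × cancer log2 fold-change matrix: loss below −1, gain above 1,
strict at the boundary. Peaks are assigned to the gene whose
strand-resolved TSS lies within 1,000 bp (nearest wins; exact ties break
to the lexicographically smaller symbol so the assignment is
deterministic). Only promoter-assigned calls enter the gene-level
analyses; enhancer–gene mapping is accepted only as an explicit input
since no catalogue is bundled.

The APG loss-bias test compares the observed loss fraction among APG
promoter SCAAs to 200 random gene sets of uniform-random size 25–40,
one-sided on losses, with the add-one estimator p = (k + 1)/(n + 1) —
finite permutations cannot honestly report p = 0. Random sets containing
no SCAA have an undefined loss fraction and count as not-more-extreme.
The neoantigen × promoter-loss association is an exact conditional odds
ratio (below); the per-cancer analysis pairs the proportion of
neoantigens and of nonantigenic mutations lying in loss genes and applies
a two-sided paired Wilcoxon signed-rank test. TF analysis counts, per
factor, the recurrent APG loss peaks (loss in more than one patient) with
a binding site strictly within 1,000 bp, selects factors bound to more
than two such regions, and tests the selected set's loss-site binding
against the genome-wide peak universe with a one-sided exact test.

## Transcriptional immuno-editing

From RNA allele counts, a mutation present in DNA is `expressed` in a
sample with ≥ 3 variant-supporting reads and `edited` with more than ten
overlapping reads and zero support; anything else is insufficient
evidence and stays blank. The depth cut is justified analytically: the
probability that a variant at true allele frequency `af` yields zero
supporting reads in `d` reads is (1 − af)^d, and d = 11 is the smallest
depth with (0.75)^d < 0.05 (`minDepthForMisclassification()`); the
achieved bound is ≈ 4.2%.

Mutations with confident status in fewer than two samples are excluded
from all summaries. A mutation is "edited" at the cohort level when
edited in at least one sample; insufficient pairs never count as
silenced. The editing odds ratio (neoantigen vs nonantigenic × edited vs
never) uses the exact conditional engine, supports clonality strata and
leave-one-cancer-out exclusion, and the clonal signal can be downsampled
to the subclonal mutation count to check whether significance survives at
matched power (significance inside the downsampling is two-sided exact
p < 0.05).

## Immune dN/dS

Opportunities are spectrum-weighted site counts per region class:
`buildOpportunities()` multiplies per-context synonymous and
nonsynonymous site counts by the 192-context relative mutation rates and
sums within ON (immunopeptidome) and OFF regions. dN/dS is
(n_non/opp_non)/(n_syn/opp_syn); immune dN/dS is the ON/OFF ratio, which
cancels any artefact (context mis-specification, global rate scaling)
shared by the two classes. Samples lacking ON- or OFF-target synonymous
mutations are ineligible rather than erroneous — with a zero synonymous
count the estimate is undefined and no amount of smoothing makes it
honest. The CI is a normal approximation on the log ratio with variance
Σ 1/count over the four counts, the standard ratio-of-rates interval; the
published display truncates at 3.5, which this package treats as a
display decision only, never applied to estimates. Clonal-only analysis
filters to clonal mutations and reuses the same machinery.

## Shared statistics

The exact 2 × 2 engine computes the conditional maximum-likelihood odds
ratio under the noncentral hypergeometric likelihood, the exact CI by
test inversion, and the two-sided exact p as the sum of null
probabilities not exceeding the observed table's. It matches a
first-principles enumeration oracle and the independent `fisher.test`
implementation on every table with total ≤ 25 (tested exhaustively).
Empty margins yield an undefined OR with p = 1.

VAF depletion uses the two-sample KS test, one-sided by default towards
"neoantigen VAFs stochastically smaller" (the direction immuno-editing
predicts), two-sided behind a flag. The small-subclone window test takes
per-biopsy proportions of high-immunogenicity neoantigens and of
nonimmunogenic mutations strictly inside (0.05, 0.1) — boundary values
excluded — and pairs them across biopsies. Wilcoxon tests use the exact
null for n ≤ 25 without ties, the normal approximation with continuity
correction otherwise, and drop zero differences. P-values are reported
unadjusted by default, matching the source analyses; a BH column is one
`p.adjust()` call away. Multivariable burden regression is a logit-link
beta regression (glmmTMB `beta_family`) with patient as a categorical
fixed effect summarised by its min–max coefficient range; exact 0/1
proportions are compressed by (y(n − 1) + 0.5)/n before fitting, the
standard remedy for boundary proportions.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes and plants a recoverable ground truth for every stage. Defaults
describe the study conditions: 20% MMRd patients; negative-binomial
coding-mutation counts with means 80 (MMRp) and 1340 (MMRd), putting
median synonymous burdens near 18 and 307; clonal fraction 0.6 with 2–4
nested subclones over random gland subsets (sufficient to exercise
clonality rules without a full coalescent); neoantigen rate 0.3 for
carcinoma and 0.18 for adenoma-private mutations; silencing odds ratio
1.5 implemented as allele dropout in RNA (alt reads 0) with
negative-binomial depth (mean 20, size 5), which makes the >10-depth/0-alt
rule reachable; SCAA events at ~4–5% per gene-cancer with loss share 0.93
for APGs vs 0.5 for background; a planted odds ratio of 1.5 for
neoantigens lying in promoter-loss genes; VAF depletion factor 0.5 on
subclonal high-immunogenicity neoantigens; immunopeptidome covering 15%
of each gene body with a 1:3 synonymous:nonsynonymous site ratio in both
region classes and uniform context spectrum (configurable, so the
opportunity correction is exercised nontrivially).

Several structures are deliberately enforced rather than emergent, so
that recovery tests are exact: clonal VAFs (0.30–0.50) and subclonal VAFs
(0.02–0.28) occupy disjoint ranges; checkpoint expression in normals is
standardised to mean 6/SD 0.4 so that planted overexpression (+5 SD) and
unremarkable tumours (z = 0) classify deterministically; random mutations
avoid APG genes, so APG/HLA alterations arise only from the per-patient
escape plan (this also mirrors the observed mutual exclusivity of APG
promoter losses and APG mutations); two APGs (IFNG, HSPA6) are simulated
as unexpressed to exercise the expression filter, and the escape plan
avoids planting in them. Hypermutant patients always receive clonal
escape. What the generator does not emulate: read-level noise, copy
number outside the HLA allele states, spatial coordinates, phylogenies
beyond the nested-subclone scheme, or correlated expression programs —
passing recovery tests therefore demonstrates correctness of the decision
rules and estimators under the assumed structure, not robustness to every
failure mode of real data.

`simulateNullCohort()` neutralises every planted effect (silencing OR 1,
no escape, equal APG/background loss rates, no VAF depletion, neutral
ON-target rate) for calibration experiments.

## Problem sizes and numerical choices in the test suite

Calibration and recovery suites run 100 seeds of 4-patient, 5-gland
hypermutant-weighted cohorts — small enough to iterate comfortably, large
enough that clonal neoantigen counts exceed 500 per cohort (the scale at
which the editing OR is informative). The null-calibration SCAA check
uses a shared neutral event rate of 0.2 so the APG set carries ~30 SCAAs
and the permutation loss fraction is fine-grained; at sparse event rates
the statistic is so discrete that ties (counted as at-least-as-extreme)
make the permutation p strongly conservative, which is safe but defeats a
uniformity check. The exact-OR engine is verified against enumeration on
all 23,751 tables with total ≤ 25; CI agreement with `fisher.test` is
asserted on the log scale because that implementation's root-finding
tolerance dominates near zero.

## Known limitations

Neoantigen labels (strong-binder counts, immunogenicity tiers) are input
annotations: no binding prediction is bundled, and the high-immunogenicity
tier used by the VAF-window test is likewise accepted as given. HLA
haplotypes are taken as given, and homozygosity handling does not
re-enter escape labelling. Per-sample chromatin accessibility is out of
scope (SCAAs are per cancer). The LOHHLA/sequenza disagreement rule
depends on a manual corroboration flag by design. The mixed-model caveat
above applies whenever lesions contribute few, strongly correlated
biopsies.
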