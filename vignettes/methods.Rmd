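---
title: "Methods: germline candidate-gene prioritization with somatic profiling"
author: "gcgerm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline candidate-gene prioritization with somatic profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcgerm)
```

## The problem

Early-onset gastric cancer (EOGC; diagnosis before the age of 51) carries a
stronger germline component than late-onset disease, yet most young patients
have no mutation in the established predisposition genes (CDH1, the Lynch
genes, APC, and the other hereditary-cancer genes). Candidate-gene discovery
in this setting proceeds by exome sequencing a small cohort of unrelated
early-onset patients and pushing every germline variant through a
prioritization funnel: automated filters for sequence quality, functional
consequence, population rarity and in-silico pathogenicity; a restriction to
genes already implicated in cancer predisposition; inheritance-model analyses
(dominant and recessive) with gene-function criteria tuned to gastric
biology (pathogen recognition for *H. pylori*, cell adhesion, stomach
function); a cohort-recurrence exclusion; read-level prevalidation; and a
final selection informed by the patients' somatic mutational profiles
(tumor mutational burden and COSMIC-style mutational signatures).

`gcgerm` implements that funnel as a reusable, fully deterministic pipeline.
Because studies of this kind typically cannot deposit patient-level exome
data, the package pairs the analysis with a seeded synthetic-cohort
generator whose ground-truth manifest makes every stage testable: the
central correctness property is that, under the default study-shaped
conditions, the pipeline's final candidate set equals the planted truth
exactly.

## The germline filtering cascade

Records enter as one allele observation per patient (biallelic, multi-allelic
sites split at the reader, alleles trimmed so that recurrence keys are
representation-independent). Five stages are applied in a fixed order;
each stage logs its input, retained and discarded counts and a
discard-reason histogram in a *stage ledger* whose conservation
(`input = retained + discarded`, `retained(i) = input(i+1)`) is checked on
every run.

1. **Quality** — total depth ≥ 10, alternate reads ≥ 4, call quality ≥ 30.
   The source analysis names "sequence quality" without thresholds; these
   defaults are declared conventions and are configurable
   (`filter_config()`).
2. **Consequence** — retain missense, nonsense, frameshift and splice-site
   classes; synonymous and "other" are discarded.
3. **Frequency** — retain variants with maximum population allele frequency
   strictly below 0.01; a missing frequency is treated as rare, because
   novel variants are the object of the analysis. The 1% default encodes
   "rare, discarding polymorphisms" and is configurable.
4. **Predictor consensus** (missense only) — six tools vote with their
   published damaging cutoffs (SIFT < 0.05, PolyPhen2 ≥ 0.446, CADD ≥ 20,
   PhyloP ≥ 2, MutationTaster ∈ {A, D}, LRT = D); a variant is damaging when
   at least half of the *non-missing* predictors vote damaging, and a
   variant with no predictor values is conservatively not damaging.
   Loss-of-function classes bypass this stage because these tools score
   amino-acid substitutions only. The majority-of-available rule is this
   package's convention; the source lists the tool panel without a
   combination rule.
5. **Term match** — case-insensitive whole-entry matching of a selection
   term list against each gene's free-text terms and category names. The
   original appendix term list is not public; `default_term_list()` is a
   documented reconstruction from the named gene functions and is intended
   to be replaced by a curated list.

Stage order affects discard *attribution* only, never final membership
(the predicates are independent); a permutation test asserts
order-insensitivity of counts and membership, and a brute-force
predicate-evaluator oracle asserts membership equality on random cohorts.

## Prioritization

Step 1 restricts to genes flagged as cancer-predisposition genes
("previously involved in germline predisposition to any type of cancer").
Because the interesting end-points of such studies include genes that are
not classical high-penetrance genes, the bundled synthetic knowledge tables
flag a broad gene set, and the restriction can be disabled (`union mode`)
for sensitivity analyses.

Step 2 applies the inheritance analyses. Genotype routes the record:
homozygous-alternate records enter the **recessive** arm and qualify when
the gene is cancer-flagged or carries the pathogen-recognition category
(the *H. pylori* rationale); heterozygous records enter the **dominant**
arm and qualify when the gene carries stomach-function, gastric-cancer
development, or one of the prioritized functions (tumor suppression, DNA
repair, apoptosis, pathogen recognition, innate immunity, gut epithelial
protection, cell adhesion) or a risk-factor function (alcohol metabolism,
gastric acid secretion). A gene may appear under both models via different
variants in different patients. Compound heterozygotes (two distinct
heterozygous variants in one gene and patient) are supported behind a flag,
default off: the source's recessive examples are homozygous and its stance
on compound heterozygotes is unstated; when enabled, phase is assumed trans
and the pair is flagged unphased.

Finally the **recurrence exclusion** removes any variant key carried by
strictly more than 25% of the cohort's patients (distinct carriers, not
alleles) — shared variants at that frequency in a rare-disease cohort are
overwhelmingly artifacts or unflagged polymorphisms.

## Prevalidation

Manual genome-browser review is replaced by four deterministic heuristics —
a reinterpretation, not a reproduction, so the original's pass/discard
split is never asserted. A candidate is discarded when (a) its locus is not
in the coding regions (half-open BED converted once at the reader; a
1-based position *p* is coding iff *p−1* ∈ [start, end)); (b) the longest
single-base run overlapping or adjacent to the locus exceeds 7 bp
(homopolymer "T-track" artifacts); (c) fewer than 4 alternate reads support
it; or (d) its variant-allele fraction is inconsistent with its genotype
(heterozygous outside [0.2, 0.8]; homozygous below 0.8). The VAF gates
stand in for strand-bias/sequencing-error review because the data model
carries no strand counts. All failing reasons are recorded; the ledger
histogram counts the first.

## Somatic profiling

Per-caller somatic callsets are merged by the published consensus rule:
**2 of 4** callers for SNVs, **2 of 3** for indels, on normalized variant
keys. Tumor mutational burden is mutations per megabase of the capture
territory (the merged capture BED; the source does not state its
denominator), with strict class boundaries: > 100 ultra-hypermutated,
> 10 hypermutated.

SNVs are classified into the 96 pyrimidine-normalized trinucleotide
channels (purine-reference substitutions are reverse-complemented), making
the catalog invariant under global reverse complement — a property test
reverse-complements the genome and every call and asserts bit-identical
matrices. Indels are classified into the 83 COSMIC-style channels by type,
length class, repeat context (homopolymer length for 1-bp events, flanking
repeat units otherwise) and microhomology for non-repeat deletions; channel
labels ship as a text fixture so naming is bit-exact.

Signature exposures are obtained by **refitting**: per sample, non-negative
least squares (Lawson–Hanson, via `pracma::lsqnonneg`) minimizes the
Euclidean distance between the observed channel counts and the
catalog-weighted sum. Signatures below 5% relative contribution are then
pruned and the reduced model refit until stable (pruning is optional).
Within a pruning iteration the refit can never have a larger residual than
simply zeroing the pruned exposures — that monotonicity is asserted in the
tests; dropping a contributing signature can of course raise the residual
relative to the unpruned fit. De-novo signature extraction (NMF) is out of
scope: refitting against a supplied catalog is the quantity the analysis
needs ("signature contribution").

Because the published COSMIC v3.1 matrices cannot be redistributed here,
the package constructs deterministic **synthetic stand-in catalogs** in
code (`synthetic_sbs96_catalog()`, `synthetic_id83_catalog()`; also shipped
as TSVs under `inst/extdata/` with `synthetic` in the file names). They
reuse the familiar identifiers (SBS1, SBS5, SBS15, SBS19, SBS21; ID1, ID2,
ID7) and the aetiology tags the analysis interprets (clock-like,
MMR-deficiency, unknown), with well-separated shapes, but their values are
not COSMIC's. Any COSMIC-layout matrix can be supplied instead via
`read_signature_catalog()`.

## Selection

Expert selection of the final candidates is irreproducible judgment; the
package replaces it with a transparent additive score:
`score = Σ category weights over the gene's categories + concordance bonus`.
The bonus applies when the patient's tumor exposures contain a signature
whose aetiology tag maps to one of the candidate's gene categories at ≥ 5%
relative contribution; the default map carries the one explicit link the
analysis uses — MMR-deficiency signatures support DNA-repair genes (the
ultra-hypermutated patient's rationale). Ties break deterministically on
(gene, chrom, pos, patient). Removing tumor data can never raise a score.

## The synthetic cohort: what it emulates, and what it does not

`generate_reference()` draws a 2 Mb single chromosome at GC 0.41 with 60
non-overlapping multi-exon genes and deliberately planted homopolymer
tracts (8–14 bp, T-rich), intergenic and exonic. `generate_germline_cohort()`
then emits a 20-patient cohort (ages drawn under the inclusion bound of 51)
in which **every background variant is constructed to fail exactly one
stage**: 600 quality failures, 1,600 synonymous/other, 1,600 common
polymorphisms, 900 benign-by-consensus missense and 300 term-list failures
per patient (5,000 total; the original reports no pre-filter counts, so
this size is a free parameter chosen to be exome-like at desk scale).
Planted truth comprises 9 dominant (heterozygous; missense and
loss-of-function mix) and 3 recessive (homozygous missense) variants on
qualifying genes at clean exonic positions, one recurrent artifact shared
by 6 of 20 patients (30% > 25%), and 2 decoys inside exonic homopolymer
tracts that must fall at prevalidation. Annotation values come from fixed
"damaging" and "benign" predictor profiles with jitter, so every filter
outcome is analytically known and the manifest can state expected per-stage
discards exactly.

`simulate_tumor_callsets()` draws SNV channels from a signature mixture and
places each at an unused reference position whose normalized trinucleotide
context matches (without replacement — no site mutates twice), so the
generated spectrum equals the drawn channels exactly and catalog column
sums equal the mutation count. Indel generation is restricted to 1-bp
homopolymer insertion/deletion channels plus one microhomology deletion
class — enough to exercise classification and refitting without exhaustive
channel synthesis. Every true mutation is written to ≥ 2 callers;
caller-private decoys (25 per caller by default) must vanish at the
consensus merge. The default tumor panel emulates nine tumors by burden
target (315.4, 43.6, 16.8 and six low-burden samples, mutations per
megabase), with `n = round(target × capture Mb)`; the ultra-hypermutated
sample carries an MMR-heavy mixture (SBS15+SBS21 at 0.75, plus ID7).

What passing tests on this cohort do **not** show: performance on real
exomes. The generator has no linkage, relatedness, mapping artifacts,
caller error models beyond private decoys, strand bias, or annotation
disagreement between tools; background classes fail exactly one filter
each, whereas real variants fail several. The synthetic results certify the
*logic* of the cascade, not its clinical yield.

## Numerical and design choices

* **Determinism.** Every generator takes a seed; `with_seed()` isolates and
  restores the RNG state, and `run_all()` threads one master seed through
  all stages, so a fixed seed and configuration reproduce byte-identical
  reports. Sub-second scale problem sizes were chosen so the full default
  run (100,020 germline records, nine tumors) completes in well under a
  minute on one CPU.
* **Catalog tolerances.** Signature columns must sum to 1 within 1e-4 and
  are then renormalized exactly; out-of-tolerance columns are rejected, not
  repaired.
* **Boundary conventions.** All published thresholds are strict
  (`> 100`, `> 10` mutations/Mb; `> 25%` recurrence); the predictor
  consensus uses `≥` at the 0.5 fraction; frequency uses `<` at 0.01.
* **Degenerate inputs.** Empty cohorts yield empty outputs with an all-zero
  ledger; a zero-mutation tumor yields zero exposures with no relative
  vector (marked absent rather than 0/0); an empty cancer-gene list warns
  and discards everything (degenerate but well-defined).
* **Entry points.** Both per-patient and joint multi-sample VCFs are read;
  annotations ride in INFO keys, with a sidecar-TSV reader as the
  alternative. The exported R functions are the interface; there is no
  shell entry point because the package's users drive it from R (see
  `run_all()` and `scripts/acceptance.R`).

## Known limitations

Structural variants, copy-number screening, non-diploid genotypes,
segregation and penetrance modeling, per-population frequency
stratification, doublet-base and transcription-strand signature channels,
and de-novo signature extraction are all out of scope. Reference-based
left-alignment of arbitrarily represented indels is limited to allele
trimming; the generators emit left-aligned representations. The prevalidation
heuristics are declared conventions standing in for visual review, and the
selection score is a declared reinterpretation of expert judgment — both are
configurable rather than claimed reproductions.
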