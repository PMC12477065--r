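---
title: "Methods: variant peptide detection and heterogeneity analysis in multi-metastasis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant peptide detection and heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and procedures: what
each stage assumes, which tunable parameters matter, how the synthetic
cohort generator works and what it does and does not emulate, and where a
genuinely open design choice was settled.

## 1. From called variants to a cohort protein database

The unit of analysis is a coding transcript with a single contiguous CDS
(length a multiple of 3, `ATG` start, one terminal stop). Variants are
transcript-relative: a 0-based CDS offset, a reference allele that must
match the CDS, and an alternate allele. The frame effect is purely a
length rule — a variant is *in-frame* iff the allele length difference is
divisible by 3 — so SNVs and ±3 nt indels are in-frame, ±1/±2 nt indels
frameshift.

**Window combinations.** Nearby in-frame variants on the same haplotype
can co-occur inside one tryptic peptide, so the database must contain
their combinations. With windows of `window_aa = 30` residues the choice
of anchoring is open (sliding, tiled or variant-anchored); we anchor a
window at each variant's first affected residue and emit every non-empty
subset of in-frame variants whose affected residues fall entirely inside
some window. This is equivalent to: a subset is emitted iff its members
span at most 30 residues. Subsets containing variants that overlap on the
reference are contradictory and never generated; subsets valid in several
windows are emitted once; output order is deterministic. Frameshift
variants are never combined with anything — the downstream sequence is
already fully determined by the shift — and are emitted singly.

**Cap.** A gene whose total combination count in a sample (in-frame
subsets plus frameshift singletons, over all its transcripts) exceeds
`max_combinations_per_gene = 10000` is dropped for that sample, which
bounds the search-space explosion in hypermutated genes. The counter
short-circuits once the cap is provably exceeded, so a window holding 30
variants does not trigger a 2^30 enumeration. We count *subsets*, not
emitted sequences; the boundary is exact (10 000 kept, 10 001 dropped).

**Emission.** In-frame subsets are applied to the CDS and translated; the
emitted record covers the affected residues plus 30 flanking residues on
each side, so any tryptic peptide overlapping a variant (at ≤ 2 missed
cleavages and ≤ 50 residues) is almost always a substring of the record.
Frameshift records run from 30 residues upstream of the first affected
codon to the first downstream stop (or the transcript end). Stop gains
truncate; stop losses read through to the next stop. Records whose
translation equals the reference protein (synonymous subsets) are never
emitted, and the empty subset — the reference itself — is excluded by
construction.

**Deduplication.** The cohort database keys every unique sequence by its
MD5 hex digest (the FASTA header *is* the digest), storing one provenance
row per (sample, record) with the prediction type and original header.
The build is invariant to sample input order, an MD5 collision between
differing sequences is a hard error, and FASTA + provenance TSV round-trip
to an identical database. Splice and novel-ORF records from external
discovery tools can be passed through with their prediction type
preserved; this package does not construct splice graphs or assemble
transcripts.

## 2. Non-reference peptide calling

Mass spectrometry cannot distinguish isoleucine from leucine, so all
sequence comparisons collapse `I` to `L` first. A PSM becomes an NRP
candidate iff (i) its q-value is at most 0.01, (ii) it carries the
external validation flag (the spectrum-level rescoring step is ingested as
a boolean, never recomputed), and (iii) its collapsed peptide is *not a
substring* of any collapsed reference protein. Substring containment is
deliberately stricter than tryptic-peptide set membership: it removes
peptides explainable by the reference under any digestion irregularity,
and it makes the reference-takes-precedence rule (a peptide matching both
a reference and a variant sequence is removed) automatic.

Candidates are searched against the collapsed cohort database, so a
peptide predicted in any sample is searched in all samples. Peptides
matching sequences of more than one gene are discarded (applied *before*
missed-cleavage merging — the stricter order, since merging could only
widen a peptide's gene footprint); peptides with no database hit are
unexplained and discarded. The variant class comes from the prediction
types of the matching records; a single gene whose matches span several
types yields class `multi`.

**Missed-cleavage merging.** Two entries merge when one collapsed peptide
is a substring of the other *and* they share at least one matching
database sequence — our operational reading of "covering the same variant
position", which avoids re-deriving per-record variant coordinates.
Merging runs to its transitive closure (union–find), so the result is a
fixpoint independent of input order; the merged key is the shortest
member and presence is the element-wise union.

Presence matrices are binary — 1 iff the NRP had at least one validated
PSM in the sample — and association analyses use NRPs detected in at
least three patients (breadth computed through the sample-to-patient
map).

## 3. Variant-level statistics

Allele-frequency classification partitions {absent} ∪ [0, 1]: absent from
the reference population (including an explicit frequency of zero) ⇒
*novel*; above 1% ⇒ *frequent*; in (0, 1%] ⇒ *removed* (too uncertain to
interpret). The 1% boundary itself is *removed*.

For mutation excess, the reference ratio r0 of novel to frequent
mutations can be pooled (Σ novel / Σ frequent, the default) or the mean
of per-gene ratios; the published description ("average ratio …
calculated for all genes") is ambiguous between the two, so both are
implemented. Each gene with n = n_novel + n_frequent ≥ 1 is tested with a
one-sided exact binomial test of n_novel successes against
p0 = r0/(1 + r0), BH-corrected; genes with adjusted p < 0.05 are flagged.
The exact binomial was chosen as the simplest test consistent with the
ratio formulation; under a null cohort drawn at the reference ratio the
flagged fraction stays below the nominal level (the BH step makes it
conservative). Deleteriousness scores are ingested, never computed:
scaled C-scores for multiple genomic mappings of one peptide are
averaged, and a mean of 20 or more (the top-1% convention) flags the
variant.

## 4. Quantitative matrix preparation

The proteomic pipeline is deterministic and ordered: log2 →
artifact floor (log2 intensity < 10, i.e. raw < 1024, becomes missing) →
median-scale normalisation → replicate averaging. The global median is
computed over all observed values *before* centring (the published order
lists the steps but not this detail; pre-centring is the fixed choice
here), after which every replicate's median equals the global median
exactly. Replicate averaging ignores missing values — a sample value is
missing only when all its replicates are — maximising retained data ahead
of the missingness filter. The ≤ 10% missingness filter runs on the
averaged, per-sample matrix (the "across the metastases" reading) and its
boundary is inclusive.

Imputation uses the stochastic minimal-value model for left-censored
label-free data: per sample, missing cells are drawn from a normal
distribution centred at the sample's q = 0.02 quantile of observed values
with spread `tune.sigma = 1` times the median per-protein observed
standard deviation. Observed cells are never altered; the draw is
deterministic under a seed; a sample with fewer than three observed
values is an error rather than a silent guess.

RNA-seq helpers mirror the published rules: the three-metric quality
classifier (good iff all of mRNA content > 76.84%, > 3.6 M assigned
reads, > 48.3% assigned; poor iff all of ≤ 60%, ≤ 2.3 M, ≤ 38.9%; medium
otherwise), replicate selection by (assigned %, M reads) with a
lexicographic id tie-break, RPKM/TPM, the strict counts > 9 in ≥ 30% of
samples transcript filter (sample threshold rounded up), and the ≥ 60%
tumour-content sample filter (boundary kept).

## 5. Heterogeneity statistics

**Consensus clustering.** Proteins quantified in at least 90% of the
analysis samples enter clustering. For each candidate k (default 2–6),
`n_resamples` subsamples of 80% of the samples are clustered with
partitioning around medoids (build + swap, deterministic) on
1 − Pearson-correlation distance; the consensus index of a pair is its
co-clustering rate among co-samplings. Final assignments at each k come
from PAM on 1 − consensus, consistent with the base method. k is chosen
from the consensus CDF area curve: the largest k whose relative area
increase is at least `elbow_threshold = 0.1` — a fixed numerical stand-in
for the visual elbow judgement, configurable. Computation uses a
canonical (sorted) sample ordering internally, so results are invariant
to column order. The published resampling fraction and repetition count
are not stated; 0.8 and 1000 are defaults, and the repeated-seed checks
in the test-suite use 150 repetitions on cohorts of ~30 metastases, where
the consensus matrix is already stable. PAM's build + swap is a local
search: on well-separated data it provably/empirically attains the
exhaustive-search optimum (asserted in the tests for n ≤ 10), which is
the regime consensus clustering operates in after resampling.

**Differential abundance** is a per-protein Welch t-test on log2
intensities with BH correction (a Wilcoxon option exists); the published
analysis names no test, and Welch is the field default for imputed
label-free matrices. Cluster-specific upregulation requires a positive
effect and adjusted p < 0.05 in *every* pairwise contrast against the
other clusters ("all relevant comparisons" read as all pairwise, which is
what makes the resulting sets cluster-unique; one-vs-rest is available
for location contrasts). Zero-variance degeneracies resolve to p = 1 at
equal means and p = 0 otherwise.

**Fisher enrichment** of NRP presence in a sample group is the one-sided
hypergeometric tail of the 2×2 table; an all-zero presence row returns
p = 1.

**Pre-ranked GSEA** uses the classic weighted running sum with weight 1:
hits increment by |score|/Σ|hit scores|, misses decrement uniformly, and
the ES is the deviation of maximum magnitude. Significance comes from
gene-label permutation (appropriate for a pre-ranked list — there are no
phenotype columns to permute), NES is ES divided by the mean |permuted
ES| of the same sign, and sets with fewer than 10 members in the ranked
universe are skipped. When the maximum positive and negative deviations
tie in magnitude the sign of the ES is numerically arbitrary; the tests
compare magnitudes in that measure-zero case.

Gene-wise protein–RNA agreement is Spearman's rho with average ranks on
pairwise-complete observations (≥ 3 pairs), BH-corrected, flagging
rho > 0.5 with adjusted p < 0.05. Sample similarity uses Pearson on
pairwise-complete abundances and Jaccard on NRP presence (two empty
presence vectors have Jaccard 1 by convention).

## 6. Survival

Kaplan–Meier estimation, log-rank tests and Cox regression delegate to
the survival package (Breslow tie handling by default, Efron switchable);
the median is the smallest time with S(t) ≤ 0.5 and is undefined when the
curve never reaches 0.5. Non-convergence or separation in a Cox fit is
flagged, never silently reported.

For survival ranking of proteins, the published model included patient id
as a random effect to absorb the correlation between metastases of one
patient. This package instead collapses metastases to one value per
patient (the mean) before a univariate Cox fit per protein — a
deterministic, dependency-free estimator that removes pseudo-replication
at the cost of discarding within-patient variance; this deviation is
deliberate and documented here. Proteins rank by signed Wald z,
descending, so a positive score — and a positive NES downstream — means
higher abundance in patients with shorter overall survival.

Single-sample signature scores are the mean z-score over the signature's
genes present (≥ 3 required); the published score formula lives in
unavailable supplementary material, and mean-z is the standard
convention. Immunotherapy-response (TIDE-like) scores are ingested, never
computed. Patients are classified by their dominant clusters with a
strict majority: exactly 50% of metastases in the target clusters counts
as `other`.

## 7. The synthetic cohort generator

The generator emulates the *structure* of a post-mortem multi-metastasis
melanoma cohort: 24 patients with 1–9 metastases each (uniform),
single-CDS intronless transcripts (60 genes of 300–900 nt by default),
120 SNVs plus 30 in-frame and 30 frameshift indels at uniform CDS
positions sparing start/stop codons, an allele-frequency spectrum of 50%
absent / 20% rare / 30% common, per-patient variant carriage with a
configurable inter-metastasis concordance (0.5 by default; the real
quantity is unreported, so it is a knob, not a claim), four proteomic
clusters as pathway-sized log2 shifts (2.0 by default, i.e. 2 within-
cluster standard deviations; tests of clustering recovery use 5), two
replicates per sample with a small replicate shift (sd 0.3) to exercise
median normalisation, ~10% missingness assigned by a logistic function of
intensity (MNAR — the regime in which minimal-value imputation is the
right recovery model; the logistic offset is solved numerically so the
realised rate matches the target), and exponential patient survival whose
hazard is the base rate (0.02/month, administratively censored at 120
months) scaled by the cluster-fraction-weighted hazard multipliers
(default 3, 1, 3, 1 — clusters 1 and 3 deleterious).

PSM tables contain the tryptic peptides of planted variant proteins
(validated, scores ~ N(25, 5)), sampled reference peptides (validated,
same score model) and random decoy-like peptides (scores ~ N(10, 3), half
validated to exercise the unexplained-peptide discard); q-values are
rank-based within a sample. Ground truth records every planted variant
with its AF class, every planted peptide (tryptic peptides of the
single-variant protein absent from the collapsed reference), the true
cluster of every sample, and the hazard multipliers. Each generator
section draws from its own seed stream, so cohorts are byte-identical
under a configuration and the proteogenomic observables can be skipped
without perturbing the abundance or survival draws.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: realistic spectra, retention times or
score distributions; splice variants and novel ORFs (records can be
passed through, but none are generated); linked haplotypes (variants are
planted independently, so multi-variant windows are rare at default
settings); location-specific proteome shifts; RNA-seq counts correlated
with protein abundance; germline/somatic structure in the AF spectrum;
and batch effects.

## 8. Numerical choices and problem sizes

Deterministic seeds flow from a single configuration or function
argument everywhere randomness exists (subsampling, permutation,
imputation, simulation); re-running any operation with the same inputs is
byte-identical. Degenerate inputs fail loudly (empty reference, constant
covariates or samples, too few observed values) rather than returning
guesses. The test-suite's repeated-seed checks run at desk scale chosen
once: 20-seed consensus-clustering recovery on 8-patient cohorts at 150
resamples, 100 Cox recovery simulations at n = 200, 20-seed survival-GSEA
recovery on default-size cohorts at 300 permutations, and exhaustive
oracles at the sizes where exhaustion is exact (all 2×2 tables with
total ≤ 12, power sets of ≤ 12 variants, all medoid pairs for n ≤ 10).

## 9. Known limitations

Transcript models are intronless single-CDS records, so genomic
coordinates, splice graphs and VEP-style consequence annotation are out
of scope. The unique-gene rule discards genuinely multi-mapping peptides
rather than apportioning them. The patient-mean collapse before survival
ranking underweights patients with many divergent metastases relative to
a true frailty model. The delta-area elbow is a threshold rule, not a
statistical test, and inherits the usual instability of k selection near
the threshold. The gene-excess test treats variants as independent
draws, which real linkage violates.
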