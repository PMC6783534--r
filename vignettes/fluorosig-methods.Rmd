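---
title: "Methods: detecting and quantifying a fluoropyrimidine mutational signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying a fluoropyrimidine mutational signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fluorosig implements the computational machinery used to detect,
quantify and time a chemotherapy-associated mutational process whose
hallmark is T>G substitutions in a CTT trinucleotide context — the
pattern known in the COSMIC catalog as signature 17, inducible in
normal and tumor cells by 5-fluorouracil (5-FU) and related
fluoropyrimidines. This vignette explains the models behind each stage,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Mutation catalogs

Somatic single base substitutions (SBSs) are classified by the
substituted pyrimidine and its two flanking bases. Purine-reference
variants are reverse-complemented before classification, giving 96
classes in the fixed COSMIC ordering returned by `mut_types_96()`.
Every matrix in the package indexes against that ordering, which is why
`read_catalog()` and `read_signatures()` re-sort on ingest and refuse
tables whose row set is not exactly the 96 canonical classes.

Catalog construction applies the filters used when SBS calls come from
a clonal-expansion experiment or a tumor/normal pipeline:

* **VAF filter** (`vaf_filter()`): a closed interval, by default
  [0.3, 0.7]. Mutations acquired before a single-cell bottleneck are
  expected near 0.5; calls outside the interval are predominantly
  post-bottleneck (in vitro) artifacts or subclonal noise. The bounds
  are read as inclusive; variants without a VAF are excluded and
  tallied rather than silently dropped.
* **Autosome filter** (`autosome_filter()`): chromosomes 1–22, with or
  without a `chr` prefix. Sex chromosomes are excluded because copy
  number (and hence expected VAF) differs between donors.
* **Hypermutant filter** (`hypermutant_filter()`): samples with a tumor
  mutational burden strictly above 10 mutations/Mbp are removed before
  signature analysis, since hypermutators dominate both absolute and
  relative contribution estimates. TMB (`tmb()`) divides the SBS count
  by the mappable genome size, default 2,858,674,662 bases (the ACGT
  content of the GRCh37 assembly). The exact contig set behind that
  constant is not re-derived here; the denominator is overridable.

Variants whose trinucleotide window contains an ambiguous base are
skipped with a tally. Soft-masked (lowercase) reference bases are
uppercased before classification.

## De novo signature extraction (NMF)

`nmf_factorize()` decomposes a 96 × S catalog V into a column-stochastic
signature matrix W (96 × K) and non-negative absolute exposures H
(K × S) by minimizing the generalized Kullback–Leibler divergence with
multiplicative updates. The KL objective is the default because it is
the default of the NMF implementations conventionally used for
mutational spectra (counts with Poisson-like noise); a Frobenius
variant is available behind the `objective` flag. Initialization is
seeded uniform(0, 1]; convergence is declared when the relative change
of the objective falls below `tol = 1e-6`, with a cap of 10,000
updates. After convergence W is rescaled to column sums of 1 and the
scale moved into H, so `W %*% H` is unchanged and H is interpretable as
mutation counts.

Rank selection follows the consensus procedure: `consensus_cophenetic()`
repeats the factorization from `n_runs` random restarts (100 is the
convention; the run index perturbs the seed deterministically), records
for every pair of samples how often they share a dominant (argmax
exposure, ties to the lowest index) signature, and summarizes the
stability of the resulting consensus matrix by the cophenetic
correlation of its average-linkage dendrogram. `select_rank()` scans a
rank range and suggests the largest rank whose cophenetic correlation
is at least 0.95 before the first drop larger than 0.05. Both
thresholds are heuristic: the suggestion is advisory and headline
analyses should fix the rank explicitly after inspecting the table.
Two degenerate cases are handled explicitly: a consensus in which all
samples always co-cluster is reported as cophenetic 1 with a warning,
and a flat high curve yields the largest rank with a warning.

On clean, strongly dominated synthetic samples the cophenetic stays
near 1 well past the planted rank — over-factorized components absorb
negligible exposure and never contest the argmax, so instability never
materializes. The planted-rank recovery test therefore uses noisy,
balanced mixtures (30 samples × 200 mutations, Dirichlet-distributed
weights with shape 3), where extra components chase sampling noise and
destabilize the consensus beyond the true rank. This is worth knowing
when applying the scan to real cohorts: a flat cophenetic curve is not
evidence for a high rank.

## Refitting and spectrum comparisons

`refit_nnls()` estimates, per sample, the non-negative exposures that
minimize the Euclidean distance between the observed 96-vector and the
signature mixture — the standard non-negative least squares refit. The
solver is a Lawson–Hanson active-set implementation (`nnls_solve()`),
exact on noiseless mixtures; tests cross-check it against an
independent solver and a brute-force grid oracle. Relative
contributions divide by the per-sample total, with all-zero samples
flagged `NA` rather than 0/0.

Spectra are compared by cosine similarity (`cosine_sim()`,
`match_to_reference()`) and by the signed difference of two normalized
spectra (`difference_spectrum()`). Cohort-level contrasts of
contribution values use the two-sided Wilcoxon rank-sum test
(`cohort_contrast()`), exact for combined sizes up to 25 without ties
and the tie-corrected normal approximation otherwise.

Refit accuracy on multinomial catalogs depends on how distinguishable
the signature profiles are. Real signatures are peaked; with the
signature-17-like profile plus two sparse random profiles, planted
mixing proportions are recovered to within ±0.03 (every signature,
every sample) at 10,000 mutations per sample, and with Pearson
correlation above 0.95 already at 5,000. A perfectly flat profile in
the basis degrades the worst-case error, which is why the planted-truth
tests use peaked profiles.

## Per-mutation attribution

Given a sample's exposures and the signature probabilities, the
probability that one mutation of class c arose from signature x is the
exposure-weighted share

$$
L_x(c) = \frac{e_x \, p_x(c)}{\sum_s e_s \, p_s(c)},
$$

which sums to 1 over signatures whenever some active signature places
mass on c (`attribution_likelihood()`). Classes on which no active
signature places mass are marked unattributable (`NA`) rather than
given an arbitrary label. A mutation is assigned to a signature when
its likelihood strictly exceeds 0.5 (`assign_origin()`) — at most one
signature can qualify — and cohort-level activity is the cumulative sum
of likelihood vectors (`cohort_cumulative()`), whose grand total equals
the number of attributable mutations.

## Clonality timing

The variant ploidy score is the purity-adjusted allele fraction times
the local total copy number (`variant_ploidy()`); a heterozygous clonal
variant in a diploid region scores 1. Scores above 1 are clonal by
definition. For scores at or below 1, `detect_subclonal_peaks()`
evaluates a Gaussian kernel density (bandwidth 0.05, the value
conventionally used for these distributions) on a grid of step 0.01
over [0, max + 3·bandwidth] and takes strict local maxima as peaks;
`classify_clonality()` assigns each sub-unity variant to the nearest
peak, subclonal if that peak lies below 1 − bandwidth. Two choices here
are ours: the nearest-peak assignment rule (the notion of a variant
being "present in a peak" is not otherwise operationalized) and a peak
height floor of 1% of the density maximum, which suppresses spurious
strict maxima caused by floating-point wiggles in regions of
essentially zero density. The subclonal search requires at least 10
sub-unity variants; all detected subclonal peaks are reported rather
than only the largest.

Samples enter the clonal-versus-subclonal contrast
(`clonal_subclonal_contrast()`) only with at least 500 subclonal
mutations and an overall focal-signature contribution of at least 5%
(both inclusive). Variants lacking adjusted VAF or copy number are
unassigned and excluded from compartment catalogs.

## Strand bias

Replication- and transcription-strand analysis restricts to mutations
with a C[N>N]T pyrimidine-normalized context (`select_cnt_context()`):
the hallmark classes of the focal signature share this envelope, and
the non-T>G members serve as in-context controls. Sample inclusion
requires a strictly greater than 2,000 absolute and strictly greater
than 25% relative signature contribution
(`high_contribution_filter()`).

Strand assignment keys on where the pyrimidine of the mutated pair
lies. For replication, annotated regions carry the role (leading or
lagging) of the reference plus strand; a variant whose reference base
is a pyrimidine takes that label directly and a purine-reference
variant takes the opposite (`assign_replication_strand()`). Published
analyses do not always state which strand their labels refer to, so
the convention here is documented and covered by a symmetry test
(flipping the annotation flips every assignment); if a cohort's labels
follow the mirrored convention, the two columns swap. For
transcription, the pyrimidine lying on the template strand (the
complement of the gene strand) is "transcribed"; overlapping genes of
opposite orientation yield unassigned (`assign_transcription_strand()`).

Counts are tabulated per substitution class
(`strand_count_matrix()`) and asymmetry is tested by the exact
conditional formulation of the two-rate Poisson comparison: given the
total N, the count on one strand is Binomial(N, 1/2) under the null,
and the two-sided p doubles the smaller tail, capped at 1
(`poisson_asymmetry_test()`). An asymptotic rate-ratio variant is
available behind a flag. Per-class p-values are reported raw, matching
the per-class annotation convention for these figures, with
Benjamini–Hochberg values emitted alongside.

## Paired biopsies

For patients biopsied before and after treatment, each patient's
samples are normalized together by the median-of-ratios size-factor
algorithm (`median_ratio_normalize()`, applied per patient by
`normalize_paired()`), which removes differences in total mutation
yield without assuming any particular mutation type is unchanged.
Types with a zero count in any sample are excluded from factor
estimation only.

`fit_type_model()` then fits, for one mutation type, a linear mixed
model of the normalized count on per-drug exposure indicators (1 for
biopsies taken after the patient received that drug), co-treatment
dose and exposure-time totals, and a patient-level random intercept.
Only drugs given to at least 3 patients enter the model. The focal
drug's p-value is the conditional F-test of its term from an ANOVA on
the fitted model; a likelihood-ratio comparison against the model
without the focal term is available via `method = "lrt"`. Two modeling
choices deserve comment. First, the random-effects structure for dose
and exposure time is under-determined at a cohort of 8–20 patients; a
patient random intercept with dose/time as fixed covariates is
identifiable at that size, and the conditional F-test is well
calibrated there (the likelihood-ratio chi-square is anticonservative
at 40 observations). Second, the dose and time covariates sum over the
*non-focal* drugs: a drug's own dose is part of the exposure being
tested, and entering it as a separate fixed competitor would absorb
the very effect the indicator measures. `scan_all_types()` iterates
over all 96 types in canonical order, reporting raw p-values (the
headline convention) with BH-adjusted values alongside; both absolute
(median-ratio normalized) and relative count modes are provided
because published descriptions use both.

## Driver-mutation risk model

The expected number of driver-activating mutations introduced into N
cells by a process with spectrum P is

$$
M^{\mathrm{active}} = f_{\mathrm{coding}} \cdot dp \cdot N \cdot \mu
  \cdot \sum_c P_c \frac{n_c}{L},
$$

with defaults: coding fraction 0.015, coding-sequence mutational
depletion dp = 0.3094464, CDS length L = 22,563,618 bp, and n_c the
number of positions whose class-c mutation activates a driver gene
(`build_oncogenic_table()` derives n from a driver-variant list,
collapsing duplicate positions). μ is parameterized as annual rate ×
duration in years because the headline quantities use two readings
that are not mutually consistent: the 50-fold treated-versus-baseline
ratio corresponds to equal durations at rates 2000 versus 40 per year,
while the "years of baseline mutagenesis equivalent to one regimen"
calculation uses a 24-week treatment (2000 × 24/52 / 40 ≈ 23 years).
Both readings are reproducible by setting the duration explicitly. The
germline-predisposition scenario
(`germline_predisposition_scenario()`) restricts n to the second-hit
positions of a single gene — a documented assumption, since no formula
for that scenario is otherwise fixed — and reports the fold against
the untreated scenario; no mapping from fold risk to onset age is
attempted. Reproducing the absolute "~300 oncogenic mutations per 10⁸
cells per treatment" figure requires the externally curated
driver-position table and reference signature profiles, which are not
shipped; with a synthetic table the model is validated against its
closed form and its exact linearity in N, μ and n.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its parameters and seed.

* `make_signature_set()` provides a signature-17-like profile with 36%
  mass on C[T>G]T, 14% on C[T>C]T and 10% on G[T>G]T (the hallmark
  composition) over a uniform floor, plus flat and random (Dirichlet)
  profiles. For planted-truth tests the random profiles use shape 0.3
  — sparse and peaked, as real signatures are.
* `sample_catalog()` draws multinomial catalogs from known mixtures;
  `emit_reference_and_vcf()` realizes a catalog as a toy contig (one
  padded block per mutation, every needed trinucleotide synthesized;
  well under 100 kb at test scale) plus a multi-sample VCF that
  rebuilds the catalog exactly.
* `simulate_clonality()` draws ploidy scores from a two-mode truncated
  normal mixture (clonal at 1.0, planted subclonal mode, SD 0.05).
* `simulate_paired_cohort()` emulates the serial-biopsy design: 20
  patients, 8 treated with the focal drug, ~3,000 mutations per
  biopsy from a 15% signature-17-like / 85% flat baseline, lognormal
  (SD 0.15) second-biopsy depth factors, a planted Poisson excess of
  3 baseline standard deviations on the effect types, and an inert
  co-administered drug in a random half of the cohort so that
  co-treatment covariates vary independently of the focal indicator.
* `simulate_strand_annotations()` draws per-variant strands at the
  requested lagging:leading odds and constructs a region annotation
  that reproduces the drawn truth exactly under the package's
  assignment convention.

These generators reproduce the *statistical structure* the methods
assume: multinomial class counts, two-mode ploidy distributions,
binomial strand counts, Poisson count excesses with patient random
effects. They do not emulate genome-scale sequence composition,
mutation rate variation along the genome, copy-number segmentation,
purity estimation error, or caller-specific artifacts — so passing
tests demonstrate correctness of the inference machinery under its own
model, not robustness to real-data violations of it.

## Problem sizes and determinism

The test suite runs the NMF recovery at 50 samples × 5,000 mutations
(4 restarts), the rank scan at 30 samples × 200 mutations over ranks
2–6 with 20 consensus runs, the mixed-model calibration at 200 null
and 200 powered replicates of the 20-patient cohort, and the exact
strand-test enumeration for all totals up to 200. These sizes were
chosen so each property is tested with comfortable statistical margin
while the whole suite completes in a few minutes on one CPU. All
stochastic steps take explicit seeds; rerunning any generator or test
with the same seed is byte-identical.

## Known limitations

* The NMF consensus is defined on dominant-signature sharing, which is
  coarse for samples with two nearly equal exposures; rank suggestions
  are advisory.
* The exact strand test conditions on the total count and therefore
  ignores differences in the opportunity (at-risk sequence) between
  strands; regions are consumed as pre-labeled annotations.
* The clonality module classifies; it does not estimate purity or
  copy number, and multi-peak subclonal architectures are reported but
  not phylogenetically resolved.
* The risk model excludes selection and clonal expansion dynamics; it
  is a per-cell mutation accounting identity.
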