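---
title: "Methods: immunogenomic comparison of primary TNBC and brain metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunogenomic comparison of primary TNBC and brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model and procedure implemented by
`brimmune`, the meaning and defaults of its parameters, what the synthetic
cohort generator does and does not cover, and the numerical choices that
affect results. It makes no empirical claims beyond what the package's
tests and acceptance script compute.

## 1. The analytical problem

Paired primary breast tumors and brain metastases differ in mutational
burden, immune infiltrate, and immune-receptor repertoires, and those
differences carry prognostic information. Measuring them requires a chain
of well-specified steps: somatic variant calls must be consensus-filtered
(archival FFPE tissue introduces deamination artifacts; tumor-only samples
lack a matched normal), burden must be normalized to covered territory,
neoantigen candidates enumerated from several source classes, expression
summarized into signature scores on a comparable scale, repertoire
diversity quantified, and survival association estimated with standard
clinical covariates. Each step in `brimmune` is a separate function with a
documented contract; the pipeline composes them.

## 2. Variant consensus filtering

**Matched-normal cascade** (`filter_matched`). Four rules applied in
order:

- R1: restrict to coding consequences.
- R2: per-caller strict quality gates (`matched_filter_gates()`):
  Cadabra indels > 10.5, Mutect2 indels > 6.8, Mutect2 SNVs > 9.2,
  Strelka2 indels > 15.2, Strelka2 SNVs > 19.7. Gates are strict
  inequalities; a call exactly at its gate fails.
- R3: corroboration for two low-confidence classes. Cadabra indels with
  quality < 35 and Strelka2 calls with SomaticEVS < 20 are kept only if
  another caller (Strelka2/Mutect2, respectively Mutect2/Cadabra) reports
  the identical (chrom, pos, ref, alt) *and* that mate passes its own
  gate (`corroborator_must_pass_gate = TRUE`; settable because a laxer
  reading — any co-occurrence — is defensible).
- R4: deduplication to one consensus row per variant, retaining the
  caller list, caller count, and best quality.

Cadabra SNVs have no published gate and are excluded unless
`cadabra_snv_gate` is given. The implementation is verified against an
independent per-row loop oracle over a grid that covers every branch.

**Tumor-only cascade** (`filter_tumor_only`), for samples without a
matched normal: coding; then MAF ≥ 0.05 with alt reads ≥ 5 and depth
≥ 40, or MAF < 0.05 with alt reads ≥ 10 and depth ≥ 80; normal MAF
≤ 0.05 (panel-of-normals style control) and maximum population allele
frequency ≤ 0.01 where annotated (absent annotations do not reject);
finally the FFPE rule: literal C>T or G>A substitutions need MAF ≥ 0.10.
The pair list is deliberately *not* expanded to reverse-complements: the
rule is applied to ref/alt exactly as written in the calls, matching how
deamination filters are applied to caller output in practice.

## 3. Burden, sharing, and copy-number segments

`compute_tmb` divides retained variants by adequately covered megabases;
`covered_megabases` sums target intervals with depth ≥ 20 (a conventional
adequacy threshold; configurable). Matched pairs are compared by exact
variant-key set operations (`pair_sharing`): Jaccard index and the shared
fraction of each side.

`sequenza_to_gistic_seg` maps a depth ratio r to `Seg.CN = log2(r) − 1`.
This is the transformation as used upstream of region-level significance
analysis, and it maps a copy-neutral ratio of 1 to −1, not 0. The
function documents this explicitly rather than silently recentering;
ratios ≤ 0 are an error naming the offending segment.

## 4. Neoantigen enumeration and binder classes

Peptide lengths are 8–11 (MHC class I). For an SNV at protein position p,
every window of length k covering p is emitted; an interior position
yields exactly k windows per length, 38 in total. Frameshifts translate
the mutant CDS in the shifted frame to the first stop codon; translation
deliberately disables alternative-initiator handling so a mid-gene
sub-sequence starting with TTG/CTG is not misread as methionine. Fusions
emit junction-spanning windows.

All indel/fusion emission reduces to one novelty rule
(`enumerate_novel_kmers`): a k-mer of the mutant protein is a candidate
iff it is not a substring of the reference protein. This single rule gives
the expected special cases — novel C-terminal tails for frameshifts,
junction-only windows for in-frame indels — without per-case logic.
`novel_positions` reports mismatch positions against the best-matching
reference window.

Expression-only antigen classes (cancer/testis, endogenous retrovirus,
viral) are called expressed above a normalized log2 threshold (default 1;
configuration, not a published constant), and somatic candidates can be
restricted to RNA-confirmed variants (`rna_confirm_variants`).

Affinity prediction is an interface: any function
`(peptides, allele) -> data.frame(peptide, allele, kd_nm)` plugs in. The
bundled `toy_affinity_predictor` is deterministic (fixed sinusoidal
position weights hashed from the allele name, mapped exponentially onto
1–50,000 nM), consumes no RNG state, and exists to exercise the machinery
reproducibly — its Kd values carry no biological meaning. Binder classes
are strict: positive Kd < 500 nM, strong Kd < 50 nM, minimum over
alleles, each peptide counted once per source class.

## 5. Expression scoring

Samples under 2×10⁷ coding reads are excluded (inclusive cutoff).
Upper-quartile normalization scales each sample so the 75th percentile of
its *nonzero* counts (type-7 quantile) equals the geometric mean of those
percentiles across samples, then applies log2(x+1). The order matters:
the percentile contract is checked on the linear scale because the type-7
quantile does not commute with the log transform. Technical replicates
are averaged after normalization on the log2 scale.

A signature's metagene score is the per-sample median of log2 expression
over the signature's genes present in the matrix (missing genes are
dropped; a fully absent signature is an error, not a silent zero).
Scores are z-scored per signature across samples; groups are compared by
a two-sided Wilcoxon rank-sum without continuity correction — chosen so
identical group multisets give p = 1 exactly — and adjusted by
Benjamini–Hochberg across the full signature family. Direction is
sign(median A − median B) with groups taken alphabetically by default
(for site labels, A = "brm", B = "primary").

## 6. Repertoire diversity

Clonotype identity is chain + CDR3; duplicates aggregate their reads.
Diversity uses the plug-in Shannon entropy in nats and the Chao–Shen
coverage-corrected estimator (coverage C = 1 − f₁/n from singletons,
Horvitz–Thompson inflation), which counters the downward bias of the
plug-in estimator in under-sampled repertoires. Group comparisons use
log10(x+1) for read counts (spanning orders of magnitude) and raw values
for entropies; samples lacking a chain are flagged in the output rather
than imputed.

## 7. Survival

`build_survival_table` measures time from one of three origins (primary
diagnosis, first metastasis, brain metastasis); patients lacking the
origin date are excluded with a reported count. `fit_cox` wraps
`survival::coxph` with the Efron approximation for ties (day-resolution
data ties routinely), stage as ordinal-linear 1–4 by default (categorical
contrasts optional), race one-hot with the largest group as reference,
and signature scores one at a time (`signature_survival_scan`).
Convergence warnings and likelihood diagnostics are attached to the
result; a non-converged fit is returned flagged, never hidden.

## 8. The synthetic cohort generator

`simulate_cohort(cohort_config())` generates, from one integer seed, a
25-patient cohort shaped like the study design: 15 primary and 19 BrM
samples, 9 matched pairs, two tumor-only BrM exomes and two BrM samples
without WES; somatic variants at 1.8 (primary) and 3.3 (BrM) true
mutations/Mb over 30 Mb with shared truncal variants in pairs; per-caller
detection and quality draws labelled with generator-side ground truth
(`should_pass`); FFPE artifacts (5/Mb, C>T/G>A, MAF < 0.10) and
population contaminants in tumor-only samples; negative-binomial
expression (dispersion 0.1) with a 2-standard-deviation depression
planted on 10 immune signatures and an elevation on a wound-healing
signature in BrM; Zipf-distributed clonotypes (richness 150 vs 60, reads
5,000 vs 500, exponent 1.0 vs 1.4); and exponential survival from BrM
diagnosis (median 438 days) with log-hazard contributions from stage,
age, and a latent score, 20% censored. These defaults *are* the study
conditions; `evaluate_recovery` compares pipeline output against the
planted truth.

The generator's scope is deliberately limited, and passing tests must be
read accordingly: it plants effects under the package's own model family
(negative-binomial counts, exponential survival, independent genes within
signatures, caller errors independent across callers). Recovery therefore
demonstrates internal consistency and correct implementation of each
contract — not robustness to misspecification, batch effects, correlated
genes, subclonal structure, or real caller error modes, none of which are
modelled. Problem sizes (25 patients, 1,000 genes, 32 signatures) are the
package's own choices to keep the full pipeline runnable in about a
minute on one CPU.

## 9. Numerical choices

- Strict vs inclusive boundaries follow each rule's published wording:
  quality gates and binder thresholds strict; support/QC minimums
  inclusive.
- Doubles are serialized with 17 significant digits so written tables
  round-trip bit-exactly, which is what makes byte-identical determinism
  of repeated runs testable.
- Derived seeds are computed modulo 2³¹−1 so every `set.seed` argument is
  a valid 32-bit integer; `local_seed` restores the caller's RNG state.
- Wilcoxon tests use the exact distribution where R provides it and the
  normal approximation when ties make the exact p-value unavailable
  (discrete TMB values); the continuity correction is disabled
  throughout (see section 5).
- BH adjustment is applied once per declared family (the 32 signatures;
  the per-chain repertoire comparisons), never pooled across analyses.

## 10. Running the pipeline

```{r}
library(brimmune)
res <- run_pipeline(cohort_config(seed = 1), out_dir = "out")
res$results$tmb_comparison
rec <- evaluate_recovery(res$results,
                         simulate_cohort(cohort_config(seed = 1))$truth)
```

The command-line wrapper `inst/scripts/brimmune.R` and the acceptance
script `scripts/acceptance.R` expose the same entry point; all outputs
are plain-text tables plus a manifest with MD5 checksums.

## Limitations

Beyond the generator scope above: the affinity predictor is a
deterministic stand-in; the FFPE rule operates on literal strand
annotation; the segment transformation's −1 offset must be taken into
account by downstream consumers; tumor-only filtering cannot remove
germline leakage absent from its annotation fields; and the survival
models assume proportional hazards and treat stage as linear by default.
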