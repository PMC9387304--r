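# brimmune

Immunogenomic comparison of primary triple-negative breast cancer (TNBC)
and brain metastases (BrM), as a tested, deterministic R pipeline.

Matched primary/metastasis cohorts are small, heavily FFPE-archived, and
their patient-level data are controlled-access, so the analytical pipeline
itself — variant consensus filtering, tumor mutational burden (TMB),
neoantigen enumeration, immune expression scoring, immune-repertoire
diversity, and survival modeling — is where reproducibility must live.
`brimmune` implements each stage as an importable, unit-tested function,
and ships a seeded synthetic cohort generator with planted ground truth so
that every stage can be exercised and verified end to end without access
to any patient data.

The package is aimed at computational biologists building or reviewing
tumor-immunogenomics analyses who need the individual steps to be
inspectable and testable rather than buried in one monolithic script.

## Methods

**Somatic variant consensus (matched normal).** Calls from three callers
(Strelka2, Mutect2, Cadabra) are restricted to coding consequences, then
gated per caller and variant class on quality Q: Cadabra indels Q > 10.5,
Mutect2 indels Q > 6.8 / SNVs Q > 9.2, Strelka2 indels Q > 15.2 / SNVs
Q > 19.7. Two low-confidence classes additionally require cross-caller
corroboration by a gate-passing mate at the same (chrom, pos, ref, alt):
Cadabra indels with Q < 35, and Strelka2 calls with SomaticEVS < 20.
Survivors are deduplicated into one consensus row per variant with caller
provenance. Cadabra SNVs are excluded by default (no published gate); an
explicit gate can be supplied.

**Tumor-only cascade.** Coding Mutect2 calls pass when allele fraction
(MAF) ≥ 0.05 with ≥ 5 alt reads and depth ≥ 40, or MAF < 0.05 with
≥ 10 alt reads and depth ≥ 80; matched-normal-free germline control uses
normal MAF ≤ 0.05 and population allele frequency ≤ 0.01; FFPE cytosine
deamination is suppressed by requiring MAF ≥ 0.10 for literal C>T and
G>A substitutions.

**TMB and sharing.** TMB = retained variants / adequately covered
megabases (intervals with depth ≥ 20 by default). Matched pairs are
compared by exact key intersection (Jaccard index and per-site shared
fractions). Sequenza segments convert to GISTIC SEG via
`Seg.CN = log2(depth ratio) − 1` (note: neutral ratio 1 maps to −1).

**Neoantigens.** Candidate peptides of length 8–11: SNVs yield every
window covering the mutated residue (Σ<sub>k=8..11</sub> k = 38 for
interior positions); frameshifts are translated in the shifted frame to
the first stop codon; fusions yield junction-spanning windows. The shared
novelty rule emits k-mers of the mutant protein absent from the reference
protein. A deterministic toy affinity predictor (fixed position weights
hashed from the allele name, Kd in 1–50,000 nM) exercises the interface;
any `(peptides, allele) -> data.frame(peptide, allele, kd_nm)` function
can be plugged in. Binders: Kd < 500 nM positive, < 50 nM strong, with
the minimum over alleles per peptide.

**Immune expression.** Samples with < 20 M coding reads are excluded.
Counts are upper-quartile normalized (per-sample nonzero 75th percentiles
equalized to their geometric mean), log2(x+1)-transformed, and technical
replicates averaged on the log scale. A signature's metagene score is the
per-sample median over its genes; groups are compared by two-sided
Wilcoxon rank-sum on z-scored signatures with Benjamini–Hochberg
adjustment across the 32-signature family.

**Repertoire.** Clonotypes (chain + CDR3) are summarized per sample and
chain by total reads, richness, plug-in Shannon entropy
(−Σ p<sub>i</sub> ln p<sub>i</sub>) and the Chao–Shen coverage-corrected
estimator. Read counts are compared on log10(x+1); entropies raw.

**Survival.** Time-to-event tables from three origins (primary diagnosis,
first metastasis, brain metastasis) feed Cox proportional-hazards models
(Efron ties) with stage (ordinal-linear by default), age, race (one-hot,
largest group as reference), and one signature score at a time;
non-convergence is flagged on the result, never silently dropped.

## Worked example

```r
library(brimmune)

# A low-quality Cadabra indel (Q = 20 < 35) rescued by a gate-passing
# Strelka2 call at the same locus:
calls <- rbind(
  data.frame(sample_id = "T1", caller = "cadabra", chrom = "chr17",
             pos = 7675088L, ref = "C", alt = "CT", variant_class = "indel",
             coding = TRUE, quality = 20, somatic_evs = NA,
             alt_reads = NA_integer_, depth = NA_integer_, maf = NA_real_,
             normal_maf = NA_real_, pop_af_max = NA_real_),
  data.frame(sample_id = "T1", caller = "strelka2", chrom = "chr17",
             pos = 7675088L, ref = "C", alt = "CT", variant_class = "indel",
             coding = TRUE, quality = 22, somatic_evs = 31,
             alt_reads = NA_integer_, depth = NA_integer_, maf = NA_real_,
             normal_maf = NA_real_, pop_af_max = NA_real_))
consensus <- filter_matched(calls)
consensus
#>   sample_id chrom     pos ref alt variant_class          callers n_callers best_quality
#> 1        T1 chr17 7675088   C  CT         indel cadabra,strelka2         2           22

compute_tmb(consensus, covered_mb = 30)
#>   sample_id n_variants covered_mb        tmb
#> 1        T1          1         30 0.03333333

# Neoantigen candidates for a p53 S10L substitution:
peps <- enumerate_snv_peptides("MEEPQSDPSVEPPLSQETFSDLWKLLPEN", 10, "L")
nrow(peps)   # 37 windows (position 10 truncates the 11-mers to 10)
#> [1] 37
head(peps[, c("peptide", "novel_positions")], 3)
#>    peptide novel_positions
#> 1 EPQSDPSL               8
#> 2 PQSDPSLE               7
#> 3 QSDPSLEP               6

aff <- predict_affinities(peps, c("HLA-A*02:01", "HLA-B*07:02"))
classify_binders(aff)[, c("source_class", "n_candidates", "n_positive", "n_strong")]
#>   source_class n_candidates n_positive n_strong
#> 1          snv           37         37        7

# Repertoire diversity of a skewed 5-clonotype sample:
shannon_entropy(c(120, 40, 25, 10, 5))     # 1.130322 nats
chao_shen_entropy(c(120, 40, 25, 10, 5))   # 1.130914 (no singletons: ~plug-in)
```

Running the whole pipeline on the default synthetic cohort (25 patients,
15 primary / 19 BrM samples, 9 matched pairs):

```r
res <- run_pipeline(cohort_config(seed = 1), out_dir = "out")
res$results$tmb_comparison
#>   median_tmb_primary median_tmb_brm            p
#> 1          0.9487179          1.825 1.457635e-06
```

The planted site difference (1.8 vs 3.3 mutations/Mb before consensus
filtering) is recovered in direction with a strongly significant
rank-sum test; 12 of 32 signatures reach q < 0.05, with all 11 planted
effects detected and a false-positive rate of 1/21 at this seed.

Or from the command line:

```sh
Rscript inst/scripts/brimmune.R run --out out --seed 1
```

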