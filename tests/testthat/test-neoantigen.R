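test_that("SNV window enumeration matches the exhaustive oracle and closed form", {
  protein <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"  # 33 aa, interior mutation
  pos <- 15L
  peps <- enumerate_snv_peptides(protein, pos, "W")
  # interior position: k windows for each k, sum over 8..11 = 38
  expect_equal(nrow(peps), 38L)
  expect_equal(as.vector(table(nchar(peps$peptide))), c(8L, 9L, 10L, 11L))
  for (k in 8:11) {
    got <- sort(peps$peptide[nchar(peps$peptide) == k])
    expect_equal(got, sort(oracle_snv_windows(protein, pos, "W", k)))
  }
  # every window carries the substituted residue at its annotated position
  novel <- as.integer(peps$novel_positions)
  expect_true(all(substr(peps$peptide, novel, novel) == "W"))
  expect_true(all(peps$source_class == "snv"))
})

test_that("SNV windows are truncated at protein boundaries", {
  protein <- paste(rep("A", 40), collapse = "")
  first <- enumerate_snv_peptides(protein, 1L, "C")
  expect_equal(nrow(first), 4L)  # one window per length
  expect_true(all(substr(first$peptide, 1, 1) == "C"))
  last <- enumerate_snv_peptides(protein, 40L, "C")
  expect_equal(nrow(last), 4L)
  near_edge <- enumerate_snv_peptides(protein, 3L, "C")
  expect_equal(nrow(near_edge), 12L)  # 3 windows per length
  for (k in 8:11) {
    expect_equal(sort(near_edge$peptide[nchar(near_edge$peptide) == k]),
                 sort(oracle_snv_windows(protein, 3L, "C", k)))
  }
})

test_that("SNV enumeration rejects degenerate substitutions", {
  protein <- paste(rep("A", 20), collapse = "")
  expect_error(enumerate_snv_peptides(protein, 5L, "A"), "reference")
  expect_error(enumerate_snv_peptides(protein, 5L, "*"), "stop")
  expect_error(enumerate_snv_peptides(protein, 0L, "C"))
  expect_error(enumerate_snv_peptides(protein, 21L, "C"))
})

test_that("CDS translation stops at the first stop codon, matching the codon-table oracle", {
  expect_equal(oracle_translate_to_stop("ATGAAATTTTAG"), "MKF")
  nts <- c("A", "C", "G", "T")
  set.seed(401)
  for (i in 1:50) {
    n_codons <- sample(5:40, 1)
    cds <- paste(sample(nts, 3 * n_codons, replace = TRUE), collapse = "")
    got <- suppressWarnings(brimmune:::.translate_to_stop(cds, warn_no_stop = FALSE))
    expect_identical(got, oracle_translate_to_stop(cds))
  }
})

test_that("frameshift peptides come from the shifted frame and validate the ref base", {
  # ATG + 9 x GCT (poly-A protein) + stop; insert A after position 10
  cds <- paste0("ATG", strrep("GCT", 9), "TAA")
  expect_error(enumerate_frameshift_peptides(cds, 10L, "C", "CA"),
               "does not match")
  # the shift destroys the downstream stop, which the function reports
  fp <- expect_warning(enumerate_frameshift_peptides(cds, 10L, "G", "GA"),
                       "no stop codon")
  # every emitted peptide is absent from the reference protein
  ref_protein <- oracle_translate_to_stop(cds)
  expect_true(all(!vapply(fp$peptide, grepl, logical(1),
                          x = ref_protein, fixed = TRUE)))
  expect_true(all(fp$source_class == "indel"))
  # and each peptide is a substring of the oracle-translated mutant protein
  mutant_cds <- paste0(substr(cds, 1, 10), "A", substr(cds, 11, nchar(cds)))
  mutant_protein <- suppressWarnings(oracle_translate_to_stop(mutant_cds))
  expect_true(all(vapply(fp$peptide, grepl, logical(1),
                         x = mutant_protein, fixed = TRUE)))
})

test_that("novel k-mer extraction emits exactly the windows absent from the reference", {
  ref <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ"
  # in-frame deletion of 3 residues: only junction-spanning windows are novel
  mut <- paste0(substr(ref, 1, 20), substr(ref, 24, nchar(ref)))
  out <- enumerate_novel_kmers(mut, ref, source_class = "indel")
  for (k in 8:11) {
    got <- sort(out$peptide[nchar(out$peptide) == k])
    expect_equal(got, sort(oracle_novel_kmers(mut, ref, k)))
    # deletion junction: exactly k-1 windows straddle it
    expect_equal(length(got), k - 1L)
  }
  # identical proteins produce nothing
  expect_equal(nrow(enumerate_novel_kmers(ref, ref, source_class = "indel")), 0L)
})

test_that("fusion peptides span the breakpoint junction", {
  p5 <- paste(rep("A", 20), collapse = "")
  p3 <- paste(rep("C", 20), collapse = "")
  fu <- enumerate_fusion_peptides(p5, p3, breakpoint_5p = 20L,
                                  breakpoint_3p = 1L)
  # long partners: k-1 junction-spanning windows per length
  expect_equal(as.vector(table(nchar(fu$peptide))), c(7L, 8L, 9L, 10L))
  # every window contains both partners' residues
  expect_true(all(grepl("A", fu$peptide) & grepl("C", fu$peptide)))
  expect_true(all(fu$source_class == "fusion"))
  # junction sequence check: windows are prefixes of A^i C^j
  expect_true(all(grepl("^A+C+$", fu$peptide)))
  # short 5' stub limits the window count
  fu2 <- enumerate_fusion_peptides("AAA", p3, breakpoint_5p = 3L,
                                   breakpoint_3p = 1L)
  expect_equal(sum(nchar(fu2$peptide) == 8), 3L)
})

test_that("toy affinity predictor is deterministic, bounded, and leaves RNG state alone", {
  peps <- c("SIINFEKL", "AAAAAAAA", "KVAELVHFL", "MMMMMMMMMM")
  a1 <- toy_affinity_predictor(peps, "HLA-A*02:01")
  a2 <- toy_affinity_predictor(peps, "HLA-A*02:01")
  expect_identical(a1, a2)
  expect_true(all(a1$kd_nm > 0 & a1$kd_nm <= 50000))
  b <- toy_affinity_predictor(peps, "HLA-B*07:02")
  expect_false(all(a1$kd_nm == b$kd_nm))
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(toy_affinity_predictor(peps, "HLA-A*02:01"))
  after <- runif(5)
  expect_identical(before, after)
  expect_error(toy_affinity_predictor("SHORT", "HLA-A*02:01"), "8-11")
})

test_that("binder classification uses strict thresholds and min over alleles", {
  mk <- function(peptide, allele, kd) {
    data.frame(sample_id = "S1", source_class = "snv", peptide = peptide,
               source_id = "g1", novel_positions = "1", allele = allele,
               kd_nm = kd, stringsAsFactors = FALSE)
  }
  preds <- rbind(
    mk("AAAAAAAA", "A1", 500), mk("AAAAAAAA", "A2", 499.999),  # min < 500
    mk("CCCCCCCC", "A1", 500), mk("CCCCCCCC", "A2", 600),      # min == 500
    mk("DDDDDDDD", "A1", 50),                                  # not strong
    mk("EEEEEEEE", "A1", 49.999)                                # strong
  )
  cls <- classify_binders(preds)
  expect_equal(cls$n_candidates, 4L)
  expect_equal(cls$n_positive, 3L)  # A, D, E (kd < 500 strictly)
  expect_equal(cls$n_strong, 1L)    # E only (kd < 50 strictly)
})

test_that("a peptide shared by two sources counts once per source class", {
  mk <- function(class, peptide, kd) {
    data.frame(sample_id = "S1", source_class = class, peptide = peptide,
               source_id = "g", novel_positions = "1", allele = "A1",
               kd_nm = kd, stringsAsFactors = FALSE)
  }
  preds <- rbind(mk("snv", "AAAAAAAA", 10), mk("snv", "AAAAAAAA", 10),
                 mk("indel", "AAAAAAAA", 10))
  cls <- classify_binders(preds)
  expect_equal(nrow(cls), 2L)
  expect_equal(sum(cls$n_candidates), 2L)  # deduplicated within class
  expect_equal(sum(cls$n_strong), 2L)
})

test_that("RNA confirmation keeps only supported variants", {
  vs <- filter_matched(rbind(
    make_call(caller = "mutect2", pos = 1, quality = 50),
    make_call(caller = "mutect2", pos = 2, quality = 50),
    make_call(caller = "mutect2", pos = 3, quality = 50)
  ))
  support <- c("chr1:1:A:G" = 4, "chr1:2:A:G" = 0)
  kept <- rna_confirm_variants(vs, support)
  expect_equal(kept$pos, 1L)  # pos 2 has zero reads, pos 3 is absent
  kept2 <- rna_confirm_variants(vs, support, min_rna_reads = 5)
  expect_equal(nrow(kept2), 0L)
})

test_that("expressed antigen calling thresholds normalized expression", {
  m <- matrix(c(0.5, 2, 3, 1, 0, 5), nrow = 3,
              dimnames = list(c("MAGEA1", "ERVK1", "HPV16_E6"),
                              c("s1", "s2")))
  fc <- c(MAGEA1 = "cta_self", ERVK1 = "erv", HPV16_E6 = "viral")
  out <- call_expressed_antigens(expr_matrix(m, normalized = TRUE), fc,
                                 threshold = 1)
  expect_equal(nrow(out), 3L)  # 2 and 3 in s1; 5 in s2; 1 is not > 1
  expect_equal(out$gene[out$sample_id == "s2"], "HPV16_E6")
  expect_error(
    call_expressed_antigens(expr_matrix(m, normalized = TRUE),
                            c(MAGEA1 = "bogus")),
    "bogus")
})
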