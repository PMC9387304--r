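test_that("per-caller gates match the published thresholds exactly", {
  g <- matched_filter_gates()
  expect_equal(g$cadabra_indel, 10.5)
  expect_equal(g$mutect2_indel, 6.8)
  expect_equal(g$mutect2_snv, 9.2)
  expect_equal(g$strelka2_indel, 15.2)
  expect_equal(g$strelka2_snv, 19.7)
  expect_equal(g$cadabra_rescue, 35)
  expect_equal(g$strelka2_evs, 20)
})

test_that("worked matched-mode examples behave as documented", {
  # high-quality cadabra indel: no corroboration needed
  a <- make_call(caller = "cadabra", ref = "A", alt = "AT", quality = 40)
  expect_equal(nrow(filter_matched(a)), 1L)

  # below gate: rejected outright
  b <- make_call(caller = "cadabra", ref = "A", alt = "AT", quality = 10.5)
  expect_equal(nrow(filter_matched(b)), 0L)

  # low-confidence band [10.5, 35): needs a gate-passing mate
  c1 <- make_call(caller = "cadabra", ref = "A", alt = "AT", quality = 20)
  expect_equal(nrow(filter_matched(c1)), 0L)
  mate <- make_call(caller = "strelka2", ref = "A", alt = "AT",
                    quality = 16, somatic_evs = 30)
  both <- filter_matched(rbind(c1, mate))
  expect_equal(nrow(both), 1L)
  expect_equal(both$callers, "cadabra,strelka2")
  expect_equal(both$n_callers, 2L)

  # a mate that fails its own gate cannot rescue
  weak_mate <- make_call(caller = "strelka2", ref = "A", alt = "AT",
                         quality = 15.2, somatic_evs = 30)
  expect_equal(nrow(filter_matched(rbind(c1, weak_mate))), 0L)

  # strelka2 with low SomaticEVS needs mutect2/cadabra corroboration
  s <- make_call(caller = "strelka2", quality = 25, somatic_evs = 10)
  expect_equal(nrow(filter_matched(s)), 0L)
  m <- make_call(caller = "mutect2", quality = 12)
  expect_equal(nrow(filter_matched(rbind(s, m))), 1L)

  # non-coding calls never pass
  nc <- make_call(caller = "mutect2", quality = 50, coding = FALSE)
  expect_equal(nrow(filter_matched(nc)), 0L)

  # cadabra SNVs are dropped by default but admit an explicit gate
  csnv <- make_call(caller = "cadabra", quality = 100)
  expect_equal(nrow(filter_matched(csnv)), 0L)
  expect_equal(nrow(filter_matched(csnv, cadabra_snv_gate = 50)), 1L)
})

test_that("matched filtering agrees with the brute-force oracle on the branch grid", {
  grid <- build_matched_grid()
  expect_gte(nrow(grid), 400L)
  got <- consensus_keys(filter_matched(grid))
  want <- oracle_filter_matched(grid)
  expect_identical(got, want)
})

test_that("matched retention is monotone in quality", {
  for (caller in c("mutect2", "strelka2", "cadabra")) {
    class <- if (caller == "cadabra") "indel" else "snv"
    alleles <- if (class == "snv") c("A", "G") else c("A", "AT")
    qs <- seq(0, 60, by = 0.5)
    kept <- vapply(qs, function(q) {
      call <- make_call(caller = caller, ref = alleles[1], alt = alleles[2],
                        quality = q, somatic_evs = 30)
      nrow(filter_matched(call)) == 1L
    }, logical(1))
    # once retained at quality q, retained at every higher quality
    expect_true(all(diff(as.integer(kept)) >= 0), info = caller)
  }
})

test_that("deduplication keeps one consensus row with caller provenance", {
  calls <- rbind(
    make_call(caller = "mutect2", quality = 50),
    make_call(caller = "strelka2", quality = 30, somatic_evs = 25),
    make_call(caller = "mutect2", pos = 200, quality = 50)
  )
  cs <- filter_matched(calls)
  expect_equal(nrow(cs), 2L)
  row1 <- cs[cs$pos == 100, ]
  expect_equal(row1$callers, "mutect2,strelka2")
  expect_equal(row1$n_callers, 2L)
  expect_equal(row1$best_quality, 50)
  expect_equal(cs$n_callers[cs$pos == 200], 1L)
})

test_that("worked tumor-only examples behave as documented", {
  base <- function(...) make_call(caller = "mutect2", quality = 30, ...)
  # relaxed support path: maf >= 0.05 with 5/40
  expect_equal(nrow(filter_tumor_only(
    base(maf = 0.2, alt_reads = 5, depth = 40))), 1L)
  # low-frequency path requires 10/80
  expect_equal(nrow(filter_tumor_only(
    base(maf = 0.04, alt_reads = 9, depth = 100))), 0L)
  expect_equal(nrow(filter_tumor_only(
    base(maf = 0.04, alt_reads = 10, depth = 80))), 1L)
  # germline leakage via normal fraction
  expect_equal(nrow(filter_tumor_only(
    base(maf = 0.3, alt_reads = 20, depth = 100, normal_maf = 0.06))), 0L)
  # population polymorphism
  expect_equal(nrow(filter_tumor_only(
    base(maf = 0.3, alt_reads = 20, depth = 100, pop_af_max = 0.02))), 0L)
  # deamination signature: C>T below 10% rejected, at 10% kept
  expect_equal(nrow(filter_tumor_only(
    base(ref = "C", alt = "T", maf = 0.08, alt_reads = 8, depth = 100))), 0L)
  expect_equal(nrow(filter_tumor_only(
    base(ref = "C", alt = "T", maf = 0.10, alt_reads = 10, depth = 100))), 1L)
  # the rule is literal C>T / G>A only: T>C at 8% passes
  expect_equal(nrow(filter_tumor_only(
    base(ref = "T", alt = "C", maf = 0.08, alt_reads = 8, depth = 100))), 1L)
})

test_that("tumor-only filtering agrees with the brute-force oracle on the clause grid", {
  grid <- build_tumor_only_grid()
  expect_gte(nrow(grid), 2000L)
  got <- consensus_keys(filter_tumor_only(grid))
  want <- oracle_filter_tumor_only(grid)
  expect_identical(got, want)
})

test_that("tumor-only filtering reports which variant is missing support fields", {
  bad <- make_call(caller = "mutect2", pos = 777, maf = NA_real_,
                   alt_reads = 10, depth = 80)
  expect_error(filter_tumor_only(bad), "chr1:777")
})

test_that("TMB is retained variants divided by covered megabases", {
  vs <- do.call(rbind, lapply(1:57, function(i) {
    make_call(caller = "mutect2", pos = i, quality = 50)
  }))
  cs <- filter_matched(vs)
  tm <- compute_tmb(cs, covered_mb = 32)
  expect_equal(tm$n_variants, 57L)
  expect_equal(tm$tmb, 57 / 32)
  expect_equal(tm$tmb, 1.78125)
  expect_error(compute_tmb(cs, covered_mb = 0), "covered")
})

test_that("covered megabases honours the depth threshold and interval widths", {
  iv <- data.frame(chrom = "chr1",
                   start = c(1L, 1001L, 5001L),
                   end = c(1000L, 3000L, 5500L),
                   depth = c(25, 19.9, 20))
  # default threshold 20: first and third intervals count
  expect_equal(covered_megabases(iv), (1000 + 500) / 1e6)
  expect_equal(covered_megabases(iv, min_depth = 10), 3500 / 1e6)
  expect_equal(covered_megabases(iv, min_depth = 30), 0)
})

test_that("pair sharing computes Jaccard and per-site fractions", {
  a <- do.call(rbind, lapply(1:3, function(i)
    make_call(caller = "mutect2", pos = i, quality = 50)))
  b <- do.call(rbind, lapply(2:4, function(i)
    make_call(sample_id = "S2", caller = "mutect2", pos = i, quality = 50)))
  sh <- pair_sharing(filter_matched(a), filter_matched(b), patient_id = "P1")
  expect_equal(sh$n_shared, 2L)
  expect_equal(sh$n_only_a, 1L)
  expect_equal(sh$n_only_b, 1L)
  expect_equal(sh$jaccard, 0.5)
  expect_equal(sh$fraction_shared_of_a, 2 / 3)
  expect_equal(sh$fraction_shared_of_b, 2 / 3)
  # empty intersection
  c2 <- filter_matched(make_call(sample_id = "S3", caller = "mutect2",
                                 pos = 99, quality = 50))
  sh0 <- pair_sharing(filter_matched(a), c2, patient_id = "P1")
  expect_equal(sh0$jaccard, 0)
})
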