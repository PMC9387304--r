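# One shared simulation keeps this file fast; tests only read from it.
SIM <- simulate_cohort(cohort_config(seed = 42))

test_that("configuration is validated field-by-field", {
  expect_error(cohort_config(not_a_field = 1), "not_a_field")
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 25L)
  expect_equal(cfg$tmb_rate_primary, 1.8)
  expect_equal(cfg$tmb_rate_brm, 3.3)
  expect_equal(cfg$covered_mb, 30)
  bad <- cfg
  bad$n_matched_pairs <- 40L  # more pairs than patients
  expect_error(validate_cohort_config(bad), "n_matched_pairs")
})

test_that("the cohort design reproduces the study layout", {
  d <- cohort_design(cohort_config())
  expect_equal(length(unique(d$patient_id)), 25L)
  expect_equal(sum(d$site == "primary"), 15L)
  expect_equal(sum(d$site == "brm"), 19L)
  # nine patients contribute both sites
  both <- table(d$patient_id)
  expect_equal(sum(both == 2L), 9L)
  expect_equal(as.vector(table(d$wes_mode)[c("matched", "tumor_only", "none")]),
               c(30L, 2L, 2L))
  # TMB-eligible samples: all primaries vs matched + tumor-only metastases
  eligible <- d[d$wes_mode != "none", ]
  expect_equal(sum(eligible$site == "primary"), 15L)
  expect_equal(sum(eligible$site == "brm"), 17L)
})

test_that("simulation is reproducible from the seed and leaves global RNG alone", {
  set.seed(777)
  probe_before <- runif(3)
  set.seed(777)
  sim_a <- simulate_cohort(cohort_config(seed = 42))
  probe_after <- runif(3)
  expect_identical(probe_before, probe_after)  # local_seed restores state
  expect_identical(sim_a$calls, SIM$calls)
  expect_identical(sim_a$counts, SIM$counts)
  expect_identical(sim_a$clinical, SIM$clinical)
  sim_b <- simulate_cohort(cohort_config(seed = 43))
  expect_false(identical(sim_b$calls, SIM$calls))
})

test_that("planted matched variants pass the filter exactly when labelled to", {
  matched <- SIM$design$sample_id[SIM$design$wes_mode == "matched"]
  for (sid in matched[1:6]) {
    truth <- SIM$truth$variants[[sid]]
    got <- consensus_keys(filter_matched(SIM$calls[[sid]]))
    want <- sort(truth$key[truth$should_pass])
    expect_identical(got, want)
  }
})

test_that("tumor-only samples carry artifacts that the filter removes completely", {
  tos <- SIM$design$sample_id[SIM$design$wes_mode == "tumor_only"]
  expect_equal(length(tos), 2L)
  for (sid in tos) {
    truth <- SIM$truth$variants[[sid]]
    expect_gt(sum(truth$role == "ffpe_artifact"), 50)
    expect_gt(sum(truth$role == "pop_contaminant"), 0)
    kept <- consensus_keys(filter_tumor_only(SIM$calls[[sid]]))
    expect_identical(kept, sort(truth$key[truth$should_pass]))
    # no artifact or contaminant survives
    expect_equal(
      length(intersect(kept, truth$key[truth$role != "true"])), 0L)
    # every artifact is the deamination signature at sub-10% frequency
    art <- SIM$calls[[sid]]
    art <- art[paste(art$chrom, art$pos, art$ref, art$alt, sep = ":") %in%
                 truth$key[truth$role == "ffpe_artifact"], ]
    expect_true(all((art$ref == "C" & art$alt == "T") |
                      (art$ref == "G" & art$alt == "A")))
    expect_true(all(art$maf < 0.10))
  }
})

test_that("expression counts cover all sequenced samples plus technical replicates", {
  expect_equal(dim(SIM$counts), c(1000L, 34L + 2L))
  expect_true(all(SIM$design$sample_id %in% colnames(SIM$counts)))
  expect_equal(sum(grepl("_rep2$", colnames(SIM$counts))), 2L)
  expect_true(all(SIM$counts >= 0))
  expect_true(all(SIM$counts == round(SIM$counts)))
  # replicate map ties each replicate to its biosample within one patient
  rm_ <- SIM$replicate_map
  expect_true(all(rm_$sample_id %in% colnames(SIM$counts)))
  expect_equal(anyDuplicated(rm_$sample_id), 0L)
})

test_that("signature ground truth marks ten immune signatures down and wound healing up", {
  sig <- SIM$truth$signatures
  expect_equal(nrow(sig), 32L)
  expect_equal(sum(sig$affected), 11L)
  expect_equal(sum(sig$effect < 0), 10L)
  expect_equal(sig$effect[sig$signature == "Wound_Healing_Fibroblast"], 2)
  expect_true(all(sig$effect[!sig$affected] == 0))
  # affected signatures actually shift in the generated counts
  norm <- upper_quartile_normalize(expr_matrix(SIM$counts))
  ss <- score_signatures(norm, SIM$gmt)
  labels <- stats::setNames(SIM$design$site, SIM$design$sample_id)
  med_diff <- apply(ss$scores[, names(labels)], 1, function(x) {
    stats::median(x[labels == "brm"]) - stats::median(x[labels == "primary"])
  })
  down <- sig$signature[sig$effect < 0]
  expect_true(all(med_diff[down] < 0))
})

test_that("clonotype repertoires are smaller and more skewed in metastases", {
  cl <- SIM$clonotypes
  validate_clonotypes(cl)
  s <- summarize_repertoire_all(cl)
  s <- merge(s, SIM$design, by = "sample_id")
  trb <- s[s$chain == "TRB", ]
  expect_gt(stats::median(trb$total_reads[trb$site == "primary"]),
            stats::median(trb$total_reads[trb$site == "brm"]))
  expect_gt(stats::median(trb$entropy[trb$site == "primary"]),
            stats::median(trb$entropy[trb$site == "brm"]))
})

test_that("clinical tables are internally consistent and survival truth is recorded", {
  clin <- SIM$clinical
  expect_silent(validate_clinical(clin))
  expect_equal(nrow(clin), 25L)
  expect_true(all(clin$t_event > clin$t_brm_dx, na.rm = TRUE))
  expect_equal(SIM$truth$loghr,
               c(stage = 0.4, age_per_decade = 0.2, score = -0.5))
  expect_equal(length(SIM$truth$latent_score), 25L)
})

test_that("survival simulator honours the requested effect size and censoring", {
  set.seed(88)
  d <- simulate_survival_data(5000, beta = c(signature_score = 0.7))
  expect_equal(attr(d, "beta"), c(signature_score = 0.7))
  # competing exponentials: censored with probability
  # rate_c / (rate_c + rate_e * exp(beta * x)), averaged over x ~ N(0, 1)
  p_cens <- stats::integrate(function(x) {
    stats::dnorm(x) / (1 + 4 * exp(0.7 * x))
  }, -Inf, Inf)$value
  expect_equal(mean(!d$event), p_cens, tolerance = 0.03)
  expect_true(all(d$time > 0))
})

test_that("written cohorts are plain text and round-trip through the readers", {
  td <- withr::local_tempdir()
  write_cohort(SIM, td)
  files <- list.files(td, recursive = TRUE, full.names = TRUE)
  expect_true(length(files) >= 40)
  # plain ASCII text everywhere
  for (f in files) {
    raw <- readBin(f, "raw", file.info(f)$size)
    expect_true(all(raw != as.raw(0)), info = f)
  }
  back <- read_caller_calls(file.path(td, "calls", "P01_primary.calls.tsv"),
                            "mutect2")
  expect_identical(back, SIM$calls$P01_primary)
  clin <- read_clinical(file.path(td, "clinical.csv"))
  expect_equal(clin$patient_id, SIM$clinical$patient_id)
  gmt <- read_gmt(file.path(td, "signatures.gmt"))
  expect_identical(gmt, SIM$gmt)
})

test_that("recovery evaluation refuses a seed mismatch", {
  res <- list(seed = 999)
  expect_error(evaluate_recovery(res, SIM$truth), "seed")
})
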