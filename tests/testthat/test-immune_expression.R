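test_that("QC retains samples at or above the read-depth cutoff", {
  metrics <- c(s1 = 2.5e7, s2 = 2e7, s3 = 1.99e7, s4 = 5e7)
  kept <- qc_filter_samples(metrics)
  expect_equal(kept, c("s1", "s2", "s4"))  # cutoff is inclusive
  expect_equal(qc_filter_samples(metrics, min_reads = 3e7), c("s4"))
})

test_that("upper-quartile normalization equalizes nonzero 75th percentiles", {
  set.seed(7)
  m <- matrix(rnbinom(400, mu = 50, size = 2), nrow = 100,
              dimnames = list(sprintf("G%03d", 1:100), paste0("s", 1:4)))
  m[1:10, 2] <- 0  # zeros must be excluded from the quartile
  norm <- upper_quartile_normalize(expr_matrix(m))
  expect_true(norm$normalized)
  # back-transform to the linear scale and recompute each sample's UQ
  linear <- 2^norm$values - 1
  uqs <- apply(linear, 2, function(x) {
    stats::quantile(x[x > 0], 0.75, names = FALSE, type = 7)
  })
  expect_lt(max(uqs) - min(uqs), 1e-9)
  # the common value is the geometric mean of the raw per-sample quartiles
  raw_uqs <- apply(m, 2, function(x) {
    stats::quantile(x[x > 0], 0.75, names = FALSE, type = 7)
  })
  expect_equal(unname(uqs[1]), exp(mean(log(raw_uqs))), tolerance = 1e-9)
})

test_that("a fixed reference quartile rescales exactly", {
  m <- matrix(c(0, 10, 20, 40), nrow = 4, dimnames = list(letters[1:4], "s1"))
  # nonzero quartile (type 7) of (10, 20, 40): 30
  norm <- upper_quartile_normalize(expr_matrix(m), reference = 60)
  expect_equal(unname(norm$values[, 1]), log2(c(0, 20, 40, 80) + 1))
  expect_error(
    upper_quartile_normalize(expr_matrix(cbind(m, s2 = c(0, 0, 0, 0)))),
    "s2")
})

test_that("technical replicates are averaged on the log2 scale", {
  vals <- matrix(c(2, 4, 6, 8, 1, 3), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a_r1", "a_r2", "b_r1")))
  rep_map <- data.frame(
    sample_id = c("a_r1", "a_r2", "b_r1"),
    biosample_id = c("a", "a", "b"),
    patient_id = c("P1", "P1", "P2"),
    stringsAsFactors = FALSE
  )
  avg <- average_technical_replicates(expr_matrix(vals, normalized = TRUE),
                                      rep_map)
  expect_equal(colnames(avg$values), c("a", "b"))
  expect_equal(unname(avg$values[, "a"]), c(mean(c(2, 6)), mean(c(4, 8))))
  expect_equal(unname(avg$values[, "b"]), c(1, 3))
  # replicates of one biosample may not span patients
  rep_map$patient_id[2] <- "P2"
  expect_error(average_technical_replicates(
    expr_matrix(vals, normalized = TRUE), rep_map), "patient")
})

test_that("metagene score is the per-sample median over signature genes present", {
  vals <- matrix(c(1, 2, 3, 9,
                   4, 5, 6, 9), nrow = 4,
                 dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  sc <- metagene_score(expr_matrix(vals, normalized = TRUE),
                       c("g1", "g2", "g3", "absent_gene"))
  expect_equal(sc, c(s1 = 2, s2 = 5))
  expect_error(metagene_score(expr_matrix(vals, normalized = TRUE),
                              c("x", "y"), name = "SigQ"), "SigQ")
})

test_that("signature scoring z-transforms across samples with a zero-variance guard", {
  set.seed(11)
  vals <- matrix(rnorm(60, 5), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  vals["g5", ] <- 3  # constant gene drives a constant signature
  gmt <- list(SigA = c("g1", "g2", "g3"), SigB = c("g4", "g6"),
              Flat = "g5")
  ss <- score_signatures(expr_matrix(vals, normalized = TRUE), gmt)
  expect_equal(dim(ss$scores), c(3L, 10L))
  for (sig in c("SigA", "SigB")) {
    expect_equal(mean(ss$z_scores[sig, ]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(ss$z_scores[sig, ]), 1, tolerance = 1e-12)
  }
  expect_true(all(ss$z_scores["Flat", ] == 0))
  # raw scores agree with metagene_score
  expect_equal(ss$scores["SigA", ],
               metagene_score(expr_matrix(vals, normalized = TRUE),
                              gmt$SigA))
})

test_that("group comparison uses exact two-sided rank tests with BH adjustment", {
  set.seed(21)
  n_sig <- 12
  scores <- matrix(rnorm(n_sig * 12), nrow = n_sig,
                   dimnames = list(sprintf("Sig%02d", 1:n_sig),
                                   sprintf("s%d", 1:12)))
  labels <- stats::setNames(rep(c("brm", "primary"), each = 6),
                            colnames(scores))
  scores[1, labels == "brm"] <- scores[1, labels == "brm"] + 10
  ss <- structure(list(scores = scores,
                       z_scores = t(scale(t(scores)))),
                  class = "signature_scores")
  cmp <- compare_signature_groups(ss, labels)
  expect_equal(cmp$signature, rownames(scores))
  # oracle: wilcoxon on z-scores, BH across the family
  z <- t(scale(t(scores)))
  p_want <- vapply(seq_len(n_sig), function(i) {
    stats::wilcox.test(z[i, labels == "brm"], z[i, labels == "primary"],
                       exact = TRUE, correct = FALSE)$p.value
  }, numeric(1))
  expect_equal(cmp$p, p_want, tolerance = 1e-12)
  expect_equal(cmp$q, oracle_bh(p_want), tolerance = 1e-12)
  expect_equal(cmp$q, stats::p.adjust(p_want, "BH"), tolerance = 1e-12)
  # direction: group A (alphabetical "brm") minus group B medians
  expect_equal(cmp$direction[1], 1)
  up <- median(scores[1, labels == "brm"])
  expect_gt(up, median(scores[1, labels == "primary"]))
})

test_that("identical group distributions give p exactly 1", {
  scores <- matrix(rep(c(1, 2, 3, 4), times = 2), nrow = 1,
                   dimnames = list("Sig01", sprintf("s%d", 1:8)))
  labels <- stats::setNames(rep(c("brm", "primary"), times = 4),
                            colnames(scores))
  # identical multisets in the two groups
  scores[1, labels == "brm"] <- c(1, 2, 3, 4)
  scores[1, labels == "primary"] <- c(1, 2, 3, 4)
  ss <- structure(list(scores = scores, z_scores = t(scale(t(scores)))),
                  class = "signature_scores")
  cmp <- compare_signature_groups(ss, labels)
  expect_identical(cmp$p, 1)
  expect_identical(cmp$direction, 0)
})

test_that("explicit group arguments flip the direction sign", {
  scores <- matrix(c(5, 5, 5, 1, 1, 1), nrow = 1,
                   dimnames = list("S", sprintf("s%d", 1:6)))
  labels <- stats::setNames(rep(c("g1", "g2"), each = 3), colnames(scores))
  ss <- structure(list(scores = scores, z_scores = t(scale(t(scores)))),
                  class = "signature_scores")
  a <- compare_signature_groups(ss, labels)  # default: A = "g1"
  b <- compare_signature_groups(ss, labels, group_a = "g2", group_b = "g1")
  expect_equal(a$direction, 1)
  expect_equal(b$direction, -1)
  expect_equal(a$p, b$p)
})
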