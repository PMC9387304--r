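# Seeded synthetic cohort generator. Produces every pipeline input with
# planted ground truth: caller call sets whose qualities straddle the filter
# gates, FFPE deamination artifacts at low allele fraction, population
# contaminants, negative-binomial expression with planted immune-signature
# depression and wound-healing elevation in brain metastases, Zipf-law
# clonotype repertoires with site-specific scale and diversity, and survival
# times under covariate-driven exponential hazards.

STOP_CODONS <- c("TAA", "TAG", "TGA")
# a tail containing a stop codon in every reading frame, appended to toy CDSs
STOP_ALL_FRAMES <- "TAAATAAATAAA"

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: 25 patients contributing 15
#' primary and 19 brain-metastasis samples with 9 matched pairs; whole-exome
#' calls for 15 primaries and 17 metastases (2 of them tumor-only); true
#' mutation rates 1.8 (primary) and 3.3 (metastasis) per megabase over 30
#' adequately covered megabases; FFPE C>T/G>A artifacts at 5 per megabase
#' with allele fraction below 10%; 32 expression signatures of which 10
#' immune signatures are depressed by 2 SD in metastases and one
#' wound-healing signature is elevated by 2 SD; a ten-fold reduction in
#' clonotype reads and a steeper Zipf exponent (lower diversity) in
#' metastases; and exponential survival with stage, age and immune-score
#' log-hazards.
#'
#' @param ... Overrides for any default field.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(...) {
  config <- list(
    seed = 1L,
    n_patients = 25L,
    n_matched_pairs = 9L,
    n_primary_only = 6L,
    n_tumor_only = 2L,
    n_brm_no_wes = 2L,
    covered_mb = 30,
    tmb_rate_primary = 1.8,
    tmb_rate_brm = 3.3,
    coding_fraction = 0.85,
    indel_fraction = 0.15,
    pair_shared_rate = 0.9,
    caller_sensitivity = c(strelka2 = 0.9, mutect2 = 0.9, cadabra = 0.8),
    decoy_rate = 1,
    ffpe_artifact_rate = 5,
    pop_contaminant_rate = 1,
    n_genes = 1000L,
    n_signatures = 32L,
    genes_per_signature = 10L,
    n_signatures_affected = 10L,
    signature_effect_brm = -2,
    wound_healing_effect_brm = 2,
    signature_sd = 0.5,
    nb_dispersion = 0.1,
    n_replicated_samples = 2L,
    clonotype_richness = c(primary = 150, brm = 60),
    clonotype_reads = c(primary = 5000, brm = 500),
    zipf_exponent = c(primary = 1.0, brm = 1.4),
    loghr_stage = 0.4,
    loghr_age_per_decade = 0.2,
    loghr_score = -0.5,
    median_os_from_brm_days = 438,
    censor_fraction = 0.2
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown cohort_config field(s): ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  validate_cohort_config(config)
}

#' @rdname cohort_config
#' @param config Candidate configuration list.
#' @export
validate_cohort_config <- function(config) {
  bad <- character(0)
  nonneg <- c("covered_mb", "tmb_rate_primary", "tmb_rate_brm", "decoy_rate",
              "ffpe_artifact_rate", "pop_contaminant_rate", "signature_sd",
              "nb_dispersion", "pair_shared_rate")
  for (f in nonneg) if (!is.numeric(config[[f]]) || any(config[[f]] < 0)) {
    bad <- c(bad, f)
  }
  if (config$n_patients < 2L) bad <- c(bad, "n_patients")
  for (f in c("coding_fraction", "indel_fraction", "censor_fraction")) {
    if (config[[f]] < 0 || config[[f]] > 1) bad <- c(bad, f)
  }
  if (any(config$caller_sensitivity < 0 | config$caller_sensitivity > 1)) {
    bad <- c(bad, "caller_sensitivity")
  }
  n_samples <- config$n_matched_pairs * 2L + config$n_primary_only +
    (config$n_patients - config$n_matched_pairs - config$n_primary_only)
  if (config$n_matched_pairs + config$n_primary_only > config$n_patients) {
    bad <- c(bad, "n_matched_pairs/n_primary_only")
  }
  if (length(bad)) {
    stop("invalid cohort_config field(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(config, class = "cohort_config")
}

# Patient/sample design table implied by the configuration.
cohort_design <- function(config) {
  np <- config$n_patients
  patient_id <- sprintf("P%02d", seq_len(np))
  pairs <- seq_len(config$n_matched_pairs)
  pri_only <- config$n_matched_pairs + seq_len(config$n_primary_only)
  brm_only <- setdiff(seq_len(np), c(pairs, pri_only))
  rows <- list()
  for (i in pairs) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = patient_id[i], site = c("primary", "brm"),
      stringsAsFactors = FALSE)
  }
  for (i in pri_only) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = patient_id[i], site = "primary", stringsAsFactors = FALSE)
  }
  for (i in brm_only) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = patient_id[i], site = "brm", stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$sample_id <- paste(design$patient_id, design$site, sep = "_")
  # WES: all primaries matched; among brm-only patients the last
  # n_brm_no_wes have no WES and the n_tumor_only before them are
  # tumor-only; everything else is matched.
  design$wes_mode <- "matched"
  brm_only_ids <- design$sample_id[design$site == "brm" &
                                   !design$patient_id %in% patient_id[pairs]]
  n_no <- config$n_brm_no_wes
  n_to <- config$n_tumor_only
  if (n_no > 0L) {
    design$wes_mode[design$sample_id %in% utils::tail(brm_only_ids, n_no)] <- "none"
  }
  if (n_to > 0L) {
    to_ids <- utils::tail(utils::head(brm_only_ids, length(brm_only_ids) - n_no), n_to)
    design$wes_mode[design$sample_id %in% to_ids] <- "tumor_only"
  }
  design[, c("sample_id", "patient_id", "site", "wes_mode")]
}

.random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

.random_indel_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ins <- stats::runif(n) < 0.5
  ref <- character(n); alt <- character(n)
  anchor <- sample(bases, n, replace = TRUE)
  for (i in seq_len(n)) {
    extra <- paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                   collapse = "")
    if (ins[i]) { ref[i] <- anchor[i]; alt[i] <- paste0(anchor[i], extra) }
    else        { ref[i] <- paste0(anchor[i], extra); alt[i] <- anchor[i] }
  }
  list(ref = ref, alt = alt)
}

# Plant a set of true somatic variants (keys + classes + coding flags).
.plant_variants <- function(n, coding_fraction, indel_fraction) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_class = character(),
                      coding = logical(), stringsAsFactors = FALSE))
  }
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(3e7, n)  # collision-free within a draw
  is_indel <- stats::runif(n) < indel_fraction
  snv <- .random_snv_alleles(sum(!is_indel))
  indel <- .random_indel_alleles(sum(is_indel))
  ref <- character(n); alt <- character(n)
  ref[!is_indel] <- snv$ref; alt[!is_indel] <- snv$alt
  ref[is_indel] <- indel$ref; alt[is_indel] <- indel$alt
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_class = ifelse(is_indel, "indel", "snv"),
    coding = stats::runif(n) < coding_fraction,
    stringsAsFactors = FALSE
  )
}

# Emit per-caller calls for planted variants, with qualities drawn to
# straddle every gate so each rule branch occurs with nonzero probability.
.matched_calls_for <- function(variants, sample_id, config) {
  gates <- matched_filter_gates()
  sens <- config$caller_sensitivity
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    callers <- character(0)
    if (stats::runif(1) < sens[["strelka2"]]) callers <- c(callers, "strelka2")
    if (stats::runif(1) < sens[["mutect2"]]) callers <- c(callers, "mutect2")
    if (v$variant_class == "indel" && stats::runif(1) < sens[["cadabra"]]) {
      callers <- c(callers, "cadabra")
    }
    for (cl in callers) {
      gate <- switch(cl,
        strelka2 = if (v$variant_class == "snv") gates$strelka2_snv
                   else gates$strelka2_indel,
        mutect2 = if (v$variant_class == "snv") gates$mutect2_snv
                  else gates$mutect2_indel,
        cadabra = gates$cadabra_indel)
      quality <- gate * stats::runif(1, 0.6, 2.5)
      if (cl == "cadabra") quality <- stats::runif(1, 5, 60)
      evs <- if (cl == "strelka2") stats::runif(1, 5, 40) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, caller = cl, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt, variant_class = v$variant_class,
        coding = v$coding, quality = quality, somatic_evs = evs,
        alt_reads = NA_integer_, depth = NA_integer_, maf = NA_real_,
        normal_maf = NA_real_, pop_af_max = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) empty_variant_calls() else do.call(rbind, rows)
}

# Generator-side restatement of the matched cascade, used to label each
# planted variant should-pass before the pipeline ever runs.
.matched_should_pass <- function(calls) {
  gates <- matched_filter_gates()
  if (!nrow(calls)) return(character(0))
  gate_of <- function(caller, class) {
    if (caller == "strelka2") {
      if (class == "snv") gates$strelka2_snv else gates$strelka2_indel
    } else if (caller == "mutect2") {
      if (class == "snv") gates$mutect2_snv else gates$mutect2_indel
    } else if (class == "indel") gates$cadabra_indel else Inf
  }
  calls$gate_pass <- vapply(seq_len(nrow(calls)), function(i) {
    calls$quality[i] > gate_of(calls$caller[i], calls$variant_class[i])
  }, logical(1))
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  retained <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!calls$coding[i] || !calls$gate_pass[i]) next
    ok <- TRUE
    mates <- key == key[i] & seq_len(nrow(calls)) != i & calls$gate_pass
    if (calls$caller[i] == "cadabra" && calls$variant_class[i] == "indel" &&
        calls$quality[i] < gates$cadabra_rescue) {
      ok <- any(mates & calls$caller %in% c("strelka2", "mutect2"))
    }
    if (ok && calls$caller[i] == "strelka2" &&
        calls$somatic_evs[i] < gates$strelka2_evs) {
      ok <- any(mates & calls$caller %in% c("mutect2", "cadabra"))
    }
    retained[i] <- ok
  }
  unique(key[retained])
}

# Tumor-only calls: planted true variants satisfy every clause by
# construction; artifacts and contaminants each violate exactly one.
.tumor_only_calls_for <- function(sample_id, config) {
  mb <- config$covered_mb
  n_true <- stats::rpois(1, config$tmb_rate_brm * mb)
  n_art <- stats::rpois(1, config$ffpe_artifact_rate * mb)
  n_pop <- stats::rpois(1, config$pop_contaminant_rate * mb)

  make <- function(n, role) {
    if (n == 0L) return(NULL)
    v <- .plant_variants(n, coding_fraction = 1, indel_fraction =
                           if (role == "true") config$indel_fraction else 0)
    depth <- as.integer(round(stats::runif(n, 80, 250)))
    if (role == "true") {
      maf <- stats::runif(n, 0.12, 0.6)
      ctga <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
      # all planted true variants satisfy the FFPE clause by construction
      maf[ctga] <- pmax(maf[ctga], 0.12)
      pop <- stats::runif(n, 0, 0.005)
      nmaf <- stats::runif(n, 0, 0.03)
    } else if (role == "ffpe_artifact") {
      ct <- stats::runif(n) < 0.5
      v$ref <- ifelse(ct, "C", "G"); v$alt <- ifelse(ct, "T", "A")
      v$variant_class <- "snv"
      maf <- stats::runif(n, 0.02, 0.0999)
      pop <- stats::runif(n, 0, 0.005)
      nmaf <- stats::runif(n, 0, 0.03)
    } else {  # population contaminant
      maf <- stats::runif(n, 0.12, 0.6)
      ctga <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
      maf[ctga] <- pmax(maf[ctga], 0.12)
      pop <- stats::runif(n, 0.02, 0.5)
      nmaf <- stats::runif(n, 0, 0.03)
    }
    alt_reads <- pmax(10L, as.integer(round(maf * depth)))
    alt_reads <- pmin(alt_reads, depth)
    data.frame(
      sample_id = sample_id, caller = "mutect2", chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, variant_class = v$variant_class,
      coding = TRUE, quality = stats::runif(n, 10, 60),
      somatic_evs = NA_real_, alt_reads = alt_reads, depth = depth,
      maf = maf, normal_maf = nmaf, pop_af_max = pop, role = role,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(make(n_true, "true"), make(n_art, "ffpe_artifact"),
               make(n_pop, "pop_contaminant"))
  if (is.null(out)) {
    out <- cbind(empty_variant_calls(), role = character(0))
  }
  # deduplicate colliding keys across roles (vanishingly rare)
  key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  out[!duplicated(key), , drop = FALSE]
}

.random_cdr3 <- function(n) {
  lens <- sample(8:16, n, replace = TRUE)
  vapply(lens, function(k) {
    paste(c("C", sample(AA_ALPHABET, k - 2L, replace = TRUE), "F"),
          collapse = "")
  }, character(1))
}

# Zipf-law clonotype counts for one sample/chain.
.zipf_clonotypes <- function(sample_id, chain, richness, total_reads,
                             exponent) {
  K <- max(2L, as.integer(richness))
  p <- (seq_len(K))^(-exponent)
  p <- p / sum(p)
  counts <- as.integer(stats::rmultinom(1, max(K, as.integer(total_reads)), p))
  keep <- counts > 0L
  cdr3 <- .random_cdr3(sum(keep))
  while (anyDuplicated(cdr3)) {
    dup <- duplicated(cdr3)
    cdr3[dup] <- .random_cdr3(sum(dup))
  }
  data.frame(sample_id = sample_id, chain = chain, cdr3 = cdr3,
             read_count = counts[keep], stringsAsFactors = FALSE)
}

#' Simulate expression counts with planted group effects
#'
#' Negative-binomial counts (gene-level dispersion) whose log2 means carry a
#' per-sample signature-level random effect shared by the genes of each
#' signature. In metastasis samples the affected immune signatures are
#' shifted down and the wound-healing signature up, each by
#' `effect x signature_sd` on the log2 scale.
#'
#' @param config A `cohort_config`.
#' @param sample_ids Sample ids to simulate.
#' @param is_brm Logical vector marking metastasis samples.
#' @return list: `counts` (genes x samples integer matrix), `gmt` (named
#'   list of signature gene sets), `truth` (data.frame signature/affected/
#'   effect), `antigen_classes` (named vector gene -> source class).
#' @export
simulate_expression_counts <- function(config, sample_ids, is_brm) {
  n_sig <- config$n_signatures
  gps <- config$genes_per_signature
  sig_names <- c(sprintf("IGS_%02d", seq_len(n_sig - 1L)),
                 "Wound_Healing_Fibroblast")
  gmt <- lapply(seq_len(n_sig), function(i) {
    sprintf("%s_G%02d", sig_names[i], seq_len(gps))
  })
  names(gmt) <- sig_names
  antigen_genes <- c(sprintf("CTA%02d", 1:30), sprintf("ERV%02d", 1:20),
                     sprintf("VIR%02d", 1:10))
  antigen_classes <- stats::setNames(
    rep(c("cta_self", "erv", "viral"), c(30, 20, 10)), antigen_genes)
  n_bg <- max(0L, config$n_genes - n_sig * gps - length(antigen_genes))
  genes <- c(unlist(gmt, use.names = FALSE), antigen_genes,
             sprintf("BG%04d", seq_len(n_bg)))

  base <- stats::runif(length(genes), 2, 9)
  names(base) <- genes
  effects <- rep(0, n_sig)
  affected <- c(rep(TRUE, min(config$n_signatures_affected, n_sig - 1L)),
                rep(FALSE, n_sig - 1L - min(config$n_signatures_affected,
                                            n_sig - 1L)), TRUE)
  effects[affected] <- config$signature_effect_brm
  effects[n_sig] <- config$wound_healing_effect_brm

  ns <- length(sample_ids)
  counts <- matrix(0L, nrow = length(genes), ncol = ns,
                   dimnames = list(genes, sample_ids))
  size <- 1 / config$nb_dispersion
  for (s in seq_len(ns)) {
    log2mu <- base
    for (i in seq_len(n_sig)) {
      u <- stats::rnorm(1, 0, config$signature_sd)
      shift <- if (is_brm[s]) effects[i] * config$signature_sd else 0
      log2mu[gmt[[i]]] <- log2mu[gmt[[i]]] + u + shift
    }
    # antigen features: on in a random subset of samples, near-silent else
    on <- stats::runif(length(antigen_genes)) < 0.4
    log2mu[antigen_genes] <- ifelse(on, stats::runif(length(antigen_genes), 4, 8),
                                    -2)
    counts[, s] <- as.integer(stats::rnbinom(length(genes), mu = 2^log2mu,
                                             size = size))
  }
  truth <- data.frame(signature = sig_names,
                      affected = affected,
                      effect = effects, stringsAsFactors = FALSE)
  list(counts = counts, gmt = gmt, truth = truth,
       antigen_classes = antigen_classes)
}

#' Simulate survival data with known log-hazards
#'
#' Exponential event times under a proportional-hazards model with a
#' standard-normal `signature_score` covariate (plus inert age/stage/race
#' columns for coverage studies), independently censored.
#'
#' @param n Number of patients.
#' @param beta Named log-hazard vector; names drawn from
#'   `signature_score`, `age_at_primary_dx`, `stage`.
#' @param baseline_rate Baseline hazard (events/day).
#' @param censor_rate Censoring hazard (0 disables censoring).
#' @return data.frame compatible with [fit_cox()]; attribute `beta` carries
#'   the generating coefficients.
#' @export
simulate_survival_data <- function(n, beta = c(signature_score = log(2)),
                                   baseline_rate = log(2) / 1000,
                                   censor_rate = log(2) / 4000) {
  covars <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    signature_score = stats::rnorm(n),
    age_at_primary_dx = stats::runif(n, 30, 70),
    stage = sample(1:4, n, replace = TRUE,
                   prob = c(0.2, 0.48, 0.24, 0.08)),
    race = sample(c("groupA", "groupB"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  lp <- rep(0, n)
  for (nm in names(beta)) lp <- lp + beta[[nm]] * covars[[nm]]
  t_event <- stats::rexp(n, rate = baseline_rate * exp(lp))
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
            else rep(Inf, n)
  covars$time <- pmin(t_event, t_cens)
  covars$event <- t_event <= t_cens
  structure(covars, beta = beta)
}

#' Simulate the full synthetic cohort
#'
#' Deterministic given `config$seed`: repeated calls with the same
#' configuration return identical values. See [cohort_config()] for the
#' study conditions the defaults emulate.
#'
#' @param config A `cohort_config`.
#' @return A `cohort_sim` list holding every pipeline input (`design`,
#'   `calls` per WES sample, `coverage`, `segments`, expression `counts`
#'   with `qc_metrics` and `replicate_map`, `gmt`, `antigen_classes`,
#'   `clonotypes`, `clinical`, `alleles`, `protein_context`,
#'   `cds_context`, `rna_support`) and `truth`, the planted ground truth.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  local_seed(config$seed, {
    design <- cohort_design(config)
    wes <- design[design$wes_mode != "none", , drop = FALSE]

    # --- somatic calls -------------------------------------------------
    calls <- list()
    truth_variants <- list()
    # patient-level trunk variants shared within matched pairs
    paired_patients <- names(which(table(design$patient_id) == 2L))
    trunks <- lapply(paired_patients, function(p) {
      n <- stats::rpois(1, config$pair_shared_rate * config$covered_mb)
      .plant_variants(n, config$coding_fraction, config$indel_fraction)
    })
    names(trunks) <- paired_patients

    for (i in seq_len(nrow(wes))) {
      sid <- wes$sample_id[i]
      site <- wes$site[i]
      if (wes$wes_mode[i] == "tumor_only") {
        tab <- .tumor_only_calls_for(sid, config)
        calls[[sid]] <- tab[, VARIANT_CALL_COLUMNS]
        key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
        truth_variants[[sid]] <- data.frame(
          key = key, role = tab$role,
          should_pass = tab$role == "true",
          variant_class = tab$variant_class,
          stringsAsFactors = FALSE)
      } else {
        rate <- if (site == "primary") config$tmb_rate_primary
                else config$tmb_rate_brm
        trunk <- trunks[[wes$patient_id[i]]]
        priv_rate <- max(0, rate - if (is.null(trunk)) 0
                                   else config$pair_shared_rate)
        private <- .plant_variants(
          stats::rpois(1, priv_rate * config$covered_mb),
          config$coding_fraction, config$indel_fraction)
        planted <- rbind(trunk, private)
        if (!is.null(planted) && nrow(planted)) {
          planted <- planted[!duplicated(paste(planted$chrom, planted$pos,
                                               planted$ref, planted$alt)), ]
        }
        tab <- .matched_calls_for(planted, sid, config)
        # decoy calls: non-coding high-quality records exercising R1
        n_decoy <- stats::rpois(1, config$decoy_rate * config$covered_mb)
        if (n_decoy > 0) {
          decoys <- .plant_variants(n_decoy, 0, config$indel_fraction)
          tab <- rbind(tab, .matched_calls_for(decoys, sid, config))
        }
        calls[[sid]] <- tab
        pass_keys <- .matched_should_pass(tab)
        pk <- if (nrow(planted)) paste(planted$chrom, planted$pos,
                                       planted$ref, planted$alt, sep = ":")
              else character(0)
        all_keys <- unique(c(pk, setdiff(
          paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":"), pk)))
        truth_variants[[sid]] <- data.frame(
          key = all_keys,
          role = ifelse(all_keys %in% pk, "true", "decoy"),
          should_pass = all_keys %in% pass_keys,
          stringsAsFactors = FALSE)
      }
    }

    # --- coverage & copy-number segments ------------------------------
    coverage <- do.call(rbind, lapply(wes$sample_id, function(sid) {
      n_iv <- 40L
      data.frame(sample_id = sid, chrom = paste0("chr", rep(1:20, 2)),
                 start = rep(seq(1, by = 1e6, length.out = n_iv / 2), 2),
                 end = rep(seq(1e6, by = 1e6, length.out = n_iv / 2), 2),
                 depth = round(stats::rlnorm(n_iv, log(60), 0.5)),
                 stringsAsFactors = FALSE)
    }))
    segments <- do.call(rbind, lapply(wes$sample_id, function(sid) {
      n_seg <- 20L
      data.frame(sample_id = sid, chrom = paste0("chr", sample(1:22, n_seg,
                                                               replace = TRUE)),
                 start = sample.int(1e8, n_seg),
                 n_markers = sample(50:5000, n_seg, replace = TRUE),
                 depth_ratio = stats::rlnorm(n_seg, 0, 0.4),
                 stringsAsFactors = FALSE)
    }))
    segments$end <- segments$start + sample.int(5e6, nrow(segments))

    # --- expression ----------------------------------------------------
    is_brm <- design$site == "brm"
    expr <- simulate_expression_counts(config, design$sample_id, is_brm)
    # technical replicates: duplicate the first n_replicated_samples columns
    rep_ids <- utils::head(design$sample_id, config$n_replicated_samples)
    counts <- expr$counts
    replicate_map <- data.frame(sample_id = design$sample_id,
                                biosample_id = design$sample_id,
                                patient_id = design$patient_id,
                                stringsAsFactors = FALSE)
    for (sid in rep_ids) {
      extra <- paste0(sid, "_rep2")
      noise <- stats::rnbinom(nrow(counts), mu = pmax(counts[, sid], 1),
                              size = 1 / config$nb_dispersion)
      counts <- cbind(counts, stats::setNames(data.frame(noise), extra)[[1]])
      colnames(counts)[ncol(counts)] <- extra
      replicate_map <- rbind(replicate_map, data.frame(
        sample_id = extra, biosample_id = sid,
        patient_id = design$patient_id[design$sample_id == sid],
        stringsAsFactors = FALSE))
    }
    qc_metrics <- stats::setNames(
      round(stats::runif(ncol(counts), 2.1e7, 6e7)), colnames(counts))

    # --- repertoire ----------------------------------------------------
    clonotypes <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      site <- design$site[i]
      do.call(rbind, lapply(CLONOTYPE_CHAINS, function(ch) {
        .zipf_clonotypes(design$sample_id[i], ch,
                         config$clonotype_richness[[site]],
                         config$clonotype_reads[[site]],
                         config$zipf_exponent[[site]])
      }))
    }))

    # --- clinical ------------------------------------------------------
    np <- config$n_patients
    patient_id <- sprintf("P%02d", seq_len(np))
    latent_score <- stats::rnorm(np)
    stage <- sample(c("I", "II", "III", "IV"), np, replace = TRUE,
                    prob = c(0.2, 0.48, 0.24, 0.08))
    age <- stats::runif(np, 29, 71)
    race <- sample(c("Caucasian", "African American", "Asian", "Other"),
                   np, replace = TRUE, prob = c(0.68, 0.24, 0.04, 0.04))
    t_met <- round(stats::rexp(np, 1 / 657))
    t_brm <- t_met + round(stats::rexp(np, 1 / 200))
    lp <- config$loghr_stage * (match(stage, c("I", "II", "III", "IV")) - 2) +
      config$loghr_age_per_decade * (age - 50) / 10 +
      config$loghr_score * latent_score
    rate <- log(2) / config$median_os_from_brm_days * exp(lp)
    surv_brm <- stats::rexp(np, rate)
    censored <- stats::runif(np) < config$censor_fraction
    t_event <- t_brm + round(ifelse(censored, surv_brm * stats::runif(np),
                                    surv_brm)) + 1
    clinical <- data.frame(
      patient_id = patient_id, age_at_primary_dx = round(age, 1),
      stage = stage, race = race, t_primary_dx = 0L, t_met_dx = t_met,
      t_brm_dx = t_brm, t_event = t_event, event = !censored,
      stringsAsFactors = FALSE
    )

    # --- neoantigen inputs --------------------------------------------
    alleles <- do.call(rbind, lapply(wes$sample_id, function(sid) {
      data.frame(sample_id = sid,
                 allele = sample(c("HLA-A*01:01", "HLA-A*02:01",
                                   "HLA-B*07:02", "HLA-B*08:01",
                                   "HLA-C*07:01", "HLA-C*04:01"), 2L),
                 stringsAsFactors = FALSE)
    }))
    protein_context <- list()
    cds_context <- list()
    rna_support <- numeric(0)
    non_stop_codons <- setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      STOP_CODONS)
    for (sid in names(truth_variants)) {
      tv <- truth_variants[[sid]]
      true_keys <- tv$key[tv$role == "true" &
                            (is.null(tv$should_pass) | tv$should_pass)]
      for (key in true_keys) {
        parts <- strsplit(key, ":", fixed = TRUE)[[1]]
        is_snv <- nchar(parts[3]) == 1L && nchar(parts[4]) == 1L
        if (is_snv) {
          prot <- paste(sample(AA_ALPHABET, 21, replace = TRUE),
                        collapse = "")
          ref_aa <- substr(prot, 11, 11)
          alt_aa <- sample(setdiff(AA_ALPHABET, ref_aa), 1)
          protein_context[[length(protein_context) + 1L]] <- data.frame(
            sample_id = sid, source_id = key, protein = prot,
            position = 11L, alt_aa = alt_aa, stringsAsFactors = FALSE)
        } else {
          body <- paste(sample(non_stop_codons, 17, replace = TRUE),
                        collapse = "")
          cds <- paste0("ATG", body, STOP_ALL_FRAMES)
          cds_context[[length(cds_context) + 1L]] <- data.frame(
            sample_id = sid, source_id = key, cds = cds,
            position = 3L + sample.int(nchar(body) - 4L, 1L),
            stringsAsFactors = FALSE)
        }
        rna_support[key] <- if (stats::runif(1) < 0.8)
          stats::rpois(1, 5) + 1 else 0
      }
    }
    protein_context <- if (length(protein_context))
      do.call(rbind, protein_context) else
      data.frame(sample_id = character(), source_id = character(),
                 protein = character(), position = integer(),
                 alt_aa = character(), stringsAsFactors = FALSE)
    cds_context <- if (length(cds_context))
      do.call(rbind, cds_context) else
      data.frame(sample_id = character(), source_id = character(),
                 cds = character(), position = integer(),
                 stringsAsFactors = FALSE)
    # ref/alt alleles for the CDS contexts (1-bp insertion frameshift)
    if (nrow(cds_context)) {
      cds_context$ref <- substr(cds_context$cds, cds_context$position,
                                cds_context$position)
      cds_context$alt <- paste0(cds_context$ref, "A")
    } else {
      cds_context$ref <- character(0); cds_context$alt <- character(0)
    }

    truth <- list(
      seed = config$seed,
      config = config,
      design = design,
      variants = truth_variants,
      signatures = expr$truth,
      latent_score = stats::setNames(latent_score, patient_id),
      loghr = c(stage = config$loghr_stage,
                age_per_decade = config$loghr_age_per_decade,
                score = config$loghr_score),
      clonotype_params = list(richness = config$clonotype_richness,
                              reads = config$clonotype_reads,
                              zipf = config$zipf_exponent)
    )
    structure(list(
      seed = config$seed, config = config, design = design, calls = calls,
      coverage = coverage, segments = segments, counts = counts,
      qc_metrics = qc_metrics, replicate_map = replicate_map,
      gmt = expr$gmt, antigen_classes = expr$antigen_classes,
      clonotypes = clonotypes, clinical = clinical, alleles = alleles,
      protein_context = protein_context, cds_context = cds_context,
      rna_support = rna_support, truth = truth
    ), class = "cohort_sim")
  })
}

#' Write a simulated cohort to the file formats the pipeline consumes
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calls_dir <- file.path(dir, "calls")
  dir.create(calls_dir, showWarnings = FALSE)
  paths <- c()
  for (sid in names(sim$calls)) {
    p <- file.path(calls_dir, paste0(sid, ".calls.tsv"))
    write_variant_calls(sim$calls[[sid]], p)
    paths[paste0("calls_", sid)] <- p
  }
  files <- list(
    coverage = function(p) write_tsv(sim$coverage, p),
    segments = function(p) write_tsv(sim$segments, p),
    expression_counts = function(p)
      write_expression_matrix(expr_matrix(sim$counts, FALSE), p),
    qc_metrics = function(p)
      write_tsv(data.frame(sample_id = names(sim$qc_metrics),
                           coding_reads = unname(sim$qc_metrics)), p),
    replicate_map = function(p) write_tsv(sim$replicate_map, p),
    clonotypes = function(p) write_clonotypes(sim$clonotypes, p),
    alleles = function(p) write_tsv(sim$alleles, p),
    protein_context = function(p) write_tsv(sim$protein_context, p),
    cds_context = function(p) write_tsv(sim$cds_context, p),
    rna_support = function(p)
      write_tsv(data.frame(key = names(sim$rna_support),
                           rna_alt_reads = unname(sim$rna_support)), p),
    antigen_classes = function(p)
      write_tsv(data.frame(gene = names(sim$antigen_classes),
                           source_class = unname(sim$antigen_classes)), p),
    design = function(p) write_tsv(sim$design, p)
  )
  for (nm in names(files)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    files[[nm]](p)
    paths[nm] <- p
  }
  p <- file.path(dir, "clinical.csv"); write_clinical(sim$clinical, p)
  paths["clinical"] <- p
  p <- file.path(dir, "signatures.gmt"); write_gmt(sim$gmt, p)
  paths["gmt"] <- p
  invisible(paths)
}

#' Evaluate pipeline recovery of the planted ground truth
#'
#' @param results Pipeline results (see [run_pipeline()]), holding the
#'   consensus variant sets, comparison tables and Cox fits plus the seed
#'   the inputs were generated under.
#' @param truth Ground truth from [simulate_cohort()].
#' @return list of recovery metrics: matched/tumor-only retention and
#'   artifact removal, signature effect detection, repertoire group
#'   p-values, and signature-score Cox association.
#' @export
evaluate_recovery <- function(results, truth) {
  if (!identical(results$seed, truth$seed)) {
    stop("results and truth were generated under different seeds")
  }
  out <- list(seed = truth$seed)

  keys_of <- function(cs) paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = ":")
  matched_pass <- 0L; matched_total <- 0L; false_keep <- 0L
  art_total <- 0L; art_kept <- 0L; to_pass <- 0L; to_total <- 0L
  for (sid in names(truth$variants)) {
    tv <- truth$variants[[sid]]
    got <- keys_of(results$consensus[[sid]])
    should <- tv$key[tv$should_pass]
    mode <- results$wes_mode[[sid]]
    if (identical(mode, "tumor_only")) {
      art <- tv$key[tv$role == "ffpe_artifact"]
      art_total <- art_total + length(art)
      art_kept <- art_kept + sum(art %in% got)
      to_total <- to_total + length(should)
      to_pass <- to_pass + sum(should %in% got)
    } else {
      matched_total <- matched_total + length(should)
      matched_pass <- matched_pass + sum(should %in% got)
    }
    false_keep <- false_keep + length(setdiff(got, should))
  }
  out$matched_retention <- if (matched_total) matched_pass / matched_total
                           else NA_real_
  out$tumor_only_retention <- if (to_total) to_pass / to_total else NA_real_
  out$artifact_removal_rate <- if (art_total) 1 - art_kept / art_total
                               else NA_real_
  out$n_false_retained <- false_keep

  if (!is.null(results$signature_comparison)) {
    cmp <- results$signature_comparison
    tr <- truth$signatures
    hit <- merge(cmp, tr, by = "signature")
    # direction convention: group A = brm (labels sort alphabetically), so
    # a depressed signature (negative effect) should show
    # sign(median_brm - median_primary) < 0, i.e. direction == sign(effect)
    detected <- hit$affected & hit$q < 0.05 &
      sign(hit$direction) == sign(hit$effect)
    out$signature_detection_rate <- sum(detected) / sum(hit$affected)
    out$signature_false_positive_rate <-
      sum(!hit$affected & hit$q < 0.05) / max(1L, sum(!hit$affected))
  }
  if (!is.null(results$repertoire_comparison)) {
    rc <- results$repertoire_comparison
    out$repertoire_p <- stats::setNames(rc$p, paste(rc$chain, rc$metric))
  }
  if (!is.null(results$cox)) {
    row <- results$cox[results$cox$covariate == "signature_score", ,
                       drop = FALSE]
    if (nrow(row)) {
      out$cox_score_loghr <- log(row$hazard_ratio)
      out$cox_score_loghr_true <- unname(truth$loghr["score"])
    }
  }
  out
}
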