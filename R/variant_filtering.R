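# Somatic variant consensus filtering: matched-normal and tumor-only filter
# cascades, FFPE deamination artifact suppression, tumor mutational burden,
# and matched-pair variant sharing.

#' Matched-mode quality gates
#'
#' Per-caller quality thresholds of the matched-normal filter cascade. Calls
#' must exceed their gate strictly; the two rescue thresholds
#' (`cadabra_rescue`, `strelka2_evs`) mark low-confidence calls that
#' additionally require a corroborating call from another caller.
#'
#' @return Named list of thresholds.
#' @export
matched_filter_gates <- function() {
  list(
    cadabra_indel  = 10.5,
    mutect2_indel  = 6.8,
    mutect2_snv    = 9.2,
    strelka2_indel = 15.2,
    strelka2_snv   = 19.7,
    cadabra_rescue = 35,
    strelka2_evs   = 20
  )
}

.variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

.passes_gate <- function(df, gates, cadabra_snv_gate = NULL) {
  q <- df$quality
  pass <- rep(FALSE, nrow(df))
  sel <- df$caller == "cadabra" & df$variant_class == "indel"
  pass[sel] <- q[sel] > gates$cadabra_indel
  sel <- df$caller == "cadabra" & df$variant_class == "snv"
  pass[sel] <- if (is.null(cadabra_snv_gate)) FALSE else q[sel] > cadabra_snv_gate
  sel <- df$caller == "mutect2" & df$variant_class == "indel"
  pass[sel] <- q[sel] > gates$mutect2_indel
  sel <- df$caller == "mutect2" & df$variant_class == "snv"
  pass[sel] <- q[sel] > gates$mutect2_snv
  sel <- df$caller == "strelka2" & df$variant_class == "indel"
  pass[sel] <- q[sel] > gates$strelka2_indel
  sel <- df$caller == "strelka2" & df$variant_class == "snv"
  pass[sel] <- q[sel] > gates$strelka2_snv
  pass & !is.na(q)
}

.as_consensus <- function(df, sample_id) {
  structure(df, class = c("consensus_variants", "data.frame"),
            sample_id = sample_id)
}

#' Matched-normal consensus filter cascade
#'
#' Retains the union over callers of calls that pass, in order: (R1) the
#' coding-only rule; (R2) the per-caller quality gate (strict `>`); (R3)
#' cross-caller corroboration for the two low-confidence classes: Cadabra
#' indels with quality < 35 need a gate-passing Strelka2 or Mutect2 call at
#' the same (chrom, pos, ref, alt), and Strelka2 calls with SomaticEVS < 20
#' need a gate-passing Mutect2 or Cadabra call; (R4) deduplication by locus
#' key, recording which callers supported each retained variant.
#'
#' Cadabra SNVs have no published gate and are excluded by default (Cadabra
#' is an indel-realignment caller); supply `cadabra_snv_gate` to admit them
#' at a chosen threshold.
#'
#' @param calls Variant-call data.frame for one tumor (all callers pooled).
#' @param gates Threshold list, see [matched_filter_gates()].
#' @param corroborator_must_pass_gate Require corroborating calls to pass
#'   their own quality gate (default TRUE).
#' @param cadabra_snv_gate Optional quality gate admitting Cadabra SNVs.
#' @param apply_ffpe Also apply the FFPE C>T/G>A minimum-MAF rule (off by
#'   default in matched mode).
#' @param ffpe_min_maf Minimum MAF for C>T/G>A substitutions when
#'   `apply_ffpe` is TRUE.
#' @return A `consensus_variants` data.frame keyed on
#'   (chrom, pos, ref, alt) with provenance columns `callers`, `n_callers`,
#'   `best_quality`.
#' @export
filter_matched <- function(calls, gates = matched_filter_gates(),
                           corroborator_must_pass_gate = TRUE,
                           cadabra_snv_gate = NULL,
                           apply_ffpe = FALSE, ffpe_min_maf = 0.10) {
  calls <- .validate_variant_calls(as.data.frame(calls))
  sample_id <- unique(calls$sample_id)
  if (length(sample_id) > 1L) {
    stop("filter_matched expects calls from a single sample, got: ",
         paste(sample_id, collapse = ", "))
  }
  if (nrow(calls) == 0L) return(.as_consensus(empty_consensus(), sample_id))
  if (any(calls$caller == "strelka2" & is.na(calls$somatic_evs))) {
    stop("strelka2 call missing somatic_evs")
  }

  key <- .variant_key(calls)
  gate_pass <- .passes_gate(calls, gates, cadabra_snv_gate)

  # corroborable keys per rescue rule: any gate-passing call (or any call at
  # all, if the symmetry switch is off) from the allowed partner callers
  corrob_pool <- if (corroborator_must_pass_gate) gate_pass else rep(TRUE, nrow(calls))
  keys_sm <- unique(key[corrob_pool & calls$caller %in% c("strelka2", "mutect2")])
  keys_mc <- unique(key[corrob_pool & calls$caller %in% c("mutect2", "cadabra")])

  keep <- calls$coding & gate_pass
  needs_cadabra_rescue <- calls$caller == "cadabra" &
    calls$variant_class == "indel" & calls$quality < gates$cadabra_rescue
  keep[needs_cadabra_rescue & !(key %in% keys_sm)] <- FALSE
  needs_evs_rescue <- calls$caller == "strelka2" &
    calls$somatic_evs < gates$strelka2_evs
  keep[needs_evs_rescue & !(key %in% keys_mc)] <- FALSE

  if (apply_ffpe) {
    ctga <- (calls$ref == "C" & calls$alt == "T") |
            (calls$ref == "G" & calls$alt == "A")
    keep[ctga & (is.na(calls$maf) | calls$maf < ffpe_min_maf)] <- FALSE
  }

  retained <- calls[keep, , drop = FALSE]
  if (nrow(retained) == 0L) return(.as_consensus(empty_consensus(), sample_id))
  ord <- order(retained$chrom, retained$pos, retained$ref, retained$alt,
               retained$caller)
  retained <- retained[ord, , drop = FALSE]
  rk <- .variant_key(retained)
  first <- !duplicated(rk)
  uk <- rk[first]
  spl_caller <- split(retained$caller, factor(rk, levels = uk))
  spl_quality <- split(retained$quality, factor(rk, levels = uk))
  out <- retained[first, c("chrom", "pos", "ref", "alt", "variant_class")]
  out$callers <- vapply(spl_caller, function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  out$n_callers <- vapply(spl_caller, function(x)
    length(unique(x)), integer(1))
  out$best_quality <- vapply(spl_quality, max, numeric(1))
  out$sample_id <- sample_id
  rownames(out) <- NULL
  .as_consensus(out[, c("sample_id", "chrom", "pos", "ref", "alt",
                        "variant_class", "callers", "n_callers",
                        "best_quality")], sample_id)
}

#' @rdname filter_matched
#' @return `empty_consensus()` returns a zero-row consensus table.
#' @export
empty_consensus <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), variant_class = character(),
             callers = character(), n_callers = integer(),
             best_quality = numeric(), stringsAsFactors = FALSE)
}

#' Tumor-only filter cascade
#'
#' For samples without a matched normal, calls (Mutect2 only) are retained
#' iff all of the following hold: protein-coding; read support (at least 5
#' supporting reads and depth >= 40, tightened to 10 reads and depth >= 80
#' when MAF < 5%); normal-tissue MAF (when annotated) <= 5%; maximum
#' subpopulation allele frequency (gnomAD / 1000 Genomes) <= 1%; and the
#' FFPE deamination rule (C>T and G>A substitutions need MAF >= 10%).
#'
#' @param calls Mutect2 variant-call data.frame with `alt_reads`, `depth`,
#'   `maf` populated.
#' @param min_maf_for_relaxed_support MAF at or above which the 5-read/40x
#'   support rule applies (below it, 10 reads/80x).
#' @param max_normal_maf Maximum tolerated normal-tissue MAF.
#' @param max_pop_af Maximum tolerated subpopulation allele frequency.
#' @param ffpe_min_maf Minimum MAF for C>T/G>A substitutions.
#' @return A `consensus_variants` data.frame (provenance: mutect2).
#' @export
filter_tumor_only <- function(calls, min_maf_for_relaxed_support = 0.05,
                              max_normal_maf = 0.05, max_pop_af = 0.01,
                              ffpe_min_maf = 0.10) {
  calls <- .validate_variant_calls(as.data.frame(calls))
  sample_id <- unique(calls$sample_id)
  if (length(sample_id) > 1L) {
    stop("filter_tumor_only expects calls from a single sample")
  }
  if (nrow(calls) == 0L) return(.as_consensus(empty_consensus(), sample_id))
  if (!all(calls$caller == "mutect2")) {
    stop("tumor-only filtering is defined for mutect2 calls only")
  }
  for (col in c("alt_reads", "depth", "maf")) {
    if (anyNA(calls[[col]])) {
      i <- which(is.na(calls[[col]]))[1L]
      stop(sprintf("missing %s for variant %s:%d %s>%s", col, calls$chrom[i],
                   calls$pos[i], calls$ref[i], calls$alt[i]))
    }
  }
  support_ok <- ifelse(
    calls$maf >= min_maf_for_relaxed_support,
    calls$alt_reads >= 5L & calls$depth >= 40L,
    calls$alt_reads >= 10L & calls$depth >= 80L
  )
  normal_ok <- is.na(calls$normal_maf) | calls$normal_maf <= max_normal_maf
  pop_ok <- is.na(calls$pop_af_max) | calls$pop_af_max <= max_pop_af
  ctga <- (calls$ref == "C" & calls$alt == "T") |
          (calls$ref == "G" & calls$alt == "A")
  ffpe_ok <- !ctga | calls$maf >= ffpe_min_maf
  keep <- calls$coding & support_ok & normal_ok & pop_ok & ffpe_ok

  retained <- calls[keep, , drop = FALSE]
  if (nrow(retained) == 0L) return(.as_consensus(empty_consensus(), sample_id))
  retained <- retained[order(retained$chrom, retained$pos, retained$ref,
                             retained$alt), , drop = FALSE]
  retained <- retained[!duplicated(.variant_key(retained)), , drop = FALSE]
  out <- data.frame(
    sample_id = sample_id, chrom = retained$chrom, pos = retained$pos,
    ref = retained$ref, alt = retained$alt,
    variant_class = retained$variant_class, callers = "mutect2",
    n_callers = 1L, best_quality = retained$quality,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  .as_consensus(out, sample_id)
}

#' Tumor mutational burden
#'
#' Small indels and substitutions surviving the filter cascade, divided by
#' the megabases of target territory adequately covered by sequencing reads.
#'
#' @param variants A `consensus_variants` table (or any data.frame of
#'   retained variants).
#' @param covered_mb Adequately covered territory in megabases (> 0).
#' @return One-row data.frame: `sample_id`, `n_variants`, `covered_mb`,
#'   `tmb` (mutations/Mb).
#' @export
compute_tmb <- function(variants, covered_mb) {
  if (!is.numeric(covered_mb) || length(covered_mb) != 1L ||
      is.na(covered_mb) || covered_mb <= 0) {
    stop("covered_mb must be a positive number of megabases")
  }
  sample_id <- attr(variants, "sample_id")
  if (is.null(sample_id)) sample_id <- unique(variants$sample_id)
  if (length(sample_id) == 0L) sample_id <- NA_character_
  n <- nrow(variants)
  data.frame(sample_id = sample_id, n_variants = n, covered_mb = covered_mb,
             tmb = n / covered_mb, stringsAsFactors = FALSE)
}

#' Adequately covered megabases
#'
#' Sums the widths of target intervals whose summarized depth meets
#' `min_depth` and converts to megabases. Intervals are 1-based inclusive
#' with a constant depth each (the usual per-interval coverage summary).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `depth`.
#' @param min_depth Depth threshold for "adequately covered" (default 20x;
#'   configurable since no standard definition exists).
#' @return Covered territory in Mb.
#' @export
covered_megabases <- function(intervals, min_depth = 20) {
  missing <- setdiff(c("chrom", "start", "end", "depth"), names(intervals))
  if (length(missing)) {
    stop("coverage table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(intervals) == 0L) stop("empty interval list")
  if (any(intervals$start > intervals$end)) stop("interval start exceeds end")
  widths <- intervals$end - intervals$start + 1
  sum(widths[intervals$depth >= min_depth]) / 1e6
}

#' Variant sharing between a matched pair
#'
#' Exact set intersection/differences on (chrom, pos, ref, alt) keys, with
#' the Jaccard index and the shared fraction of each set.
#'
#' @param set_a,set_b `consensus_variants` tables for the two tumors.
#' @param patient_id Optional patient label for the output row.
#' @return One-row data.frame: `patient_id`, `n_shared`, `n_only_a`,
#'   `n_only_b`, `jaccard`, `fraction_shared_of_a`, `fraction_shared_of_b`.
#' @export
pair_sharing <- function(set_a, set_b, patient_id = NA_character_) {
  ka <- unique(.variant_key(set_a))
  kb <- unique(.variant_key(set_b))
  n_shared <- length(intersect(ka, kb))
  n_only_a <- length(setdiff(ka, kb))
  n_only_b <- length(setdiff(kb, ka))
  union_n <- n_shared + n_only_a + n_only_b
  data.frame(
    patient_id = patient_id,
    n_shared = n_shared, n_only_a = n_only_a, n_only_b = n_only_b,
    jaccard = if (union_n == 0L) NA_real_ else n_shared / union_n,
    fraction_shared_of_a = if (length(ka)) n_shared / length(ka) else NA_real_,
    fraction_shared_of_b = if (length(kb)) n_shared / length(kb) else NA_real_,
    stringsAsFactors = FALSE
  )
}
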