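# End-to-end runner wiring the stages together: simulate (or read) inputs,
# consensus filtering, TMB and matched-pair sharing, neoantigen candidate
# generation and binder counting, signature scoring and group comparison,
# repertoire summaries, and survival association; writes one report
# directory with a manifest.

.stage_result <- function(ok, value = NULL, error = NULL) {
  list(ok = ok, value = value, error = error)
}

.try_stage <- function(name, manifest_env, code) {
  res <- tryCatch(.stage_result(TRUE, value = code),
                  error = function(e) .stage_result(FALSE,
                                                    error = conditionMessage(e)))
  manifest_env$stages[[name]] <- list(ok = res$ok, error = res$error)
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a simulated cohort (or on
#' files previously written with [write_cohort()]): variant consensus
#' filtering per WES sample, TMB with a primary-vs-metastasis comparison,
#' matched-pair sharing, copy-number segment conversion, neoantigen peptide
#' enumeration with toy affinity prediction and per-source binder counts,
#' expression QC/normalization/replicate averaging and signature group
#' comparison, repertoire summaries and comparisons, and per-origin Cox
#' models with a signature-score covariate. A failing stage stops only its
#' downstream dependents.
#'
#' @param config A `cohort_config`; its seed drives every random draw.
#' @param out_dir Output directory for input files, report tables and the
#'   run manifest.
#' @param input_dir Optional directory of pre-written cohort inputs; when
#'   NULL (default) the cohort is simulated from `config` and written under
#'   `out_dir/inputs`.
#' @param signature_for_survival Signature whose per-patient score enters
#'   the Cox models (default the first signature).
#' @return Invisibly, a list with the per-stage results, the report-table
#'   paths, and the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         input_dir = NULL,
                         signature_for_survival = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report_dir <- file.path(out_dir, "report")
  dir.create(report_dir, showWarnings = FALSE)
  env <- new.env()
  env$stages <- list()

  # --- inputs ---------------------------------------------------------
  sim <- NULL
  if (is.null(input_dir)) {
    sim <- simulate_cohort(config)
    input_dir <- file.path(out_dir, "inputs")
    write_cohort(sim, input_dir)
  }
  design <- utils::read.delim(file.path(input_dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  env$stages$inputs <- list(ok = TRUE, error = NULL)

  results <- list(seed = config$seed, design = design)
  tables <- list()

  # --- variant filtering ---------------------------------------------
  filt <- .try_stage("variant_filtering", env, {
    wes <- design[design$wes_mode != "none", , drop = FALSE]
    consensus <- list()
    wes_mode <- list()
    for (i in seq_len(nrow(wes))) {
      sid <- wes$sample_id[i]
      calls <- read_caller_calls(
        file.path(input_dir, "calls", paste0(sid, ".calls.tsv")),
        caller = "mutect2")  # dialect files carry their own caller column
      consensus[[sid]] <- if (wes$wes_mode[i] == "tumor_only") {
        filter_tumor_only(calls)
      } else {
        filter_matched(calls)
      }
      wes_mode[[sid]] <- wes$wes_mode[i]
    }
    list(consensus = consensus, wes_mode = wes_mode)
  })
  if (filt$ok) {
    results$consensus <- filt$value$consensus
    results$wes_mode <- filt$value$wes_mode
    variants_flat <- do.call(rbind, lapply(results$consensus, as.data.frame))
    rownames(variants_flat) <- NULL
    tables$variants <- variants_flat
  }

  # --- TMB -------------------------------------------------------------
  tmb <- .try_stage("tmb", env, {
    if (!filt$ok) stop("variant filtering failed upstream")
    coverage <- utils::read.delim(file.path(input_dir, "coverage.tsv"),
                                  stringsAsFactors = FALSE)
    rows <- lapply(names(results$consensus), function(sid) {
      cov <- coverage[coverage$sample_id == sid, , drop = FALSE]
      mb <- covered_megabases(cov)
      compute_tmb(results$consensus[[sid]], mb)
    })
    tmb_tab <- do.call(rbind, rows)
    tmb_tab$site <- design$site[match(tmb_tab$sample_id, design$sample_id)]
    pri <- tmb_tab$tmb[tmb_tab$site == "primary"]
    brm <- tmb_tab$tmb[tmb_tab$site == "brm"]
    cmp <- data.frame(
      median_tmb_primary = stats::median(pri),
      median_tmb_brm = stats::median(brm),
      p = suppressWarnings(.wilcox_two_sided(brm, pri))
    )
    list(per_sample = tmb_tab, comparison = cmp)
  })
  if (tmb$ok) {
    results$tmb <- tmb$value$per_sample
    results$tmb_comparison <- tmb$value$comparison
    tables$tmb_summary <- tmb$value$per_sample
    tables$tmb_comparison <- tmb$value$comparison
  }

  # --- matched-pair sharing -------------------------------------------
  share <- .try_stage("pair_sharing", env, {
    if (!filt$ok) stop("variant filtering failed upstream")
    paired <- names(which(table(design$patient_id[
      design$wes_mode == "matched"]) == 2L))
    rows <- lapply(paired, function(p) {
      sids <- design$sample_id[design$patient_id == p &
                               design$wes_mode == "matched"]
      a <- results$consensus[[sids[design$site[match(sids, design$sample_id)] == "primary"][1L]]]
      b <- results$consensus[[sids[design$site[match(sids, design$sample_id)] == "brm"][1L]]]
      pair_sharing(a, b, patient_id = p)
    })
    do.call(rbind, rows)
  })
  if (share$ok) {
    results$sharing <- share$value
    tables$pair_sharing <- share$value
  }

  # --- copy-number segment conversion ---------------------------------
  seg <- .try_stage("seg_conversion", env, {
    segs <- utils::read.delim(file.path(input_dir, "segments.tsv"),
                              stringsAsFactors = FALSE)
    sequenza_to_gistic_seg(segs)
  })
  if (seg$ok) tables$segments_gistic <- seg$value

  # --- expression ------------------------------------------------------
  expr_stage <- .try_stage("expression", env, {
    counts <- read_expression_matrix(
      file.path(input_dir, "expression_counts.tsv"))
    qc <- utils::read.delim(file.path(input_dir, "qc_metrics.tsv"),
                            stringsAsFactors = FALSE)
    keep <- qc_filter_samples(stats::setNames(qc$coding_reads, qc$sample_id))
    counts$values <- counts$values[, intersect(colnames(counts$values), keep),
                                   drop = FALSE]
    normalized <- upper_quartile_normalize(counts)
    rep_map <- utils::read.delim(file.path(input_dir, "replicate_map.tsv"),
                                 stringsAsFactors = FALSE)
    rep_map <- rep_map[rep_map$sample_id %in% colnames(normalized$values), ,
                       drop = FALSE]
    averaged <- average_technical_replicates(normalized, rep_map)
    gmt <- read_gmt(file.path(input_dir, "signatures.gmt"))
    scores <- score_signatures(averaged, gmt)
    labels <- stats::setNames(design$site, design$sample_id)
    cmp <- compare_signature_groups(scores, labels)
    list(normalized = averaged, scores = scores, comparison = cmp)
  })
  if (expr_stage$ok) {
    results$scores <- expr_stage$value$scores
    results$signature_comparison <- expr_stage$value$comparison
    tables$signature_scores <- data.frame(
      signature = rownames(expr_stage$value$scores$scores),
      expr_stage$value$scores$scores, check.names = FALSE)
    tables$signature_comparison <- expr_stage$value$comparison
  }

  # --- neoantigen ------------------------------------------------------
  neo <- .try_stage("neoantigen", env, {
    if (!filt$ok) stop("variant filtering failed upstream")
    prot <- utils::read.delim(file.path(input_dir, "protein_context.tsv"),
                              stringsAsFactors = FALSE)
    cds <- utils::read.delim(file.path(input_dir, "cds_context.tsv"),
                             stringsAsFactors = FALSE)
    rna <- utils::read.delim(file.path(input_dir, "rna_support.tsv"),
                             stringsAsFactors = FALSE)
    rna_support <- stats::setNames(rna$rna_alt_reads, rna$key)
    alleles <- utils::read.delim(file.path(input_dir, "alleles.tsv"),
                                 stringsAsFactors = FALSE)
    candidates <- list()
    for (sid in names(results$consensus)) {
      confirmed <- rna_confirm_variants(results$consensus[[sid]], rna_support)
      keys <- paste(confirmed$chrom, confirmed$pos, confirmed$ref,
                    confirmed$alt, sep = ":")
      pc <- prot[prot$sample_id == sid & prot$source_id %in% keys, ,
                 drop = FALSE]
      for (j in seq_len(nrow(pc))) {
        candidates[[length(candidates) + 1L]] <- enumerate_snv_peptides(
          pc$protein[j], pc$position[j], pc$alt_aa[j],
          sample_id = sid, source_id = pc$source_id[j])
      }
      cc <- cds[cds$sample_id == sid & cds$source_id %in% keys, ,
                drop = FALSE]
      for (j in seq_len(nrow(cc))) {
        candidates[[length(candidates) + 1L]] <- suppressWarnings(
          enumerate_frameshift_peptides(
            cc$cds[j], cc$position[j], cc$ref[j], cc$alt[j],
            sample_id = sid, source_id = cc$source_id[j]))
      }
    }
    cand <- if (length(candidates)) do.call(rbind, candidates)
            else empty_peptides()
    # expressed CTA/ERV/viral features contribute one representative
    # peptide per expressed feature, derived deterministically from the
    # gene name
    if (expr_stage$ok) {
      fc <- utils::read.delim(file.path(input_dir, "antigen_classes.tsv"),
                              stringsAsFactors = FALSE)
      expressed <- call_expressed_antigens(
        expr_stage$value$normalized,
        stats::setNames(fc$source_class, fc$gene))
      if (nrow(expressed)) {
        pep <- vapply(expressed$gene, function(g) {
          idx <- (utf8ToInt(g) %% 20L) + 1L
          paste(AA_ALPHABET[rep_len(idx, 9L)], collapse = "")
        }, character(1))
        cand <- rbind(cand, data.frame(
          sample_id = expressed$sample_id,
          source_class = expressed$source_class, peptide = unname(pep),
          source_id = expressed$gene, novel_positions = "",
          stringsAsFactors = FALSE))
      }
    }
    preds <- list()
    for (sid in unique(cand$sample_id)) {
      al <- alleles$allele[alleles$sample_id == sid]
      if (!length(al)) al <- "HLA-A*02:01"
      preds[[sid]] <- predict_affinities(
        cand[cand$sample_id == sid, , drop = FALSE], al)
    }
    predictions <- if (length(preds)) do.call(rbind, preds)
                   else cbind(empty_peptides(), allele = character(0),
                              kd_nm = numeric(0))
    rownames(predictions) <- NULL
    classify_binders(predictions)
  })
  if (neo$ok) {
    results$binder_counts <- neo$value
    tables$binder_counts <- neo$value
  }

  # --- repertoire ------------------------------------------------------
  rep_stage <- .try_stage("repertoire", env, {
    clono <- read_clonotypes(file.path(input_dir, "clonotypes.tsv"))
    summaries <- summarize_repertoire_all(clono)
    labels <- stats::setNames(design$site, design$sample_id)
    cmp <- rbind(
      compare_repertoire_groups(summaries, labels, "total_reads"),
      compare_repertoire_groups(summaries, labels, "entropy"),
      compare_repertoire_groups(summaries, labels, "entropy_corrected"))
    list(summaries = summaries, comparison = cmp)
  })
  if (rep_stage$ok) {
    results$repertoire <- rep_stage$value$summaries
    results$repertoire_comparison <- rep_stage$value$comparison
    tables$repertoire_summary <- rep_stage$value$summaries
    tables$repertoire_comparison <- rep_stage$value$comparison
  }

  # --- survival --------------------------------------------------------
  surv <- .try_stage("survival", env, {
    clinical <- read_clinical(file.path(input_dir, "clinical.csv"))
    scores <- NULL
    if (expr_stage$ok) {
      sc <- expr_stage$value$scores$scores
      sig <- signature_for_survival %||% rownames(sc)[1L]
      # per-patient score: the primary sample where available, else the
      # metastasis sample
      per_patient <- vapply(clinical$patient_id, function(p) {
        sids <- design$sample_id[design$patient_id == p]
        sids <- sids[order(design$site[match(sids, design$sample_id)],
                           decreasing = TRUE)]  # primary first
        sids <- intersect(sids, colnames(sc))
        if (length(sids)) sc[sig, sids[1L]] else NA_real_
      }, numeric(1))
      scores <- per_patient
    }
    fits <- lapply(SURVIVAL_ORIGINS, function(origin) {
      rows <- suppressMessages(
        build_survival_table(clinical, origin, scores = scores))
      if (!is.null(scores)) {
        rows <- rows[!is.na(rows$signature_score), , drop = FALSE]
      }
      fit <- fit_cox(rows)
      fit$origin <- origin
      fit
    })
    do.call(rbind, fits)
  })
  if (surv$ok) {
    results$cox <- surv$value
    tables$cox_results <- surv$value
  }

  # --- report + manifest ----------------------------------------------
  table_paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(report_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    table_paths[nm] <- p
  }
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    stages = env$stages,
    tables = lapply(names(table_paths), function(nm) {
      list(name = nm, path = table_paths[[nm]],
           rows = nrow(tables[[nm]]),
           md5 = unname(tools::md5sum(table_paths[[nm]])))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  failed <- names(Filter(function(s) !isTRUE(s$ok), env$stages))
  if (length(failed)) {
    warning("stage(s) failed: ", paste(failed, collapse = ", "))
  }
  invisible(list(results = results, tables = table_paths,
                 manifest = manifest, manifest_path = manifest_path,
                 seed = config$seed,
                 consensus = results$consensus,
                 wes_mode = results$wes_mode,
                 signature_comparison = results$signature_comparison,
                 repertoire_comparison = results$repertoire_comparison,
                 cox = results$cox,
                 failed_stages = failed))
}

#' Load a YAML pipeline configuration
#'
#' @param path YAML file whose top-level keys override [cohort_config()]
#'   defaults.
#' @return A `cohort_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cohort_config, raw)
}
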