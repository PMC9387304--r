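# In-silico MHC class I candidate peptide enumeration from tumor antigen
# sources (SNVs, frameshift/in-frame indels, gene fusions, expressed
# CTA/self, ERV and viral features), pluggable affinity prediction, and
# 500/50 nM binder classification.

ANTIGEN_SOURCES <- c("snv", "indel", "fusion", "splice", "cta_self", "erv",
                     "viral")
MHC_LENGTHS_DEFAULT <- 8:11

.check_peptide_alphabet <- function(x) {
  residues <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  alien <- setdiff(residues, AA_ALPHABET)
  if (length(alien)) {
    stop("non-standard residue(s) in peptide: ", paste(alien, collapse = ", "))
  }
  invisible(TRUE)
}

.peptide_row <- function(sample_id, source_class, peptide, source_id,
                         novel_positions) {
  data.frame(
    sample_id = sample_id, source_class = source_class, peptide = peptide,
    source_id = source_id,
    novel_positions = vapply(novel_positions, paste, character(1),
                             collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' @rdname enumerate_snv_peptides
#' @return `empty_peptides()` returns a zero-row candidate table.
#' @export
empty_peptides <- function() {
  data.frame(sample_id = character(), source_class = character(),
             peptide = character(), source_id = character(),
             novel_positions = character(), stringsAsFactors = FALSE)
}

#' Enumerate SNV-derived candidate peptides
#'
#' All k-mers of the mutated protein whose window covers the substituted
#' residue, for each requested length. Interior positions yield exactly k
#' windows per length; windows are truncated at the sequence ends.
#'
#' @param protein Reference protein sequence (single string, 1-based
#'   indexing).
#' @param position Position of the substituted residue (1-based).
#' @param alt_aa Mutant residue (must differ from the reference residue;
#'   stop gains are handled by the truncation machinery, not here).
#' @param lengths Peptide lengths to emit (default 8-11, standard MHC-I).
#' @param sample_id,source_id Labels carried into the candidate table.
#' @return Candidate-peptide data.frame with `novel_positions` marking the
#'   mutated index within each window.
#' @export
enumerate_snv_peptides <- function(protein, position, alt_aa,
                                   lengths = MHC_LENGTHS_DEFAULT,
                                   sample_id = NA_character_,
                                   source_id = NA_character_) {
  L <- nchar(protein)
  if (position < 1L || position > L) stop("position outside protein")
  ref_aa <- substr(protein, position, position)
  if (identical(alt_aa, ref_aa)) {
    stop("alternate residue equals the reference residue")
  }
  if (identical(alt_aa, "*")) {
    stop("stop-gain substitutions are handled by truncation enumeration")
  }
  .check_peptide_alphabet(alt_aa)
  mutant <- paste0(substr(protein, 1L, position - 1L), alt_aa,
                   substr(protein, position + 1L, L))
  rows <- lapply(sort(unique(lengths)), function(k) {
    starts <- seq.int(max(1L, position - k + 1L), min(position, L - k + 1L))
    starts <- starts[starts >= 1L & starts + k - 1L <= L]
    if (!length(starts)) return(NULL)
    peptides <- substring(mutant, starts, starts + k - 1L)
    .peptide_row(sample_id, "snv", peptides, source_id,
                 as.list(position - starts + 1L))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_peptides() else out
}

.translate_to_stop <- function(nt, warn_no_stop = TRUE, context = "CDS") {
  nt <- toupper(nt)
  usable <- nchar(nt) - nchar(nt) %% 3L
  if (usable < 3L) return("")
  # no.init.codon: a frame-shifted or mid-gene sequence must not have its
  # first codon reinterpreted as an alternative initiator (TTG/CTG -> M)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, usable)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    substr(aa, 1L, stop_at - 1L)
  } else {
    if (warn_no_stop) {
      warning("no stop codon encountered before the end of the ", context,
              "; translated to sequence end")
    }
    aa
  }
}

# Positions of a peptide that differ from the best-matching (fewest
# mismatches) equal-length window of any reference protein. A peptide that
# is a substring of a reference protein has no novel positions.
.novel_positions <- function(peptide, reference_proteins) {
  k <- nchar(peptide)
  pep <- strsplit(peptide, "")[[1]]
  best <- seq_len(k)  # worst case: everything novel
  for (ref in reference_proteins) {
    L <- nchar(ref)
    if (L < k) next
    refc <- strsplit(ref, "")[[1]]
    for (start in seq_len(L - k + 1L)) {
      mism <- which(pep != refc[start:(start + k - 1L)])
      if (length(mism) < length(best)) best <- mism
      if (!length(best)) return(integer(0))
    }
  }
  best
}

#' Enumerate indel-derived candidate peptides
#'
#' Applies the indel to the coding sequence, translates the mutant CDS with
#' the standard codon table from the start codon through the first stop in
#' the (possibly shifted) reading frame, and emits the k-mers of the mutant
#' protein that are absent from the reference protein. Frameshifts produce
#' novel C-terminal tails; in-frame indels produce junction-spanning windows
#' only.
#'
#' @param cds Reference coding sequence (nucleotides, in frame from
#'   position 1).
#' @param position 1-based position of the first affected base.
#' @param ref,alt Reference and alternate alleles at that position (VCF
#'   style, anchored).
#' @param lengths Peptide lengths to emit.
#' @param sample_id,source_id Labels carried into the candidate table.
#' @return Candidate-peptide data.frame (`source_class = "indel"`).
#' @export
enumerate_frameshift_peptides <- function(cds, position, ref, alt,
                                          lengths = MHC_LENGTHS_DEFAULT,
                                          sample_id = NA_character_,
                                          source_id = NA_character_) {
  cds <- toupper(cds)
  if (identical(ref, alt)) stop("indel with alt equal to ref")
  if (substr(cds, position, position + nchar(ref) - 1L) != toupper(ref)) {
    stop("ref allele does not match the CDS at the given position")
  }
  mutant_cds <- paste0(substr(cds, 1L, position - 1L), toupper(alt),
                       substr(cds, position + nchar(ref), nchar(cds)))
  ref_protein <- .translate_to_stop(cds, warn_no_stop = FALSE)
  mut_protein <- .translate_to_stop(mutant_cds, context = "mutant CDS")
  enumerate_novel_kmers(mut_protein, ref_protein, lengths,
                        sample_id = sample_id, source_id = source_id,
                        source_class = "indel")
}

#' @rdname enumerate_frameshift_peptides
#' @param mutant_protein,reference_protein Protein sequences to compare.
#' @param source_class Antigen source label for the emitted rows.
#' @details `enumerate_novel_kmers()` is the shared core: every k-mer of the
#'   mutant protein that is not a substring of the reference protein is
#'   emitted, with `novel_positions` the mismatch positions against the
#'   best-matching reference window.
#' @export
enumerate_novel_kmers <- function(mutant_protein, reference_protein,
                                  lengths = MHC_LENGTHS_DEFAULT,
                                  sample_id = NA_character_,
                                  source_id = NA_character_,
                                  source_class = "indel") {
  refs <- reference_protein[nchar(reference_protein) > 0L]
  rows <- lapply(sort(unique(lengths)), function(k) {
    L <- nchar(mutant_protein)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    peptides <- substring(mutant_protein, starts, starts + k - 1L)
    novel <- !vapply(peptides, function(p)
      any(vapply(refs, function(r) grepl(p, r, fixed = TRUE), logical(1))),
      logical(1))
    if (!any(novel)) return(NULL)
    peptides <- peptides[novel]
    np <- lapply(peptides, .novel_positions, reference_proteins = refs)
    .peptide_row(sample_id, source_class, peptides, source_id, np)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_peptides())
  rownames(out) <- NULL
  out
}

#' Enumerate fusion-junction candidate peptides
#'
#' Concatenates the retained portion of the 5' partner protein with the
#' portion of the 3' partner from its breakpoint onward (frame preserved per
#' the provided breakpoint phase) and emits the k-mers spanning the junction
#' (containing residues from both partners).
#'
#' @param protein_5p,protein_3p Partner protein sequences.
#' @param breakpoint_5p Last retained residue of the 5' partner (1-based).
#' @param breakpoint_3p First retained residue of the 3' partner (1-based).
#' @param lengths Peptide lengths to emit.
#' @param sample_id,source_id Labels carried into the candidate table.
#' @return Candidate-peptide data.frame (`source_class = "fusion"`).
#' @export
enumerate_fusion_peptides <- function(protein_5p, protein_3p, breakpoint_5p,
                                      breakpoint_3p,
                                      lengths = MHC_LENGTHS_DEFAULT,
                                      sample_id = NA_character_,
                                      source_id = NA_character_) {
  if (breakpoint_5p < 1L || breakpoint_5p > nchar(protein_5p)) {
    stop("breakpoint_5p outside the 5' partner protein")
  }
  if (breakpoint_3p < 1L || breakpoint_3p > nchar(protein_3p)) {
    stop("breakpoint_3p outside the 3' partner protein")
  }
  left <- substr(protein_5p, 1L, breakpoint_5p)
  right <- substr(protein_3p, breakpoint_3p, nchar(protein_3p))
  junction <- paste0(left, right)
  j <- nchar(left)  # junction lies between positions j and j+1
  rows <- lapply(sort(unique(lengths)), function(k) {
    Lj <- nchar(junction)
    starts <- seq.int(max(1L, j - k + 2L), min(j, Lj - k + 1L))
    starts <- starts[starts >= 1L & starts + k - 1L <= Lj & starts <= j &
                     starts + k - 1L >= j + 1L]
    if (!length(starts)) return(NULL)
    peptides <- substring(junction, starts, starts + k - 1L)
    np <- lapply(peptides, .novel_positions,
                 reference_proteins = c(protein_5p, protein_3p))
    .peptide_row(sample_id, "fusion", peptides, source_id, np)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_peptides())
  rownames(out) <- NULL
  out
}

#' Call expressed antigen features from RNA alone
#'
#' CTA/self, ERV and viral antigen features are called expressed in a sample
#' when their normalized log2 expression exceeds the threshold; only
#' expressed features contribute their peptide sets downstream.
#'
#' @param expression Normalized `expr_matrix`.
#' @param feature_classes Named character vector or data.frame
#'   (`gene`, `source_class`) mapping genes to `cta_self`/`erv`/`viral`.
#' @param threshold Expression threshold on the normalized log2 scale
#'   (default 1; no published value exists, so this is configuration).
#' @return data.frame `sample_id`, `gene`, `source_class`, `expression`.
#' @export
call_expressed_antigens <- function(expression, feature_classes,
                                    threshold = 1) {
  if (is.data.frame(feature_classes)) {
    fc <- stats::setNames(feature_classes$source_class, feature_classes$gene)
  } else {
    fc <- feature_classes
  }
  bad <- setdiff(unique(unname(fc)), ANTIGEN_SOURCES)
  if (length(bad)) stop("unknown antigen source class(es): ",
                        paste(bad, collapse = ", "))
  genes <- intersect(names(fc), rownames(expression$values))
  if (!length(genes)) {
    stop("no antigen feature genes found in the expression matrix")
  }
  vals <- expression$values[genes, , drop = FALSE]
  hits <- which(vals > threshold, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(sample_id = character(), gene = character(),
                      source_class = character(), expression = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    sample_id = colnames(vals)[hits[, "col"]],
    gene = rownames(vals)[hits[, "row"]],
    source_class = unname(fc[rownames(vals)[hits[, "row"]]]),
    expression = vals[hits],
    stringsAsFactors = FALSE
  )
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

#' Confirm variant expression with RNA read support
#'
#' @param variants A `consensus_variants` table.
#' @param rna_support Named numeric vector: variant key
#'   (`chrom:pos:ref:alt`) to RNA alt read count. Keys absent from the
#'   vector count as zero support.
#' @param min_rna_reads Minimum RNA alt reads to confirm (default 1).
#' @return The confirmed subset of `variants`.
#' @export
rna_confirm_variants <- function(variants, rna_support, min_rna_reads = 1) {
  keys <- .variant_key(variants)
  support <- rna_support[keys]
  support[is.na(support)] <- 0
  out <- variants[support >= min_rna_reads, , drop = FALSE]
  rownames(out) <- NULL
  .as_consensus(out, attr(variants, "sample_id"))
}

.allele_hash <- function(allele) {
  codes <- utf8ToInt(allele)
  sum(codes * seq_along(codes) * 131) %% 100003
}

#' Deterministic toy MHC-I affinity predictor
#'
#' A fixed position-weight scheme seeded from the allele name: each
#' (residue, position, allele) combination contributes a bounded weight, the
#' peptide score is the mean weight, and the score is mapped exponentially
#' onto roughly 1-50,000 nM. The same (peptide, allele) pair always yields
#' the same Kd, with no random-number state consumed. This is a bundled
#' stand-in exercising the predictor interface; an external affinity tool
#' can be plugged in wherever a function with this signature is accepted.
#'
#' @param peptides Character vector of peptides (lengths 8-11).
#' @param allele MHC-I allele name (e.g. `"HLA-A*02:01"`).
#' @return data.frame `peptide`, `allele`, `kd_nm`.
#' @export
toy_affinity_predictor <- function(peptides, allele) {
  if (!length(peptides)) {
    return(data.frame(peptide = character(), allele = character(),
                      kd_nm = numeric(), stringsAsFactors = FALSE))
  }
  lens <- nchar(peptides)
  if (any(lens < 8L | lens > 11L)) {
    stop("peptides must be 8-11 residues long")
  }
  .check_peptide_alphabet(peptides)
  h <- .allele_hash(allele)
  scores <- vapply(peptides, function(p) {
    aa_idx <- match(strsplit(p, "")[[1]], AA_ALPHABET)
    pos <- seq_along(aa_idx)
    mean(sin(aa_idx * 31 + pos * 7 + h))
  }, numeric(1), USE.NAMES = FALSE)
  # scores in [-1, 1]; map exponentially to ~1..50,000 nM
  kd <- exp(((scores + 1) / 2) * log(5e4))
  data.frame(peptide = peptides, allele = allele, kd_nm = kd,
             stringsAsFactors = FALSE)
}

#' Predict affinities for candidate peptides over sample alleles
#'
#' @param candidates Candidate-peptide data.frame.
#' @param alleles Character vector of MHC-I alleles for the sample.
#' @param predictor Function `(peptides, allele) -> data.frame(peptide,
#'   allele, kd_nm)`; defaults to [toy_affinity_predictor()].
#' @return data.frame with candidate columns plus `allele` and `kd_nm`.
#' @export
predict_affinities <- function(candidates, alleles,
                               predictor = toy_affinity_predictor) {
  if (!nrow(candidates)) {
    out <- candidates
    out$allele <- character(0)
    out$kd_nm <- numeric(0)
    return(out)
  }
  per_allele <- lapply(alleles, function(a) {
    pred <- predictor(candidates$peptide, a)
    stopifnot(all(c("peptide", "allele", "kd_nm") %in% names(pred)))
    cbind(candidates, pred[, c("allele", "kd_nm")])
  })
  out <- do.call(rbind, per_allele)
  rownames(out) <- NULL
  out
}

#' Classify binders and count them per antigen source
#'
#' A peptide counts as a positive binder iff its minimum Kd over alleles is
#' strictly below 500 nM, and a strong binder iff strictly below 50 nM.
#' Each distinct (peptide, source_class) is counted once per sample;
#' duplicated prediction rows and row order do not affect the counts.
#'
#' @param predictions Output of [predict_affinities()] (must carry
#'   `sample_id`, `source_class`, `peptide`, `kd_nm`).
#' @param positive_nm,strong_nm Classification thresholds in nM.
#' @return data.frame `sample_id`, `source_class`, `n_candidates`,
#'   `n_positive`, `n_strong`.
#' @export
classify_binders <- function(predictions, positive_nm = 500, strong_nm = 50) {
  req <- c("sample_id", "source_class", "peptide", "kd_nm")
  missing <- setdiff(req, names(predictions))
  if (length(missing)) {
    stop("prediction table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(predictions$source_class), ANTIGEN_SOURCES)
  if (length(bad)) stop("unknown antigen source class(es): ",
                        paste(bad, collapse = ", "))
  if (!nrow(predictions)) {
    return(data.frame(sample_id = character(), source_class = character(),
                      n_candidates = integer(), n_positive = integer(),
                      n_strong = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(predictions$sample_id, predictions$source_class,
               predictions$peptide, sep = "\r")
  min_kd <- tapply(predictions$kd_nm, key, min)
  info <- predictions[!duplicated(key), c("sample_id", "source_class")]
  info$min_kd <- as.numeric(min_kd[key[!duplicated(key)]])
  grp <- paste(info$sample_id, info$source_class, sep = "\r")
  ug <- !duplicated(grp)
  out <- data.frame(
    sample_id = info$sample_id[ug], source_class = info$source_class[ug],
    stringsAsFactors = FALSE
  )
  split_kd <- split(info$min_kd, factor(grp, levels = grp[ug]))
  out$n_candidates <- vapply(split_kd, length, integer(1))
  out$n_positive <- vapply(split_kd, function(x)
    sum(x < positive_nm), integer(1))
  out$n_strong <- vapply(split_kd, function(x)
    sum(x < strong_nm), integer(1))
  out <- out[order(out$sample_id, out$source_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
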