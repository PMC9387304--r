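# Expression QC, upper-quartile log2 normalization, technical-replicate
# averaging, immune gene-signature metagene scoring, and rank-based group
# comparison with FDR control.

#' QC-filter samples by coding read count
#'
#' Samples with fewer than `min_reads` coding reads are excluded (strict
#' "less than"; a sample at exactly the cutoff is retained). The default
#' 20 million coding reads approximates the minimal depth for
#' microarray-equivalent detection.
#'
#' @param metrics Named numeric vector of per-sample coding read counts.
#' @param min_reads Inclusion cutoff (default 2e7).
#' @return Character vector of retained sample ids.
#' @export
qc_filter_samples <- function(metrics, min_reads = 2e7) {
  if (any(metrics < 0, na.rm = TRUE)) stop("negative read counts")
  names(metrics)[!is.na(metrics) & metrics >= min_reads]
}

.uq_nonzero <- function(x) {
  nz <- x[x > 0]
  if (!length(nz)) return(NA_real_)
  stats::quantile(nz, 0.75, type = 7, names = FALSE)
}

#' Upper-quartile log2 normalization
#'
#' Per sample, the scale factor is the linear-interpolation 75th percentile
#' of that sample's nonzero gene counts. Counts are rescaled so every sample
#' shares a common upper quartile (the geometric mean of the per-sample
#' upper quartiles, or a fixed reference), then transformed log2(x + 1).
#' Scaling precedes the log transform.
#'
#' @param counts Raw-count `expr_matrix` (or plain genes x samples matrix).
#' @param reference Optional fixed common upper quartile; default is the
#'   geometric mean of the per-sample upper quartiles.
#' @return Normalized `expr_matrix` (`normalized = TRUE`).
#' @export
upper_quartile_normalize <- function(counts, reference = NULL) {
  if (is.matrix(counts)) counts <- expr_matrix(counts, normalized = FALSE)
  if (counts$normalized) stop("matrix is already normalized")
  v <- counts$values
  if (any(v < 0)) stop("negative counts")
  uq <- apply(v, 2, .uq_nonzero)
  if (anyNA(uq)) {
    stop("sample with all-zero counts: ",
         paste(colnames(v)[is.na(uq)], collapse = ", "))
  }
  ref <- if (is.null(reference)) exp(mean(log(uq))) else reference
  scaled <- sweep(v, 2, ref / uq, `*`)
  expr_matrix(log2(scaled + 1), normalized = TRUE)
}

#' Average technical replicates
#'
#' Gene-wise arithmetic mean of replicate columns on the normalized log2
#' scale, yielding one column per biological sample.
#'
#' @param expression Normalized `expr_matrix`.
#' @param replicate_map data.frame with columns `sample_id`,
#'   `biosample_id`, and optionally `patient_id` (groups spanning more than
#'   one patient are rejected).
#' @return `expr_matrix` with one column per biological sample.
#' @export
average_technical_replicates <- function(expression, replicate_map) {
  stopifnot(inherits(expression, "expr_matrix"))
  req <- c("sample_id", "biosample_id")
  missing <- setdiff(req, names(replicate_map))
  if (length(missing)) {
    stop("replicate map missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(replicate_map$patient_id)) {
    n_pat <- tapply(replicate_map$patient_id, replicate_map$biosample_id,
                    function(x) length(unique(x)))
    if (any(n_pat > 1L)) {
      stop("replicate group spans multiple patients: ",
           paste(names(n_pat)[n_pat > 1L], collapse = ", "))
    }
  }
  v <- expression$values
  missing_samples <- setdiff(replicate_map$sample_id, colnames(v))
  if (length(missing_samples)) {
    stop("replicate map names samples absent from the matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  bio <- unique(replicate_map$biosample_id)
  out <- vapply(bio, function(b) {
    cols <- replicate_map$sample_id[replicate_map$biosample_id == b]
    rowMeans(v[, cols, drop = FALSE])
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), bio))
  expr_matrix(out, normalized = expression$normalized)
}

#' Metagene score for one signature
#'
#' The per-sample median of normalized log2 expression over the signature
#' genes present in the matrix. Duplicate gene symbols within a signature
#' and gene order do not affect the score.
#'
#' @param expression Normalized `expr_matrix`.
#' @param signature Character vector of gene symbols.
#' @param name Signature name used in error messages.
#' @return Named numeric vector of per-sample scores (median log2 units).
#' @export
metagene_score <- function(expression, signature, name = "signature") {
  stopifnot(inherits(expression, "expr_matrix"))
  if (!expression$normalized) {
    stop("metagene scores are defined on the normalized log2 scale")
  }
  genes <- intersect(unique(signature), rownames(expression$values))
  if (!length(genes)) {
    stop("no genes of ", name, " found in the expression matrix")
  }
  apply(expression$values[genes, , drop = FALSE], 2, stats::median)
}

#' Score a family of signatures
#'
#' @param expression Normalized `expr_matrix`.
#' @param gmt Named list of gene sets (see [read_gmt()]).
#' @return A `signature_scores` object: `scores` and per-signature
#'   standardized `z_scores` (signatures x samples matrices).
#' @export
score_signatures <- function(expression, gmt) {
  scores <- t(vapply(names(gmt), function(nm) {
    metagene_score(expression, gmt[[nm]], name = nm)
  }, numeric(ncol(expression$values))))
  colnames(scores) <- colnames(expression$values)
  z <- t(apply(scores, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(scores)
  structure(list(scores = scores, z_scores = z), class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("signature_scores: %d signatures x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

.wilcox_two_sided <- function(a, b) {
  if (!length(a) || !length(b)) stop("a comparison group is empty")
  # no continuity correction: a fully overlapping comparison (W at its
  # null mean) yields p = 1 exactly
  stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL,
                     correct = FALSE)$p.value
}

#' Compare signature scores between two groups
#'
#' Per signature: scores are Z-transformed across all samples, a two-sided
#' Wilcoxon rank-sum test (exact for small tie-free samples, otherwise
#' normal approximation with mid-ranks and tie-corrected variance) compares
#' the groups, and Benjamini-Hochberg adjustment is applied across the
#' signature family. Direction is the sign of (group A median - group B
#' median) on the z scale.
#'
#' @param scores A `signature_scores` object.
#' @param labels Named character vector sample id -> group label
#'   (exactly two levels, e.g. "primary"/"brm").
#' @param group_a,group_b Which label is group A / group B; default the
#'   first and second sorted unique label.
#' @return data.frame `signature`, `direction`, `p`, `q`.
#' @export
compare_signature_groups <- function(scores, labels, group_a = NULL,
                                     group_b = NULL) {
  stopifnot(inherits(scores, "signature_scores"))
  samples <- intersect(colnames(scores$z_scores), names(labels))
  if (!length(samples)) stop("no labeled samples found in score table")
  lab <- labels[samples]
  levels <- sort(unique(lab))
  if (length(levels) != 2L) stop("labels must define exactly two groups")
  if (is.null(group_a)) group_a <- levels[1L]
  if (is.null(group_b)) group_b <- levels[2L]
  a_ids <- samples[lab == group_a]
  b_ids <- samples[lab == group_b]
  if (!length(a_ids) || !length(b_ids)) stop("a comparison group is empty")
  z <- scores$z_scores[, samples, drop = FALSE]
  res <- lapply(rownames(z), function(sig) {
    a <- z[sig, a_ids]
    b <- z[sig, b_ids]
    p <- suppressWarnings(.wilcox_two_sided(a, b))
    data.frame(signature = sig,
               direction = sign(stats::median(a) - stats::median(b)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
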