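# Readers/writers for the external formats the pipeline consumes, plus the
# Sequenza -> GISTIC segment conversion. All downstream modules work on the
# plain data.frames produced here.

VARIANT_CALLERS <- c("strelka2", "mutect2", "cadabra")
CLONOTYPE_CHAINS <- c("TRA", "TRB", "IGH", "IGK", "IGL")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

VARIANT_CALL_COLUMNS <- c(
  "sample_id", "caller", "chrom", "pos", "ref", "alt", "variant_class",
  "coding", "quality", "somatic_evs", "alt_reads", "depth", "maf",
  "normal_maf", "pop_af_max"
)

#' Default per-caller VCF field mapping
#'
#' The printed filter thresholds name per-caller quality scores but not VCF
#' fields, so the mapping from VCF records to the `quality` (and, for
#' Strelka2, `somatic_evs`) columns is configuration. Each entry gives the
#' source of the caller's quality score, either `"QUAL"` (the VCF QUAL
#' column) or `"INFO:<key>"`.
#'
#' @return Named list with one entry per supported caller.
#' @export
caller_field_defaults <- function() {
  list(
    strelka2 = list(quality = "INFO:QSS", somatic_evs = "INFO:SomaticEVS"),
    mutect2  = list(quality = "INFO:TLOD"),
    cadabra  = list(quality = "QUAL")
  )
}

#' Coding consequence whitelist
#'
#' Consequence strings (one configured annotation key per VCF) counted as
#' protein-coding for the coding-only filter rule. No annotation engine is
#' embedded; the consequence must already be present in the input.
#'
#' @return Character vector of consequence terms.
#' @export
coding_consequences <- function() {
  c("missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
    "start_lost", "frameshift_variant", "inframe_insertion",
    "inframe_deletion", "protein_altering_variant", "coding_sequence_variant")
}

.classify_variant <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

.validate_variant_calls <- function(df) {
  stopifnot(all(VARIANT_CALL_COLUMNS %in% names(df)))
  bad <- !df$caller %in% VARIANT_CALLERS
  if (any(bad)) {
    stop("unknown caller(s): ", paste(unique(df$caller[bad]), collapse = ", "))
  }
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  expect_class <- .classify_variant(df$ref, df$alt)
  if (any(df$variant_class != expect_class)) {
    i <- which(df$variant_class != expect_class)[1L]
    stop(sprintf("variant_class inconsistent with alleles at row %d (%s>%s)",
                 i, df$ref[i], df$alt[i]))
  }
  both <- !is.na(df$alt_reads) & !is.na(df$depth)
  if (any(both & df$alt_reads > df$depth)) {
    stop("alt_reads exceeds depth for at least one call")
  }
  df
}

.read_vcf_calls <- function(path, caller, field_map, coding_key,
                            coding_whitelist) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(empty_variant_calls())
  }
  info_of <- function(key, numeric = TRUE) {
    vals <- vcfR::extract.info(vcf, element = key, as.numeric = numeric)
    if (is.null(vals)) rep(NA_real_, n) else vals
  }
  spec <- field_map[[caller]]
  if (is.null(spec)) stop("no field mapping configured for caller ", caller)
  field_vals <- function(src) {
    if (identical(src, "QUAL")) {
      suppressWarnings(as.numeric(fix[, "QUAL"]))
    } else if (grepl("^INFO:", src)) {
      info_of(sub("^INFO:", "", src))
    } else {
      stop("unsupported field source: ", src)
    }
  }
  quality <- field_vals(spec$quality)
  if (all(is.na(quality))) {
    stop(sprintf("configured quality field '%s' missing from %s", spec$quality,
                 path))
  }
  somatic_evs <- if (!is.null(spec$somatic_evs)) field_vals(spec$somatic_evs)
                 else rep(NA_real_, n)
  csq <- vcfR::extract.info(vcf, element = coding_key)
  coding <- if (is.null(csq)) rep(FALSE, n) else {
    vapply(strsplit(ifelse(is.na(csq), "", csq), "[,&]"),
           function(x) any(x %in% coding_whitelist), logical(1))
  }
  depth <- info_of("DP")
  alt_reads <- info_of("AD_ALT")
  maf <- info_of("MAF")
  normal_maf <- info_of("NMAF")
  pop_af <- info_of("POPAF")
  sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))

  rows <- lapply(seq_len(n), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0L || any(!nzchar(alts))) {
      stop(sprintf("unparseable ALT in %s record %d", path, i))
    }
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos)) stop(sprintf("unparseable POS in %s record %d", path, i))
    data.frame(
      sample_id = sample_id, caller = caller, chrom = fix[i, "CHROM"],
      pos = pos, ref = fix[i, "REF"], alt = alts,
      variant_class = .classify_variant(fix[i, "REF"], alts),
      coding = coding[i], quality = quality[i], somatic_evs = somatic_evs[i],
      alt_reads = alt_reads[i], depth = depth[i], maf = maf[i],
      normal_maf = normal_maf[i], pop_af_max = pop_af[i],
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  out$alt_reads <- as.integer(round(out$alt_reads))
  out$depth <- as.integer(round(out$depth))
  .validate_variant_calls(out)
}

#' Read one caller's somatic calls
#'
#' Accepts either VCF v4.x or the package's tabular dialect (a TSV with the
#' `VariantCall` columns). VCF records are split per ALT allele; the caller's
#' quality score is mapped from the configured field and the coding flag is
#' derived from a configured consequence annotation key.
#'
#' @param path Path to a VCF (`##fileformat=VCF...` header) or variant TSV.
#' @param caller One of `"strelka2"`, `"mutect2"`, `"cadabra"`.
#' @param field_map Per-caller quality field mapping, see
#'   [caller_field_defaults()].
#' @param coding_key INFO key holding the consequence annotation.
#' @param coding_whitelist Consequence terms counted as coding.
#' @return A data.frame of variant calls, one row per ALT allele.
#' @export
read_caller_calls <- function(path, caller,
                              field_map = caller_field_defaults(),
                              coding_key = "Consequence",
                              coding_whitelist = coding_consequences()) {
  caller <- match.arg(caller, VARIANT_CALLERS)
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    .read_vcf_calls(path, caller, field_map, coding_key, coding_whitelist)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(c("sample_id", "chrom", "pos", "ref", "alt"), names(df))
    if (length(missing)) {
      stop("variant table missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    if (is.null(df$caller)) df$caller <- caller
    for (col in VARIANT_CALL_COLUMNS) {
      if (is.null(df[[col]])) df[[col]] <- NA_real_
    }
    if (all(is.na(df$variant_class))) {
      df$variant_class <- .classify_variant(df$ref, df$alt)
    }
    df$coding <- as.logical(df$coding)
    df$pos <- as.integer(df$pos)
    # coerce to the canonical schema so all-NA columns keep their types
    for (col in c("alt_reads", "depth")) df[[col]] <- as.integer(df[[col]])
    for (col in c("quality", "somatic_evs", "maf", "normal_maf",
                  "pop_af_max")) {
      df[[col]] <- as.numeric(df[[col]])
    }
    for (col in c("sample_id", "caller", "chrom", "ref", "alt",
                  "variant_class")) {
      df[[col]] <- as.character(df[[col]])
    }
    .validate_variant_calls(df[, VARIANT_CALL_COLUMNS])
  }
}

#' @rdname read_caller_calls
#' @return `empty_variant_calls()` returns a zero-row variant call table.
#' @export
empty_variant_calls <- function() {
  df <- data.frame(
    sample_id = character(), caller = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    variant_class = character(), coding = logical(), quality = numeric(),
    somatic_evs = numeric(), alt_reads = integer(), depth = integer(),
    maf = numeric(), normal_maf = numeric(), pop_af_max = numeric(),
    stringsAsFactors = FALSE
  )
  df
}

#' Convert Sequenza depth-ratio segments to GISTIC SEG rows
#'
#' Applies the log2(x) - 1 transformation to the raw Sequenza depth ratio,
#' producing the six-column SEG layout. Note the convention maps a neutral
#' depth ratio of 1 to Seg.CN -1 (not 0); the transformation is applied
#' exactly as used upstream of GISTIC, and values should be interpreted
#' accordingly.
#'
#' @param segments data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `n_markers`, `depth_ratio` (all coordinates 1-based inclusive).
#' @return data.frame with columns `Sample`, `Chromosome`, `Start`, `End`,
#'   `Num_Probes`, `Seg.CN`.
#' @export
sequenza_to_gistic_seg <- function(segments) {
  req <- c("sample_id", "chrom", "start", "end", "n_markers", "depth_ratio")
  missing <- setdiff(req, names(segments))
  if (length(missing)) {
    stop("segment table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!(segments$depth_ratio > 0) | is.na(segments$depth_ratio))
  if (length(bad)) {
    stop(sprintf("non-positive depth ratio in segment %s:%d-%d (row %d)",
                 segments$chrom[bad[1]], segments$start[bad[1]],
                 segments$end[bad[1]], bad[1]))
  }
  if (any(segments$start > segments$end)) stop("segment start exceeds end")
  data.frame(
    Sample = segments$sample_id,
    Chromosome = segments$chrom,
    Start = segments$start,
    End = segments$end,
    Num_Probes = segments$n_markers,
    Seg.CN = log2(segments$depth_ratio) - 1,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

#' Read a gene-level expression count matrix
#'
#' TSV with gene symbols in the first column and one column per sample.
#'
#' @param path TSV path.
#' @return An `expr_matrix` object (genes x samples), `normalized = FALSE`.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- genes
  expr_matrix(values, normalized = FALSE)
}

#' Construct an expression matrix object
#'
#' @param values Numeric genes x samples matrix with dimnames.
#' @param normalized Whether values are on the normalized log2 scale.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, normalized = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  structure(list(values = values, normalized = normalized),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "log2-normalized" else "raw counts"))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, then gene symbols per line).
#' @return Named list of unique gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("GMT line with fewer than 3 fields: ", substr(line, 1, 60))
    }
    unique(parts[-c(1L, 2L)])
  })
  names(sets) <- vapply(lines, function(line) {
    strsplit(line, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an AIRR-style clonotype table
#'
#' @param path TSV with columns `sample_id`, `chain`, `cdr3`, `read_count`.
#' @return Validated clonotype data.frame.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_clonotypes(df)
}

#' @rdname read_clonotypes
#' @param df Clonotype data.frame to validate in place.
#' @export
validate_clonotypes <- function(df) {
  req <- c("sample_id", "chain", "cdr3", "read_count")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("clonotype table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !df$chain %in% CLONOTYPE_CHAINS
  if (any(bad)) {
    stop("unknown chain label(s): ", paste(unique(df$chain[bad]), collapse = ", "))
  }
  if (any(df$read_count < 1L)) stop("read_count must be >= 1")
  residues <- unique(strsplit(paste(df$cdr3, collapse = ""), "")[[1]])
  alien <- setdiff(residues, AA_ALPHABET)
  if (length(alien)) {
    stop("CDR3 contains non-amino-acid character(s): ",
         paste(alien, collapse = ", "))
  }
  df$read_count <- as.integer(df$read_count)
  df[, req]
}

#' Read the clinical table
#'
#' CSV with one row per patient: `patient_id`, `age_at_primary_dx`, `stage`
#' (I-IV), `race`, day-offset columns `t_primary_dx`, `t_met_dx`, `t_brm_dx`,
#' `t_event`, and logical `event`. Date ordering is validated where present.
#'
#' @param path CSV path.
#' @return Validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param df Clinical data.frame to validate.
#' @export
validate_clinical <- function(df) {
  req <- c("patient_id", "age_at_primary_dx", "stage", "race", "t_primary_dx",
           "t_met_dx", "t_brm_dx", "t_event", "event")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("clinical table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(df$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage must be one of I, II, III, IV")
  }
  df$event <- as.logical(df$event)
  ord <- function(a, b, label) {
    both <- !is.na(a) & !is.na(b)
    if (any(a[both] > b[both])) {
      stop("clinical date ordering violated (", label, ") for patient ",
           df$patient_id[both][which(a[both] > b[both])[1]])
    }
  }
  ord(df$t_primary_dx, df$t_met_dx, "primary <= met")
  ord(df$t_met_dx, df$t_brm_dx, "met <= brm")
  ord(df$t_brm_dx, df$t_event, "brm <= event")
  df[, req]
}

#' Tab-separated writers for pipeline tables
#'
#' All writers emit TSV with a header row, no quoting of numerics, and `NA`
#' for missing optional fields, so that reading the file back reproduces the
#' table field-for-field.
#'
#' @param df Table to write.
#' @param path Output path.
#' @name writers
NULL

#' @rdname writers
#' @export
write_tsv <- function(df, path) {
  # 17 significant digits round-trips IEEE doubles exactly through text
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_variant_calls <- function(df, path) write_tsv(df, path)

#' @rdname writers
#' @export
write_clonotypes <- function(df, path) write_tsv(df, path)

#' @rdname writers
#' @param x An `expr_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname writers
#' @export
write_clinical <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_seg <- function(df, path) write_tsv(df, path)
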