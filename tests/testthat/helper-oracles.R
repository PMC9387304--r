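# Independent brute-force oracles, written rule-by-rule with explicit loops
# and kept deliberately separate from the vectorized package implementations.

make_call <- function(sample_id = "S1", caller = "mutect2", chrom = "chr1",
                      pos = 100L, ref = "A", alt = "G",
                      variant_class = NULL, coding = TRUE, quality = 50,
                      somatic_evs = NA_real_, alt_reads = NA_integer_,
                      depth = NA_integer_, maf = NA_real_,
                      normal_maf = NA_real_, pop_af_max = NA_real_) {
  if (is.null(variant_class)) {
    variant_class <- if (nchar(ref) == 1 && nchar(alt) == 1) "snv" else "indel"
  }
  data.frame(sample_id = sample_id, caller = caller, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt,
             variant_class = variant_class, coding = coding,
             quality = quality, somatic_evs = somatic_evs,
             alt_reads = as.integer(alt_reads), depth = as.integer(depth),
             maf = maf, normal_maf = normal_maf, pop_af_max = pop_af_max,
             stringsAsFactors = FALSE)
}

consensus_keys <- function(cs) {
  sort(paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = ":"))
}

# --- matched cascade, one decision at a time ---------------------------
oracle_gate <- function(caller, variant_class, quality) {
  if (caller == "cadabra") {
    if (variant_class == "indel") return(quality > 10.5)
    return(FALSE)  # no published gate for cadabra SNVs
  }
  if (caller == "mutect2") {
    if (variant_class == "indel") return(quality > 6.8)
    return(quality > 9.2)
  }
  if (caller == "strelka2") {
    if (variant_class == "indel") return(quality > 15.2)
    return(quality > 19.7)
  }
  stop("unknown caller")
}

oracle_filter_matched <- function(calls) {
  retained_keys <- character(0)
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (!row$coding) next
    if (!oracle_gate(row$caller, row$variant_class, row$quality)) next
    key <- paste(row$chrom, row$pos, row$ref, row$alt, sep = ":")
    # corroboration for the two low-confidence classes
    find_mate <- function(callers) {
      for (j in seq_len(nrow(calls))) {
        if (j == i) next
        mate <- calls[j, ]
        mkey <- paste(mate$chrom, mate$pos, mate$ref, mate$alt, sep = ":")
        if (mkey == key && mate$caller %in% callers &&
            oracle_gate(mate$caller, mate$variant_class, mate$quality)) {
          return(TRUE)
        }
      }
      FALSE
    }
    if (row$caller == "cadabra" && row$variant_class == "indel" &&
        row$quality < 35) {
      if (!find_mate(c("strelka2", "mutect2"))) next
    }
    if (row$caller == "strelka2" && row$somatic_evs < 20) {
      if (!find_mate(c("mutect2", "cadabra"))) next
    }
    retained_keys <- c(retained_keys, key)
  }
  sort(unique(retained_keys))
}

oracle_filter_tumor_only <- function(calls) {
  retained_keys <- character(0)
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (!row$coding) next
    if (row$maf >= 0.05) {
      if (!(row$alt_reads >= 5 && row$depth >= 40)) next
    } else {
      if (!(row$alt_reads >= 10 && row$depth >= 80)) next
    }
    if (!is.na(row$normal_maf) && row$normal_maf > 0.05) next
    if (!is.na(row$pop_af_max) && row$pop_af_max > 0.01) next
    is_ct <- row$ref == "C" && row$alt == "T"
    is_ga <- row$ref == "G" && row$alt == "A"
    if ((is_ct || is_ga) && row$maf < 0.10) next
    retained_keys <- c(retained_keys,
                       paste(row$chrom, row$pos, row$ref, row$alt, sep = ":"))
  }
  sort(unique(retained_keys))
}

# --- peptide enumeration by exhaustive substring listing ----------------
oracle_snv_windows <- function(protein, position, alt_aa, k) {
  mutant <- protein
  substr(mutant, position, position) <- alt_aa
  peps <- character(0)
  for (start in seq_len(max(0L, nchar(mutant) - k + 1L))) {
    end <- start + k - 1L
    if (start <= position && position <= end) {
      peps <- c(peps, substr(mutant, start, end))
    }
  }
  peps
}

# hand-coded standard codon table (independent of Biostrings)
ORACLE_CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_translate_to_stop <- function(nt) {
  nt <- toupper(nt)
  aa <- character(0)
  i <- 1L
  while (i + 2L <= nchar(nt)) {
    codon <- substr(nt, i, i + 2L)
    res <- ORACLE_CODON_TABLE[[codon]]
    if (res == "*") break
    aa <- c(aa, res)
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

oracle_novel_kmers <- function(mutant, reference, k) {
  peps <- character(0)
  for (start in seq_len(max(0L, nchar(mutant) - k + 1L))) {
    p <- substr(mutant, start, start + k - 1L)
    if (!grepl(p, reference, fixed = TRUE)) peps <- c(peps, p)
  }
  unique(peps)
}

oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  h <- 0
  for (c_i in counts) {
    p <- c_i / n
    h <- h - p * log(p)
  }
  h
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (rank in rev(seq_len(m))) {
    i <- ord[rank]
    q[i] <- min(prev, p[i] * m / rank)
    prev <- q[i]
  }
  q
}

# --- deterministic rule-branch grids -----------------------------------
# Every caller x class x quality-band x corroboration combination, each at
# its own locus so corroboration is controlled exactly.
build_matched_grid <- function() {
  rows <- list()
  pos <- 0L
  qualities <- list(
    strelka2_snv = c(10, 19.7, 19.8, 50),
    strelka2_indel = c(10, 15.2, 15.3, 50),
    mutect2_snv = c(5, 9.2, 9.3, 50),
    mutect2_indel = c(3, 6.8, 6.9, 50),
    cadabra_indel = c(5, 10.5, 10.6, 34.9, 35, 50)
  )
  evs_values <- c(5, 19.9, 20, 30)
  mates <- c("none", "passing", "failing")
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (caller in c("strelka2", "mutect2", "cadabra")) {
    for (class in c("snv", "indel")) {
      if (caller == "cadabra" && class == "snv") {
        qs <- c(10, 50)
      } else {
        qs <- qualities[[paste(caller, class, sep = "_")]]
      }
      alleles <- if (class == "snv") list(ref = "A", alt = "G")
                 else list(ref = "A", alt = "AT")
      for (q in qs) for (coding in c(TRUE, FALSE)) {
        evs_set <- if (caller == "strelka2") evs_values else NA_real_
        for (evs in evs_set) for (mate in mates) {
          pos <- pos + 1L
          call <- make_call(caller = caller, pos = pos, ref = alleles$ref,
                            alt = alleles$alt, coding = coding, quality = q,
                            somatic_evs = evs)
          if (mate != "none") {
            mate_caller <- if (caller == "mutect2") "strelka2" else "mutect2"
            mate_gate <- if (mate_caller == "strelka2") {
              if (class == "snv") 19.7 else 15.2
            } else {
              if (class == "snv") 9.2 else 6.8
            }
            mq <- if (mate == "passing") mate_gate + 5 else mate_gate - 1
            call <- rbind(call, make_call(
              caller = mate_caller, pos = pos, ref = alleles$ref,
              alt = alleles$alt, coding = coding, quality = mq,
              somatic_evs = if (mate_caller == "strelka2") 30 else NA_real_))
          }
          add(call)
        }
      }
    }
  }
  do.call(rbind, rows)
}

build_tumor_only_grid <- function() {
  grid <- expand.grid(
    maf = c(0.03, 0.05, 0.08, 0.10, 0.30),
    alt_reads = c(4L, 5L, 9L, 10L, 12L),
    depth = c(39L, 40L, 79L, 80L, 150L),
    ctga = c(TRUE, FALSE),
    pop_af = c(NA, 0.005, 0.02),
    normal_maf = c(NA, 0.01, 0.06),
    coding = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$alt_reads <= grid$depth, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_call(caller = "mutect2", pos = i,
              ref = if (g$ctga) "C" else "A",
              alt = if (g$ctga) "T" else "G",
              coding = g$coding, quality = 30,
              alt_reads = g$alt_reads, depth = g$depth, maf = g$maf,
              normal_maf = g$normal_maf, pop_af_max = g$pop_af)
  })
  do.call(rbind, rows)
}
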