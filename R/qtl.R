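## QTL-specific normalization: allele verification/correction against a
## variant reference with genome-FASTA fallback, rsID assignment, target
## annotation, per-gene-tissue BH FDR, SNP/INDEL + significance splitting.

#' Load a variant reference (variant table + genome FASTA)
#'
#' The variant reference backs allele verification: a dbSNP-style table of
#' known variants (TSV, optionally bgzipped: columns `chrom`, `start`
#' (0-based), `end`, `rsid`, `ref`, `alts` with comma-separated alternate
#' alleles) plus an indexed genome FASTA used as a fallback when a variant
#' is absent from the table. Any backend exposing the same columns can be
#' substituted (a full-scale tabix-backed table is an interchangeable
#' implementation of this contract).
#'
#' @param variant_table Path to the variant TSV (plain or bgzipped).
#' @param genome_fasta Path to the genome FASTA (a `.fai` index is created
#'   if absent).
#' @return An `fg_variant_reference` object.
#' @export
load_variant_reference <- function(variant_table, genome_fasta) {
  lines <- read_lines_maybe_gz(variant_table)
  cols <- c("chrom", "start", "end", "rsid", "ref", "alts")
  if (length(lines)) {
    vars <- fread(text = paste(lines, collapse = "\n"), sep = "\t",
      header = identical(strsplit(lines[1], "\t")[[1]][1], "chrom"),
      colClasses = "character")
    setnames(vars, cols)
    vars[, start := as.integer(start)]
    vars[, end := as.integer(end)]
  } else {
    vars <- data.table(chrom = character(), start = integer(),
      end = integer(), rsid = character(), ref = character(),
      alts = character())
  }
  ## exploded one-row-per-alt view for vectorized allele matching
  if (nrow(vars)) {
    vars_long <- vars[, .(alt_one = strsplit(alts, ",", fixed = TRUE)[[1]]),
      by = .(chrom, start, end, rsid, ref)]
  } else {
    vars_long <- data.table(chrom = character(), start = integer(),
      end = integer(), rsid = character(), ref = character(),
      alt_one = character())
  }
  if (!file.exists(paste0(genome_fasta, ".fai"))) indexFa(genome_fasta)
  fa <- FaFile(genome_fasta)
  seqlen <- stats::setNames(
    GenomicRanges::width(scanFaIndex(fa)),
    as.character(GenomicRanges::seqnames(scanFaIndex(fa)))
  )
  ref <- list(
    variants = vars, variants_long = vars_long,
    genome_fasta = genome_fasta, seqlengths = seqlen
  )
  class(ref) <- "fg_variant_reference"
  ref
}

#' @export
print.fg_variant_reference <- function(x, ...) {
  cat(sprintf(
    "<fg_variant_reference> %d variant sites, genome: %s (%d contigs)\n",
    nrow(x$variants), x$genome_fasta, length(x$seqlengths)
  ))
  invisible(x)
}

## Fetch genome bases for 0-based half-open intervals; NA where the request
## leaves the contig (treated as non-matching, never an error).
genome_bases <- function(ref, chrom, start0, len) {
  n <- length(chrom)
  out <- rep(NA_character_, n)
  maxlen <- ref$seqlengths[chrom]
  ok <- !is.na(maxlen) & !is.na(start0) & !is.na(len) & len > 0 &
    start0 >= 0 & (start0 + len) <= maxlen
  if (any(ok)) {
    gr <- GRanges(chrom[ok], IRanges(start0[ok] + 1L, start0[ok] + len[ok]))
    seqs <- scanFa(FaFile(ref$genome_fasta), param = gr)
    out[ok] <- toupper(as.character(seqs))
  }
  out
}

## Is this a strand-ambiguous (palindromic) SNP allele pair?
is_palindromic <- function(ref_allele, alt_allele) {
  p <- paste0(ref_allele, alt_allele)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Verify and correct QTL alleles against the variant reference
#'
#' The central QTL harmonization step. Each record's `(ref_allele,
#' alt_allele)` pair is compared with the variant reference at its
#' coordinates:
#' \itemize{
#'   \item matches the reference orientation: record passes unchanged
#'     (`flip_status = "match"`);
#'   \item swapped relative to the reference: alleles are swapped, `beta`
#'     is negated, `alt_allele_freq` is complemented
#'     (`flip_status = "flipped"`);
#'   \item absent from the variant table, but one stated allele equals the
#'     genome base(s) at the coordinates: that allele is oriented as
#'     reference, statistics flipped if needed
#'     (`flip_status = "genome_resolved"`);
#'   \item otherwise `flip_status = "unresolved"`; the caller routes such
#'     records to the rejects report.
#' }
#' If an `effect_allele` column is present and equals the stated reference
#' allele, the effect is first re-expressed on the alternate allele, so
#' that after harmonization effect statistics are always on the alternate
#' allele (`effect_allele == alt_allele`). `|beta|` and `pvalue` are never
#' altered; only the sign of `beta` and the frequency complement change.
#' Multi-allelic reference sites match if the record's alternate equals any
#' listed alternate. Strand-ambiguous palindromic pairs (A/T, C/G) are
#' resolved by position + allele match only; their count is logged.
#'
#' @param rec A `data.table` of QTL records with columns `chrom` (normalized),
#'   `start` (0-based), `ref_allele`, `alt_allele`, `beta` (numeric), and
#'   optionally `effect_allele`, `alt_allele_freq`.
#' @param ref An `fg_variant_reference`.
#' @return `rec` with harmonized alleles/statistics and added columns
#'   `flip_status`, `end` (recomputed from the reference-allele length) and
#'   `variant_type` (`"SNP"`/`"INDEL"` from allele lengths).
#' @export
harmonize_alleles <- function(rec, ref) {
  rec <- copy(rec)
  n <- nrow(rec)
  if (n == 0L) {
    rec[, flip_status := character(0)]
    rec[, variant_type := character(0)]
    if (!"alt_allele_freq" %in% names(rec)) {
      rec[, alt_allele_freq := numeric(0)]
    }
    return(rec)
  }
  rec[, ref_allele := toupper(ref_allele)]
  rec[, alt_allele := toupper(alt_allele)]
  if (!"alt_allele_freq" %in% names(rec)) rec[, alt_allele_freq := NA_real_]
  has_effect <- "effect_allele" %in% names(rec)
  if (has_effect) rec[, effect_allele := toupper(effect_allele)]

  valid <- grepl("^[ACGT]+$", rec$ref_allele) &
    grepl("^[ACGT]+$", rec$alt_allele) &
    rec$ref_allele != rec$alt_allele
  rec[, flip_status := ifelse(valid, NA_character_, "unresolved")]

  ## express effect statistics on the stated alternate allele first
  if (has_effect) {
    on_ref <- valid & !is.na(rec$effect_allele) &
      rec$effect_allele == rec$ref_allele
    rec[on_ref, `:=`(beta = -beta, alt_allele_freq = 1 - alt_allele_freq)]
  }

  rec[, .rid := .I]
  cand <- merge(
    rec[valid, .(.rid, chrom, start, ref_allele, alt_allele)],
    ref$variants_long,
    by = c("chrom", "start"), allow.cartesian = TRUE
  )
  if (nrow(cand)) {
    cand[, cand_match := ref_allele == ref & alt_allele == alt_one]
    cand[, cand_flip := alt_allele == ref & ref_allele == alt_one]
    hit <- cand[cand_match | cand_flip,
      .(status = if (any(cand_match)) "match" else "flipped"),
      by = .rid]
  } else {
    hit <- data.table(.rid = integer(), status = character())
  }
  in_table <- rec$.rid %in% unique(cand$.rid)

  st <- rep(NA_character_, n)
  st[hit$.rid] <- hit$status
  ## position present in the table but alleles irreconcilable -> unresolved
  st[in_table & is.na(st) & valid] <- "unresolved"

  ## genome fallback for positions absent from the variant table
  need_fb <- which(valid & !in_table & is.na(st))
  if (length(need_fb)) {
    g_ref <- genome_bases(ref, rec$chrom[need_fb], rec$start[need_fb],
      nchar(rec$ref_allele[need_fb]))
    as_is <- !is.na(g_ref) & g_ref == rec$ref_allele[need_fb]
    st[need_fb[as_is]] <- "genome_resolved"
    rest <- need_fb[!as_is]
    if (length(rest)) {
      g_alt <- genome_bases(ref, rec$chrom[rest], rec$start[rest],
        nchar(rec$alt_allele[rest]))
      swap_fb <- !is.na(g_alt) & g_alt == rec$alt_allele[rest]
      st[rest[swap_fb]] <- "genome_resolved_swap"
      st[rest[!swap_fb]] <- "unresolved"
    }
  }
  st[is.na(st)] <- "unresolved"

  swap <- st == "flipped" | st == "genome_resolved_swap"
  if (any(swap)) {
    tmp <- rec$ref_allele[swap]
    rec$ref_allele[swap] <- rec$alt_allele[swap]
    rec$alt_allele[swap] <- tmp
    rec$beta[swap] <- -rec$beta[swap]
    rec$alt_allele_freq[swap] <- 1 - rec$alt_allele_freq[swap]
  }
  st[st == "genome_resolved_swap"] <- "genome_resolved"
  rec[, flip_status := ifelse(rec$flip_status %in% "unresolved",
    "unresolved", st)]
  if (has_effect) {
    rec[flip_status != "unresolved", effect_allele := alt_allele]
  }

  n_palin <- sum(st %in% c("match", "flipped") &
    nchar(rec$ref_allele) == 1L & nchar(rec$alt_allele) == 1L &
    is_palindromic(rec$ref_allele, rec$alt_allele))
  if (n_palin > 0) {
    fg_log(
      n_palin, " strand-ambiguous palindromic SNP(s) resolved by ",
      "position + allele match"
    )
  }

  rec[, end := start + nchar(ref_allele)]
  rec[, variant_type := ifelse(
    nchar(ref_allele) == 1L & nchar(alt_allele) == 1L, "SNP", "INDEL")]
  rec[, .rid := NULL]
  rec[]
}

#' Assign rsIDs from the variant reference
#'
#' Sets `rsid` for records whose (position, alleles) key, in harmonized
#' orientation, is present in the variant table. Records resolved only via
#' the genome fallback keep `rsid = NA`; their original `variant_id` is
#' preserved verbatim and used as the output name.
#'
#' @param rec Harmonized QTL records (after [harmonize_alleles()]).
#' @param ref An `fg_variant_reference`.
#' @return `rec` with an `rsid` column.
#' @export
assign_rsid <- function(rec, ref) {
  rec <- copy(rec)
  if (nrow(rec) == 0L) {
    rec[, rsid := character(0)]
    return(rec)
  }
  rec[, .rid := .I]
  hits <- merge(
    rec[, .(.rid, chrom, start, ref_allele, alt_allele)],
    ref$variants_long,
    by = c("chrom", "start"), allow.cartesian = TRUE
  )
  hits <- hits[ref_allele == ref & alt_allele == alt_one]
  rec[, rsid := NA_character_]
  if (nrow(hits)) {
    hits <- hits[!duplicated(.rid)]
    rec[hits$.rid, rsid := hits$rsid]
  }
  rec[, .rid := NULL]
  rec[]
}

#' Load a gene model table
#'
#' TSV with columns `target_id`, `gene_symbol`, `chrom`, `strand`,
#' `tss_position` (1-based). Production tables are derived from gene-model
#' annotation attributes; tests generate small synthetic ones.
#'
#' @param path Path to the TSV.
#' @return `data.table` keyed by `target_id`.
#' @export
load_gene_model <- function(path) {
  genes <- fread(path, sep = "\t", header = TRUE,
    colClasses = list(character = c("target_id", "gene_symbol", "chrom",
      "strand")))
  stopifnot(all(c("target_id", "gene_symbol", "strand", "tss_position")
    %in% names(genes)))
  genes[, tss_position := as.integer(tss_position)]
  setkey(genes, target_id)
  genes
}

#' Annotate QTL target genes
#'
#' Fills `gene_symbol`, `target_strand` and the signed `tss_distance` for
#' records whose `target_id` is present in the gene model. The distance is
#' measured from the TSS to the variant (1-based position) and is positive
#' when the variant lies downstream of the TSS in the gene's transcription
#' direction: `pos - tss` on the `+` strand, `tss - pos` on the `-` strand.
#' Unknown targets are annotated with the `"."` sentinel and counted in a
#' warning.
#'
#' @param rec QTL records with `target_id`, `chrom`, `start` (0-based).
#' @param genes Gene model from [load_gene_model()].
#' @return `rec` with `gene_symbol`, `target_strand`, `tss_distance`.
#' @export
annotate_target <- function(rec, genes) {
  rec <- copy(rec)
  if (nrow(rec) == 0L) {
    rec[, `:=`(gene_symbol = character(0), target_strand = character(0),
      tss_distance = integer(0))]
    return(rec)
  }
  idx <- match(rec$target_id, genes$target_id)
  rec[, gene_symbol := ifelse(is.na(idx), NA_SENTINEL,
    genes$gene_symbol[idx])]
  rec[, target_strand := ifelse(is.na(idx), NA_SENTINEL,
    genes$strand[idx])]
  pos1 <- rec$start + 1L
  tss <- genes$tss_position[idx]
  rec[, tss_distance := ifelse(is.na(idx), NA_integer_,
    ifelse(genes$strand[idx] == "+", pos1 - tss, tss - pos1))]
  n_unknown <- sum(is.na(idx))
  if (n_unknown > 0) {
    fg_warn(n_unknown, " QTL record(s) with target_id absent from the ",
      "gene model; annotated with '.'")
  }
  rec[]
}

#' Per-gene-tissue Benjamini-Hochberg FDR correction
#'
#' Within each `(target_id, tissue)` group, records lacking an FDR value
#' receive the Benjamini-Hochberg step-up adjusted p-value
#' (`stats::p.adjust(p, "BH")` over the group's missing-FDR records).
#' Records arriving with an FDR pass through unchanged; output order is
#' preserved. Records with a p-value outside `(0, 1]` (or missing) are
#' separated into a rejects table.
#'
#' @param rec QTL records with numeric `pvalue`, optional numeric `fdr`,
#'   and grouping columns `target_id`, `tissue`.
#' @return List with `records` (FDR populated) and `rejects`.
#' @export
compute_fdr <- function(rec) {
  rec <- copy(rec)
  if (!"fdr" %in% names(rec)) rec[, fdr := NA_real_]
  bad <- is.na(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1
  rejects <- rec[bad]
  rec <- rec[!bad]
  if (nrow(rec)) {
    rec[is.na(fdr), fdr := p.adjust(pvalue, method = "BH"),
      by = .(target_id, tissue)]
  }
  list(records = rec, rejects = rejects)
}

#' Split harmonized QTL records by variant type and significance
#'
#' Produces the four output record sets: full SNP, full INDEL, significant
#' SNP and significant INDEL, where significant means `fdr < threshold`
#' (strict inequality). The two full sets partition the accepted records;
#' the significant sets are subsets of them. All four sets are emitted even
#' when empty.
#'
#' @param rec QTL records with `variant_type` and `fdr` populated.
#' @param threshold Significance threshold on FDR (default 0.05).
#' @return Named list of four `data.table`s: `SNP_full`, `INDEL_full`,
#'   `SNP_significant`, `INDEL_significant`.
#' @export
split_qtl_outputs <- function(rec, threshold = 0.05) {
  list(
    SNP_full = rec[variant_type == "SNP"],
    INDEL_full = rec[variant_type == "INDEL"],
    SNP_significant = rec[variant_type == "SNP" & fdr < threshold],
    INDEL_significant = rec[variant_type == "INDEL" & fdr < threshold]
  )
}

## Fixed output field order of harmonized QTL tracks (16 standard fields,
## then passthrough). Column 4 carries the rsID when assigned, else the
## input variant identifier.
qtl_output_fields <- function() {
  c(
    "chrom", "start", "end", "name", "ref", "alt", "beta", "se", "pvalue",
    "fdr", "alt_allele_freq", "target_id", "gene_symbol", "target_strand",
    "tss_distance", "tissue"
  )
}

## Render harmonized QTL records into a render-ready table for
## sort_compress_index(): 16 standard columns then passthrough.
render_qtl <- function(rec) {
  pt_cols <- grep("^pt\\.", names(rec), value = TRUE)
  out <- data.table(
    chrom = rec$chrom,
    start = rec$start,
    end = rec$end,
    name = ifelse(!is.na(rec$rsid), rec$rsid,
      if ("variant_id" %in% names(rec)) {
        ifelse(is.na(rec$variant_id) | rec$variant_id == NA_SENTINEL,
          paste0(rec$chrom, "_", rec$start + 1L, "_", rec$ref_allele, "_",
            rec$alt_allele),
          rec$variant_id)
      } else {
        paste0(rec$chrom, "_", rec$start + 1L, "_", rec$ref_allele, "_",
          rec$alt_allele)
      }),
    ref = rec$ref_allele,
    alt = rec$alt_allele,
    beta = fmt_num(rec$beta),
    se = fmt_num(rec$se),
    pvalue = fmt_num(rec$pvalue),
    fdr = fmt_num(rec$fdr),
    alt_allele_freq = fmt_num(rec$alt_allele_freq),
    target_id = rec$target_id,
    gene_symbol = rec$gene_symbol,
    target_strand = rec$target_strand,
    tss_distance = fmt_int(rec$tss_distance),
    tissue = rec$tissue
  )
  for (p in pt_cols) out[[p]] <- rec[[p]]
  out
}
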