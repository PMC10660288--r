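## Synthetic-fixture generators: every input the pipelines need — dialect-
## varied data files, MDTs, file configs, mock variant reference, genome
## FASTA, gene models — with recorded ground truth for recovery tests.
## Same seed => byte-identical fixtures.

DNA <- c("A", "C", "G", "T")

write_config_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

#' Generate a mock variant reference, genome FASTA and gene model
#'
#' Builds a toy two-chromosome genome (names `chr1`/`chr2`), a variant
#' table consistent with it (every reference allele equals the genome bases
#' at its coordinates — SNVs, insertions and deletions, some sites
#' multi-allelic), and a gene model with transcription start sites on both
#' strands. The variant table is written bgzip-compressed with a tabix
#' index, standing in for a dbSNP-scale backend with the same contract.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed; the same seed reproduces identical bytes.
#' @param n_sites Number of variant-table sites.
#' @param n_genes Number of genes (alternating strand).
#' @param chrom_len Length of each toy chromosome in bp.
#' @return An `fg_reference_fixture`: paths (`genome_fasta`,
#'   `variant_table`, `gene_model`), the underlying tables, and the genome
#'   sequences.
#' @export
gen_reference <- function(dir, seed = 1L, n_sites = 400L, n_genes = 8L,
                          chrom_len = 10000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir <- normalizePath(dir)
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  genome <- vapply(chroms, function(ch) {
    paste(sample(DNA, chrom_len, replace = TRUE), collapse = "")
  }, character(1))
  fasta <- file.path(dir, "genome.fa")
  writeXStringSet(DNAStringSet(genome), fasta)
  if (file.exists(paste0(fasta, ".fai"))) unlink(paste0(fasta, ".fai"))
  indexFa(fasta)

  base_at <- function(ch, start0, len) {
    substr(genome[[ch]], start0 + 1L, start0 + len)
  }

  per_chrom <- ceiling(n_sites / length(chroms))
  sites <- rbindlist(lapply(chroms, function(ch) {
    pos <- sort(sample(seq(10L, chrom_len - 20L), per_chrom))
    data.table(chrom = ch, start = pos)
  }))[seq_len(n_sites)]
  kind <- sample(c("snv", "del", "ins"), nrow(sites), replace = TRUE,
    prob = c(0.8, 0.1, 0.1))
  ref <- character(nrow(sites))
  alts <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; s <- sites$start[i]
    anchor <- base_at(ch, s, 1L)
    if (kind[i] == "snv") {
      ref[i] <- anchor
      n_alt <- sample(1:2, 1)
      alts[i] <- paste(sample(setdiff(DNA, anchor), n_alt), collapse = ",")
    } else if (kind[i] == "del") {
      len <- sample(2:4, 1)
      ref[i] <- base_at(ch, s, len)
      alts[i] <- anchor
    } else {
      ref[i] <- anchor
      alts[i] <- paste0(anchor,
        paste(sample(DNA, sample(1:3, 1), replace = TRUE), collapse = ""))
    }
  }
  sites[, `:=`(ref = ref, alts = alts, end = start + nchar(ref))]
  setorder(sites, chrom, start)
  sites <- sites[!duplicated(paste(chrom, start))]
  sites[, rsid := sprintf("rs%07d", 100L + 7L * seq_len(.N))]
  vt_plain <- file.path(dir, "variants.tsv")
  fwrite(sites[, .(chrom, start, end, rsid, ref, alts)], vt_plain,
    sep = "\t", quote = FALSE)
  vt_gz <- paste0(vt_plain, ".gz")
  bgzip(vt_plain, dest = vt_gz, overwrite = TRUE)
  unlink(vt_plain)
  indexTabix(vt_gz, seq = 1L, start = 2L, end = 3L, zeroBased = TRUE,
    skip = 1L)

  strands <- rep(c("+", "-"), length.out = n_genes)
  genes <- data.table(
    target_id = sprintf("G%04d", seq_len(n_genes)),
    gene_symbol = sprintf("SYM%d", seq_len(n_genes)),
    chrom = rep(chroms, length.out = n_genes),
    strand = strands,
    tss_position = sample(seq(500L, chrom_len - 500L), n_genes)
  )
  gm_path <- file.path(dir, "gene_model.tsv")
  fwrite(genes, gm_path, sep = "\t", quote = FALSE)

  out <- list(
    genome_fasta = fasta, variant_table = vt_gz, gene_model = gm_path,
    genome = genome, sites = sites, genes = genes, seed = seed,
    chrom_len = chrom_len
  )
  class(out) <- "fg_reference_fixture"
  out
}

#' Generate a synthetic QTL dataset in two dialects, with ground truth
#'
#' Emits the same underlying variant-gene associations rendered in two
#' dialects — a "wide" file (tab-separated, header, 1-based single
#' position, chr-prefixed names, extra passthrough columns, in the style
#' of reprocessed many-column eQTL releases) and a "compact" file
#' (comma-separated, headerless, 0-based start/end, bare chromosome
#' numbers, in the style of minimal published eQTL tables) — plus matching
#' file configs, an MDT describing both, and a system config pointing at
#' the reference.
#'
#' A `flip_fraction` of records is rendered in swapped-allele orientation
#' (alleles exchanged, effect negated, frequency complemented), and a
#' `missing_ref_fraction` of variants is absent from the variant table but
#' consistent with the genome FASTA, exercising the genome fallback. The
#' manifest records ground truth (true orientation, effect, frequency,
#' rsID) for every row, so harmonization output can be checked exactly.
#' Effect sizes are normal; p-values are a null-uniform/signal mixture so
#' significance splitting is non-trivial at the default 0.05 threshold.
#'
#' @param dir Output directory.
#' @param n_variants Number of association rows.
#' @param flip_fraction Fraction rendered in swapped orientation.
#' @param missing_ref_fraction Fraction absent from the variant table.
#' @param seed Integer seed.
#' @param reference An `fg_reference_fixture`, or `NULL` to generate one
#'   (under `dir`/reference) with the same seed.
#' @param n_genes Genes in the generated reference (when `reference` is
#'   `NULL`).
#' @return An `fg_fixture` list: `files` (all written paths), `manifest`
#'   (ground-truth `data.table`), `reference`, `seed`.
#' @export
gen_qtl_dataset <- function(dir, n_variants = 1000L, flip_fraction = 0.3,
                            missing_ref_fraction = 0.01, seed = 1L,
                            reference = NULL, n_genes = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir <- normalizePath(dir)
  if (is.null(reference)) {
    reference <- gen_reference(file.path(dir, "reference"), seed = seed,
      n_genes = n_genes)
  }
  set.seed(seed + 1L)
  n <- as.integer(n_variants)
  sites <- reference$sites
  genome <- reference$genome

  n_missing <- if (n > 0L) round(missing_ref_fraction * n) else 0L
  n_known <- n - n_missing

  if (n > 0L) {
    pick <- sample(nrow(sites), n_known, replace = n_known > nrow(sites))
    known <- sites[pick]
    ## vectorized random pick among each site's alternate alleles
    alt_lists <- strsplit(sites$alts, ",", fixed = TRUE)[pick]
    k <- lengths(alt_lists)
    sel <- ceiling(runif(n_known) * k)
    known[, alt_pick := unlist(alt_lists)[cumsum(k) - k + sel]]

    ## positions not in the table, reference allele = genome base
    avail <- lapply(names(genome), function(ch) {
      setdiff(seq(10L, reference$chrom_len - 20L), sites[chrom == ch, start])
    })
    names(avail) <- names(genome)
    miss_chrom <- sample(names(genome), n_missing, replace = TRUE)
    miss_start <- vapply(miss_chrom, function(ch) sample(avail[[ch]], 1),
      integer(1))
    miss_ref <- vapply(seq_len(n_missing), function(i) {
      substr(genome[[miss_chrom[i]]], miss_start[i] + 1L, miss_start[i] + 1L)
    }, character(1))
    miss_alt <- vapply(miss_ref, function(r) sample(setdiff(DNA, r), 1),
      character(1))

    truth <- data.table(
      chrom = c(known$chrom, miss_chrom),
      start = c(known$start, as.integer(miss_start)),
      true_ref = c(known$ref, miss_ref),
      true_alt = c(known$alt_pick, miss_alt),
      rsid = c(known$rsid, rep(NA_character_, n_missing)),
      in_reference = rep(c(TRUE, FALSE), c(n_known, n_missing))
    )
    truth <- truth[sample(.N)] # interleave
  } else {
    truth <- data.table(chrom = character(), start = integer(),
      true_ref = character(), true_alt = character(), rsid = character(),
      in_reference = logical())
  }

  beta <- rnorm(n, 0, 0.5)
  se <- abs(rnorm(n, 0.05, 0.02)) + 1e-3
  af <- runif(n, 0.01, 0.99)
  signal <- runif(n) < 0.3
  pval <- runif(n)
  pval[signal] <- 10^(-runif(sum(signal), 2, 8))
  flipped <- runif(n) < flip_fraction
  genes <- reference$genes
  target <- sample(genes$target_id, n, replace = TRUE)
  tissue <- rep("hippocampus", n)

  ## round-trip values through the rendering used in the files so the
  ## manifest holds exactly what a perfect harmonization must reproduce
  rt <- function(x) as.numeric(sprintf("%.6g", x))
  truth[, `:=`(
    true_beta = rt(beta), true_af = rt(af), se = rt(se), pvalue = rt(pval),
    flipped = flipped, target_id = target, tissue = tissue,
    variant_type = ifelse(nchar(true_ref) == 1L & nchar(true_alt) == 1L,
      "SNP", "INDEL")
  )]
  truth[, row := .I]

  stated_ref <- ifelse(flipped, truth$true_alt, truth$true_ref)
  stated_alt <- ifelse(flipped, truth$true_ref, truth$true_alt)
  stated_beta <- ifelse(flipped, -truth$true_beta, truth$true_beta)
  stated_af <- ifelse(flipped, 1 - truth$true_af, truth$true_af)
  variant_id <- paste(sub("^chr", "", truth$chrom), truth$start + 1L,
    stated_ref, stated_alt, sep = "_")

  wide <- data.table(
    molecular_trait_id = truth$target_id,
    variant_id = variant_id,
    chromosome = truth$chrom,
    position = truth$start + 1L,
    ref = stated_ref,
    alt = stated_alt,
    beta = sprintf("%.6g", stated_beta),
    se = sprintf("%.6g", truth$se),
    pvalue = sprintf("%.6g", truth$pvalue),
    alt_freq = sprintf("%.6g", stated_af),
    tissue = truth$tissue,
    ac = as.integer(round(stated_af * 1000)),
    an = 1000L,
    r2 = sprintf("%.6g", runif(n, 0.3, 1)),
    type = truth$variant_type,
    median_tpm = sprintf("%.6g", runif(n, 0, 50))
  )
  wide_path <- file.path(dir, "eqtl_wide.tsv")
  fwrite(wide, wide_path, sep = "\t", quote = FALSE)

  compact <- data.table(
    chrom = sub("^chr", "", truth$chrom),
    start = truth$start,
    end = truth$start + nchar(stated_ref),
    variant = variant_id,
    ref = stated_ref,
    alt = stated_alt,
    af = sprintf("%.6g", stated_af),
    beta = sprintf("%.6g", stated_beta),
    se = sprintf("%.6g", truth$se),
    pvalue = sprintf("%.6g", truth$pvalue),
    gene = truth$target_id,
    tissue = truth$tissue
  )
  compact_path <- file.path(dir, "eqtl_compact.csv")
  fwrite(compact, compact_path, sep = ",", quote = FALSE,
    col.names = FALSE)

  cfg_wide <- write_config_lines(file.path(dir, "config_wide.txt"), c(
    "# wide eQTL dialect: tab, header, 1-based position, chr-prefixed",
    "delimiter = tab", "has_header = true", "coordinate_base = 1",
    "chrom_style = chr_prefixed",
    "chromosome -> chrom", "position -> pos", "variant_id -> variant_id",
    "ref -> ref", "alt -> alt", "beta -> beta", "se -> se",
    "pvalue -> pvalue", "alt_freq -> alt_allele_freq",
    "molecular_trait_id -> target_id", "tissue -> tissue",
    "passthrough = ac, an, r2, type, median_tpm"
  ))
  cfg_compact <- write_config_lines(file.path(dir, "config_compact.txt"), c(
    "# compact eQTL dialect: comma, headerless, 0-based, bare chromosomes",
    "delimiter = comma", "has_header = false", "coordinate_base = 0",
    "chrom_style = bare",
    "1 -> chrom", "2 -> start", "3 -> end", "4 -> variant_id",
    "5 -> ref", "6 -> alt", "7 -> alt_allele_freq", "8 -> beta",
    "9 -> se", "10 -> pvalue", "11 -> target_id", "12 -> tissue"
  ))

  mdt <- data.table(
    track_id = c("eqtl_wide", "eqtl_compact"),
    datatype = "qtl",
    biosample_term = "hippocampus",
    biosample_type = "tissue",
    life_stage = "adult",
    assay_type = "RNA-seq",
    genome_build = "GRCh38",
    data_source = "TOYQTL",
    doi = "10.0000/toy.qtl",
    file_path = c(wide_path, compact_path),
    config_path = c(cfg_wide, cfg_compact),
    study = "pilot"
  )
  mdt_path <- file.path(dir, "mdt.tsv")
  fwrite(mdt, mdt_path, sep = "\t", quote = FALSE)

  sys_path <- write_config_lines(file.path(dir, "system.ini"), c(
    "[references]",
    paste0("variant_reference = ", reference$variant_table),
    paste0("genome_fasta = ", reference$genome_fasta),
    paste0("gene_model = ", reference$gene_model)
  ))

  out <- list(
    files = list(
      wide = wide_path, compact = compact_path,
      config_wide = cfg_wide, config_compact = cfg_compact,
      mdt = mdt_path, system_config = sys_path
    ),
    manifest = truth,
    reference = reference,
    seed = seed
  )
  class(out) <- "fg_fixture"
  out
}

#' Generate a synthetic annotated-intervals dataset
#'
#' BED-like rows in shuffled genomic order with mixed chromosome naming
#' styles (bare and chr-prefixed in the same file), 1-based coordinates,
#' scores partly outside \[0, 1000\] (exercising clamping) and extra
#' passthrough columns. Writes the data file, its config and a one-row
#' MDT.
#'
#' @param dir Output directory.
#' @param n Number of intervals.
#' @param seed Integer seed.
#' @return An `fg_fixture` with `files` and a ground-truth `manifest`
#'   (normalized intervals and the expected clamp count).
#' @export
gen_intervals <- function(dir, n = 300L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir <- normalizePath(dir)
  set.seed(seed + 2L)
  n <- as.integer(n)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start0 <- sample(seq(0L, 9000L), n, replace = TRUE)
  width <- sample(50:500, n, replace = TRUE)
  end0 <- start0 + width
  score <- round(runif(n, -50, 1500), 1)
  truth <- data.table(
    chrom = chrom, start = start0, end = end0,
    name = sprintf("peak_%d", seq_len(n)),
    score = score,
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    signal = sprintf("%.6g", runif(n, 0, 30)),
    summit = as.integer(start0 + round(width / 2))
  )
  clamp_count <- sum(score < 0 | score > 1000)

  render <- copy(truth)
  ## mixed chromosome naming style within one file
  bare <- runif(n) < 0.5
  render[, chrom := ifelse(bare, sub("^chr", "", chrom), chrom)]
  render[, start := start + 1L] # 1-based rendering
  render <- render[sample(.N)]  # shuffled input order
  setnames(render, c("seqname", "begin", "stop", "peak", "score", "strand",
    "signal", "summit"))
  data_path <- file.path(dir, "peaks.tsv")
  fwrite(render, data_path, sep = "\t", quote = FALSE)

  cfg <- write_config_lines(file.path(dir, "config_peaks.txt"), c(
    "delimiter = tab", "has_header = true", "coordinate_base = 1",
    "seqname -> chrom", "begin -> start", "stop -> end", "peak -> name",
    "score -> score", "strand -> strand",
    "passthrough = signal, summit"
  ))
  mdt <- data.table(
    track_id = "peaks1", datatype = "intervals",
    biosample_term = "cortex", biosample_type = "tissue",
    life_stage = "adult", assay_type = "ChIP-seq",
    genome_build = "GRCh37", data_source = "TOYPEAKS",
    doi = "", file_path = data_path, config_path = cfg,
    antibody = "H3K27ac"
  )
  mdt_path <- file.path(dir, "mdt.tsv")
  fwrite(mdt, mdt_path, sep = "\t", quote = FALSE)

  out <- list(
    files = list(data = data_path, config = cfg, mdt = mdt_path),
    manifest = list(intervals = truth, clamp_count = clamp_count),
    seed = seed
  )
  class(out) <- "fg_fixture"
  out
}

#' Generate a synthetic chromatin-interactions dataset
#'
#' Anchor-pair rows with a mix of score-only, p-value-only and fully null
#' significance columns, extra passthrough columns, at least one
#' self-interaction (identical anchors) and at least one
#' inter-chromosomal pair. Coordinates are 0-based, chr-prefixed. Writes
#' the data file, its config and a one-row MDT.
#'
#' @param dir Output directory.
#' @param n Number of interactions.
#' @param seed Integer seed.
#' @return An `fg_fixture` with `files` and a `manifest` (per-row expected
#'   IDs, significance-column pattern, self/trans flags).
#' @export
gen_interactions <- function(dir, n = 100L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir <- normalizePath(dir)
  set.seed(seed + 3L)
  n <- as.integer(n)
  stopifnot(n >= 3L)
  chrom1 <- sample(c("chr1", "chr2"), n, replace = TRUE)
  chrom2 <- chrom1
  trans <- runif(n) < 0.15
  chrom2[trans] <- ifelse(chrom1[trans] == "chr1", "chr2", "chr1")
  chrom2[2] <- ifelse(chrom1[2] == "chr1", "chr2", "chr1") # guaranteed trans
  start1 <- sample(seq(0L, 9000L), n, replace = TRUE)
  end1 <- start1 + sample(100:1000, n, replace = TRUE)
  start2 <- sample(seq(0L, 9000L), n, replace = TRUE)
  end2 <- start2 + sample(100:1000, n, replace = TRUE)
  ## guaranteed self-interaction
  chrom2[3] <- chrom1[3]; start2[3] <- start1[3]; end2[3] <- end1[3]

  pattern <- sample(c("score", "pvalue", "none"), n, replace = TRUE)
  pattern[1:3] <- c("score", "pvalue", "none")
  score <- rep(NA_real_, n)
  score[pattern == "score"] <- round(runif(sum(pattern == "score"), 0, 1200))
  pval <- rep(NA_real_, n)
  pval[pattern == "pvalue"] <- 10^(-runif(sum(pattern == "pvalue"), 0.5, 9))

  render <- data.table(
    chr_a = chrom1, start_a = start1, end_a = end1,
    chr_b = chrom2, start_b = start2, end_b = end2,
    score_col = ifelse(is.na(score), ".", fmt_int(score)),
    pval_col = ifelse(is.na(pval), ".", sprintf("%.6g", pval)),
    cell_line = sample(c("GM12878", "K562"), n, replace = TRUE),
    reads = sample(10:5000, n, replace = TRUE)
  )
  data_path <- file.path(dir, "loops.tsv")
  fwrite(render, data_path, sep = "\t", quote = FALSE)

  cfg <- write_config_lines(file.path(dir, "config_loops.txt"), c(
    "delimiter = tab", "has_header = true", "coordinate_base = 0",
    "chr_a -> chrom1", "start_a -> start1", "end_a -> end1",
    "chr_b -> chrom2", "start_b -> start2", "end_b -> end2",
    "score_col -> score", "pval_col -> pvalue",
    "passthrough = cell_line, reads"
  ))
  mdt <- data.table(
    track_id = "loops1", datatype = "interactions",
    biosample_term = "left ventricle", biosample_type = "tissue",
    life_stage = "adult", assay_type = "Hi-C",
    genome_build = "GRCh38", data_source = "TOY3D",
    doi = "", file_path = data_path, config_path = cfg,
    protocol = "in-situ"
  )
  mdt_path <- file.path(dir, "mdt.tsv")
  fwrite(mdt, mdt_path, sep = "\t", quote = FALSE)

  manifest <- data.table(
    row = seq_len(n), interaction_id = seq_len(n),
    chrom1 = chrom1, start1 = start1, end1 = end1,
    chrom2 = chrom2, start2 = start2, end2 = end2,
    pattern = pattern, score = score, pvalue = pval,
    self = chrom1 == chrom2 & start1 == start2 & end1 == end2,
    trans = chrom1 != chrom2
  )
  out <- list(
    files = list(data = data_path, config = cfg, mdt = mdt_path),
    manifest = manifest,
    seed = seed
  )
  class(out) <- "fg_fixture"
  out
}

#' Generate a complete multi-datatype project fixture
#'
#' One MDT describing five tracks — the two QTL dialects, an intervals
#' track and an interactions track — plus every data file, config and
#' reference resource, ready for [run_project()]. Used to exercise the
#' driver end-to-end.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_qtl,n_intervals,n_interactions Per-datatype sizes.
#' @return List with `mdt`, `system_config`, and the component fixtures
#'   (`qtl`, `intervals`, `interactions`).
#' @export
gen_project <- function(dir, seed = 1L, n_qtl = 500L, n_intervals = 200L,
                        n_interactions = 60L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir <- normalizePath(dir)
  qtl <- gen_qtl_dataset(file.path(dir, "qtl"), n_variants = n_qtl,
    seed = seed)
  iv <- gen_intervals(file.path(dir, "intervals"), n = n_intervals,
    seed = seed)
  ia <- gen_interactions(file.path(dir, "interactions"),
    n = n_interactions, seed = seed)

  rows <- rbindlist(list(
    fread(qtl$files$mdt, colClasses = "character"),
    fread(iv$files$mdt, colClasses = "character"),
    fread(ia$files$mdt, colClasses = "character")
  ), fill = TRUE)
  ## one shared extra column; per-fixture extras merge into it
  extras <- setdiff(names(rows), c(mdt_required_columns(),
    mdt_optional_columns()))
  rows[, batch := "demo"]
  rows <- rows[, c(mdt_required_columns(), mdt_optional_columns(),
    "batch"), with = FALSE]
  mdt_path <- file.path(dir, "mdt.tsv")
  fwrite(rows, mdt_path, sep = "\t", quote = FALSE, na = "")

  list(
    mdt = mdt_path,
    system_config = qtl$files$system_config,
    qtl = qtl, intervals = iv, interactions = ia
  )
}
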