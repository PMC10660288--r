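## QTL pipeline: allele harmonization, rsIDs, target annotation, BH FDR,
## splitting.

local_reference <- function(seed = 11L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fx <- gen_reference(dir, seed = seed)
  list(
    fixture = fx,
    ref = load_variant_reference(fx$variant_table, fx$genome_fasta)
  )
}

## Build QTL records against known reference sites. `swap` renders a row in
## swapped-allele orientation relative to the reference.
rec_from_sites <- function(sites, swap = FALSE, beta = 0.5, af = 0.3) {
  alt1 <- vapply(strsplit(sites$alts, ","), `[`, character(1), 1L)
  data.table::data.table(
    chrom = sites$chrom,
    start = sites$start,
    end = sites$end,
    ref_allele = if (swap) alt1 else sites$ref,
    alt_allele = if (swap) sites$ref else alt1,
    beta = if (swap) -beta else beta,
    alt_allele_freq = if (swap) 1 - af else af,
    pvalue = 0.01,
    target_id = "G0001",
    tissue = "hippocampus"
  )
}

test_that("matching records pass unchanged; swapped records are corrected", {
  r <- local_reference()
  sites <- r$fixture$sites[1:20]
  ok <- harmonize_alleles(rec_from_sites(sites), r$ref)
  expect_true(all(ok$flip_status == "match"))
  expect_identical(ok$beta, rep(0.5, 20))
  expect_identical(ok$ref_allele, sites$ref)

  fl <- harmonize_alleles(rec_from_sites(sites, swap = TRUE), r$ref)
  expect_true(all(fl$flip_status == "flipped"))
  ## orientation restored: alleles, effect sign, frequency complement
  expect_identical(fl$ref_allele, sites$ref)
  expect_equal(fl$beta, rep(0.5, 20))
  expect_equal(fl$alt_allele_freq, rep(0.3, 20))
})

test_that("harmonization is involutive and conserves |beta| and p-values", {
  r <- local_reference()
  sites <- r$fixture$sites[31:60]
  mixed <- rbind(rec_from_sites(sites[1:15]),
    rec_from_sites(sites[16:30], swap = TRUE))
  once <- harmonize_alleles(mixed, r$ref)
  twice <- harmonize_alleles(once, r$ref)
  expect_true(all(twice$flip_status == "match"))
  expect_identical(twice$beta, once$beta)
  expect_identical(twice$ref_allele, once$ref_allele)
  expect_identical(twice$alt_allele, once$alt_allele)
  ## magnitude and p-values untouched by harmonization
  expect_equal(abs(once$beta), abs(mixed$beta))
  expect_identical(once$pvalue, mixed$pvalue)
})

test_that("genome fallback resolves table-absent variants; garbage is rejected", {
  r <- local_reference()
  fx <- r$fixture
  used <- fx$sites[chrom == "chr1", start]
  pos <- setdiff(5000:5050, used)[1:3]
  gbase <- substr(rep(fx$genome[["chr1"]], 3), pos + 1, pos + 1)
  other <- vapply(gbase, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
    character(1))
  rec <- data.table::data.table(
    chrom = "chr1", start = as.integer(pos), end = as.integer(pos) + 1L,
    ref_allele = c(gbase[1], other[2], "A"),
    alt_allele = c(other[1], gbase[2], "A"), # row 3: ref == alt, invalid
    beta = c(1, 1, 1), alt_allele_freq = c(0.2, 0.2, 0.2),
    pvalue = 0.5, target_id = "G0001", tissue = "t"
  )
  out <- harmonize_alleles(rec, r$ref)
  expect_identical(out$flip_status,
    c("genome_resolved", "genome_resolved", "unresolved"))
  ## row 2 was swapped relative to the genome: statistics flipped
  expect_identical(out$beta, c(1, -1, 1))
  expect_identical(out$ref_allele[2], gbase[2])
  ## genome-resolved records never gain an rsID
  withid <- assign_rsid(out, r$ref)
  expect_true(all(is.na(withid$rsid[1:2])))
})

test_that("rsIDs come from the reference for records in harmonized orientation", {
  r <- local_reference()
  sites <- r$fixture$sites[5:14]
  rec <- harmonize_alleles(rec_from_sites(sites, swap = TRUE), r$ref)
  rec <- assign_rsid(rec, r$ref)
  expect_identical(rec$rsid, sites$rsid)
})

test_that("target annotation follows the strand-aware sign convention", {
  genes <- data.table::data.table(
    target_id = c("Gp", "Gm"),
    gene_symbol = c("PLUS1", "MINUS1"),
    chrom = "chr1",
    strand = c("+", "-"),
    tss_position = c(1000L, 2000L)
  )
  rec <- data.table::data.table(
    chrom = "chr1", start = c(1499L, 1499L, 1499L),
    target_id = c("Gp", "Gm", "Gunknown")
  )
  expect_warning(out <- annotate_target(rec, genes), "absent")
  ## + strand, TSS 1000, variant at 1500: 500 bp downstream
  expect_identical(out$tss_distance[1], 500L)
  ## - strand, TSS 2000, same variant: also 500 bp downstream of the TSS
  ## in transcription direction
  expect_identical(out$tss_distance[2], 500L)
  expect_identical(out$gene_symbol, c("PLUS1", "MINUS1", "."))
  expect_true(is.na(out$tss_distance[3]))
})

test_that("compute_fdr matches the frozen BH example and the m=1 identity", {
  rec <- data.table::data.table(
    pvalue = c(0.01, 0.02, 0.03, 0.04),
    target_id = "G1", tissue = "t"
  )
  out <- compute_fdr(rec)$records
  expect_equal(out$fdr, rep(0.04, 4))

  one <- compute_fdr(data.table::data.table(pvalue = 0.2,
    target_id = "G1", tissue = "t"))$records
  expect_equal(one$fdr, 0.2)
})

test_that("compute_fdr equals an independent step-up oracle per group", {
  set.seed(123)
  n_groups <- 200L
  rows <- data.table::rbindlist(lapply(seq_len(n_groups), function(g) {
    m <- sample(1:50, 1)
    ## mixture with duplicated p-values to exercise ties
    p <- round(runif(m), sample(2:6, 1))
    p[p == 0] <- 1e-6
    data.table::data.table(
      pvalue = p,
      target_id = sprintf("G%03d", g %% 37L), # genes recur across tissues
      tissue = sprintf("tis%d", g)
    )
  }))
  rows <- rows[sample(.N)] # interleave groups; order must be preserved
  out <- compute_fdr(rows)$records
  expect_identical(out$pvalue, rows$pvalue) # order preserved
  expected <- rows[, .(idx = .I, oracle = bh_step_up_oracle(pvalue)),
    by = .(target_id, tissue)]
  data.table::setorder(expected, idx)
  expect_true(all(abs(out$fdr - expected$oracle) < 1e-12))
  ## fdr >= p everywhere; monotone in p-value rank within each group
  expect_true(all(out$fdr >= out$pvalue))
  mono <- out[, all(diff(fdr[order(pvalue)]) >= -1e-15),
    by = .(target_id, tissue)]
  expect_true(all(mono$V1))
})

test_that("pre-existing FDR passes through; invalid p-values are rejected", {
  rec <- data.table::data.table(
    pvalue = c(0.01, 0.5, 2, NA, 0),
    fdr = c(0.123, NA, NA, NA, NA),
    target_id = "G1", tissue = "t"
  )
  res <- compute_fdr(rec)
  expect_identical(nrow(res$rejects), 3L)
  expect_identical(res$records$fdr[1], 0.123) # trusted as provided
  expect_equal(res$records$fdr[2], 0.5)
})

test_that("split_qtl_outputs partitions by type with strict significance", {
  rec <- data.table::data.table(
    variant_type = rep(c("SNP", "INDEL"), c(10, 2)),
    fdr = c(0.01, 0.02, 0.04, rep(0.5, 6), 0.05, 0.9, 0.06)
  )
  sp <- split_qtl_outputs(rec, threshold = 0.05)
  expect_identical(vapply(sp, nrow, integer(1)),
    c(SNP_full = 10L, INDEL_full = 2L, SNP_significant = 3L,
      INDEL_significant = 0L))
  ## the full tracks partition the records
  expect_identical(nrow(sp$SNP_full) + nrow(sp$INDEL_full), nrow(rec))
  ## fdr exactly at the threshold is excluded (strict inequality)
  expect_false(any(sp$SNP_significant$fdr == 0.05))
  ## threshold 1 (with fdr <= 1 by construction, fdr < 1 here) keeps all
  sp2 <- split_qtl_outputs(rec, threshold = 1.000001)
  expect_identical(nrow(sp2$SNP_significant), nrow(sp2$SNP_full))
})
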