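## Type-independent steps: chromosome/coordinate normalization, column
## mapping, sort+compress+index, output hierarchy.

test_that("normalize_chrom handles the naming dialects and is idempotent", {
  expect_identical(normalize_chrom("1"), "chr1")
  expect_identical(normalize_chrom("MT"), "chrM")
  expect_identical(normalize_chrom("chrMT"), "chrM")
  expect_identical(normalize_chrom("chr2"), "chr2")
  expect_identical(normalize_chrom(c("x", "Y", "CHR3")),
    c("chrX", "chrY", "chr3"))
  expect_identical(normalize_chrom("weird_contig"), "chrweird_contig")
  expect_error(normalize_chrom(""), "empty")
  ## idempotence over a mixed set
  set.seed(1)
  raw <- c(as.character(1:22), "X", "Y", "MT", paste0("chr", c(1:22, "X")))
  once <- normalize_chrom(raw)
  expect_identical(normalize_chrom(once), once)
})

test_that("convert_coordinates implements both base conventions", {
  expect_identical(convert_coordinates(100L, 200L, base = 1),
    list(start = 99L, end = 200L))
  expect_identical(convert_coordinates(99L, 200L, base = 0),
    list(start = 99L, end = 200L))
  ## single position (SNP) becomes a 1-bp interval
  expect_identical(convert_coordinates(100L, NA, base = 1),
    list(start = 99L, end = 100L))
  ## invalid rows surface as NA for per-row rejection
  bad <- convert_coordinates(c(0L, 10L, 5L), c(5L, 3L, 10L), base = 1)
  expect_identical(is.na(bad$start), c(TRUE, TRUE, FALSE))
  ## 0-based empty interval is invalid
  expect_true(is.na(convert_coordinates(7L, 7L, base = 0)$start))
})

test_that("map_columns permutes to the standard layout and rejects short rows", {
  cfg <- make_config(
    c("has_header = false", "2 -> chrom", "3 -> start", "4 -> end",
      "1 -> score"),
    "intervals"
  )
  raw <- data.table::data.table(
    V1 = c("17", "900"), V2 = c("chr1", "chr2"),
    V3 = c("100", "50"), V4 = c("200", "70")
  )
  m <- map_columns(raw, cfg)
  expect_identical(names(m$records),
    c(".line", "chrom", "start", "end", "name", "score"))
  expect_identical(m$records$chrom, c("chr1", "chr2"))
  expect_identical(m$records$score, c("17", "900"))
  expect_identical(m$records$name, c(".", "."))
  expect_identical(nrow(m$rejects), 0L)

  ## short row (NA fill) is rejected with its line number
  raw2 <- data.table::data.table(
    V1 = c("1", "2"), V2 = c("chr1", "chr1"),
    V3 = c("10", "20"), V4 = c("99", NA)
  )
  m2 <- map_columns(raw2, cfg)
  expect_identical(m2$rejects$line, 2L)
  expect_identical(nrow(m2$records), 1L)

  ## identity map on an already-standard row is a fixed point
  id_cfg <- make_config(
    c("has_header = false", "coordinate_base = 0",
      "1 -> chrom", "2 -> start", "3 -> end", "passthrough = *"),
    "intervals"
  )
  raw3 <- data.table::data.table(V1 = "chr1", V2 = "99", V3 = "200",
    V4 = "peak_1", V5 = "88")
  m3 <- map_columns(raw3, id_cfg)
  out <- unlist(m3$records[1, !".line"], use.names = FALSE)
  expect_identical(out, c("chr1", "99", "200", "peak_1", "88"))
})

test_that("sort_compress_index orders deterministically and keeps duplicates", {
  dir <- withr::local_tempdir()
  rec <- data.table::data.table(
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    start = c(5L, 300L, 100L, 100L),
    end = c(15L, 400L, 200L, 200L),
    name = c("d", "c", "a", "a")
  )
  trk <- sort_compress_index(rec, file.path(dir, "t.bed.gz"))
  lines <- track_lines(trk)
  expect_identical(lines, c(
    "chr1\t100\t200\ta", "chr1\t100\t200\ta",
    "chr1\t300\t400\tc", "chr2\t5\t15\td"
  ))
  expect_identical(trk$n_records, 4L)
  expect_true(file.exists(trk$index_path))

  ## region query equals the linear-scan overlap oracle
  expect_identical(
    query_track(trk, "chr1", 150L, 160L),
    overlap_scan_oracle(lines, "chr1", 150L, 160L)
  )
  expect_identical(query_track(trk, "chr1", 250L, 260L), character(0))
  expect_identical(query_track(trk, "chr9", 0L, 100L), character(0))
})

test_that("indexed queries match the linear-scan oracle on random regions", {
  dir <- withr::local_tempdir()
  set.seed(99)
  n <- 400L
  rec <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:9000, n, replace = TRUE)
  )
  rec[, end := start + sample(10:400, n, replace = TRUE)]
  rec[, name := sprintf("iv%d", .I)]
  trk <- sort_compress_index(rec, file.path(dir, "r.bed.gz"))
  lines <- track_lines(trk)
  for (i in 1:120) {
    ch <- sample(c("chr1", "chr2"), 1)
    s <- sample(0:9500, 1)
    e <- s + sample(1:600, 1)
    expect_identical(
      sort(query_track(trk, ch, s, e)),
      sort(overlap_scan_oracle(lines, ch, s, e))
    )
  }
})

test_that("empty record sets produce a valid, queryable empty track", {
  dir <- withr::local_tempdir()
  expect_warning(
    trk <- sort_compress_index(data.table::data.table(),
      file.path(dir, "empty.bed.gz")),
    "empty"
  )
  expect_identical(trk$n_records, 0L)
  expect_true(file.exists(trk$index_path))
  expect_identical(query_track(trk, "chr1", 0L, 1e6), character(0))
})

test_that("build_output_path orders applicable hierarchy components", {
  expect_identical(
    build_output_path("trk9", "qtl", "RNA-seq", "hg38", "bed19",
      significance_tier = "FDR0.05", variant_type = "SNP"),
    "FDR0.05/SNP/RNA-seq/bed19/GRCh38/trk9.bed.gz"
  )
  expect_identical(
    build_output_path("marks", "intervals", "ChIP-seq", "hg19", "bed6plus"),
    "ChIP-seq/bed6plus/GRCh37/marks.bed.gz"
  )
  expect_identical(
    build_output_path("hic1", "interactions", "Hi-C", "GRCh38",
      "bedInteract"),
    "Hi-C/bedInteract/GRCh38/hic1.bed.gz"
  )
})

test_that("clamp_score clamps out-of-range scores with a warning", {
  expect_warning(out <- clamp_score(c(-5, 0, 500, 1000, 1500)), "clamped")
  expect_identical(out, c(0L, 0L, 500L, 1000L, 1000L))
  expect_no_warning(clamp_score(c(0, 1000)))
})
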