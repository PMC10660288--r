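## Interactions pipeline: IDs, score/value, names, anchor expansion,
## query duality.

test_that("interaction IDs follow original appearance, not genomic order", {
  rec <- data.table::data.table(
    chrom1 = c("chr2", "chr1", "chr1"),
    start1 = c(5000L, 9000L, 100L)
  )
  out <- assign_interaction_ids(rec)
  expect_identical(out$interaction_id, 1:3)
  ## deterministic on re-read
  expect_identical(assign_interaction_ids(rec)$interaction_id, 1:3)
  ## the genomically-early interaction keeps its high id
  expect_identical(out[chrom1 == "chr1" & start1 == 100L, interaction_id], 3L)
})

test_that("score/value gaps are filled per the stated closed forms", {
  rec <- data.table::data.table(
    score = c(1, 100, NA, NA, 700),
    value = c(NA, NA, 3.5, NA, 1.25)
  )
  out <- compute_score_value(rec)
  expect_equal(out$value[1], 0)       # -log10(1)
  expect_equal(out$value[2], -2)      # -log10(100), literal form
  expect_identical(out$score[3], 0L)  # value present, score null sentinel
  expect_equal(out$value[3], 3.5)     # provided values never overwritten
  expect_identical(out$score[4], 0L)  # both missing -> null sentinels
  expect_true(is.na(out$value[4]))
  expect_identical(out$score[5], 700L)
  expect_equal(out$value[5], 1.25)
})

test_that("a mapped significance column takes precedence for gap filling", {
  rec <- data.table::data.table(
    score = c(NA, 500, NA),
    value = c(NA, NA, NA),
    pvalue = c(0.01, 0.001, NA)
  )
  out <- compute_score_value(rec)
  expect_equal(out$value[1], 2)         # -log10(p)
  expect_identical(out$score[1], 20L)   # min(1000, round(-10*log10 p))
  expect_equal(out$value[2], 3)         # p wins over -log10(score)
  expect_identical(out$score[2], 500L)  # mapped score kept
  expect_identical(out$score[3], 0L)    # nothing available -> nulls
  expect_true(is.na(out$value[3]))
  ## tiny p-values cap the derived score at 1000
  capped <- compute_score_value(data.table::data.table(
    score = NA_real_, value = NA_real_, pvalue = 1e-200))
  expect_identical(capped$score, 1000L)
})

test_that("interaction names combine source, id, score and value", {
  rec <- data.table::data.table(
    interaction_id = c(7L, 8L), score = c(500L, 0L), value = c(2.5, NA))
  out <- build_interaction_name(rec, "TOY3D")
  expect_identical(out$name,
    c("TOY3D:7:score=500:value=2.5", "TOY3D:8:score=0:value=."))
})

test_that("expand_anchors emits one A and one B line per interaction", {
  rec <- data.table::data.table(
    chrom1 = c("chr1", "chr1"), start1 = c(100L, 40L), end1 = c(200L, 90L),
    chrom2 = c("chr1", "chr1"), start2 = c(5000L, 40L), end2 = c(5100L, 90L),
    interaction_id = c(3L, 4L), score = c(10L, 0L), value = c(1, NA),
    name = c("S:3:a", "S:4:b")
  )
  expect_warning(out <- expand_anchors(rec), "self-interaction")
  expect_identical(nrow(out), 4L)
  a3 <- out[anchor_id == "3A"]
  b3 <- out[anchor_id == "3B"]
  ## keyed on each anchor's own coordinates
  expect_identical(a3$chrom, "chr1")
  expect_identical(a3$start, 100L)
  expect_identical(a3$end, 200L)
  expect_identical(b3$start, 5000L)
  ## both lines carry identical interaction-level fields
  shared <- setdiff(names(out), c("chrom", "start", "end", "anchor_id"))
  expect_identical(a3[, shared, with = FALSE], b3[, shared, with = FALSE])
  ## full interaction recoverable from the B line alone
  expect_identical(b3$source_start, "100")
  expect_identical(b3$target_start, "5000")
})

test_that("a fixture track conserves 2N lines with queryable anchors", {
  dir <- withr::local_tempdir()
  fx <- gen_interactions(file.path(dir, "ia"), n = 40L, seed = 3L)
  plans <- generate_plans(fx$files$mdt, file.path(dir, "out"))
  rep <- suppressWarnings(execute_plans(plans, quiet = TRUE))
  expect_identical(rep$exit_status, 0L)
  gz <- list.files(file.path(dir, "out"), pattern = "loops1\\.bed\\.gz$",
    recursive = TRUE, full.names = TRUE)
  lines <- track_lines(gz)
  expect_identical(length(lines), 2L * 40L)

  fields <- data.table::as.data.table(
    do.call(rbind, strsplit(lines, "\t", fixed = TRUE)))
  ids <- sub("[AB]$", "", fields$V19)
  roles <- sub("^[0-9]+", "", fields$V19)
  ## exactly one A and one B per id
  tab <- table(ids, roles)
  expect_true(all(tab == 1L))
  ## identical interaction-level fields within each pair (name col 4)
  per_id <- split(fields$V4, ids)
  expect_true(all(vapply(per_id, function(x) length(unique(x)) == 1L,
    logical(1))))

  ## query duality: either anchor region retrieves the interaction
  man <- fx$manifest
  for (i in seq_len(nrow(man))) {
    hitA <- query_track(gz, man$chrom1[i], man$start1[i], man$end1[i])
    hitB <- query_track(gz, man$chrom2[i], man$start2[i], man$end2[i])
    expect_true(any(grepl(sprintf("(^|\t)%d[AB](\t|$)", man$interaction_id[i]), hitA)))
    expect_true(any(grepl(sprintf("(^|\t)%d[AB](\t|$)", man$interaction_id[i]), hitB)))
  }
})
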