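## Driver: plan generation, fail-fast validation, execution modes,
## per-track isolation.

local_project <- function(seed = 5L, envir = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = envir)
  fx <- gen_project(file.path(dir, "proj"), seed = seed, n_qtl = 120L,
    n_intervals = 80L, n_interactions = 30L)
  list(dir = dir, fx = fx)
}

## Digest of everything a run produced: per-track payload md5s (recorded in
## the metadata table) plus the metadata table bytes themselves.
run_digest <- function(out_dir) {
  meta <- file.path(out_dir, "metadata.tsv")
  list(
    metadata_md5 = unname(tools::md5sum(meta)),
    tracks = data.table::fread(meta, sep = "\t")[, .(output_path, md5,
      n_records)]
  )
}

test_that("plans mirror each datatype's stage list and serialize for dry runs", {
  p <- local_project()
  plans <- generate_plans(p$fx$mdt, file.path(p$dir, "out"),
    system_config = p$fx$system_config)
  expect_length(plans, 4L)
  by_type <- split(plans, vapply(plans, `[[`, "", "datatype"))
  expect_true("harmonize_alleles" %in% by_type$qtl[[1]]$stages)
  expect_true("expand_anchors" %in% by_type$interactions[[1]]$stages)
  expect_false("harmonize_alleles" %in% by_type$intervals[[1]]$stages)
  ## dry run prints the plans and writes nothing
  out2 <- file.path(p$dir, "dry_out")
  expect_output(
    run_project(p$fx$mdt, out2, system_config = p$fx$system_config,
      dry_run = TRUE),
    "fg_plan"
  )
  expect_false(dir.exists(out2))
})

test_that("one invalid config aborts the whole batch before any processing", {
  p <- local_project()
  ## corrupt the intervals config
  cfg <- p$fx$intervals$files$config
  writeLines(c(readLines(cfg), "5 -> zorp"), cfg)
  out <- file.path(p$dir, "out_failfast")
  expect_error(
    generate_plans(p$fx$mdt, out, system_config = p$fx$system_config),
    "no track was processed"
  )
  expect_false(dir.exists(out))
})

test_that("all four execution modes produce identical artifacts", {
  p <- local_project()
  modes <- c("sequential", "threaded", "by_chromosome", "by_file")
  digests <- lapply(modes, function(m) {
    out <- file.path(p$dir, paste0("out_", m))
    rep <- suppressWarnings(run_project(p$fx$mdt, out,
      system_config = p$fx$system_config, mode = m, threads = 2L,
      quiet = TRUE))
    expect_identical(rep$exit_status, 0L)
    run_digest(out)
  })
  for (i in 2:4) {
    expect_identical(digests[[i]]$metadata_md5, digests[[1]]$metadata_md5)
    expect_identical(digests[[i]]$tracks, digests[[1]]$tracks)
  }
})

test_that("by_chromosome on a single-chromosome file equals sequential", {
  dir <- withr::local_tempdir()
  fx <- gen_intervals(file.path(dir, "iv"), n = 60L, seed = 9L)
  ## restrict the input to one chromosome (degenerate partition)
  lines <- readLines(fx$files$data)
  keep <- c(lines[1], grep("^(chr)?1\t", lines[-1], value = TRUE))
  writeLines(keep, fx$files$data)
  reps <- lapply(c("sequential", "by_chromosome"), function(m) {
    out <- file.path(dir, paste0("out_", m))
    suppressWarnings(run_project(fx$files$mdt, out, mode = m,
      quiet = TRUE))
    run_digest(out)
  })
  expect_identical(reps[[1]], reps[[2]])
})

test_that("a failing track is reported and skipped; siblings complete", {
  p <- local_project()
  plans <- generate_plans(p$fx$mdt, file.path(p$dir, "out_fail"),
    system_config = p$fx$system_config)
  ## make one input unreadable after validation
  unlink(p$fx$interactions$files$data)
  rep <- suppressWarnings(execute_plans(plans, quiet = TRUE))
  expect_identical(rep$exit_status, 1L)
  expect_identical(sum(rep$table$status == "failed"), 1L)
  expect_identical(sum(rep$table$status == "ok"), 3L)
  expect_identical(rep$failures[[1]]$track_id, "loops1")
  ## completed tracks made it into the project metadata
  meta <- data.table::fread(rep$metadata_path, sep = "\t")
  expect_false("loops1" %in% meta$track_id)
  expect_true(all(c("peaks1", "eqtl_wide") %in% meta$track_id))
  ## no partial outputs from the failed track
  expect_length(list.files(file.path(p$dir, "out_fail"),
    pattern = "loops1", recursive = TRUE), 0L)
})

test_that("row conservation holds: accepted records + rejects = input rows", {
  dir <- withr::local_tempdir()
  fx <- gen_intervals(file.path(dir, "iv"), n = 50L, seed = 13L)
  ## plant two broken rows: short row and inverted coordinates
  lines <- readLines(fx$files$data)
  lines <- c(lines, "chr1\t50", "chr1\t100\t20\tbadpeak\t5\t+\t1\t2")
  writeLines(lines, fx$files$data)
  rep <- suppressWarnings(run_project(fx$files$mdt,
    file.path(dir, "out"), quiet = TRUE))
  expect_identical(rep$table$n_records, 50L)
  expect_identical(rep$table$n_rejects, 2L)
  rej <- data.table::fread(file.path(dir, "out", "rejects",
    "peaks1.rejects.tsv"), sep = "\t")
  expect_identical(nrow(rej), 2L)
  expect_setequal(rej$line, c(52L, 53L))
})
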