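## End-to-end driver: per-file pipeline plans, execution modes, run report.

#' Read a system configuration file
#'
#' INI-style `key = value` text (section headers in `[...]` are ignored)
#' holding system-specific paths and defaults: `variant_reference`,
#' `genome_fasta`, `gene_model` (required for QTL inputs) and optionally
#' `fdr_threshold`. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
read_system_config <- function(path) {
  if (!file.exists(path)) stop("system config not found: ", path)
  lines <- trimws(sub("[#;].*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  base_dir <- dirname(normalizePath(path))
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("unparseable system-config line: '", ln, "'")
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    if (key %in% c("variant_reference", "genome_fasta", "gene_model") &&
        !grepl("^/", val)) {
      val <- file.path(base_dir, val)
    }
    out[[key]] <- val
  }
  if (!is.null(out$fdr_threshold)) {
    out$fdr_threshold <- as.numeric(out$fdr_threshold)
  }
  out
}

## Stage lists mirror the processing graph: standard pre-steps, then
## datatype-specific steps, then standard post-steps.
plan_stages <- function(datatype) {
  pre <- c("read_input", "map_columns", "normalize_chrom",
    "convert_coordinates")
  mid <- switch(datatype,
    intervals = character(0),
    qtl = c("harmonize_alleles", "assign_rsid", "annotate_target",
      "compute_fdr", "split_outputs"),
    interactions = c("assign_ids", "compute_score_value", "build_name",
      "expand_anchors")
  )
  post <- c("sort_compress_index", "compute_track_stats",
    "assemble_metadata")
  c(pre, mid, post)
}

#' Generate per-file pipeline plans from an MDT
#'
#' Validates the MDT and every referenced file config up front and builds
#' one inspectable plan per input file. Any configuration error anywhere in
#' the batch aborts before any data processing starts (fail-fast), with all
#' errors reported together.
#'
#' @param mdt_path Path to the minimal descriptions table.
#' @param out_dir Project output directory.
#' @param system_config Path to a system config file, or a named list (see
#'   [read_system_config()]). Required when the MDT contains QTL rows.
#' @param fdr_threshold QTL significance threshold; a `fdr_threshold` entry
#'   in the system config overrides this default.
#' @param vocabulary Optional custom vocabulary table.
#' @return An `fg_plan_list` (list of `fg_plan` objects).
#' @export
generate_plans <- function(mdt_path, out_dir, system_config = NULL,
                           fdr_threshold = 0.05,
                           vocabulary = load_vocabulary()) {
  descriptors <- parse_mdt(mdt_path)
  sys <- if (is.character(system_config)) {
    read_system_config(system_config)
  } else {
    system_config %||% list()
  }
  if (!is.null(sys$fdr_threshold)) fdr_threshold <- sys$fdr_threshold

  problems <- character(0)
  configs <- vector("list", length(descriptors))
  for (i in seq_along(descriptors)) {
    d <- descriptors[[i]]
    cfg <- try(parse_file_config(d$config_path, d$datatype), silent = TRUE)
    if (inherits(cfg, "try-error")) {
      problems <- c(problems, sprintf(
        "track '%s': %s", d$track_id, trimws(attr(cfg, "condition")$message)
      ))
    } else {
      configs[[i]] <- cfg
    }
    if (d$datatype == "qtl") {
      for (key in c("variant_reference", "genome_fasta", "gene_model")) {
        if (is.null(sys[[key]])) {
          problems <- c(problems, sprintf(
            "track '%s': QTL processing requires '%s' in the system config",
            d$track_id, key
          ))
        } else if (!file.exists(sys[[key]])) {
          problems <- c(problems, sprintf(
            "track '%s': %s not readable: %s", d$track_id, key, sys[[key]]
          ))
        }
      }
    }
  }
  if (length(problems)) {
    stop(
      "plan generation failed; no track was processed:\n  ",
      paste(unique(problems), collapse = "\n  ")
    )
  }

  plans <- lapply(seq_along(descriptors), function(i) {
    d <- descriptors[[i]]
    plan <- list(
      track_id = d$track_id,
      datatype = d$datatype,
      stages = plan_stages(d$datatype),
      input = d$file_path,
      config = configs[[i]],
      descriptor = d,
      out_dir = out_dir,
      fdr_threshold = fdr_threshold,
      reference_paths = sys[c("variant_reference", "genome_fasta",
        "gene_model")],
      vocabulary = vocabulary,
      chromosome_split_eligible = TRUE
    )
    class(plan) <- "fg_plan"
    plan
  })
  class(plans) <- c("fg_plan_list", "list")
  plans
}

#' @export
print.fg_plan <- function(x, ...) {
  cat(sprintf("<fg_plan> %s [%s]\n  input:  %s\n  stages: %s\n",
    x$track_id, x$datatype, x$input, paste(x$stages, collapse = " -> ")))
  invisible(x)
}

#' @export
print.fg_plan_list <- function(x, ...) {
  cat(sprintf("<fg_plan_list> %d plan(s)\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

## ---- per-datatype runners ------------------------------------------------

## Returns list(outputs = list(list(records, relpath, format_type)),
##              rejects = data.table(line, reason, raw),
##              n_accepted)
run_intervals <- function(prep, plan) {
  rec <- prep$records
  d <- plan$descriptor
  std <- intersect(
    c("chrom", "start", "end", "name", "score", "strand"), names(rec)
  )
  pt_cols <- grep("^pt\\.", names(rec), value = TRUE)
  out <- rec[, c(std, pt_cols), with = FALSE]
  if ("score" %in% std) {
    sc <- clamp_score(parse_num(out$score), context = "interval score")
    out[, score := fmt_int(sc)]
  }
  fmt <- paste0("bed", length(std), if (length(pt_cols)) "plus" else "")
  relpath <- build_output_path(d$track_id, "intervals", d$assay_type,
    d$genome_build, fmt)
  list(
    outputs = list(list(records = out, relpath = relpath, format_type = fmt)),
    rejects = prep$rejects,
    n_accepted = nrow(out)
  )
}

run_qtl <- function(prep, plan, by_chromosome = FALSE, threads = 1L) {
  rec <- prep$records
  rejects <- prep$rejects
  d <- plan$descriptor
  ref <- load_variant_reference(
    plan$reference_paths$variant_reference,
    plan$reference_paths$genome_fasta
  )
  genes <- load_gene_model(plan$reference_paths$gene_model)

  setnames(rec, old = c("ref", "alt"), new = c("ref_allele", "alt_allele"))
  for (col in c("beta", "se", "pvalue", "fdr", "alt_allele_freq")) {
    if (col %in% names(rec)) rec[[col]] <- parse_num(rec[[col]])
  }
  if (!"se" %in% names(rec)) rec[, se := NA_real_]
  if (!"tissue" %in% names(rec) ||
      all(rec$tissue %in% c(NA_SENTINEL, NA_character_))) {
    rec[, tissue := d$biosample_term]
  }
  bad_beta <- is.na(rec$beta)
  if (any(bad_beta)) {
    rejects <- rbind(rejects, reject_rows(rec, bad_beta,
      "missing or non-numeric beta"))
    rec <- rec[!bad_beta]
  }

  per_chrom <- function(part) {
    part <- harmonize_alleles(part, ref)
    part <- assign_rsid(part, ref)
    annotate_target(part, genes)
  }
  if (by_chromosome && nrow(rec)) {
    parts <- split(rec, by = "chrom", sorted = TRUE)
    parts <- if (threads > 1L) {
      mclapply(parts, per_chrom, mc.cores = threads)
    } else {
      lapply(parts, per_chrom)
    }
    rec <- rbindlist(parts)
    setorder(rec, .line) # restore input order before FDR and rendering
  } else {
    rec <- per_chrom(rec)
  }

  unresolved <- rec$flip_status == "unresolved"
  if (any(unresolved)) {
    rejects <- rbind(rejects, reject_rows(rec, unresolved,
      "unresolved alleles"))
    rec <- rec[!unresolved]
  }
  fdr_res <- compute_fdr(rec)
  if (nrow(fdr_res$rejects)) {
    rejects <- rbind(rejects, reject_rows(fdr_res$rejects,
      rep(TRUE, nrow(fdr_res$rejects)), "p-value outside (0, 1]"))
  }
  rec <- fdr_res$records

  thr <- plan$fdr_threshold
  splits <- split_qtl_outputs(rec, threshold = thr)
  tier <- paste0("FDR", format(thr, scientific = FALSE, trim = TRUE))
  fmt <- "bed16"
  outputs <- list(
    list(records = render_qtl(splits$SNP_full),
      relpath = build_output_path(d$track_id, "qtl", d$assay_type,
        d$genome_build, fmt, variant_type = "SNP"),
      format_type = fmt),
    list(records = render_qtl(splits$INDEL_full),
      relpath = build_output_path(d$track_id, "qtl", d$assay_type,
        d$genome_build, fmt, variant_type = "INDEL"),
      format_type = fmt),
    list(records = render_qtl(splits$SNP_significant),
      relpath = build_output_path(d$track_id, "qtl", d$assay_type,
        d$genome_build, fmt, significance_tier = tier,
        variant_type = "SNP"),
      format_type = fmt),
    list(records = render_qtl(splits$INDEL_significant),
      relpath = build_output_path(d$track_id, "qtl", d$assay_type,
        d$genome_build, fmt, significance_tier = tier,
        variant_type = "INDEL"),
      format_type = fmt)
  )
  list(outputs = outputs, rejects = rejects, n_accepted = nrow(rec))
}

run_interactions <- function(prep, plan, by_chromosome = FALSE,
                             threads = 1L) {
  rec <- prep$records
  d <- plan$descriptor
  ## IDs are assigned in input order, before any splitting or sorting
  rec <- assign_interaction_ids(rec)
  for (col in c("score", "value", "pvalue")) {
    if (col %in% names(rec)) rec[[col]] <- parse_num(rec[[col]])
  }
  per_chunk <- function(part) {
    part <- compute_score_value(part)
    build_interaction_name(part, d$data_source)
  }
  if (by_chromosome && nrow(rec)) {
    parts <- split(rec, by = "chrom1", sorted = TRUE)
    parts <- if (threads > 1L) {
      mclapply(parts, per_chunk, mc.cores = threads)
    } else {
      lapply(parts, per_chunk)
    }
    rec <- rbindlist(parts)
    setorder(rec, .line)
  } else {
    rec <- per_chunk(rec)
  }
  out <- expand_anchors(rec)
  fmt <- "bedInteract"
  relpath <- build_output_path(d$track_id, "interactions", d$assay_type,
    d$genome_build, fmt)
  list(
    outputs = list(list(records = out, relpath = relpath,
      format_type = fmt)),
    rejects = prep$rejects,
    n_accepted = nrow(rec)
  )
}

## Read a raw input table per the config dialect. A completely empty file
## (valid: a dataset may legitimately have zero records) yields a 0-row
## table whose column count covers every positional reference in the
## config, so mapping still resolves.
read_raw_input <- function(path, config) {
  if (!file.exists(path)) stop("input file not readable: ", path)
  if (file.size(path) == 0L) {
    refs <- suppressWarnings(as.integer(c(names(config$column_map),
      config$passthrough_columns)))
    k <- max(c(refs, 1L), na.rm = TRUE)
    return(as.data.table(stats::setNames(rep(list(character(0)), k),
      paste0("V", seq_len(k)))))
  }
  fread(path, sep = config$delimiter, header = config$has_header,
    colClasses = "character", quote = "", fill = TRUE)
}

## Render a subset of records into reject-report rows.
reject_rows <- function(rec, mask, reason) {
  sub <- rec[mask]
  keep <- setdiff(names(sub), ".line")
  data.table(
    line = sub$.line,
    reason = rep(reason, nrow(sub)),
    raw = if (nrow(sub)) {
      do.call(paste, c(lapply(sub[, keep, with = FALSE], as.character),
        sep = "\t"))
    } else character(0)
  )
}

## ---- plan execution ------------------------------------------------------

run_plan <- function(plan, mode = "sequential", threads = 1L) {
  stopifnot(inherits(plan, "fg_plan"))
  config <- plan$config
  d <- plan$descriptor
  timings <- c()
  tick <- function() proc.time()[["elapsed"]]

  t0 <- tick()
  raw <- read_raw_input(plan$input, config)
  timings["read"] <- tick() - t0

  t0 <- tick()
  prep <- prepare_records(raw, config, plan$datatype)
  timings["prepare"] <- tick() - t0

  t0 <- tick()
  by_chrom <- identical(mode, "by_chromosome")
  res <- switch(plan$datatype,
    intervals = run_intervals(prep, plan),
    qtl = run_qtl(prep, plan, by_chromosome = by_chrom, threads = threads),
    interactions = run_interactions(prep, plan, by_chromosome = by_chrom,
      threads = threads)
  )
  timings["transform"] <- tick() - t0

  ## write outputs into a per-track temp dir, then move atomically so a
  ## failing track can never leave partial outputs among its siblings
  t0 <- tick()
  tmp_root <- file.path(plan$out_dir, paste0(".tmp-", plan$track_id))
  unlink(tmp_root, recursive = TRUE)
  cat_assign <- resolve_categories(d$biosample_term, plan$vocabulary)
  meta_rows <- list()
  n_records_total <- 0L
  for (out in res$outputs) {
    rr <- out$records
    if (".line" %in% names(rr)) rr <- rr[, !".line"]
    tmp_path <- file.path(tmp_root, out$relpath)
    track <- sort_compress_index(rr, tmp_path)
    stats <- compute_track_stats(track)
    meta_rows[[length(meta_rows) + 1L]] <- assemble_metadata(
      d, cat_assign, stats, out$relpath, out$format_type
    )
    n_records_total <- n_records_total + track$n_records
  }
  ## move into place
  tmp_files <- list.files(tmp_root, recursive = TRUE, full.names = TRUE,
    all.files = TRUE)
  for (f in tmp_files) {
    rel <- sub(paste0("^", tmp_root, "/"), "", f)
    final <- file.path(plan$out_dir, rel)
    dir.create(dirname(final), recursive = TRUE, showWarnings = FALSE)
    file.rename(f, final)
  }
  unlink(tmp_root, recursive = TRUE)

  rejects <- res$rejects
  if (nrow(rejects)) {
    setorder(rejects, line)
    rej_dir <- file.path(plan$out_dir, "rejects")
    dir.create(rej_dir, recursive = TRUE, showWarnings = FALSE)
    ## raw lines may embed the output delimiter; quote the field
    fwrite(rejects,
      file.path(rej_dir, paste0(plan$track_id, ".rejects.tsv")),
      sep = "\t", quote = "auto")
  }
  timings["write"] <- tick() - t0

  list(
    track_id = plan$track_id,
    status = "ok",
    metadata = meta_rows,
    n_outputs = length(res$outputs),
    n_records = n_records_total,
    n_rejects = nrow(rejects),
    timings = timings
  )
}

#' Execute pipeline plans
#'
#' Runs every plan and consolidates project metadata. Four execution modes
#' are available; all produce byte-identical final outputs:
#' \describe{
#'   \item{sequential}{plans processed one after another on one CPU.}
#'   \item{threaded, by_file}{plans processed in parallel worker processes.}
#'   \item{by_chromosome}{each file's records are partitioned by
#'     normalized chromosome, the row-local type-specific steps run per
#'     partition (in parallel when `threads > 1`), and partitions are
#'     merged back into input order before FDR correction, sorting and
#'     indexing. FDR is always computed after the merge, so gene-tissue
#'     groups spanning chromosomes (trans-QTLs) are corrected jointly.}
#' }
#' A failing track is reported and skipped; the remaining tracks complete.
#'
#' @param plans An `fg_plan_list` from [generate_plans()].
#' @param mode Execution mode.
#' @param threads Worker count for the parallel modes.
#' @param quiet Suppress progress logging.
#' @return An `fg_run_report`; its `exit_status` is nonzero if any track
#'   failed.
#' @export
execute_plans <- function(plans,
                          mode = c("sequential", "threaded",
                            "by_chromosome", "by_file"),
                          threads = 2L, quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(plans) > 0L)
  out_dir <- plans[[1]]$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  runner <- function(plan) {
    tryCatch(
      run_plan(plan, mode = mode, threads = threads),
      error = function(e) {
        list(track_id = plan$track_id, status = "failed",
          error = conditionMessage(e), metadata = list(),
          n_outputs = 0L, n_records = 0L, n_rejects = 0L,
          timings = c())
      }
    )
  }
  results <- if (mode %in% c("threaded", "by_file") && threads > 1L) {
    mclapply(plans, runner, mc.cores = threads)
  } else {
    lapply(plans, runner)
  }
  ## a worker killed mid-run surfaces as a try-error
  results <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "try-error") || is.null(r$status)) {
      list(track_id = plans[[i]]$track_id, status = "failed",
        error = as.character(r), metadata = list(), n_outputs = 0L,
        n_records = 0L, n_rejects = 0L, timings = c())
    } else r
  })

  meta_rows <- unlist(lapply(results, `[[`, "metadata"), recursive = FALSE)
  metadata_path <- if (length(meta_rows)) {
    consolidate_project(meta_rows, out_dir)
  } else NA_character_

  tab <- rbindlist(lapply(results, function(r) data.table(
    track_id = r$track_id, status = r$status,
    n_outputs = r$n_outputs, n_records = r$n_records,
    n_rejects = r$n_rejects,
    elapsed = round(sum(r$timings), 3)
  )))
  failures <- Filter(function(r) r$status == "failed", results)

  ## run provenance (timestamps, versions) goes to the log, never into the
  ## metadata table, which must be reproducible byte-for-byte
  log_path <- file.path(out_dir, "run.log")
  cat(
    sprintf("run finished: %s\nmode: %s  threads: %d\n",
      format(Sys.time(), "%Y-%m-%d %H:%M:%S"), mode, threads),
    sprintf("fgharmonize version: %s\n",
      as.character(utils::packageVersion("fgharmonize"))),
    file = log_path
  )
  fwrite(tab, log_path, sep = "\t", append = TRUE, quote = FALSE,
    col.names = TRUE)

  if (!quiet) {
    for (r in results) {
      if (r$status == "ok") {
        fg_log(sprintf("%s: ok (%d output(s), %d record(s), %d reject(s))",
          r$track_id, r$n_outputs, r$n_records, r$n_rejects))
      } else {
        fg_log(sprintf("%s: FAILED: %s", r$track_id, r$error))
      }
    }
  }

  report <- list(
    table = tab,
    failures = lapply(failures, function(r) {
      list(track_id = r$track_id, error = r$error)
    }),
    metadata_path = metadata_path,
    out_dir = out_dir,
    mode = mode,
    exit_status = if (length(failures)) 1L else 0L
  )
  class(report) <- "fg_run_report"
  report
}

#' @export
print.fg_run_report <- function(x, ...) {
  cat(sprintf("<fg_run_report> mode=%s  out_dir=%s\n", x$mode, x$out_dir))
  print(x$table)
  if (length(x$failures)) {
    cat("failures:\n")
    for (f in x$failures) cat("  ", f$track_id, ": ", f$error, "\n", sep = "")
  }
  invisible(x)
}

#' Run a full harmonization project
#'
#' Convenience wrapper: [generate_plans()] then [execute_plans()]. With
#' `dry_run = TRUE` the plans are printed and returned without writing any
#' output, for inspection of the generated per-file pipelines.
#'
#' @inheritParams generate_plans
#' @inheritParams execute_plans
#' @param dry_run Print plans instead of executing.
#' @return `fg_run_report`, or the `fg_plan_list` when `dry_run = TRUE`.
#' @export
run_project <- function(mdt_path, out_dir, system_config = NULL,
                        mode = "sequential", threads = 2L,
                        fdr_threshold = 0.05, dry_run = FALSE,
                        quiet = FALSE) {
  plans <- generate_plans(mdt_path, out_dir, system_config = system_config,
    fdr_threshold = fdr_threshold)
  if (dry_run) {
    print(plans)
    return(invisible(plans))
  }
  execute_plans(plans, mode = mode, threads = threads, quiet = quiet)
}
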