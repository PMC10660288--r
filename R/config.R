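## Config model: minimal descriptions table (MDT), per-file configs,
## controlled-vocabulary category resolution.

#' Required MDT columns
#'
#' Column names every minimal descriptions table must provide. Any further
#' columns are preserved, in order, in each descriptor's `extra` field and
#' later serialized into the `track_description` metadata column.
#'
#' @return Character vector of required column names.
#' @export
mdt_required_columns <- function() {
  c(
    "track_id", "datatype", "biosample_term", "assay_type", "genome_build",
    "data_source", "file_path", "config_path"
  )
}

## Optional, recognized MDT columns (not folded into `extra`).
mdt_optional_columns <- function() c("biosample_type", "life_stage", "doi")

fg_datatypes <- function() c("intervals", "qtl", "interactions")

#' Parse a minimal descriptions table (MDT)
#'
#' The MDT is a tab-separated file with a header row and one row per input
#' data file, carrying biological (biosample, assay), source (project, DOI)
#' and file (data path, config path) information. It is the single required
#' argument of a harmonization run: every pipeline is generated from it.
#'
#' Relative `file_path`/`config_path` entries are resolved against the
#' directory containing the MDT. Validation reports *all* offending rows
#' (unreadable paths, bad datatypes/builds), not just the first.
#'
#' @param path Path to the MDT file.
#' @param check_paths Verify that `file_path` and `config_path` reference
#'   readable files (default `TRUE`).
#' @return A list of `fg_track_descriptor` objects, one per data row.
#' @seealso [write_mdt()] for the inverse, [generate_plans()] for the driver.
#' @export
parse_mdt <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("MDT file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
    quote = "", fill = TRUE)
  req <- mdt_required_columns()
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop(
      "MDT is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (nrow(dt) == 0L) {
    fg_warn("MDT has a header but no data rows: ", path)
    return(list())
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base_dir, p))
  }
  dt[, file_path := resolve(file_path)]
  dt[, config_path := resolve(config_path)]

  problems <- character(0)
  bad_dt <- which(!dt$datatype %in% fg_datatypes())
  for (i in bad_dt) {
    problems <- c(problems, sprintf(
      "row %d (%s): unknown datatype '%s' (expected one of %s)",
      i, dt$track_id[i], dt$datatype[i], paste(fg_datatypes(), collapse = "/")
    ))
  }
  build_ok <- vapply(dt$genome_build, function(b) {
    !inherits(try(normalize_genome_build(b), silent = TRUE), "try-error")
  }, logical(1))
  for (i in which(!build_ok)) {
    problems <- c(problems, sprintf(
      "row %d (%s): unsupported genome_build '%s'",
      i, dt$track_id[i], dt$genome_build[i]
    ))
  }
  if (check_paths) {
    for (i in seq_len(nrow(dt))) {
      if (!file.exists(dt$file_path[i])) {
        problems <- c(problems, sprintf(
          "row %d (%s): file_path not readable: %s",
          i, dt$track_id[i], dt$file_path[i]
        ))
      }
      if (!file.exists(dt$config_path[i])) {
        problems <- c(problems, sprintf(
          "row %d (%s): config_path not readable: %s",
          i, dt$track_id[i], dt$config_path[i]
        ))
      }
    }
  }
  dup <- dt$track_id[duplicated(dt$track_id)]
  if (length(dup)) {
    problems <- c(problems, paste0(
      "duplicate track_id value(s): ", paste(unique(dup), collapse = ", ")
    ))
  }
  if (length(problems)) {
    stop("MDT validation failed:\n  ", paste(problems, collapse = "\n  "))
  }

  known <- c(req, mdt_optional_columns())
  extra_cols <- setdiff(names(dt), known)
  empty_na <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(x)) NA_character_ else x
  }
  lapply(seq_len(nrow(dt)), function(i) {
    extra <- as.list(dt[i, extra_cols, with = FALSE])
    extra <- lapply(extra, as.character)
    desc <- list(
      track_id = dt$track_id[i],
      datatype = dt$datatype[i],
      biosample_term = dt$biosample_term[i],
      biosample_type = if ("biosample_type" %in% names(dt)) empty_na(dt$biosample_type[i]) else NA_character_,
      life_stage = if ("life_stage" %in% names(dt)) empty_na(dt$life_stage[i]) else NA_character_,
      assay_type = dt$assay_type[i],
      genome_build = normalize_genome_build(dt$genome_build[i]),
      data_source = dt$data_source[i],
      doi = if ("doi" %in% names(dt)) empty_na(dt$doi[i]) else NA_character_,
      file_path = dt$file_path[i],
      config_path = dt$config_path[i],
      extra = extra
    )
    class(desc) <- "fg_track_descriptor"
    desc
  })
}

#' Write track descriptors back to MDT format
#'
#' Inverse of [parse_mdt()]; parsing the written file yields descriptors
#' identical up to path normalization (round-trip stability).
#'
#' @param descriptors List of `fg_track_descriptor` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mdt <- function(descriptors, path) {
  stopifnot(length(descriptors) > 0L)
  extra_cols <- names(descriptors[[1]]$extra)
  rows <- lapply(descriptors, function(d) {
    base <- data.table(
      track_id = d$track_id, datatype = d$datatype,
      biosample_term = d$biosample_term, biosample_type = d$biosample_type,
      life_stage = d$life_stage, assay_type = d$assay_type,
      genome_build = d$genome_build, data_source = d$data_source,
      doi = d$doi, file_path = d$file_path, config_path = d$config_path
    )
    for (k in extra_cols) base[[k]] <- d$extra[[k]]
    base
  })
  out <- rbindlist(rows)
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.fg_track_descriptor <- function(x, ...) {
  cat(sprintf(
    "<fg_track_descriptor> %s [%s] %s / %s (%s)\n  file:   %s\n  config: %s\n",
    x$track_id, x$datatype, x$biosample_term, x$assay_type, x$genome_build,
    x$file_path, x$config_path
  ))
  if (length(x$extra)) {
    cat("  extra: ", paste(names(x$extra), unlist(x$extra), sep = "=",
      collapse = "; "), "\n")
  }
  invisible(x)
}

#' Standard output fields per datatype
#'
#' The standard fields each datatype's file config may map, split into
#' required and optional, in canonical output order. For `qtl`, the variant
#' position may be given either as a single 1-based `pos` column or as
#' `start`(+`end`); requiredness of the position is checked specially.
#'
#' @param datatype One of `"intervals"`, `"qtl"`, `"interactions"`.
#' @return List with `required` and `optional` character vectors.
#' @export
standard_fields <- function(datatype) {
  switch(match.arg(datatype, fg_datatypes()),
    intervals = list(
      required = c("chrom", "start", "end"),
      optional = c("name", "score", "strand")
    ),
    qtl = list(
      required = c("chrom", "ref", "alt", "beta", "pvalue", "target_id"),
      optional = c(
        "pos", "start", "end", "variant_id", "effect_allele", "se", "fdr",
        "alt_allele_freq", "tissue"
      )
    ),
    interactions = list(
      required = c("chrom1", "start1", "end1", "chrom2", "start2", "end2"),
      optional = c(
        "name", "score", "value", "pvalue", "strand1", "strand2",
        "experiment", "color"
      )
    )
  )
}

#' Parse a file config
#'
#' File configs describe input-to-output reformatting for one input file
#' type: which input column (by header name or 1-based position) feeds each
#' standard output field, plus dialect attributes. The grammar is flat text,
#' one entry per line:
#' \preformatted{
#'   # comment
#'   delimiter = tab            # tab|comma|space|semicolon|pipe or literal
#'   has_header = true
#'   coordinate_base = 1        # 0 or 1
#'   chrom_style = auto         # auto|bare|chr_prefixed (declarative)
#'   passthrough = colA, colB   # or "*" = every unmapped column, in order
#'   chromosome -> chrom        # mapping: input column -> standard field
#'   3 -> pos                   # positional mapping (1-based input column)
#' }
#' Defaults: `delimiter=tab`, `has_header=true`, `coordinate_base=1`,
#' `chrom_style=auto`, no passthrough.
#'
#' @param path Path to the config file.
#' @param datatype Datatype the config is validated against. If `NULL`, a
#'   `datatype = ...` line must be present in the config itself.
#' @return An `fg_file_config` object.
#' @export
parse_file_config <- function(path, datatype = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- list(
    delimiter = "\t", has_header = TRUE, coordinate_base = 1L,
    chrom_style = "auto", passthrough = character(0)
  )
  map_in <- character(0)  # input column refs
  map_out <- character(0) # standard field names

  for (ln in lines) {
    if (grepl("->", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed mapping line: '", ln, "'")
      map_in <- c(map_in, trimws(parts[1]))
      map_out <- c(map_out, trimws(parts[2]))
    } else if (grepl("=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(parts[1])
      val <- trimws(paste(parts[-1], collapse = "="))
      switch(key,
        delimiter = {
          kv$delimiter <- switch(val,
            tab = "\t", comma = ",", space = " ", semicolon = ";",
            pipe = "|", val
          )
          if (nchar(kv$delimiter) != 1L) {
            stop("delimiter must be a single character, got: '", val, "'")
          }
        },
        has_header = kv$has_header <- tolower(val) %in% c("true", "yes", "1"),
        coordinate_base = {
          if (!val %in% c("0", "1")) stop("coordinate_base must be 0 or 1")
          kv$coordinate_base <- as.integer(val)
        },
        chrom_style = {
          if (!val %in% c("auto", "bare", "chr_prefixed")) {
            stop("chrom_style must be auto, bare or chr_prefixed")
          }
          kv$chrom_style <- val
        },
        passthrough = {
          kv$passthrough <- if (identical(val, "*")) "*" else
            trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        },
        datatype = {
          if (is.null(datatype)) datatype <- val
        },
        stop("unknown config key: '", key, "'")
      )
    } else {
      stop("unparseable config line: '", ln, "'")
    }
  }

  if (is.null(datatype)) {
    stop("datatype not supplied and no 'datatype =' line in config: ", path)
  }
  datatype <- match.arg(datatype, fg_datatypes())
  fields <- standard_fields(datatype)
  valid <- c(fields$required, fields$optional)

  unknown <- setdiff(map_out, valid)
  if (length(unknown)) {
    stop(
      "unknown standard field(s) for datatype '", datatype, "': ",
      paste(unknown, collapse = ", "), "\n  valid fields: ",
      paste(valid, collapse = ", ")
    )
  }
  dup_out <- unique(map_out[duplicated(map_out)])
  if (length(dup_out)) {
    stop(
      "standard field(s) mapped more than once: ",
      paste(dup_out, collapse = ", ")
    )
  }
  dup_in <- unique(map_in[duplicated(map_in)])
  if (length(dup_in)) {
    stop(
      "input column(s) mapped to two output fields: ",
      paste(dup_in, collapse = ", ")
    )
  }
  need <- fields$required
  if (datatype == "qtl") {
    if (!any(c("pos", "start") %in% map_out)) {
      stop("qtl config must map a variant position: either 'pos' or 'start'")
    }
  }
  missing_req <- setdiff(need, map_out)
  if (length(missing_req)) {
    stop(
      "config does not map required field(s) for datatype '", datatype,
      "': ", paste(missing_req, collapse = ", ")
    )
  }

  cfg <- list(
    datatype = datatype,
    column_map = stats::setNames(map_out, map_in),
    delimiter = kv$delimiter,
    has_header = kv$has_header,
    coordinate_base = kv$coordinate_base,
    chrom_style = kv$chrom_style,
    passthrough_columns = kv$passthrough
  )
  class(cfg) <- "fg_file_config"
  cfg
}

#' @export
print.fg_file_config <- function(x, ...) {
  delim <- switch(x$delimiter, "\t" = "tab", "," = "comma", " " = "space",
    x$delimiter)
  cat(sprintf(
    "<fg_file_config> datatype=%s delimiter=%s header=%s base=%d style=%s\n",
    x$datatype, delim, x$has_header, x$coordinate_base, x$chrom_style
  ))
  cat("  map: ", paste(names(x$column_map), x$column_map, sep = " -> ",
    collapse = "; "), "\n")
  if (length(x$passthrough_columns)) {
    cat("  passthrough: ", paste(x$passthrough_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load the bundled tissue/system controlled vocabulary
#'
#' A small editable TSV (columns `term`, `tissue_category`,
#' `system_category`) mapping free-text biosample terms to standardized
#' tissue and system categories. The bundled table covers common tissues;
#' projects can supply their own with the same columns.
#'
#' @param path Optional path to a custom vocabulary TSV.
#' @return A `data.table` with the three columns.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.tsv", package = "fgharmonize")
  }
  voc <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("term", "tissue_category", "system_category") %in% names(voc)))
  voc
}

#' Resolve standardized tissue and system categories for a biosample term
#'
#' Lookup is exact but case-insensitive. Terms absent from the vocabulary
#' degrade to `"uncategorized"`/`"uncategorized"` with a warning, never an
#' error, so one unrecognized label cannot block a batch run. The system
#' category is a function of the tissue category (many-to-one).
#'
#' @param biosample_term Free-text tissue/cell-type label.
#' @param vocabulary Vocabulary table from [load_vocabulary()].
#' @return List with `tissue_category` and `system_category`.
#' @export
resolve_categories <- function(biosample_term, vocabulary = load_vocabulary()) {
  key <- tolower(trimws(as.character(biosample_term)))
  hit <- which(tolower(vocabulary$term) == key)
  if (length(hit) == 0L || is.na(key) || !nzchar(key)) {
    fg_warn(
      "biosample term not in vocabulary, categorizing as 'uncategorized': '",
      biosample_term, "'"
    )
    return(list(
      tissue_category = "uncategorized",
      system_category = "uncategorized"
    ))
  }
  list(
    tissue_category = vocabulary$tissue_category[hit[1]],
    system_category = vocabulary$system_category[hit[1]]
  )
}
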