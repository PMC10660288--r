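## Metadata engine: per-track statistics, standardized track metadata,
## project-level consolidation.

#' Compute per-track file statistics
#'
#' Recomputes, from a written track, the three file statistics recorded in
#' the standardized metadata: the record count, the genomic base-pair
#' coverage (size of the union of the track's `[start, end)` intervals, so
#' overlapping records are counted once), and the md5 digest of the
#' uncompressed payload (so compression settings never change a track's
#' identity).
#'
#' @param track An `fg_track` or path to a track file.
#' @return List with `n_records`, `bp_coverage`, `md5`.
#' @export
compute_track_stats <- function(track) {
  path <- track_path(track)
  if (!file.exists(path)) stop("track file not readable: ", path)
  lines <- read_lines_maybe_gz(path)
  n <- length(lines)
  if (n == 0L) {
    return(list(n_records = 0L, bp_coverage = 0L, md5 = md5_of_lines(character(0))))
  }
  dt <- fread(text = paste(lines, collapse = "\n"), sep = "\t",
    header = FALSE, colClasses = "character", quote = "",
    select = 1:3, col.names = c("chrom", "start", "end"))
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  cov <- dt[, .(bp = sum(width(reduce(IRanges(start + 1L, end))))),
    by = chrom][, sum(bp)]
  list(n_records = n, bp_coverage = as.integer(cov), md5 = md5_of_lines(lines))
}

## Serialize descriptor extras as "k1=v1;k2=v2" in MDT column order.
serialize_extras <- function(extra) {
  if (length(extra) == 0L) return("")
  paste(names(extra), unlist(extra), sep = "=", collapse = ";")
}

#' Fixed column order of the project metadata table
#'
#' @return Character vector naming, in order, the columns of every
#'   per-track metadata row and of the consolidated project table.
#' @export
metadata_columns <- function() {
  c(
    "track_id", "datatype", "output_path", "format_type", "genome_build",
    "assay_type", "biosample_term", "biosample_type", "life_stage",
    "data_source", "doi", "tissue_category", "system_category",
    "n_records", "bp_coverage", "md5", "track_description"
  )
}

#' Assemble standardized metadata for one output track
#'
#' Combines the track descriptor (MDT row), the resolved tissue/system
#' categories, the computed file statistics and the output location into
#' one metadata row. A single input file can yield several output tracks
#' (QTL splitting produces four); each gets its own row sharing the source
#' fields. Any additional MDT columns are serialized into the
#' `track_description` column as `key=value` pairs in MDT column order.
#' The table carries no timestamps or hostnames, keeping reruns
#' byte-identical; run provenance goes to the run log instead.
#'
#' @param desc An `fg_track_descriptor`.
#' @param cat Category assignment from [resolve_categories()].
#' @param stats Statistics from [compute_track_stats()].
#' @param output_path Relative output path of the track.
#' @param format_type Output format label (e.g. `"bed6plus"`).
#' @param track_id Optional override of the descriptor's track id (used for
#'   split QTL outputs).
#' @return One-row `data.table` with the columns of [metadata_columns()].
#' @export
assemble_metadata <- function(desc, cat, stats, output_path, format_type,
                              track_id = desc$track_id) {
  data.table(
    track_id = track_id,
    datatype = desc$datatype,
    output_path = output_path,
    format_type = format_type,
    genome_build = desc$genome_build,
    assay_type = desc$assay_type,
    biosample_term = desc$biosample_term,
    biosample_type = desc$biosample_type %||% NA_character_,
    life_stage = desc$life_stage %||% NA_character_,
    data_source = desc$data_source,
    doi = desc$doi %||% NA_character_,
    tissue_category = cat$tissue_category,
    system_category = cat$system_category,
    n_records = stats$n_records,
    bp_coverage = stats$bp_coverage,
    md5 = stats$md5,
    track_description = serialize_extras(desc$extra)
  )
}

#' Consolidate project-level metadata
#'
#' Writes the single project metadata table: one row per emitted output
#' track, integrated across datatypes, fixed column order, rows ordered
#' deterministically by `output_path`. Two tracks may not collide on the
#' same output path; a collision is a hard error naming both tracks.
#'
#' @param rows List of metadata rows from [assemble_metadata()] (or a
#'   `data.table` of them).
#' @param project_dir Project root; the table is written to
#'   `<project_dir>/metadata.tsv`.
#' @return Path of the written table, invisibly.
#' @export
consolidate_project <- function(rows, project_dir) {
  meta <- if (is.data.frame(rows)) as.data.table(rows) else rbindlist(rows)
  stopifnot(identical(names(meta), metadata_columns()))
  dup <- meta$output_path[duplicated(meta$output_path)]
  if (length(dup)) {
    offenders <- meta[output_path %in% dup,
      paste0(track_id, " -> ", output_path)]
    stop(
      "output path collision between tracks:\n  ",
      paste(offenders, collapse = "\n  ")
    )
  }
  setorder(meta, output_path)
  dir.create(project_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(project_dir, "metadata.tsv")
  fwrite(meta, out, sep = "\t", quote = FALSE, na = "")
  invisible(out)
}
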