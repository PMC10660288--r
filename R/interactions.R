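## Chromatin-interaction pipeline: interaction IDs, score/value, names,
## per-anchor expansion into interact-convention records.

#' Assign interaction IDs in input order
#'
#' Each interaction gets a unique 1-based ID equal to its position in the
#' input file, assigned before any sorting — an interaction appearing late
#' in the file but early on the genome keeps its high ID. Re-reading the
#' same file therefore reproduces identical IDs.
#'
#' @param rec `data.table` of interaction records in input order.
#' @return `rec` with an `interaction_id` column.
#' @export
assign_interaction_ids <- function(rec) {
  rec <- copy(rec)
  rec[, interaction_id := seq_len(.N)]
  rec[]
}

#' Compute interact-format score and value
#'
#' The interact convention carries a `score` (integer in \[0, 1000\]
#' indicating interaction strength) and a `value` (double). Missing members
#' of the pair are calculated or given null sentinels:
#' \itemize{
#'   \item when a significance column (`pvalue`) is mapped and present, it
#'     takes precedence for filling gaps: `value = -log10(p)` and
#'     `score = min(1000, round(-10 * log10(p)))`;
#'   \item otherwise a missing `value` is computed literally as
#'     `-log10(score)` for `score > 0` (null for `score = 0`);
#'   \item a missing `score` with no significance column gets the null
#'     sentinel `0`; if both are missing, `score = 0` and `value` is null.
#'   \item values present in the input are never overwritten.
#' }
#' Mapped scores outside \[0, 1000\] are clamped with a warning. Note the
#' literal `-log10(score)` reading is dimensionally odd for a 0-1000 score
#' (negative above 1); see the package vignette for why both behaviors are
#' provided and how precedence is decided.
#'
#' @param rec `data.table` with optional numeric columns `score`, `value`,
#'   `pvalue` (NA = missing).
#' @return `rec` with `score` (integer, 0 = null) and `value` (numeric,
#'   NA = null) filled.
#' @export
compute_score_value <- function(rec) {
  rec <- copy(rec)
  n <- nrow(rec)
  if (!"score" %in% names(rec)) rec[, score := NA_real_]
  if (!"value" %in% names(rec)) rec[, value := NA_real_]
  rec[, score := as.numeric(score)]
  rec[, value := as.numeric(value)]
  has_p <- if ("pvalue" %in% names(rec)) !is.na(rec$pvalue) & rec$pvalue > 0
    else rep(FALSE, n)

  rec[!is.na(score), score := as.numeric(clamp_score(score,
    context = "interaction score"))]

  miss_v <- is.na(rec$value)
  rec[miss_v & has_p, value := -log10(pvalue)]
  rec[is.na(value) & !is.na(score) & score > 0, value := -log10(score)]

  miss_s <- is.na(rec$score)
  rec[miss_s & has_p, score := pmin(1000, round(-10 * log10(pvalue)))]
  rec[is.na(score), score := 0]
  rec[, score := as.integer(score)]
  rec[]
}

#' Build human-readable interaction names
#'
#' Combines the interaction's data source, unique ID, score and value into
#' a deterministic colon-joined template
#' `"<data_source>:<id>:score=<score>:value=<value>"`, with null values
#' rendered as `"."`. Names are unique within a track whenever IDs are.
#' These names give interactions context in genome-browser displays.
#'
#' @param rec `data.table` with `interaction_id`, `score`, `value`.
#' @param data_source Project/source label from the track descriptor.
#' @return `rec` with a `name` column.
#' @export
build_interaction_name <- function(rec, data_source) {
  rec <- copy(rec)
  rec[, name := sprintf(
    "%s:%d:score=%d:value=%s",
    data_source, interaction_id, score, fmt_num(value)
  )]
  rec[]
}

## interact-convention field order written after the anchor-key columns.
interact_fields <- function() {
  c(
    "chrom", "start", "end", "name", "score", "value", "experiment",
    "color", "source_chrom", "source_start", "source_end", "source_name",
    "source_strand", "target_chrom", "target_start", "target_end",
    "target_name", "target_strand"
  )
}

#' Expand interactions into per-anchor records
#'
#' Writes each interaction on two lines — one per anchor — so that a region
#' query hitting either anchor retrieves the interaction. Line A is keyed
#' (first three columns) on the source anchor's own coordinates, line B on
#' the target anchor's; both carry the complete interact field set (name,
#' score, value, both anchors' coordinates and names, experiment, color)
#' plus an `anchor_id` column (`"<id>A"` / `"<id>B"`) and any preserved
#' passthrough columns, so the full interaction is recoverable from either
#' line. Self-interactions (both anchors on identical coordinates) are
#' allowed and counted in a warning.
#'
#' @param rec Interaction records with normalized anchors (`chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`), `interaction_id`,
#'   `score`, `value`, `name`; optional `strand1`, `strand2`, `experiment`,
#'   `color`, passthrough `pt.*` columns.
#' @return Render-ready `data.table` of `2 * nrow(rec)` anchor records:
#'   columns `chrom`, `start`, `end`, then the remaining interact fields,
#'   `anchor_id`, and passthrough.
#' @export
expand_anchors <- function(rec) {
  n <- nrow(rec)
  pt_cols <- grep("^pt\\.", names(rec), value = TRUE)
  get_or <- function(col, default) {
    if (col %in% names(rec)) {
      v <- as.character(rec[[col]])
      ifelse(is.na(v) | !nzchar(v), default, v)
    } else rep(default, n)
  }
  n_self <- sum(rec$chrom1 == rec$chrom2 & rec$start1 == rec$start2 &
    rec$end1 == rec$end2)
  if (n_self > 0) {
    fg_warn(n_self, " self-interaction(s) with identical anchors")
  }

  common <- data.table(
    name = rec$name,
    score = fmt_int(rec$score),
    value = fmt_num(rec$value),
    experiment = get_or("experiment", NA_SENTINEL),
    color = get_or("color", "0"),
    source_chrom = rec$chrom1,
    source_start = fmt_int(rec$start1),
    source_end = fmt_int(rec$end1),
    source_name = paste0(rec$interaction_id, "A"),
    source_strand = get_or("strand1", NA_SENTINEL),
    target_chrom = rec$chrom2,
    target_start = fmt_int(rec$start2),
    target_end = fmt_int(rec$end2),
    target_name = paste0(rec$interaction_id, "B"),
    target_strand = get_or("strand2", NA_SENTINEL)
  )
  for (p in pt_cols) common[[p]] <- as.character(rec[[p]])

  a <- data.table(chrom = rec$chrom1, start = rec$start1, end = rec$end1,
    common, anchor_id = paste0(rec$interaction_id, "A"))
  b <- data.table(chrom = rec$chrom2, start = rec$start2, end = rec$end2,
    common, anchor_id = paste0(rec$interaction_id, "B"))
  ## column order: anchor key, interact fields 4..18, anchor_id, passthrough
  out <- rbind(a, b)
  setcolorder(out, c(
    "chrom", "start", "end", "name", "score", "value", "experiment",
    "color", "source_chrom", "source_start", "source_end", "source_name",
    "source_strand", "target_chrom", "target_start", "target_end",
    "target_name", "target_strand", "anchor_id", pt_cols
  ))
  out
}
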