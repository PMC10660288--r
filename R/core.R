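## Type-independent harmonization steps: chromosome and coordinate
## normalization, column mapping, sorting + bgzip + tabix, output hierarchy.

#' Normalize chromosome names
#'
#' Maps the naming dialects found in the wild onto the chr-prefixed UCSC
#' convention: bare numbers gain the prefix (`"1"` -> `"chr1"`), mitochondrial
#' aliases collapse (`"MT"`, `"chrMT"` -> `"chrM"`), sex chromosomes are
#' upper-cased, prefix case is normalized, and unknown contigs simply gain a
#' `chr` prefix if absent. Idempotent: already-normalized names pass through.
#'
#' @param name Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_chrom(c("1", "chr2", "MT", "x", "ChrY"))
#' @export
normalize_chrom <- function(name) {
  name <- as.character(name)
  if (any(is.na(name) | !nzchar(trimws(name)))) {
    stop("empty chromosome name")
  }
  core <- sub("^[Cc][Hh][Rr]", "", trimws(name))
  core[toupper(core) == "MT"] <- "M"
  sex <- toupper(core) %in% c("X", "Y", "M")
  core[sex] <- toupper(core[sex])
  paste0("chr", core)
}

#' Convert genomic coordinates to 0-based half-open convention
#'
#' 1-based inclusive `(s, e)` becomes `(s - 1, e)`; 0-based input passes
#' through; a single position (no end) becomes the 1-bp interval covering
#' it. Invalid rows (start below base, end before start, missing start)
#' yield `NA` in both outputs so callers can route them to rejects rather
#' than abort the run.
#'
#' @param start Integer vector of start coordinates in the input convention.
#' @param end Integer vector of end coordinates, or `NA` for single
#'   positions.
#' @param base Coordinate base of the input: `0` or `1`.
#' @return List with integer vectors `start` and `end` (0-based half-open);
#'   `NA` marks invalid rows.
#' @examples
#' convert_coordinates(100, 200, base = 1) # (99, 200)
#' convert_coordinates(100, NA, base = 1)  # (99, 100): a SNP position
#' @export
convert_coordinates <- function(start, end = NA_integer_, base = 1L) {
  base <- as.integer(base)
  stopifnot(base %in% c(0L, 1L))
  n <- length(start)
  start <- as.integer(start)
  end <- rep_len(as.integer(end), n)
  ok <- !is.na(start) & start >= base &
    (is.na(end) | (if (base == 1L) end >= start else end > start))
  s0 <- ifelse(ok, start - base, NA_integer_)
  e0 <- ifelse(ok, ifelse(is.na(end), s0 + 1L, if (base == 1L) end else end),
    NA_integer_)
  list(start = as.integer(s0), end = as.integer(e0))
}

## Resolve one config column reference (header name or 1-based position)
## against the input column names. Returns the input column name or NA.
resolve_col_ref <- function(ref, input_names, has_header) {
  idx <- suppressWarnings(as.integer(ref))
  if (!is.na(idx)) {
    if (idx >= 1L && idx <= length(input_names)) return(input_names[idx])
    return(NA_character_)
  }
  if (!has_header) {
    stop("column reference by name ('", ref, "') requires has_header=true")
  }
  if (ref %in% input_names) return(ref)
  NA_character_
}

#' Map raw input columns onto standard fields
#'
#' Applies a file config's column map to a raw table (all columns read as
#' character), producing the standard fields in canonical output order
#' followed by the configured passthrough columns. Rows lacking a value in
#' any mapped required field are routed to a rejects table with their input
#' line number and a reason; the run continues.
#'
#' Unmapped *trailing* optional fields are omitted from the output (BED
#' `n`+ convention); a gap before a mapped later field is filled with the
#' `"."` sentinel. This makes the standard step chain a byte-level fixed
#' point on its own output under an identity config.
#'
#' @param raw A `data.table` of character columns as read from the input
#'   file (header names, or `V1..Vn` for headerless files).
#' @param config An `fg_file_config`.
#' @param datatype Datatype to map for; defaults to the config's.
#' @return List with `records` (mapped `data.table`; passthrough column
#'   names prefixed `pt.`, plus a bookkeeping `.line` column holding input
#'   file line numbers) and `rejects` (`data.table(line, reason, raw)`).
#'   Line numbers count file lines, including any header.
#' @export
map_columns <- function(raw, config, datatype = config$datatype) {
  stopifnot(inherits(config, "fg_file_config"))
  fields <- standard_fields(datatype)
  order_all <- unique(c(fields$required, fields$optional))
  cmap <- config$column_map

  src <- vapply(names(cmap), resolve_col_ref, character(1),
    input_names = names(raw), has_header = config$has_header)
  if (anyNA(src)) {
    stop(
      "config maps input column(s) absent from the file: ",
      paste(names(cmap)[is.na(src)], collapse = ", ")
    )
  }
  mapped_fields <- unname(cmap)

  ## standard fields present, in canonical order; trailing unmapped
  ## optionals dropped, interior gaps sentinel-filled
  present <- order_all %in% mapped_fields
  keep_upto <- max(c(0L, which(present)))
  out_fields <- order_all[seq_len(keep_upto)]
  ## required fields always kept even if canonical order puts them late
  out_fields <- union(out_fields, intersect(order_all, mapped_fields))
  out_fields <- order_all[order_all %in% out_fields]

  line_offset <- if (config$has_header) 1L else 0L
  records <- data.table(.line = seq_len(nrow(raw)) + line_offset)
  for (f in out_fields) {
    if (f %in% mapped_fields) {
      records[[f]] <- raw[[src[match(f, mapped_fields)]]]
    } else {
      records[[f]] <- rep(NA_SENTINEL, nrow(raw))
    }
  }

  ## passthrough columns
  pt <- config$passthrough_columns
  if (length(pt) == 1L && identical(pt, "*")) {
    pt_src <- setdiff(names(raw), src)
  } else if (length(pt)) {
    pt_src <- vapply(pt, resolve_col_ref, character(1),
      input_names = names(raw), has_header = config$has_header)
    if (anyNA(pt_src)) {
      stop(
        "passthrough column(s) absent from the file: ",
        paste(pt[is.na(pt_src)], collapse = ", ")
      )
    }
  } else {
    pt_src <- character(0)
  }
  for (p in pt_src) records[[paste0("pt.", p)]] <- raw[[p]]

  ## reject rows with missing values in mapped required fields (short rows
  ## read with fill=TRUE surface as NA)
  req_here <- intersect(c(
    fields$required,
    if (datatype == "qtl") intersect(c("pos", "start"), mapped_fields)
  ), out_fields)
  bad <- rep(FALSE, nrow(records))
  for (f in req_here) {
    v <- records[[f]]
    bad <- bad | is.na(v) | !nzchar(v) | v == NA_SENTINEL
  }
  rejects <- data.table(
    line = records$.line[bad],
    reason = rep("missing value in required mapped field", sum(bad)),
    raw = if (any(bad)) do.call(paste, c(as.list(raw[bad]), sep = config$delimiter)) else character(0)
  )
  records <- records[!bad]
  list(records = records, rejects = rejects)
}

## Deterministic total order used for every output track:
## chrom lexicographic (C locale) on normalized names, then start, then end,
## then the full rendered line as tie-break (duplicates stay adjacent,
## re-sorting is stable).
order_track_lines <- function(chrom, start, end, lines) {
  order(chrom, start, end, lines, method = "radix")
}

#' Sort, compress and index a harmonized track
#'
#' Renders a table of harmonized records to BED-convention text, sorts it
#' with a deterministic total order (chromosome lexicographic on normalized
#' names, then start, end, full line), writes a bgzip-compressed copy and a
#' tabix index. An empty record set yields a valid (indexed) empty track
#' with a warning.
#'
#' @param records A render-ready `data.table`: columns `chrom` (character,
#'   normalized), `start`, `end` (integer, 0-based half-open), then any
#'   further columns already rendered as character.
#' @param out_path Output path for the compressed track; `.gz` appended if
#'   absent.
#' @return An `fg_track` object: paths, record count, and the md5 of the
#'   uncompressed payload.
#' @export
sort_compress_index <- function(records, out_path) {
  if (!grepl("\\.gz$", out_path)) out_path <- paste0(out_path, ".gz")
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

  if (nrow(records) == 0L) {
    fg_warn("writing empty track: ", out_path)
    lines <- character(0)
  } else {
    stopifnot(identical(names(records)[1:3], c("chrom", "start", "end")))
    render <- records
    render[["start"]] <- fmt_int(records[["start"]])
    render[["end"]] <- fmt_int(records[["end"]])
    lines <- do.call(paste, c(as.list(render), sep = "\t"))
    ord <- order_track_lines(records$chrom, records$start, records$end, lines)
    lines <- lines[ord]
  }
  plain <- sub("\\.gz$", "", out_path)
  writeLines(lines, plain)
  md5 <- unname(md5sum(plain))
  bgzip(plain, dest = out_path, overwrite = TRUE)
  unlink(plain)
  idx <- indexTabix(out_path, seq = 1L, start = 2L, end = 3L,
    zeroBased = TRUE)
  track <- list(
    data_path = out_path, index_path = idx,
    n_records = length(lines), sorted = TRUE, md5 = md5
  )
  class(track) <- "fg_track"
  track
}

#' @export
print.fg_track <- function(x, ...) {
  cat(sprintf(
    "<fg_track> %s\n  records: %d  sorted: %s  md5(payload): %s\n",
    x$data_path, x$n_records, x$sorted, x$md5
  ))
  invisible(x)
}

## Accept either an fg_track or a path to a .gz track.
track_path <- function(track) {
  if (inherits(track, "fg_track")) track$data_path else track
}

#' Read a track's records
#'
#' @param track An `fg_track` or path to a bgzipped track file.
#' @return `data.table` of character columns (no header in track files), or
#'   an empty `data.table` for empty tracks.
#' @export
read_track <- function(track) {
  lines <- read_lines_maybe_gz(track_path(track))
  if (length(lines) == 0L) return(data.table())
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = FALSE,
    colClasses = "character", quote = "")
}

#' Region query on an indexed track
#'
#' Returns the track lines overlapping `[start, end)` (0-based half-open)
#' on `chrom`, via the tabix index. Chromosomes absent from the index
#' (including queries on empty tracks) return zero lines rather than
#' erroring.
#'
#' @param track An `fg_track` or path to a bgzipped, tabix-indexed track.
#' @param chrom Chromosome name (normalized automatically).
#' @param start,end 0-based half-open query interval.
#' @return Character vector of matching lines (possibly empty).
#' @export
query_track <- function(track, chrom, start, end) {
  path <- track_path(track)
  chrom <- normalize_chrom(chrom)
  seqs <- headerTabix(path)$seqnames
  if (!chrom %in% seqs) return(character(0))
  param <- GRanges(chrom, IRanges(start + 1L, end))
  unname(unlist(scanTabix(path, param = param), use.names = FALSE))
}

#' Build the output-hierarchy path for a track
#'
#' Output files are placed in a fixed folder hierarchy, applicable
#' components only, in the order: association significance tier (QTLs
#' only), variant type (QTLs only), assay type, output format type, genome
#' build, file name. E.g. significant SNP eQTLs from an RNA-seq study on
#' GRCh38 land under `FDR0.05/SNP/RNA-seq/<format>/GRCh38/<track_id>.bed.gz`,
#' while interval tracks omit the first two components.
#'
#' @param track_id Track identifier (becomes the file stem).
#' @param datatype Datatype (affects no component directly; tiers are
#'   passed explicitly).
#' @param assay_type Assay label, e.g. `"ChIP-seq"`, `"RNA-seq"`, `"Hi-C"`.
#' @param genome_build Genome build in any accepted spelling.
#' @param format_type Output format label, e.g. `"bed6plus"`, `"bed19"`,
#'   `"bedInteract"`; used verbatim.
#' @param significance_tier Optional tier label, e.g. `"FDR0.05"`.
#' @param variant_type Optional `"SNP"` or `"INDEL"`.
#' @return Relative path (character).
#' @examples
#' build_output_path("trk1", "qtl", "RNA-seq", "hg38", "bed19",
#'   significance_tier = "FDR0.05", variant_type = "SNP")
#' @export
build_output_path <- function(track_id, datatype, assay_type, genome_build,
                              format_type, significance_tier = NULL,
                              variant_type = NULL) {
  comps <- c(
    significance_tier, variant_type, assay_type, format_type,
    genome_build_dir(genome_build), paste0(track_id, ".bed.gz")
  )
  comps <- gsub("[^A-Za-z0-9._+-]", "_", comps)
  do.call(file.path, as.list(comps))
}

#' Clamp BED scores into [0, 1000]
#'
#' @param score Numeric vector (NA allowed).
#' @param context Label used in the warning.
#' @return Integer vector clamped to the BED score range; a single warning
#'   reports how many values were clamped.
#' @export
clamp_score <- function(score, context = "score") {
  out_of_range <- sum(!is.na(score) & (score < 0 | score > 1000))
  if (out_of_range > 0) {
    fg_warn(
      out_of_range, " ", context,
      " value(s) outside [0, 1000] were clamped"
    )
  }
  as.integer(round(pmin(pmax(score, 0), 1000)))
}

## Standard-step preparation shared by all datatypes: map columns, normalize
## chromosome names, convert coordinates to 0-based half-open. Returns
## records with integer `start`/`end` columns (canonical names, also for the
## qtl single-position case and both interaction anchors) plus the
## accumulated rejects table. Records keep their `.line` bookkeeping column.
prepare_records <- function(raw, config, datatype = config$datatype) {
  m <- map_columns(raw, config, datatype)
  rec <- m$records
  rejects <- m$rejects
  if (nrow(rec) == 0L) return(list(records = rec, rejects = rejects))

  drop_bad <- function(rec, rejects, bad, reason) {
    if (any(bad)) {
      rejects <- rbind(rejects, data.table(
        line = rec$.line[bad],
        reason = rep(reason, sum(bad)),
        raw = do.call(paste, c(as.list(rec[bad, !".line"]), sep = "\t"))
      ))
    }
    list(rec = rec[!bad], rejects = rejects)
  }

  if (datatype == "interactions") {
    rec[, chrom1 := normalize_chrom(chrom1)]
    rec[, chrom2 := normalize_chrom(chrom2)]
    bad <- rep(FALSE, nrow(rec))
    for (a in c("1", "2")) {
      conv <- convert_coordinates(
        parse_int(rec[[paste0("start", a)]]),
        parse_int(rec[[paste0("end", a)]]),
        base = config$coordinate_base
      )
      rec[[paste0("start", a)]] <- conv$start
      rec[[paste0("end", a)]] <- conv$end
      bad <- bad | is.na(conv$start)
    }
    res <- drop_bad(rec, rejects, bad, "invalid coordinates")
    return(list(records = res$rec, rejects = res$rejects))
  }

  rec[, chrom := normalize_chrom(chrom)]
  mapped <- unname(config$column_map)
  if (datatype == "qtl" && "pos" %in% mapped) {
    s_in <- parse_int(rec$pos)
    e_in <- rep(NA_integer_, nrow(rec))
    rec[, pos := NULL]
  } else {
    s_in <- parse_int(rec$start)
    e_in <- if ("end" %in% names(rec)) parse_int(rec$end) else
      rep(NA_integer_, nrow(rec))
  }
  conv <- convert_coordinates(s_in, e_in, base = config$coordinate_base)
  rec[, start := conv$start]
  rec[, end := conv$end]
  res <- drop_bad(rec, rejects, is.na(conv$start), "invalid coordinates")
  list(records = res$rec, rejects = res$rejects)
}
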