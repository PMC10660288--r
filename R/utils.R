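## Internal helpers shared across modules.

## BED missing-value sentinel.
NA_SENTINEL <- "."

`%||%` <- function(a, b) if (is.null(a)) b else a

## Render a double for track output. Fixed %.6g so that re-rendering a
## parsed value reproduces the same bytes (needed for idempotence and
## dialect-equivalence guarantees). NA -> "." sentinel.
fmt_num <- function(x) {
  out <- rep(NA_SENTINEL, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.6g", x[ok])
  out
}

## Render an integer-valued vector without scientific notation.
fmt_int <- function(x) {
  out <- rep(NA_SENTINEL, length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], scientific = FALSE, trim = TRUE)
  out
}

## Parse a character column to numeric, "." and "" treated as missing.
parse_num <- function(x) {
  x[x %in% c(NA_SENTINEL, "", "NA", "nan", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

parse_int <- function(x) {
  x[x %in% c(NA_SENTINEL, "", "NA")] <- NA_character_
  suppressWarnings(as.integer(as.numeric(x)))
}

## Package-level logging: messages to stderr, optionally copied to a file.
fg_log <- function(..., file = NULL) {
  msg <- paste0("[fgharmonize] ", ...)
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}

fg_warn <- function(...) warning(paste0(...), call. = FALSE)

## Canonical genome-build labels; the two supported builds only.
normalize_genome_build <- function(x) {
  key <- tolower(trimws(x))
  out <- ifelse(key %in% c("grch38", "hg38", "grch38/hg38", "grch38.p14"),
    "GRCh38/hg38",
    ifelse(key %in% c("grch37", "hg19", "grch37/hg19"), "GRCh37/hg19",
      NA_character_
    )
  )
  if (anyNA(out)) {
    stop(
      "unsupported genome_build value(s): ",
      paste(unique(x[is.na(out)]), collapse = ", "),
      " (supported: GRCh37/hg19, GRCh38/hg38)"
    )
  }
  out
}

## Directory component of a canonical build label: "GRCh38/hg38" -> "GRCh38".
genome_build_dir <- function(x) sub("/.*$", "", normalize_genome_build(x))

## md5 of a character vector of lines, as if written with trailing newlines.
md5_of_lines <- function(lines) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(md5sum(tmp))
}

## Read the uncompressed payload of a (possibly bgzipped) text file.
read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}
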