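## Shared helpers: independent oracles and tiny fixture builders used
## across the suite.

## Independent Benjamini-Hochberg step-up oracle, coded from the
## definition: adj_i = min_{j >= rank(i)} p_(j) * m / j, clamped at 1.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Linear-scan overlap oracle over a track's uncompressed lines:
## 0-based half-open interval overlap on the first three columns.
overlap_scan_oracle <- function(lines, chrom, start, end) {
  if (length(lines) == 0L) return(character(0))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ch <- vapply(f, `[`, character(1), 1L)
  s <- as.integer(vapply(f, `[`, character(1), 2L))
  e <- as.integer(vapply(f, `[`, character(1), 3L))
  lines[ch == chrom & s < end & e > start]
}

## Brute-force per-base coverage oracle: enumerate covered bases as a set.
coverage_enum_oracle <- function(chrom, start, end) {
  keys <- unlist(lapply(seq_along(chrom), function(i) {
    if (end[i] <= start[i]) return(character(0))
    paste0(chrom[i], ":", seq(start[i], end[i] - 1L))
  }))
  length(unique(keys))
}

## Write a throwaway file config and parse it.
make_config <- function(lines, datatype) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  parse_file_config(path, datatype)
}

## Read a track's uncompressed payload lines.
track_lines <- function(path) {
  con <- gzfile(if (is.character(path)) path else path$data_path, "rt")
  on.exit(close(con))
  readLines(con)
}

## Cut track lines down to their first k tab-separated fields.
cut_fields <- function(lines, k) {
  vapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    paste(x[seq_len(k)], collapse = "\t")
  }, character(1))
}

## A minimal valid MDT on disk referencing existing files.
write_test_mdt <- function(path, rows) {
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "")
  path
}
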