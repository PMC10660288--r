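---
title: "Harmonizing heterogeneous functional-genomics tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous functional-genomics tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgharmonize)
library(data.table)
```

## The problem

Functional-genomics (FG) data — epigenetic peak calls, QTL summary
statistics, chromatin-interaction calls — arrive as delimited text in
incompatible dialects: different delimiters, with or without header rows,
0- or 1-based coordinates, bare (`1`) or prefixed (`chr1`) chromosome
names, and arbitrary column sets and orders. The same eQTL release may
circulate in a minimal nine-column table and a reprocessed nineteen-column
one. None of these are directly usable by coordinate-indexed query tools.

`fgharmonize` converts such files into sorted, bgzip-compressed,
tabix-indexed tracks in the BED convention (0-based, half-open, tab
separated), driven entirely by two small text inputs:

* the **minimal descriptions table (MDT)** — one row of biological, source
  and file information per input file; and
* a **file config** per input file type — an input-column to
  standard-field map plus dialect attributes (delimiter, header,
  coordinate base).

From the MDT the driver generates one inspectable pipeline plan per file
(`generate_plans()`), runs the plans (`execute_plans()`), and consolidates
one project-level metadata table.

## Type-independent standard steps

Every datatype passes through the same chain: column mapping
(`map_columns()`), chromosome-name normalization (`normalize_chrom()`:
`1 → chr1`, `MT/chrMT → chrM`, prefix case fixed, unknown contigs gain the
prefix), coordinate conversion (`convert_coordinates()`: 1-based inclusive
`(s, e) → (s−1, e)`; a bare position becomes the covering 1-bp interval),
then sorting, compression and indexing (`sort_compress_index()`).

Numerical and ordering choices worth stating explicitly:

* **Sort order** is a deterministic total order: chromosome
  *lexicographic* on normalized names (the tabix convention; `chr10`
  before `chr2`), then start, then end, then the full rendered line as a
  tie-break. Duplicate records are retained and end up adjacent, and
  re-sorting sorted output is a no-op.
* **Missing values** are rendered as the BED `"."` sentinel. For interval
  tracks, *trailing* unmapped optional fields are omitted entirely
  (BED3+/BED6+ style) rather than sentinel-filled; only interior gaps are
  filled. This is what makes the standard chain *idempotent*: running it
  on its own output under an identity config reproduces the bytes
  exactly, a property the test suite checks on every emitted track.
* **Floating-point rendering** uses a fixed `%.6g` format everywhere, so a
  value that round-trips through parse-and-render is byte-stable. This is
  load-bearing for both idempotence and the dialect-equivalence guarantee.
* **BED scores** are clamped into `[0, 1000]` with a warning counting the
  clamped values.
* **Malformed rows** (short rows, invalid coordinates, unparseable effect
  sizes, out-of-range p-values, unresolvable alleles) never abort a run:
  each goes to a per-track `rejects/` sidecar with its input line number
  and a reason, and the conservation identity
  `accepted + rejected = input rows` holds exactly.
* **Empty inputs** are legitimate: a zero-record dataset yields valid,
  indexed, empty tracks and a metadata row with `n_records = 0`.

Outputs land in a fixed folder hierarchy, applicable components only:
significance tier / variant type (QTLs only) / assay type / format type /
genome build / file. The genome build is metadata only — there is no
liftover.

## QTL normalization

QTL records carry alleles and allele-oriented statistics, so reformatting
alone is not enough; records must agree on *which* allele the effect is
expressed on.

**Allele harmonization** (`harmonize_alleles()`) compares each record's
`(ref, alt)` pair against a variant reference at its coordinates:

* matching orientation → unchanged (`match`);
* swapped orientation → alleles exchanged, `beta := −beta`,
  `alt_allele_freq := 1 − alt_allele_freq` (`flipped`);
* position absent from the variant table, but one stated allele equal to
  the genome bases at the coordinates → that allele becomes the
  reference, statistics flipped if needed (`genome_resolved`);
* otherwise `unresolved`, routed to rejects.

The transform is an involution — applying it twice restores the original —
and conserves `|beta|` and the p-value; only the effect sign and the
frequency complement change. Standard errors cannot change under a pure
allele swap and are left untouched. Design choices where conventions had
to be fixed:

* Effect statistics are normalized to the **alternate allele**
  (`effect_allele == alt` after harmonization), the prevailing convention
  in eQTL releases. If an input maps an `effect_allele` column naming the
  reference allele, the record is first re-expressed on the alternate.
* Multi-allelic reference sites match if the record's alternate equals
  *any* listed alternate, and the rsID comes from that site.
* Strand-ambiguous palindromic pairs (A/T, C/G) are resolved by position
  and allele match only; no frequency-based disambiguation is attempted.
  Their count is logged so users can audit it.
* Variant type is classified from allele lengths (both length 1 → SNP,
  otherwise INDEL).
* INDEL lookups join on `(chrom, start)` rather than `(chrom, start,
  end)`, because a swapped INDEL's stated reference length (and hence its
  end) differs from the true site's; the end coordinate is recomputed from
  the harmonized reference allele.

**rsID assignment** uses the harmonized orientation; records resolved only
via the genome fallback keep their input identifier verbatim.
**Target annotation** fills gene symbol, strand and a signed TSS distance;
the sign convention is positive when the variant lies downstream of the
TSS in the transcription direction (`pos − tss` on `+`, `tss − pos` on
`−`). **FDR correction** applies Benjamini–Hochberg per
`(target gene, tissue)` group — via `stats::p.adjust(method = "BH")`, with
an independently hand-coded step-up oracle in the tests — only to records
that arrive without an FDR; provided FDR values are trusted. Finally,
records are split into four tracks: full and significant (strictly
`fdr < 0.05` by default) for each of SNP and INDEL, all four emitted even
when empty. Splitting by type before tier (or vice versa) is
observationally equivalent; type-then-tier is used.

The variant reference is an abstract contract — a table keyed by
position with rsID, reference and alternates, plus indexed FASTA access.
The bundled test backend is a small bgzip+tabix TSV and a toy FASTA; a
dbSNP-scale tabix-backed table is an interchangeable implementation.

## Chromatin interactions

Interaction tables become UCSC interact-convention records with one line
*per anchor*, so a region query hitting either end retrieves the
interaction. IDs are assigned by original file appearance (1..N, before
any sorting); each interaction emits an `A` (source-keyed) and `B`
(target-keyed) line carrying the complete field set, so either line alone
recovers both anchors. After sorting, the two lines of a pair may be far
apart; pairing is by ID, never adjacency.

The interact `score` (integer, 0–1000) and `value` (double) are filled
when absent. The stated closed form for a missing value, `−log10(score)`,
is dimensionally odd for a 0–1000 score — it is negative for any score
above 1 — but it is implemented literally as stated. Because the more
plausible reading is a significance transform, a column mapped as
`pvalue` takes precedence when present: `value = −log10(p)` and a missing
score is derived as `min(1000, round(−10·log10(p)))`. Both behaviors are
intentional and documented here; neither is presented as the only
defensible reading. Null sentinels are `0` for score and `"."` for value.
Names follow the fixed template
`<data_source>:<id>:score=<s>:value=<v>` — content was prescribed, the
colon-joined format is this package's choice.

## Metadata

Each output track gets one metadata row: the MDT fields, standardized
tissue/system categories from a bundled controlled vocabulary
(case-insensitive exact lookup; unknown terms degrade to
`uncategorized` with a warning rather than failing a batch), the output
path, and three computed file statistics — record count, base-pair
coverage (size of the union of `[start, end)` intervals, overlaps counted
once, computed with `IRanges::reduce()`), and the md5 of the
*uncompressed* payload, so recompression can never change a track's
identity. Extra MDT columns are serialized into a `track_description`
column as `key=value;…` pairs. The project table is ordered by output
path and contains no timestamps or hostnames — reruns are byte-identical;
run provenance goes to a separate `run.log`.

## Execution modes

Plans run `sequential`, `threaded`/`by_file` (parallel across input
files via forked workers), or `by_chromosome` (a file's records
partitioned by normalized chromosome, row-local steps run per partition,
partitions merged back into input order before anything order- or
group-sensitive). All modes produce byte-identical artifacts; the suite
compares digests across all four. One deliberate constraint: per-group
FDR is always computed *after* the chromosome merge, because a gene's
variants may span chromosomes (trans-QTLs) and per-partition correction
would change the group sizes. Failures are isolated per track — outputs
are staged in a temporary directory and moved into place only on success —
so one bad file cannot corrupt or block its siblings, and the run report
carries a nonzero exit status if anything failed.

## The synthetic-fixture module

All tests run on generated inputs with recorded ground truth
(`gen_reference()`, `gen_qtl_dataset()`, `gen_intervals()`,
`gen_interactions()`, `gen_project()`); the same seed reproduces
byte-identical fixtures. The generators emulate:

* a toy two-chromosome genome (10 kb per chromosome) with a variant table
  whose reference alleles provably equal the genome bases, including
  multi-allelic sites, insertions and deletions;
* the same associations rendered in two dialects (wide: tab, header,
  1-based position, chr-prefixed, extra columns; compact: comma,
  headerless, 0-based, bare chromosomes);
* planted allele flips (default 30% of records) and variants absent from
  the variant table but consistent with the genome (default 1%),
  exercising the fallback path;
* effect sizes drawn from a normal distribution and p-values from a
  null-uniform/signal mixture, so the significance split is non-trivial
  at the 0.05 default;
* interval scores partly outside `[0, 1000]` and shuffled, mixed-style
  chromosome names; interactions with score-only, p-value-only and fully
  null significance patterns, at least one self-interaction and one
  inter-chromosomal pair.

What the fixtures do **not** emulate: real genome scale (contig count,
chromosome length, variant density), strand-flip errors requiring
reverse-complement reasoning, realistic LD or frequency structure, or the
content of any real release. A passing suite therefore demonstrates the
engine's correctness properties (orientation recovery, index/query
agreement, conservation, determinism) — not distributional realism.

## Problem sizes and tolerances

The test suite checks dialect equivalence on 1000 associations; BH
correction against the oracle on 200 random gene–tissue groups (agreement
to 1e-12, plus monotonicity and `fdr ≥ p`); orientation recovery on 1000
records with the planted fractions above (100% resolution, exact beta
equality); index correctness on 40 random region queries per track across
all datatypes against a linear-scan oracle; and cross-mode determinism by
digest. The run-time scaling property (log–log slope of wall time vs
input size ≤ 1.3) is measured in the test suite at 5k/20k/80k rows, and
in `scripts/acceptance.R` at 10k/100k/1M rows; the smaller test sizes
keep the default suite fast while spanning a 16-fold range.

## Known limitations

* Flat vocabulary lookup only — no ontology-graph reasoning; unknown
  biosample terms become `uncategorized`.
* No liftover; the genome build is carried as metadata.
* No remote inputs; files must be local.
* The dbSNP- and gene-model-scale backends are out of scope; the
  contracts are pluggable and only toy backends ship with the package.
* Giggle-style collection indexing is external; the package only arranges
  outputs in an indexable hierarchy.
* Chromosome-split parallelism cannot parallelize the FDR step (see
  above); for QTL-heavy projects `by_file` parallelism is the effective
  mode.
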