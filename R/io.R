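# I/O for the standard formats the pipeline consumes. External dialects
# (1-based FASTA-land coordinates, narrowPeak columns) are converted to the
# package's 0-based half-open convention here and nowhere else.

#' Read a FASTA genome
#'
#' Sequences are uppercased on input; record order is preserved. The record
#' name is the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  if (file.size(path) == 0) {
    abort(sprintf("FASTA file is empty: %s", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("FASTA file contains no records: %s", path))
  }
  nm <- sub("\\s.*$", "", names(set))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA header: %s", dup[1]))
  }
  tibble(name = nm, sequence = unname(toupper(as.character(set))))
}

#' Write a genome table to FASTA
#'
#' @param genome Data frame with columns `name` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  stopifnot(all(c("name", "sequence") %in% names(genome)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(genome))) {
    writeLines(paste0(">", genome$name[i]), con)
    s <- genome$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A tibble with columns `name` and `sequence` (uppercase).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTQ file not found: %s", path))
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(
    name = sub("\\s.*$", "", names(set)),
    sequence = unname(toupper(as.character(set)))
  )
}

write_fastq <- function(reads, path) {
  stopifnot(all(c("name", "sequence") %in% names(reads)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(
      paste0("@", reads$name[i]),
      reads$sequence[i],
      "+",
      strrep("I", nchar(reads$sequence[i]))
    ), con)
  }
  invisible(path)
}

narrowpeak_cols <- c(
  "chrom", "start", "end", "name", "score", "strand",
  "signal_value", "p_log10", "q_log10", "summit_offset"
)

parse_coord <- function(x, path, lines, what) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: non-integer %s coordinate at line %d: '%s'",
      path, what, lines[bad[1]], x[bad[1]]
    ))
  }
  as.integer(v)
}

#' Read peaks or intervals from BED6 / narrowPeak
#'
#' BED is consumed as 0-based half-open; a missing strand column becomes
#' `"."`. For narrowPeak (the ENCODE 10-column dialect), column 5 is the
#' integer peak score, column 7 the signal value, columns 8/9 the -log10
#' p/q values (-1 encodes missing and is read as `NA`) and column 10 the
#' summit offset from the peak start (-1 for no summit).
#'
#' @param path Path to a tab-separated BED file.
#' @param kind `"bed6"` (3 to 6 columns) or `"narrowPeak"` (exactly 10).
#' @return A tibble of intervals; narrowPeak adds `signal_value`, `p_log10`,
#'   `q_log10` and `summit_offset` columns.
#' @export
read_bed <- function(path, kind = c("bed6", "narrowPeak")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path))
  }
  raw <- readLines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(raw)
  raw <- raw[keep]
  lines <- which(keep)
  if (length(raw) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = numeric(), strand = character()
    )
    if (kind == "narrowPeak") {
      out$signal_value <- numeric()
      out$p_log10 <- numeric()
      out$q_log10 <- numeric()
      out$summit_offset <- integer()
    }
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  need <- if (kind == "bed6") 3L else 10L
  bad <- which(ncol < need | (kind == "narrowPeak" & ncol != 10L))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: expected %s columns but found %d at line %d",
      path, if (kind == "bed6") ">= 3" else "exactly 10", ncol[bad[1]], lines[bad[1]]
    ))
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- parse_coord(col(2), path, lines, "start")
  end <- parse_coord(col(3), path, lines, "end")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: start >= end at line %d ([%d, %d))",
      path, lines[bad[1]], start[bad[1]], end[bad[1]]
    ))
  }
  strand <- col(6)
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  score_chr <- col(5)
  out <- tibble(
    chrom = col(1),
    start = start,
    end = end,
    name = col(4),
    score = suppressWarnings(as.numeric(score_chr)),
    strand = strand
  )
  if (kind == "narrowPeak") {
    na_if_neg1 <- function(v) ifelse(v == -1, NA_real_, v)
    out$signal_value <- suppressWarnings(as.numeric(col(7)))
    out$p_log10 <- na_if_neg1(suppressWarnings(as.numeric(col(8))))
    out$q_log10 <- na_if_neg1(suppressWarnings(as.numeric(col(9))))
    out$summit_offset <- parse_coord(col(10), path, lines, "summit")
    bad <- which(out$summit_offset != -1L &
      (out$summit_offset < 0L | out$summit_offset >= out$end - out$start))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: summit offset outside peak at line %d", path, lines[bad[1]]
      ))
    }
  }
  out
}

#' Write intervals to BED6 or narrowPeak
#'
#' The dialect is chosen from the columns present: a `summit_offset` column
#' selects narrowPeak, otherwise BED6 (missing name/score/strand filled with
#' `.`/`0`/`.`). Writing then reading back reproduces every field the format
#' represents.
#'
#' @param x Data frame of intervals.
#' @param path Output path.
#' @param kind `"auto"`, `"bed6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, kind = c("auto", "bed6", "narrowPeak")) {
  kind <- match.arg(kind)
  validate_intervals(x)
  if (kind == "auto") {
    kind <- if ("summit_offset" %in% names(x)) "narrowPeak" else "bed6"
  }
  get_col <- function(nm, default) {
    v <- if (nm %in% names(x)) x[[nm]] else rep(default, nrow(x))
    v[is.na(v)] <- default
    v
  }
  name <- get_col("name", ".")
  score <- get_col("score", 0)
  strand <- get_col("strand", ".")
  lines <- if (kind == "bed6") {
    sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s",
      x$chrom, as.integer(x$start), as.integer(x$end),
      name, format(score, trim = TRUE, scientific = FALSE), strand
    )
  } else {
    sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
      x$chrom, as.integer(x$start), as.integer(x$end),
      name, as.integer(score), strand,
      format(get_col("signal_value", 0), trim = TRUE, scientific = FALSE),
      format(get_col("p_log10", -1), trim = TRUE, scientific = FALSE),
      format(get_col("q_log10", -1), trim = TRUE, scientific = FALSE),
      as.integer(get_col("summit_offset", -1))
    )
  }
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) abort(sprintf("cannot write BED file: %s", path))
  invisible(path)
}

#' Write a binned signal track to bedGraph
#'
#' One line per bin by default, so that [read_bedgraph()] recovers the bins
#' exactly; `drop_zero = TRUE` omits zero-valued bins (the usual compression
#' for sparse tracks).
#'
#' @param track A `binned_track` (or any interval data frame with a `value`
#'   column).
#' @param path Output path.
#' @param drop_zero Omit zero-valued bins?
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  stopifnot("value" %in% names(track))
  validate_intervals(track, arg = "track")
  x <- track
  if (drop_zero) x <- x[x$value != 0, , drop = FALSE]
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    x$chrom, as.integer(x$start), as.integer(x$end),
    format(x$value, trim = TRUE, scientific = FALSE)
  )
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) abort(sprintf("cannot write bedGraph file: %s", path))
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("bedGraph file not found: %s", path))
  }
  raw <- readLines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(raw)
  raw <- raw[keep]
  lines <- which(keep)
  if (length(raw) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), value = numeric()
    ))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    abort(sprintf(
      "%s: bedGraph needs 4 columns (line %d)",
      path, lines[which(lengths(fields) < 4)[1]]
    ))
  }
  tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = parse_coord(vapply(fields, `[`, character(1), 2), path, lines, "start"),
    end = parse_coord(vapply(fields, `[`, character(1), 3), path, lines, "end"),
    value = as.numeric(vapply(fields, `[`, character(1), 4))
  )
}

#' Remove intervals overlapping a blacklist
#'
#' Keeps the intervals with zero base pairs of overlap with any blacklist
#' region (half-open abutment is not overlap); input order is preserved.
#'
#' @param x Data frame of intervals.
#' @param blacklist Data frame of blacklist regions.
#' @return The retained rows of `x`.
#' @export
filter_blacklist <- function(x, blacklist) {
  validate_intervals(x)
  validate_intervals(blacklist, arg = "blacklist")
  if (nrow(x) == 0 || nrow(blacklist) == 0) {
    return(as_tibble(x))
  }
  lv <- union(unique(x$chrom), unique(blacklist$chrom))
  hit <- IRanges::overlapsAny(
    as_gr(x, levels = lv), as_gr(blacklist, levels = lv),
    ignore.strand = TRUE
  )
  as_tibble(x[!hit, , drop = FALSE])
}

#' Read fragment placements from a BED file
#'
#' Fragments are the unit of all coverage, FriP and spike-in computations:
#' strandless placements of sequenced (deduplicated) molecules.
#'
#' @param path Path to a >= 3 column BED file.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path) {
  read_bed(path, kind = "bed6")[, c("chrom", "start", "end")]
}

#' Fragment placements from aligned proper pairs (SAM/BAM adapter)
#'
#' Optional adapter for alignment output: each properly paired alignment
#' with a positive template length contributes one fragment
#' `[pos - 1, pos - 1 + TLEN)`. Plain-text SAM is converted on the fly.
#'
#' @param path Path to a SAM or BAM file with paired-end alignments.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_fragments_sam <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("SAM/BAM file not found: %s", path))
  }
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest, overwrite = TRUE))
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$isize) & res$isize > 0 & !is.na(res$pos)
  tibble(
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + res$isize[keep]
  )
}
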