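# Shared interval helpers. All coordinates in the package are 0-based
# half-open (BED native); conversion to the 1-based closed convention of
# GenomicRanges happens only inside as_gr()/gr_tbl().

interval_cols <- c("chrom", "start", "end")

validate_intervals <- function(x, arg = "x", chrom_sizes = NULL) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing_cols <- setdiff(interval_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) {
    return(invisible(x))
  }
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(sprintf("`%s`: start/end must be numeric", arg))
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s`: invalid interval at row %d (need 0 <= start < end, got [%s, %s))",
      arg, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
    ))
  }
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(sprintf(
        "`%s`: chromosome(s) not in chrom_sizes: %s",
        arg, paste(unknown, collapse = ", ")
      ))
    }
    over <- which(x$end > sizes[x$chrom])
    if (length(over) > 0) {
      abort(sprintf(
        "`%s`: interval at row %d extends beyond its chromosome", arg, over[1]
      ))
    }
  }
  invisible(x)
}

# Named numeric vector of chromosome lengths from any accepted
# representation (named vector, or a data frame with chrom/size columns).
as_chrom_sizes <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(x)
  }
  if (is.data.frame(x)) {
    size_col <- intersect(c("size", "length", "seqlength"), names(x))[1]
    if (!is.na(size_col) && "chrom" %in% names(x)) {
      return(setNames(x[[size_col]], x$chrom))
    }
  }
  abort("chrom_sizes must be a named numeric vector or a data frame with columns chrom and size")
}

#' Chromosome sizes of a genome table
#'
#' @param genome A data frame with columns `name` and `sequence`, as returned
#'   by [read_fasta()] or [make_genome()].
#' @return A tibble with columns `chrom` and `size`.
#' @export
chrom_sizes <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("name", "sequence") %in% names(genome)))
  tibble(chrom = genome$name, size = nchar(genome$sequence))
}

as_gr <- function(x, chrom_sizes = NULL, levels = NULL) {
  seqlengths <- NULL
  seqnames_levels <- levels
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    seqlengths <- sizes
    seqnames_levels <- names(sizes)
  }
  if (nrow(x) == 0) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
    return(gr)
  }
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqnames_levels %||% unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

gr_tbl <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer()
    ))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into their base-pair union (adjacent
#' intervals that merely abut in half-open coordinates are also merged,
#' matching `bedtools merge` defaults).
#'
#' @param x Data frame of intervals (`chrom`, `start`, `end`).
#' @return Tibble of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  gr_tbl(GenomicRanges::reduce(as_gr(x)))
}

total_width <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# number of rows of `x` overlapping >= 1 bp of `y`
n_overlapping <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  lv <- union(unique(x$chrom), unique(y$chrom))
  sum(IRanges::overlapsAny(
    as_gr(x, levels = lv), as_gr(y, levels = lv),
    ignore.strand = TRUE
  ))
}

# count of [as, ae) intervals overlapping any of the sorted, disjoint
# [bs, be) intervals: the only candidates are the closest B start at or
# left of each A start and the one immediately right of it
count_overlapping_sorted <- function(as_, ae, bs, be) {
  j <- findInterval(as_, bs)
  left_hit <- j >= 1 & be[pmax(j, 1L)] > as_
  right_hit <- j < length(bs) & bs[pmin(j + 1L, length(bs))] < ae
  sum(left_hit | right_hit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
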