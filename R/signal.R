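# Coverage tracks, enrichment QC metrics and a toy enrichment caller.

#' Binned signal track
#'
#' A tibble of fixed-width bins (`chrom`, `start`, `end`, `value`) carrying
#' its bin size and normalization label (`"raw"`, `"RPGC"` or `"spike"`) as
#' attributes. The last bin of a chromosome may be shorter.
#'
#' @param chrom,start,end,value Bin columns.
#' @param bin_size Bin width in bp.
#' @param norm Normalization label.
#' @return A `binned_track` tibble.
#' @name binned_track
NULL

new_binned_track <- function(chrom, start, end, value, bin_size, norm) {
  out <- tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    value = as.numeric(value)
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "norm") <- norm
  class(out) <- c("binned_track", class(out))
  out
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "# binned_track: bin_size = %d bp, norm = %s\n",
    attr(x, "bin_size"), attr(x, "norm")
  ))
  NextMethod()
}

track_bin_size <- function(track) {
  bs <- attr(track, "bin_size")
  if (is.null(bs)) abort("not a binned_track: missing bin_size attribute")
  bs
}

track_norm <- function(track) attr(track, "norm") %||% "raw"

track_chrom_sizes <- function(track) {
  sizes <- tapply(track$end, track$chrom, max)
  setNames(as.numeric(sizes), names(sizes))
}

genome_bins <- function(chrom_sizes, bin_size) {
  sizes <- as_chrom_sizes(chrom_sizes)
  out <- lapply(names(sizes), function(ch) {
    starts <- seq(0L, sizes[[ch]] - 1L, by = bin_size)
    tibble(
      chrom = ch,
      start = as.integer(starts),
      end = as.integer(pmin(starts + bin_size, sizes[[ch]]))
    )
  })
  dplyr::bind_rows(out)
}

# Per-bin statistic of per-bp fragment depth, one chromosome at a time.
# mode "sum" gives total bp of coverage per bin, "mean" per-bp mean depth.
bin_depth_stat <- function(intervals, chrom_sizes, bin_size, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  sizes <- as_chrom_sizes(chrom_sizes)
  unlist(lapply(names(sizes), function(ch) {
    size <- sizes[[ch]]
    rows <- intervals$chrom == ch
    ir <- IRanges::IRanges(
      start = intervals$start[rows] + 1L,
      end = pmin(intervals$end[rows], size)
    )
    cov <- IRanges::coverage(ir, width = size)
    starts <- seq(0L, size - 1L, by = bin_size)
    v <- IRanges::Views(cov, start = starts + 1L, end = pmin(starts + bin_size, size))
    if (mode == "mean") IRanges::viewMeans(v) else IRanges::viewSums(v)
  }), use.names = FALSE)
}

# bp of each bin covered by >= 1 interval (intervals assumed pre-merged).
bin_covered_bp <- function(merged, chrom_sizes, bin_size) {
  if (nrow(merged) == 0) {
    bins <- genome_bins(chrom_sizes, bin_size)
    return(numeric(nrow(bins)))
  }
  bin_depth_stat(merged, chrom_sizes, bin_size, mode = "sum")
}

#' Fragment coverage track
#'
#' Per-bin mean per-base-pair fragment depth, optionally RPGC-normalized
#' (reads per genome coverage, "1x genome coverage"): values are multiplied
#' by `effective_genome_size / sum(fragment lengths)` so that the
#' genome-wide mean coverage is 1.
#'
#' @param fragments Data frame of fragment placements (`chrom`, `start`,
#'   `end`).
#' @param chrom_sizes Chromosome sizes (named vector or chrom/size table).
#' @param bin_size Bin width in bp (default 5, the resolution used for
#'   browser tracks).
#' @param norm `"raw"` or `"RPGC"`.
#' @param effective_genome_size Required for RPGC; typically the total
#'   mappable genome length.
#' @return A [binned_track].
#' @export
coverage_track <- function(fragments, chrom_sizes, bin_size = 5,
                           norm = c("raw", "RPGC"),
                           effective_genome_size = NULL) {
  norm <- match.arg(norm)
  stopifnot(bin_size >= 1)
  sizes <- as_chrom_sizes(chrom_sizes)
  validate_intervals(fragments, arg = "fragments", chrom_sizes = sizes)
  values <- bin_depth_stat(fragments, sizes, bin_size, mode = "mean")
  if (norm == "RPGC") {
    if (is.null(effective_genome_size) || effective_genome_size <= 0) {
      abort("RPGC normalization needs effective_genome_size > 0")
    }
    total_bp <- sum(fragments$end - fragments$start)
    if (total_bp == 0) {
      abort("RPGC factor is undefined for an empty fragment set")
    }
    values <- values * (effective_genome_size / total_bp)
  }
  bins <- genome_bins(sizes, bin_size)
  new_binned_track(bins$chrom, bins$start, bins$end, values,
    bin_size = bin_size, norm = norm
  )
}

#' Fraction of fragments in peaks (FriP)
#'
#' The standard CUT&Tag / ChIP signal-to-noise metric: the fraction of
#' fragments overlapping at least one base pair of any peak. Because the
#' test is per fragment, FriP is invariant under merging of the peak set.
#'
#' @param fragments Data frame of fragment placements (non-empty).
#' @param peaks Data frame of peak intervals.
#' @return A fraction in [0, 1].
#' @export
frip <- function(fragments, peaks) {
  validate_intervals(fragments, arg = "fragments")
  if (nrow(fragments) == 0) {
    abort("FriP is undefined for an empty fragment set")
  }
  validate_intervals(peaks, arg = "peaks")
  n_overlapping(fragments, peaks) / nrow(fragments)
}

#' Fingerprint curve
#'
#' Cumulative fraction of total signal over genome bins ranked by ascending
#' fragment count. A uniform library follows the diagonal; a well-enriched
#' one hugs the x axis until the most-covered bins. The curve starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param fragments Data frame of fragment placements.
#' @param chrom_sizes Chromosome sizes.
#' @param bin_size Bin width in bp (default 500, the usual fingerprint
#'   resolution).
#' @return A `fingerprint_curve` tibble with columns `frac_bins`,
#'   `frac_signal`.
#' @export
fingerprint <- function(fragments, chrom_sizes, bin_size = 500) {
  stopifnot(bin_size >= 1)
  sizes <- as_chrom_sizes(chrom_sizes)
  validate_intervals(fragments, arg = "fragments", chrom_sizes = sizes)
  bins <- genome_bins(sizes, bin_size)
  counts <- GenomicRanges::countOverlaps(
    as_gr(bins, levels = names(sizes)),
    as_gr(fragments, levels = names(sizes)),
    ignore.strand = TRUE
  )
  total <- sum(counts)
  if (total == 0) {
    abort("fingerprint is undefined for zero total fragment count")
  }
  sorted <- sort(counts)
  n <- length(sorted)
  out <- tibble(
    frac_bins = c(0, seq_len(n) / n),
    frac_signal = c(0, cumsum(sorted) / total)
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("fingerprint_curve", class(out))
  out
}

#' Telomeric read content
#'
#' Fraction of reads containing at least `min_tandem` consecutive copies of
#' the telomeric repeat unit (default `TTAGGG`) or of its reverse
#' complement (`CCCTAA`), so the estimate is orientation-invariant. Tandem
#' string matching approximates alignment against a telomeric repeat
#' pseudogenome.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `sequence` column (e.g. from [read_fastq()]).
#' @param unit Repeat unit.
#' @param min_tandem Minimum number of consecutive copies (default 3,
#'   approximating a short-read aligner seed).
#' @return Fraction of telomeric reads.
#' @export
telomeric_fraction <- function(reads, unit = "TTAGGG", min_tandem = 3) {
  stopifnot(min_tandem >= 1)
  if (is.data.frame(reads)) {
    stopifnot("sequence" %in% names(reads))
    reads <- reads$sequence
  }
  if (length(reads) == 0) {
    abort("telomeric_fraction is undefined for an empty read set")
  }
  reads <- toupper(reads)
  fwd <- strrep(toupper(unit), min_tandem)
  rev <- strrep(revcomp(toupper(unit)), min_tandem)
  mean(grepl(fwd, reads, fixed = TRUE) | grepl(rev, reads, fixed = TRUE))
}

#' Signal profile matrix over windows
#'
#' Mean track value in `n_bins` equal sub-bins of each window (all windows
#' must have the same width, divisible by `n_bins`). Minus-strand windows
#' are reversed so that columns always run 5' to 3'. Sub-bins that fall
#' entirely off the chromosome are `NA`; partially clipped sub-bins average
#' over their in-range part.
#'
#' @param track A [binned_track].
#' @param windows Data frame of equal-width intervals, optionally with a
#'   `strand` column.
#' @param n_bins Number of columns of the output matrix.
#' @return A numeric matrix, rows = windows, columns = sub-bins.
#' @export
profile_matrix <- function(track, windows, n_bins = 50) {
  validate_intervals(windows, arg = "windows")
  stopifnot(n_bins >= 1)
  widths <- unique(windows$end - windows$start)
  if (length(widths) != 1) {
    abort("all windows must have the same width")
  }
  if (widths %% n_bins != 0) {
    abort("window width must be divisible by n_bins")
  }
  sub <- widths / n_bins
  bin_size <- track_bin_size(track)
  sizes <- track_chrom_sizes(track)
  # per-bp cumulative sums of the track, one vector per chromosome
  cums <- lapply(names(sizes), function(ch) {
    rows <- track$chrom == ch
    size <- sizes[[ch]]
    per_bp <- rep(track$value[rows], times = track$end[rows] - track$start[rows])
    c(0, cumsum(per_bp))
  })
  names(cums) <- names(sizes)
  mat <- matrix(NA_real_, nrow = nrow(windows), ncol = n_bins)
  for (i in seq_len(nrow(windows))) {
    ch <- windows$chrom[i]
    if (!ch %in% names(sizes)) {
      next
    }
    size <- sizes[[ch]]
    cs <- cums[[ch]]
    a <- windows$start[i] + (seq_len(n_bins) - 1) * sub
    b <- a + sub
    a0 <- pmax(a, 0)
    b0 <- pmin(b, size)
    ok <- b0 > a0
    vals <- rep(NA_real_, n_bins)
    vals[ok] <- (cs[b0[ok] + 1] - cs[a0[ok] + 1]) / (b0[ok] - a0[ok])
    if ("strand" %in% names(windows) && identical(windows$strand[i], "-")) {
      vals <- rev(vals)
    }
    mat[i, ] <- vals
  }
  rownames(mat) <- if ("name" %in% names(windows)) windows$name else NULL
  class(mat) <- c("profile_matrix", class(mat))
  attr(mat, "sub_bin") <- sub
  mat
}

#' Toy enrichment peak caller
#'
#' Self-contained stand-in for a dedicated peak caller, sufficient to close
#' the synthetic pipeline: bins whose value exceeds
#' `mean + z_threshold * sd` of the *nonzero* bins (sparse tagmentation
#' leaves most bins empty; a global sd would be deflated) are merged across
#' gaps of at most `merge_gap` bins, and regions with at least `min_run`
#' qualifying bins are reported. The peak score is the region's mean fold
#' enrichment over the genome-wide mean, scaled by 10 and capped at 1000.
#'
#' @param track A [binned_track].
#' @param z_threshold Threshold in sd units over the nonzero-bin mean.
#' @param min_run Minimum number of qualifying bins per peak.
#' @param merge_gap Maximum gap (in bins) bridged when merging.
#' @return A tibble of peaks in narrowPeak-like columns (`signal_value` is
#'   the fold enrichment, `summit_offset` the offset of the maximal bin).
#' @export
call_enriched_bins <- function(track, z_threshold = 3, min_run = 2, merge_gap = 1) {
  stopifnot(nrow(track) > 0)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    signal_value = numeric(), p_log10 = numeric(), q_log10 = numeric(),
    summit_offset = integer()
  )
  nz <- track$value[track$value > 0]
  if (length(nz) < 2) {
    return(empty)
  }
  thr <- mean(nz) + z_threshold * sd(nz)
  flagged <- track$value > thr
  if (!any(flagged)) {
    return(empty)
  }
  genome_mean <- mean(track$value)
  out <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    f <- which(flagged[rows])
    if (length(f) == 0) next
    brk <- c(0, which(diff(f) > merge_gap + 1), length(f))
    for (k in seq_len(length(brk) - 1)) {
      idx <- f[(brk[k] + 1):brk[k + 1]]
      if (length(idx) < min_run) next
      span <- rows[min(idx)]:rows[max(idx)]
      fold <- mean(track$value[span]) / genome_mean
      maxbin <- span[which.max(track$value[span])]
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = track$start[rows[min(idx)]],
        end = track$end[rows[max(idx)]],
        score = min(1000, round(10 * fold)),
        signal_value = fold,
        summit_offset = as.integer(track$start[maxbin] - track$start[rows[min(idx)]])
      )
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  tibble(
    chrom = res$chrom, start = res$start, end = res$end,
    name = sprintf("peak_%d", seq_len(nrow(res))),
    score = res$score, strand = ".",
    signal_value = res$signal_value,
    p_log10 = NA_real_, q_log10 = NA_real_,
    summit_offset = res$summit_offset
  )
}
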