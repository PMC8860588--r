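# Putative G-quadruplex sequence (PQS) scanning.
#
# Four motif classes are supported:
#   canonical   G{3,} loop{1,7}  x 4 G-runs          (one strand)
#   extended    G{3,} loop{1,12} x 4 G-runs          (one strand)
#   two_tetrad  (G{2} loop{1,12}){3,} G{2}           (relaxed, two quartets)
#   interstrand 4 blocks of G{3,} (A) / C{3,} (B), loops {1,7}, where the
#               C-runs supply G-runs from the opposite strand; the 8
#               A-leading block compositions AAAA..ABBB are scanned in
#               reference-strand coordinates (AAAA is the canonical motif).
#
# Default matching is leftmost, greedy and non-overlapping per strand --
# plain regular-expression engine semantics. Loops are restricted to
# [ACGT], so N never participates in a run or a loop. Minus-strand matches
# (intra-strand classes) are found by scanning the reverse complement with
# the same G-pattern and mirroring coordinates, i.e. the minus strand is
# read in its own 5'->3' direction; this makes strand symmetry exact.

pqs_classes <- c("canonical", "extended", "two_tetrad", "interstrand")

interstrand_compositions <- c(
  "AAAA", "AAAB", "AABA", "AABB", "ABAA", "ABAB", "ABBA", "ABBB"
)

#' PQS pattern specification
#'
#' Describes one motif class: minimum G-run length, loop-length range and,
#' for the inter-strand class, the A/B block composition (A = G-run on the
#' reference strand, B = C-run, i.e. a G-run on the opposite strand).
#'
#' @param class_id One of `"canonical"`, `"extended"`, `"two_tetrad"`,
#'   `"interstrand"`.
#' @param composition A 4-letter string over \{A, B\}; required for (and only
#'   used by) the inter-strand class. Only the 8 A-leading compositions are
#'   valid: B-leading compositions are their reverse-complement mirrors.
#' @return A list with elements `class_id`, `composition`, `min_run`,
#'   `loop_min`, `loop_max`, `blocks` and the PCRE `pattern` used for
#'   plus-strand matching.
#' @export
pqs_pattern <- function(class_id, composition = NULL) {
  if (length(class_id) != 1 || !class_id %in% pqs_classes) {
    abort(sprintf(
      "unknown PQS class '%s' (expected one of %s)",
      paste(class_id, collapse = ","), paste(pqs_classes, collapse = ", ")
    ))
  }
  spec <- switch(class_id,
    canonical = list(min_run = 3L, loop_min = 1L, loop_max = 7L, blocks = 4L),
    extended = list(min_run = 3L, loop_min = 1L, loop_max = 12L, blocks = 4L),
    two_tetrad = list(min_run = 2L, loop_min = 1L, loop_max = 12L, blocks = NA_integer_),
    interstrand = list(min_run = 3L, loop_min = 1L, loop_max = 7L, blocks = 4L)
  )
  if (class_id == "interstrand") {
    if (is.null(composition) || !composition %in% interstrand_compositions) {
      abort(sprintf(
        "inter-strand composition must be one of: %s",
        paste(interstrand_compositions, collapse = ", ")
      ))
    }
    spec$composition <- composition
  } else {
    spec$composition <- "AAAA"
  }
  spec$class_id <- class_id
  loop <- sprintf("[ACGT]{%d,%d}", spec$loop_min, spec$loop_max)
  spec$pattern <- switch(class_id,
    canonical = ,
    extended = sprintf("(?:G{3,}%s){3}G{3,}", loop),
    two_tetrad = sprintf("(?:G{2}%s){3,}G{2}", loop),
    interstrand = {
      blocks <- ifelse(strsplit(composition, "")[[1]] == "A", "G{3,}", "C{3,}")
      paste0(paste0(blocks[1:3], loop, collapse = ""), blocks[4])
    }
  )
  spec
}

revcomp <- function(s) {
  vapply(
    s,
    function(x) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    },
    character(1),
    USE.NAMES = FALSE
  )
}

# Non-overlapping leftmost-greedy matches of a PCRE on one string;
# returns 0-based half-open (start, end).
regex_matches <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}

# ---- overlapping-placement enumeration (distinct intervals) --------------

run_lengths_from <- function(chars, letter) {
  is_l <- chars == letter
  n <- length(is_l)
  out <- integer(n)
  run <- 0L
  for (i in n:1) {
    run <- if (is_l[i]) run + 1L else 0L
    out[i] <- run
  }
  out
}

# Distinct (start, end) with >= 1 valid placement of a fixed 4-block
# pattern (run letters per block, open-ended runs >= min_run, loops in
# [loop_min, loop_max]). Memoized reachability over (position, block).
enumerate_fixed_blocks <- function(chars, letters, min_run, loop_min, loop_max) {
  n <- length(chars)
  runs <- list(
    G = run_lengths_from(chars, "G"),
    C = run_lengths_from(chars, "C")
  )
  nb <- length(letters)
  memo <- new.env(parent = emptyenv())
  rec <- function(pos, bi) {
    if (pos > n) {
      return(integer(0))
    }
    key <- sprintf("%d.%d", pos, bi)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    r <- runs[[letters[bi]]][pos]
    res <- if (r < min_run) {
      integer(0)
    } else if (bi == nb) {
      pos + (min_run:r)
    } else {
      qs <- (pos + min_run + loop_min):(pos + r + loop_max)
      sort(unique(unlist(lapply(qs, rec, bi = bi + 1L))))
    }
    memo[[key]] <- res
    res
  }
  starts <- which(runs[[letters[1]]] >= min_run)
  out <- lapply(starts, function(s) {
    ends <- rec(s, 1L)
    if (length(ends) == 0) NULL else data.frame(start = s - 1L, end = ends - 1L)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(start = integer(), end = integer()) else res
}

# Same for the two-tetrad repeated-group pattern (G{2} loop){3,} G{2}.
# State: position x completed iterations (capped at 3).
enumerate_two_tetrad <- function(chars, loop_min = 1L, loop_max = 12L) {
  n <- length(chars)
  runG <- run_lengths_from(chars, "G")
  memo <- new.env(parent = emptyenv())
  rec <- function(pos, k) {
    if (pos > n) {
      return(integer(0))
    }
    key <- sprintf("%d.%d", pos, k)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    res <- integer(0)
    if (runG[pos] >= 2L) {
      if (k >= 3L) res <- pos + 2L
      qs <- (pos + 2L + loop_min):(pos + 2L + loop_max)
      res <- sort(unique(c(res, unlist(lapply(qs, rec, k = min(k + 1L, 3L))))))
    }
    memo[[key]] <- res
    res
  }
  starts <- which(runG >= 2L)
  out <- lapply(starts, function(s) {
    ends <- rec(s, 0L)
    if (length(ends) == 0) NULL else data.frame(start = s - 1L, end = ends - 1L)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(start = integer(), end = integer()) else res
}

overlapping_matches <- function(seq, spec) {
  chars <- strsplit(seq, "")[[1]]
  if (spec$class_id == "two_tetrad") {
    enumerate_two_tetrad(chars, spec$loop_min, spec$loop_max)
  } else {
    letters <- ifelse(strsplit(spec$composition, "")[[1]] == "A", "G", "C")
    enumerate_fixed_blocks(chars, letters, spec$min_run, spec$loop_min, spec$loop_max)
  }
}

mirror_coords <- function(df, n) {
  if (nrow(df) == 0) {
    return(df)
  }
  data.frame(start = n - df$end, end = n - df$start)
}

scan_one_strand <- function(seq, spec, overlapping) {
  if (overlapping) {
    overlapping_matches(seq, spec)
  } else {
    regex_matches(seq, spec$pattern)
  }
}

#' Scan a genome for putative G-quadruplex sequences
#'
#' Finds PQS matches of one motif class over every sequence of a genome
#' table. Intra-strand classes are scanned on both strands by default, the
#' minus strand being read 5'->3' on the reverse complement; inter-strand
#' compositions are defined in reference-strand coordinates and carry
#' strand `"."` (except `AAAA`, which is the canonical plus-strand motif).
#'
#' With `overlapping = FALSE` (default) matching is leftmost, greedy and
#' non-overlapping per strand, as a regular-expression engine reports;
#' `overlapping = TRUE` enumerates every distinct interval with at least
#' one valid block/loop placement.
#'
#' @param genome Data frame with columns `name`, `sequence`.
#' @param class_id Motif class (see [pqs_pattern()]).
#' @param composition Inter-strand composition(s); one or more of the 8
#'   A-leading strings. Ignored for intra-strand classes.
#' @param strand `"both"`, `"plus"` or `"minus"` (intra-strand classes only).
#' @param overlapping Enumerate all distinct placements instead of the
#'   non-overlapping regex scan?
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `class_id`, `composition`, `matched_seq`, sorted by (chrom, start, end).
#' @export
#' @examples
#' g <- data.frame(name = "chr1", sequence = "GGGAGGGAGGGAGGG")
#' scan_pqs(g, "canonical")
scan_pqs <- function(genome, class_id = "canonical", composition = NULL,
                     strand = c("both", "plus", "minus"), overlapping = FALSE) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(genome), all(c("name", "sequence") %in% names(genome)))
  if (class_id == "interstrand") {
    comps <- composition %||% interstrand_compositions
    out <- map_dfr_base(comps, function(comp) {
      scan_pqs_interstrand(genome, comp, overlapping)
    })
    return(sort_matches(out))
  }
  spec <- pqs_pattern(class_id)
  out <- map_dfr_base(seq_len(nrow(genome)), function(i) {
    seq <- toupper(genome$sequence[i])
    n <- nchar(seq)
    res <- list()
    if (strand %in% c("both", "plus")) {
      df <- scan_one_strand(seq, spec, overlapping)
      if (nrow(df) > 0) {
        res$plus <- cbind(df, strand = "+")
      }
    }
    if (strand %in% c("both", "minus")) {
      df <- mirror_coords(scan_one_strand(revcomp(seq), spec, overlapping), n)
      if (nrow(df) > 0) {
        res$minus <- cbind(df, strand = "-")
      }
    }
    df <- do.call(rbind, res)
    if (is.null(df) || nrow(df) == 0) {
      return(NULL)
    }
    tibble(
      chrom = genome$name[i],
      start = df$start,
      end = df$end,
      strand = df$strand,
      class_id = class_id,
      composition = spec$composition,
      matched_seq = substring(seq, df$start + 1, df$end)
    )
  })
  sort_matches(out)
}

scan_pqs_interstrand <- function(genome, composition, overlapping = FALSE) {
  spec <- pqs_pattern("interstrand", composition)
  map_dfr_base(seq_len(nrow(genome)), function(i) {
    seq <- toupper(genome$sequence[i])
    df <- scan_one_strand(seq, spec, overlapping)
    if (nrow(df) == 0) {
      return(NULL)
    }
    tibble(
      chrom = genome$name[i],
      start = df$start,
      end = df$end,
      strand = if (composition == "AAAA") "+" else ".",
      class_id = "interstrand",
      composition = composition,
      matched_seq = substring(seq, df$start + 1, df$end)
    )
  })
}

empty_matches <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), class_id = character(), composition = character(),
    matched_seq = character()
  )
}

sort_matches <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    return(empty_matches())
  }
  x[order(x$chrom, x$start, x$end, x$strand), , drop = FALSE]
}

map_dfr_base <- function(xs, f) {
  out <- lapply(xs, f)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(NULL)
  }
  dplyr::bind_rows(out)
}

#' Base-pair union of PQS matches across classes
#'
#' Merges the match intervals of the selected classes/compositions into
#' disjoint regions. The "non-canonical trans-strand" PQS set of an
#' inter-strand scan is the union over the 7 compositions other than
#' `AAAA`.
#'
#' @param matches Match tibble from [scan_pqs()] (possibly several scans
#'   row-bound together).
#' @param classes Classes to include; defaults to all present. An empty
#'   selection returns an empty tibble.
#' @param compositions Optional filter on the `composition` column.
#' @return Tibble of merged intervals.
#' @export
pqs_union <- function(matches, classes = NULL, compositions = NULL) {
  stopifnot(is.data.frame(matches))
  x <- matches
  if (!is.null(classes)) {
    x <- x[x$class_id %in% classes, , drop = FALSE]
  }
  if (!is.null(compositions)) {
    x <- x[x$composition %in% compositions, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  merge_intervals(x)
}

#' Motif occupancy track
#'
#' Fraction of each fixed-size bin covered by at least one match (bases
#' under overlapping matches are counted once); values are in [0, 1].
#'
#' @param matches Data frame of match intervals.
#' @param chrom_sizes Chromosome sizes (named vector or chrom/size table).
#' @param bin_size Bin width in bp.
#' @return A [binned_track] with `norm = "raw"`.
#' @export
pqs_coverage <- function(matches, chrom_sizes, bin_size = 5) {
  stopifnot(bin_size >= 1)
  sizes <- as_chrom_sizes(chrom_sizes)
  validate_intervals(matches, arg = "matches", chrom_sizes = sizes)
  merged <- if (nrow(matches) > 0) merge_intervals(matches) else matches
  bins <- genome_bins(sizes, bin_size)
  covered <- bin_covered_bp(merged, sizes, bin_size)
  new_binned_track(
    bins$chrom, bins$start, bins$end,
    value = covered / bin_size,
    bin_size = bin_size, norm = "raw"
  )
}

#' CpG dinucleotide track
#'
#' One 2-bp interval per CG occurrence, in plus-strand coordinates
#' (occurrences cannot overlap, so the set is overlap-free by
#' construction). Used as the CpG-density reference track.
#'
#' @param genome Data frame with columns `name`, `sequence`.
#' @return Tibble of intervals with strand `"+"`.
#' @export
cpg_track <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("name", "sequence") %in% names(genome)))
  out <- map_dfr_base(seq_len(nrow(genome)), function(i) {
    seq <- toupper(genome$sequence[i])
    m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (m[1] == -1) {
      return(NULL)
    }
    tibble(
      chrom = genome$name[i],
      start = as.integer(m) - 1L,
      end = as.integer(m) + 1L,
      strand = "+"
    )
  })
  out %||% tibble(
    chrom = character(), start = integer(), end = integer(), strand = character()
  )
}

#' Fraction of peaks containing a PQS
#'
#' @param peaks Data frame of peak intervals (must be non-empty).
#' @param pqs Data frame of PQS intervals (e.g. from [pqs_union()]).
#' @return Fraction of peaks overlapping >= 1 bp of any PQS interval.
#' @export
fraction_peaks_with_pqs <- function(peaks, pqs) {
  validate_intervals(peaks, arg = "peaks")
  if (nrow(peaks) == 0) {
    abort("fraction_peaks_with_pqs() is undefined for an empty peak set")
  }
  validate_intervals(pqs, arg = "pqs")
  n_overlapping(peaks, pqs) / nrow(peaks)
}
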