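# Independent brute-force PQS matching oracle.
#
# Enumerates block/loop placements by explicit recursive search in the
# regex engine's preference order (leftmost start; at each quantifier the
# greedy choice first; non-overlapping continuation after each match).
# Deliberately shares no code with the package scanner: runs are measured
# by walking the character vector, matches are built by depth-first
# search over run lengths and loop lengths.

oracle_run_len <- function(chars, pos, letter) {
  n <- length(chars)
  r <- 0L
  while (pos + r <= n && chars[pos + r] == letter) r <- r + 1L
  r
}

# Greedy-first search for a fixed sequence of blocks (letters), runs of
# length >= min_run, loops of [ACGT] in [lmin, lmax]. Returns the 1-based
# inclusive end of the preferred match starting exactly at `pos`, or NULL.
oracle_match_fixed <- function(chars, pos, letters, min_run, lmin, lmax) {
  n <- length(chars)
  acgt <- c("A", "C", "G", "T")
  rec <- function(p, bi) {
    if (p > n) {
      return(NULL)
    }
    r <- oracle_run_len(chars, p, letters[bi])
    if (r < min_run) {
      return(NULL)
    }
    if (bi == length(letters)) {
      return(p + r - 1L) # final run is greedy: take it all
    }
    for (L in seq(r, min_run)) {
      loop_start <- p + L
      max_l <- min(lmax, n - loop_start + 1L)
      if (max_l < lmin) next
      # loop characters must be in [ACGT]
      ok_len <- 0L
      while (ok_len < max_l && chars[loop_start + ok_len] %in% acgt) ok_len <- ok_len + 1L
      if (ok_len < lmin) next
      for (l in seq(min(ok_len, lmax), lmin)) {
        res <- rec(loop_start + l, bi + 1L)
        if (!is.null(res)) {
          return(res)
        }
      }
    }
    NULL
  }
  rec(pos, 1L)
}

# Same for the repeated-group two-tetrad pattern (GG loop){3,} GG.
oracle_match_two_tetrad <- function(chars, pos, lmin = 1L, lmax = 12L) {
  n <- length(chars)
  acgt <- c("A", "C", "G", "T")
  rec <- function(p, iters) {
    if (p + 1L > n || chars[p] != "G" || chars[p + 1L] != "G") {
      return(NULL)
    }
    loop_start <- p + 2L
    max_l <- min(lmax, n - loop_start + 1L)
    if (max_l >= lmin) {
      ok_len <- 0L
      while (ok_len < max_l && chars[loop_start + ok_len] %in% acgt) ok_len <- ok_len + 1L
      if (ok_len >= lmin) {
        for (l in seq(min(ok_len, lmax), lmin)) {
          res <- rec(loop_start + l, iters + 1L)
          if (!is.null(res)) {
            return(res)
          }
        }
      }
    }
    if (iters >= 3L) {
      return(p + 1L) # exit the group, final GG at p
    }
    NULL
  }
  rec(pos, 0L)
}

# Leftmost, non-overlapping scan over one strand. Returns 0-based
# half-open intervals.
oracle_scan_strand <- function(chars, match_at, candidate_starts) {
  out_start <- integer(0)
  out_end <- integer(0)
  pos <- 1L
  for (s in candidate_starts) {
    if (s < pos) next
    e <- match_at(s)
    if (!is.null(e)) {
      out_start <- c(out_start, s - 1L)
      out_end <- c(out_end, e)
      pos <- e + 1L
    }
  }
  data.frame(start = out_start, end = out_end)
}

oracle_revcomp_chars <- function(chars) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]))
}

# Full oracle: intra-strand classes on both strands (minus = scan of the
# reverse complement, mirrored), inter-strand compositions on the
# reference strand. Returns tibble(start, end, strand), 0-based half-open.
oracle_scan <- function(seq, class_id, composition = NULL) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  params <- switch(class_id,
    canonical = list(min_run = 3L, lmin = 1L, lmax = 7L),
    extended = list(min_run = 3L, lmin = 1L, lmax = 12L),
    two_tetrad = list(min_run = 2L, lmin = 1L, lmax = 12L),
    interstrand = list(min_run = 3L, lmin = 1L, lmax = 7L)
  )
  starts_of <- function(ch, letter, k) {
    hit <- ch == letter
    ok <- hit
    for (j in seq_len(k - 1)) ok <- ok & c(hit[-seq_len(j)], rep(FALSE, j))
    which(ok)
  }
  scan_g_pattern <- function(ch) {
    if (class_id == "two_tetrad") {
      oracle_scan_strand(
        ch,
        function(s) oracle_match_two_tetrad(ch, s, params$lmin, params$lmax),
        starts_of(ch, "G", 2L)
      )
    } else {
      letters <- if (class_id == "interstrand") {
        ifelse(strsplit(composition, "")[[1]] == "A", "G", "C")
      } else {
        rep("G", 4L)
      }
      oracle_scan_strand(
        ch,
        function(s) {
          oracle_match_fixed(ch, s, letters, params$min_run, params$lmin, params$lmax)
        },
        starts_of(ch, letters[1], params$min_run)
      )
    }
  }
  if (class_id == "interstrand") {
    df <- scan_g_pattern(chars)
    df$strand <- rep(
      if (identical(composition, "AAAA")) "+" else ".",
      nrow(df)
    )
    return(df[order(df$start), , drop = FALSE])
  }
  plus <- scan_g_pattern(chars)
  plus$strand <- rep("+", nrow(plus))
  rc <- oracle_revcomp_chars(chars)
  minus <- scan_g_pattern(rc)
  minus <- data.frame(
    start = n - minus$end, end = n - minus$start,
    strand = rep("-", nrow(minus))
  )
  out <- rbind(plus, minus)
  if (nrow(out) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Random DNA with uniform base composition.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# strip a match tibble down to comparable columns
match_coords <- function(x) {
  out <- data.frame(start = x$start, end = x$end, strand = x$strand)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
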