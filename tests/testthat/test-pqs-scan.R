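g1 <- function(seq) data.frame(name = "chr1", sequence = seq)

test_that("pattern specs encode the four motif classes", {
  can <- pqs_pattern("canonical")
  expect_equal(can$min_run, 3L)
  expect_equal(c(can$loop_min, can$loop_max), c(1L, 7L))
  ext <- pqs_pattern("extended")
  expect_equal(ext$loop_max, 12L)
  tt <- pqs_pattern("two_tetrad")
  expect_equal(tt$min_run, 2L)
  expect_equal(tt$loop_max, 12L)
  is <- pqs_pattern("interstrand", "AABB")
  expect_equal(is$composition, "AABB")
  expect_error(pqs_pattern("bogus"), "unknown PQS class")
  expect_error(pqs_pattern("interstrand", "BBBB"), "composition")
  expect_error(pqs_pattern("interstrand"), "composition")
})

test_that("minimal motif instances are matched with correct strand", {
  m <- scan_pqs(g1("GGGAGGGAGGGAGGG"), "canonical")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  expect_equal(m$strand, "+")
  expect_equal(m$composition, "AAAA")

  m <- scan_pqs(g1("CCCTCCCTCCCTCCC"), "canonical")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  expect_equal(m$strand, "-")

  m <- scan_pqs(g1("GGAGGAGGAGG"), "two_tetrad")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 11L)

  # N breaks runs and loops alike
  expect_equal(nrow(scan_pqs(g1("GGGNGGGAGGGAGGG"), "canonical")), 0)
})

test_that("interstrand compositions match A/B block layouts in reference coordinates", {
  m <- scan_pqs(g1("GGGAGGGACCCACCC"), "interstrand", composition = "AABB")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  expect_equal(m$strand, ".")

  m <- scan_pqs(g1("GGGACCCAGGGACCC"), "interstrand", composition = "ABAB")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)

  # AAAA is definitionally the canonical plus-strand motif
  s <- withr::with_seed(5, rand_dna(2000))
  g <- g1(s)
  aaaa <- scan_pqs(g, "interstrand", composition = "AAAA")
  can_plus <- scan_pqs(g, "canonical", strand = "plus")
  expect_equal(aaaa[, c("start", "end")], can_plus[, c("start", "end")])
  expect_equal(unique(aaaa$strand), if (nrow(aaaa)) "+" else character(0))
})

test_that("non-overlapping scans equal the brute-force placement oracle", {
  withr::local_seed(421)
  comps <- c("AAAA", "AAAB", "AABA", "AABB", "ABAA", "ABAB", "ABBA", "ABBB")
  for (i in 1:6) {
    s <- rand_dna(10000)
    g <- g1(s)
    for (cl in c("canonical", "extended", "two_tetrad")) {
      got <- match_coords(scan_pqs(g, cl))
      want <- oracle_scan(s, cl)
      rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("class %s, seq %d", cl, i))
    }
    comp <- comps[(i %% 8) + 1]
    got <- match_coords(scan_pqs(g, "interstrand", composition = comp))
    want <- oracle_scan(s, "interstrand", comp)
    rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("interstrand %s, seq %d", comp, i))
  }
})

test_that("overlapping mode enumerates distinct placements and contains greedy matches", {
  # two chained canonical instances: greedy takes one match, overlapping
  # mode reports every distinct placement interval
  s <- "GGGAGGGAGGGAGGGAGGG" # 5 G-runs
  greedy <- scan_pqs(g1(s), "canonical", strand = "plus")
  expect_equal(nrow(greedy), 1)
  all_p <- scan_pqs(g1(s), "canonical", strand = "plus", overlapping = TRUE)
  expect_gt(nrow(all_p), 1)
  # every greedy match interval must appear among the placements
  expect_true(all(
    paste(greedy$start, greedy$end) %in% paste(all_p$start, all_p$end)
  ))
  # placements include the two extreme 4-run windows
  expect_true(all(c("0 15", "4 19") %in% paste(all_p$start, all_p$end)))
})

test_that("strand symmetry: reverse complement mirrors intervals and compositions", {
  withr::local_seed(77)
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  mirror <- function(m, n) {
    out <- data.frame(
      start = n - m$end, end = n - m$start,
      strand = chartr("+-", "-+", m$strand)
    )
    out[order(out$start, out$end, out$strand), ]
  }
  for (i in 1:4) {
    s <- rand_dna(10000)
    n <- nchar(s)
    for (cl in c("canonical", "extended", "two_tetrad")) {
      fwd <- match_coords(scan_pqs(g1(s), cl))
      rev <- match_coords(scan_pqs(g1(rc(s)), cl))
      want <- mirror(rev, n)
      rownames(want) <- NULL
      expect_equal(fwd, want, info = cl)
    }
    # interstrand: composition X on seq <-> A/B-swapped reversed
    # composition on the reverse complement (AAAB <-> ABBB)
    for (pair in list(c("AAAB", "ABBB"), c("AABB", "AABB"), c("ABAB", "ABAB"))) {
      fwd <- scan_pqs(g1(s), "interstrand", composition = pair[1])
      rev <- scan_pqs(g1(rc(s)), "interstrand", composition = pair[2])
      got <- data.frame(start = fwd$start, end = fwd$end)
      want <- data.frame(start = n - rev$end, end = n - rev$start)
      want <- want[order(want$start, want$end), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste(pair, collapse = "<->"))
    }
  }
})

test_that("pqs_union merges selected classes and honors empty selections", {
  m <- dplyr::bind_rows(
    tibble::tibble(
      chrom = "chr1", start = 0L, end = 15L, strand = "+",
      class_id = "canonical", composition = "AAAA", matched_seq = ""
    ),
    tibble::tibble(
      chrom = "chr1", start = 0L, end = 20L, strand = "+",
      class_id = "extended", composition = "AAAA", matched_seq = ""
    ),
    tibble::tibble(
      chrom = "chr1", start = 100L, end = 120L, strand = ".",
      class_id = "interstrand", composition = "AABB", matched_seq = ""
    )
  )
  u <- pqs_union(m)
  expect_equal(u$start, c(0L, 100L))
  expect_equal(u$end, c(20L, 120L))

  u <- pqs_union(m, classes = c("canonical", "extended"))
  expect_equal(u$end, 20L)

  expect_equal(nrow(pqs_union(m, classes = character(0))), 0)

  # non-canonical trans-strand set excludes AAAA
  u <- pqs_union(m, classes = "interstrand", compositions = setdiff(
    c("AAAA", "AAAB", "AABA", "AABB", "ABAA", "ABAB", "ABBA", "ABBB"), "AAAA"
  ))
  expect_equal(u$start, 100L)
})

test_that("pqs_coverage reports per-bin occupancy, counting bases once", {
  m <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  tr <- pqs_coverage(m, c(chr1 = 20), bin_size = 5)
  expect_equal(tr$value, c(1, 1, 0, 0))

  tr <- pqs_coverage(m[0, ], c(chr1 = 20), bin_size = 5)
  expect_equal(tr$value, rep(0, 4))

  # overlapping matches are clamped by union
  m2 <- tibble::tibble(chrom = "chr1", start = c(0L, 3L), end = c(8L, 10L))
  tr <- pqs_coverage(m2, c(chr1 = 20), bin_size = 5)
  expect_true(all(tr$value <= 1))
  expect_equal(tr$value[1:2], c(1, 1))
})

test_that("cpg_track finds every CG dinucleotide", {
  expect_equal(cpg_track(g1("ACGCGT"))$start, c(1L, 3L))
  expect_equal(nrow(cpg_track(g1("GGGG"))), 0)
  cg <- cpg_track(g1("CGCG"))
  expect_equal(cg$start, c(0L, 2L))
  expect_equal(cg$end, c(2L, 4L))
})

test_that("fraction_peaks_with_pqs counts peaks touching any PQS", {
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L)
  )
  pqs <- tibble::tibble(
    chrom = "chr1", start = c(10L, 120L, 210L), end = c(20L, 130L, 220L)
  )
  expect_equal(fraction_peaks_with_pqs(peaks, pqs), 0.75)
  expect_equal(fraction_peaks_with_pqs(peaks, pqs[0, ]), 0)
  expect_equal(fraction_peaks_with_pqs(peaks[1:3, ], pqs), 1)
  expect_error(fraction_peaks_with_pqs(peaks[0, ], pqs), "empty")
})

test_that("scan output is deterministic and sorted", {
  s <- withr::with_seed(3, rand_dna(5000))
  a <- scan_pqs(g1(s), "two_tetrad")
  b <- scan_pqs(g1(s), "two_tetrad")
  expect_identical(a, b)
  expect_true(!is.unsorted(a$start))
  # matched_seq is the genome slice
  expect_equal(a$matched_seq, substring(s, a$start + 1, a$end))
})
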