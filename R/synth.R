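# Synthetic study system: a small multi-chromosome genome with implanted
# PQS truth sites, a separate spike-in genome, and CUT&Tag-like fragment
# libraries enriched at the truth sites over a uniform background.
#
# The background is i.i.d. with G-run suppression (no run of >= 3 G or
# >= 3 C), so the canonical scanner fires on implanted sites and nowhere
# else: truth and scanner output coincide by construction.

sim_letters <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' The generator's defaults define the study conditions: three 100-kb
#' sample chromosomes plus one 20-kb spike-in chromosome, 25 implanted
#' sites per PQS class (canonical, extended, two-tetrad, inter-strand; the
#' inter-strand sites cycle through the 7 non-AAAA compositions), 20-fold
#' enrichment of fragments at truth sites, 100,000 fragments of length
#' ~ Normal(150, 30) truncated to [30, 1000], and a 5% spike-in fraction
#' mirroring the constant-amount spike-in protocol. `mung_bean_factor`
#' emulates single-strand-specific nuclease pretreatment by leaving only
#' that fraction of the truth-site draw probability in mung-bean mode.
#'
#' @param seed Integer seed governing every random choice.
#' @param chrom_sizes Named vector of sample chromosome sizes.
#' @param spike_chrom_sizes Named vector of spike-in chromosome sizes
#'   (names must carry the spike prefix, e.g. `dm_chr1`).
#' @param gc_content Background GC fraction.
#' @param n_sites_per_class Implanted truth sites per PQS class.
#' @param enrichment_fold Truth-site draw weight relative to background.
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp).
#' @param library_size Total fragments per library.
#' @param spike_fraction Expected fraction of fragments from the spike-in
#'   genome.
#' @param mung_bean_factor Residual truth-site signal in mung-bean mode.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 100000, chr2 = 100000, chr3 = 100000),
                       spike_chrom_sizes = c(dm_chr1 = 20000),
                       gc_content = 0.4,
                       n_sites_per_class = 25,
                       enrichment_fold = 20,
                       frag_len_mean = 150,
                       frag_len_sd = 30,
                       library_size = 100000,
                       spike_fraction = 0.05,
                       mung_bean_factor = 0.15) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = chrom_sizes,
    spike_chrom_sizes = spike_chrom_sizes,
    gc_content = gc_content,
    n_sites_per_class = as.integer(n_sites_per_class),
    enrichment_fold = enrichment_fold,
    frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd,
    library_size = as.integer(library_size),
    spike_fraction = spike_fraction,
    mung_bean_factor = mung_bean_factor
  )
  stopifnot(
    all(cfg$chrom_sizes > 0), all(cfg$spike_chrom_sizes > 0),
    cfg$gc_content > 0, cfg$gc_content < 1,
    cfg$n_sites_per_class >= 0,
    cfg$enrichment_fold >= 1,
    cfg$library_size > 0,
    cfg$spike_fraction >= 0, cfg$spike_fraction < 1,
    cfg$mung_bean_factor >= 0, cfg$mung_bean_factor <= 1
  )
  class(cfg) <- "sim_config"
  cfg
}

# i.i.d. background with no run of >= 3 G or >= 3 C: offending bases are
# redrawn until the sequence is clean (converges in a handful of rounds).
sample_background <- function(n, gc_content) {
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  x <- sample(sim_letters, n, replace = TRUE, prob = probs)
  if (n >= 3) {
    repeat {
      i <- 3:n
      bad <- i[x[i] == x[i - 1] & x[i] == x[i - 2] & x[i] %in% c("G", "C")]
      if (length(bad) == 0) break
      x[bad] <- sample(sim_letters, length(bad), replace = TRUE, prob = probs)
    }
  }
  paste(x, collapse = "")
}

loop_seq <- function(len) {
  paste(sample(c("A", "T"), len, replace = TRUE), collapse = "")
}

# Exact motif instance of one class. Loop bases are drawn from {A, T} so
# implants never create incidental G/C runs; the extended class forces its
# first loop to 8-12 bp so the canonical scanner cannot fire on it.
make_site_seq <- function(class_id, composition) {
  switch(class_id,
    canonical = {
      loops <- sample(1:7, 3, replace = TRUE)
      paste0(
        "GGG", loop_seq(loops[1]), "GGG", loop_seq(loops[2]),
        "GGG", loop_seq(loops[3]), "GGG"
      )
    },
    extended = {
      loops <- c(sample(8:12, 1), sample(1:12, 2, replace = TRUE))
      paste0(
        "GGG", loop_seq(loops[1]), "GGG", loop_seq(loops[2]),
        "GGG", loop_seq(loops[3]), "GGG"
      )
    },
    two_tetrad = {
      loops <- sample(1:12, 3, replace = TRUE)
      paste0(
        "GG", loop_seq(loops[1]), "GG", loop_seq(loops[2]),
        "GG", loop_seq(loops[3]), "GG"
      )
    },
    interstrand = {
      blocks <- ifelse(strsplit(composition, "")[[1]] == "A", "GGG", "CCC")
      loops <- sample(1:7, 3, replace = TRUE)
      paste0(
        blocks[1], loop_seq(loops[1]), blocks[2], loop_seq(loops[2]),
        blocks[3], loop_seq(loops[3]), blocks[4]
      )
    }
  )
}

#' Generate the synthetic genome with implanted PQS truth sites
#'
#' Builds G-run-suppressed background chromosomes and implants exact motif
#' instances of each PQS class at uniformly spaced, non-overlapping
#' positions, flanked by 1-bp non-G/C guard bases so each implant is
#' recovered at its exact coordinates. The spike-in genome is pure
#' background in its own chromosome namespace. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (tibble `name`/`sequence`),
#'   `spike` (idem), `truth` (match tibble with `class_id`, `composition`,
#'   `strand`, `matched_seq`) and `config`.
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    seqs <- lapply(config$chrom_sizes, function(n) sample_background(n, config$gc_content))
    spike_seqs <- lapply(config$spike_chrom_sizes, function(n) {
      sample_background(n, config$gc_content)
    })
    classes <- c("canonical", "extended", "two_tetrad", "interstrand")
    n_sites <- config$n_sites_per_class * length(classes)
    truth <- empty_matches()
    if (n_sites > 0) {
      non_aaaa <- setdiff(interstrand_compositions, "AAAA")
      site_class <- rep_len(classes, n_sites)
      comp_pool <- rep_len(non_aaaa, sum(site_class == "interstrand"))
      site_comp <- ifelse(site_class == "interstrand", NA, "AAAA")
      site_comp[site_class == "interstrand"] <- comp_pool
      sizes <- config$chrom_sizes
      cum <- cumsum(as.numeric(sizes))
      total <- cum[length(cum)]
      spacing <- total / n_sites
      rows <- vector("list", n_sites)
      for (k in seq_len(n_sites)) {
        site_seq <- make_site_seq(site_class[k], site_comp[k])
        len <- nchar(site_seq)
        if (spacing < len + 4) {
          abort("genome too small for the requested number of implant sites")
        }
        center <- (k - 0.5) * spacing
        ci <- which(center <= cum)[1]
        offset <- center - c(0, cum)[ci]
        ch <- names(sizes)[ci]
        start0 <- round(offset - len / 2) # 0-based implant start
        start0 <- max(1, min(start0, sizes[[ci]] - len - 1))
        # guard bases so background G/C runs cannot extend the implant
        s <- seqs[[ci]]
        substr(s, start0, start0) <- "T" # 1-based position start0 = bp before implant
        substr(s, start0 + 1, start0 + len) <- site_seq
        substr(s, start0 + len + 1, start0 + len + 1) <- "T"
        seqs[[ci]] <- s
        rows[[k]] <- tibble(
          chrom = ch, start = start0, end = start0 + len,
          strand = if (site_class[k] == "interstrand" && site_comp[k] != "AAAA") "." else "+",
          class_id = site_class[k], composition = site_comp[k],
          matched_seq = site_seq
        )
      }
      truth <- sort_matches(dplyr::bind_rows(rows))
    }
    list(
      genome = tibble(name = names(config$chrom_sizes), sequence = unlist(seqs, use.names = FALSE)),
      spike = tibble(
        name = names(config$spike_chrom_sizes),
        sequence = unlist(spike_seqs, use.names = FALSE)
      ),
      truth = truth,
      config = config
    )
  })
}

#' Simulate a CUT&Tag-like fragment library
#'
#' Draws `library_size` fragments: a `spike_fraction` share lands uniformly
#' on the spike-in genome; each remaining fragment is, with probability
#' `enrichment_fold / (enrichment_fold + 1)`, centered on a random truth
#' site with a Gaussian positional offset (sd = the fragment's length),
#' and otherwise placed uniformly on the sample genome. Fragment lengths
#' are Normal(`frag_len_mean`, `frag_len_sd`) truncated to [30, 1000].
#' In mung-bean mode the truth-site draw probability is multiplied by
#' `mung_bean_factor`, emulating nuclease depletion of G4 signal.
#'
#' @param sim Output of [make_genome()].
#' @param mung_bean Simulate the nuclease-pretreated library?
#' @param seed Seed; defaults to `config$seed + 1` (native) or
#'   `config$seed + 2` (mung bean) so the two conditions are independent
#'   but reproducible.
#' @return A tibble of fragments (`chrom`, `start`, `end`, `genome`
#'   = `"sample"` or `"spike"`).
#' @export
simulate_fragments <- function(sim, mung_bean = FALSE, seed = NULL) {
  config <- sim$config
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% (config$seed + if (mung_bean) 2L else 1L)
  p_truth <- config$enrichment_fold / (config$enrichment_fold + 1)
  if (mung_bean) p_truth <- p_truth * config$mung_bean_factor
  if (nrow(sim$truth) == 0 && config$enrichment_fold > 1) {
    abort("cannot simulate an enriched library without truth sites")
  }
  sizes <- config$chrom_sizes
  spike_sizes <- config$spike_chrom_sizes
  withr::with_seed(seed, {
    n <- config$library_size
    lens <- round(rnorm(n, config$frag_len_mean, config$frag_len_sd))
    while (any(bad <- lens < 30 | lens > 1000)) {
      lens[bad] <- round(rnorm(sum(bad), config$frag_len_mean, config$frag_len_sd))
    }
    is_spike <- runif(n) < config$spike_fraction
    chrom <- character(n)
    start <- numeric(n)
    # spike-in fragments: uniform on the spike genome
    ns <- sum(is_spike)
    if (ns > 0) {
      sc <- sample(names(spike_sizes), ns, replace = TRUE, prob = spike_sizes)
      sl <- pmin(lens[is_spike], spike_sizes[sc])
      chrom[is_spike] <- sc
      start[is_spike] <- floor(runif(ns) * (spike_sizes[sc] - sl + 1))
      lens[is_spike] <- sl
    }
    # sample-genome fragments: truth-site enriched over uniform background
    si <- which(!is_spike)
    at_truth <- runif(length(si)) < p_truth
    ti <- si[at_truth]
    if (length(ti) > 0) {
      pick <- sample(nrow(sim$truth), length(ti), replace = TRUE)
      centers <- floor((sim$truth$start + sim$truth$end) / 2)[pick] +
        round(rnorm(length(ti), 0, lens[ti]))
      chrom[ti] <- sim$truth$chrom[pick]
      start[ti] <- centers - floor(lens[ti] / 2)
    }
    bi <- si[!at_truth]
    if (length(bi) > 0) {
      bc <- sample(names(sizes), length(bi), replace = TRUE, prob = sizes)
      chrom[bi] <- bc
      start[bi] <- floor(runif(length(bi)) * (sizes[bc] - lens[bi] + 1))
    }
    # shift fragments fully inside their chromosome, preserving length
    all_sizes <- c(sizes, spike_sizes)
    start <- pmax(0, pmin(start, all_sizes[chrom] - lens))
    tibble(
      chrom = chrom,
      start = as.integer(start),
      end = as.integer(start + lens),
      genome = ifelse(is_spike, "spike", "sample")
    )
  })
}

fragment_sequences <- function(fragments, sim) {
  seqs <- setNames(
    c(sim$genome$sequence, sim$spike$sequence),
    c(sim$genome$name, sim$spike$name)
  )
  substring(seqs[fragments$chrom], fragments$start + 1, fragments$end)
}

write_bed3 <- function(x, path) {
  writeLines(
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end)),
    path
  )
  invisible(path)
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates the genome, truth annotation and native / mung-bean fragment
#' libraries for one configuration and writes them as plain-text files:
#' `genome.fa`, `spike.fa`, `truth.bed`, `fragments_native.bed`,
#' `fragments_mb.bed`, optionally `fragments.fastq`, and `config.json`.
#' Regenerating with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param fastq Also write the native fragment sequences as FASTQ?
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, config = sim_config(), fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config)
  native <- simulate_fragments(sim, mung_bean = FALSE)
  mb <- simulate_fragments(sim, mung_bean = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    spike = file.path(dir, "spike.fa"),
    truth = file.path(dir, "truth.bed"),
    fragments_native = file.path(dir, "fragments_native.bed"),
    fragments_mb = file.path(dir, "fragments_mb.bed"),
    config = file.path(dir, "config.json")
  )
  write_fasta(sim$genome, paths$genome)
  write_fasta(sim$spike, paths$spike)
  truth_bed <- sim$truth
  truth_bed$name <- paste(truth_bed$class_id, truth_bed$composition, sep = ":")
  truth_bed$score <- 0
  write_bed(truth_bed, paths$truth, kind = "bed6")
  write_bed3(native, paths$fragments_native)
  write_bed3(mb, paths$fragments_mb)
  if (fastq) {
    paths$fastq <- file.path(dir, "fragments.fastq")
    reads <- tibble(
      name = sprintf("frag_%d", seq_len(nrow(native))),
      sequence = fragment_sequences(native, sim)
    )
    write_fastq(reads, paths$fastq)
  }
  cfg <- unclass(config)
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  cfg$spike_chrom_sizes <- as.list(cfg$spike_chrom_sizes)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
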