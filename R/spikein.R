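# Exogenous spike-in (qCUT&Tag) scaling. A constant amount of tagmented
# spike-in chromatin (e.g. Drosophila S2 DNA at 5% of sample) is added to
# every library; tracks can then be rescaled relative to the constant
# spike-in content, which preserves genuine global signal differences that
# per-library normalizations such as RPGC erase.

#' Split fragments into sample and spike-in genomes
#'
#' Spike-in chromosomes are identified by a name prefix (e.g. `"dm_"`);
#' the partition is exhaustive and disjoint. An empty spike-in set is an
#' error because the scale factor would be undefined downstream.
#'
#' @param fragments Data frame of fragment placements.
#' @param spike_prefix Chromosome-name prefix of the spike-in genome.
#' @return A list with elements `sample` and `spike`, each a tibble of
#'   fragments.
#' @export
split_by_genome <- function(fragments, spike_prefix = "dm_") {
  validate_intervals(fragments, arg = "fragments")
  is_spike <- startsWith(fragments$chrom, spike_prefix)
  if (!any(is_spike)) {
    abort(sprintf(
      "no fragments on spike-in chromosomes (prefix '%s'); scale factor undefined",
      spike_prefix
    ))
  }
  list(
    sample = as_tibble(fragments[!is_spike, , drop = FALSE]),
    spike = as_tibble(fragments[is_spike, , drop = FALSE])
  )
}

#' Spike-in scale factors
#'
#' For each sample, `factor = spike_count(reference) / spike_count(sample)`
#' so the reference factor is 1 and, after scaling, spike-in totals are
#' equal across samples. Counts are deduplicated fragment counts on the
#' spike-in genome.
#'
#' @param spike_counts Named numeric vector of spike fragment counts, or a
#'   data frame with columns `sample` and `spike_count`.
#' @param reference Reference sample name; defaults to the first sample.
#' @return A `scale_factors` tibble with columns `sample`, `spike_count`,
#'   `factor`.
#' @export
scale_factors <- function(spike_counts, reference = NULL) {
  if (is.data.frame(spike_counts)) {
    stopifnot(all(c("sample", "spike_count") %in% names(spike_counts)))
    counts <- setNames(spike_counts$spike_count, spike_counts$sample)
  } else {
    if (is.null(names(spike_counts))) {
      abort("spike_counts must be named by sample")
    }
    counts <- spike_counts
  }
  if (any(counts <= 0)) {
    abort("all spike-in counts must be > 0")
  }
  reference <- reference %||% names(counts)[1]
  if (!reference %in% names(counts)) {
    abort(sprintf("reference sample '%s' not among samples", reference))
  }
  out <- tibble(
    sample = names(counts),
    spike_count = as.numeric(counts),
    factor = as.numeric(counts[[reference]]) / as.numeric(counts)
  )
  attr(out, "reference") <- reference
  class(out) <- c("scale_factors", class(out))
  out
}

#' Apply a spike-in scale factor to a track
#'
#' Multiplies every bin by `factor` and relabels the track `"spike"`.
#'
#' @param track A [binned_track].
#' @param factor Positive scale factor (one element of [scale_factors()]).
#' @return The rescaled [binned_track].
#' @export
apply_scaling <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort("factor must be a single positive number")
  }
  new_binned_track(
    track$chrom, track$start, track$end, track$value * factor,
    bin_size = track_bin_size(track), norm = "spike"
  )
}
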