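---
title: "Models and methods in g4kit: PQS scanning, CUT&Tag signal metrics and spike-in scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in g4kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4kit)
```

g4kit implements the computational layer of a G-quadruplex (G4) CUT&Tag
experiment: predicting putative G-quadruplex sequences (PQS) in a genome,
measuring the quality and enrichment of CUT&Tag fragment libraries,
normalizing coverage within and across samples, and testing whether peak
sets coincide more than chance allows. Everything is exercisable on a
self-contained synthetic study system, so the whole pipeline is testable
without any external download. This vignette explains the models, the
tunable parameters, and the design decisions — in the spirit of the methods
sections of the mature Bioconductor analysis packages.

## The PQS motif model

A G-quadruplex is a four-stranded structure of stacked guanine quartets;
its sequence signature is four runs of guanines separated by short loops.
g4kit scans four motif classes:

| class | pattern | loops | strand model |
|---|---|---|---|
| `canonical` | G₃₊ L G₃₊ L G₃₊ L G₃₊ | 1–7 bp | single strand |
| `extended` | G₃₊ L G₃₊ L G₃₊ L G₃₊ | 1–12 bp | single strand |
| `two_tetrad` | (G₂ L)₃₊ G₂ | 1–12 bp | single strand |
| `interstrand` | 4 blocks of A = G₃₊ or B = C₃₊ | 1–7 bp | both strands |

The inter-strand class captures G4s whose quartets are fed by G-runs on
*both* duplex strands: in reference-strand coordinates, an `A` block is a
G-run and a `B` block is a C-run (i.e. a G-run on the opposite strand).
Only the eight A-leading compositions `AAAA` … `ABBB` are scanned, because
a B-leading composition is the reverse-complement mirror of an A-leading
one and would double-count. `AAAA` is by definition the canonical
single-strand motif; the "non-canonical trans-strand" PQS set is the union
of the other seven compositions.

Two readings of the two-tetrad pattern deserve comment. The relaxed motif
is written as a G₂ run followed by a loop, the pair repeated at least three
times, then a closing G₂ — i.e. the PCRE `(?:G{2}[ACGT]{1,12}){3,}G{2}`.
A literal nesting of two quantifiers on the loop (`{1,12}{3,}`) is not a
valid expression, so the repeated-group reading is the one implemented,
and it is stated here prominently because it admits matches with more than
four G-runs (long chains of G₂ blocks are absorbed into one match).

Matching semantics:

* **Default scan** — leftmost, greedy, non-overlapping per strand: exactly
  what a regular-expression engine reports. This matters for counting:
  a run of six Gs is one G₃₊ block, not two, and two chained motif
  instances may merge into one match.
* **Overlapping scan** (`overlapping = TRUE`) — every *distinct interval*
  admitting at least one valid block/loop placement, computed by a
  memoized reachability search over run and loop placements. This mode
  makes containment relations exact (every canonical match interval is an
  extended placement, since 1–7 bp loops are a subset of 1–12 bp loops)
  and is what the test suite's independent brute-force oracle is compared
  against.
* **Loop alphabet** — `[ACGT]`, never `N`: an ambiguous base terminates
  both runs and loops, so gapped assembly stretches cannot inflate calls.
* **Minus strand** — intra-strand classes are scanned on the reverse
  complement and the coordinates mirrored back, i.e. the minus strand is
  read in its own 5′→3′ direction. The alternative — scanning a C-run
  pattern left-to-right in reference coordinates — finds the same
  candidate placements but can resolve *overlapping* candidates
  differently, because non-overlapping greedy selection depends on scan
  direction. Reading each strand 5′→3′ makes strand symmetry exact: the
  scan of a reverse-complemented chromosome is always the mirror image of
  the original. Inter-strand compositions are defined in reference-strand
  coordinates and scanned left-to-right; their mirror relation
  (`AAAB` ↔ `ABBB`) is exact up to the same selection caveat, which
  requires five or more interleaved G/C runs within loop range and is
  vanishingly rare outside adversarial constructions.

`pqs_coverage()` converts matches into a per-bin occupancy track (fraction
of bin base pairs under at least one match), `cpg_track()` emits one 2-bp
interval per CG dinucleotide as the CpG-density reference, and
`fraction_peaks_with_pqs()` reports how many peaks of a set contain any
PQS — the motif-validation statistic used when ranking peak callers.

## Peak-set statistics

* `top_n_by_score()` ranks by the integer BED column-5 peak-caller score
  (not the signal value), breaking ties by (chrom, start) so that
  "top 1000 peaks" is reproducible.
* `consensus_peaks()` defines high-confidence peaks as the base-pair
  intersection of the replicate peak unions — the segments supported by
  every replicate. Interval intersection tools admit a second reading
  ("whole peaks of replicate 1 that overlap all others"), which is
  available as `method = "first_overlap_all"`; the bp-intersection is the
  default because it is symmetric in the replicates and idempotent.
* `overlap_partition()` classifies peaks of two sets as shared or
  set-specific by ≥ 1 bp overlap, reporting counts from both sides plus a
  base-pair Jaccard index.
* `annotate_by_states()` assigns each peak to the chromatin-state segment
  (e.g. a ChromHMM segmentation) with which it shares the most base
  pairs; ties go to the state that appears first in the segmentation
  file, and peaks in annotation gaps are reported as `unannotated` and
  excluded from the fractions.
* `window_regions()` builds the ±flank windows (default use: ±3 kb around
  transcription start sites or enhancer centers) with clipping at
  chromosome ends and deduplication of identical windows.

### The randomization overlap test

`randomized_overlap_test()` asks whether set A overlaps set B more than
expected for randomly placed intervals. The statistic is the number of A
intervals overlapping any B interval. The null model relocates every B
interval uniformly within its own chromosome, preserving lengths and
forbidding self-overlap (rejection sampling); chromosome identity is kept
because chromosome-level composition differences are not what the test
should detect. The empirical p-value uses the add-one correction

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_{\text{iter}} + 1},$$

which is never exactly zero and is uniformly distributed on a discrete
grid under the null (up to conservative mass from ties in the integer
statistic). The test suite verifies this calibration: over 200 independent
data-set pairs with 199 randomizations each, the p-values pass a
Kolmogorov–Smirnov uniformity check at α = 0.01. When several pairs are
tested, apply `p.adjust(..., method = "BH")` to the returned p-values.

## Signal metrics and normalization

**Coverage and RPGC.** `coverage_track()` computes per-bin mean per-bp
fragment depth at a default 5 bp resolution (the resolution used for
browser-style tracks). RPGC ("reads per genome coverage", 1× coverage)
multiplies by `effective_genome_size / Σ fragment lengths`, making the
genome-wide mean exactly 1; the effective genome size is a required,
explicit argument — there is no hidden species table. Fragments, not
single-end reads, are the unit throughout, because tagmentation data is
paired-end by construction; `read_fragments_sam()` adapts proper pairs if
alignment output is the starting point.

**FriP.** `frip()` is the fraction of fragments overlapping ≥ 1 bp of any
peak — the standard signal-to-noise summary. It is a per-fragment test,
hence invariant under merging of the peak set.

**Fingerprint.** `fingerprint()` ranks genome bins by ascending fragment
count and accumulates the signal share, the classic enrichment diagnostic:
a uniform library traces the diagonal, a sharply enriched one stays near
zero until the last bins. `glance()` on the curve reports the area under
it and the signal share of the top 1% of bins.

**Telomeric content.** `telomeric_fraction()` counts reads containing at
least `min_tandem` consecutive copies of `TTAGGG` (or its reverse
complement `CCCTAA`, making the estimate orientation-invariant). Tandem
string matching stands in for alignment against a telomeric repeat
pseudogenome; `min_tandem = 3` (18 bp of exact repeat) approximates a
short-read aligner's seed requirement. This is an approximation: reads
with sequencing errors inside every repeat window are missed, and
interspersed single units do not count.

**Toy enrichment caller.** `call_enriched_bins()` exists so the synthetic
pipeline closes without an external peak caller; it is deliberately not a
reimplementation of a Poisson local-background model. Bins above
`mean + z·sd` *of the nonzero bins* (sparse tagmentation leaves most bins
empty; a global sd would be deflated) are merged across gaps of at most
`merge_gap` bins, and regions with at least `min_run` qualifying bins are
reported with a score equal to 10 × fold-enrichment over the genome mean,
capped at 1000. In the end-to-end pipeline a merge gap of 10 bins (50 bp
at the default bin size) is used so that stochastic dips inside one
enriched site do not split it into shoulder peaks.

## Spike-in (qCUT&Tag) scaling

Per-library normalizations such as RPGC force every sample to the same
mean and therefore erase genuine global differences in signal abundance.
The quantitative variant of the assay adds a constant amount of tagmented
exogenous chromatin (e.g. *Drosophila* S2, 5% of sample) to every library;
since the spike-in content is constant, the number of fragments mapping to
the spike-in genome is inversely proportional to the sample material being
sequenced, and

$$\text{factor}_s = \frac{\text{spike count}_{\text{reference}}}{\text{spike count}_s}$$

rescales tracks onto a common absolute scale (`scale_factors()`,
`apply_scaling()`). Factors are defined on deduplicated fragment counts
assigned to the spike-in genome by chromosome-name prefix
(`split_by_genome()`), not on DNA mass — the wet-lab mixing ratio is an
upstream constant that the simulator emulates with its spike fraction.
The acceptance suite reproduces the method's rationale in simulation: a
2× global signal difference with constant spike content is preserved by
spike scaling and erased by RPGC.

## The synthetic study system

`sim_config()` fixes the study conditions; its defaults are the conditions
under which all acceptance properties are evaluated:

* **Genome** — three 100-kb sample chromosomes plus one 20-kb spike-in
  chromosome in its own namespace (`dm_chr1`), background drawn i.i.d. at
  40% GC with *G-run suppression*: no background run of ≥ 3 G or ≥ 3 C.
  Suppression is implemented by redrawing offending bases until the
  sequence is clean, which preserves the i.i.d. marginal up to the run
  constraint and runs in linear time. Suppression is what makes truth and
  scanner output coincide: without it, incidental background PQS would be
  indistinguishable from implants.
* **Implants** — 25 sites per class for the four classes (the inter-strand
  sites cycle through the seven non-`AAAA` compositions), uniformly
  spaced and non-overlapping, each an exact motif instance with loop bases
  drawn from {A, T} and 1-bp non-G/C guard bases at both ends so that no
  background base can extend a match. Extended-class implants force one
  loop of 8–12 bp so the canonical scanner cannot fire on them; canonical
  truth intervals are therefore recovered *exactly*, and canonical false
  positives on the background are structurally zero. Two-tetrad implants
  are recovered by overlap rather than exact coordinates, because G₂ runs
  legitimately occur in the suppressed background and the greedy scan may
  chain through them.
* **Fragments** — `library_size` = 100,000 per library; each fragment is
  spike-in with probability 0.05 (uniform placement on the spike genome),
  otherwise truth-site-derived with probability fold/(fold + 1) at the
  default `enrichment_fold` = 20 (centered on a random truth site with a
  Gaussian offset whose sd equals the fragment's length), otherwise
  uniform background. Lengths are Normal(150, 30) truncated to
  [30, 1000] bp. This is intentionally a minimal enrichment model:
  Tn5 insertion sequence bias, nucleosome phasing, replicate-level
  biological variability and read errors are out of scope, so passing
  tests demonstrate the *computational* contracts, not robustness to
  those real-data features.
* **Mung-bean mode** — single-strand-specific nuclease pretreatment
  digests the single-stranded regions that accompany G4 structures and
  should deplete true G4 signal while leaving random background
  tagmentation; the simulator multiplies the truth-site draw probability
  by `mung_bean_factor` = 0.15. The factor is a simulator parameter
  chosen to represent a strong but incomplete depletion; with it, the
  expected truth-window FriP drops from
  $p + (1-p)w \approx 0.97$ to $0.15p + (1-0.15p)w \approx 0.47$
  (with $p = 20/21$ and window fraction $w = 1/3$), a ≈ 51% reduction —
  the direction and magnitude the acceptance suite checks.

One arithmetic consequence of these defaults is worth stating: the 100
truth sites with ±500 bp windows cover one third of the 300-kb sample
genome, so truth-window FriP is bounded by 1 and can exceed the window
base-pair fraction by at most a factor of 3; the observed enrichment ratio
at default parameters is ≈ 2.9×. The unit tests therefore assert the FriP
value predicted by the enrichment arithmetic (±0.02) rather than an
arbitrary fold threshold.

Determinism: every generator function derives its randomness from
`config$seed` (the fragment simulator offsets the seed by +1 for native
and +2 for mung-bean libraries so the two conditions are independent but
individually reproducible), and `write_fixture_bundle()` output is
byte-identical across regenerations with the same configuration.

## Numerical and interface conventions

* All coordinates are 0-based half-open everywhere inside the package
  (BED native); 1-based external conventions are converted at the I/O
  boundary only. Chromosome names match by exact string equality — no
  `chr` aliasing — because silent aliasing corrupts overlap counts.
* `read_bed()` reports the offending line number for coordinate errors;
  `-1` in narrowPeak p/q columns becomes `NA`; write-then-read is the
  identity on every field a format represents.
* Degenerate inputs fail loudly where a statistic is undefined (FriP of
  an empty fragment set, fraction of an empty peak set, RPGC of an empty
  library, scale factors with a zero spike count) and degrade gracefully
  where a value exists (empty blacklist, empty match set, constant track
  → no peaks).
* Tibbles in, tibbles out: every user-facing function takes a plain data
  frame first, so pipelines compose with the pipe; interval arithmetic is
  delegated to GenomicRanges/IRanges internally. Result objects
  (`fingerprint_curve`, `overlap_permutation`, `state_annotation`,
  `binned_track`, `profile_matrix`) carry `autoplot()` methods and, where
  a model-like summary makes sense, broom-style `tidy()`/`glance()`
  methods.

## Problem sizes used in the checks

The test suite validates the scanner against an independent brute-force
placement oracle on 50 random 10-kb sequences per class, runs the
calibration study at 200 data-set pairs × 199 randomizations, and runs all
simulation-based checks at the default 100,000-fragment library on the
320-kb synthetic genome — sizes at which every property above is measured
in seconds while keeping the binomial sampling error of the spike-factor
recovery (≈ 1.5%) well inside its 3% check.

## Known limitations

* The scanner scores nothing: no thermodynamic stability (G4Hunter- or
  pqsfinder-style scores), no bulged or imperfect runs beyond the
  two-tetrad relaxation, no RNA G4s.
* The toy caller is not a peak caller for real data; consume MACS2
  narrowPeak files via `read_bed(kind = "narrowPeak")` for real analyses.
* The randomization null keeps intervals on their chromosome and uniform;
  GC- or accessibility-matched null models are out of scope.
* Telomeric content by tandem matching undercounts error-rich reads
  relative to alignment-based estimation.
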