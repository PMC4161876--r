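---
title: "Screening ectopic olfactory receptor expression from CAGE data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ectopic olfactory receptor expression from CAGE data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectocage)
library(dplyr)
```

## The problem

Olfactory receptor (OR) genes, the largest mammalian gene family, are
canonically expressed in olfactory sensory neurons, where CAGE (Cap Analysis
of Gene Expression) profiling shows they use *sharp* promoters — a single
dominant transcription start site (TSS) — in contrast to the broad
initiation (~100 bp of dispersed start sites) typical of most mammalian
promoters. A recurring question is whether particular ORs are also
transcribed *ectopically*, in tissues such as the substantia nigra, and if
so from which promoters.

Because deep CAGE data usually exist for one species' olfactory epithelium
but the tissue of interest is assayed in another species, the screen is
cross-species: take the TSS catalogue of the source genome, project a fixed
window around each TSS onto the target genome through a whole-genome
alignment, and ask whether CAGE tags in target-tissue libraries accumulate
in the projected windows. `ectocage` implements that screen end to end,
together with the downstream quantifications such a study leans on:
maximum-parsimony homology analysis of receptor protein sequences, ΔΔCt
relative qPCR quantification, and ratiometric Ca²⁺ response scoring.

Every stage is exercisable on synthetic data with planted ground truth, so
the pipeline is testable without any external download.

## Pipeline model

1. **Windows.** For each source-genome TSS, a window
   `[tss − w/2, tss + w/2)` with `w = 200` bp (`build_tss_windows()`). All
   internal coordinates are 0-based half-open; conversions happen only at
   I/O boundaries.
2. **Lift.** Each window is mapped through the single highest-scoring UCSC
   chain overlapping it (`lift_intervals()`). Each base maps through the
   chain's aligned blocks; the lifted window is the plus-strand hull of the
   mapped bases. Outcomes are statuses, not errors: `mapped` (fraction of
   mapped bases ≥ `min_match`, default 0.95 — the conventional lift-over
   threshold), `low_coverage`, `split` (internal target gap beyond
   tolerance), `unmapped`. When several windows lift to *identical* target
   coordinates, the first in input order is kept and later ones are
   discarded and reported (`lift_windows_dedup()`) — the treatment of
   receptor pairs so similar that their promoter windows align to the same
   place.
3. **Quantify.** Tag counts are 5′-end counts: a CTSS record contributes to
   an interval when its position lies in `[start, end)`. Window counting is
   strand-blind by default; whole-locus counting (`sum5end()`) is
   strand-matched. TPM is `count / library_total × 10⁶`, so TPM over all
   positions of a library sums to one million.
4. **Screen.** Pooled counts over an explicit library subset feed two
   filters: strictly above the third quartile of all screened windows, and
   strictly above an absolute cutoff (default 100 tags). Windows not
   corresponding to any receptor locus are artifacts; the dominant TSS of
   each remaining window is classified relative to its locus (at the
   annotated start, upstream-proximal, far upstream — discarded, intragenic,
   at the 3′ end). Verdicts: `discarded_far_upstream` ≻ `artifact` ≻
   `filtered` ≻ `candidate`.
5. **Shape.** A promoter profile is summarised by its dominant-position
   fraction and the 10–90% positional spread of the cumulative tag
   distribution (`iq_width`). `sharp` means `iq_width ≤ 4` bp *or*
   dominance ≥ 0.5; `broad` otherwise; below 20 tags no call is made
   (`undetermined`). The thresholds follow the sharp/broad promoter
   literature; all three are exposed.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `width` (windows) | 200 | bp | promoter window projected across genomes |
| `min_match` | 0.95 | fraction | conventional lift-over minimum match |
| `gap_tolerance` | `width·(1−min_match)` | bp | internal target gap before a lift is `split`; fix it to decouple split calls from `min_match` |
| `abs_cutoff` | 100 | tags | absolute evidence floor of the screen |
| `sharp_width` | 4 | bp | max 10–90% spread for a sharp call |
| `sharp_dominance` | 0.5 | fraction | dominant-TSS fraction for a sharp call |
| `min_tags_for_shape` | 20 | tags | below this, shape is `undetermined` |
| `at_start_tol` | 50 | bp | "at the annotated start" tolerance |
| `upstream_min/max` | 500 / 2000 | bp | upstream-proximal band |
| `far_upstream` | 5000 | bp | beyond this upstream, discarded |
| `three_prime_tol` | 500 | bp | "at the 3′ end" tolerance |
| `artifact_max_distance` | 10000 | bp | window-to-locus radius for artifact and locus assignment |
| responder `threshold` | 20 | % ΔR/R₀ | Ca²⁺ responder criterion (a declared convention) |
| responder `max_latency` | 30 | s | onset must follow the stimulus promptly |

The quartile uses linear interpolation between order statistics
(`stats::quantile` type 7) by default, switchable to nearest rank (type 1);
both filters use strict inequalities, mirroring "more than". The library
subset pooled in the screen is a **required** argument: pooling all atlas
libraries versus only the tissue of interest changes the quartile threshold,
and that choice should never be implicit.

## Design choices where the design was open

* **Artifact calls and upstream promoters.** An artifact is a window whose
  tags cannot be attributed to any receptor locus. A strict overlap rule
  contradicts the TSS-position taxonomy, which classifies dominant TSSs up
  to and beyond 5000 bp upstream — positions a 200-bp window cannot overlap.
  `flag_artifacts()` therefore defaults to strict overlap as a primitive,
  but `run_screen()` assigns each window the nearest gene locus within
  `artifact_max_distance` (default 10 kb, comfortably containing the
  far-upstream boundary) and flags as artifacts only windows with no gene
  locus inside that radius — or only pseudogene loci, where spurious tag
  pile-ups are a known failure mode (`pseudogene_is_artifact = TRUE`). The
  mechanised artifact call stands in for what was historically a manual
  inspection step, and is recorded as such in the run metadata.
* **Class evaluation order.** `three_prime_end` is evaluated before
  `intragenic`: a TSS at the 3′ end necessarily lies inside the locus body,
  so the reverse order would make the 3′-end class unreachable. The
  unannotated band between `at_start_tol` and `upstream_min` falls to
  `unclassified` rather than being silently absorbed by a neighbour class.
* **Split lifts.** Whether split mappings should survive the screen is
  genuinely arguable; they are excluded by default and admitted with
  `keep_split = TRUE`, with the gap tolerance exposed separately from
  `min_match` so the two axes can be controlled independently.
* **Close-neighbour-interchange neighbourhood.** `cni_search()` examines all
  topologies within topological distance 4 of the current tree — up to two
  nearest-neighbour interchanges, the classical close-neighbour set — with
  single interchanges scanned first and the first strict improvement
  accepted (search level 0). A plain single-NNI neighbourhood was measurably
  insufficient: on random 6–7-taxon alignments about 2% of searches ended in
  single-NNI local optima that persisted across all ten random-addition
  restarts, while the distance-4 neighbourhood matched exhaustive
  enumeration on 600 independent instances. Random addition inserts taxa in
  seeded random order, each on the first edge attaining the minimum Fitch
  score of the partial tree.
* **Fitch on the basal trichotomy.** Unrooted binary trees carry one
  degree-3 node; folding its children sequentially equals rooting the tree
  along any edge, so no explicit re-rooting is needed. Scores are invariant
  under re-rooting and leaf permutation (property-tested).
* **Percent identity.** Global alignment with match +1, mismatch 0, linear
  gap −1; identity is matches over aligned columns *excluding terminal-gap
  columns*, so length overhangs do not dilute the value. Published pairwise
  identities for receptor homologs depend on unstated alignment schemes and
  are treated as approximate external references, not test fixtures.
* **ΔΔCt conventions.** Technical replicates are collapsed by mean Ct;
  multiple reference genes enter as the arithmetic mean of their Ct values
  (the geometric mean on the expression scale); fold change is `2^(−ΔΔCt)`,
  assuming perfect doubling per cycle. Group-level statistics (t-tests,
  ANOVA) are deliberately delegated to base R.
* **Ca²⁺ baseline.** `R₀` defaults to the mean ratio over all pre-stimulus
  samples, which is robust to channel noise; `r0_at_t0 = TRUE` restores the
  literal ratio-at-time-zero definition. The responder criterion (peak
  ΔR/R₀ ≥ 20% with onset within 30 s) is a declared convention of this
  package — no community standard exists — and both values are echoed in
  output metadata. Duration is measured between half-peak crossings.

## What the synthetic data emulate — and what they do not

`simulation_config()` fixes the study conditions; the generators are fully
deterministic given its seed.

* `simulate_genomes()` lays out receptor loci on a source genome and
  homologous loci (plus pseudogene decoys) on a target genome, connected by
  multi-block chains with an aligned 20-bp indel outside the promoter
  window and a configurable fraction of strand flips. Three engineered
  window pairs lift to identical target coordinates (`collision_pairs = 3`),
  produced by pointing the second member's chain at the first member's
  target window; a configurable receptor subset has no chain at all.
* `simulate_ctss()` draws one multinomial of `depth_per_library` tags per
  library over planted promoters (sharp: 92% of promoter weight at the
  dominant TSS; broad: uniform over `broad_width = 100` bp into the locus),
  pseudogene pile-ups (30 bp, in a configurable subset of libraries),
  uniform background over annotated loci, and a bulk remainder bin standing
  in for the rest of the transcriptome. The bulk bin makes each library's
  total exactly its depth, so planted TPM expectations are exact; when
  nothing is planted and the background rate is zero the libraries are
  empty instead. Planted expression levels default to 1500–4000 TPM
  (log-uniform), far enough above the 100-tag cutoff that recovery failures
  indicate pipeline defects rather than sampling noise.
* `simulate_ct_table()` plants per-gene fold changes (default 4, 1, 0.25)
  as Ct shifts of −log₂(fold) in test samples, with Gaussian per-well noise
  (SD 0.2 cycles) over reference and target genes, calibrator and test
  samples, and technical duplicates.
* `simulate_calcium()` draws responders at a fraction of 11/37 with
  amplitudes from Normal(80.5, 26) % ΔR/R₀, onset within 10 s of stimulus,
  half-peak durations of 1–2 min, sampled every 3 s; Gaussian noise is
  added to each fluorescence channel *before* ratioing, so ratiometric
  artifacts arise naturally.

What passing tests on these data do **not** show: real CAGE backgrounds are
not uniform (the decoy pile-up shape is an explicit stand-in — no noise
model for spurious accumulation near pseudogenes is published); real chains
contain nested inversions and paralogous alignments the generator does not
attempt; promoter shapes in vivo form a continuum rather than a two-class
mixture; and the qPCR model omits amplification-efficiency deviations from
2. Recovery of planted truth validates the *machinery*, not the biological
thresholds.

## Numerical choices and degenerate inputs

* Quartiles: type 7 (default) or type 1; with fewer than four windows the
  quartile filter refuses to run.
* Dominant TSS ties break to the smallest coordinate; no peak decomposition
  is attempted (deliberately out of scope).
* `iq_width` is the distance between the first positions where the
  cumulative tag distribution reaches 10% and 90%; a single-position
  promoter has width 0.
* Empty CTSS files parse to empty libraries; zero-tag intervals profile as
  `total_tags = 0` with `NA` statistics; TPM refuses a zero denominator;
  heat-map rescaling refuses an all-zero matrix; population summaries refuse
  an empty population.
* Collision identity requires exact `(chrom, start, end, strand)` equality
  of the lifted windows.
* All chain coordinates are converted to plus-strand half-open intervals at
  parse time; `write_chain()` inverts the conversion, and writing then
  reading a chain file is byte-stable.

## Problem sizes in the test-suite experiments

The packaged experiments use desk-scale sizes chosen to make statistical
assertions sharp: 550 random intervals against a per-base brute-force lift
oracle; 20 seeded screen replicates of 24 receptors + 5 decoys across 3
libraries of 10⁵ tags; 200 loci for shape recovery at ≥ 50 tags per locus;
100 random 6–7-taxon alignments against full 105/945-topology enumeration;
50 seeded qPCR panels; 20 seeded Ca²⁺ populations of 37 traces. A planted
4.29-TPM sharp promoter in a 10⁶-tag library ties the TPM arithmetic to a
realistic single-receptor expression level.

## Known limitations

* One chain per window: no multi-chain stitching, by design — the screen
  wants one putative promoter per receptor.
* The screen's thresholds (quartile, 100 tags) are faithful to their
  origin, including their arbitrariness; the package reports both filter
  flags so users can re-draw the line.
* Parsimony search is heuristic; equality with exhaustive enumeration is
  only guaranteed where enumeration is feasible (≤ ~9 taxa), which the
  acceptance experiments exploit.
* `percent_identity()` reports a single optimal alignment's identity;
  co-optimal alignments can differ in identity by small amounts.
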