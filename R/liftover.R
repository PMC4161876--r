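#' Build promoter windows centered on TSS positions
#'
#' For each annotated transcription start site, builds the fixed-width
#' promoter window `[tss - width/2, tss + width/2)` on the source genome,
#' clipped at position 0. The default width of 200 bp is the window used to
#' project OR promoter regions across genomes.
#'
#' @param tss_table Tibble with columns `id`, `chrom`, `tss` and optionally
#'   `strand` (defaults to `+`).
#' @param width Window width in bp; must be even and >= 2.
#' @return A tibble of windows: `id`, `chrom`, `start`, `end`, `strand`, one
#'   row per input TSS, ids preserved in input order.
#' @export
build_tss_windows <- function(tss_table, width = 200L) {
  check_scalar_number(width, "width", min = 2)
  if (width %% 2 != 0) abort("`width` must be even")
  stopifnot(all(c("id", "chrom", "tss") %in% names(tss_table)))
  half <- as.integer(width / 2)
  tibble(
    id = tss_table$id,
    chrom = tss_table$chrom,
    start = pmax(0L, as.integer(tss_table$tss) - half),
    end = as.integer(tss_table$tss) + half,
    strand = if ("strand" %in% names(tss_table)) tss_table$strand else "+"
  )
}

# Map one interval through one chain's blocks. Returns list(n_mapped, lo, hi)
# of mapped-base count and the plus-strand hull of mapped target positions.
map_through_blocks <- function(start, end, blocks, tgt_strand) {
  ov_s <- pmax(start, blocks$src_start)
  ov_e <- pmin(end, blocks$src_end)
  keep <- ov_e > ov_s
  if (!any(keep)) return(list(n_mapped = 0L, lo = NA_real_, hi = NA_real_))
  b <- blocks[keep, , drop = FALSE]
  ov_s <- ov_s[keep]; ov_e <- ov_e[keep]
  if (tgt_strand == "+") {
    lo <- b$tgt_start + (ov_s - b$src_start)
    hi <- b$tgt_start + (ov_e - b$src_start)
  } else {
    lo <- b$tgt_end - (ov_e - b$src_start)
    hi <- b$tgt_end - (ov_s - b$src_start)
  }
  list(n_mapped = sum(ov_e - ov_s), lo = min(lo), hi = max(hi))
}

#' Lift genomic intervals through a chain set
#'
#' Maps each interval from the source genome to the target genome through the
#' single highest-scoring chain overlapping it (no multi-chain stitching).
#' Every base is mapped through the chain's aligned blocks; the target
#' interval is the plus-strand hull of the mapped bases. Outcomes are reported
#' as statuses, never errors:
#'
#' * `mapped` — mapped fraction >= `min_match` and internal target gaps within
#'   tolerance;
#' * `low_coverage` — some bases mapped, but fewer than `min_match`;
#' * `split` — mapped bases land non-contiguously on the target, with an
#'   internal gap exceeding `gap_tolerance`;
#' * `unmapped` — no overlapping chain, or no base falls in an aligned block.
#'
#' @param intervals Tibble with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param chains A [chain_set()].
#' @param min_match Minimum fraction of interval bases that must map
#'   (default 0.95, the conventional lift-over default).
#' @param gap_tolerance Maximum internal target-side gap (bp) tolerated inside
#'   a mapped interval before it is called `split`. Default `NULL` uses each
#'   interval's unmapped allowance, `floor(width * (1 - min_match))`. Pass a
#'   fixed number to make split calls independent of `min_match`.
#' @return A tibble: `id`, `chrom`, `start`, `end`, `strand`, `status`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `tgt_strand`, `chain_id`,
#'   `mapped_fraction`. Target coordinates are reported for every status with
#'   at least one mapped base; only `status == "mapped"` passes the filters
#'   downstream.
#' @export
lift_intervals <- function(intervals, chains, min_match = 0.95,
                           gap_tolerance = NULL) {
  stopifnot(inherits(chains, "chain_set"))
  check_scalar_number(min_match, "min_match", min = 0, max = 1)
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(intervals)))
  check_interval(intervals$chrom, intervals$start, intervals$end)
  strand_in <- if ("strand" %in% names(intervals)) intervals$strand else
    rep("+", nrow(intervals))

  blocks_by_chain <- split(chains$blocks, chains$blocks$chain_id)
  ctab <- chains$chains

  n <- nrow(intervals)
  status <- character(n)
  tgt_chrom <- rep(NA_character_, n); tgt_strand <- rep(NA_character_, n)
  tgt_start <- rep(NA_real_, n); tgt_end <- rep(NA_real_, n)
  chain_id <- rep(NA_integer_, n); frac <- numeric(n)

  for (i in seq_len(n)) {
    s <- intervals$start[i]; e <- intervals$end[i]; width <- e - s
    cand <- ctab[ctab$src_chrom == intervals$chrom[i] &
                   ctab$src_start < e & ctab$src_end > s, , drop = FALSE]
    if (nrow(cand) == 0L) { status[i] <- "unmapped"; next }
    cand <- cand[order(-cand$score, cand$chain_id), , drop = FALSE]
    best <- cand[1L, ]
    hit <- map_through_blocks(
      s, e, blocks_by_chain[[as.character(best$chain_id)]], best$tgt_strand
    )
    if (hit$n_mapped == 0L) { status[i] <- "unmapped"; next }
    chain_id[i] <- best$chain_id
    tgt_chrom[i] <- best$tgt_chrom
    tgt_strand[i] <- if (strand_in[i] == "+") best$tgt_strand else
      if (best$tgt_strand == "+") "-" else "+"
    tgt_start[i] <- hit$lo; tgt_end[i] <- hit$hi
    frac[i] <- hit$n_mapped / width
    tol <- gap_tolerance %||% floor(width * (1 - min_match))
    internal_gap <- (hit$hi - hit$lo) - hit$n_mapped
    status[i] <- if (internal_gap > tol) "split"
      else if (frac[i] < min_match) "low_coverage"
      else "mapped"
  }

  tibble(
    id = intervals$id, chrom = intervals$chrom,
    start = intervals$start, end = intervals$end, strand = strand_in,
    status = status, tgt_chrom = tgt_chrom, tgt_start = tgt_start,
    tgt_end = tgt_end, tgt_strand = tgt_strand, chain_id = chain_id,
    mapped_fraction = frac
  )
}

#' Lift promoter windows and discard duplicate target coordinates
#'
#' Lifts a set of TSS windows with [lift_intervals()] and resolves lift
#' collisions: when several windows map to exactly the same target
#' coordinates (`chrom`, `start`, `end`, `strand` all equal), the
#' first-in-input-order window is kept and every subsequent member of the
#' group is discarded and reported — the rule applied to the three receptor
#' pairs whose 200-bp windows produced identical lifted coordinates.
#'
#' @inheritParams lift_intervals
#' @param windows Window tibble from [build_tss_windows()].
#' @return A list with elements `results` (the [lift_intervals()] tibble plus
#'   a logical `discarded` column) and `discarded` (character vector of
#'   discarded window ids, in input order).
#' @export
lift_windows_dedup <- function(windows, chains, min_match = 0.95,
                               gap_tolerance = NULL) {
  res <- lift_intervals(windows, chains, min_match, gap_tolerance)
  key <- ifelse(
    res$status == "mapped",
    paste(res$tgt_chrom, res$tgt_start, res$tgt_end, res$tgt_strand),
    NA_character_
  )
  res$discarded <- duplicated(key, incomparables = NA)
  list(results = res, discarded = res$id[res$discarded])
}
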