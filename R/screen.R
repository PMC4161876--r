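#' Pool per-library tag counts
#'
#' Sums window tag counts over an explicit library subset. The subset is a
#' required choice, not a default: which libraries feed the screen (e.g. all
#' atlas libraries versus the substantia-nigra libraries alone) changes the
#' quartile threshold and must be stated.
#'
#' @param counts Tibble `id`, `library`, `count` from [count_tags()].
#' @param library_subset Character vector of library ids to pool; must be
#'   non-empty and present in `counts`.
#' @return A tibble `id`, `pooled_count`.
#' @export
pool_counts <- function(counts, library_subset) {
  if (length(library_subset) == 0L) abort("`library_subset` must be non-empty")
  missing <- setdiff(library_subset, unique(counts$library))
  if (length(missing) > 0L) {
    abort(sprintf("libraries not in counts: %s", paste(missing, collapse = ", ")))
  }
  counts |>
    filter(.data$library %in% library_subset) |>
    group_by(id = .data$id) |>
    summarise(pooled_count = sum(.data$count), .groups = "drop")
}

#' Third-quartile filter
#'
#' Flags windows whose pooled tag count strictly exceeds the third quartile
#' of the pooled counts over all windows in the screen.
#'
#' @param pooled_counts Numeric vector of pooled counts (>= 4 values).
#' @param method Percentile method: `"linear"` (interpolation between order
#'   statistics, [stats::quantile()] type 7) or `"nearest"` (nearest rank,
#'   type 1).
#' @return A list with `q3` (the quartile value) and `flags` (logical,
#'   `pooled_count > q3`).
#' @export
quartile_filter <- function(pooled_counts, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(pooled_counts) < 4L) {
    abort("quartile filter needs at least 4 windows")
  }
  q3 <- unname(quantile(
    pooled_counts, probs = 0.75,
    type = if (method == "linear") 7L else 1L
  ))
  list(q3 = q3, flags = pooled_counts > q3)
}

#' Absolute tag-count cutoff filter
#'
#' Flags windows with strictly more than `abs_cutoff` pooled tags ("more
#' than" is strict: a window exactly at the cutoff fails). The default of 100
#' tags is the arbitrary visual-inspection cutoff of the original screen.
#'
#' @param pooled_counts Numeric vector of pooled counts.
#' @param abs_cutoff Non-negative cutoff (default 100).
#' @return Logical vector.
#' @export
absolute_cutoff_filter <- function(pooled_counts, abs_cutoff = 100) {
  check_scalar_number(abs_cutoff, "abs_cutoff", min = 0)
  pooled_counts > abs_cutoff
}

#' Flag artifact windows
#'
#' A lifted window whose tags cannot be assigned to any receptor locus is an
#' artifact: it overlaps no annotated locus of the screened gene family, or —
#' when `pseudogene_is_artifact` — only pseudogene loci, where spurious tag
#' accumulation is common.
#'
#' @param windows Tibble with target coordinates `tgt_chrom`, `tgt_start`,
#'   `tgt_end` (rows without coordinates are flagged).
#' @param annotation Target-genome annotation from [read_bed()].
#' @param pseudogene_is_artifact Treat windows near only pseudogene loci as
#'   artifacts (default `TRUE`).
#' @param max_distance Maximum gap (bp) between window and locus for the
#'   window to count as corresponding to that locus. The default 0 requires
#'   overlap; [run_screen()] widens it so that legitimate upstream promoter
#'   windows, which need not overlap their gene body, are not flagged.
#' @return Logical vector, one per row of `windows`.
#' @export
flag_artifacts <- function(windows, annotation, pseudogene_is_artifact = TRUE,
                           max_distance = 0) {
  genes <- annotation |>
    filter(if (pseudogene_is_artifact) .data$biotype == "gene" else TRUE)
  vapply(seq_len(nrow(windows)), function(i) {
    if (is.na(windows$tgt_chrom[i])) return(TRUE)
    gap <- pmax(
      genes$start - windows$tgt_end[i],
      windows$tgt_start[i] - genes$end, 0
    )
    !any(genes$chrom == windows$tgt_chrom[i] & gap <= max_distance)
  }, logical(1))
}

#' Classify a dominant TSS position relative to its annotated locus
#'
#' Computes the signed distance `d` from the dominant TSS to the annotated
#' start in transcription orientation (positive = upstream of the start) and
#' assigns, in order:
#'
#' * `at_annotated_start` — `|d| <= at_start_tol`;
#' * `upstream_proximal` — `upstream_min <= d <= upstream_max` (-500 to
#'   -2000 bp);
#' * `upstream_far_discard` — `d > far_upstream` (>5000 bp upstream; such
#'   windows are not investigated further);
#' * `three_prime_end` — within `three_prime_tol` of the locus 3' end;
#' * `intragenic` — strictly inside the locus body;
#' * `unclassified` — anything else (including the unstated gap between
#'   `at_start_tol` and `upstream_min`).
#'
#' @param dominant_tss Dominant TSS position(s); `NA` gives `unclassified`.
#' @param locus_start,locus_end,locus_strand Locus coordinates (0-based
#'   half-open) and strand, recycled against `dominant_tss`.
#' @param at_start_tol,upstream_min,upstream_max,far_upstream,three_prime_tol
#'   Class boundaries in bp.
#' @return Character vector of position classes.
#' @export
classify_tss_position <- function(dominant_tss, locus_start, locus_end,
                                  locus_strand,
                                  at_start_tol = 50, upstream_min = 500,
                                  upstream_max = 2000, far_upstream = 5000,
                                  three_prime_tol = 500) {
  n <- max(length(dominant_tss), length(locus_start))
  pos <- rep_len(dominant_tss, n)
  ls <- rep_len(locus_start, n); le <- rep_len(locus_end, n)
  st <- rep_len(locus_strand, n)
  annot_start <- ifelse(st == "+", ls, le - 1)
  three_prime <- ifelse(st == "+", le - 1, ls)
  d <- ifelse(st == "+", annot_start - pos, pos - annot_start)
  dplyr::case_when(
    is.na(pos) ~ "unclassified",
    abs(d) <= at_start_tol ~ "at_annotated_start",
    d >= upstream_min & d <= upstream_max ~ "upstream_proximal",
    d > far_upstream ~ "upstream_far_discard",
    abs(pos - three_prime) <= three_prime_tol ~ "three_prime_end",
    pos > ls & pos < le - 1 ~ "intragenic",
    TRUE ~ "unclassified"
  )
}

#' Run the ectopic-expression screening cascade
#'
#' The full candidate screen: lift source-genome TSS windows through the
#' chain set (discarding duplicate lifted coordinates), count CAGE tags
#' starting in each mapped window over an explicit library subset, apply the
#' third-quartile and absolute tag-count filters, flag artifact windows not
#' corresponding to any receptor locus, locate each window's dominant TSS and
#' classify its position relative to the annotated locus. Verdicts are
#' assigned with precedence `discarded_far_upstream` over `artifact` over
#' `filtered` over `candidate`; a window is a `candidate` only when it passes
#' the absolute cutoff and is neither artifact nor far upstream.
#'
#' @param ctss Target-genome CTSS tibble (stacked libraries).
#' @param windows Source-genome window tibble from [build_tss_windows()].
#' @param chains A [chain_set()] from source to target genome.
#' @param annotation Target-genome annotation from [read_bed()].
#' @param library_subset Libraries whose counts are pooled (required; see
#'   [pool_counts()]).
#' @param min_match,gap_tolerance Lift parameters, see [lift_intervals()].
#' @param abs_cutoff Absolute pooled tag-count cutoff (default 100).
#' @param percentile_method Quartile method, see [quartile_filter()].
#' @param pseudogene_is_artifact See [flag_artifacts()].
#' @param artifact_max_distance Maximum gap (bp) between a window and a gene
#'   locus for the window to correspond to that locus, used both for the
#'   artifact flag and for assigning the locus against which the TSS position
#'   is classified. Default 10000 bp, comfortably containing the far-upstream
#'   class boundary so genuinely upstream promoters are classified rather
#'   than flagged.
#' @param keep_split Also count and screen `split` lifts (default `FALSE`).
#' @param strand_aware_windows Strand-match window counting (default `FALSE`).
#' @param ... Class boundaries passed to [classify_tss_position()].
#' @return An object of class `or_screen`: list with `candidates` (the
#'   per-window table, ordered by window id), `counts` (long per-library
#'   counts), `discarded` (collision-discarded ids), `q3`, `stage_counts` and
#'   `params`. Use [tidy()] / [glance()] / [autoplot()] on it, and
#'   [write_candidates()] on `tidy()` output.
#' @export
run_screen <- function(ctss, windows, chains, annotation, library_subset,
                       min_match = 0.95, gap_tolerance = NULL,
                       abs_cutoff = 100,
                       percentile_method = c("linear", "nearest"),
                       pseudogene_is_artifact = TRUE,
                       artifact_max_distance = 10000, keep_split = FALSE,
                       strand_aware_windows = FALSE, ...) {
  percentile_method <- match.arg(percentile_method)
  lift <- lift_windows_dedup(windows, chains, min_match, gap_tolerance)
  res <- lift$results
  usable_status <- if (keep_split) c("mapped", "split") else "mapped"
  in_screen <- res$status %in% usable_status & !res$discarded

  ctss_sub <- ctss |> filter(.data$library %in% library_subset)
  tgt_windows <- res[in_screen, ] |>
    mutate(w_chrom = .data$tgt_chrom, w_start = .data$tgt_start,
           w_end = .data$tgt_end) |>
    select(id = "id", chrom = "w_chrom", start = "w_start", end = "w_end",
           strand = "tgt_strand")

  counts <- count_tags(ctss, tgt_windows, strand_aware = strand_aware_windows)
  pooled <- pool_counts(counts, library_subset)
  total_subset <- sum(library_totals(ctss_sub)$total_tags)

  qf <- quartile_filter(pooled$pooled_count, method = percentile_method)
  pooled$above_q3 <- qf$flags
  pooled$above_abs_cutoff <- absolute_cutoff_filter(pooled$pooled_count, abs_cutoff)
  pooled$pooled_tpm <- tpm(pooled$pooled_count, total_subset)

  scr <- res[in_screen, ] |> left_join(pooled, by = "id")
  scr$artifact <- flag_artifacts(
    scr, annotation, pseudogene_is_artifact, max_distance = artifact_max_distance
  )

  prof <- promoter_profiles(ctss_sub, tgt_windows, strand_aware = strand_aware_windows)
  scr <- scr |> left_join(prof |> select("id", "dominant_pos"), by = "id")

  # assign each window the gene locus it corresponds to: best overlap, else
  # nearest gene within artifact_max_distance (upstream windows need not
  # overlap the gene body)
  genes <- annotation |> filter(.data$biotype == "gene")
  locus_of <- purrr::map_dfr(seq_len(nrow(scr)), function(i) {
    same <- genes$chrom == scr$tgt_chrom[i]
    gap <- pmax(genes$start - scr$tgt_end[i], scr$tgt_start[i] - genes$end, 0)
    gap[!same] <- Inf
    if (nrow(genes) == 0L || min(gap) > artifact_max_distance) {
      return(tibble(locus_id = NA_character_, l_start = NA_real_,
                    l_end = NA_real_, l_strand = NA_character_))
    }
    j <- which.min(gap)
    tibble(locus_id = genes$locus_id[j], l_start = genes$start[j],
           l_end = genes$end[j], l_strand = genes$strand[j])
  })
  scr <- dplyr::bind_cols(scr, locus_of)
  scr$tss_position_class <- ifelse(
    is.na(scr$locus_id), "unclassified",
    classify_tss_position(
      scr$dominant_pos, scr$l_start, scr$l_end, scr$l_strand, ...
    )
  )
  scr$verdict <- dplyr::case_when(
    scr$tss_position_class == "upstream_far_discard" ~ "discarded_far_upstream",
    scr$artifact ~ "artifact",
    !scr$above_abs_cutoff ~ "filtered",
    TRUE ~ "candidate"
  )

  # windows that never reached counting: unmapped/low-coverage/split/collision
  out_rows <- res[!in_screen, ] |>
    mutate(
      pooled_count = NA_real_, pooled_tpm = NA_real_, above_q3 = FALSE,
      above_abs_cutoff = FALSE, artifact = FALSE, dominant_pos = NA_real_,
      locus_id = NA_character_, l_start = NA_real_, l_end = NA_real_,
      l_strand = NA_character_, tss_position_class = "unclassified",
      verdict = "filtered"
    )
  candidates <- bind_rows(scr, out_rows) |>
    mutate(lift_status = ifelse(.data$discarded, "collision", .data$status)) |>
    select(
      id = "id", chrom = "chrom", start = "start", end = "end",
      strand = "strand", lift_status = "lift_status",
      tgt_chrom = "tgt_chrom", tgt_start = "tgt_start", tgt_end = "tgt_end",
      tgt_strand = "tgt_strand", mapped_fraction = "mapped_fraction",
      pooled_count = "pooled_count", pooled_tpm = "pooled_tpm",
      above_q3 = "above_q3", above_abs_cutoff = "above_abs_cutoff",
      artifact = "artifact", dominant_pos = "dominant_pos",
      locus_id = "locus_id", tss_position_class = "tss_position_class",
      verdict = "verdict"
    ) |>
    arrange(.data$id)

  counts_wide <- counts |>
    tidyr::pivot_wider(
      names_from = "library", values_from = "count", names_prefix = "n_"
    )
  candidates <- candidates |> left_join(counts_wide, by = "id")

  structure(
    list(
      candidates = candidates,
      counts = counts,
      discarded = lift$discarded,
      q3 = qf$q3,
      stage_counts = c(
        n_windows = nrow(windows),
        n_mapped = sum(res$status == "mapped" & !res$discarded),
        n_collision_discarded = length(lift$discarded),
        n_screened = sum(in_screen),
        n_above_q3 = sum(pooled$above_q3),
        n_above_abs_cutoff = sum(pooled$above_abs_cutoff),
        n_artifact = sum(scr$artifact),
        n_far_upstream = sum(scr$tss_position_class == "upstream_far_discard"),
        n_candidates = sum(scr$verdict == "candidate")
      ),
      params = list(
        library_subset = library_subset, min_match = min_match,
        gap_tolerance = gap_tolerance, abs_cutoff = abs_cutoff,
        percentile_method = percentile_method,
        pseudogene_is_artifact = pseudogene_is_artifact,
        artifact_max_distance = artifact_max_distance,
        keep_split = keep_split,
        strand_aware_windows = strand_aware_windows,
        artifact_call = "mechanized stand-in for manual inspection"
      )
    ),
    class = "or_screen"
  )
}

#' @export
print.or_screen <- function(x, ...) {
  cat("<or_screen> candidate screen\n")
  sc <- x$stage_counts
  cat(sprintf(
    "  %d windows -> %d mapped (%d collision-discarded), q3 = %.2f\n",
    sc["n_windows"], sc["n_mapped"], sc["n_collision_discarded"], x$q3
  ))
  cat(sprintf(
    "  %d > q3, %d > %s tags, %d artifacts, %d candidates\n",
    sc["n_above_q3"], sc["n_above_abs_cutoff"],
    format(x$params$abs_cutoff), sc["n_artifact"], sc["n_candidates"]
  ))
  invisible(x)
}

#' @rdname run_screen
#' @param x,object An `or_screen` object.
#' @param ... Unused.
#' @method tidy or_screen
#' @export
tidy.or_screen <- function(x, ...) {
  x$candidates
}

#' @rdname run_screen
#' @method glance or_screen
#' @export
glance.or_screen <- function(x, ...) {
  as_tibble(as.list(x$stage_counts)) |>
    mutate(q3 = x$q3, abs_cutoff = x$params$abs_cutoff, .before = 1)
}

#' @rdname run_screen
#' @method autoplot or_screen
#' @export
autoplot.or_screen <- function(object, ...) {
  dat <- object$candidates |> filter(!is.na(.data$pooled_count))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = stats::reorder(.data$id, .data$pooled_count),
      y = .data$pooled_count + 1, fill = .data$verdict
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$q3 + 1, linetype = 2) +
    ggplot2::geom_hline(
      yintercept = object$params$abs_cutoff + 1, linetype = 3
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "pooled tags + 1 (dashed: Q3, dotted: absolute cutoff)"
    ) +
    ggplot2::theme_minimal()
}
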