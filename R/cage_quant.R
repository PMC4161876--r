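#' Count CAGE tags starting in intervals
#'
#' Counts the tags whose 5' ends fall inside each interval (`pos` in
#' `[start, end)`, half-open). With `strand_aware = TRUE` only tags on the
#' interval's strand are counted — the convention for whole-locus `sum5end`
#' counting — while window counting over lifted promoter windows is
#' strand-blind by default.
#'
#' @param ctss CTSS tibble (`library`, `chrom`, `pos`, `strand`, `count`);
#'   several libraries may be stacked.
#' @param intervals Tibble with columns `id`, `chrom`, `start`, `end` and,
#'   when `strand_aware`, `strand`.
#' @param strand_aware Count only tags matching the interval strand?
#' @return A tibble `id` x `library` with a `count` column, zero-filled so
#'   every interval appears for every library present in `ctss`.
#' @export
count_tags <- function(ctss, intervals, strand_aware = FALSE) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(intervals)))
  check_interval(intervals$chrom, intervals$start, intervals$end)
  if (strand_aware && !"strand" %in% names(intervals)) {
    abort("strand-aware counting needs a `strand` column on `intervals`")
  }
  libs <- unique(ctss$library)
  if (length(libs) == 0L) {
    # an empty library set still answers zero for every interval
    return(tibble(id = intervals$id, library = NA_character_, count = 0L))
  }
  hits <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    sub <- ctss[ctss$chrom == intervals$chrom[i] &
                  ctss$pos >= intervals$start[i] &
                  ctss$pos < intervals$end[i], , drop = FALSE]
    if (strand_aware) sub <- sub[sub$strand == intervals$strand[i], , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub |>
      group_by(library = .data$library) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(id = intervals$id[i])
  })
  grid <- tidyr::expand_grid(id = intervals$id, library = libs)
  if (nrow(hits) == 0L) {
    return(grid |> mutate(count = 0L))
  }
  out <- left_join(grid, hits, by = c("id", "library"))
  out$count[is.na(out$count)] <- 0L
  out
}

#' Whole-locus 5'-end tag counts (sum5end)
#'
#' Sums, per library, the CAGE tags whose 5' ends fall anywhere inside each
#' annotated locus, matched to the locus strand.
#'
#' @param ctss CTSS tibble.
#' @param loci Annotation tibble from [read_bed()] (`locus_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @return A tibble `locus_id` x `library` with a `count` column.
#' @export
sum5end <- function(ctss, loci) {
  count_tags(
    ctss,
    loci |> rename(id = "locus_id"),
    strand_aware = TRUE
  ) |>
    rename(locus_id = "id")
}

#' Tags per million
#'
#' `count / total_tags * 1e6`. `total_tags` is the library's total tag count
#' (`sum(count)` over its CTSS records), so TPM values over all positions of a
#' library sum to one million.
#'
#' @param count Tag count(s).
#' @param total_tags Library total tag count(s); must be positive.
#' @return Numeric TPM value(s).
#' @export
tpm <- function(count, total_tags) {
  if (any(total_tags <= 0)) abort("`total_tags` must be > 0 to compute TPM")
  count / total_tags * 1e6
}

#' Per-library total tag counts
#'
#' @param ctss CTSS tibble.
#' @return A tibble with columns `library` and `total_tags`.
#' @export
library_totals <- function(ctss) {
  ctss |>
    group_by(library = .data$library) |>
    summarise(total_tags = sum(.data$count), .groups = "drop")
}

#' Positional promoter profiles
#'
#' Summarises the tag-position distribution inside each interval, pooled over
#' all libraries in `ctss`: the total tag count, the dominant TSS (the
#' position with the most tags, smallest coordinate on ties), its fraction of
#' the total, and the 10th-90th percentile positional spread (`iq_width`, in
#' bp) of the cumulative tag distribution.
#'
#' @inheritParams count_tags
#' @param strand_aware Match the interval strand (default `TRUE`; profiles
#'   are usually taken over annotated loci).
#' @return A tibble with one row per interval: `id`, `total_tags`,
#'   `dominant_pos`, `dominant_fraction`, `iq_width`. Intervals without tags
#'   get `total_tags = 0` and `NA` statistics.
#' @export
promoter_profiles <- function(ctss, intervals, strand_aware = TRUE) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(intervals)))
  purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    sub <- ctss[ctss$chrom == intervals$chrom[i] &
                  ctss$pos >= intervals$start[i] &
                  ctss$pos < intervals$end[i], , drop = FALSE]
    if (strand_aware) sub <- sub[sub$strand == intervals$strand[i], , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(tibble(
        id = intervals$id[i], total_tags = 0L, dominant_pos = NA_integer_,
        dominant_fraction = NA_real_, iq_width = NA_real_
      ))
    }
    per_pos <- sub |>
      group_by(pos = .data$pos) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      arrange(.data$pos)
    total <- sum(per_pos$count)
    dom_i <- which.max(per_pos$count)  # which.max takes the first maximum
    cum <- cumsum(per_pos$count)
    q10 <- per_pos$pos[which(cum >= 0.1 * total)[1]]
    q90 <- per_pos$pos[which(cum >= 0.9 * total)[1]]
    tibble(
      id = intervals$id[i], total_tags = total,
      dominant_pos = per_pos$pos[dom_i],
      dominant_fraction = per_pos$count[dom_i] / total,
      iq_width = as.numeric(q90 - q10)
    )
  })
}

#' Classify promoter shape
#'
#' Labels each profile `sharp` when initiation is concentrated — positional
#' 10-90% spread at most `sharp_width` bp *or* a dominant TSS carrying at
#' least `sharp_dominance` of the tags — and `broad` otherwise (dispersed
#' initiation over on the order of a hundred bases). Profiles with fewer than
#' `min_tags_for_shape` tags are `undetermined`.
#'
#' @param profiles Tibble from [promoter_profiles()].
#' @param min_tags_for_shape Minimum tags for a shape call (default 20).
#' @param sharp_width Maximum 10-90% spread (bp) for a sharp call (default 4).
#' @param sharp_dominance Minimum dominant-position tag fraction for a sharp
#'   call (default 0.5).
#' @return `profiles` with an added `shape` column
#'   (`sharp`/`broad`/`undetermined`).
#' @export
classify_shape <- function(profiles, min_tags_for_shape = 20,
                           sharp_width = 4, sharp_dominance = 0.5) {
  profiles |>
    mutate(shape = dplyr::case_when(
      .data$total_tags < min_tags_for_shape ~ "undetermined",
      .data$iq_width <= sharp_width |
        .data$dominant_fraction >= sharp_dominance ~ "sharp",
      TRUE ~ "broad"
    ))
}

#' Receptor-by-library TPM quantification
#'
#' Convenience wrapper producing, for a set of intervals, per-library tag
#' counts and TPM values in long format.
#'
#' @inheritParams count_tags
#' @return A tibble `id`, `library`, `count`, `total_tags`, `tpm`.
#' @export
quantify_tpm <- function(ctss, intervals, strand_aware = FALSE) {
  count_tags(ctss, intervals, strand_aware = strand_aware) |>
    left_join(library_totals(ctss), by = "library") |>
    mutate(tpm = tpm(.data$count, .data$total_tags))
}

#' Plot a promoter tag profile
#'
#' Bar plot of per-position 5'-end tag counts inside one interval, pooled over
#' libraries; the dominant TSS is highlighted.
#'
#' @param ctss CTSS tibble.
#' @param interval One-row tibble with `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param strand_aware Match the interval strand (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_promoter_profile <- function(ctss, interval, strand_aware = TRUE) {
  stopifnot(nrow(interval) == 1L)
  sub <- ctss[ctss$chrom == interval$chrom &
                ctss$pos >= interval$start & ctss$pos < interval$end, , drop = FALSE]
  if (strand_aware) sub <- sub[sub$strand == interval$strand, , drop = FALSE]
  per_pos <- sub |>
    group_by(pos = .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop")
  prof <- promoter_profiles(ctss, interval, strand_aware = strand_aware)
  ggplot2::ggplot(per_pos, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(
      xintercept = prof$dominant_pos, colour = "firebrick", linetype = 2
    ) +
    ggplot2::labs(
      x = sprintf("%s position (bp)", interval$chrom), y = "5'-end tags",
      title = sprintf("%s (%d tags)", interval$id, prof$total_tags)
    ) +
    ggplot2::theme_minimal()
}
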