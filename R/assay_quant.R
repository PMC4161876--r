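#' Reference-normalised Ct (delta Ct)
#'
#' `delta_ct = ct_target - mean(ct_references)`: the target gene's threshold
#' cycle normalised against the arithmetic mean of the internal-control Ct
#' values (equivalent to the geometric mean on the expression scale).
#'
#' @param ct_target Target-gene Ct value(s), cycles.
#' @param ct_references Numeric vector of reference-gene Ct values for the
#'   same sample (>= 1 value).
#' @return Numeric delta-Ct value(s).
#' @export
delta_ct <- function(ct_target, ct_references) {
  if (length(ct_references) == 0L || anyNA(ct_references)) {
    abort("need at least one non-missing reference Ct")
  }
  ct_target - mean(ct_references)
}

#' Calibrator-normalised delta-delta Ct and fold change
#'
#' `delta_delta_ct = dct_sample - mean(dct_calibrators)`, and the relative
#' expression fold change `2^(-delta_delta_ct)` (1 when the sample equals the
#' calibrator mean, assuming perfect doubling per cycle).
#'
#' @param dct_sample Sample delta-Ct value(s).
#' @param dct_calibrators Numeric vector of calibrator-sample delta-Ct values
#'   for the same gene (non-empty).
#' @return Numeric delta-delta-Ct value(s).
#' @export
delta_delta_ct <- function(dct_sample, dct_calibrators) {
  if (length(dct_calibrators) == 0L || anyNA(dct_calibrators)) {
    abort("need at least one non-missing calibrator delta-Ct")
  }
  dct_sample - mean(dct_calibrators)
}

#' @rdname delta_delta_ct
#' @param ddct Delta-delta-Ct value(s).
#' @export
fold_change <- function(ddct) {
  2^(-ddct)
}

#' Relative quantification of a Ct table (delta-delta-Ct method)
#'
#' Collapses technical replicates by mean Ct, normalises each target gene
#' against the arithmetic mean of the reference genes within each sample
#' ([delta_ct()]), subtracts the mean calibrator delta-Ct per gene
#' ([delta_delta_ct()]) and reports `2^(-ddCt)` fold changes.
#'
#' @param ct_table Long tibble with columns `sample`, `gene`, `ct` and
#'   optionally `replicate` (technical replicates).
#' @param reference_genes Character vector of internal-control gene names
#'   (e.g. GUSB, XPNPEP1, AARS); must be present in the table.
#' @param calibrator_samples Character vector of calibrator sample names;
#'   must be present in the table.
#' @return A tibble with one row per (sample, target gene): `sample`, `gene`,
#'   `ct`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
ddct <- function(ct_table, reference_genes, calibrator_samples) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  if (!all(reference_genes %in% ct_table$gene)) {
    abort("reference genes missing from the Ct table")
  }
  if (!all(calibrator_samples %in% ct_table$sample)) {
    abort("calibrator samples missing from the Ct table")
  }
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  collapsed <- ct_table |>
    group_by(sample = .data$sample, gene = .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref_means <- collapsed |>
    filter(.data$gene %in% reference_genes) |>
    group_by(sample = .data$sample) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  dct <- collapsed |>
    filter(!.data$gene %in% reference_genes) |>
    left_join(ref_means, by = "sample") |>
    mutate(delta_ct = .data$ct - .data$ref_ct)
  cal_means <- dct |>
    filter(.data$sample %in% calibrator_samples) |>
    group_by(gene = .data$gene) |>
    summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
  dct |>
    left_join(cal_means, by = "gene") |>
    mutate(
      delta_delta_ct = .data$delta_ct - .data$cal_dct,
      fold_change = fold_change(.data$delta_delta_ct)
    ) |>
    select("sample", "gene", "ct", "delta_ct", "delta_delta_ct", "fold_change")
}

#' Rescale a delta-delta-Ct matrix for heat-map display
#'
#' Divides every entry by the maximum absolute delta-delta-Ct, mapping the
#' largest-magnitude entry to +/-1 (the matrix2png-style rescaled normalised
#' fold expression, ddCt / ddCt_max). Idempotent.
#'
#' @param x Either a numeric matrix, or a tibble with a `delta_delta_ct`
#'   column (e.g. from [ddct()]).
#' @return The matrix rescaled, or the tibble with an added `rescaled`
#'   column. Errors if all entries are zero.
#' @export
rescale_heatmap <- function(x) {
  if (is.matrix(x)) {
    m <- max(abs(x))
    if (m == 0) abort("all-zero matrix cannot be rescaled")
    return(x / m)
  }
  stopifnot("delta_delta_ct" %in% names(x))
  m <- max(abs(x$delta_delta_ct))
  if (m == 0) abort("all delta-delta-Ct values are zero")
  x |> mutate(rescaled = .data$delta_delta_ct / m)
}

#' Reporter-assay fold increase over control
#'
#' `signal / control_signal` — e.g. reporter activity in odor-stimulated
#' wells relative to the vehicle control.
#'
#' @param signal Measured signal(s).
#' @param control_signal Control signal(s); must be positive.
#' @return Numeric fold increase(s).
#' @export
fold_increase <- function(signal, control_signal) {
  if (any(control_signal <= 0)) abort("control signal must be > 0")
  signal / control_signal
}

#' @rdname fold_increase
#' @return `fold_increase_summary()`: a one-row tibble with the mean, SD and
#'   n of per-replicate fold increases.
#' @export
fold_increase_summary <- function(signal, control_signal) {
  folds <- fold_increase(signal, control_signal)
  tibble(
    mean_fold = mean(folds), sd_fold = stats::sd(folds), n = length(folds)
  )
}

#' Heat map of rescaled delta-delta-Ct values
#'
#' @param ddct_table Tibble from [ddct()] (rescaled on the fly with
#'   [rescale_heatmap()] if needed).
#' @return A ggplot object.
#' @export
plot_ddct_heatmap <- function(ddct_table) {
  if (!"rescaled" %in% names(ddct_table)) {
    ddct_table <- rescale_heatmap(ddct_table)
  }
  ggplot2::ggplot(
    ddct_table,
    ggplot2::aes(x = .data$sample, y = .data$gene, fill = .data$rescaled)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "navy", mid = "white", high = "firebrick", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ddCt / ddCt_max") +
    ggplot2::theme_minimal()
}
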