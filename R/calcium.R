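#' Fluorescence ratio of a two-channel trace
#'
#' Adds the fura-2 ratio `r = f340 / f380` to a trace tibble. Ratioing
#' cancels dye loading and illumination differences, so responses are
#' comparable across cells.
#'
#' @param trace Tibble with columns `time`, `f340`, `f380` (one trace, or
#'   several stacked with a `trace_id` column).
#' @return The tibble with an added `r` column. Errors if any `f380 <= 0`.
#' @export
ratio_trace <- function(trace) {
  stopifnot(all(c("time", "f340", "f380") %in% names(trace)))
  if (any(trace$f380 <= 0)) abort("f380 must be positive everywhere")
  trace |> mutate(r = .data$f340 / .data$f380)
}

#' Baseline ratio
#'
#' The pre-stimulus baseline `R0`: by default the mean ratio over all samples
#' before stimulus onset (robust to channel noise); with `r0_at_t0 = TRUE`
#' the literal ratio at the first time point is used instead.
#'
#' @param r Ratio values.
#' @param time Matching time values (seconds).
#' @param t_on Stimulus onset (seconds).
#' @param r0_at_t0 Use the single first sample as the baseline.
#' @return The scalar baseline `R0`.
#' @export
baseline <- function(r, time, t_on, r0_at_t0 = FALSE) {
  stopifnot(length(r) == length(time))
  if (r0_at_t0) return(r[which.min(time)])
  pre <- r[time < t_on]
  if (length(pre) == 0L) return(r[which.min(time)])
  mean(pre)
}

#' Response percentage
#'
#' `(r - r0) / r0 * 100` — the fractional ratio change over baseline,
#' in percent (`dR/R0 x 100`).
#'
#' @param r Ratio value(s).
#' @param r0 Baseline ratio; must be positive.
#' @return Numeric percentage(s).
#' @export
response_percent <- function(r, r0) {
  if (any(r0 <= 0)) abort("baseline R0 must be > 0")
  (r - r0) / r0 * 100
}

#' Per-trace response calls
#'
#' For each trace: the baseline `R0`, the peak post-stimulus response
#' (`dR/R0`, percent), the half-peak onset latency from stimulus onset, the
#' duration above half peak, and the responder flag (peak at least
#' `threshold` percent with onset within `max_latency` seconds).
#'
#' @param traces Trace tibble (`trace_id`, `time`, `f340`, `f380`).
#' @param t_on,t_off Stimulus window, seconds.
#' @param threshold Responder threshold, percent `dR/R0` (default 20).
#' @param max_latency Maximum onset latency, seconds (default 30).
#' @param r0_at_t0 See [baseline()].
#' @return A tibble with one row per trace: `trace_id`, `r0`, `peak_pct`,
#'   `onset_latency`, `duration`, `responder`.
#' @export
calcium_calls <- function(traces, t_on, t_off, threshold = 20,
                          max_latency = 30, r0_at_t0 = FALSE) {
  stopifnot(all(c("trace_id", "time", "f340", "f380") %in% names(traces)))
  check_scalar_number(t_on, "t_on"); check_scalar_number(t_off, "t_off")
  if (t_on >= t_off) abort("t_on must be before t_off")
  rt <- ratio_trace(traces)
  rt |>
    group_by(trace_id = .data$trace_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d |> arrange(.data$time)
      r0 <- baseline(d$r, d$time, t_on, r0_at_t0)
      resp <- response_percent(d$r, r0)
      post <- d$time >= t_on
      peak <- max(resp[post])
      above <- post & resp >= peak / 2
      onset <- if (peak > 0 && any(above)) min(d$time[above]) - t_on else NA_real_
      duration <- if (peak > 0 && any(above)) {
        max(d$time[above]) - min(d$time[above])
      } else 0
      tibble(
        r0 = r0, peak_pct = peak, onset_latency = onset, duration = duration
      )
    }) |>
    ungroup() |>
    mutate(responder = classify_responder(
      .data$peak_pct, .data$onset_latency, threshold, max_latency
    ))
}

#' Responder classification
#'
#' A cell responds when its peak `dR/R0` reaches `threshold` percent with an
#' onset within `max_latency` seconds of stimulus onset. Both values are
#' conventions of this package (no community standard exists) and are echoed
#' in run metadata.
#'
#' @param peak_pct Peak response(s), percent.
#' @param onset_latency Onset latency(ies), seconds (`NA` = never crossed).
#' @param threshold,max_latency Classification parameters.
#' @return Logical vector.
#' @export
classify_responder <- function(peak_pct, onset_latency, threshold = 20,
                               max_latency = 30) {
  peak_pct >= threshold & !is.na(onset_latency) & onset_latency <= max_latency
}

#' Population response summary
#'
#' The responder fraction (percent, one decimal — e.g. 11 of 37 cells gives
#' 29.7) and the mean and SD of peak amplitudes over responders only.
#'
#' @param calls Tibble from [calcium_calls()].
#' @return A one-row tibble: `n`, `n_responders`, `fraction_pct`,
#'   `mean_amplitude`, `sd_amplitude`.
#' @export
summarize_population <- function(calls) {
  if (nrow(calls) == 0L) abort("empty population")
  resp <- calls |> filter(.data$responder)
  tibble(
    n = nrow(calls),
    n_responders = nrow(resp),
    fraction_pct = round(100 * nrow(resp) / nrow(calls), 1),
    mean_amplitude = if (nrow(resp)) mean(resp$peak_pct) else NA_real_,
    sd_amplitude = if (nrow(resp) > 1) stats::sd(resp$peak_pct) else NA_real_
  )
}

#' Plot calcium response traces
#'
#' `dR/R0` (percent) over time for every trace, stimulus window shaded;
#' coloured by responder call when `calls` is supplied.
#'
#' @inheritParams calcium_calls
#' @param calls Optional tibble from [calcium_calls()].
#' @return A ggplot object.
#' @export
plot_calcium_traces <- function(traces, t_on, t_off, calls = NULL,
                                r0_at_t0 = FALSE) {
  rt <- ratio_trace(traces) |>
    group_by(trace_id = .data$trace_id) |>
    dplyr::group_modify(function(d, key) {
      r0 <- baseline(d$r, d$time, t_on, r0_at_t0)
      d |> mutate(resp = response_percent(.data$r, r0))
    }) |>
    ungroup()
  if (!is.null(calls)) {
    rt <- rt |> left_join(calls |> select("trace_id", "responder"),
                          by = "trace_id")
  } else {
    rt$responder <- NA
  }
  ggplot2::ggplot(
    rt,
    ggplot2::aes(
      x = .data$time, y = .data$resp,
      group = .data$trace_id, colour = .data$responder
    )
  ) +
    ggplot2::annotate(
      "rect", xmin = t_on, xmax = t_off, ymin = -Inf, ymax = Inf,
      alpha = 0.1, fill = "steelblue"
    ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "dR/R0 (%)", colour = "responder") +
    ggplot2::theme_minimal()
}
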