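#' Line survival curve
#'
#' Per-generation proportion of surviving lines per treatment. A line with
#' `extinction_generation = e` is counted as extinct from generation `e`
#' onward; lines with `NA` are censored at the horizon. Duplicated lines
#' (rows of their own) inherit their source's pre-duplication history, so
#' every record spans the whole horizon and the curve is non-increasing.
#'
#' @param records Survival records: tibble with `line_id`, `treatment`,
#'   `extinction_generation` (integer or `NA`).
#' @param horizon Last generation of the experiment.
#' @return A tibble of class `survival_curve_df`: `treatment`, `generation`
#'   (0..horizon), `n_lines`, `n_surviving`, `surviving_pct`.
#' @export
survival_curve <- function(records, horizon = 33) {
  if (!nrow(records)) abort("No survival records.")
  ext <- records$extinction_generation
  if (any(!is.na(ext) & (ext < 1 | ext > horizon))) {
    abort("Extinction generations must lie within [1, horizon].")
  }
  out <- tidyr::crossing(
    records |> select("line_id", "treatment", "extinction_generation"),
    generation = 0:horizon
  ) |>
    mutate(alive = is.na(.data$extinction_generation) |
             .data$extinction_generation > .data$generation) |>
    group_by(.data$treatment, .data$generation) |>
    summarise(n_lines = n(), n_surviving = sum(.data$alive),
              .groups = "drop") |>
    mutate(surviving_pct = 100 * .data$n_surviving / .data$n_lines)
  class(out) <- c("survival_curve_df", class(out))
  out
}

#' Interval extinction rates
#'
#' Extinction rate per line-generation at risk within consecutive intervals
#' of the horizon (default: thirds of generations 1..33), per treatment. A
#' line is at risk in every generation up to and including its extinction
#' generation; censored lines are at risk throughout. Rates are expressed
#' as percentages.
#'
#' @param records Survival records (see [survival_curve()]).
#' @param intervals List of `c(first, last)` generation pairs partitioning
#'   the horizon.
#' @param horizon Last generation (used for the default thirds).
#' @return A tibble: `treatment`, `interval`, `from`, `to`, `n_extinct`,
#'   `line_generations`, `rate_pct`.
#' @export
interval_extinction_rate <- function(records, intervals = NULL,
                                     horizon = 33) {
  if (is.null(intervals)) {
    cuts <- round(seq(0, horizon, length.out = 4))
    intervals <- purrr::map(seq_len(3), ~ c(cuts[.x] + 1, cuts[.x + 1]))
  }
  bounds <- do.call(rbind, intervals)
  if (any(bounds[, 1] > bounds[, 2])) abort("Malformed intervals.")
  ord <- order(bounds[, 1])
  b <- bounds[ord, , drop = FALSE]
  if (nrow(b) > 1 && any(b[-1, 1] <= b[-nrow(b), 2])) {
    abort("Intervals overlap.")
  }
  purrr::map_dfr(seq_along(intervals), function(k) {
    lo <- intervals[[k]][1]; hi <- intervals[[k]][2]
    records |>
      group_by(.data$treatment) |>
      summarise(
        interval = k, from = lo, to = hi,
        n_extinct = sum(!is.na(.data$extinction_generation) &
                          .data$extinction_generation >= lo &
                          .data$extinction_generation <= hi),
        line_generations = sum(pmax(0, pmin(
          ifelse(is.na(.data$extinction_generation), hi,
                 .data$extinction_generation), hi) - lo + 1)),
        .groups = "drop"
      ) |>
      mutate(rate_pct = ifelse(.data$line_generations > 0,
                               100 * .data$n_extinct / .data$line_generations,
                               NA_real_))
  })
}
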