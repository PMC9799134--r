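#' Flag trials for exclusion
#'
#' Applies the three trial-exclusion criteria to a trial table carrying
#' kinematic summaries:
#' * **slow** — mean movement speed below 20 cm/s (strict);
#' * **curved** — maximum path deviation from the straight home-endpoint line
#'   above 2 cm;
#' * **outlier** — within each subject x session x phase x target-location
#'   cell, endpoints whose Euclidean distance from the componentwise-median
#'   endpoint exceeds 8 times the IQR of those distances.
#'
#' The three flags are computed independently on the full input (a trial can
#' trip several); `excluded` is their union. Cells with fewer than `min_cell`
#' trials skip the outlier rule with a warning.
#'
#' @param trials Trial tibble with columns `subject_id`, `session`, `phase`,
#'   `location_deg`, `endpoint_x_cm`, `endpoint_y_cm`, `mean_speed_cm_s`,
#'   `max_dev_cm`.
#' @param speed_threshold_cm_s,curvature_threshold_cm,iqr_multiplier Rule
#'   parameters (20 cm/s, 2 cm, 8).
#' @param min_cell Minimum cell size for the outlier rule.
#' @return The input tibble with logical columns `slow_flag`, `curved_flag`,
#'   `outlier_flag`, `excluded` appended.
#' @export
flag_exclusions <- function(trials, speed_threshold_cm_s = SLOW_SPEED_CM_S,
                            curvature_threshold_cm = 2, iqr_multiplier = 8,
                            min_cell = 4) {
  trials$slow_flag <- trials$mean_speed_cm_s < speed_threshold_cm_s
  trials$curved_flag <- trials$max_dev_cm > curvature_threshold_cm
  trials$outlier_flag <- FALSE

  cell <- interaction(trials$subject_id, trials$session, trials$phase,
                      trials$location_deg, drop = TRUE)
  small <- 0L
  for (idx in split(seq_len(nrow(trials)), cell)) {
    if (length(idx) < min_cell) {
      small <- small + 1L
      next
    }
    mx <- median(trials$endpoint_x_cm[idx])
    my <- median(trials$endpoint_y_cm[idx])
    d <- sqrt((trials$endpoint_x_cm[idx] - mx)^2 + (trials$endpoint_y_cm[idx] - my)^2)
    trials$outlier_flag[idx] <- d > iqr_multiplier * iqr_linear(d)
  }
  if (small > 0) {
    warning(small, " cell(s) with fewer than ", min_cell,
            " trials skipped the outlier rule")
  }
  trials$excluded <- trials$slow_flag | trials$curved_flag | trials$outlier_flag
  trials
}

#' Summarize exclusion rates
#'
#' Per subject, priming condition, and phase: counts and percentages of
#' slow, curved, and outlier flags, mirroring the "% of trials (range)"
#' reporting format.
#'
#' @param trials Output of [flag_exclusions()].
#' @return A list with `per_subject` (tibble of counts and percentages) and
#'   `overall` (mean, SD, and range of the percentage per criterion and
#'   condition x phase).
#' @export
exclusion_summary <- function(trials) {
  per_subject <- trials |>
    dplyr::group_by(.data$subject_id, .data$priming_condition, .data$phase) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_slow = sum(.data$slow_flag),
      n_curved = sum(.data$curved_flag),
      n_outlier = sum(.data$outlier_flag),
      pct_slow = 100 * .data$n_slow / .data$n_trials,
      pct_curved = 100 * .data$n_curved / .data$n_trials,
      pct_outlier = 100 * .data$n_outlier / .data$n_trials,
      .groups = "drop"
    )
  overall <- per_subject |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = "criterion", values_to = "pct",
                        names_prefix = "pct_") |>
    dplyr::group_by(.data$priming_condition, .data$phase, .data$criterion) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct), sd_pct = sd(.data$pct),
      min_pct = min(.data$pct), max_pct = max(.data$pct),
      .groups = "drop"
    )
  list(per_subject = per_subject, overall = overall)
}
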