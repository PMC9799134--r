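#' Task geometry and perturbation constants
#'
#' The paradigm uses three target locations 15 cm from the home position
#' (straight ahead and 30 degrees clockwise/counterclockwise), arc- or
#' line-shaped priming targets of 8 cm length, and eight endpoint-feedback
#' perturbations: rotations of +/-8.53 or +/-5.71 degrees and radial gain
#' changes of +/-0.15 or +/-0.10.
#'
#' @name task_constants
NULL

TARGET_RADIUS_CM <- 15
TARGET_EXTENT_CM <- 8
DOT_DIAMETER_CM <- 0.8
TARGET_LOCATIONS_DEG <- c(-30, 0, 30)
ROTATION_MAGNITUDES_DEG <- c(8.53, 5.71)
GAIN_DELTAS <- c(0.15, 0.10)
ARC_CENTRAL_ANGLE_DEG <- 30.56 # central angle of the 8 cm arc at 15 cm radius

N_PRIMING_BLOCKS <- 7
TRIALS_PER_PRIMING_BLOCK <- 60
FEEDBACK_FRACTION <- 0.25
N_MINIBLOCKS <- 90
MINIBLOCK_LENGTHS <- c(3, 4, 5)
BREAK_AFTER_MINIBLOCKS <- c(30, 60)

#' Target specification
#'
#' @param shape One of `"arc"`, `"radial_line"`, `"dot"`.
#' @param location_deg Target-center bearing relative to straight ahead,
#'   degrees, clockwise positive; one of -30, 0, 30.
#' @return A one-row tibble with the target geometry (radius, extent, and, for
#'   arcs, the central angle in degrees).
#' @export
target_spec <- function(shape = c("arc", "radial_line", "dot"), location_deg = 0) {
  shape <- match.arg(shape)
  stopifnot(location_deg %in% TARGET_LOCATIONS_DEG)
  tibble::tibble(
    shape = shape,
    location_deg = location_deg,
    radius_cm = TARGET_RADIUS_CM,
    extent_cm = if (shape == "dot") DOT_DIAMETER_CM else TARGET_EXTENT_CM,
    central_angle_deg = if (shape == "arc") rad2deg(TARGET_EXTENT_CM / TARGET_RADIUS_CM) else NA_real_
  )
}

#' Endpoint-feedback perturbation
#'
#' Validates the perturbation kind/magnitude against the eight values used in
#' the paradigm (rotation +/-8.53 or +/-5.71 degrees; gain delta +/-0.15 or
#' +/-0.10; `"none"` must have magnitude 0).
#'
#' @param kind `"none"`, `"rotation"`, or `"gain"`.
#' @param magnitude Signed degrees (rotation, clockwise positive) or signed
#'   gain delta (gain; the cursor radius is multiplied by `1 + magnitude`).
#' @return A one-row tibble with columns `kind` and `magnitude`.
#' @export
perturbation <- function(kind = c("none", "rotation", "gain"), magnitude = 0) {
  kind <- match.arg(kind)
  ok <- switch(kind,
    none = magnitude == 0,
    rotation = any(abs(abs(magnitude) - ROTATION_MAGNITUDES_DEG) < 1e-9),
    gain = magnitude == 0 || any(abs(abs(magnitude) - GAIN_DELTAS) < 1e-9)
  )
  if (!ok) {
    stop("disallowed magnitude ", magnitude, " for perturbation kind '", kind, "'")
  }
  tibble::tibble(kind = kind, magnitude = magnitude)
}

#' The eight test-phase perturbations
#'
#' @return A tibble with one row per perturbation (`kind`, `magnitude`):
#'   rotations of +/-8.53 and +/-5.71 degrees and gain deltas of +/-0.15 and
#'   +/-0.10.
#' @export
perturbation_set <- function() {
  tibble::tibble(
    kind = rep(c("rotation", "gain"), each = 4),
    magnitude = c(
      ROTATION_MAGNITUDES_DEG, -ROTATION_MAGNITUDES_DEG,
      GAIN_DELTAS, -GAIN_DELTAS
    )
  )
}

#' Build the test-phase mini-block schedule
#'
#' Ninety mini-blocks of 3-5 trials each are arranged in 9 consecutive cycles
#' of 10; every cycle contains each of the eight perturbations exactly once
#' plus two veridical-feedback mini-blocks, in shuffled order. Marginal balance
#' is exact: each perturbation occurs in 9 mini-blocks (3 at each length and 3
#' at each target location), veridical feedback in 18 (6 per length, 6 per
#' location), so each length and each location occur in 30 mini-blocks.
#'
#' @param seed Integer seed for the pseudorandomization (`NULL` to use the
#'   current RNG state).
#' @return A tibble with one row per mini-block: `miniblock`, `cycle`,
#'   `n_trials`, `location_deg`, `pert_kind`, `pert_magnitude`, and
#'   `break_after` (TRUE after mini-blocks 30 and 60). The perturbation is
#'   applied on the penultimate trial of the mini-block.
#' @export
build_test_schedule <- function(seed = NULL) {
  with_seed_or_inherit(seed, {
    pset <- perturbation_set()
    kinds <- c(pset$kind, "none")
    mags <- c(pset$magnitude, 0)
    n_inst <- c(rep(9L, 8), 18L)

    cycle <- integer(0)
    n_trials <- integer(0)
    loc <- numeric(0)
    kind <- character(0)
    mag <- numeric(0)
    for (i in seq_along(kinds)) {
      n <- n_inst[i]
      reps <- n / 3L
      cycle <- c(cycle, if (i == 9L) sample(rep(seq_len(9L), each = 2L)) else sample(seq_len(9L)))
      n_trials <- c(n_trials, sample(rep(as.integer(MINIBLOCK_LENGTHS), reps)))
      loc <- c(loc, sample(rep(TARGET_LOCATIONS_DEG, reps)))
      kind <- c(kind, rep(kinds[i], n))
      mag <- c(mag, rep(mags[i], n))
    }
    # concatenate cycles, shuffled within each cycle
    ord <- order(cycle, sample.int(length(cycle)))
    mb <- seq_len(N_MINIBLOCKS)
    fast_tibble(
      miniblock = mb, cycle = cycle[ord], n_trials = n_trials[ord],
      location_deg = loc[ord], pert_kind = kind[ord], pert_magnitude = mag[ord],
      break_after = mb %in% BREAK_AFTER_MINIBLOCKS
    )
  })
}

#' Build the priming-phase trial schedule
#'
#' Seven blocks of 60 trials; within every block each of the three target
#' locations appears 20 times in pseudorandom order, and exactly 15 trials
#' (25%) carry one-dimensional endpoint feedback.
#'
#' @param condition `"arc"` (direction redundant) or `"line"` (extent
#'   redundant); sets the target shape for every priming trial.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A tibble with one row per trial: `block`, `trial`, `location_deg`,
#'   `shape`, `feedback`.
#' @export
build_priming_schedule <- function(condition = c("arc", "line"), seed = NULL) {
  condition <- match.arg(condition)
  shape <- if (condition == "arc") "arc" else "radial_line"
  with_seed_or_inherit(seed, {
    per_block <- TRIALS_PER_PRIMING_BLOCK
    n_fb <- as.integer(FEEDBACK_FRACTION * per_block)
    blocks <- lapply(seq_len(N_PRIMING_BLOCKS), function(b) {
      loc <- sample(rep(TARGET_LOCATIONS_DEG, per_block / 3L))
      fb <- logical(per_block)
      fb[sample.int(per_block, n_fb)] <- TRUE
      tibble::tibble(
        block = b, trial = seq_len(per_block),
        location_deg = loc, shape = shape, feedback = fb
      )
    })
    dplyr::bind_rows(blocks)
  })
}

#' Assemble a full session schedule
#'
#' Combines a priming schedule for the given condition with a test-phase
#' mini-block schedule. Within a subject the test schedule is meant to be
#' reused across the two sessions (pass the same `test` table), matching the
#' paradigm.
#'
#' @param condition `"arc"` or `"line"` priming.
#' @param seed Integer seed used for both phases when `priming`/`test` are not
#'   supplied.
#' @param priming,test Optional pre-built phase schedules.
#' @return An object of class `session_schedule`: a list with elements
#'   `condition`, `priming`, `test`.
#' @export
session_schedule <- function(condition = c("arc", "line"), seed = NULL,
                             priming = NULL, test = NULL) {
  condition <- match.arg(condition)
  if (is.null(priming) || is.null(test)) {
    seeds <- with_seed_or_inherit(seed, sample.int(.Machine$integer.max, 2))
    if (is.null(priming)) priming <- build_priming_schedule(condition, seeds[1])
    if (is.null(test)) test <- build_test_schedule(seeds[2])
  }
  structure(
    list(condition = condition, priming = priming, test = test),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(
    "<session_schedule> ", x$condition, "-priming: ",
    nrow(x$priming), " priming trials, ",
    nrow(x$test), " mini-blocks (", sum(x$test$n_trials), " test trials)\n",
    sep = ""
  )
  invisible(x)
}
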