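#' Signed perturbation size in centimeters
#'
#' Rotations and gains are placed on a common scale as the displacement of the
#' cursor from the true endpoint for a 15 cm reach: a rotation of `theta`
#' degrees maps to `15 * tan(theta)` cm of lateral displacement (clockwise
#' positive) and a gain delta `g` to `15 * g` cm of radial displacement
#' (overshoot positive). Both +/-8.53 degrees and gain +/-0.15 map to
#' +/-2.25 cm; +/-5.71 degrees and gain +/-0.10 map to +/-1.50 cm.
#'
#' @param kind `"rotation"` or `"gain"` (vectorized).
#' @param magnitude Signed degrees or gain delta.
#' @param reference_extent_cm Reach extent used for the conversion (15 cm).
#' @return Signed perturbation in cm.
#' @export
signed_perturbation_cm <- function(kind, magnitude,
                                   reference_extent_cm = TARGET_RADIUS_CM) {
  n <- max(length(kind), length(magnitude))
  kind <- rep_len(kind, n)
  magnitude <- rep_len(magnitude, n)
  if (any(kind == "none")) stop("veridical feedback has no perturbation size")
  near <- function(a, b) abs(abs(a) - b) < 1e-9
  ok_rot <- kind != "rotation" |
    near(magnitude, ROTATION_MAGNITUDES_DEG[1]) | near(magnitude, ROTATION_MAGNITUDES_DEG[2])
  ok_gain <- kind != "gain" | magnitude == 0 |
    near(magnitude, GAIN_DELTAS[1]) | near(magnitude, GAIN_DELTAS[2])
  if (!all(ok_rot & ok_gain)) stop("disallowed perturbation magnitude")
  ifelse(kind == "rotation",
    reference_extent_cm * tan(deg2rad(magnitude)),
    reference_extent_cm * magnitude
  )
}

#' Build the perturbed-to-test pair table
#'
#' One observation per perturbed mini-block whose perturbed and test trials
#' both survive exclusion. The response is the change from the perturbed to
#' the test trial in the perturbed dimension only: direction change (degrees)
#' for rotation mini-blocks, extent change (cm) for gain mini-blocks; the
#' other dimension is ignored to avoid interference between dimensions.
#' `delta_z` is the z-transform of the responses pooled across both
#' dimensions within each subject, used by the combined regression model.
#'
#' @param trials Trial tibble from [simulate_session()]/[simulate_cohort()],
#'   optionally carrying exclusion flags (`excluded`).
#' @param include_veridical If `TRUE`, veridical mini-blocks contribute
#'   zero-perturbation observations in both dimensions; by default they are
#'   dropped (their dimension is undefined).
#' @return A tibble with one row per pair observation: identifiers, target
#'   location, `dimension`, `pert_kind`, `pert_magnitude`, `pert_cm`,
#'   `delta_native`, `delta_z`, `rt_perturbed_ms`, `rt_test_ms`.
#' @export
build_pair_table <- function(trials, include_veridical = FALSE) {
  te <- trials[trials$phase == "test", , drop = FALSE]
  if (nrow(te) == 0) stop("no test-phase trials")
  ep <- endpoint_metrics(te$endpoint_x_cm, te$endpoint_y_cm, te$location_deg)
  key <- paste(te$subject_id, te$session, te$miniblock, sep = "\r")
  ip <- which(te$role == "perturbed")
  it <- which(te$role == "test")
  it <- it[match(key[ip], key[it])]
  stopifnot(!anyNA(it))

  kind <- te$pert_kind[ip]
  mag <- te$pert_magnitude[ip]
  keep_kind <- if (include_veridical) rep(TRUE, length(ip)) else kind != "none"
  ok <- keep_kind
  if ("excluded" %in% names(te)) {
    ok <- ok & !te$excluded[ip] & !te$excluded[it]
  }
  ip <- ip[ok]; it <- it[ok]; kind <- kind[ok]; mag <- mag[ok]

  dim_obs <- ifelse(kind == "rotation", "direction", "extent")
  d_dir <- ep$direction_deg[it] - ep$direction_deg[ip]
  d_ext <- ep$extent_cm[it] - ep$extent_cm[ip]
  delta <- ifelse(dim_obs == "direction", d_dir, d_ext)
  pert_cm <- ifelse(kind == "none", 0,
                    signed_perturbation_cm(ifelse(kind == "none", "gain", kind),
                                           mag))

  pairs <- fast_tibble(
    subject_id = te$subject_id[ip], session = te$session[ip],
    priming_condition = te$priming_condition[ip],
    miniblock = te$miniblock[ip], location_deg = te$location_deg[ip],
    pert_kind = kind, pert_magnitude = mag,
    dimension = dim_obs, pert_cm = pert_cm, delta_native = delta,
    rt_perturbed_ms = te$rt_ms[ip], rt_test_ms = te$rt_ms[it]
  )
  if (include_veridical) {
    ver <- pairs$pert_kind == "none"
    if (any(ver)) {
      extra <- pairs[ver, , drop = FALSE]
      pairs$dimension[ver] <- "direction"
      pairs$delta_native[ver] <- d_dir[ver]
      extra$dimension <- "extent"
      extra$delta_native <- d_ext[ver]
      pairs <- dplyr::bind_rows(pairs, extra)
    }
  }
  # pooled within-subject standardization across both dimensions
  mu <- tapply(pairs$delta_native, pairs$subject_id, mean)
  sdv <- tapply(pairs$delta_native, pairs$subject_id, sd)
  sid <- as.character(pairs$subject_id)
  pairs$delta_z <- (pairs$delta_native - mu[sid]) / sdv[sid]
  pairs
}

COMBINED_TERMS <- c(
  "(Intercept)", "pert_cm", "priming", "dimension",
  "pert_cm:priming", "pert_cm:dimension", "priming:dimension",
  "pert_cm:priming:dimension"
)
DIMWISE_TERMS <- c("(Intercept)", "pert_cm", "priming", "pert_cm:priming")

# design matrix of the combined model (dummy codes: arc = 1, direction = 1)
combined_design <- function(pairs) {
  p <- pairs$pert_cm
  pr <- as.numeric(pairs$priming_condition == "arc")
  d <- as.numeric(pairs$dimension == "direction")
  m <- cbind(1, p, pr, d, p * pr, p * d, pr * d, p * pr * d)
  colnames(m) <- COMBINED_TERMS
  m
}

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  n <- length(y)
  k <- fit$rank
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(
    coef = fit$coefficients,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aic = -2 * ll + 2 * (k + 1),
    bic = -2 * ll + log(n) * (k + 1),
    n_obs = n
  )
}

#' Fit per-subject regression models of single-trial motor correction
#'
#' For each subject fits:
#' * the **combined** model: standardized response `delta_z` regressed on the
#'   signed perturbation (cm), priming (dummy-coded, arc = 1), spatial
#'   dimension (dummy-coded, direction = 1), all two-way interactions, and
#'   the three-way interaction;
#' * two **dimension-wise** models on the native-unit responses (perturbation,
#'   priming, and their interaction), separately for direction and extent;
#' * an **adaptation-gating** pair: an intercept-only null model versus a
#'   perturbation-only model on `delta_z`, compared by BIC and AIC. A subject
#'   is flagged a non-adapter when either criterion favors the null model.
#'
#' @param pairs Pair table from [build_pair_table()].
#' @param per_target If `TRUE`, the combined and dimension-wise models are
#'   additionally fit per target location.
#' @return A list of class `subject_fits` with tibbles `coefficients`
#'   (`subject_id`, `model`, `location`, `term`, `estimate`), `glance`
#'   (fit statistics per model), and `adapters` (`delta_bic`, `delta_aic`,
#'   `adapter`). `location` is `"all"` for fits pooling locations.
#' @export
fit_subject_models <- function(pairs, per_target = FALSE) {
  subjects <- sort(unique(pairs$subject_id))
  coefs <- list()
  glance <- list()
  adapters <- list()

  fit_one <- function(sub, model, location) {
    if (model == "combined") {
      X <- combined_design(sub)
      y <- sub$delta_z
      terms <- COMBINED_TERMS
    } else {
      dim_keep <- if (model == "dimensionwise_direction") "direction" else "extent"
      sub <- sub[sub$dimension == dim_keep, , drop = FALSE]
      p <- sub$pert_cm
      pr <- as.numeric(sub$priming_condition == "arc")
      X <- cbind(1, p, pr, p * pr)
      colnames(X) <- DIMWISE_TERMS
      y <- sub$delta_native
      terms <- DIMWISE_TERMS
    }
    if (nrow(X) < ncol(X) + 2) stop("too few observations for model '", model, "'")
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient design for model '", model, "' (missing cells, e.g. a ",
           "single priming condition or dimension present)")
    }
    f <- ols_fit(X, y)
    list(
      coefs = tibble::tibble(
        subject_id = sub$subject_id[1], model = model, location = location,
        term = terms, estimate = unname(f$coef)
      ),
      glance = tibble::tibble(
        subject_id = sub$subject_id[1], model = model, location = location,
        r_squared = f$r_squared, aic = f$aic, bic = f$bic, n_obs = f$n_obs
      )
    )
  }

  for (s in subjects) {
    sub <- pairs[pairs$subject_id == s, , drop = FALSE]
    models <- c("combined", "dimensionwise_direction", "dimensionwise_extent")
    for (m in models) {
      r <- fit_one(sub, m, "all")
      coefs[[length(coefs) + 1]] <- r$coefs
      glance[[length(glance) + 1]] <- r$glance
      if (per_target) {
        for (loc in sort(unique(sub$location_deg))) {
          rl <- fit_one(sub[sub$location_deg == loc, , drop = FALSE], m, as.character(loc))
          coefs[[length(coefs) + 1]] <- rl$coefs
          glance[[length(glance) + 1]] <- rl$glance
        }
      }
    }
    # adaptation-evidence gating: null vs perturbation-only model
    y <- sub$delta_z
    null_fit <- ols_fit(cbind(`(Intercept)` = rep(1, length(y))), y)
    pert_fit <- ols_fit(cbind(`(Intercept)` = 1, pert_cm = sub$pert_cm), y)
    dbic <- null_fit$bic - pert_fit$bic
    daic <- null_fit$aic - pert_fit$aic
    adapters[[length(adapters) + 1]] <- tibble::tibble(
      subject_id = s, delta_bic = dbic, delta_aic = daic,
      adapter = !(dbic < 0 || daic < 0)
    )
  }

  structure(
    list(
      coefficients = dplyr::bind_rows(coefs),
      glance = dplyr::bind_rows(glance),
      adapters = dplyr::bind_rows(adapters)
    ),
    class = "subject_fits"
  )
}

#' Extract one coefficient across subjects
#'
#' @param fits A `subject_fits` object.
#' @param term Coefficient name (e.g. `"pert_cm:priming:dimension"`).
#' @param model Model name (default `"combined"`).
#' @param location `"all"` or a target location as character.
#' @return A named numeric vector of per-subject estimates.
#' @export
coef_across_subjects <- function(fits, term, model = "combined", location = "all") {
  cc <- fits$coefficients
  sel <- cc$term == term & cc$model == model & cc$location == location
  setNames(cc$estimate[sel], cc$subject_id[sel])
}

#' Gate subjects by combined-model fit quality
#'
#' @param fits A `subject_fits` object.
#' @param thresholds R-squared thresholds.
#' @return A tibble with one row per threshold: `threshold`, `n_subjects`,
#'   and a list-column `subjects` of retained subject ids (combined model,
#'   all locations, `r_squared >= threshold`). Subsets are nested by
#'   construction.
#' @export
r2_gate <- function(fits, thresholds = c(0.05, 0.1, 0.15, 0.2)) {
  g <- fits$glance
  g <- g[g$model == "combined" & g$location == "all", , drop = FALSE]
  rows <- lapply(thresholds, function(th) {
    keep <- g$subject_id[g$r_squared >= th]
    if (length(keep) == 0) warning("no subjects pass R^2 threshold ", th)
    tibble::tibble(threshold = th, n_subjects = length(keep), subjects = list(keep))
  })
  dplyr::bind_rows(rows)
}

# fast path: per-subject three-way coefficient of the combined model
threeway_coefs <- function(pairs) {
  vapply(split(pairs, pairs$subject_id), function(sub) {
    X <- combined_design(sub)
    unname(stats::lm.fit(X, sub$delta_z)$coefficients[8])
  }, 0)
}
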