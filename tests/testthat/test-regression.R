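test_that("signed perturbation sizes match the cm equivalences", {
  expect_equal(round(signed_perturbation_cm("rotation", 8.53), 2), 2.25)
  expect_equal(round(signed_perturbation_cm("rotation", -5.71), 2), -1.5)
  expect_equal(round(signed_perturbation_cm("gain", 0.15), 2), 2.25)
  expect_equal(round(signed_perturbation_cm("gain", -0.15), 2), -2.25)
  expect_equal(round(signed_perturbation_cm("gain", 0.1), 2), 1.5)
  expect_equal(signed_perturbation_cm("gain", 0), 0)
  expect_error(signed_perturbation_cm("rotation", 12), "disallowed")
  expect_error(signed_perturbation_cm("none", 0), "veridical")
})

test_that("pair table keeps one observation per surviving perturbed mini-block", {
  p <- agent_params(p_slow = 0, p_curved = 0, p_outlier = 0)
  tr <- two_session_trials(p, seed = 61, phases = "test")
  pairs <- build_pair_table(tr)
  expect_equal(nrow(pairs), 2 * 72) # 72 perturbed mini-blocks per session
  expect_true(all(pairs$pert_kind != "none"))
  # rotation mini-blocks contribute direction, gain mini-blocks extent
  expect_true(all(pairs$dimension[pairs$pert_kind == "rotation"] == "direction"))
  expect_true(all(pairs$dimension[pairs$pert_kind == "gain"] == "extent"))
  # standardization is within-subject across both dimensions pooled
  expect_equal(mean(pairs$delta_z), 0, tolerance = 1e-12)
  expect_equal(sd(pairs$delta_z), 1, tolerance = 1e-12)

  # veridical mini-blocks appear only on request, with zero perturbation
  with_ver <- build_pair_table(tr, include_veridical = TRUE)
  expect_equal(nrow(with_ver), 2 * (72 + 2 * 18))
  expect_true(all(with_ver$pert_cm[with_ver$pert_kind == "none"] == 0))

  # excluding either trial of a pair drops the pair
  tr2 <- tr
  tr2$excluded <- FALSE
  drop_id <- tr2$trial_id[tr2$phase == "test" & tr2$role == "perturbed"][1]
  tr2$excluded[tr2$trial_id == drop_id] <- TRUE
  pairs2 <- build_pair_table(tr2)
  expect_equal(nrow(pairs2), nrow(pairs) - 1)
})

test_that("OLS recovers a noiseless linear model exactly", {
  grid <- expand.grid(
    pert_cm = c(-2.25, -1.5, 1.5, 2.25),
    priming_condition = c("arc", "line"),
    dimension = c("direction", "extent"),
    rep = 1:3, stringsAsFactors = FALSE
  )
  beta <- c(0.2, -0.4, 0.1, -0.3, 0.25, 0.15, -0.05, -0.35)
  pr <- as.numeric(grid$priming_condition == "arc")
  dm <- as.numeric(grid$dimension == "direction")
  X <- cbind(1, grid$pert_cm, pr, dm, grid$pert_cm * pr, grid$pert_cm * dm,
             pr * dm, grid$pert_cm * pr * dm)
  pairs <- tibble::tibble(
    subject_id = 1L, session = 1L,
    priming_condition = grid$priming_condition,
    miniblock = seq_len(nrow(grid)), location_deg = 0,
    pert_kind = ifelse(dm == 1, "rotation", "gain"),
    pert_magnitude = 0.15, dimension = grid$dimension,
    pert_cm = grid$pert_cm,
    delta_native = drop(X %*% beta), delta_z = drop(X %*% beta),
    rt_perturbed_ms = 480, rt_test_ms = 460
  )
  fits <- fit_subject_models(pairs)
  combined <- fits$coefficients[fits$coefficients$model == "combined", ]
  expect_equal(combined$estimate, beta, tolerance = 1e-9)
  expect_equal(fits$glance$r_squared[fits$glance$model == "combined"], 1,
               tolerance = 1e-12)
})

test_that("dimension-wise slopes equal -B exactly for a noiseless agent", {
  p <- noise_free_params(lambda_dir = 1, lambda_ext = 1)
  p$b0_dir <- 0.4
  p$b0_ext <- 0.5
  p$kappa <- 0.1
  tr <- two_session_trials(p, seed = 62, phases = "test")
  fits <- fit_subject_models(build_pair_table(tr))
  cc <- fits$coefficients

  # extent (cm/cm): baseline is line priming, B = b0 + kappa
  ext <- cc[cc$model == "dimensionwise_extent", ]
  expect_equal(ext$estimate[ext$term == "pert_cm"], -0.6, tolerance = 1e-9)
  expect_equal(ext$estimate[ext$term == "pert_cm:priming"], 0.1, tolerance = 1e-9)

  # direction (deg/cm): the model pools both rotation magnitudes, so the
  # exact OLS slope is -B * sum(theta * x) / sum(x^2) with x = 15 tan(theta)
  dir <- cc[cc$model == "dimensionwise_direction", ]
  th <- c(8.53, -8.53, 5.71, -5.71)
  x <- 15 * tan(th * pi / 180)
  deg_per_cm <- sum(th * x) / sum(x^2)
  expect_equal(dir$estimate[dir$term == "pert_cm"], -0.4 * deg_per_cm,
               tolerance = 1e-9)
  expect_equal(dir$estimate[dir$term == "pert_cm:priming"], -0.1 * deg_per_cm,
               tolerance = 1e-9)
})

test_that("swapping dummy assignment flips interaction signs but not fit quality", {
  p <- agent_params(kappa = 0.2, p_slow = 0, p_curved = 0, p_outlier = 0)
  tr <- two_session_trials(p, seed = 63, phases = "test")
  pairs <- build_pair_table(tr)
  pr1 <- as.numeric(pairs$priming_condition == "arc")
  dm <- as.numeric(pairs$dimension == "direction")
  m1 <- lm(pairs$delta_z ~ pairs$pert_cm * pr1 * dm)
  pr2 <- 1 - pr1
  m2 <- lm(pairs$delta_z ~ pairs$pert_cm * pr2 * dm)
  s1 <- summary(m1)
  s2 <- summary(m2)
  expect_equal(s1$r.squared, s2$r.squared, tolerance = 1e-12)
  t1 <- s1$coefficients["pairs$pert_cm:pr1:dm", "t value"]
  t2 <- s2$coefficients["pairs$pert_cm:pr2:dm", "t value"]
  expect_equal(abs(t1), abs(t2), tolerance = 1e-9)
  expect_equal(coef(m1)[["pairs$pert_cm:pr1:dm"]],
               -coef(m2)[["pairs$pert_cm:pr2:dm"]], tolerance = 1e-9)
})

test_that("response standardization leaves t statistics invariant", {
  p <- agent_params(kappa = 0.2, p_slow = 0, p_curved = 0, p_outlier = 0)
  tr <- two_session_trials(p, seed = 64, phases = "test")
  pairs <- build_pair_table(tr)
  X <- cbind(reachprime:::combined_design(pairs))
  tvals <- function(y) {
    f <- lm(y ~ X - 1)
    summary(f)$coefficients[, "t value"]
  }
  # z-scoring is an affine map, so all slope t statistics are invariant
  # (the intercept t absorbs the location shift)
  expect_equal(tvals(pairs$delta_z)[-1], tvals(pairs$delta_native * 3.7 - 1.2)[-1],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("R-squared gating yields nested subsets and empties above the range", {
  fits <- list(
    glance = tibble::tibble(
      subject_id = 1:10, model = "combined", location = "all",
      r_squared = c(0.02, 0.05, 0.08, 0.1, 0.12, 0.15, 0.2, 0.25, 0.3, 0.41),
      aic = NA, bic = NA, n_obs = 144
    )
  )
  g <- r2_gate(fits, thresholds = c(0, 0.05, 0.1, 0.15, 0.2))
  expect_equal(g$n_subjects, c(10L, 9L, 7L, 5L, 4L))
  for (i in 2:nrow(g)) {
    expect_true(all(g$subjects[[i]] %in% g$subjects[[i - 1]]))
  }
  expect_warning(g2 <- r2_gate(fits, thresholds = 0.5), "no subjects")
  expect_equal(g2$n_subjects, 0L)
})

test_that("BIC/AIC gating separates adapting from non-adapting subjects", {
  # strong adaptation: perturbation model should win both criteria
  p_strong <- agent_params(b0_dir = 0.5, b0_ext = 0.5, kappa = 0,
                           sigma_plan_dir = 0.5, sigma_plan_ext = 0.25,
                           sigma_exec_dir = 0.3, sigma_exec_ext = 0.1,
                           p_slow = 0, p_curved = 0, p_outlier = 0)
  tr <- two_session_trials(p_strong, seed = 65, phases = "test")
  fits <- fit_subject_models(build_pair_table(tr))
  expect_true(all(fits$adapters$adapter))

  # pure-noise agent: null model should win for most simulated subjects
  p_null <- agent_params(b0_dir = 0, b0_ext = 0, kappa = 0,
                         p_slow = 0, p_curved = 0, p_outlier = 0)
  flags <- vapply(1:8, function(i) {
    tri <- two_session_trials(p_null, seed = 100 + i, phases = "test")
    f <- fit_subject_models(build_pair_table(tri))
    f$adapters$adapter
  }, TRUE)
  expect_lt(mean(flags), 0.5)
})

test_that("rank-deficient designs are rejected with an informative error", {
  p <- agent_params(p_slow = 0, p_curved = 0, p_outlier = 0)
  sc <- session_schedule("arc", seed = 66)
  tr <- simulate_session(sc, p, seed = 67, phases = "test")
  pairs <- build_pair_table(tr) # single session: only one priming condition
  expect_error(fit_subject_models(pairs), "missing cells")
})
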