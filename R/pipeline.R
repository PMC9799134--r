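#' Analysis run configuration
#'
#' Bundles everything needed for a fully reproducible simulated-cohort run.
#'
#' @param n_subjects Cohort size (33 in the reference paradigm).
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @param params [agent_params()] shared by the cohort before between-subject
#'   jitter.
#' @param subject_cv Coefficient of variation of the multiplicative lognormal
#'   between-subject jitter applied to noise SDs and baseline learning rates
#'   (0 = homogeneous cohort).
#' @param include_veridical Include veridical mini-blocks as zero-perturbation
#'   observations in the regressions.
#' @param apply_exclusions Apply the trial-exclusion rules before analysis.
#' @param r2_thresholds R-squared thresholds for the fit-quality sensitivity
#'   analysis.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 33, seed = 1, params = agent_params(),
                       subject_cv = 0.2, include_veridical = FALSE,
                       apply_exclusions = TRUE,
                       r2_thresholds = c(0.05, 0.1, 0.15, 0.2),
                       out_dir = NULL) {
  stopifnot(n_subjects >= 3, inherits(params, "agent_params"))
  structure(
    list(
      n_subjects = n_subjects, seed = seed, params = params,
      subject_cv = subject_cv, include_veridical = include_veridical,
      apply_exclusions = apply_exclusions, r2_thresholds = r2_thresholds,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$params <- x$params[!vapply(x$params, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$params <- do.call(agent_params, x$params)
  do.call(run_config, x)
}

# between-subject lognormal jitter on noise SDs and baseline learning rates
jitter_params <- function(params, cv) {
  if (cv <= 0) return(params)
  p <- unclass(params)
  for (nm in c("sigma_plan_dir", "sigma_plan_ext", "sigma_exec_dir", "sigma_exec_ext")) {
    p[[nm]] <- p[[nm]] * exp(rnorm(1, 0, cv))
  }
  for (nm in c("b0_dir", "b0_ext")) {
    p[[nm]] <- min(1, p[[nm]] * exp(rnorm(1, 0, cv)))
  }
  do.call(agent_params, p)
}

#' Simulate a full two-session cohort
#'
#' Each subject completes an arc-priming and a line-priming session (order
#' counterbalanced across subjects); the test-phase mini-block order is
#' pseudorandomized per subject but identical across that subject's two
#' sessions. Between-subject heterogeneity is introduced as lognormal jitter
#' on the noise SDs and baseline learning rates.
#'
#' @param n_subjects Number of subjects.
#' @param params Shared [agent_params()].
#' @param seed Integer master seed.
#' @param subject_cv Between-subject jitter CV (see [run_config()]).
#' @param phases Phases to simulate.
#' @param trajectories If `TRUE`, also return stylus trajectories (large).
#' @return A trial tibble, or `list(trials, trajectories)` when
#'   `trajectories = TRUE`.
#' @export
simulate_cohort <- function(n_subjects = 33, params = agent_params(), seed = 1,
                            subject_cv = 0.2, phases = c("priming", "test"),
                            trajectories = FALSE) {
  subject_seeds <- with_seed_or_inherit(seed, {
    sample.int(.Machine$integer.max, n_subjects)
  })
  empty_priming <- build_priming_schedule("arc", 1)[0, ]
  all_trials <- vector("list", n_subjects)
  all_traj <- if (trajectories) vector("list", n_subjects) else NULL

  for (i in seq_len(n_subjects)) {
    res <- withr::with_seed(subject_seeds[i], {
      p_i <- jitter_params(params, subject_cv)
      test_tab <- build_test_schedule()
      first <- if (i %% 2 == 1) "arc" else "line"
      conds <- c(first, setdiff(c("arc", "line"), first))
      sess <- lapply(1:2, function(ss) {
        priming <- if ("priming" %in% phases) {
          build_priming_schedule(conds[ss])
        } else {
          empty_priming
        }
        sched <- session_schedule(conds[ss], priming = priming, test = test_tab)
        simulate_session(sched, p_i, subject_id = i, session = ss,
                         phases = phases, trajectories = trajectories)
      })
      sess
    })
    if (trajectories) {
      all_trials[[i]] <- dplyr::bind_rows(res[[1]]$trials, res[[2]]$trials)
      all_traj[[i]] <- dplyr::bind_rows(res[[1]]$trajectories, res[[2]]$trajectories)
    } else {
      all_trials[[i]] <- dplyr::bind_rows(res)
    }
  }
  trials <- dplyr::bind_rows(all_trials)
  if (trajectories) {
    list(trials = trials, trajectories = dplyr::bind_rows(all_traj))
  } else {
    trials
  }
}

# paired comparison of explored variability between priming conditions
planned_variability_comparisons <- function(vartab, phase, family = 2) {
  sub <- vartab[vartab$phase == phase & vartab$stage == "endpoint" &
                  vartab$location == "avg", , drop = FALSE]
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "priming_condition", "dimension", "explored_pct")],
    names_from = "priming_condition", values_from = "explored_pct"
  )
  dir <- wide[wide$dimension == "direction", ]
  ext <- wide[wide$dimension == "extent", ]
  out <- dplyr::bind_rows(
    cbind(comparison = "direction: arc vs line",
          paired_t_bonferroni(dir$arc, dir$line, family)),
    cbind(comparison = "extent: line vs arc",
          paired_t_bonferroni(ext$line, ext$arc, family))
  )
  out$phase <- phase
  tibble::as_tibble(out)
}

#' Run the full simulated-study analysis
#'
#' Orchestrates simulate - exclude - variability - regression - group stats
#' end to end for one cohort: explored-variability ANOVA and planned
#' comparisons for priming and test phases, the combined three-way regression
#' test (overall, per target location, under R-squared gating, and excluding
#' BIC/AIC non-adapters), dimension-wise follow-ups at the left target,
#' between-subject correlations of priming effects on learning versus
#' variability, and the response-time analysis. Intermediate tables are
#' written as CSV when `config$out_dir` is set.
#'
#' @param config A [run_config()].
#' @return A list of class `reachprime_results` containing all intermediate
#'   and final tables (see [replicate_study_table()] for the condensed view).
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  trials <- simulate_cohort(
    n_subjects = config$n_subjects, params = config$params,
    seed = config$seed, subject_cv = config$subject_cv
  )
  trials <- flag_exclusions(trials)
  if (!config$apply_exclusions) {
    trials$excluded <- FALSE
  }
  excl <- exclusion_summary(trials)

  vartab <- phase_variability_table(trials, keep_locations = TRUE)
  var_avg <- vartab[vartab$stage == "endpoint" & vartab$location == "avg", ]
  anovas <- dplyr::bind_rows(lapply(c("priming", "test"), function(ph) {
    res <- rm_anova_2x2(var_avg[var_avg$phase == ph, ],
                        "explored_pct", "subject_id",
                        "priming_condition", "dimension")
    res$phase <- ph
    res
  }))
  planned <- dplyr::bind_rows(
    planned_variability_comparisons(vartab, "priming"),
    planned_variability_comparisons(vartab, "test")
  )

  pairs <- build_pair_table(trials, include_veridical = config$include_veridical)
  fits <- fit_subject_models(pairs, per_target = TRUE)

  tw_all <- one_sample_t_coeffs(
    coef_across_subjects(fits, "pert_cm:priming:dimension")
  )
  tw_all$scope <- "all targets"
  tw_loc <- dplyr::bind_rows(lapply(TARGET_LOCATIONS_DEG, function(loc) {
    res <- one_sample_t_coeffs(
      coef_across_subjects(fits, "pert_cm:priming:dimension",
                           location = as.character(loc)),
      family = 3
    )
    res$scope <- paste("target", loc)
    res
  }))

  followups <- dplyr::bind_rows(lapply(
    c(dimensionwise_direction = "direction", dimensionwise_extent = "extent"),
    function(dm) {
      model <- paste0("dimensionwise_", dm)
      res <- one_sample_t_coeffs(
        coef_across_subjects(fits, "pert_cm:priming", model = model,
                             location = "-30"),
        family = 2
      )
      res$scope <- paste(dm, "at left target")
      res
    }
  ))

  gates <- r2_gate(fits, config$r2_thresholds)
  tw_coef <- coef_across_subjects(fits, "pert_cm:priming:dimension")
  gated <- dplyr::bind_rows(lapply(seq_len(nrow(gates)), function(i) {
    keep <- as.character(gates$subjects[[i]])
    if (length(keep) < 3) {
      return(NULL)
    }
    res <- one_sample_t_coeffs(tw_coef[keep])
    res$scope <- sprintf("R^2 >= %.2f (%d subjects)", gates$threshold[i], length(keep))
    res
  }))
  ad <- fits$adapters
  adapters_only <- as.character(ad$subject_id[ad$adapter])
  tw_adapters <- if (length(adapters_only) >= 3) {
    res <- one_sample_t_coeffs(tw_coef[adapters_only])
    res$scope <- sprintf("adapters only (%d subjects)", length(adapters_only))
    res
  } else {
    NULL
  }

  correlations <- priming_effect_correlations(fits, vartab)
  rt <- within_subject_rt_analysis(pairs)

  results <- structure(
    list(
      config = config, trials = trials, exclusions = excl,
      variability = vartab, anovas = anovas, planned_comparisons = planned,
      pairs = pairs, fits = fits, threeway_all = tw_all,
      threeway_by_target = tw_loc, followups = followups,
      r2_gates = gates, threeway_gated = gated, threeway_adapters = tw_adapters,
      correlations = correlations, rt_analysis = rt
    ),
    class = "reachprime_results"
  )
  results$study_table <- replicate_study_table(results)
  if (!is.null(config$out_dir)) {
    write_results(results, config$out_dir)
  }
  results
}

#' Between-subject correlations of priming effects on learning and variability
#'
#' At the left target location (the location with the largest initial
#' variability in the paradigm), correlates each subject's priming-related
#' gain in redundant-dimension learning rate (from the dimension-wise
#' regression interaction) with the priming-related change in explored
#' variability during the priming phase, per dimension, Bonferroni family 2.
#'
#' @param fits A `subject_fits` object fit with `per_target = TRUE`.
#' @param vartab Output of [phase_variability_table()] with
#'   `keep_locations = TRUE`.
#' @param location Target location (as character) at which effects are
#'   correlated; `"-30"` is the left target.
#' @return A tibble with one row per dimension.
#' @export
priming_effect_correlations <- function(fits, vartab, location = "-30") {
  v <- vartab[vartab$phase == "priming" & vartab$stage == "endpoint" &
                vartab$location == location, ]
  wide <- tidyr::pivot_wider(
    v[, c("subject_id", "priming_condition", "dimension", "explored_pct")],
    names_from = "priming_condition", values_from = "explored_pct"
  )
  dplyr::bind_rows(lapply(c("direction", "extent"), function(dm) {
    model <- paste0("dimensionwise_", dm)
    inter <- coef_across_subjects(fits, "pert_cm:priming", model = model,
                                  location = location)
    # priming-related gain in learning along the redundant dimension:
    # arc adds direction learning (slopes are negative), line adds extent learning
    learning_effect <- if (dm == "direction") -inter else inter
    w <- wide[wide$dimension == dm, ]
    var_effect <- if (dm == "direction") w$arc - w$line else w$line - w$arc
    var_effect <- var_effect[match(names(learning_effect), as.character(w$subject_id))]
    res <- pearson_between_subjects(var_effect, unname(learning_effect), family = 2)
    res$dimension <- dm
    res
  }))
}

#' Condensed table of the study's statistical readouts
#'
#' One row per test computed by [run_full_analysis()] on the simulated
#' cohort: ANOVA interactions, planned variability comparisons, the combined
#' three-way regression test at every scope, follow-ups, correlations, and
#' response-time tests.
#'
#' @param results A `reachprime_results` object.
#' @return A tibble with columns `test`, `statistic`, `df`, `p_raw`,
#'   `p_corrected`, `effect_size`, `n`.
#' @export
replicate_study_table <- function(results) {
  row <- function(test, statistic, df, p_raw, p_corr, effect, n) {
    tibble::tibble(
      test = test, statistic = statistic, df = df, p_raw = p_raw,
      p_corrected = p_corr, effect_size = effect, n = n
    )
  }
  an <- results$anovas[results$anovas$effect == "A:B", ]
  rows <- list(
    row(paste0("ANOVA priming x dimension (", an$phase, ")"),
        an$statistic, an$df2, an$p_raw, an$p_raw, an$partial_eta_sq, an$n)
  )
  pc <- results$planned_comparisons
  rows <- c(rows, list(row(
    paste0("planned: ", pc$comparison, " (", pc$phase, ")"),
    pc$statistic, pc$df, pc$p_raw, pc$p_bonferroni, pc$cohens_d, pc$n
  )))
  tw <- dplyr::bind_rows(
    results$threeway_all, results$threeway_by_target,
    results$followups, results$threeway_gated, results$threeway_adapters
  )
  rows <- c(rows, list(row(
    paste0("three-way/follow-up: ", tw$scope),
    tw$statistic, tw$df, tw$p_raw, tw$p_bonferroni, tw$cohens_d, tw$n
  )))
  co <- results$correlations
  rows <- c(rows, list(row(
    paste0("correlation learning~variability (", co$dimension, ", left target)"),
    co$statistic, co$df, co$p_raw, co$p_bonferroni, co$r_squared, co$n
  )))
  if (!is.null(results$rt_analysis)) {
    rc <- results$rt_analysis$rt_change
    rr <- results$rt_analysis$rt_correction_cor
    rows <- c(rows, list(
      row("RT perturbed vs test", rc$statistic, rc$df, rc$p_raw,
          rc$p_bonferroni, rc$cohens_d, rc$n),
      row(paste0("RT change ~ |correction| (", rr$dimension, ")"),
          rr$statistic, rr$df, rr$p_raw, rr$p_bonferroni, rr$mean_r_squared, rr$n)
    ))
  }
  dplyr::bind_rows(rows)
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(results$trials, "trials.csv")
  wcsv(results$pairs, "pairs.csv")
  wcsv(results$variability, "variability.csv")
  wcsv(results$exclusions$per_subject, "exclusions_per_subject.csv")
  wcsv(results$exclusions$overall, "exclusions_overall.csv")
  wcsv(results$fits$coefficients, "coefficients.csv")
  wcsv(results$fits$glance, "model_fit_stats.csv")
  wcsv(results$fits$adapters, "adapters.csv")
  wcsv(results$study_table, "study_table.csv")
  jsonlite::write_json(results$study_table, file.path(out_dir, "study_table.json"),
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}

#' Parameter-recovery study for the priming effect on learning
#'
#' Simulates replicate cohorts (test phase only), runs the combined
#' per-subject regression and the group-level one-sample t test of the
#' three-way interaction in each, and reports rejection rates. With the
#' priming-dependent learning increment `kappa > 0` the test should reject in
#' the hypothesized direction (negative mean coefficient under the package's
#' dummy coding); with `kappa = 0` the rejection rate estimates the type-I
#' error.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param n_subjects Subjects per cohort.
#' @param params [agent_params()] for the cohorts.
#' @param seed Integer master seed.
#' @param alpha Significance level.
#' @param subject_cv Between-subject jitter CV.
#' @return A list with `results` (per-cohort tibble: `p`, `mean_coef`,
#'   `reject`, `reject_hypothesized`), `rejection_rate`, and
#'   `rejection_rate_hypothesized`.
#' @export
priming_recovery_study <- function(n_cohorts, n_subjects = 33,
                                   params = agent_params(), seed = 1,
                                   alpha = 0.05, subject_cv = 0.2) {
  cohort_seeds <- with_seed_or_inherit(seed, {
    sample.int(.Machine$integer.max, n_cohorts)
  })
  res <- vector("list", n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    trials <- simulate_cohort(
      n_subjects = n_subjects, params = params, seed = cohort_seeds[cc],
      subject_cv = subject_cv, phases = "test"
    )
    pairs <- build_pair_table(trials)
    coefs <- threeway_coefs(pairs)
    tt <- t.test(coefs, mu = 0)
    res[[cc]] <- tibble::tibble(
      cohort = cc, p = tt$p.value, mean_coef = mean(coefs),
      reject = tt$p.value < alpha,
      reject_hypothesized = tt$p.value < alpha && mean(coefs) < 0
    )
  }
  results <- dplyr::bind_rows(res)
  list(
    results = results,
    rejection_rate = mean(results$reject),
    rejection_rate_hypothesized = mean(results$reject_hypothesized)
  )
}
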