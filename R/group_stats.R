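bonferroni <- function(p, family) pmin(1, family * p)

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete subject x factor A (2 levels) x
#' factor B (2 levels) design, with each effect tested against its own
#' effect-by-subject error stratum (df 1, n - 1) and partial eta squared
#' computed as `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data A data frame in long format.
#' @param value,subject,factor_a,factor_b Column names (strings).
#' @return A tibble with one row per effect (`A`, `B`, `A:B`): `statistic`
#'   (F), `df1`, `df2`, `p_raw`, `partial_eta_sq`, `n`.
#' @export
rm_anova_2x2 <- function(data, value, subject, factor_a, factor_b) {
  d <- data.frame(
    y = data[[value]],
    subject = factor(data[[subject]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2) stop("both factors must have 2 levels")
  counts <- table(d$subject, d$A, d$B)
  if (any(counts != 1)) stop("design must be complete: one value per subject and cell")
  n <- nlevels(d$subject)

  fit <- aov(y ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  effect_row <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    ss_eff <- tab[i, "Sum Sq"]
    ss_err <- tab[j, "Sum Sq"]
    f_val <- tab[i, "F value"]
    p_val <- tab[i, "Pr(>F)"]
    if (ss_eff < 1e-12) { # zero effect: define F = 0 even if the error SS is 0
      f_val <- 0
      p_val <- 1
    }
    tibble::tibble(
      effect = term, statistic = f_val,
      df1 = tab[i, "Df"], df2 = tab[j, "Df"],
      p_raw = p_val,
      partial_eta_sq = if (ss_eff < 1e-12) 0 else ss_eff / (ss_eff + ss_err),
      n = n
    )
  }
  dplyr::bind_rows(
    effect_row("Error: subject:A", "A"),
    effect_row("Error: subject:B", "B"),
    effect_row("Error: subject:A:B", "A:B")
  )
}

#' Paired t test with Bonferroni correction
#'
#' Two-tailed dependent-samples t test; Cohen's d is the mean of the paired
#' differences divided by their standard deviation.
#'
#' @param x,y Paired measurements.
#' @param family Bonferroni family size.
#' @return A one-row tibble: `statistic` (t), `df`, `p_raw`,
#'   `p_bonferroni`, `cohens_d`, `mean_diff`, `n`, `family`.
#' @export
paired_t_bonferroni <- function(x, y, family = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (sd(d) == 0) stop("zero-variance differences: paired t undefined")
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    kind = "paired_t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_raw = tt$p.value, p_bonferroni = bonferroni(tt$p.value, family),
    cohens_d = mean(d) / sd(d), mean_diff = mean(d),
    n = length(x), family = family
  )
}

#' One-sample t test of coefficients against zero
#'
#' Used to test per-subject regression coefficients at the group level.
#'
#' @param coefs Per-subject coefficients.
#' @param family Bonferroni family size.
#' @param mu Null value.
#' @return A one-row tibble as in [paired_t_bonferroni()].
#' @export
one_sample_t_coeffs <- function(coefs, family = 1, mu = 0) {
  stopifnot(length(coefs) >= 3)
  if (sd(coefs) == 0) stop("zero-variance coefficients: t undefined")
  tt <- t.test(coefs, mu = mu)
  tibble::tibble(
    kind = "one_sample_t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_raw = tt$p.value, p_bonferroni = bonferroni(tt$p.value, family),
    cohens_d = (mean(coefs) - mu) / sd(coefs), mean_diff = mean(coefs) - mu,
    n = length(coefs), family = family
  )
}

#' Pearson correlation between subjects
#'
#' @param xs,ys Paired per-subject values.
#' @param family Bonferroni family size.
#' @return A one-row tibble: `r`, `r_squared`, `statistic` (t), `df`,
#'   `p_raw`, `p_bonferroni`, `n`, `family`.
#' @export
pearson_between_subjects <- function(xs, ys, family = 1) {
  stopifnot(length(xs) == length(ys), length(xs) >= 4)
  if (sd(xs) == 0 || sd(ys) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(xs, ys, method = "pearson")
  r <- unname(ct$estimate)
  tibble::tibble(
    kind = "pearson",
    r = r, r_squared = r^2,
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_raw = ct$p.value, p_bonferroni = bonferroni(ct$p.value, family),
    n = length(xs), family = family
  )
}

#' Group test of within-subject correlations via Fisher z
#'
#' Per-subject Pearson correlations are atanh-transformed and tested against
#' zero with a two-tailed one-sample t test.
#'
#' @param rs Per-subject correlation coefficients (`NA` dropped).
#' @param family Bonferroni family size.
#' @return A one-row tibble with the mean r, mean r squared, and the t test
#'   on the Fisher z values.
#' @export
fisher_z_onesample <- function(rs, family = 1) {
  rs <- rs[!is.na(rs)]
  stopifnot(length(rs) >= 3)
  z <- atanh(rs)
  if (sd(z) == 0 && mean(z) == 0) {
    return(tibble::tibble(
      kind = "fisher_z_t", mean_r = 0, mean_r_squared = 0,
      statistic = 0, df = length(rs) - 1, p_raw = 1, p_bonferroni = 1,
      n = length(rs), family = family
    ))
  }
  tt <- t.test(z, mu = 0)
  tibble::tibble(
    kind = "fisher_z_t",
    mean_r = mean(rs), mean_r_squared = mean(rs^2),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_raw = tt$p.value, p_bonferroni = bonferroni(tt$p.value, family),
    n = length(rs), family = family
  )
}

#' Response-time analysis of perturbed versus test trials
#'
#' Tests (a) whether response times change from the perturbed to the test
#' trial (paired t across subjects on per-subject mean RTs) and (b) whether
#' the within-subject RT change correlates with the magnitude of the motor
#' correction, per dimension (per-subject Pearson r, Fisher-z one-sample t).
#' A degenerate all-constant RT difference yields t = 0, p = 1 rather than an
#' error.
#'
#' @param pairs Pair table from [build_pair_table()] (needs `rt_perturbed_ms`,
#'   `rt_test_ms`, `delta_native`, `dimension`).
#' @return A list with `rt_change` (one-row tibble) and `rt_correction_cor`
#'   (one row per dimension).
#' @export
within_subject_rt_analysis <- function(pairs) {
  if (!all(c("rt_perturbed_ms", "rt_test_ms") %in% names(pairs)) ||
      all(is.na(pairs$rt_perturbed_ms))) {
    warning("response times missing; RT analysis skipped")
    return(NULL)
  }
  by_subj <- pairs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      rt_perturbed = mean(.data$rt_perturbed_ms),
      rt_test = mean(.data$rt_test_ms),
      .groups = "drop"
    )
  d <- by_subj$rt_perturbed - by_subj$rt_test
  rt_change <- if (sd(d) == 0 && mean(d) == 0) {
    tibble::tibble(
      kind = "paired_t", statistic = 0, df = nrow(by_subj) - 1,
      p_raw = 1, p_bonferroni = 1, cohens_d = 0, mean_diff = 0,
      n = nrow(by_subj), family = 1
    )
  } else {
    paired_t_bonferroni(by_subj$rt_perturbed, by_subj$rt_test)
  }
  rt_change$mean_rt_perturbed <- mean(by_subj$rt_perturbed)
  rt_change$mean_rt_test <- mean(by_subj$rt_test)

  cors <- dplyr::bind_rows(lapply(c("direction", "extent"), function(dm) {
    sub <- pairs[pairs$dimension == dm, , drop = FALSE]
    rs <- vapply(split(sub, sub$subject_id), function(ss) {
      drt <- ss$rt_test_ms - ss$rt_perturbed_ms
      corr <- abs(ss$delta_native)
      if (sd(drt) == 0 || sd(corr) == 0) NA_real_ else cor(drt, corr)
    }, 0)
    out <- if (sum(!is.na(rs)) < 3) {
      tibble::tibble(
        kind = "fisher_z_t", mean_r = NA_real_, mean_r_squared = NA_real_,
        statistic = NA_real_, df = NA_real_, p_raw = NA_real_,
        p_bonferroni = NA_real_, n = sum(!is.na(rs)), family = 1
      )
    } else {
      fisher_z_onesample(rs)
    }
    out$dimension <- dm
    out
  }))
  list(rt_change = rt_change, rt_correction_cor = cors)
}
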