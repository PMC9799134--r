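#' Generative agent parameters
#'
#' Parameters of the simulated reacher. Endpoints are generated per trial as
#' `aim + planning draw + execution draw`, decomposed into direction (degrees
#' about the home position, relative to the target bearing, clockwise positive)
#' and extent (cm relative to the 15 cm target radius). The aim absorbs each
#' planning draw and is pulled back toward the target by a per-dimension gain
#' `lambda`; a small gain lets planning noise accumulate as a
#' lag-1-autocorrelated random walk along that dimension. On a perturbed trial
#' the next-trial aim in the perturbed dimension shifts by `-B * error`, with
#' `B = b0 + kappa` when that dimension was redundant during the session's
#' priming and `B = b0` otherwise.
#'
#' @param sigma_plan_dir,sigma_exec_dir Planning/execution noise SD for
#'   direction, degrees.
#' @param sigma_plan_ext,sigma_exec_ext Planning/execution noise SD for
#'   extent, cm.
#' @param lambda_redundant,lambda_constrained Aim-correction gain in `[0, 1]`
#'   applied to the redundant and the constrained dimension, respectively
#'   (direction is redundant under arc priming, extent under line priming).
#' @param lambda_dir,lambda_ext Optional explicit per-dimension gains; when
#'   supplied they override the redundant/constrained mapping.
#' @param b0_dir,b0_ext Baseline single-trial learning rates in `[0, 1]`.
#' @param kappa Increment of the learning rate for the dimension that was
#'   redundant during priming (the hypothesized priming effect; `0` switches
#'   it off).
#' @param p_slow,p_curved,p_outlier Per-trial artifact probabilities: slow
#'   movements (mean speed below 20 cm/s), strongly curved paths (maximum
#'   deviation above 2 cm), and gross endpoint outliers (10-14 cm from the
#'   target).
#' @param rt_mean_ms,rt_sd_ms,rt_test_drop_ms Response-time model: Gaussian
#'   with the given mean and SD, with the mean lowered by `rt_test_drop_ms` on
#'   mini-block test trials.
#' @param traj_jitter_cm Positional jitter SD added to simulated trajectory
#'   samples during the movement.
#' @return An object of class `agent_params` (a validated list).
#' @export
agent_params <- function(sigma_plan_dir = 1.95, sigma_plan_ext = 0.88,
                         sigma_exec_dir = 1.17, sigma_exec_ext = 0.12,
                         lambda_redundant = 0.2, lambda_constrained = 0.9,
                         lambda_dir = NULL, lambda_ext = NULL,
                         b0_dir = 0.15, b0_ext = 0.15, kappa = 0.15,
                         p_slow = 0.013, p_curved = 0.001, p_outlier = 0.001,
                         rt_mean_ms = 484, rt_sd_ms = 60, rt_test_drop_ms = 23,
                         traj_jitter_cm = 0.002) {
  p <- list(
    sigma_plan_dir = sigma_plan_dir, sigma_plan_ext = sigma_plan_ext,
    sigma_exec_dir = sigma_exec_dir, sigma_exec_ext = sigma_exec_ext,
    lambda_redundant = lambda_redundant, lambda_constrained = lambda_constrained,
    lambda_dir = lambda_dir, lambda_ext = lambda_ext,
    b0_dir = b0_dir, b0_ext = b0_ext, kappa = kappa,
    p_slow = p_slow, p_curved = p_curved, p_outlier = p_outlier,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    rt_test_drop_ms = rt_test_drop_ms, traj_jitter_cm = traj_jitter_cm
  )
  sds <- unlist(p[c("sigma_plan_dir", "sigma_plan_ext", "sigma_exec_dir", "sigma_exec_ext")])
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  unit <- unlist(p[c(
    "lambda_redundant", "lambda_constrained", "b0_dir", "b0_ext",
    "p_slow", "p_curved", "p_outlier"
  )])
  if (any(unit < 0 | unit > 1)) stop("gains, rates, and probabilities must be in [0, 1]")
  if (kappa < 0) stop("kappa must be >= 0")
  for (nm in c("lambda_dir", "lambda_ext")) {
    if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1)) {
      stop(nm, " must be in [0, 1]")
    }
  }
  structure(p, class = "agent_params")
}

# per-dimension aim-correction gains for a given priming condition
resolve_lambdas <- function(params, condition) {
  lam_dir <- params$lambda_dir %||%
    if (condition == "arc") params$lambda_redundant else params$lambda_constrained
  lam_ext <- params$lambda_ext %||%
    if (condition == "line") params$lambda_redundant else params$lambda_constrained
  c(dir = lam_dir, ext = lam_ext)
}

#' Apply an endpoint-feedback perturbation to a movement endpoint
#'
#' Rotations add the signed magnitude (degrees, clockwise positive) to the
#' endpoint bearing about the home position while keeping radial distance
#' veridical; gain perturbations multiply the radial distance by
#' `1 + magnitude` while keeping the bearing veridical.
#'
#' @param x,y Endpoint coordinates, cm relative to the home position
#'   (straight ahead = +y).
#' @param kind Perturbation kind (`"none"`, `"rotation"`, `"gain"`); recycled
#'   against the coordinates.
#' @param magnitude Signed magnitude (degrees or gain delta).
#' @return A tibble with cursor coordinates `x`, `y`.
#' @export
apply_perturbation <- function(x, y, kind = "none", magnitude = 0) {
  n <- max(length(x), length(y), length(kind), length(magnitude))
  x <- rep_len(x, n); y <- rep_len(y, n)
  kind <- rep_len(kind, n); magnitude <- rep_len(magnitude, n)
  r <- sqrt(x^2 + y^2)
  if (any(r == 0 & kind != "none")) {
    stop("endpoint at the home position has no defined bearing; cannot perturb")
  }
  theta <- bearing_deg(x, y)
  theta <- ifelse(kind == "rotation", theta + magnitude, theta)
  r <- ifelse(kind == "gain", r * (1 + magnitude), r)
  fast_tibble(x = r * sin(deg2rad(theta)), y = r * cos(deg2rad(theta)))
}

#' Simulate a one-dimensional aim-point walk
#'
#' The core aim recursion in a single dimension, exposed for studying its
#' random-walk behavior: `endpoint[t] = aim[t] + plan[t] + exec[t]`,
#' `aim[t+1] = (1 - lambda) * (aim[t] + plan[t])`. With `lambda = 0` the
#' endpoints follow a cumulative sum of planning draws plus independent
#' execution noise: variance about the start grows linearly at slope
#' `sigma_plan^2` and the series is positively lag-1 autocorrelated.
#'
#' @param n_trials Number of trials.
#' @param sigma_plan,sigma_exec Noise SDs.
#' @param lambda Aim-correction gain in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial`, `aim`, `plan`, `exec`, `endpoint`.
#' @export
simulate_endpoint_walk <- function(n_trials, sigma_plan, sigma_exec, lambda,
                                   seed = NULL) {
  with_seed_or_inherit(seed, {
    plan <- rnorm(n_trials, 0, sigma_plan)
    exec <- rnorm(n_trials, 0, sigma_exec)
    aim <- numeric(n_trials)
    a <- 0
    for (t in seq_len(n_trials)) {
      aim[t] <- a
      a <- (1 - lambda) * (a + plan[t])
    }
    tibble::tibble(
      trial = seq_len(n_trials), aim = aim, plan = plan, exec = exec,
      endpoint = aim + plan + exec
    )
  })
}

# expand a session schedule into one row per trial
expand_schedule <- function(schedule, phases) {
  parts <- list()
  if ("priming" %in% phases && nrow(schedule$priming) > 0) {
    pr <- schedule$priming
    n <- nrow(pr)
    parts$priming <- fast_tibble(
      phase = rep("priming", n), block = pr$block, miniblock = rep(NA_integer_, n),
      trial = pr$trial, role = rep("plain", n), shape = pr$shape,
      location_deg = pr$location_deg, feedback = pr$feedback,
      pert_kind = rep("none", n), pert_magnitude = rep(0, n)
    )
  }
  if ("test" %in% phases) {
    te <- schedule$test
    idx <- rep.int(seq_len(nrow(te)), te$n_trials)
    within <- sequence(te$n_trials)
    n_tr <- te$n_trials[idx]
    n <- length(idx)
    role <- rep("plain", n)
    role[within == n_tr - 1L] <- "perturbed"
    role[within == n_tr] <- "test"
    perturbed <- role == "perturbed"
    kind <- rep("none", n)
    kind[perturbed] <- te$pert_kind[idx][perturbed]
    mag <- rep(0, n)
    mag[perturbed] <- te$pert_magnitude[idx][perturbed]
    parts$test <- fast_tibble(
      phase = rep("test", n), block = rep(NA_integer_, n), miniblock = te$miniblock[idx],
      trial = within, role = role, shape = rep("dot", n),
      location_deg = te$location_deg[idx],
      feedback = perturbed,
      pert_kind = kind, pert_magnitude = mag
    )
  }
  if (length(parts) == 1) parts[[1]] else dplyr::bind_rows(parts)
}

#' Simulate one experimental session
#'
#' Runs the generative agent over a session schedule, producing per-trial
#' endpoints, cursor positions on perturbed trials, response times, injected
#' artifacts, and analytically derived movement summaries (duration, path
#' length, mean speed, maximum path deviation). Optionally also generates
#' 200-Hz minimum-jerk stylus trajectories for every trial.
#'
#' @param schedule A [session_schedule()].
#' @param params An [agent_params()] object.
#' @param subject_id,session Identifiers stored in the output.
#' @param seed Optional integer seed.
#' @param phases Phases to simulate (`"priming"`, `"test"`, or both).
#' @param trajectories If `TRUE`, return a list with elements `trials` and
#'   `trajectories` (long-format samples keyed by `trial_id`); otherwise just
#'   the trial tibble.
#' @return A tibble of trials, or a list when `trajectories = TRUE`.
#' @export
simulate_session <- function(schedule, params, subject_id = 1L, session = 1L,
                             seed = NULL, phases = c("priming", "test"),
                             trajectories = FALSE) {
  stopifnot(inherits(schedule, "session_schedule"), inherits(params, "agent_params"))
  condition <- schedule$condition
  lam <- resolve_lambdas(params, condition)
  b_dir <- params$b0_dir + params$kappa * (condition == "arc")
  b_ext <- params$b0_ext + params$kappa * (condition == "line")

  tab <- expand_schedule(schedule, phases)
  n <- nrow(tab)

  with_seed_or_inherit(seed, {
    p_dir <- rnorm(n, 0, params$sigma_plan_dir)
    p_ext <- rnorm(n, 0, params$sigma_plan_ext)
    e_dir <- rnorm(n, 0, params$sigma_exec_dir)
    e_ext <- rnorm(n, 0, params$sigma_exec_ext)
    inj_slow <- runif(n) < params$p_slow
    inj_curved <- runif(n) < params$p_curved
    inj_outlier <- runif(n) < params$p_outlier

    dir_off <- numeric(n)
    ext_off <- numeric(n)
    a_dir <- 0
    a_ext <- 0
    role <- tab$role
    kind <- tab$pert_kind
    mag <- tab$pert_magnitude
    is_rot <- role == "perturbed" & kind == "rotation"
    is_gain <- role == "perturbed" & kind == "gain"
    one_m_ld <- 1 - lam[["dir"]]
    one_m_le <- 1 - lam[["ext"]]
    for (t in seq_len(n)) {
      d <- a_dir + p_dir[t] + e_dir[t]
      x <- a_ext + p_ext[t] + e_ext[t]
      dir_off[t] <- d
      ext_off[t] <- x
      a_dir <- one_m_ld * (a_dir + p_dir[t])
      a_ext <- one_m_le * (a_ext + p_ext[t])
      if (is_rot[t]) {
        a_dir <- a_dir - b_dir * mag[t]
      } else if (is_gain[t]) {
        a_ext <- a_ext - b_ext * mag[t] * (TARGET_RADIUS_CM + x)
      }
    }

    bearing <- tab$location_deg + dir_off
    radius <- TARGET_RADIUS_CM + ext_off
    ex <- radius * sin(deg2rad(bearing))
    ey <- radius * cos(deg2rad(bearing))

    # gross outliers: endpoint displaced 10-14 cm from the target center
    if (any(inj_outlier)) {
      k <- which(inj_outlier)
      ang <- runif(length(k), 0, 2 * pi)
      dist <- runif(length(k), 10, 14)
      tx <- TARGET_RADIUS_CM * sin(deg2rad(tab$location_deg[k]))
      ty <- TARGET_RADIUS_CM * cos(deg2rad(tab$location_deg[k]))
      ex[k] <- tx + dist * cos(ang)
      ey[k] <- ty + dist * sin(ang)
      radius[k] <- sqrt(ex[k]^2 + ey[k]^2)
    }

    # movement summaries: clean mean speed drawn at 24-36 cm/s (above the
    # 20 cm/s threshold for any plausible extent), slow artifacts at 10-15 cm/s
    speed_draw <- runif(n, 24, 36)
    speed_draw[inj_slow] <- runif(sum(inj_slow), 10, 15)
    duration <- radius / speed_draw * 1000
    bulge <- rep(0, n)
    bulge[inj_curved] <- runif(sum(inj_curved), 2.5, 4)
    path_len <- radius * (1 + 2 * (bulge / radius)^2)
    mean_speed <- path_len / (duration / 1000)

    rt <- rnorm(n, params$rt_mean_ms - params$rt_test_drop_ms * (role == "test"),
                params$rt_sd_ms)
    rt <- pmax(rt, 150)

    cursor_x <- rep(NA_real_, n)
    cursor_y <- rep(NA_real_, n)
    pert_rows <- which(kind != "none")
    if (length(pert_rows) > 0) {
      cur <- apply_perturbation(ex[pert_rows], ey[pert_rows],
                                kind[pert_rows], mag[pert_rows])
      cursor_x[pert_rows] <- cur$x
      cursor_y[pert_rows] <- cur$y
    }

    trial_id <- sprintf("s%03d_ss%d_t%04d", subject_id, session, seq_len(n))

    trials <- fast_tibble(
      trial_id = trial_id,
      subject_id = rep(subject_id, n), session = rep(session, n),
      priming_condition = rep(condition, n),
      phase = tab$phase, block = tab$block, miniblock = tab$miniblock,
      trial = tab$trial, role = role, shape = tab$shape,
      location_deg = tab$location_deg, feedback = tab$feedback,
      pert_kind = kind, pert_magnitude = mag,
      endpoint_x_cm = ex, endpoint_y_cm = ey,
      cursor_x_cm = cursor_x, cursor_y_cm = cursor_y,
      duration_ms = duration, path_length_cm = path_len,
      mean_speed_cm_s = mean_speed, max_dev_cm = bulge,
      rt_ms = rt,
      injected_slow = inj_slow, injected_curved = inj_curved,
      injected_outlier = inj_outlier
    )

    if (!trajectories) {
      return(trials)
    }
    traj <- simulate_trajectories(trials, params)
    list(trials = trials, trajectories = traj)
  })
}

#' Generate minimum-jerk stylus trajectories for simulated trials
#'
#' Each reach is a minimum-jerk path from the home position to the trial
#' endpoint sampled at 200 Hz over the trial's movement duration, with a
#' perpendicular sinusoidal bulge on injected curved trials, small positional
#' jitter during the movement, and a 60 ms stationary tail after the endpoint.
#'
#' @param trials A trial tibble from [simulate_session()].
#' @param params The [agent_params()] used for the simulation (jitter SD).
#' @return A long tibble with columns `trial_id`, `t_ms`, `x_cm`, `y_cm`.
#' @export
simulate_trajectories <- function(trials, params) {
  dt <- 5
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    n_move <- max(2L, round(trials$duration_ms[i] / dt))
    tau <- seq(0, 1, length.out = n_move + 1)
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    ex <- trials$endpoint_x_cm[i]
    ey <- trials$endpoint_y_cm[i]
    x <- ex * s
    y <- ey * s
    h <- trials$max_dev_cm[i]
    if (h > 0) {
      r <- sqrt(ex^2 + ey^2)
      x <- x + h * sin(pi * s) * (ey / r)
      y <- y - h * sin(pi * s) * (ex / r)
    }
    mid <- seq_len(n_move - 1) + 1L
    x[mid] <- x[mid] + rnorm(length(mid), 0, params$traj_jitter_cm)
    y[mid] <- y[mid] + rnorm(length(mid), 0, params$traj_jitter_cm)
    n_tail <- 12L
    x <- c(x, rep(ex, n_tail))
    y <- c(y, rep(ey, n_tail))
    out[[i]] <- tibble::tibble(
      trial_id = trials$trial_id[i],
      t_ms = (seq_along(x) - 1) * dt,
      x_cm = x, y_cm = y
    )
  }
  dplyr::bind_rows(out)
}
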