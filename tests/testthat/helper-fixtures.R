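# shared fixtures built in code

noise_free_params <- function(...) {
  agent_params(
    sigma_plan_dir = 0, sigma_plan_ext = 0,
    sigma_exec_dir = 0, sigma_exec_ext = 0,
    b0_dir = 0, b0_ext = 0, kappa = 0,
    p_slow = 0, p_curved = 0, p_outlier = 0,
    traj_jitter_cm = 0, ...
  )
}

# one subject, two sessions (arc then line) sharing the test schedule
two_session_trials <- function(params, seed = 1, phases = c("priming", "test")) {
  test_tab <- build_test_schedule(seed)
  empty_priming <- build_priming_schedule("arc", 1)[0, ]
  sess <- lapply(1:2, function(ss) {
    cond <- c("arc", "line")[ss]
    priming <- if ("priming" %in% phases) {
      build_priming_schedule(cond, seed + ss)
    } else {
      empty_priming
    }
    sched <- session_schedule(cond, priming = priming, test = test_tab)
    simulate_session(sched, params, subject_id = 1L, session = ss,
                     seed = seed + 10 * ss, phases = phases)
  })
  dplyr::bind_rows(sess)
}

make_traj <- function(t_ms, x_cm, y_cm) {
  tibble::tibble(t_ms = t_ms, x_cm = x_cm, y_cm = y_cm)
}

# straight reach along +y: minimum-jerk motion over move_ms, then frozen tail
straight_reach_traj <- function(extent_cm = 15, move_ms = 500, tail_ms = 100,
                                dt = 5) {
  t_move <- seq(0, move_ms, by = dt)
  s <- {
    tau <- t_move / move_ms
    10 * tau^3 - 15 * tau^4 + 6 * tau^5
  }
  t_tail <- seq(move_ms + dt, move_ms + tail_ms, by = dt)
  make_traj(
    c(t_move, t_tail),
    rep(0, length(t_move) + length(t_tail)),
    c(extent_cm * s, rep(extent_cm, length(t_tail)))
  )
}
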