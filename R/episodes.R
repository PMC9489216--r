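#' Simulate one test episode of the trained agent
#'
#' Loops greedy action selection, environment transition, stochastic
#' observation at the true state, and Bayesian belief update until the source
#' is found or `max_steps` is exhausted. Observations are drawn from the
#' environment maps -- by default the same Bernoulli maps the agent was
#' trained on, or perturbed maps for robustness evaluations (the agent's
#' internal likelihood model always stays the training `spec`).
#'
#' @param spec a [build_spec()] object (the agent's model).
#' @param H a trained [alpha_set()].
#' @param prior initial belief vector.
#' @param start_state true initial cell `c(ix, iy)` (source-relative grid
#'   index).
#' @param max_steps episode cap (default 1000 steps).
#' @param seed integer seed; fixed seeds reproduce episodes bit-identically.
#' @param env_maps environment maps: `NULL` (use the model's maps), a list
#'   `list(air =, ground =)` of [detection_rate_map()]s, or a
#'   `function(step)` returning such a list (time-varying plumes).
#' @param likelihood_floor lower bound on the model's detection likelihood
#'   used in belief updates; keep 0 for a matched environment, set small
#'   (e.g. `1e-4`) when the environment differs from the model so that a
#'   detection the model deems impossible does not collapse the belief.
#' @param on_mismatch what to do when an observation has zero predictive
#'   probability under the model (possible only when the environment
#'   differs from the model, e.g. a true state outside the prior's
#'   support): `"error"` (default) aborts with a diagnostic; `"stop"` ends
#'   the episode at the previous step with outcome `"timeout"` and
#'   attribute `aborted_step` set.
#'
#' @return A tibble of class `sniff_trajectory`, one row per step with
#'   columns `step`, `x`, `y` (source-relative displacement, cells), `action`,
#'   `observation`, `air_sniff`, `entropy` (nats, post-update belief) and
#'   `value` (post-update `value_of`). Attributes: `outcome` (`"found"` or
#'   `"timeout"`), `start_state`, `seed`, `cell_size`, `step_duration`,
#'   `origin`.
#' @export
run_episode <- function(spec, H, prior, start_state, max_steps = 1000,
                        seed = 1, env_maps = NULL, likelihood_floor = 0,
                        on_mismatch = c("error", "stop")) {
  stopifnot(inherits(spec, "pomdp_spec"), inherits(H, "alpha_set"))
  on_mismatch <- match.arg(on_mismatch)
  start_state <- check_state(spec, start_state)
  check_belief(spec, prior)
  env_at <- episode_env(spec, env_maps)

  n <- max_steps
  step_x <- integer(n); step_y <- integer(n)
  act <- character(n); obs <- character(n)
  ent <- numeric(n); val <- numeric(n)
  outcome <- "timeout"
  t_used <- 0L
  aborted_step <- NA_integer_

  withr::with_seed(seed, {
    b <- prior
    s <- state_index(spec, start_state)
    for (t in seq_len(max_steps)) {
      a <- greedy_action(b, H, spec, likelihood_floor)
      s <- spec$perm[[a]][s]
      env <- env_at(t)
      o <- if (s == spec$origin_index) {
        "source_found"
      } else {
        p <- if (a == "stay_sniff_air") env$air[s] else env$ground[s]
        if (stats::runif(1) < p) "detection" else "no_detection"
      }
      b_new <- tryCatch(
        belief_update(spec, b, a, o, likelihood_floor),
        error = function(e) {
          if (on_mismatch == "error") {
            stop(sprintf("episode aborted at step %d: %s", t,
                         conditionMessage(e)), call. = FALSE)
          }
          NULL
        }
      )
      if (is.null(b_new)) { aborted_step <- t; break }
      b <- b_new
      st <- index_state(spec, s)
      step_x[t] <- st[1] - spec$origin[1]
      step_y[t] <- st[2] - spec$origin[2]
      act[t] <- a; obs[t] <- o
      ent[t] <- belief_entropy(b)
      val[t] <- value_of(b, H)
      t_used <- t
      if (o == "source_found") { outcome <- "found"; break }
    }
  })

  idx <- seq_len(t_used)
  traj <- tibble::tibble(
    step = idx, x = step_x[idx], y = step_y[idx], action = act[idx],
    observation = obs[idx], air_sniff = act[idx] == "stay_sniff_air",
    entropy = ent[idx], value = val[idx]
  )
  class(traj) <- c("sniff_trajectory", class(traj))
  attr(traj, "outcome") <- outcome
  attr(traj, "start_state") <- start_state
  attr(traj, "seed") <- seed
  attr(traj, "cell_size") <- spec$cell_size
  attr(traj, "step_duration") <- spec$step_duration
  attr(traj, "origin") <- spec$origin
  attr(traj, "aborted_step") <- aborted_step
  traj
}

# environment map accessor: values as vectors over the linear state space
episode_env <- function(spec, env_maps) {
  as_env <- function(m) {
    stopifnot(inherits(m$air, "detection_rate_map"),
              inherits(m$ground, "detection_rate_map"))
    list(air = as.vector(m$air$values), ground = as.vector(m$ground$values))
  }
  if (is.null(env_maps)) {
    env <- list(air = as.vector(spec$air_map$values),
                ground = as.vector(spec$ground_map$values))
    function(step) env
  } else if (is.function(env_maps)) {
    function(step) as_env(env_maps(step))
  } else {
    env <- as_env(env_maps)
    function(step) env
  }
}

#' Episode outcome
#'
#' @param traj a [run_episode()] trajectory.
#' @return `"found"` or `"timeout"`.
#' @export
episode_outcome <- function(traj) attr(traj, "outcome")

#' Run a battery of test episodes
#'
#' Full cross of starting positions, observation seeds and stochastic
#' realizations (each seed/realization pair indexes an independent detection
#' history; identical seed, realization and start reproduce the episode
#' exactly).
#'
#' @param spec,H,prior as in [run_episode()].
#' @param starts list of true start states `c(ix, iy)`, or a two-column
#'   matrix (one start per row).
#' @param n_seeds,n_realizations battery dimensions.
#' @param max_steps per-episode cap.
#' @param env_maps,likelihood_floor passed to [run_episode()].
#' @param keep_trajectories if `TRUE` (default), attach each trajectory in a
#'   list-column.
#'
#' @return A tibble with one row per episode: `start_x`, `start_y`
#'   (displacement cells), `seed`, `realization`, `outcome`, `steps`,
#'   `air_sniffs`, `first_detection_step` (NA if none), `excess_steps`
#'   (NA for timeouts), and optionally `trajectory`.
#' @export
run_battery <- function(spec, H, prior, starts, n_seeds = 2,
                        n_realizations = 5, max_steps = 1000,
                        env_maps = NULL, likelihood_floor = 0,
                        keep_trajectories = TRUE) {
  if (is.matrix(starts)) starts <- asplit(starts, 1)
  if (length(starts) == 0L) stop("`starts` must be nonempty", call. = FALSE)
  grid <- tidyr::expand_grid(
    start = seq_along(starts),
    seed = seq_len(n_seeds),
    realization = seq_len(n_realizations)
  )
  rows <- purrr::pmap(grid, function(start, seed, realization) {
    st <- as.integer(starts[[start]])
    ep_seed <- (seed * 100003L + realization * 101L) %% 2147483647L
    traj <- run_episode(spec, H, prior, st, max_steps = max_steps,
                        seed = ep_seed, env_maps = env_maps,
                        likelihood_floor = likelihood_floor)
    det <- which(traj$observation == "detection")
    found <- episode_outcome(traj) == "found"
    out <- tibble::tibble(
      start_x = st[1] - spec$origin[1], start_y = st[2] - spec$origin[2],
      seed = seed, realization = realization,
      outcome = episode_outcome(traj), steps = nrow(traj),
      air_sniffs = sum(traj$air_sniff),
      first_detection_step = if (length(det)) det[1] else NA_integer_,
      excess_steps = if (found) excess_steps(traj) else NA_integer_
    )
    if (keep_trajectories) out$trajectory <- list(traj)
    out
  })
  dplyr::bind_rows(rows)
}

#' Robustness evaluation under perturbed plumes
#'
#' Re-runs episode batteries in perturbed environments (rescaled or
#' meandering plumes built with [perturb_map()]) while the agent keeps the
#' static model it was trained with. Because the environment no longer
#' matches the model, belief updates use a small `likelihood_floor`.
#'
#' @param H,spec,prior,starts as in [run_battery()].
#' @param perturbations named list; each element is either
#'   `list(air =, ground =)` maps or a `function(step)` returning such a list.
#' @param n_seeds,n_realizations,max_steps battery dimensions.
#' @param likelihood_floor model regularisation for mismatched environments.
#' @return A tibble with one row per perturbation: `perturbation`,
#'   `n_episodes`, `success_rate`, `mean_steps` (successful episodes only;
#'   NA when none succeed) and `mean_air_sniffs`.
#' @export
robustness_eval <- function(H, spec, prior, starts, perturbations,
                            n_seeds = 2, n_realizations = 5, max_steps = 1000,
                            likelihood_floor = 1e-4) {
  purrr::imap(perturbations, function(pert, name) {
    bat <- run_battery(spec, H, prior, starts, n_seeds, n_realizations,
                       max_steps = max_steps, env_maps = pert,
                       likelihood_floor = likelihood_floor,
                       keep_trajectories = FALSE)
    ok <- bat$outcome == "found"
    tibble::tibble(
      perturbation = name,
      n_episodes = nrow(bat),
      success_rate = mean(ok),
      mean_steps = if (any(ok)) mean(bat$steps[ok]) else NA_real_,
      mean_air_sniffs = mean(bat$air_sniffs)
    )
  }) |> dplyr::bind_rows()
}
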