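#' Grid POMDP for dual-modality olfactory search
#'
#' Assembles the decision problem faced by the searcher. The latent state is
#' the agent's displacement from the odor source on the map grid; the agent
#' chooses among six actions (four ground-sniffing moves, sniff the ground in
#' place, sniff the air in place) and receives one of three observations
#' (`no_detection`, `detection`, `source_found`). Moves translate the
#' displacement one cell; moves that would exit the grid leave it unchanged.
#' An agent whose displacement is zero observes `source_found` with
#' probability one and the search ends; elsewhere the detection probability is
#' the ground map for ground-sniffing actions and the air map for
#' `stay_sniff_air`, with the remainder going to `no_detection`.
#'
#' A unit reward for finding the source is discounted per step by
#' `gamma = exp(-lambda * step_duration)`.
#'
#' @param air_map,ground_map matched [detection_rate_map()]s on the same grid.
#' @param gamma per-step discount factor in (0, 1).
#' @param step_length metres travelled per move (defaults to the cell size).
#' @param step_duration seconds per decision step.
#' @param ground_only if `TRUE`, drop `stay_sniff_air` (the ground-only
#'   ablation used to quantify the benefit of alternation).
#'
#' @return An object of class `pomdp_spec` with fields `n_x`, `n_y`,
#'   `n_states`, `origin` (source cell index), `actions`, `observations`,
#'   `gamma`, `lambda` (implied discount rate, 1/s), `step_length`,
#'   `step_duration`, the two maps, and precomputed transition permutations.
#' @export
build_spec <- function(air_map, ground_map, gamma = 0.99,
                       step_length = NULL, step_duration = 1 / 3,
                       ground_only = FALSE) {
  stopifnot(inherits(air_map, "detection_rate_map"),
            inherits(ground_map, "detection_rate_map"))
  if (!identical(dim(air_map$values), dim(ground_map$values)) ||
      !identical(air_map$origin, ground_map$origin) ||
      air_map$cell_size != ground_map$cell_size) {
    stop("air and ground maps must share grid, origin and cell size",
         call. = FALSE)
  }
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must lie in (0, 1)", call. = FALSE)
  if (is.null(step_length)) step_length <- air_map$cell_size
  n_x <- nrow(air_map$values); n_y <- ncol(air_map$values)
  actions <- c("move_up", "move_down", "move_left", "move_right",
               "stay_sniff_ground", "stay_sniff_air")
  if (ground_only) actions <- actions[actions != "stay_sniff_air"]

  ix <- rep(seq_len(n_x), times = n_y)
  iy <- rep(seq_len(n_y), each = n_x)
  lin <- function(i, j) (j - 1L) * n_x + i
  perm <- list(
    move_up    = lin(pmax(ix - 1L, 1L), iy),   # upwind: x decreases
    move_down  = lin(pmin(ix + 1L, n_x), iy),  # downwind
    move_left  = lin(ix, pmax(iy - 1L, 1L)),
    move_right = lin(ix, pmin(iy + 1L, n_y)),
    stay_sniff_ground = lin(ix, iy),
    stay_sniff_air    = lin(ix, iy)
  )[actions]

  origin_index <- lin(air_map$origin[1], air_map$origin[2])
  det_ground <- as.vector(ground_map$values)
  det_air <- as.vector(air_map$values)
  det_ground[origin_index] <- 0
  det_air[origin_index] <- 0

  structure(
    list(
      n_x = n_x, n_y = n_y, n_states = n_x * n_y,
      origin = air_map$origin, origin_index = origin_index,
      actions = actions, n_actions = length(actions),
      observations = c("no_detection", "detection", "source_found"),
      gamma = gamma, lambda = -log(gamma) / step_duration,
      step_length = step_length, step_duration = step_duration,
      cell_size = air_map$cell_size,
      air_map = air_map, ground_map = ground_map,
      det = list(ground = det_ground, air = det_air),
      perm = perm
    ),
    class = "pomdp_spec"
  )
}

#' @export
print.pomdp_spec <- function(x, ...) {
  cat(sprintf(
    "<pomdp_spec> %d x %d grid (%d states), %d actions, gamma = %.4g, step %.3g m / %.3g s\n",
    x$n_x, x$n_y, x$n_states, x$n_actions, x$gamma, x$step_length,
    x$step_duration
  ))
  invisible(x)
}

#' Paper-scale configuration
#'
#' The full-size study configuration: a 300 x 60 grid of 12 cm cells
#' (18,000 states), a 28.6 m x 3.4 m uniform prior, discount 0.99, three
#' sniffs per second and 12 cm steps, with default air/ground plume geometry
#' scaled to the prior length.
#'
#' @return list with elements `spec` (a `pomdp_spec`) and `prior`
#'   (a belief vector).
#' @export
full_scale_spec <- function() {
  pair_params <- default_plume_pair(28.6)
  pair <- make_dns_like_pair(pair_params$air, pair_params$ground,
                             grid_shape = c(300L, 60L), cell_size = 0.12,
                             origin = c(31L, 30L))
  spec <- build_spec(pair$air, pair$ground, gamma = 0.99,
                     step_length = 0.12, step_duration = 1 / 3)
  list(spec = spec, prior = make_prior(spec, 28.6, 3.4))
}

# linear index <-> (ix, iy)
state_index <- function(spec, state) {
  (as.integer(state[2]) - 1L) * spec$n_x + as.integer(state[1])
}
index_state <- function(spec, index) {
  index <- as.integer(index)
  c(((index - 1L) %% spec$n_x) + 1L, ((index - 1L) %/% spec$n_x) + 1L)
}

check_state <- function(spec, state) {
  state <- as.integer(state)
  if (length(state) != 2L || state[1] < 1L || state[1] > spec$n_x ||
      state[2] < 1L || state[2] > spec$n_y) {
    stop("`state` lies outside the grid", call. = FALSE)
  }
  state
}

check_action <- function(spec, action) {
  if (!action %in% spec$actions) {
    stop(sprintf("unknown action '%s'", action), call. = FALSE)
  }
  action
}

#' Deterministic state transition
#'
#' Moves translate the source-relative displacement by one cell in the
#' action's direction (`move_up` is upwind: it decreases `x`); the two stay
#' actions leave the state unchanged; moves that would exit the grid clamp
#' (state unchanged along that axis).
#'
#' @param spec a [build_spec()] object.
#' @param state integer cell index `c(ix, iy)`.
#' @param action action name.
#' @return The successor state `c(ix, iy)`.
#' @export
transition <- function(spec, state, action) {
  state <- check_state(spec, state)
  check_action(spec, action)
  index_state(spec, spec$perm[[action]][state_index(spec, state)])
}

# detection-probability vector over states for an action (model likelihood)
action_det <- function(spec, action, floor = 0) {
  det <- if (action == "stay_sniff_air") spec$det$air else spec$det$ground
  if (floor > 0) {
    det <- pmax(det, floor)
    det[spec$origin_index] <- 0
  }
  det
}

#' Observation likelihood at a state
#'
#' `P(o | s, a)` over the three observations. At the source cell
#' (displacement zero) `source_found` has probability one; elsewhere the
#' detection probability comes from the map matching the action's sensing
#' modality.
#'
#' @inheritParams transition
#' @return named numeric vector over
#'   `c(no_detection, detection, source_found)`.
#' @export
observation_likelihood <- function(spec, state, action) {
  state <- check_state(spec, state)
  check_action(spec, action)
  s <- state_index(spec, state)
  if (s == spec$origin_index) {
    out <- c(no_detection = 0, detection = 0, source_found = 1)
  } else {
    p <- action_det(spec, action)[s]
    out <- c(no_detection = 1 - p, detection = p, source_found = 0)
  }
  out
}

#' Uniform rectangular prior belief
#'
#' A uniform belief over a rectangle of the grid: displacements
#' `x` in `[0, L_x)` downwind of the source and a crosswind window of width
#' `L_y` centered on the source axis. Lengths are rounded up to whole cells.
#'
#' @param spec a [build_spec()] object.
#' @param L_x,L_y prior length and width in metres.
#' @return A belief vector (numeric, length `n_states`, summing to one).
#' @export
make_prior <- function(spec, L_x, L_y) {
  h <- spec$cell_size
  l_cells <- as.integer(ceiling(L_x / h - 1e-9))
  w_cells <- as.integer(ceiling(L_y / h - 1e-9))
  half <- (w_cells - 1L) %/% 2L
  ix <- spec$origin[1] + 0:(l_cells - 1L)
  iy <- (spec$origin[2] - half):(spec$origin[2] - half + w_cells - 1L)
  if (min(ix) < 1L || max(ix) > spec$n_x || min(iy) < 1L || max(iy) > spec$n_y) {
    stop("prior support does not fit on the grid", call. = FALSE)
  }
  b <- numeric(spec$n_states)
  cells <- as.vector(outer(ix, (iy - 1L) * spec$n_x, `+`))
  b[cells] <- 1 / length(cells)
  b
}

check_belief <- function(spec, belief) {
  if (length(belief) != spec$n_states) {
    stop("belief length does not match the state space", call. = FALSE)
  }
  if (any(belief < -1e-12) || abs(sum(belief) - 1) > 1e-9) {
    stop("belief must be nonnegative and sum to one", call. = FALSE)
  }
  invisible(belief)
}

# b_pred(s') = sum_s T(s'|s,a) b(s); deterministic transitions = scatter-add
predicted_belief <- function(spec, belief, action) {
  idx <- spec$perm[[action]]
  rs <- rowsum(belief, group = idx)
  out <- numeric(spec$n_states)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Probability of finding the source after an action
#'
#' \eqn{\Gamma_a = \sum_s b(s) \, 1[\mathrm{transition}(s, a) = \mathrm{source}]}:
#' the belief mass that the action moves onto the source cell.
#'
#' @param spec a [build_spec()] object.
#' @param belief belief vector.
#' @param action action name.
#' @return numeric scalar in `[0, 1]`.
#' @export
source_prob <- function(spec, belief, action) {
  check_belief(spec, belief)
  check_action(spec, action)
  predicted_belief(spec, belief, action)[spec$origin_index]
}

#' Predictive observation distribution
#'
#' \eqn{P(o | b, a) = \sum_{s'} [\sum_s T(s'|s,a) b(s)] P(o | s', a)}.
#'
#' @inheritParams source_prob
#' @param likelihood_floor optional lower bound applied to the model's
#'   detection probability away from the source (regularises updates when the
#'   true environment differs from the model; 0 = exact model).
#' @return named numeric vector over the three observations (sums to one).
#' @export
obs_predictive <- function(spec, belief, action, likelihood_floor = 0) {
  check_belief(spec, belief)
  check_action(spec, action)
  bp <- predicted_belief(spec, belief, action)
  p_found <- bp[spec$origin_index]
  det <- action_det(spec, action, likelihood_floor)
  p_det <- sum(bp * det)  # det is zero at the origin
  c(no_detection = 1 - p_found - p_det, detection = p_det,
    source_found = p_found)
}

#' Bayesian belief update
#'
#' \eqn{b'(s') \propto P(o | s', a) \sum_s T(s' | s, a) b(s)}, normalised.
#' Observing `source_found` collapses the belief to a point mass at the
#' source cell. An observation with zero predictive probability signals a
#' mismatch between environment and model and raises an error.
#'
#' @inheritParams obs_predictive
#' @param observation one of `"no_detection"`, `"detection"`,
#'   `"source_found"`.
#' @return The posterior belief vector.
#' @export
belief_update <- function(spec, belief, action, observation,
                          likelihood_floor = 0) {
  check_belief(spec, belief)
  check_action(spec, action)
  if (!observation %in% spec$observations) {
    stop(sprintf("unknown observation '%s'", observation), call. = FALSE)
  }
  bp <- predicted_belief(spec, belief, action)
  if (observation == "source_found") {
    if (bp[spec$origin_index] <= 0) {
      stop("observation 'source_found' has zero predictive probability",
           call. = FALSE)
    }
    out <- numeric(spec$n_states)
    out[spec$origin_index] <- 1
    return(out)
  }
  det <- action_det(spec, action, likelihood_floor)
  w <- if (observation == "detection") det else 1 - det
  w[spec$origin_index] <- 0  # the source cell always reveals itself
  post <- bp * w
  z <- sum(post)
  if (z <= 1e-300) {
    stop(sprintf("observation '%s' has zero predictive probability (model mismatch)",
                 observation), call. = FALSE)
  }
  post / z
}

#' Shannon entropy of a belief (nats)
#'
#' \eqn{-\sum_s b(s) \log b(s)} with \eqn{0 \log 0 = 0}.
#'
#' @param belief belief vector.
#' @return numeric scalar, nats.
#' @export
belief_entropy <- function(belief) {
  p <- belief[belief > 0]
  -sum(p * log(p))
}

#' Belief as a grid matrix / tibble
#'
#' Reshape a belief vector to the map grid for inspection or plotting.
#'
#' @param spec a [build_spec()] object.
#' @param belief belief vector.
#' @return `belief_matrix()`: an `n_x` x `n_y` matrix. `belief_to_tibble()`:
#'   a tibble with source-relative `x`, `y` (m) and `prob`.
#' @export
belief_matrix <- function(spec, belief) {
  matrix(belief, spec$n_x, spec$n_y)
}

#' @rdname belief_matrix
#' @export
belief_to_tibble <- function(spec, belief) {
  h <- spec$cell_size
  tibble::tibble(
    x = rep((seq_len(spec$n_x) - spec$origin[1]) * h, times = spec$n_y),
    y = rep((seq_len(spec$n_y) - spec$origin[2]) * h, each = spec$n_x),
    prob = belief
  )
}
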