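# Shared toy problems and independent oracles.

# n x 1 corridor POMDP: source at cell 1, arbitrary per-cell detection rates
# for the two modalities (first entry, the source cell, is irrelevant).
corridor_spec <- function(ground_rates, air_rates = ground_rates,
                          gamma = 0.9, cell_size = 1) {
  n <- length(ground_rates)
  origin <- c(1L, 1L)
  air <- detection_rate_map(matrix(air_rates, n, 1), cell_size, origin, "air")
  ground <- detection_rate_map(matrix(ground_rates, n, 1), cell_size, origin,
                               "ground")
  build_spec(air, ground, gamma = gamma, step_length = cell_size,
             step_duration = 1)
}

# Dense belief-grid value iteration for the 3-cell corridor. After any
# non-found observation the posterior mass at the source cell is zero, so
# the reachable beliefs form the invariant 1-D family b = (0, q, 1 - q);
# V is computed on a fine q-grid by exact Bellman iteration with linear
# interpolation, independently of the package's alpha-vector machinery.
corridor3_grid_vi <- function(spec, n_grid = 40001, iter_tol = 1e-13,
                              max_iter = 5000) {
  stopifnot(spec$n_states == 3L)
  g <- as.vector(spec$ground_map$values)  # rates at cells 1..3
  a_ <- as.vector(spec$air_map$values)
  gam <- spec$gamma
  q <- seq(0, 1, length.out = n_grid)
  V <- numeric(n_grid)
  interp <- function(qq) {
    qq <- pmin(pmax(qq, 0), 1)
    pos <- qq * (n_grid - 1) + 1
    lo <- pmin(floor(pos), n_grid - 1)
    w <- pos - lo
    V[lo] * (1 - w) + V[lo + 1] * w
  }
  # per action: predicted belief over (cell1, cell2, cell3) from (0, q, 1-q)
  # move_up: (q, 1-q, 0); move_down: (0, 0, 1); stays: (0, q, 1-q)
  rates <- function(action) if (action == "stay_sniff_air") a_ else g
  step_q <- function(bp, action) {
    r <- rates(action)
    gamma_a <- bp[[1]]
    p_det2 <- bp[[2]] * r[2]; p_det3 <- bp[[3]] * r[3]
    p_no2 <- bp[[2]] * (1 - r[2]); p_no3 <- bp[[3]] * (1 - r[3])
    p_det <- p_det2 + p_det3
    p_no <- p_no2 + p_no3
    q_det <- ifelse(p_det > 0, p_det2 / p_det, 0)
    q_no <- ifelse(p_no > 0, p_no2 / p_no, 0)
    list(gamma_a = gamma_a, p_det = p_det, p_no = p_no,
         q_det = q_det, q_no = q_no)
  }
  preds <- list(
    move_up = function(q) list(q, 1 - q, rep(0, length(q))),
    move_down = function(q) list(rep(0, length(q)), rep(0, length(q)),
                                 rep(1, length(q))),
    stay = function(q) list(rep(0, length(q)), q, 1 - q)
  )
  acts <- list(c("move_up", "ground"), c("move_down", "ground"),
               c("stay", "ground"), c("stay", "air"))
  for (it in seq_len(max_iter)) {
    Qmax <- rep(-Inf, n_grid)
    for (ac in acts) {
      bp <- preds[[ac[1]]](q)
      action <- if (ac[2] == "air") "stay_sniff_air" else "stay_sniff_ground"
      st <- step_q(bp, action)
      Qa <- st$gamma_a + gam * (st$p_no * interp(st$q_no) +
                                  st$p_det * interp(st$q_det))
      Qmax <- pmax(Qmax, Qa)
    }
    delta <- max(abs(Qmax - V))
    V <- Qmax
    if (delta < iter_tol) break
  }
  q_at <- function(qq) {
    # exact Bellman application at the query beliefs, per action class
    out <- list()
    for (ac in acts) {
      bp <- preds[[ac[1]]](qq)
      action <- if (ac[2] == "air") "stay_sniff_air" else "stay_sniff_ground"
      st <- step_q(bp, action)
      out[[paste(ac[1], ac[2], sep = "_")]] <-
        st$gamma_a + gam * (st$p_no * interp(st$q_no) +
                              st$p_det * interp(st$q_det))
    }
    out
  }
  list(q = q, V = V, q_at = q_at,
       value_at = function(qq) do.call(pmax, q_at(qq)))
}

# belief on the corridor-3 invariant family
corridor3_belief <- function(q) c(0, q, 1 - q)

# deterministic flat map pair on a small 2-D grid, for mechanical tests
small_pair <- function(n_x = 12, n_y = 7, origin = c(3L, 4L), h = 0.12,
                       air_peak = 0.3, ground_peak = 0.6) {
  air <- make_separable_map(
    plume_params(x_thr = 6 * h, y_thr = 2 * h, peak_rate = air_peak),
    c(n_x, n_y), h, origin, "air")
  ground <- make_separable_map(
    plume_params(x_thr = 2 * h, y_thr = 1 * h, peak_rate = ground_peak),
    c(n_x, n_y), h, origin, "ground")
  list(air = air, ground = ground)
}

small_spec <- function(gamma = 0.95, ...) {
  pair <- small_pair(...)
  build_spec(pair$air, pair$ground, gamma = gamma)
}

random_belief <- function(spec_or_n) {
  n <- if (inherits(spec_or_n, "pomdp_spec")) spec_or_n$n_states else spec_or_n
  b <- stats::rexp(n)
  b / sum(b)
}
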