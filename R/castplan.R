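#' Uniform marginal prior over the crosswind axis
#'
#' Discretisation of the marginal belief \eqn{\tilde b(y)} used by the
#' cast-and-sniff planner: a uniform density over `[-L_y/2, L_y/2]` on
#' `n_cells` cell centers.
#'
#' @param L_y prior width (m).
#' @param n_cells number of grid cells (default resolves `L_y / 200`).
#' @return tibble with columns `y` (m) and `prob` (sums to one).
#' @export
uniform_marginal_prior <- function(L_y, n_cells = 201) {
  y <- seq(-L_y / 2, L_y / 2, length.out = n_cells)
  tibble::tibble(y = y, prob = rep(1 / n_cells, n_cells))
}

# crosswind detection kernel: probability that a sniff at displacement u
# from the target's crosswind position detects it
cast_kernel <- function(u, y_thr) exp(-u^2 / (2 * y_thr^2))

# expected discounted detection probability of a candidate displacement
# sequence, expanded to depth length(dy). `surv` is the (unnormalised)
# survivor mass over target positions `y`; normalisation factors cancel
# through the recursion, so the plain product form is exact. The inner
# product-and-decay loop is compiled (src/plan_value.cpp).
plan_value <- function(dy, pos, y, surv, y_thr, lambda, v, t_sniff) {
  plan_value_cpp(as.numeric(dy), pos, y, surv, y_thr, lambda, v, t_sniff)
}

# one cyclic pass of coordinate-wise line searches (gradient-free pattern
# search): each displacement in turn is optimised on a bracketing grid over
# [-L_y, L_y] and polished by golden-section search
coord_pass <- function(par, fn, L_y, n_grid = 81) {
  grid <- seq(-L_y, L_y, length.out = n_grid)
  for (i in seq_along(par)) {
    obj_i <- function(z) { q <- par; q[i] <- z; fn(q) }
    vals <- vapply(grid, obj_i, numeric(1))
    j <- which.min(vals)
    lo <- grid[max(1, j - 1)]; hi <- grid[min(n_grid, j + 1)]
    o <- stats::optimize(obj_i, c(lo, hi), tol = 1e-9)
    if (o$objective <= min(vals)) par[i] <- o$minimum else par[i] <- grid[j]
  }
  par
}

# fine local coordinate polish: golden-section search in a +/- radius
# window around each current displacement
local_pass <- function(par, fn, radius) {
  for (i in seq_along(par)) {
    obj_i <- function(z) { q <- par; q[i] <- z; fn(q) }
    o <- stats::optimize(obj_i, c(par[i] - radius, par[i] + radius),
                         tol = 1e-10)
    if (o$objective < fn(par)) par[i] <- o$minimum
  }
  par
}

# structured candidate displacement sequences: expanding zigzags, constant
# one-way sweeps and there-and-back patterns at several spacings, a
# stay-in-place plan, and the warm continuation of the previous decision
plan_starts <- function(nsteps, y_thr, warm = NULL) {
  starts <- list(rep(0, nsteps))
  k <- seq_len(nsteps)
  for (s in c(1.5, 2.2, 3) * y_thr) {
    posz <- (-1)^(k + 1) * ceiling(k / 2) * s  # expanding zigzag positions
    starts <- c(starts, list(
      rep(s, nsteps), rep(-s, nsteps),
      diff(c(0, posz)), diff(c(0, -posz))
    ))
    # one-turn sweeps: constant spacing with a single counterturn at step m
    for (m in seq_len(nsteps - 1)) {
      tb <- rep(s, nsteps); tb[(m + 1):nsteps] <- -s
      starts <- c(starts, list(tb, -tb))
    }
  }
  if (!is.null(warm)) starts <- c(list(warm), starts)
  starts
}

# deterministic derivative-free optimisation of the displacement sequence:
# the structured starts are screened by value, and the best few are refined
# by cyclic coordinate descent (pattern search) until the value stops
# improving. A dense line search handles depth 1.
optimise_plan <- function(pos, y, surv, y_thr, lambda, v, t_sniff, nsteps,
                          L_y, warm = NULL) {
  fn <- function(dy) -plan_value(dy, pos, y, surv, y_thr, lambda, v, t_sniff)
  if (nsteps == 1L) {
    grid <- seq(-L_y, L_y, length.out = 801)
    vals <- vapply(grid, fn, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(fn, c(lo, hi), tol = 1e-10)
    return(list(par = opt$minimum, value = -opt$objective))
  }
  descend <- function(par) {
    val <- fn(par)
    for (pass in 1:8) {
      par2 <- coord_pass(par, fn, L_y)
      val2 <- fn(par2)
      if (val2 >= val - 1e-12) break
      par <- par2; val <- val2
    }
    list(par = par, val = val)
  }
  starts <- plan_starts(nsteps, y_thr, warm)
  sv <- vapply(starts, fn, numeric(1))
  keep <- order(sv)[seq_len(min(4L, length(starts)))]
  best <- NULL
  for (i in keep) {
    cand <- descend(starts[[i]])
    if (is.null(best) || cand$val < best$val) best <- cand
  }
  # simplex polish catches coupled-coordinate improvements the cyclic
  # passes miss, then fine local line searches at the kernel scale
  o <- stats::optim(best$par, fn, method = "Nelder-Mead",
                    control = list(maxit = 200 * nsteps, reltol = 1e-12))
  if (o$value < best$val) best <- descend(o$par)
  for (r in c(2, 0.5) * y_thr) {
    par <- local_pass(best$par, fn, r)
    val <- fn(par)
    if (val < best$val) best <- list(par = par, val = val)
  }
  list(par = best$par, value = -best$val)
}

#' Receding-horizon cast-and-sniff planner
#'
#' Plans where to sniff along the crosswind axis. At each decision the
#' depth-`nsteps` Bellman recursion
#' \deqn{V(\tilde b) = \max_{\Delta y} \{[\Gamma_{\tilde b}(\Delta y) +
#'  (1 - \Gamma_{\tilde b}(\Delta y)) V(\tilde b')] e^{-\lambda(|\Delta y|/v + t_{sniff})}\}}
#' is expanded over the next `nsteps` sniff displacements and optimised by
#' deterministic multistart Nelder-Mead (a dense line search at depth 1);
#' the first displacement is executed, the marginal belief is updated by
#' Bayes' rule conditional on no detection
#' (\eqn{\tilde b'(y) \propto \tilde b(y) (1 - g(y_{sniff} - y))} with
#' \eqn{g(u) = e^{-u^2 / 2 y_{thr}^2}}), and the procedure repeats. The
#' optimised strategy is the expanding zigzag: alternating casts of growing
#' amplitude until the prior's width is covered.
#'
#' @param marginal_prior tibble (`y`, `prob`) as from
#'   [uniform_marginal_prior()].
#' @param params an [mvt_params()] (uses `y_thr`, `lambda`, `v`, `t_sniff`,
#'   `L_y`).
#' @param nsteps optimisation depth (>= 1).
#' @param n_sniffs number of executed sniffs, or fewer if the survival
#'   probability first drops below `stop_survival`.
#' @param stop_survival stop once the conditional no-detection probability
#'   falls below this value.
#' @param start_pos initial crosswind position (m).
#' @return tibble of class `cast_plan`, one row per executed sniff:
#'   `sniff`, `dy` (displacement, m), `pos` (sniff position, m), `t`
#'   (cumulative time, s), `survival` (`c(t)` after the sniff). Attributes:
#'   `nsteps`, `params`, `marginal_prior`.
#' @export
plan_cast_sniff <- function(marginal_prior, params, nsteps,
                            n_sniffs = 60, stop_survival = 0.02,
                            start_pos = 0) {
  stopifnot(inherits(params, "mvt_params"))
  if (nsteps < 1) stop("`nsteps` must be >= 1", call. = FALSE)
  y <- marginal_prior$y
  prob <- marginal_prior$prob
  if (abs(sum(prob) - 1) > 1e-9) stop("marginal prior must sum to 1", call. = FALSE)
  y_thr <- params$y_thr; lambda <- params$lambda
  v <- params$v; t_sniff <- params$t_sniff; L_y <- params$L_y

  if (diff(range(y[prob > 0])) == 0) {
    # degenerate prior: a single occupied cell; sniff in place
    out <- tibble::tibble(sniff = 1L, dy = 0, pos = start_pos,
                          t = t_sniff,
                          survival = sum(prob * (1 - cast_kernel(start_pos - y, y_thr))))
    class(out) <- c("cast_plan", class(out))
    attr(out, "nsteps") <- as.integer(nsteps)
    attr(out, "params") <- params
    return(out)
  }

  surv <- prob
  pos <- start_pos
  t_cum <- 0
  warm <- NULL
  rows <- vector("list", n_sniffs)
  for (k in seq_len(n_sniffs)) {
    opt <- optimise_plan(pos, y, surv, y_thr, lambda, v, t_sniff, nsteps,
                         L_y, warm)
    dy1 <- opt$par[1]
    warm <- if (nsteps > 1) c(opt$par[-1], opt$par[length(opt$par)]) else NULL
    pos <- pos + dy1
    t_cum <- t_cum + abs(dy1) / v + t_sniff
    surv <- surv * (1 - cast_kernel(pos - y, y_thr))
    rows[[k]] <- tibble::tibble(sniff = k, dy = dy1, pos = pos, t = t_cum,
                                survival = sum(surv))
    if (sum(surv) < stop_survival) break
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cast_plan", class(out))
  attr(out, "nsteps") <- as.integer(nsteps)
  attr(out, "params") <- params
  attr(out, "marginal_prior") <- marginal_prior
  out
}

#' No-detection decay of the cast-and-sniff planner
#'
#' Runs the planner and computes `c(t)` -- the probability of not having
#' detected the target after casting for time `t`, conditional on the target
#' being in the patch -- by exact marginalisation over target positions
#' (target position distributed as the marginal prior, detection probability
#' `g` at each sniff). The exponential rate `kappa` is fitted by least
#' squares on `log c(t)` over the earliest 90% of the decay
#' (points with `c >= 0.1`).
#'
#' @inheritParams plan_cast_sniff
#' @param marginal_prior defaults to [uniform_marginal_prior()] of the
#'   params' `L_y`.
#' @return list with `kappa` (fitted rate, 1/s), `samples` (tibble `t`, `c`),
#'   and `plan` (the executed [plan_cast_sniff()] tibble).
#' @export
estimate_decay <- function(params, nsteps, marginal_prior = NULL,
                           n_sniffs = 80, stop_survival = 0.05,
                           start_pos = 0) {
  stopifnot(inherits(params, "mvt_params"))
  if (is.null(marginal_prior)) {
    marginal_prior <- uniform_marginal_prior(params$L_y)
  }
  plan <- plan_cast_sniff(marginal_prior, params, nsteps,
                          n_sniffs = n_sniffs, stop_survival = stop_survival,
                          start_pos = start_pos)
  samples <- tibble::tibble(t = c(0, plan$t), c = c(1, plan$survival))
  if (any(diff(samples$c) > 1e-12)) {
    stop("no-detection curve is not non-increasing (planner inconsistency)",
         call. = FALSE)
  }
  window <- samples$c >= 0.1 & samples$c > 0
  if (sum(window) < 3) window <- samples$c > 0
  fit <- stats::lm(log(c) ~ t, data = samples[window, ])
  list(kappa = -unname(stats::coef(fit)[2]), samples = samples, plan = plan)
}

#' Casting rate as a function of optimisation depth
#'
#' Fits the exponential no-detection rate `kappa` of [estimate_decay()] for
#' each planning depth, and reports the smallest depth whose rate is within
#' `rel_tol` of the deepest (plateau) rate. The rate grows with depth --
#' longer lookahead widens the zigzag optimally -- and saturates once the
#' horizon covers a full sweep of the prior.
#'
#' @param params an [mvt_params()].
#' @param depths integer vector of optimisation depths to scan.
#' @param rel_tol relative tolerance defining the plateau (default 5%).
#' @param ... passed to [estimate_decay()].
#' @return list with `table` (tibble `depth`, `kappa`) and
#'   `saturation_depth`.
#' @export
kappa_saturation <- function(params, depths = 1:12, rel_tol = 0.05, ...) {
  tab <- purrr::map_dfr(depths, function(d) {
    tibble::tibble(depth = d, kappa = estimate_decay(params, d, ...)$kappa)
  })
  plateau <- tab$kappa[which.max(tab$depth)]
  ok <- abs(tab$kappa - plateau) <= rel_tol * plateau
  list(table = tab,
       saturation_depth = min(tab$depth[ok]),
       plateau = plateau)
}
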