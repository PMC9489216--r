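test_that("terminal episode value matches the closed form and its limits", {
  expect_equal(boundary_value(1, 1, 2), 0.25)
  # undiscounted limit: the prior mass of the last patch
  expect_equal(boundary_value(3, 1e-12, 4), 1 / 4, tolerance = 1e-10)
  # single patch, detection much faster than discounting: near-certain reward
  expect_gt(boundary_value(1e6, 1, 1), 0.999)
  expect_error(boundary_value(-1, 1, 2), "positive")
})

test_that("episode value recursion reproduces the exponential closed form", {
  for (ratio in c(2, 5, 10)) {
    lambda <- 0.5; kappa <- ratio * lambda
    N <- 6; tau <- 0.05 / lambda  # lambda * tau = 0.05
    params <- mvt_params(lambda = lambda, v = 1, x_thr = tau, y_thr = 0.05,
                         L_x = N * tau, L_y = 1, N = N)
    sched <- episode_values(function(t) exp(-kappa * t), params)
    ref <- exponential_schedule(kappa, lambda, N, tau)
    expect_lt(max(abs(sched$cast_time[-N] - ref$cast_time[-N])), 1e-6)
    expect_lt(max(abs(sched$value - ref$value)), 1e-9)
    # casting times increase as the search progresses
    expect_true(all(diff(sched$cast_time[-N]) > 0))
    # terminal value agrees with the boundary closed form
    expect_equal(sched$value[N], boundary_value(kappa, lambda, N),
                 tolerance = 1e-9)
  }
})

test_that("no detectable signal means no casting before the final patch", {
  params <- mvt_params(lambda = 0.5, v = 1, x_thr = 0.5, y_thr = 0.05,
                       L_x = 2, L_y = 1, N = 4)
  sched <- episode_values(function(t) rep(1, length(t)), params)
  expect_equal(sched$cast_time[-4], rep(0, 3))
  expect_equal(sched$value, rep(0, 4))
})

test_that("marginal_time satisfies its defining identity and boundary clip", {
  expect_equal(marginal_time(1, 0.5, 2, 0, 1 / 3), log(3))
  # kappa e^{lambda tau} = N lambda V_next: marginal boundary, t_n = 0
  kappa <- 1.3; lambda <- 0.4; tau <- 0.2; N <- 3
  V_next <- kappa * exp(lambda * tau) / (N * lambda)
  expect_equal(marginal_time(kappa, lambda, N, tau, V_next), 0)
  # at the returned time, -c'(t_n) = N lambda e^{-lambda tau} V_{n+1}
  V2 <- boundary_value(kappa, lambda, N)
  tn <- marginal_time(kappa, lambda, N, tau, V2)
  expect_lt(abs(kappa * exp(-kappa * tn) -
                  N * lambda * exp(-lambda * tau) * V2), 1e-9)
  # agreement with the numerical argmax of the value recursion
  params <- mvt_params(lambda = lambda, v = 1, x_thr = tau, y_thr = 0.05,
                       L_x = N * tau, L_y = 1, N = N)
  sched <- episode_values(function(t) exp(-kappa * t), params)
  t_closed <- marginal_time(kappa, lambda, N, tau, sched$value[2])
  expect_lt(abs(sched$cast_time[1] - t_closed), 1e-6)
})

test_that("values with and without Bayesian updates agree to near machine precision", {
  ds <- list(
    exponential = function(t) ifelse(is.finite(t), 1 - exp(-1.2 * t), 1),
    weibull = function(t) ifelse(is.finite(t), 1 - exp(-(0.8 * t)^1.6), 1),
    saturating = function(t) ifelse(is.finite(t), 0.9 * (1 - exp(-2 * t)) +
                                      0.1 * (1 - exp(-0.2 * t)), 1)
  )
  withr::with_seed(31, {
    for (nm in names(ds)) {
      for (rep in 1:5) {
        N <- sample(2:5, 1)
        prior <- stats::rexp(N); prior <- prior / sum(prior)
        times <- stats::runif(N - 1, 0, 2)
        lambda <- stats::runif(1, 0.2, 1)
        tau <- stats::runif(1, 0, 0.5)
        v1 <- mvt_value_no_update(prior, ds[[nm]], lambda, tau, times)
        v2 <- bayes_value_oracle(prior, ds[[nm]], lambda, tau, times)
        expect_lt(abs(v1 - v2), 1e-12)
      }
    }
  })
  # skipping every patch (times 0, tau 0): only the last patch pays
  d <- ds$exponential
  prior <- c(0.2, 0.3, 0.5)
  v <- bayes_value_oracle(prior, d, 0.5, 0, c(0, 0))
  r_inf <- 1.2 / (1.2 + 0.5)
  expect_equal(v, 0.5 * r_inf, tolerance = 1e-10)
})

test_that("optimal times from the recursion also maximise the Bayesian form", {
  kappa <- 1; lambda <- 0.5; tau <- 0.1; N <- 3
  d <- function(t) ifelse(is.finite(t), 1 - exp(-kappa * t), 1)
  params <- mvt_params(lambda = lambda, v = 1, x_thr = tau, y_thr = 0.05,
                       L_x = N * tau, L_y = 1, N = N)
  sched <- episode_values(function(t) exp(-kappa * t), params)
  t_opt <- sched$cast_time[1:2]
  prior <- rep(1 / 3, 3)
  v_opt <- bayes_value_oracle(prior, d, lambda, tau, t_opt)
  expect_equal(v_opt, sched$value[1], tolerance = 1e-8)
  # perturbing the times never improves the Bayesian value
  withr::with_seed(17, {
    for (rep in 1:25) {
      tp <- pmax(t_opt + stats::rnorm(2, 0, 0.15), 0)
      expect_lte(bayes_value_oracle(prior, d, lambda, tau, tp),
                 v_opt + 1e-9)
    }
  })
})

test_that("undiscounted limit recovers total detection probability", {
  d <- function(t) ifelse(is.finite(t), 1 - exp(-2 * t), 1)
  prior <- c(0.3, 0.3, 0.4)
  times <- c(0.8, 1.1)
  v <- mvt_value_no_update(prior, d, 1e-9, 0.3, times)
  expected <- prior[1] * d(times[1]) + prior[2] * d(times[2]) + prior[3] * 1
  expect_equal(v, expected, tolerance = 1e-6)
})

test_that("planner zigzags with growing amplitude and respects degenerate priors", {
  params <- mvt_params(lambda = 0.5, v = 1, x_thr = 1, y_thr = 0.05,
                       L_x = 4, L_y = 1, t_sniff = 0)
  plan <- plan_cast_sniff(uniform_marginal_prior(1), params, nsteps = 6,
                          n_sniffs = 12)
  # displacements alternate sign (after the first) and positions expand
  # toward the prior's edges
  sides <- sign(plan$pos[plan$pos != 0])
  expect_true(any(sides > 0) && any(sides < 0))
  expect_gt(max(abs(plan$pos)), 0.3)  # reaches well beyond the center
  running_max <- cummax(abs(plan$pos))
  expect_gte(stats::cor(seq_along(running_max), running_max), 0.5)

  # one-sided prior, depth 1: single displacement toward that side
  lop <- uniform_marginal_prior(1)
  lop$prob <- ifelse(lop$y > 0.3, 1, 0); lop$prob <- lop$prob / sum(lop$prob)
  p1 <- plan_cast_sniff(lop, params, nsteps = 1, n_sniffs = 1)
  expect_gt(p1$dy[1], 0.25)

  # sniff covers the whole prior: stay in place
  wide <- mvt_params(lambda = 0.5, v = 1, x_thr = 1, y_thr = 2, L_x = 4,
                     L_y = 1, t_sniff = 0)
  pw <- plan_cast_sniff(uniform_marginal_prior(1), wide, nsteps = 3,
                        n_sniffs = 3)
  expect_lt(max(abs(pw$pos)), 0.05)

  # degenerate (single-cell) prior: the trivial stay plan
  degen <- tibble::tibble(y = c(-0.1, 0, 0.1), prob = c(0, 1, 0))
  pd <- plan_cast_sniff(degen, params, nsteps = 2)
  expect_equal(pd$dy, 0)
})

test_that("planner value expansion matches an independent normalised Bayes recursion", {
  params <- mvt_params(lambda = 0.4, v = 1, x_thr = 1, y_thr = 0.07,
                       L_x = 4, L_y = 1, t_sniff = 0.1)
  prior <- uniform_marginal_prior(1, n_cells = 41)
  bayes_value <- function(dy, pos, b) {
    # literal recursion: V = [Gamma + (1 - Gamma) V(b')] * discount
    if (!length(dy)) return(0)
    pos2 <- pos + dy[1]
    g <- exp(-(pos2 - prior$y)^2 / (2 * params$y_thr^2))
    gam <- sum(b * g)
    b_next <- b * (1 - g)
    if (sum(b_next) > 0) b_next <- b_next / sum(b_next)
    disc <- exp(-params$lambda * (abs(dy[1]) / params$v + params$t_sniff))
    (gam + (1 - gam) * bayes_value(dy[-1], pos2, b_next)) * disc
  }
  withr::with_seed(23, {
    for (rep in 1:10) {
      dy <- stats::rnorm(4, 0, 0.2)
      v1 <- sniffr:::plan_value(dy, 0, prior$y, prior$prob, params$y_thr,
                                params$lambda, params$v, params$t_sniff)
      v2 <- bayes_value(dy, 0, prior$prob)
      expect_equal(v1, v2, tolerance = 1e-12)
    }
  })
})

test_that("single certain sniff on a point prior ends the search immediately", {
  params <- mvt_params(lambda = 0.5, v = 1, x_thr = 1, y_thr = 0.03,
                       L_x = 4, L_y = 1, t_sniff = 0.2)
  degen <- tibble::tibble(y = c(-0.2, 0, 0.2), prob = c(0, 1, 0))
  fitlike <- plan_cast_sniff(degen, params, nsteps = 2)
  # g = 1 at the prior's cell: survival drops to zero at the first sniff
  expect_equal(fitlike$survival[1], 0, tolerance = 1e-12)
})

test_that("fitted casting rate falls with sniffing time and grows with depth", {
  base <- mvt_params(lambda = 0.5, v = 1, x_thr = 1, y_thr = 0.05,
                     L_x = 4, L_y = 1, t_sniff = 0)
  # t_sniff grid {0, 0.5, 1} * (y_thr / v): kappa strictly decreasing
  kappas <- vapply(c(0, 0.5, 1) * base$y_thr / base$v, function(ts) {
    p <- mvt_params(lambda = 0.5, v = 1, x_thr = 1, y_thr = 0.05,
                    L_x = 4, L_y = 1, t_sniff = ts)
    estimate_decay(p, nsteps = 4)$kappa
  }, numeric(1))
  expect_true(all(diff(kappas) < 0))
  # kappa non-decreasing at small depths (up to optimizer tolerance)
  k13 <- vapply(c(1, 3), function(d) estimate_decay(base, d)$kappa, numeric(1))
  expect_gt(k13[2], k13[1] * 0.98)
})
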