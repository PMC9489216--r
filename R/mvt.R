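#' Parameters of the marginal-value casting theory
#'
#' The analytic model of the pre-detection search: the agent sweeps a uniform
#' prior of length `L_x` and width `L_y` in `N ~ L_x / x_thr` episodes
#' ("patches"); in each it casts-and-sniffs for a time `t_n`, then surges
#' upwind by the plume range `x_thr` (taking `tau = x_thr / v` seconds).
#' Detections while casting arrive at rate `kappa`; the unit reward for
#' detecting odor is discounted at rate `lambda`.
#'
#' @param lambda reward discount rate (1/s).
#' @param v travel speed (m/s).
#' @param x_thr plume detection range (m).
#' @param y_thr plume width scale (m): sigma of the crosswind detection
#'   kernel `g(u) = exp(-u^2 / (2 y_thr^2))`.
#' @param L_x,L_y prior length and width (m).
#' @param t_sniff time per air sniff (s).
#' @param N number of episodes/patches; defaults to `round(L_x / x_thr)`.
#' @param kappa casting detection rate (1/s), if known.
#' @return object of class `mvt_params`.
#' @export
mvt_params <- function(lambda, v, x_thr, y_thr, L_x, L_y, t_sniff = 0,
                       N = NULL, kappa = NULL) {
  if (any(c(lambda, v, x_thr, y_thr, L_x, L_y) <= 0) || t_sniff < 0) {
    stop("rates and lengths must be positive (t_sniff >= 0)", call. = FALSE)
  }
  if (is.null(N)) N <- max(1L, as.integer(round(L_x / x_thr)))
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  structure(
    list(lambda = lambda, v = v, x_thr = x_thr, y_thr = y_thr,
         L_x = L_x, L_y = L_y, t_sniff = t_sniff, N = as.integer(N),
         kappa = kappa, tau = x_thr / v),
    class = "mvt_params"
  )
}

#' Terminal episode value
#'
#' In the last patch the agent casts indefinitely; with an exponential
#' no-detection curve `c(t) = exp(-kappa t)` this gives the closed form
#' `V_N = kappa / (N (kappa + lambda))`.
#'
#' @param kappa casting detection rate (1/s).
#' @param lambda discount rate (1/s).
#' @param N number of patches.
#' @return numeric scalar.
#' @export
boundary_value <- function(kappa, lambda, N) {
  if (kappa <= 0 || lambda < 0 || N < 1) {
    stop("arguments must be positive (N >= 1)", call. = FALSE)
  }
  kappa / (N * (kappa + lambda))
}

# r(t) = int_0^t d'(s) e^{-lambda s} ds, by parts so only d is needed:
# r(t) = e^{-lambda t} d(t) + lambda int_0^t d(s) e^{-lambda s} ds
discounted_reward <- function(d, lambda, t) {
  if (is.infinite(t)) {
    # substitute u = lambda * s: well conditioned for arbitrarily small lambda
    return(stats::integrate(function(u) d(u / lambda) * exp(-u),
                            0, Inf, rel.tol = 1e-12)$value)
  }
  if (t <= 0) return(0)
  exp(-lambda * t) * d(t) +
    lambda * stats::integrate(function(s) d(s) * exp(-lambda * s),
                              0, t, rel.tol = 1e-12)$value
}

#' Episode value recursion
#'
#' Backward recursion for the expected discounted reward at the start of each
#' episode,
#' \deqn{V_n = \max_t \{ -\tfrac{1}{N}\int_0^t c'(s) e^{-\lambda s} ds +
#'   e^{-\lambda (t + \tau)} V_{n+1} \},}
#' where `c(t)` is the probability of not having detected odor after casting
#' for time `t`, conditional on the target being in the current patch
#' (`c(0) = 1`, non-increasing). The maximising `t` is the optimal casting
#' duration `t_n`; in the final patch the agent casts indefinitely
#' (`t_N = Inf`). The inner maximisation brackets every sign change of the
#' marginal condition on a scan grid and polishes each root, so
#' non-exponential (even multimodal-gain) curves are handled.
#'
#' @param c_fun vectorised no-detection function `c(t)`.
#' @param params an [mvt_params()] (fields `lambda`, `tau`, `N` are used).
#' @param t_max scan horizon for the inner optimisation; default extends
#'   until discounted gains are negligible.
#' @return tibble of class `episode_schedule`: columns `n`, `value`
#'   (\eqn{V_n}) and `cast_time` (\eqn{t_n}, seconds; `Inf` for `n = N`).
#' @export
episode_values <- function(c_fun, params, t_max = NULL) {
  stopifnot(inherits(params, "mvt_params"))
  lam <- params$lambda; tau <- params$tau; N <- params$N
  if (abs(c_fun(0) - 1) > 1e-8) stop("c(0) must equal 1", call. = FALSE)
  d_fun <- function(s) 1 - c_fun(s)
  if (is.null(t_max)) {
    t_max <- 1 / lam
    while (exp(-lam * t_max) * c_fun(t_max) > 1e-12 && t_max < 700 / lam) {
      t_max <- 2 * t_max
    }
  }
  gain <- function(t) discounted_reward(d_fun, lam, t) / N
  r_inf <- discounted_reward(d_fun, lam, Inf) / N

  values <- numeric(N); times <- numeric(N)
  values[N] <- r_inf; times[N] <- Inf
  cprime <- function(t) {
    h <- 1e-6 * max(1, t)
    (c_fun(t + h) - c_fun(max(t - h, 0))) / (h + min(t, h))
  }
  for (n in rev(seq_len(max(0, N - 1)))) {
    v_next <- values[n + 1]
    # marginal condition: phi(t) = -c'(t)/N - lambda e^{-lambda tau} V_{n+1}
    phi <- function(t) -cprime(t) / N - lam * exp(-lam * tau) * v_next
    obj <- function(t) gain(t) + exp(-lam * (t + tau)) * v_next
    ts <- seq(0, t_max, length.out = 401)
    ph <- vapply(ts, phi, numeric(1))
    cand <- c(0, t_max)
    flips <- which(ph[-1] * ph[-length(ph)] < 0)
    for (i in flips) {
      root <- stats::uniroot(phi, c(ts[i], ts[i + 1]), tol = 1e-12)$root
      cand <- c(cand, root)
    }
    ov <- vapply(cand, obj, numeric(1))
    best <- which.max(ov)
    times[n] <- cand[best]
    values[n] <- ov[best]
    if (!is.finite(values[n])) {
      stop("inner optimisation failed in episode value recursion", call. = FALSE)
    }
  }
  out <- tibble::tibble(n = seq_len(N), value = values, cast_time = times)
  class(out) <- c("episode_schedule", class(out))
  attr(out, "params") <- params
  out
}

#' Marginal-value casting time (exponential detection)
#'
#' Closed form of the patch-leaving condition for an exponential no-detection
#' curve `c(t) = exp(-kappa t)`:
#' \deqn{t_n = \kappa^{-1} \log\!\big(\kappa e^{\lambda\tau} / (N \lambda V_{n+1})\big),}
#' clipped at zero when the argument of the logarithm is below one.
#'
#' @param kappa casting detection rate (1/s).
#' @param lambda discount rate (1/s).
#' @param N number of patches.
#' @param tau inter-patch travel time `x_thr / v` (s).
#' @param V_next value of the next episode.
#' @return numeric scalar `t_n` (s).
#' @export
marginal_time <- function(kappa, lambda, N, tau, V_next) {
  arg <- kappa * exp(lambda * tau) / (N * lambda * V_next)
  if (arg <= 1) return(0)
  log(arg) / kappa
}

#' Exponential-c casting schedule
#'
#' Convenience wrapper: solves the whole casting-time schedule for
#' `c(t) = exp(-kappa t)` using [boundary_value()] and [marginal_time()]
#' backwards from the last patch.
#'
#' @inheritParams marginal_time
#' @return tibble (`episode_schedule`): `n`, `value`, `cast_time`.
#' @export
exponential_schedule <- function(kappa, lambda, N, tau) {
  values <- numeric(N); times <- numeric(N)
  values[N] <- boundary_value(kappa, lambda, N)
  times[N] <- Inf
  r_fun <- function(t) kappa / (kappa + lambda) * (1 - exp(-(kappa + lambda) * t))
  for (n in rev(seq_len(N - 1))) {
    times[n] <- marginal_time(kappa, lambda, N, tau, values[n + 1])
    values[n] <- r_fun(times[n]) / N +
      exp(-lambda * (times[n] + tau)) * values[n + 1]
  }
  out <- tibble::tibble(n = seq_len(N), value = values, cast_time = times)
  class(out) <- c("episode_schedule", class(out))
  out
}

#' Episode value without Bayesian updates
#'
#' Direct expansion of the expected discounted reward for given casting
#' times: \eqn{V_1 = \sum_n p_n r(t_n) e^{-\lambda \sum_{m<n} (t_m + \tau)}}
#' with \eqn{t_N = \infty}.
#'
#' @param prior probability vector over the `N` patches.
#' @param d_fun detection CDF `d(t)` conditional on the target being in the
#'   sampled patch (`d(0) = 0`, non-decreasing).
#' @param lambda discount rate (1/s).
#' @param tau inter-patch travel time (s).
#' @param times casting times `t_1, ..., t_{N-1}` (the last patch is cast
#'   indefinitely).
#' @return numeric scalar `V_1`.
#' @export
mvt_value_no_update <- function(prior, d_fun, lambda, tau, times) {
  N <- length(prior)
  if (abs(sum(prior) - 1) > 1e-9 || any(prior < 0)) {
    stop("`prior` must be a probability vector", call. = FALSE)
  }
  if (length(times) != N - 1) {
    stop("`times` must have length N - 1", call. = FALSE)
  }
  tt <- c(times, Inf)
  v <- 0; elapsed <- 0
  for (n in seq_len(N)) {
    v <- v + prior[n] * discounted_reward(d_fun, lambda, tt[n]) *
      exp(-lambda * elapsed)
    elapsed <- elapsed + tt[n] + tau
  }
  v
}

#' Episode value via explicit Bayesian updates
#'
#' Evaluates the same expected discounted reward by the posterior recursion:
#' after failing to detect in patch `n` for time `t_n`, the patch
#' probabilities are renormalised by Bayes' rule and the recursion continues
#' with the posterior. Equal to [mvt_value_no_update()] for every prior,
#' detection CDF and time vector -- the Bayes normalisers telescope through
#' the recursion and cancel.
#'
#' @inheritParams mvt_value_no_update
#' @return numeric scalar `V_1`.
#' @export
bayes_value_oracle <- function(prior, d_fun, lambda, tau, times) {
  N <- length(prior)
  if (abs(sum(prior) - 1) > 1e-9 || any(prior < 0)) {
    stop("`prior` must be a probability vector", call. = FALSE)
  }
  if (length(times) != N - 1) {
    stop("`times` must have length N - 1", call. = FALSE)
  }
  q <- prior
  tt <- c(times, Inf)
  value <- 0
  disc <- 1
  for (n in seq_len(N)) {
    r_n <- discounted_reward(d_fun, lambda, tt[n])
    value <- value + disc * q[n] * r_n
    if (n < N) {
      dn <- d_fun(tt[n])
      z <- 1 - q[n] * dn
      if (z <= 0) break
      q_new <- q / z
      q_new[n] <- q[n] * (1 - dn) / z
      q <- q_new
      # the posterior is renormalised, so the continuation is weighted by
      # the no-detection probability z in addition to the time discount
      disc <- disc * exp(-lambda * (tt[n] + tau)) * z
    }
  }
  value
}
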