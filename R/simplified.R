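#' Simplified air-only POMDP experiment
#'
#' Builds and trains the reduced decision problem used to test the
#' marginal-value theory: detections are possible only when sniffing in the
#' air, the airborne detection map is a rectangle of range `x_thr` and width
#' `y_thr`, and the uniform prior has dimensions `L_x` x `L_y` with
#' `L_x = N x_thr` patches. Moves are silent (the ground map is identically
#' zero).
#'
#' @param x_thr,y_thr rectangular plume range and full width (m).
#' @param L_y prior width (m).
#' @param L_x prior length (m); defaults to `4 * x_thr` (N = 4 patches).
#' @param cell_size grid cell (m).
#' @param peak_rate per-sniff detection probability inside the rectangle.
#' @param gamma per-step discount.
#' @param n_episodes,points_per_episode,seed training configuration for
#'   [train()].
#' @param margin_cells upwind/lateral grid margin beyond the prior.
#' @return list with `spec`, `prior`, `H` (trained alpha set) and `params`
#'   (the matching [mvt_params()], using the agent's speed
#'   `step_length / step_duration` and discount rate `-log(gamma) / step_duration`).
#' @export
simplified_pomdp_experiment <- function(x_thr, y_thr, L_y, L_x = 4 * x_thr,
                                        cell_size = 0.12, peak_rate = 1,
                                        gamma = 0.99, n_episodes = 20,
                                        points_per_episode = 60, seed = 1,
                                        margin_cells = 8L) {
  h <- cell_size
  lx <- as.integer(ceiling(L_x / h - 1e-9))
  ly <- as.integer(ceiling(L_y / h - 1e-9))
  n_x <- margin_cells + lx + 12L
  n_y <- ly + 2L * margin_cells + (1L - (ly %% 2L))  # odd width, centered
  origin <- c(margin_cells + 1L, (n_y + 1L) %/% 2L)
  air <- make_separable_map(
    plume_params(x_thr, y_thr, peak_rate, shape = "rectangular"),
    grid_shape = c(n_x, n_y), cell_size = h, origin = origin,
    modality = "air"
  )
  ground <- detection_rate_map(matrix(0, n_x, n_y), h, origin, "ground")
  spec <- build_spec(air, ground, gamma = gamma, step_length = h,
                     step_duration = 1 / 3)
  prior <- make_prior(spec, L_x, L_y)
  H <- train(spec, prior, n_episodes, points_per_episode, seed = seed)
  params <- mvt_params(
    lambda = spec$lambda, v = spec$step_length / spec$step_duration,
    x_thr = x_thr, y_thr = y_thr, L_x = L_x, L_y = L_y,
    t_sniff = spec$step_duration
  )
  list(spec = spec, prior = prior, H = H, params = params)
}

#' Surge length, cast width and casting times of the air-only agent
#'
#' Runs no-detection test episodes of a trained simplified agent and
#' measures, via [patch_decomposition()], the mean upwind displacement
#' between consecutive casting bouts (surge length), the lateral extent of
#' casting bouts (cast width), and the time spent casting in each successive
#' patch. The theory predicts surge length = `x_thr`, cast width = `L_y`,
#' and per-patch casting times that grow as the search progresses.
#'
#' Episodes are started with the true state displaced beyond the prior's
#' downwind edge, so the sweep of the (wrong) belief produces a full
#' conditional-on-no-detection trajectory; episodes containing any detection
#' are excluded, as are (for the casting-time series) final patches
#' truncated by the episode cap.
#'
#' @param experiment a [simplified_pomdp_experiment()] result.
#' @param seeds observation seeds, one episode per seed.
#' @param max_steps episode cap; the default budgets 1.3 times the estimated
#'   length of a full `N`-patch cast-and-surge sweep, so that the episode
#'   ends shortly after the sweep rather than continuing into residual
#'   mopping-up behaviour.
#' @param k segmentation run length (see [classify_segments()]).
#' @return list with `patches` (per episode and patch), `surges` (per
#'   episode and inter-patch gap) and `summary` (one row: `n_episodes`,
#'   `n_patches` (median), `surge_length` and `cast_width` means with their
#'   theoretical values `x_thr`, `L_y`). The reported cast width is the
#'   swept width: the lateral span of the casting bout's positions plus the
#'   sensor footprint `y_thr`, since a sniff detects a stripe `y_thr` wide
#'   and covering `L_y` only requires visiting a span of `L_y - y_thr`.
#' @export
simplified_pomdp_summary <- function(experiment, seeds = 1:5,
                                     max_steps = NULL, k = 3) {
  spec <- experiment$spec
  par <- experiment$params
  lx <- as.integer(ceiling(par$L_x / spec$cell_size - 1e-9))
  start_margin <- 10L
  if (is.null(max_steps)) {
    ly <- ceiling(par$L_y / spec$cell_size)
    xthr_c <- ceiling(par$x_thr / spec$cell_size)
    ythr_c <- max(1, floor(par$y_thr / spec$cell_size))
    sweep <- par$N * (ly + ceiling(ly / ythr_c)) + (par$N - 1) * xthr_c
    max_steps <- as.integer(round(1.3 * sweep))
  }
  start <- c(spec$origin[1] + lx + start_margin, spec$origin[2])
  if (start[1] > spec$n_x) stop("grid too short for the test start", call. = FALSE)
  eps <- lapply(seeds, function(s) {
    # the true start sits outside the prior's support, so once the belief
    # is exhausted the model cannot explain further observations; the
    # episode is truncated there rather than aborted
    run_episode(spec, experiment$H, experiment$prior, start,
                max_steps = max_steps, seed = s, on_mismatch = "stop")
  })
  no_det <- vapply(eps, function(tr) !any(tr$observation == "detection") &&
                     episode_outcome(tr) != "found", logical(1))
  eps <- eps[no_det]
  if (!length(eps)) {
    stop("all test episodes contained detections; cannot summarise the no-detection sweep",
         call. = FALSE)
  }
  decomp <- lapply(seq_along(eps), function(i) {
    d <- patch_decomposition(eps[[i]], k = k)
    if (nrow(d$patches)) d$patches$episode <- i
    if (nrow(d$surges)) d$surges$episode <- i
    d
  })
  patches <- dplyr::bind_rows(lapply(decomp, `[[`, "patches"))
  surges <- dplyr::bind_rows(lapply(decomp, `[[`, "surges"))
  complete <- patches[!patches$truncated, , drop = FALSE]
  # swept width = lateral extent of the sniff positions plus the sensor
  # footprint: a sniff detects a stripe y_thr wide, so covering the prior
  # width L_y only requires visiting a span of L_y - y_thr
  width <- mean(complete$cast_width) - spec$cell_size + par$y_thr
  summary <- tibble::tibble(
    n_episodes = length(eps),
    n_patches = stats::median(vapply(decomp, function(d) nrow(d$patches),
                                     numeric(1))),
    surge_length = mean(surges$surge_length),
    cast_width = width,
    x_thr = par$x_thr,
    L_y = par$L_y
  )
  list(patches = patches, surges = surges, summary = summary)
}
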