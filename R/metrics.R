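#' Cast/surge segmentation of a trajectory
#'
#' Labels each step: `surge` if it lies in a run of at least `k` consecutive
#' upwind moves; `cast` if it lies in a run of at least `k` consecutive steps
#' each of which is a crosswind move or an air sniff; `other` otherwise. The
#' two qualifying step sets are disjoint (an upwind move can never be part of
#' a cast run), so the labels partition the steps; `cast` takes precedence by
#' construction order.
#'
#' @param traj a [run_episode()] trajectory (or any tibble with an `action`
#'   column).
#' @param k run length threshold (default 3).
#' @return `traj` with an added character column `segment`.
#' @export
classify_segments <- function(traj, k = 3) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  a <- traj$action
  lab <- rep("other", length(a))
  lab[run_member(a == "move_up", k)] <- "surge"
  lab[run_member(a %in% c("move_left", "move_right", "stay_sniff_air"), k)] <- "cast"
  out <- traj
  out$segment <- lab
  out
}

# steps belonging to a TRUE-run of length >= k
run_member <- function(flag, k) {
  r <- rle(flag)
  rep(r$values & r$lengths >= k, r$lengths)
}

#' Air-sniff rate
#'
#' Fraction of (masked) steps on which the agent pauses to sniff the air
#' rather than move and sniff the ground.
#'
#' @param traj a trajectory tibble with columns `action` / `air_sniff`.
#' @param mask optional logical vector selecting steps; must select at least
#'   one step.
#' @return numeric scalar in `[0, 1]`.
#' @export
air_sniff_rate <- function(traj, mask = NULL) {
  air <- traj$action == "stay_sniff_air"
  if (is.null(mask)) mask <- rep(TRUE, length(air))
  if (length(mask) != length(air)) {
    stop("`mask` length must match the trajectory", call. = FALSE)
  }
  if (!any(mask)) stop("`mask` selects no steps", call. = FALSE)
  mean(air[mask])
}

#' Air-sniff rate by distance to the source
#'
#' Pools steps across trajectories and stratifies them either by Euclidean
#' distance to the source (metres, via `breaks`) or by position relative to
#' the airborne plume (`inside` / `outside` the `level` isoline of the air
#' map). Distances use the true (experimenter-side) state. Strata with no
#' steps are reported with `NA` rate, not zero.
#'
#' @param trajs a single trajectory, a list of trajectories, or a
#'   [run_battery()] tibble with a `trajectory` list-column.
#' @param spec the [build_spec()] the episodes were run in.
#' @param breaks numeric break points (m) for distance bins; if `NULL`, steps
#'   are partitioned inside/outside the air plume isoline.
#' @param level relative isoline level of the air map (default 0.1).
#' @return tibble with `stratum`, `n_steps`, `air_sniff_rate`.
#' @export
rate_by_distance <- function(trajs, spec, breaks = NULL, level = 0.1) {
  trajs <- as_trajectory_list(trajs)
  steps <- dplyr::bind_rows(lapply(trajs, function(tr) {
    tibble::tibble(x = tr$x, y = tr$y, air = tr$action == "stay_sniff_air")
  }))
  h <- spec$cell_size
  if (is.null(breaks)) {
    rate <- spec$air_map$values[cbind(steps$x + spec$origin[1],
                                      steps$y + spec$origin[2])]
    thr <- level * max(spec$air_map$values)
    steps$stratum <- ifelse(rate >= thr & rate > 0, "inside", "outside")
    lev <- c("inside", "outside")
  } else {
    d <- h * sqrt(steps$x^2 + steps$y^2)
    steps$stratum <- as.character(cut(d, breaks, include.lowest = TRUE))
    lev <- as.character(levels(cut(numeric(0), breaks, include.lowest = TRUE)))
  }
  steps |>
    dplyr::group_by(stratum = factor(stratum, levels = lev)) |>
    dplyr::summarise(n_steps = dplyr::n(), air_sniff_rate = mean(air)) |>
    tidyr::complete(stratum) |>
    dplyr::ungroup()
}

#' Excess path length of a successful episode
#'
#' Number of steps taken to reach the source minus the grid shortest-path
#' step count from the start (Manhattan distance in cells, since moves are
#' axis-aligned).
#'
#' @param traj a [run_episode()] trajectory with outcome `"found"`.
#' @return integer scalar (>= 0 for an optimal grid path).
#' @export
excess_steps <- function(traj) {
  if (!identical(attr(traj, "outcome"), "found")) {
    stop("excess steps are defined for successful episodes only", call. = FALSE)
  }
  start <- attr(traj, "start_state") - attr(traj, "origin")
  nrow(traj) - (abs(start[1]) + abs(start[2]))
}

#' Five-number summary of excess steps
#'
#' Median, quartiles, 10th/90th percentiles and the upper outlier fence
#' (75th percentile + 1.5 IQR) of `excess_steps` over the successful episodes
#' of a battery.
#'
#' @param battery a [run_battery()] tibble.
#' @return one-row tibble.
#' @export
excess_summary <- function(battery) {
  x <- battery$excess_steps[battery$outcome == "found"]
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  tibble::tibble(
    n = length(x), q10 = q[1], q25 = q[2], median = q[3], q75 = q[4],
    q90 = q[5], outlier_fence = q[4] + 1.5 * (q[4] - q[2])
  )
}

#' Entropy and value time series
#'
#' Per-step belief entropy (nats) and value under the trained alpha set,
#' with detection steps flagged; the traces behind the
#' "entropy plummets, value jumps at detection" picture.
#'
#' @param traj a [run_episode()] trajectory.
#' @return tibble with `step`, `entropy`, `value`, `detection`.
#' @export
entropy_value_series <- function(traj) {
  tibble::tibble(
    step = traj$step, entropy = traj$entropy, value = traj$value,
    detection = traj$observation == "detection"
  )
}

as_trajectory_list <- function(trajs) {
  if (inherits(trajs, "sniff_trajectory")) return(list(trajs))
  if (is.data.frame(trajs) && "trajectory" %in% names(trajs)) {
    return(trajs$trajectory)
  }
  if (is.list(trajs)) return(trajs)
  stop("cannot interpret `trajs` as trajectories", call. = FALSE)
}

#' Patch decomposition of a no-detection trajectory
#'
#' Splits a trajectory at its surge bouts (maximal runs of `surge` labels
#' from [classify_segments()]): each maximal inter-surge interval containing
#' at least one `cast` step is one explored patch. Returns per-patch casting
#' effort and geometry, and the upwind displacement of each surge separating
#' consecutive patches -- the quantities the marginal-value theory predicts
#' to equal the prior width, to grow with patch index, and to equal the
#' plume detection range, respectively.
#'
#' @param traj a trajectory (will be segmented with [classify_segments()]).
#' @param k run length threshold for segmentation.
#' @return list with `patches` (tibble: `patch`, `cast_steps`, `cast_time`
#'   (s), `cast_width` (m), `truncated` -- TRUE for the final patch of a
#'   timeout episode, whose casting is cut short by the episode cap) and
#'   `surges` (tibble: `gap`, `surge_length` (m)).
#' @export
patch_decomposition <- function(traj, k = 3) {
  seg <- classify_segments(traj, k)
  h <- attr(traj, "cell_size") %||% 1
  dt <- attr(traj, "step_duration") %||% 1
  lab <- seg$segment
  r <- rle(lab == "surge")
  # patch id: intervals between surge runs
  bounds <- cumsum(r$lengths)
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  interval <- data.frame(start = starts, end = bounds, surge = r$values)
  non_surge <- interval[!interval$surge, , drop = FALSE]
  patches <- purrr::pmap(non_surge[c("start", "end")], function(start, end) {
    idx <- start:end
    cast_idx <- idx[lab[idx] == "cast"]
    if (!length(cast_idx)) return(NULL)
    tibble::tibble(
      first_cast = cast_idx[1], last_cast = cast_idx[length(cast_idx)],
      cast_steps = length(cast_idx),
      cast_time = length(cast_idx) * dt,
      cast_width = (max(seg$y[cast_idx]) - min(seg$y[cast_idx]) + 1L) * h
    )
  }) |> dplyr::bind_rows()
  if (nrow(patches)) {
    patches$patch <- seq_len(nrow(patches))
    patches$truncated <- FALSE
    if (identical(attr(traj, "outcome"), "timeout")) {
      patches$truncated[nrow(patches)] <- TRUE
    }
  }
  surges <- if (nrow(patches) >= 2) {
    tibble::tibble(
      gap = seq_len(nrow(patches) - 1),
      surge_length = abs(seg$x[patches$first_cast[-1]] -
                           seg$x[patches$last_cast[-nrow(patches)]]) * h
    )
  } else {
    tibble::tibble(gap = integer(), surge_length = numeric())
  }
  list(patches = patches[c("patch", "cast_steps", "cast_time", "cast_width",
                           "truncated")],
       surges = surges)
}
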