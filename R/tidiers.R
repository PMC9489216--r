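#' Tidy an alpha set
#'
#' One row per hyperplane with its generating action and coefficient
#' summaries.
#'
#' @param x an [alpha_set()].
#' @param ... unused.
#' @return tibble with `index`, `action`, `min`, `max`, `mean`.
#' @export
tidy.alpha_set <- function(x, ...) {
  tibble::tibble(
    index = seq_len(ncol(x$A)),
    action = x$actions,
    min = apply(x$A, 2, min),
    max = apply(x$A, 2, max),
    mean = colMeans(x$A)
  )
}

#' @rdname tidy.alpha_set
#' @return `glance()`: one row with `n_vectors`, `n_states`, `max_value`
#'   (largest coefficient, an upper bound on the representable value) and,
#'   when the set was produced by [train()], `n_episodes`.
#' @export
glance.alpha_set <- function(x, ...) {
  hist <- attr(x, "history")
  tibble::tibble(
    n_vectors = ncol(x$A),
    n_states = nrow(x$A),
    max_value = max(x$A),
    n_episodes = if (!is.null(hist) && nrow(hist)) max(hist$episode) else NA_integer_
  )
}

#' Tidy an episode schedule
#'
#' @param x an `episode_schedule` from [episode_values()] or
#'   [exponential_schedule()].
#' @param ... unused.
#' @return the schedule as a plain tibble (`n`, `value`, `cast_time`).
#' @export
tidy.episode_schedule <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("n", "value", "cast_time")])
}

#' Tidy a trajectory
#'
#' @param x a [run_episode()] trajectory.
#' @param k segmentation run length.
#' @param ... unused.
#' @return the per-step tibble with the `segment` labels added.
#' @export
tidy.sniff_trajectory <- function(x, k = 3, ...) {
  tibble::as_tibble(classify_segments(x, k))
}

#' @rdname tidy.sniff_trajectory
#' @return `glance()`: one row with `outcome`, `steps`, `air_sniffs`,
#'   `air_sniff_rate`, `first_detection_step`, `final_entropy`.
#' @export
glance.sniff_trajectory <- function(x, ...) {
  det <- which(x$observation == "detection")
  tibble::tibble(
    outcome = attr(x, "outcome"),
    steps = nrow(x),
    air_sniffs = sum(x$air_sniff),
    air_sniff_rate = mean(x$air_sniff),
    first_detection_step = if (length(det)) det[1] else NA_integer_,
    final_entropy = x$entropy[nrow(x)]
  )
}
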