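#' Detection-rate map
#'
#' A gridded per-sniff detection probability map \eqn{r(x, y)} for one sensing
#' modality ("air" or "ground"). Coordinates are source-relative: the source
#' sits at the `origin` cell, `x` increases downwind (an agent downwind of the
#' source has `x > 0`) and `y` is crosswind. Cell centers are spaced
#' `cell_size` metres apart, so the cell with (1-based) index `(i, j)` has
#' center displacement `((i - origin[1]) * cell_size, (j - origin[2]) * cell_size)`.
#'
#' @param values numeric matrix (`n_x` rows by `n_y` columns) of per-sniff
#'   detection probabilities, all in `[0, 1]`.
#' @param cell_size length of a grid cell in metres.
#' @param origin integer vector `c(ix, iy)`: grid index of the source cell.
#' @param modality `"air"` or `"ground"`.
#'
#' @return An object of class `detection_rate_map`.
#' @export
detection_rate_map <- function(values, cell_size, origin,
                               modality = c("air", "ground")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be a numeric matrix without NA", call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a positive scalar", call. = FALSE)
  }
  origin <- as.integer(origin)
  if (length(origin) != 2L ||
      origin[1] < 1L || origin[1] > nrow(values) ||
      origin[2] < 1L || origin[2] > ncol(values)) {
    stop("`origin` must index a cell inside the grid", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = cell_size, origin = origin,
         modality = modality),
    class = "detection_rate_map"
  )
}

#' @export
print.detection_rate_map <- function(x, ...) {
  cat(sprintf(
    "<detection_rate_map [%s]> %d x %d cells of %.3g m, source at (%d, %d), max rate %.3g\n",
    x$modality, nrow(x$values), ncol(x$values), x$cell_size,
    x$origin[1], x$origin[2], max(x$values)
  ))
  invisible(x)
}

#' @export
dim.detection_rate_map <- function(x) dim(x$values)

# Source-relative cell-center coordinates (m) along each axis.
map_axis <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    (seq_len(nrow(map$values)) - map$origin[1]) * map$cell_size
  } else {
    (seq_len(ncol(map$values)) - map$origin[2]) * map$cell_size
  }
}

#' Plume geometry parameters
#'
#' Parameters of an idealised separable detection-probability map,
#' \eqn{r(x, y) = \mathrm{peak}\, f(x) g(y)}. For `shape = "separable_gaussian"`,
#' \eqn{f(x) = 1} on \eqn{0 < x \le x_{thr}} and
#' \eqn{g(y) = \exp(-y^2 / 2 y_{thr}^2)} (so `y_thr` is the Gaussian width
#' scale). For `shape = "rectangular"`, the map is `peak_rate` on
#' \eqn{0 < x \le x_{thr}}, \eqn{|y| \le y_{thr}/2} (so `y_thr` is the full
#' crosswind width) and zero elsewhere.
#'
#' @param x_thr downwind detection range in metres (> 0).
#' @param y_thr crosswind width scale in metres (> 0); Gaussian sigma for
#'   `separable_gaussian`, full width for `rectangular`. May be `Inf` for a
#'   crosswind-uniform map.
#' @param peak_rate per-sniff detection probability inside the plume core,
#'   in `(0, 1]`.
#' @param shape `"separable_gaussian"` or `"rectangular"`.
#'
#' @return An object of class `plume_params`.
#' @export
plume_params <- function(x_thr, y_thr, peak_rate,
                         shape = c("separable_gaussian", "rectangular")) {
  shape <- match.arg(shape)
  if (!is.numeric(x_thr) || length(x_thr) != 1L || x_thr <= 0) {
    stop("`x_thr` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(y_thr) || length(y_thr) != 1L || y_thr <= 0) {
    stop("`y_thr` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(peak_rate) || length(peak_rate) != 1L ||
      peak_rate <= 0 || peak_rate > 1) {
    stop("`peak_rate` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(x_thr = x_thr, y_thr = y_thr, peak_rate = peak_rate,
                 shape = shape),
            class = "plume_params")
}

#' Build a separable detection-rate map
#'
#' Evaluates the idealised plume of [plume_params()] at cell centers of a
#' source-relative grid. The map is zero for `x <= 0` (upwind of the source)
#' and for `x > x_thr`.
#'
#' @param params a [plume_params()] object.
#' @param grid_shape integer vector `c(n_x, n_y)`.
#' @param cell_size cell length in metres.
#' @param origin source cell index `c(ix, iy)`; defaults to
#'   `c(max(2, round(0.1 * n_x)), (n_y + 1) %/% 2)`, i.e. a small upwind
#'   margin and a crosswind-centered source.
#' @param modality `"air"` or `"ground"`.
#'
#' @return A [detection_rate_map()] whose `plume_params` are retained as an
#'   attribute (used by [perturb_map()] to rescale analytically).
#' @export
make_separable_map <- function(params, grid_shape, cell_size, origin = NULL,
                               modality = "air") {
  stopifnot(inherits(params, "plume_params"))
  grid_shape <- as.integer(grid_shape)
  if (is.null(origin)) {
    origin <- c(max(2L, as.integer(round(0.1 * grid_shape[1]))),
                (grid_shape[2] + 1L) %/% 2L)
  }
  x <- (seq_len(grid_shape[1]) - origin[1]) * cell_size
  y <- (seq_len(grid_shape[2]) - origin[2]) * cell_size
  if (max(x) < params$x_thr) {
    stop("grid too short: it must contain x_thr downwind of the origin",
         call. = FALSE)
  }
  eps <- 1e-6 * cell_size  # guard against float jitter at range boundaries
  f <- as.numeric(x > eps & x <= params$x_thr + eps)
  g <- if (params$shape == "separable_gaussian") {
    if (is.finite(params$y_thr)) exp(-y^2 / (2 * params$y_thr^2)) else rep(1, length(y))
  } else {
    as.numeric(abs(y) <= params$y_thr / 2 + eps)
  }
  vals <- params$peak_rate * outer(f, g)
  out <- detection_rate_map(vals, cell_size, origin, modality)
  attr(out, "plume_params") <- params
  out
}

#' Build a matched (air, ground) map pair
#'
#' Produces two detection-rate maps on the same grid, emulating the
#' qualitative structure of detection statistics measured at nose height and
#' at the ground: the airborne plume must be longer (`air$x_thr > ground$x_thr`)
#' and at least as wide (`air$y_thr >= ground$y_thr`) as the ground plume, so
#' that for every isoline level the air map's supra-level area is at least the
#' ground map's.
#'
#' @param air,ground [plume_params()] for each modality.
#' @inheritParams make_separable_map
#' @return A list with elements `air` and `ground`.
#' @export
make_dns_like_pair <- function(air, ground, grid_shape, cell_size,
                               origin = NULL) {
  stopifnot(inherits(air, "plume_params"), inherits(ground, "plume_params"))
  if (air$x_thr < ground$x_thr || air$y_thr < ground$y_thr) {
    stop("air plume must satisfy x_thr >= ground x_thr and y_thr >= ground y_thr",
         call. = FALSE)
  }
  list(
    air = make_separable_map(air, grid_shape, cell_size, origin, "air"),
    ground = make_separable_map(ground, grid_shape, cell_size, origin, "ground")
  )
}

#' Default plume pair mimicking measured detection maps
#'
#' Convenience defaults for a matched pair: the airborne detection range is
#' 0.6 of the prior length and the ground range 0.1 of it; widths scale with
#' the range (air aspect ratio 6:1, ground 4:1). Airborne detections are
#' sparser per sniff (`0.25`) than ground detections near the source (`0.8`).
#'
#' @param prior_length length of the uniform prior's downwind extent (m).
#' @param air_peak,ground_peak per-sniff peak detection probabilities.
#' @return list of two [plume_params()], elements `air` and `ground`.
#' @export
default_plume_pair <- function(prior_length, air_peak = 0.25,
                               ground_peak = 0.8) {
  list(
    air = plume_params(x_thr = 0.6 * prior_length,
                       y_thr = 0.1 * prior_length,
                       peak_rate = air_peak),
    ground = plume_params(x_thr = 0.1 * prior_length,
                          y_thr = 0.025 * prior_length,
                          peak_rate = ground_peak)
  )
}

#' Perturb a detection-rate map
#'
#' Produces the perturbed plumes used for robustness evaluations: `"rescale"`
#' multiplies both `x_thr` and `y_thr` by `magnitude` (the plume grows or
#' shrinks isotropically); `"meander"` rigidly rotates the map about the
#' source by the time-dependent angle
#' \eqn{\theta(t) = \mathrm{magnitude} \cdot \sin(2\pi \cdot \mathrm{frequency} \cdot t)}
#' (radians), using nearest-cell resampling with values clipped to `[0, 1]`
#' and zero outside the base grid.
#'
#' @param base a [detection_rate_map()].
#' @param mode `"rescale"` or `"meander"`.
#' @param magnitude scale factor (> 0) for `"rescale"`; rotation amplitude in
#'   radians for `"meander"`.
#' @param frequency meander frequency (>= 0), in cycles per unit of `t`.
#' @param t time at which the meander angle is evaluated.
#' @return A [detection_rate_map()].
#' @export
perturb_map <- function(base, mode = c("rescale", "meander"), magnitude,
                        frequency = 0, t = 0) {
  stopifnot(inherits(base, "detection_rate_map"))
  mode <- match.arg(mode)
  if (mode == "rescale") {
    if (magnitude <= 0) stop("`magnitude` must be > 0 for rescale", call. = FALSE)
    params <- attr(base, "plume_params")
    max_x <- (nrow(base$values) - base$origin[1]) * base$cell_size
    if (!is.null(params) && params$x_thr * magnitude <= max_x) {
      new_params <- plume_params(params$x_thr * magnitude,
                                 params$y_thr * magnitude,
                                 params$peak_rate, params$shape)
      out <- make_separable_map(new_params, dim(base$values), base$cell_size,
                                base$origin, base$modality)
      return(out)
    }
    # scaled plume outgrows the grid (or no analytic form): resample the
    # base values, truncating at the grid boundary
    return(resample_map(base, function(x, y) cbind(x / magnitude, y / magnitude)))
  }
  if (frequency < 0) stop("`frequency` must be >= 0", call. = FALSE)
  theta <- magnitude * sin(2 * pi * frequency * t)
  if (theta == 0) return(base)
  # value at (x, y) is the base value at the point rotated back by -theta
  ct <- cos(theta); st <- sin(theta)
  resample_map(base, function(x, y) cbind(ct * x + st * y, -st * x + ct * y))
}

# Nearest-cell resampling of a map under a coordinate pullback.
resample_map <- function(base, pullback) {
  nx <- nrow(base$values); ny <- ncol(base$values)
  x <- map_axis(base, "x"); y <- map_axis(base, "y")
  grid <- expand.grid(x = x, y = y)
  src <- pullback(grid$x, grid$y)
  i <- as.integer(round(src[, 1] / base$cell_size)) + base$origin[1]
  j <- as.integer(round(src[, 2] / base$cell_size)) + base$origin[2]
  inside <- i >= 1L & i <= nx & j >= 1L & j <= ny
  vals <- numeric(nx * ny)
  vals[inside] <- base$values[cbind(i[inside], j[inside])]
  out <- detection_rate_map(matrix(pmin(pmax(vals, 0), 1), nx, ny),
                            base$cell_size, base$origin, base$modality)
  out
}

#' Sample per-sniff binary observations from a map
#'
#' One independent Bernoulli trial per sniff: a sniff at `state` returns
#' `"detection"` with probability `map$values[state]` and `"no_detection"`
#' otherwise. Draws consume the current R random-number stream, so a fixed
#' seed reproduces the observation sequence exactly.
#'
#' @param map a [detection_rate_map()].
#' @param state integer cell index `c(ix, iy)` (within the grid).
#' @param n number of independent sniffs to draw.
#' @return character vector of length `n` with values `"detection"` /
#'   `"no_detection"`.
#' @export
sample_observation <- function(map, state, n = 1) {
  stopifnot(inherits(map, "detection_rate_map"))
  state <- as.integer(state)
  if (length(state) != 2L ||
      state[1] < 1L || state[1] > nrow(map$values) ||
      state[2] < 1L || state[2] > ncol(map$values)) {
    stop("`state` lies outside the grid", call. = FALSE)
  }
  p <- map$values[state[1], state[2]]
  ifelse(stats::runif(n) < p, "detection", "no_detection")
}

#' Isoline extent of a detection-rate map
#'
#' Bounding box of the supra-level region \eqn{\{r \ge \mathrm{level} \cdot \max r\}},
#' in source-relative metres. Extents count whole cells
#' (`extent = span of cell centers + one cell`), so a rectangular plume of
#' range `x_thr` aligned with the grid reports `extent_x = x_thr`. An empty
#' region yields zero extents.
#'
#' @param map a [detection_rate_map()].
#' @param level relative level in `(0, 1)`.
#' @return A one-row tibble with columns `x_min`, `x_max`, `y_min`, `y_max`
#'   (cell-center coordinates, m), `extent_x`, `extent_y` (m), and
#'   `half_extent_y` (max |y| over the region, m).
#' @export
isoline_extent <- function(map, level) {
  stopifnot(inherits(map, "detection_rate_map"))
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  thr <- level * max(map$values)
  sel <- which(map$values >= thr & map$values > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L || max(map$values) == 0) {
    return(tibble::tibble(x_min = NA_real_, x_max = NA_real_,
                          y_min = NA_real_, y_max = NA_real_,
                          extent_x = 0, extent_y = 0, half_extent_y = 0))
  }
  h <- map$cell_size
  xs <- (sel[, 1] - map$origin[1]) * h
  ys <- (sel[, 2] - map$origin[2]) * h
  tibble::tibble(
    x_min = min(xs), x_max = max(xs), y_min = min(ys), y_max = max(ys),
    extent_x = max(xs) - min(xs) + h,
    extent_y = max(ys) - min(ys) + h,
    half_extent_y = max(abs(ys))
  )
}

#' Supra-level area of a map
#'
#' Area (m^2) of the region where the detection rate is at least
#' `level * max(rate)`; used for the matched-pair invariant that the airborne
#' plume covers at least the ground plume at every level.
#'
#' @inheritParams isoline_extent
#' @return numeric scalar, in m^2.
#' @export
isoline_area <- function(map, level) {
  stopifnot(inherits(map, "detection_rate_map"))
  thr <- level * max(map$values)
  sum(map$values >= thr & map$values > 0) * map$cell_size^2
}

#' Convert a detection-rate map to a tibble
#'
#' One row per cell with source-relative coordinates, handy for ggplot2.
#'
#' @param map a [detection_rate_map()].
#' @return tibble with columns `x`, `y` (m) and `rate`.
#' @export
map_to_tibble <- function(map) {
  stopifnot(inherits(map, "detection_rate_map"))
  tibble::tibble(
    x = rep(map_axis(map, "x"), times = ncol(map$values)),
    y = rep(map_axis(map, "y"), each = nrow(map$values)),
    rate = as.vector(map$values)
  )
}

#' Write / read a detection-rate map as CSV + JSON metadata
#'
#' The values matrix is written as a headerless CSV (rows = downwind cells)
#' next to a JSON sidecar `<path>.json` holding `cell_size`, `origin` and
#' `modality`.
#'
#' @param map a [detection_rate_map()].
#' @param path path of the CSV file to write.
#' @return `write_detection_map()` returns `path` invisibly;
#'   `read_detection_map()` returns the [detection_rate_map()].
#' @export
write_detection_map <- function(map, path) {
  stopifnot(inherits(map, "detection_rate_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(cell_size = map$cell_size, origin = map$origin,
               modality = map$modality)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_detection_map
#' @export
read_detection_map <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  detection_rate_map(vals, meta$cell_size, meta$origin, meta$modality)
}
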