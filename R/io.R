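#' Serialize an alpha set
#'
#' Writes the hyperplane coefficients as a TSV array (one column per vector)
#' plus a JSON header `<path>.json` recording the generating actions and,
#' when available, training provenance (grid shape, discount, seed are the
#' caller's to include via `meta`).
#'
#' @param H an [alpha_set()].
#' @param path TSV file path.
#' @param meta optional named list merged into the JSON header.
#' @return `write_alpha_set()` returns `path` invisibly; `read_alpha_set()`
#'   returns the [alpha_set()].
#' @export
write_alpha_set <- function(H, path, meta = list()) {
  stopifnot(inherits(H, "alpha_set"))
  utils::write.table(H$A, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  header <- c(list(actions = H$actions, n_states = nrow(H$A)), meta)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_alpha_set
#' @export
read_alpha_set <- function(path) {
  A <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(A) <- NULL
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  alpha_set(A, header$actions)
}

#' Write a trajectory as CSV + JSON summary
#'
#' One row per step; the episode-level attributes (outcome, start, seed) go
#' to a JSON sidecar.
#'
#' @param traj a [run_episode()] trajectory.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(tibble::as_tibble(traj), path, row.names = FALSE)
  meta <- list(outcome = attr(traj, "outcome"),
               start_state = attr(traj, "start_state"),
               seed = attr(traj, "seed"),
               cell_size = attr(traj, "cell_size"),
               step_duration = attr(traj, "step_duration"),
               origin = attr(traj, "origin"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
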