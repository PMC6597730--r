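#' Read and write trajectory tables
#'
#' Plain-CSV trajectory dialect shared by the simulator and the tracker:
#' one row per particle per frame with header
#' `particle_id,frame,t_s,x_um,y_um`. Extra columns (e.g. the ground-truth
#' `heading`) round-trip unchanged.
#'
#' @param traj Trajectory tibble.
#' @param path CSV path.
#' @return `write_trajectories()`: `path`, invisibly. `read_trajectories()`:
#'   a trajectory tibble.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(all(c("particle_id", "frame", "t_s", "x_um", "y_um") %in% names(traj)))
  readr::write_csv(traj, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("particle_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(req, names(traj))
  if (length(missing)) {
    rlang::abort(paste0("Trajectory CSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  traj
}
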