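#' Time-averaged mean squared displacement of a trajectory
#'
#' For each integer lag `k` with `k*dt <= max_lag_s`, averages the squared
#' 2-D displacement over all `N - k` overlapping start times:
#' \deqn{MSD(k\Delta) = \langle (x(t+k\Delta)-x(t))^2 + (y(t+k\Delta)-y(t))^2 \rangle_t}
#' Overlapping-window averaging uses every available displacement pair, the
#' standard choice for single-particle tracking.
#'
#' @param traj Trajectory tibble with columns `t_s`, `x_um`, `y_um` and
#'   (optionally) `particle_id`; multiple particles are processed per particle.
#'   Sampling must be uniform; the time origin is irrelevant.
#' @param max_lag_s Largest lag to evaluate, s. Default: a quarter of the
#'   trajectory duration (time-averaged MSD values beyond that are too noisy
#'   to be useful).
#' @return A tibble with columns `particle_id`, `lag_s`, `msd_um2`, `n_pairs`.
#' @export
#' @examples
#' traj <- tibble::tibble(
#'   particle_id = 1, t_s = 0:2, x_um = c(0, 1, 2), y_um = 0
#' )
#' compute_msd(traj) # MSD(1) = 1, MSD(2) = 4
compute_msd <- function(traj, max_lag_s = NULL) {
  stopifnot(is.data.frame(traj))
  req <- c("t_s", "x_um", "y_um")
  if (!all(req %in% names(traj))) {
    rlang::abort("`traj` needs columns t_s, x_um, y_um (and optionally particle_id).")
  }
  if (!"particle_id" %in% names(traj)) traj$particle_id <- 1L
  traj |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_modify(~ msd_single(.x, max_lag_s)) |>
    dplyr::ungroup()
}

msd_single <- function(d, max_lag_s) {
  n <- nrow(d)
  if (n < 2) rlang::abort("Trajectory must have at least 2 frames.")
  t <- d$t_s
  dt <- t[2] - t[1]
  gaps <- diff(t)
  bad <- which(abs(gaps - dt) > 1e-9)
  if (length(bad)) {
    rlang::abort(sprintf(
      "Non-uniform timestamps: gap between samples %d and %d is %.9g s (expected %.9g s).",
      bad[1], bad[1] + 1L, gaps[bad[1]], dt
    ))
  }
  if (is.null(max_lag_s)) max_lag_s <- (t[n] - t[1]) / 4
  if (max_lag_s > t[n] - t[1]) {
    rlang::abort("`max_lag_s` exceeds the trajectory duration minus one frame.")
  }
  k_max <- floor(max_lag_s / dt + 1e-9)
  if (k_max < 1) rlang::abort("`max_lag_s` is shorter than one frame interval.")
  x <- d$x_um
  y <- d$y_um
  msd <- numeric(k_max)
  for (k in seq_len(k_max)) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    msd[k] <- mean(dx * dx + dy * dy)
  }
  tibble::tibble(
    lag_s = seq_len(k_max) * dt,
    msd_um2 = msd,
    n_pairs = n - seq_len(k_max)
  )
}

#' Ensemble mean and s.e.m. of per-particle MSD curves
#'
#' Averages per-particle MSD values lag by lag (unweighted mean across
#' particles) and reports the standard error of the mean across particles. If
#' particles have different numbers of lags, the common (intersection) lag
#' grid is used.
#'
#' @param msd A per-particle MSD tibble as returned by [compute_msd()].
#' @return A tibble with columns `lag_s`, `msd_um2`, `sem_um2`, `n_particles`.
#'   With a single particle, `sem_um2` is `NA` (undefined).
#' @export
ensemble_msd <- function(msd) {
  stopifnot(is.data.frame(msd), all(c("particle_id", "lag_s", "msd_um2") %in% names(msd)))
  n_part <- dplyr::n_distinct(msd$particle_id)
  if (n_part == 1) {
    warning("Single particle: s.e.m. across particles is undefined.", call. = FALSE)
  }
  msd |>
    dplyr::group_by(.data$lag_s) |>
    dplyr::filter(dplyr::n() == n_part) |> # intersection of lag grids
    dplyr::summarise(
      sem_um2 = stats::sd(.data$msd_um2) / sqrt(n_part),
      msd_um2 = mean(.data$msd_um2),
      n_particles = n_part,
      .groups = "drop"
    ) |>
    dplyr::select("lag_s", "msd_um2", "sem_um2", "n_particles") |>
    dplyr::arrange(.data$lag_s)
}
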