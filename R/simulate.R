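#' Simulate one active Brownian particle trajectory
#'
#' Euler–Maruyama integration of the 2-D active-Brownian-particle (ABP)
#' Langevin equations with internal step \eqn{\delta = 1/(fps \cdot substeps)}:
#' \deqn{\theta \leftarrow \theta + \sqrt{2 D_r \delta}\,\xi_\theta, \quad
#'       x \leftarrow x + v\cos\theta\,\delta + \sqrt{2 D_t \delta}\,\xi_x, \quad
#'       y \leftarrow y + v\sin\theta\,\delta + \sqrt{2 D_t \delta}\,\xi_y}
#' with standard-normal \eqn{\xi}. Positions are recorded every `substeps`-th
#' internal step, i.e. at the camera frame rate. The short-lag ensemble MSD of
#' this process is \eqn{4 D_t t + v^2 t^2}; the full closed form is
#' [msd_abp_theory()].
#'
#' @param v Propulsion speed, µm s⁻¹ (≥ 0).
#' @param D_t Translational diffusion coefficient, µm² s⁻¹ (≥ 0).
#' @param D_r Rotational diffusion coefficient, s⁻¹ (> 0).
#' @param fps Frame rate, s⁻¹ (default 25, a typical optical-microscopy
#'   recording rate for these particles).
#' @param duration_s Recorded duration, s (default 30).
#' @param seed Optional integer seed; identical seed and parameters give a
#'   bit-identical trajectory.
#' @param substeps Internal integration steps per frame (default 10, i.e.
#'   δ = 4 ms at 25 FPS — small enough that per-step advection and heading
#'   decorrelation are tiny relative to the frame-scale displacements).
#' @param x0,y0 Initial position, µm.
#' @param heading0 Initial heading in radians; `NULL` draws uniformly on
#'   `[0, 2π)` so the ensemble is isotropic.
#' @param particle_id Identifier stored in the output.
#' @return A tibble with columns `particle_id`, `frame` (0-based), `t_s`
#'   (starting at 0, spacing `1/fps`), `x_um`, `y_um`, and the ground-truth
#'   `heading` in radians.
#' @export
#' @examples
#' traj <- simulate_abp(v = 2.07, D_t = 0.239, D_r = 0.1792, duration_s = 5, seed = 1)
#' head(traj)
simulate_abp <- function(v, D_t, D_r, fps = 25, duration_s = 30, seed = NULL,
                         substeps = 10, x0 = 0, y0 = 0, heading0 = NULL,
                         particle_id = 1L) {
  check_nonnegative(v, "v")
  check_nonnegative(D_t, "D_t")
  check_positive(D_r, "D_r")
  check_positive(fps, "fps")
  check_positive(duration_s, "duration_s")
  stopifnot(substeps >= 1, substeps == as.integer(substeps))

  n_frames <- floor(duration_s * fps) # frames after frame 0
  n_int <- n_frames * substeps
  delta <- 1 / (fps * substeps)

  with_seed_or_stream(seed, {
    th0 <- if (is.null(heading0)) stats::runif(1, 0, 2 * pi) else heading0
    # theta has no positional feedback, so the whole path vectorizes:
    # headings are a Gaussian random walk, positions a cumulative sum.
    dth <- stats::rnorm(n_int, sd = sqrt(2 * D_r * delta))
    theta <- th0 + cumsum(dth)
    theta_prev <- c(th0, theta[-n_int]) # heading at the start of each step
    dx <- v * cos(theta_prev) * delta
    dy <- v * sin(theta_prev) * delta
    if (D_t > 0) {
      sd_t <- sqrt(2 * D_t * delta)
      dx <- dx + stats::rnorm(n_int, sd = sd_t)
      dy <- dy + stats::rnorm(n_int, sd = sd_t)
    }
    keep <- seq.int(substeps, n_int, by = substeps)
    tibble::tibble(
      particle_id = particle_id,
      frame = 0:n_frames,
      t_s = (0:n_frames) / fps,
      x_um = x0 + c(0, cumsum(dx)[keep]),
      y_um = y0 + c(0, cumsum(dy)[keep]),
      heading = c(th0, theta[keep])
    )
  })
}

#' Simulate an ensemble of independent ABP trajectories
#'
#' @inheritParams simulate_abp
#' @param n_particles Number of independent particles.
#' @param seed Optional master seed; particle `i` uses `seed + i - 1` so
#'   ensembles are reproducible and extendable.
#' @param x0,y0 Either scalars (shared origin) or length-`n_particles`
#'   vectors of per-particle origins, µm.
#' @return A long tibble of all trajectories (one row per particle per frame).
#' @export
simulate_ensemble <- function(n_particles, v, D_t, D_r, fps = 25,
                              duration_s = 30, seed = NULL, substeps = 10,
                              x0 = 0, y0 = 0) {
  stopifnot(n_particles >= 1)
  x0 <- rep_len(x0, n_particles)
  y0 <- rep_len(y0, n_particles)
  purrr::map_dfr(seq_len(n_particles), function(i) {
    simulate_abp(
      v = v, D_t = D_t, D_r = D_r, fps = fps, duration_s = duration_s,
      seed = if (is.null(seed)) NULL else seed + i - 1L,
      substeps = substeps, x0 = x0[i], y0 = y0[i], particle_id = i
    )
  })
}

#' Add localization noise to trajectories
#'
#' Adds i.i.d. Gaussian offsets of standard deviation `sigma_um` to `x_um`
#' and `y_um`, emulating finite localization precision of the tracking step.
#' A noise level σ inflates every MSD value by an additive plateau of 4σ².
#'
#' @param traj Trajectory tibble (any number of particles).
#' @param sigma_um Localization standard deviation per coordinate, µm (≥ 0;
#'   0 returns the input unchanged).
#' @param seed Optional integer seed.
#' @return The trajectory tibble with perturbed coordinates.
#' @export
add_localization_noise <- function(traj, sigma_um, seed = NULL) {
  check_nonnegative(sigma_um, "sigma_um")
  if (sigma_um == 0) {
    return(traj)
  }
  n <- nrow(traj)
  with_seed_or_stream(seed, {
    traj$x_um <- traj$x_um + stats::rnorm(n, sd = sigma_um)
    traj$y_um <- traj$y_um + stats::rnorm(n, sd = sigma_um)
    traj
  })
}
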