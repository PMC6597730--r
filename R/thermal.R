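#' Thermal and geometric parameters of a diffusing microsphere
#'
#' Bundles the quantities entering the Stokes–Einstein relations: particle
#' radius, absolute temperature and solvent viscosity, plus the Boltzmann
#' constant. Defaults describe a 1.00 µm-radius silica sphere in a water-like
#' medium at 24 °C (viscosity 0.9107×10⁻³ kg m⁻¹ s⁻¹).
#'
#' @param radius_um Particle radius in µm.
#' @param temperature_K Absolute temperature in K (24 °C = 297.15 K).
#' @param viscosity Dynamic viscosity of the solvent in kg m⁻¹ s⁻¹.
#' @return An object of class `thermal_params`.
#' @export
#' @examples
#' tp <- thermal_params()
#' rotational_diffusion(tp)
thermal_params <- function(radius_um = 1.00,
                           temperature_K = 297.15,
                           viscosity = 0.9107e-3) {
  check_positive(radius_um, "radius_um")
  check_positive(temperature_K, "temperature_K")
  check_positive(viscosity, "viscosity")
  structure(
    list(
      radius_um = radius_um,
      temperature_K = temperature_K,
      viscosity = viscosity,
      boltzmann_k = 1.380649e-23 # J/K, exact SI value
    ),
    class = "thermal_params"
  )
}

#' @export
print.thermal_params <- function(x, ...) {
  cat("<thermal_params>\n")
  cat(sprintf("  radius        %.3f um\n", x$radius_um))
  cat(sprintf("  temperature   %.2f K\n", x$temperature_K))
  cat(sprintf("  viscosity     %.4e kg/m/s\n", x$viscosity))
  cat(sprintf("  D_t           %.4f um^2/s\n", translational_diffusion(x)))
  cat(sprintf("  D_r           %.4f 1/s\n", rotational_diffusion(x)))
  invisible(x)
}

#' Stokes–Einstein translational diffusion coefficient
#'
#' \eqn{D_t = k_B T / (6 \pi \eta r)}, returned in µm² s⁻¹. At the default
#' parameters this is ≈ 0.239 µm² s⁻¹.
#'
#' @param tp A [thermal_params()] object.
#' @return Translational diffusion coefficient in µm² s⁻¹.
#' @export
translational_diffusion <- function(tp) {
  stopifnot(inherits(tp, "thermal_params"))
  r_m <- tp$radius_um * 1e-6
  d_m2_s <- tp$boltzmann_k * tp$temperature_K / (6 * pi * tp$viscosity * r_m)
  d_m2_s * 1e12
}

#' Stokes–Einstein rotational diffusion coefficient
#'
#' \eqn{D_r = k_B T / (8 \pi \eta r^3)} in s⁻¹. For a 1.00 µm-radius sphere at
#' 297.15 K in a 0.9107×10⁻³ kg m⁻¹ s⁻¹ solvent this evaluates to 0.1792 s⁻¹.
#'
#' @inheritParams translational_diffusion
#' @return Rotational diffusion coefficient in s⁻¹.
#' @export
rotational_diffusion <- function(tp) {
  stopifnot(inherits(tp, "thermal_params"))
  r_m <- tp$radius_um * 1e-6
  tp$boltzmann_k * tp$temperature_K / (8 * pi * tp$viscosity * r_m^3)
}

#' Rotational diffusion time
#'
#' \eqn{\tau_r = 1 / D_r}: the timescale over which the particle heading
#' decorrelates, and hence the scale that bounds the propulsive fit window.
#' At the default thermal parameters, \eqn{\tau_r \approx 5.579} s.
#'
#' @param D_r Rotational diffusion coefficient in s⁻¹; must be > 0.
#' @return Rotational diffusion time in s.
#' @export
rotational_time <- function(D_r) {
  check_positive(D_r, "D_r")
  1 / D_r
}

#' Rotational scales as a one-row tibble
#'
#' Convenience wrapper deriving both `D_r` and `tau_r` from thermal parameters.
#'
#' @inheritParams translational_diffusion
#' @return A tibble with columns `D_r_per_s` and `tau_r_s` (their product is
#'   exactly 1 by construction).
#' @export
rotational_scale <- function(tp) {
  d_r <- rotational_diffusion(tp)
  tibble::tibble(D_r_per_s = d_r, tau_r_s = rotational_time(d_r))
}

#' Closed-form MSD of an active Brownian particle
#'
#' The exact ensemble MSD of a 2-D particle self-propelling at speed `v` with
#' translational diffusion `D_t` and heading decorrelation `D_r`:
#' \deqn{MSD(t) = 4 D_t t + 2 v^2 \tau_r^2 (t/\tau_r + e^{-t/\tau_r} - 1)}
#' which reduces to \eqn{4 D_t t + v^2 t^2} for \eqn{t \ll \tau_r} (the
#' propulsive regime) and to \eqn{(4 D_t + v^2 \tau_r) t} for
#' \eqn{t \gg \tau_r}.
#'
#' @param lag_s Vector of lag times in s.
#' @param v Propulsion speed in µm s⁻¹.
#' @param D_t Translational diffusion coefficient in µm² s⁻¹.
#' @param D_r Rotational diffusion coefficient in s⁻¹.
#' @return MSD values in µm², one per lag.
#' @export
msd_abp_theory <- function(lag_s, v, D_t, D_r) {
  check_nonnegative(v, "v")
  check_nonnegative(D_t, "D_t")
  check_positive(D_r, "D_r")
  tau <- 1 / D_r
  4 * D_t * lag_s + 2 * v^2 * tau^2 * (lag_s / tau + exp(-lag_s / tau) - 1)
}
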