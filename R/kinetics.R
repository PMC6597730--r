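#' Catalytic rate parameters driving the simulated propulsion
#'
#' A Michaelis–Menten-type rate law extended with competitive inhibition
#' (inhibitor raises the apparent substrate half-saturation) and substrate
#' inhibition (rate declines again at excess substrate through an
#' \eqn{S^2/K_s} term). The relative rate maps linearly to a ground-truth
#' propulsion speed via `speed_coupling`.
#'
#' @param v_rel_max Maximal relative rate (dimensionless, normalized to 1).
#' @param K_m_mM Substrate half-saturation constant, mM.
#' @param K_i_mM Competitive-inhibitor constant, mM (`Inf` disables).
#' @param K_s_mM Substrate-inhibition constant, mM (`Inf` disables; when
#'   finite must be ≥ `K_m_mM`).
#' @param speed_coupling Propulsion speed per unit relative rate, µm s⁻¹.
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' kp <- kinetic_params(K_m_mM = 30, K_s_mM = 400, speed_coupling = 2)
#' relative_rate(30, 0, kp) # half-saturation shifted down by S^2/Ks term
kinetic_params <- function(v_rel_max = 1,
                           K_m_mM,
                           K_i_mM = Inf,
                           K_s_mM = Inf,
                           speed_coupling = 1) {
  check_positive(v_rel_max, "v_rel_max")
  check_positive(K_m_mM, "K_m_mM")
  check_nonnegative(K_i_mM, "K_i_mM", allow_inf = TRUE)
  if (K_i_mM <= 0) abort_domain("`K_i_mM` must be positive (Inf to disable).")
  check_nonnegative(K_s_mM, "K_s_mM", allow_inf = TRUE)
  if (K_s_mM <= 0) abort_domain("`K_s_mM` must be positive (Inf to disable).")
  if (is.finite(K_s_mM) && K_s_mM < K_m_mM) {
    abort_domain("`K_s_mM` must be >= `K_m_mM` when substrate inhibition is enabled.")
  }
  check_nonnegative(speed_coupling, "speed_coupling")
  structure(
    list(
      v_rel_max = v_rel_max, K_m_mM = K_m_mM, K_i_mM = K_i_mM,
      K_s_mM = K_s_mM, speed_coupling = speed_coupling
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf(
    "  v_rel_max %.3g | K_m %.3g mM | K_i %.3g mM | K_s %.3g mM | coupling %.3g um/s\n",
    x$v_rel_max, x$K_m_mM, x$K_i_mM, x$K_s_mM, x$speed_coupling
  ))
  invisible(x)
}

#' Urease-like kinetics preset
#'
#' Illustrative constants for a urease-functionalized micromotor: the peak of
#' the dose–response sits near \eqn{\sqrt{K_m K_s} \approx 110} mM substrate,
#' the maximal propulsion coupling is 2.07 µm s⁻¹, and the competitive
#' inhibitor constant (0.1 mM, the µM-range affinity typical of hydroxamate
#' inhibitors of urease) makes single-digit-mM inhibitor cut the rate by more
#' than half even at excess substrate. These constants are illustrative
#' presets, not fitted to any experimental curve; they only reproduce the
#' qualitative dose–response shapes.
#'
#' @return A [kinetic_params()] object.
#' @export
urease_kinetics <- function() {
  kinetic_params(
    v_rel_max = 1, K_m_mM = 30, K_i_mM = 0.1, K_s_mM = 400,
    speed_coupling = 2.07
  )
}

#' Relative catalytic rate under competitive and substrate inhibition
#'
#' \deqn{rate(S, I) = \frac{v_{max} S}{K_m (1 + I/K_i) + S (1 + S/K_s)}}
#' With `I = 0` and `K_s = Inf` this is exactly Michaelis–Menten. The rate is
#' unimodal in `S` when `K_s` is finite, peaking at
#' \eqn{S^* = \sqrt{K_m K_s (1 + I/K_i)}}, and strictly decreasing in `I` for
#' any `S > 0`.
#'
#' @param S Substrate concentration(s), mM; vectorized.
#' @param I Inhibitor concentration(s), mM; vectorized (recycled against `S`).
#' @param kp A [kinetic_params()] object.
#' @return Relative rate(s) in `[0, v_rel_max]`.
#' @export
relative_rate <- function(S, I = 0, kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(!is.finite(S)) || any(S < 0)) abort_domain("`S` must be finite and >= 0.")
  if (any(!is.finite(I)) || any(I < 0)) abort_domain("`I` must be finite and >= 0.")
  inhib <- if (is.finite(kp$K_i_mM)) 1 + I / kp$K_i_mM else rep(1, length(I))
  sub <- if (is.finite(kp$K_s_mM)) 1 + S / kp$K_s_mM else rep(1, length(S))
  out <- kp$v_rel_max * S / (kp$K_m_mM * inhib + S * sub)
  out[S == 0] <- 0
  out
}

#' Propulsion speed from a relative catalytic rate
#'
#' Linear coupling: `speed = speed_coupling * rate`. Linearity is the
#' generative assumption behind the speed–activity correlation analysis.
#'
#' @param rate Relative rate(s) in `[0, 1]`.
#' @param kp A [kinetic_params()] object.
#' @return Speed(s) in µm s⁻¹.
#' @export
speed_from_rate <- function(rate, kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate > 1)) {
    abort_domain("`rate` must lie in [0, 1].")
  }
  kp$speed_coupling * rate
}

#' Evaluate a dose–response table of rates and ground-truth speeds
#'
#' @param conditions Data frame with columns `substrate_mM` and
#'   `inhibitor_mM`; other columns (e.g. `label`, `n_particles`) pass through.
#' @param kp A [kinetic_params()] object.
#' @return The input as a tibble with `rate` and `true_speed_um_s` appended.
#' @export
#' @examples
#' dose_response(
#'   tibble::tibble(substrate_mM = c(0, 1, 10, 50, 100, 200, 300), inhibitor_mM = 0),
#'   urease_kinetics()
#' )
dose_response <- function(conditions, kp) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1)
  req <- c("substrate_mM", "inhibitor_mM")
  missing <- setdiff(req, names(conditions))
  if (length(missing)) {
    rlang::abort(paste0("`conditions` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(conditions)
  out$rate <- relative_rate(out$substrate_mM, out$inhibitor_mM, kp)
  out$true_speed_um_s <- speed_from_rate(out$rate, kp)
  out
}

#' Simulated enzymatic-activity readout
#'
#' Stands in for a colorimetric activity assay: the relative rate plus
#' multiplicative Gaussian noise with coefficient of variation `cv`
#' (default 5%), truncated at zero.
#'
#' @param rate Relative rate(s).
#' @param cv Coefficient of variation of the readout noise.
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy activity value(s), same length as `rate`.
#' @export
measure_activity <- function(rate, cv = 0.05, seed = NULL) {
  check_nonnegative(cv, "cv")
  with_seed_or_stream(seed, {
    pmax(rate * (1 + stats::rnorm(length(rate), sd = cv)), 0)
  })
}
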