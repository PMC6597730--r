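#' Run an in-silico dose–response sweep
#'
#' Full replication of a motility experiment on synthetic ground truth. For
#' every condition (a substrate/inhibitor pair): the kinetic model sets the
#' true propulsion speed; `n_particles` independent active-Brownian
#' trajectories are simulated at the camera settings; optionally each
#' trajectory is rendered to frames and re-tracked (`mode = "video"`);
#' per-particle MSDs are computed and fitted in the propulsive window; the
#' condition is summarized as mean speed ± s.e.m. with a propulsion call, an
#' ensemble-MSD fit, and a noisy activity readout.
#'
#' Each condition draws its random numbers from [condition_seed()] of the
#' master seed and the condition label, so results are independent of the
#' order in which conditions are listed. A failing condition is reported with
#' `NA` estimates and an `error` message; the remaining conditions still run.
#'
#' @param conditions Data frame with columns `substrate_mM`, `inhibitor_mM`,
#'   and optionally `n_particles` (default 20) and `label` (default built
#'   from the concentrations).
#' @param kinetics A [kinetic_params()] object (default [urease_kinetics()]).
#' @param thermal A [thermal_params()] object; sets `D_t`, `D_r` and the fit
#'   window via `tau_r`.
#' @param fps,duration_s Camera settings (defaults 25 FPS, 30 s).
#' @param n_particles Default particles per condition when the conditions
#'   table has no `n_particles` column (default 20).
#' @param window_frac Propulsive fit window as a fraction of `tau_r`.
#' @param activity_cv Coefficient of variation of the simulated activity
#'   readout (default 0.05).
#' @param localization_sigma_um Localization noise added to trajectories in
#'   `mode = "trajectory"` (µm; default 0 = ideal tracking).
#' @param mode `"trajectory"` fits the simulated coordinates directly;
#'   `"video"` renders each condition to frames, re-detects and re-links, and
#'   fits the tracked coordinates.
#' @param seed Master seed (integer).
#' @param geom A [frame_geometry()] for `mode = "video"`; particles are laid
#'   out on a grid with margins sized to keep them in the field of view.
#' @return A tibble with one row per condition: concentrations, relative
#'   `rate`, `true_speed_um_s`, `activity`, `mean_v_um_s`, `sem_v_um_s`,
#'   ensemble-fit `v_ens_um_s` and `D_t_ens_um2_s`, `n_particles`,
#'   `propulsive`, `p_value`, `seed_used`, `error`.
#' @export
#' @examples
#' \donttest{
#' conditions <- tibble::tibble(substrate_mM = c(0, 100), inhibitor_mM = 0)
#' run_sweep(conditions, seed = 1, duration_s = 10, n_particles = 5)
#' }
run_sweep <- function(conditions,
                      kinetics = urease_kinetics(),
                      thermal = thermal_params(),
                      fps = 25, duration_s = 30, n_particles = 20,
                      window_frac = 0.2, activity_cv = 0.05,
                      localization_sigma_um = 0,
                      mode = c("trajectory", "video"),
                      seed = 1L,
                      geom = NULL) {
  mode <- match.arg(mode)
  tbl <- dose_response(conditions, kinetics)
  if (!"n_particles" %in% names(tbl)) tbl$n_particles <- n_particles
  if (!"label" %in% names(tbl)) {
    tbl$label <- sprintf("S%g_I%g", tbl$substrate_mM, tbl$inhibitor_mM)
  }
  D_t <- translational_diffusion(thermal)
  D_r <- rotational_diffusion(thermal)
  tau_r <- rotational_time(D_r)

  res <- purrr::pmap_dfr(
    list(tbl$label, tbl$true_speed_um_s, tbl$rate, tbl$n_particles),
    function(label, v_true, rate, n_p) {
      s <- condition_seed(seed, label)
      out <- tryCatch(
        {
          est <- run_condition(
            v_true, n_p, D_t, D_r, tau_r, fps, duration_s, window_frac,
            localization_sigma_um, mode, s, geom
          )
          act <- measure_activity(rate, cv = activity_cv, seed = s + 7L)
          dplyr::bind_cols(est, tibble::tibble(activity = act, error = NA_character_))
        },
        error = function(e) {
          warning(sprintf("Condition '%s' failed: %s", label, conditionMessage(e)),
            call. = FALSE
          )
          tibble::tibble(
            mean_v_um_s = NA_real_, sem_v_um_s = NA_real_,
            v_ens_um_s = NA_real_, D_t_ens_um2_s = NA_real_,
            n_tracked = NA_integer_, propulsive = NA, p_value = NA_real_,
            activity = NA_real_, error = conditionMessage(e)
          )
        }
      )
      out$seed_used <- s
      out
    }
  )
  dplyr::bind_cols(tbl, res)
}

run_condition <- function(v_true, n_p, D_t, D_r, tau_r, fps, duration_s,
                          window_frac, loc_sigma, mode, seed, geom) {
  if (mode == "trajectory") {
    trajs <- simulate_ensemble(
      n_p, v_true, D_t, D_r,
      fps = fps, duration_s = duration_s, seed = seed
    )
    if (loc_sigma > 0) {
      trajs <- add_localization_noise(trajs, loc_sigma, seed = seed + 13L)
    }
  } else {
    if (is.null(geom)) {
      # margin sized for the expected excursion of the fastest particle
      margin <- 3 * sqrt(msd_abp_theory(duration_s, max(v_true, 0.5), D_t, D_r))
      side_um <- margin * 2
      geom <- frame_geometry(
        width_px = ceiling(side_um / 0.2), height_px = ceiling(side_um / 0.2),
        pixel_size_um = 0.2, fps = fps
      )
    }
    fov_x <- (geom$width_px - 1) * geom$pixel_size_um
    fov_y <- (geom$height_px - 1) * geom$pixel_size_um
    trajs <- simulate_ensemble(
      n_p, v_true, D_t, D_r,
      fps = fps, duration_s = duration_s, seed = seed,
      x0 = rep(fov_x / 2, n_p), y0 = rep(fov_y / 2, n_p)
    )
    # one particle per stack: motility recordings typically follow one motor
    # at a time, and this keeps spots from colliding in a shared field of view
    trajs <- purrr::map_dfr(split(trajs, trajs$particle_id), function(tr) {
      stack <- render_frames(tr, geom)
      tracked <- track_stack(stack,
        min_track_length = max(2, floor(nrow(tr) / 2))
      )
      if (!nrow(tracked)) rlang::abort("Tracking lost the particle.")
      tracked$particle_id <- tr$particle_id[1]
      tracked
    })
  }
  msd <- compute_msd(trajs, max_lag_s = min(window_frac * tau_r, duration_s / 4))
  per <- fit_particles(msd, tau_r = tau_r, window_frac = window_frac)
  summ <- speed_summary(per)
  ens <- fit_propulsive(ensemble_msd(msd), tau_r = tau_r, window_frac = window_frac)
  tibble::tibble(
    mean_v_um_s = summ$mean_v_um_s, sem_v_um_s = summ$sem_v_um_s,
    v_ens_um_s = ens$v_um_s, D_t_ens_um2_s = ens$D_t_um2_s,
    n_tracked = dplyr::n_distinct(trajs$particle_id),
    propulsive = summ$propulsive, p_value = summ$p_value
  )
}

#' Correlate fitted speed with enzymatic activity
#'
#' Ordinary least squares of condition-mean speed on condition-mean activity,
#' reporting slope, intercept and the adjusted R²
#' \eqn{1 - (1 - R^2)(n - 1)/(n - 2)} for the single-predictor fit.
#'
#' @param table A sweep table (e.g. from [run_sweep()]).
#' @param speed_col,activity_col Column names (strings) of the speed and
#'   activity variables.
#' @return An object of class `speed_activity_fit` (see its `tidy()` and
#'   `glance()` methods).
#' @export
correlate_speed_activity <- function(table, speed_col = "mean_v_um_s",
                                     activity_col = "activity") {
  stopifnot(is.data.frame(table))
  d <- tibble::tibble(
    speed = table[[speed_col]],
    activity = table[[activity_col]]
  )
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) rlang::abort("Need at least 3 conditions with finite speed and activity.")
  if (stats::sd(d$activity) == 0) rlang::abort("Activity has zero variance; correlation undefined.")
  fit <- stats::lm(speed ~ activity, data = d)
  s <- summary(fit)
  structure(
    list(
      slope = stats::coef(fit)[["activity"]],
      intercept = stats::coef(fit)[["(Intercept)"]],
      r_squared = s$r.squared,
      r_squared_adj = s$adj.r.squared,
      n = nrow(d),
      lm = fit, data = d
    ),
    class = "speed_activity_fit"
  )
}

#' @export
print.speed_activity_fit <- function(x, ...) {
  cat("<speed_activity_fit>\n")
  cat(sprintf(
    "  speed = %.4f + %.4f * activity   (n = %d, adj. R^2 = %.4f)\n",
    x$intercept, x$slope, x$n, x$r_squared_adj
  ))
  invisible(x)
}

#' @rdname correlate_speed_activity
#' @param x A `speed_activity_fit`.
#' @param ... Unused.
#' @export
tidy.speed_activity_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = summary(x$lm)$coefficients[, 2]
  )
}

#' @rdname correlate_speed_activity
#' @export
glance.speed_activity_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, r_squared_adj = x$r_squared_adj,
    slope = x$slope, intercept = x$intercept, n = x$n
  )
}

#' Percent speed drop relative to a reference condition
#'
#' \eqn{100 (1 - v / v_{ref})} per condition: the standard way inhibition
#' strength is reported for motility titrations.
#'
#' @param table A sweep table.
#' @param reference Either a row index or a `label` value identifying the
#'   reference condition.
#' @param speed_col Column holding the speeds.
#' @return The table with a `speed_drop_pct` column appended.
#' @export
percent_speed_drop <- function(table, reference = 1L,
                               speed_col = "mean_v_um_s") {
  stopifnot(is.data.frame(table), speed_col %in% names(table))
  ref_row <- if (is.character(reference)) {
    which(table$label == reference)[1]
  } else {
    as.integer(reference)
  }
  if (is.na(ref_row) || ref_row < 1 || ref_row > nrow(table)) {
    rlang::abort("Reference condition not found.")
  }
  v_ref <- table[[speed_col]][ref_row]
  if (!is.finite(v_ref) || v_ref <= 0) {
    rlang::abort("Reference speed must be finite and > 0.")
  }
  table$speed_drop_pct <- 100 * (1 - table[[speed_col]] / v_ref)
  table
}

#' Read a sweep configuration from YAML or JSON
#'
#' The file holds thermal parameters, a kinetics preset or explicit
#' constants, acquisition settings, the master seed, and a `conditions` list
#' of `{substrate_mM, inhibitor_mM, n_particles, label}` entries. Missing
#' entries fall back to the function defaults of [run_sweep()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `conditions` (tibble), `kinetics`,
#'   `thermal`, and `settings` (named list), ready to splice into
#'   [run_sweep()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  conditions <- tibble::as_tibble(dplyr::bind_rows(cfg$conditions))
  kin <- if (is.null(cfg$kinetics)) {
    urease_kinetics()
  } else if (is.character(cfg$kinetics)) {
    switch(cfg$kinetics,
      urease = urease_kinetics(),
      rlang::abort(sprintf("Unknown kinetics preset '%s'.", cfg$kinetics))
    )
  } else {
    do.call(kinetic_params, cfg$kinetics)
  }
  th <- if (is.null(cfg$thermal)) thermal_params() else do.call(thermal_params, cfg$thermal)
  settings <- cfg[setdiff(names(cfg), c("conditions", "kinetics", "thermal"))]
  list(conditions = conditions, kinetics = kin, thermal = th, settings = settings)
}
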