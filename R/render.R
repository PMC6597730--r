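#' Frame-stack geometry and imaging model
#'
#' Describes the synthetic camera: field of view, sampling, point-spread
#' width, and intensity model. Each particle is drawn as an isotropic Gaussian
#' spot of standard deviation `psf_sigma_um` and peak amplitude `amplitude`
#' on a constant `background`; pixel noise is optional. The mapping from
#' sample coordinates to pixels puts the center of the first pixel at
#' (0, 0) µm, with x running along columns and y along rows.
#'
#' The defaults (0.1 µm/px, σ_PSF = 0.3 µm) are stated assumptions for a
#' high-magnification setup, not measured instrument values.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_size_um Pixel pitch, µm per pixel.
#' @param fps Frame rate, s⁻¹.
#' @param psf_sigma_um Gaussian spot standard deviation, µm.
#' @param amplitude Peak spot intensity above background, counts.
#' @param background Constant background level, counts.
#' @param noise `"none"`, `"gaussian"` (additive, sd `noise_sd`) or
#'   `"poisson"` (shot noise on the full intensity).
#' @param noise_sd Standard deviation of Gaussian pixel noise, counts.
#' @return An object of class `frame_geometry`.
#' @export
frame_geometry <- function(width_px = 128, height_px = 128,
                           pixel_size_um = 0.1, fps = 25,
                           psf_sigma_um = 0.3, amplitude = 5000,
                           background = 400,
                           noise = c("none", "gaussian", "poisson"),
                           noise_sd = 20) {
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(fps, "fps")
  check_positive(psf_sigma_um, "psf_sigma_um")
  check_positive(amplitude, "amplitude")
  check_nonnegative(background, "background")
  check_nonnegative(noise_sd, "noise_sd")
  stopifnot(width_px >= 4, height_px >= 4)
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um, fps = fps, psf_sigma_um = psf_sigma_um,
      amplitude = amplitude, background = background,
      noise = match.arg(noise), noise_sd = noise_sd
    ),
    class = "frame_geometry"
  )
}

#' Render trajectories into a microscopy-like frame stack
#'
#' Draws every particle present at each frame as a Gaussian intensity spot
#' (evaluated on a ±4σ window around the particle for speed) and adds the
#' configured pixel noise. Particles outside the field of view trigger one
#' warning and are clipped (only the in-frame part of their spot is drawn).
#'
#' @param trajs Trajectory tibble (columns `particle_id`, `frame`, `x_um`,
#'   `y_um`); all particles must share the frame grid's rate.
#' @param geom A [frame_geometry()].
#' @param seed Optional seed for the pixel noise.
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   `height_px × width_px` matrices, counts) and `geom`.
#' @export
render_frames <- function(trajs, geom, seed = NULL) {
  stopifnot(inherits(geom, "frame_geometry"), is.data.frame(trajs))
  stopifnot(all(c("particle_id", "frame", "x_um", "y_um") %in% names(trajs)))
  frames_idx <- sort(unique(trajs$frame))
  w <- geom$width_px
  h <- geom$height_px
  px <- geom$pixel_size_um
  sig_px <- geom$psf_sigma_um / px
  half <- ceiling(4 * sig_px)
  clipped <- FALSE

  by_frame <- split(trajs, trajs$frame)
  out <- with_seed_or_stream(seed, {
    lapply(frames_idx, function(fi) {
      img <- matrix(geom$background, nrow = h, ncol = w)
      d <- by_frame[[as.character(fi)]]
      for (j in seq_len(nrow(d))) {
        # pixel-center convention: pixel (row 1, col 1) sits at (0, 0) um
        cx <- d$x_um[j] / px + 1
        cy <- d$y_um[j] / px + 1
        if (cx < 1 || cx > w || cy < 1 || cy > h) clipped <<- TRUE
        c_lo <- max(1L, floor(cx - half))
        c_hi <- min(w, ceiling(cx + half))
        r_lo <- max(1L, floor(cy - half))
        r_hi <- min(h, ceiling(cy + half))
        if (c_lo > c_hi || r_lo > r_hi) next # spot entirely outside
        cols <- c_lo:c_hi
        rows <- r_lo:r_hi
        gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
        gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
        img[rows, cols] <- img[rows, cols] + geom$amplitude * outer(gy, gx)
      }
      img <- switch(geom$noise,
        none = img,
        gaussian = img + matrix(stats::rnorm(h * w, sd = geom$noise_sd), h, w),
        poisson = matrix(stats::rpois(h * w, lambda = pmax(img, 0)), h, w)
      )
      pmax(img, 0)
    })
  })
  if (clipped) {
    warning("Some particle positions fall outside the field of view; spots clipped.",
      call. = FALSE
    )
  }
  structure(
    list(frames = out, first_frame = frames_idx[1], geom = geom),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  g <- x$geom
  cat(sprintf(
    "<frame_stack> %d frames, %d x %d px, %.3g um/px, %g fps\n",
    length(x$frames), g$height_px, g$width_px, g$pixel_size_um, g$fps
  ))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit grayscale TIFF pages; acquisition metadata
#' (fps, pixel size, PSF width, intensity scale) goes to a JSON sidecar so a
#' stack can be re-read without loss.
#'
#' @param stack A `frame_stack`.
#' @param tif_path Output TIFF path.
#' @param sidecar_path Output JSON path (default: `tif_path` with `.json`).
#' @return `write_frame_stack()`: the paths, invisibly. `read_frame_stack()`:
#'   a `frame_stack`.
#' @export
write_frame_stack <- function(stack, tif_path,
                              sidecar_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(stack, "frame_stack"))
  top <- max(vapply(stack$frames, max, numeric(1)), 1)
  scale <- max(top, 65535) # counts per full-scale, kept >= 16-bit range
  pages <- lapply(stack$frames, function(f) pmin(f / scale, 1))
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 16)
  g <- stack$geom
  jsonlite::write_json(
    list(
      fps = g$fps, pixel_size_um = g$pixel_size_um,
      psf_sigma_um = g$psf_sigma_um, intensity_scale = scale,
      first_frame = stack$first_frame,
      width_px = g$width_px, height_px = g$height_px
    ),
    sidecar_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(tif = tif_path, json = sidecar_path))
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(tif_path,
                             sidecar_path = sub("\\.tiff?$", ".json", tif_path)) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  frames <- lapply(pages, function(p) p * meta$intensity_scale)
  geom <- frame_geometry(
    width_px = ncol(frames[[1]]), height_px = nrow(frames[[1]]),
    pixel_size_um = meta$pixel_size_um, fps = meta$fps,
    psf_sigma_um = meta$psf_sigma_um
  )
  structure(
    list(frames = frames, first_frame = meta$first_frame %||% 0L, geom = geom),
    class = "frame_stack"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
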