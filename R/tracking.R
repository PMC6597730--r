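#' Detect particle spots in a frame or frame stack
#'
#' Per frame: pixels above `threshold` that are 8-neighborhood local maxima
#' become candidate spots; candidates closer than `min_sep_um` are merged into
#' the brighter one; each survivor is refined to sub-pixel precision by a
#' background-subtracted intensity-weighted centroid over a square window of
#' radius `3 * psf_sigma_um`. The background is the frame median (robust, as
#' spots occupy a small fraction of the field).
#'
#' @param x A `frame_stack` or a single numeric matrix (one frame).
#' @param pixel_size_um Pixel pitch, µm/px; taken from the stack when `x` is
#'   a `frame_stack`.
#' @param threshold Absolute intensity threshold, or `"auto"`: background
#'   median plus 25% of the frame's dynamic range.
#' @param min_sep_um Minimal separation between detections, µm.
#' @param psf_sigma_um Expected spot standard deviation, µm (sets the
#'   centroid window); taken from the stack metadata when available.
#' @return A tibble with columns `frame`, `x_um`, `y_um`, `intensity`
#'   (background-subtracted integrated window intensity). Frames with no
#'   detections contribute no rows.
#' @export
detect_spots <- function(x, pixel_size_um = NULL, threshold = "auto",
                         min_sep_um = 1, psf_sigma_um = NULL) {
  if (inherits(x, "frame_stack")) {
    frames <- x$frames
    frame_ids <- x$first_frame + seq_along(frames) - 1L
    pixel_size_um <- pixel_size_um %||% x$geom$pixel_size_um
    psf_sigma_um <- psf_sigma_um %||% x$geom$psf_sigma_um
  } else if (is.matrix(x)) {
    frames <- list(x)
    frame_ids <- 0L
  } else {
    rlang::abort("`x` must be a frame_stack or a numeric matrix.")
  }
  check_positive(pixel_size_um, "pixel_size_um")
  psf_sigma_um <- psf_sigma_um %||% (3 * pixel_size_um)
  check_positive(psf_sigma_um, "psf_sigma_um")
  check_positive(min_sep_um, "min_sep_um")

  purrr::map2_dfr(frames, frame_ids, function(img, fid) {
    det <- detect_frame(img, pixel_size_um, threshold, min_sep_um, psf_sigma_um)
    if (nrow(det)) det$frame <- fid
    det
  }) |>
    (\(d) if (nrow(d)) dplyr::relocate(d, "frame") else
      tibble::tibble(frame = integer(), x_um = double(), y_um = double(), intensity = double()))()
}

detect_frame <- function(img, px, threshold, min_sep_um, psf_sigma_um) {
  h <- nrow(img)
  w <- ncol(img)
  bg <- stats::median(img)
  thr <- if (identical(threshold, "auto")) {
    bg + 0.25 * (max(img) - bg)
  } else {
    threshold
  }
  empty <- tibble::tibble(x_um = double(), y_um = double(), intensity = double())
  if (max(img) <= thr) {
    return(empty)
  }
  # 8-neighborhood local maxima (interior pixels only), vectorized by shifts
  core <- img[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & core >= img[2:(h - 1) + dr, 2:(w - 1) + dc]
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(empty)
  }
  peaks <- tibble::tibble(
    row = idx[, 1] + 1L, col = idx[, 2] + 1L,
    peak = img[cbind(idx[, 1] + 1L, idx[, 2] + 1L)]
  )
  # merge peaks closer than min_sep into the brighter one
  peaks <- peaks[order(-peaks$peak), ]
  min_sep_px <- min_sep_um / px
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      d2 <- (peaks$row[j] - peaks$row[i])^2 + (peaks$col[j] - peaks$col[i])^2
      keep[j[d2 < min_sep_px^2]] <- FALSE
    }
  }
  peaks <- peaks[keep, ]
  # sub-pixel refinement: background-subtracted intensity-weighted centroid
  win <- ceiling(3 * psf_sigma_um / px)
  res <- purrr::pmap_dfr(peaks, function(row, col, peak) {
    rows <- max(1L, row - win):min(h, row + win)
    cols <- max(1L, col - win):min(w, col + win)
    patch <- pmax(img[rows, cols, drop = FALSE] - bg, 0)
    tot <- sum(patch)
    if (tot <= 0) {
      return(NULL)
    }
    cr <- sum(rowSums(patch) * rows) / tot
    cc <- sum(colSums(patch) * cols) / tot
    tibble::tibble(
      x_um = (cc - 1) * px, y_um = (cr - 1) * px, intensity = tot
    )
  })
  if (is.null(res) || !nrow(res)) empty else res
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment under a maximal per-frame displacement: for each
#' consecutive frame pair, candidate (track, detection) pairs within
#' `max_disp_um * gap` are resolved jointly by minimal total displacement
#' (exact matching on each connected component of the candidate graph; exact
#' cost ties broken deterministically towards the lowest particle id).
#' Unmatched detections start new tracks; a track may vanish for up to
#' `memory` frames, during which its last position persists (gap frames are
#' filled with the last seen position so output sampling stays uniform).
#' Tracks shorter than `min_track_length` frames are dropped.
#'
#' @param dets Detection tibble from [detect_spots()] (columns `frame`,
#'   `x_um`, `y_um`; `intensity` optional).
#' @param fps Frame rate, s⁻¹ (sets the `t_s` column of the output).
#' @param max_disp_um Maximal displacement per frame, µm. The default 0.8
#'   covers the advective step of a ~2 µm s⁻¹ particle at 25 FPS plus five
#'   standard deviations of the per-frame diffusive step at the reference
#'   translational diffusion (0.24 µm² s⁻¹), so genuine links are essentially
#'   never cut while well-separated particles stay unambiguous.
#' @param min_track_length Minimal track length in frames (default 250, i.e.
#'   10 s at 25 FPS, so every kept track supports MSD lags of several
#'   seconds).
#' @param memory Number of consecutive frames a particle may go undetected
#'   without terminating its track (default 0).
#' @return A trajectory tibble (`particle_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`) with `t_s` starting at 0 for each track.
#' @export
link_tracks <- function(dets, fps = 25, max_disp_um = 0.8,
                        min_track_length = 250, memory = 0) {
  stopifnot(is.data.frame(dets), all(c("frame", "x_um", "y_um") %in% names(dets)))
  check_positive(max_disp_um, "max_disp_um")
  stopifnot(min_track_length >= 2, memory >= 0)
  if (!nrow(dets)) {
    return(tibble::tibble(
      particle_id = integer(), frame = integer(), t_s = double(),
      x_um = double(), y_um = double()
    ))
  }
  dets <- dets[order(dets$frame, dets$x_um, dets$y_um), ]
  frames <- sort(unique(dets$frame))
  by_frame <- split(dets, dets$frame)

  # active track state
  tracks <- list() # id -> list(frames, x, y, last_seen)
  next_id <- 1L
  active <- integer()

  for (f in frames) {
    d <- by_frame[[as.character(f)]]
    nd <- nrow(d)
    # drop tracks that have been invisible too long
    if (length(active)) {
      gaps <- f - vapply(tracks[active], function(tr) tr$last_seen, numeric(1))
      active <- active[gaps <= memory + 1]
    }
    assigned_det <- rep(NA_integer_, nd) # det index -> track id
    if (length(active) && nd) {
      last_x <- vapply(tracks[active], function(tr) tr$x[length(tr$x)], numeric(1))
      last_y <- vapply(tracks[active], function(tr) tr$y[length(tr$y)], numeric(1))
      gaps <- f - vapply(tracks[active], function(tr) tr$last_seen, numeric(1))
      cost <- outer(last_x, d$x_um, "-")^2 + outer(last_y, d$y_um, "-")^2
      lim2 <- (max_disp_um * gaps)^2 # per-track allowance grows with the gap
      feas <- sweep(cost, 1, lim2, "<=")
      match <- match_min_cost(cost, feas)
      assigned_det[match$det] <- active[match$track]
      for (k in seq_along(match$det)) {
        id <- active[match$track[k]]
        tr <- tracks[[id]]
        # fill any gap frames by persisting the last seen position
        if (tr$last_seen + 1 <= f - 1) {
          gap_frames <- seq(tr$last_seen + 1, f - 1)
          tr$frames <- c(tr$frames, gap_frames)
          tr$x <- c(tr$x, rep(tr$x[length(tr$x)], length(gap_frames)))
          tr$y <- c(tr$y, rep(tr$y[length(tr$y)], length(gap_frames)))
        }
        tr$frames <- c(tr$frames, f)
        tr$x <- c(tr$x, d$x_um[match$det[k]])
        tr$y <- c(tr$y, d$y_um[match$det[k]])
        tr$last_seen <- f
        tracks[[id]] <- tr
      }
    }
    # unmatched detections start new tracks
    for (j in which(is.na(assigned_det))) {
      tracks[[next_id]] <- list(
        frames = f, x = d$x_um[j], y = d$y_um[j], last_seen = f
      )
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }

  kept <- purrr::keep(seq_along(tracks), function(id) {
    length(tracks[[id]]$frames) >= min_track_length
  })
  purrr::map_dfr(seq_along(kept), function(i) {
    tr <- tracks[[kept[i]]]
    tibble::tibble(
      particle_id = i,
      frame = as.integer(tr$frames),
      t_s = (tr$frames - tr$frames[1]) / fps,
      x_um = tr$x, y_um = tr$y
    )
  })
}

# Minimal-total-cost bipartite matching restricted to feasible pairs.
# Exact (exhaustive over assignments) on each connected component of the
# candidate graph; components larger than `cap` tracks fall back to greedy
# nearest-neighbour with a warning. Ties resolved towards lower track index.
match_min_cost <- function(cost, feas, cap = 6L) {
  nt <- nrow(cost)
  nd <- ncol(cost)
  out_track <- integer()
  out_det <- integer()
  if (!any(feas)) {
    return(list(track = out_track, det = out_det))
  }
  # connected components over the bipartite candidate graph
  comp_t <- rep(0L, nt)
  comp_d <- rep(0L, nd)
  cid <- 0L
  for (s in seq_len(nt)) {
    if (comp_t[s] != 0L || !any(feas[s, ])) next
    cid <- cid + 1L
    qt <- s
    while (length(qt)) {
      t0 <- qt[1]
      qt <- qt[-1]
      if (comp_t[t0] != 0L) next
      comp_t[t0] <- cid
      for (dd in which(feas[t0, ] & comp_d == 0L)) {
        comp_d[dd] <- cid
        qt <- c(qt, which(feas[, dd] & comp_t == 0L))
      }
    }
  }
  for (cc in seq_len(cid)) {
    ts <- which(comp_t == cc)
    ds <- which(comp_d == cc)
    if (length(ts) == 1L && length(ds) == 1L) {
      out_track <- c(out_track, ts)
      out_det <- c(out_det, ds)
      next
    }
    if (length(ts) > cap) {
      warning("Dense detection cluster: falling back to greedy linking.", call. = FALSE)
      sub <- greedy_match(cost[ts, ds, drop = FALSE], feas[ts, ds, drop = FALSE])
    } else {
      sub <- exact_match(cost[ts, ds, drop = FALSE], feas[ts, ds, drop = FALSE])
    }
    out_track <- c(out_track, ts[sub$track])
    out_det <- c(out_det, ds[sub$det])
  }
  list(track = out_track, det = out_det)
}

# exhaustive search over feasible partial assignments, maximizing the number
# of matches first and minimizing total cost second
exact_match <- function(cost, feas) {
  nt <- nrow(cost)
  nd <- ncol(cost)
  best <- list(n = -1L, cost = Inf, track = integer(), det = integer())
  rec <- function(t0, used_d, track, det, acc) {
    if (t0 > nt) {
      n <- length(track)
      if (n > best$n || (n == best$n && acc < best$cost - 1e-15)) {
        best <<- list(n = n, cost = acc, track = track, det = det)
      }
      return(invisible())
    }
    # option: leave track t0 unmatched
    rec(t0 + 1L, used_d, track, det, acc)
    for (dd in which(feas[t0, ] & !used_d)) {
      u <- used_d
      u[dd] <- TRUE
      rec(t0 + 1L, u, c(track, t0), c(det, dd), acc + cost[t0, dd])
    }
  }
  rec(1L, rep(FALSE, nd), integer(), integer(), 0)
  best[c("track", "det")]
}

greedy_match <- function(cost, feas) {
  work <- cost
  work[!feas] <- Inf
  track <- integer()
  det <- integer()
  while (any(is.finite(work))) {
    k <- which(work == min(work), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ] # tie -> lowest indices
    track <- c(track, k[1])
    det <- c(det, k[2])
    work[k[1], ] <- Inf
    work[, k[2]] <- Inf
  }
  list(track = track, det = det)
}

#' Track a rendered stack end to end
#'
#' Convenience wrapper: [detect_spots()] then [link_tracks()] with the
#' stack's own metadata.
#'
#' @param stack A `frame_stack`.
#' @param threshold,min_sep_um Passed to [detect_spots()].
#' @param max_disp_um,min_track_length,memory Passed to [link_tracks()].
#' @return A trajectory tibble.
#' @export
track_stack <- function(stack, threshold = "auto", min_sep_um = 1,
                        max_disp_um = 0.8, min_track_length = 250,
                        memory = 0) {
  dets <- detect_spots(stack,
    threshold = threshold, min_sep_um = min_sep_um
  )
  link_tracks(dets,
    fps = stack$geom$fps, max_disp_um = max_disp_um,
    min_track_length = min_track_length, memory = memory
  )
}
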