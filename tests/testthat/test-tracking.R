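geom_small <- function(psf_sigma_um = 0.3) {
  frame_geometry(
    width_px = 48, height_px = 48, pixel_size_um = 0.1,
    psf_sigma_um = psf_sigma_um
  )
}

# place a particle at fractional pixel (col, row); pixel (1,1) sits at (0,0) um
px_traj <- function(col, row, frame = 0, id = 1L, pixel_size = 0.1) {
  tibble::tibble(
    particle_id = id, frame = frame,
    x_um = (col - 1) * pixel_size, y_um = (row - 1) * pixel_size
  )
}

test_that("blank frames yield an empty detection table", {
  blank <- matrix(100, 32, 32)
  det <- detect_spots(blank, pixel_size_um = 0.1, threshold = 150)
  expect_equal(nrow(det), 0)
  expect_named(det, c("frame", "x_um", "y_um", "intensity"))
})

test_that("a noiseless Gaussian spot is localized to better than 0.05 px", {
  # PSF narrow enough that the centroid window stays inside the frame: the
  # intensity-weighted centroid is only unbiased for an untruncated spot
  g <- geom_small(psf_sigma_um = 0.15)
  truth <- px_traj(12.30, 7.70)
  st <- render_frames(truth, g)
  det <- detect_spots(st)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - truth$x_um) / 0.1, 0.05)
  expect_lt(abs(det$y_um - truth$y_um) / 0.1, 0.05)
  # sweep sub-pixel phases
  for (off in c(0.25, 0.5, 0.75)) {
    truth <- px_traj(20 + off, 15 + 1 - off)
    det <- detect_spots(render_frames(truth, g))
    expect_lt(abs(det$x_um - truth$x_um) / 0.1, 0.05)
    expect_lt(abs(det$y_um - truth$y_um) / 0.1, 0.05)
  }
})

test_that("close spots merge to the brighter one; distant spots stay separate", {
  g <- geom_small()
  close_pair <- dplyr::bind_rows(px_traj(20, 20), px_traj(23, 20, id = 2L))
  det <- detect_spots(render_frames(close_pair, g), min_sep_um = 1)
  expect_equal(nrow(det), 1)
  far_pair <- dplyr::bind_rows(px_traj(10, 10), px_traj(40, 40, id = 2L))
  det2 <- detect_spots(render_frames(far_pair, g), min_sep_um = 1)
  expect_equal(nrow(det2), 2)
})

test_that("a particle present in every frame links into one full trajectory", {
  dets <- tibble::tibble(
    frame = 0:19, x_um = 2 + 0.05 * (0:19), y_um = 3, intensity = 1
  )
  tr <- link_tracks(dets, fps = 25, max_disp_um = 0.3, min_track_length = 10)
  expect_equal(length(unique(tr$particle_id)), 1)
  expect_equal(nrow(tr), 20)
  expect_equal(tr$t_s, (0:19) / 25)
})

test_that("a single missed frame is bridged by memory", {
  dets <- tibble::tibble(
    frame = c(0:8, 10:19), x_um = 2 + 0.02 * c(0:8, 10:19), y_um = 1, intensity = 1
  )
  broken <- link_tracks(dets, fps = 25, max_disp_um = 0.3, min_track_length = 5, memory = 0)
  expect_equal(length(unique(broken$particle_id)), 2)
  bridged <- link_tracks(dets, fps = 25, max_disp_um = 0.3, min_track_length = 5, memory = 1)
  expect_equal(length(unique(bridged$particle_id)), 1)
  expect_equal(nrow(bridged), 20) # gap frame filled by persistence
  expect_equal(bridged$x_um[bridged$frame == 9], 2 + 0.02 * 8)
})

test_that("linking is invariant to detection row order", {
  set.seed(8)
  m <- ref_motion()
  truth <- dplyr::bind_rows(
    simulate_abp(1, m$D_t, m$D_r, duration_s = 2, seed = 1, x0 = 0, particle_id = 1L),
    simulate_abp(1, m$D_t, m$D_r, duration_s = 2, seed = 2, x0 = 30, particle_id = 2L)
  )
  dets <- dplyr::transmute(truth, frame, x_um, y_um, intensity = 1)
  shuffled <- dets[sample(nrow(dets)), ]
  a <- link_tracks(dets, fps = 25, min_track_length = 10)
  b <- link_tracks(shuffled, fps = 25, min_track_length = 10)
  expect_equal(
    dplyr::arrange(a, particle_id, frame),
    dplyr::arrange(b, particle_id, frame)
  )
})

test_that("well-separated rendered particles are tracked with no swaps and sub-pixel accuracy", {
  m <- ref_motion()
  g <- frame_geometry(
    width_px = 160, height_px = 160, pixel_size_um = 0.2,
    fps = 25, psf_sigma_um = 0.3
  )
  truth <- dplyr::bind_rows(
    simulate_abp(0.8, m$D_t, m$D_r, duration_s = 6, seed = 11, x0 = 9, y0 = 9, particle_id = 1L),
    simulate_abp(0.8, m$D_t, m$D_r, duration_s = 6, seed = 12, x0 = 23, y0 = 23, particle_id = 2L)
  )
  st <- render_frames(truth, g)
  tracked <- track_stack(st, min_track_length = 100)
  expect_equal(length(unique(tracked$particle_id)), 2)
  # full recall: every frame of both particles recovered
  expect_equal(nrow(tracked), nrow(truth))
  # match tracked ids to ground truth by first position, then check RMS and swaps
  for (tid in unique(tracked$particle_id)) {
    tk <- dplyr::filter(tracked, particle_id == tid)
    first <- tk[tk$frame == min(tk$frame), ]
    true_id <- truth$particle_id[which.min(
      (truth$x_um - first$x_um)^2 + (truth$y_um - first$y_um)^2
    )]
    tru <- dplyr::filter(truth, particle_id == true_id)
    j <- dplyr::inner_join(tk, tru, by = "frame", suffix = c("", "_true"))
    expect_equal(nrow(j), nrow(tru)) # no identity swaps mid-track
    rms_px <- sqrt(mean(
      (j$x_um - j$x_um_true)^2 + (j$y_um - j$y_um_true)^2
    )) / g$pixel_size_um
    expect_lt(rms_px, 0.05)
  }
})
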