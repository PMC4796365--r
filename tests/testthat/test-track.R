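geom_px1 <- channel_geometry(7, 2, 15, 50, 1)

mk_masks <- function(offsets, shape = c(20, 100)) {
  lapply(offsets, function(o) {
    cell <- matrix(FALSE, shape[1], shape[2]); cell[6:15, (11:30) + o] <- TRUE
    nuc <- matrix(FALSE, shape[1], shape[2]); nuc[8:13, (16:25) + o] <- TRUE
    list(cell = cell, nuc = nuc)
  })
}

test_that("translation moves the centre of mass by exactly the pixel shift", {
  tr <- build_track(mk_masks(c(0, 2)), geom_px1, frame_interval_min = 2)
  expect_equal(diff(tr$cell_com_x_um), 2)      # 2 px at 1 um/px
  expect_equal(diff(tr$nuc_com_x_um), 2)
  v <- instantaneous_velocity(tr, 2, geom_px1)
  expect_equal(v[2], 1)                         # 2 um / 2 min
})

test_that("static masks give zero velocity and reversals give negative values", {
  tr0 <- build_track(mk_masks(c(0, 0, 0)), geom_px1, 2)
  expect_equal(instantaneous_velocity(tr0, 2, geom_px1)[-1], c(0, 0))
  trr <- build_track(mk_masks(c(10, 6, 2)), geom_px1, 2)
  expect_true(all(instantaneous_velocity(trr, 2, geom_px1)[-1] < 0))
})

test_that("front and back edges are mask extremes along the migration direction", {
  tr <- build_track(mk_masks(c(0, 0)), geom_px1, 2)
  expect_equal(tr$cell_front_x_um[1], 30 - 0.5)
  expect_equal(tr$cell_back_x_um[1], 11 - 0.5)
  g_rev <- channel_geometry(7, 2, 15, 50, 1, migration_direction = -1)
  tr2 <- build_track(mk_masks(c(0, 0)), g_rev, 2)
  expect_equal(tr2$cell_front_x_um[1], 11 - 0.5)
})

test_that("too few valid frames raise TrackTooShort", {
  expect_error(build_track(list(NULL, NULL, mk_masks(0)[[1]]), geom_px1, 2),
               class = "TrackTooShort")
})

test_that("displacements telescope to the net displacement", {
  offs <- c(0, 3, 5, 6, 10, 12)
  tr <- build_track(mk_masks(offs), geom_px1, 2)
  v <- instantaneous_velocity(tr, 2, geom_px1)
  expect_equal(sum(v, na.rm = TRUE) * 2,
               tr$cell_com_x_um[length(offs)] - tr$cell_com_x_um[1])
})

test_that("velocity depends only on masks, not intensity offsets", {
  masks <- mk_masks(c(0, 2, 5))
  frames1 <- lapply(1:3, function(k) list(actin = matrix(10, 20, 100),
                                          dna = matrix(10, 20, 100)))
  frames2 <- lapply(1:3, function(k) list(actin = matrix(99, 20, 100),
                                          dna = matrix(10, 20, 100)))
  t1 <- build_track(masks, geom_px1, 2, frames = frames1)
  t2 <- build_track(masks, geom_px1, 2, frames = frames2)
  expect_equal(instantaneous_velocity(t1, 2, geom_px1),
               instantaneous_velocity(t2, 2, geom_px1))
})

test_that("normalized velocity variation reproduces hand arithmetic", {
  # nucleus walks toward and through the constriction at constant speed,
  # then the in-constriction speed drops to 59% of baseline
  pos <- c(10, 18, 26, 34, 42, 46.72, 51.44, 56.16, 60.88, 68.88)
  masks <- lapply(pos, function(p) {
    cell <- matrix(FALSE, 20, 150)
    cols <- pmax(1, round(p) - 10):pmin(150, round(p) + 10)
    cell[4:17, cols] <- TRUE
    nuc <- matrix(FALSE, 20, 150)
    nc <- pmax(1, round(p) - 3):pmin(150, round(p) + 3)
    nuc[8:13, nc] <- TRUE
    list(cell = cell, nuc = nuc)
  })
  tr <- build_track(masks, geom_px1, 2)
  tr$nuc_int_com_x_um <- pos                     # exact positions
  tr$nuc_front_x_um <- pos + 3.5
  tr$nuc_back_x_um <- pos - 3.5
  nvv <- normalized_velocity_variation(tr, geom_px1, 2)
  expect_equal(nvv$v_pre, 4, tolerance = 1e-9)
  expect_equal(mean(nvv$series, na.rm = TRUE), (2.36 - 4) / 4, tolerance = 1e-9)
  # constant speed -> 0 everywhere; doubled speed -> +1
  tr2 <- tr
  tr2$nuc_int_com_x_um <- seq(10, by = 8, length.out = 10)
  tr2$nuc_front_x_um <- tr2$nuc_int_com_x_um + 3.5
  tr2$nuc_back_x_um <- tr2$nuc_int_com_x_um - 3.5
  nvv2 <- normalized_velocity_variation(tr2, geom_px1, 2)
  expect_true(all(abs(stats::na.omit(nvv2$series)) < 1e-9))
})

test_that("a missing baseline raises UndefinedBaseline", {
  pos <- c(50, 55, 60)                           # starts already engaged
  masks <- mk_masks(rep(0, 3))
  tr <- build_track(masks, geom_px1, 2)
  tr$nuc_front_x_um <- pos + 3; tr$nuc_back_x_um <- pos - 3
  tr$nuc_int_com_x_um <- pos
  expect_error(normalized_velocity_variation(tr, geom_px1, 2),
               class = "UndefinedBaseline")
})

test_that("tracked centres on noiseless frames stay within one pixel of truth", {
  cfg <- small_config(2, seed = 31)
  lat <- sample_cohort(cfg, n = 1, outcome = "passed")
  lat$speed_um_min <- 5
  rmv <- render_movie(lat, cfg, noise = FALSE)
  ms <- measure_movie(rmv$movie, cfg$geometry, metrics = character(0))
  tru <- rmv$truth$frames
  # cell centroid: checked while the cell shape is stationary (fully in
  # the wide channel); during the squeeze the thresholded outline
  # deforms asymmetrically and only edge positions stay meaningful
  pl <- constrictr:::constriction_planes(cfg$geometry)
  ok <- !is.na(ms$track$cell_com_x_um) & tru$cell_front_x < pl$entrance
  expect_true(all(abs(ms$track$cell_com_x_um[ok] - tru$cell_com_x[ok]) <=
                    cfg$geometry$pixel_size_um))
  # the DNA-intensity-weighted nuclear centre is accurate everywhere,
  # including deep inside the constriction
  okn <- !is.na(ms$track$nuc_int_com_x_um)
  expect_true(all(abs(ms$track$nuc_int_com_x_um[okn] - tru$nuc_int_com_x[okn]) <=
                    cfg$geometry$pixel_size_um))
})

test_that("zero-slowdown cohorts show no in-constriction velocity change", {
  res <- cached("w3_zero_slowdown",
                run_cohort(small_config(3, seed = 41, slowdown_sd = 0), n = 15,
                           outcome = "passed", metrics = "kinematics"))
  nvv <- res$cells$nvv_mean
  s <- summarize_values(stats::na.omit(nvv))
  expect_lt(abs(s$mean), max(3 * s$sem, 0.02))
})
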