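test_that("the speed law realizes the target truncated moments", {
  cfg <- synth_config(seed = 1)
  m <- constrictr:::truncnorm_moments(cfg$speed_law$mu, cfg$speed_law$sigma,
                                      cfg$speed_floor_um_min)
  expect_equal(unname(m["mean"]), 4.48, tolerance = 1e-4)
  expect_equal(unname(m["sd"]), 3.93, tolerance = 1e-4)
  lat <- sample_cohort(cfg, n = 10000)
  expect_gte(min(lat$speed_um_min), cfg$speed_floor_um_min)
  expect_equal(mean(lat$speed_um_min), 4.48, tolerance = 3 * 3.93 / sqrt(10000) / 4.48)
})

test_that("latent calibration fractions sit inside exact binomial intervals", {
  n <- 10000
  for (W in c(1, 1.5, 3)) {
    cfg <- synth_config(geometry = default_geometry(W), seed = 90 + W * 2)
    lat <- sample_cohort(cfg, n = n)
    p <- constrictr:::lookup_width_map(cfg$passage_prob_by_width, W)
    ci <- stats::binom.test(round(p * n), n)$conf.int
    expect_gte(mean(lat$outcome == "passed"), ci[1])
    expect_lte(mean(lat$outcome == "passed"), ci[2])
  }
  cfg <- synth_config(seed = 97)
  lat <- sample_cohort(cfg, n = n, outcome = "passed")
  ci <- stats::binom.test(round(0.93 * n), n)$conf.int
  expect_gte(mean(lat$enriched), ci[1]); expect_lte(mean(lat$enriched), ci[2])
  # forced outcomes and degenerate probability maps
  expect_true(all(lat$outcome == "passed"))
  cfg1 <- synth_config(seed = 98, passage_prob_by_width = c("2" = 1))
  expect_true(all(sample_cohort(cfg1, n = 500)$outcome == "passed"))
})

test_that("a width missing from the map errors when interpolation is off", {
  cfg <- synth_config(geometry = default_geometry(2.25), seed = 1)
  expect_error(sample_cohort(cfg, n = 5, interpolate = FALSE),
               class = "WidthNotInMap")
  expect_silent(sample_cohort(cfg, n = 5))
})

test_that("the same seed reproduces bitwise-identical movies and latents", {
  cfg <- synth_config(seed = 33, n_frames = 30)
  lat1 <- sample_cohort(cfg, n = 3)
  lat2 <- sample_cohort(cfg, n = 3)
  expect_identical(lat1, lat2)
  m1 <- render_movie(lat1[2, ], cfg)
  m2 <- render_movie(lat2[2, ], cfg)
  expect_identical(m1$movie$data, m2$movie$data)
  expect_identical(m1$truth$events, m2$truth$events)
})

test_that("ground-truth event times are ordered and outcome-consistent", {
  cfg <- small_config(1.5, seed = 44)
  lat <- sample_cohort(cfg, n = 30)
  for (i in seq_len(30)) {
    sched <- constrictr:::cell_schedule(lat[i, ], cfg)
    ev <- sched$events
    ts <- c(ev$t_cell_entry, ev$t_nuc_entry, ev$t_nuc_exit, ev$t_cell_exit)
    expect_true(all(diff(stats::na.omit(ts)) >= -1e-9))
    if (lat$outcome[i] == "passed") expect_false(anyNA(ts))
    else expect_true(is.na(ev$t_cell_exit) && !is.na(ev$t_reversal))
  }
})

test_that("integrated DNA signal is conserved through the squeeze (pre-noise)", {
  cfg <- small_config(1.5, seed = 45)
  lat <- sample_cohort(cfg, n = 1, outcome = "passed")
  lat$speed_um_min <- 5
  rmv <- render_movie(lat, cfg, noise = FALSE)
  bg <- cfg$dna_bg * prod(cfg$image_shape)
  tot <- apply(rmv$movie$data[, , 2, ], 3, sum) - bg
  keep <- rmv$truth$frames$nuc_back_x > 2 &
    rmv$truth$frames$nuc_front_x < 256 * 0.325 - 2
  expect_lt(diff(range(tot[keep])) / stats::median(tot[keep]), 0.02)
})

test_that("the squeezed nucleus stays within the constriction width plus blur", {
  cfg <- small_config(1.5, seed = 46)
  lat <- sample_cohort(cfg, n = 1, outcome = "passed")
  rmv <- render_movie(lat, cfg, noise = FALSE, return_masks = TRUE)
  iv <- constrictr:::constriction_interval(cfg$geometry)
  px <- cfg$geometry$pixel_size_um
  for (k in seq_along(rmv$truth$masks)) {
    nm <- rmv$truth$masks[[k]]$nuc
    xc <- constrictr:::pixel_center_x(cfg$geometry, ncol(nm))
    inside <- xc >= iv[1] & xc < iv[2]
    if (!any(nm[, inside])) next
    thick <- max(colSums(nm[, inside, drop = FALSE])) * px
    expect_lte(thick, cfg$geometry$constriction_width_um + 2 * px)
  }
})

test_that("pre-noise frames are nonnegative and noise is clamped at zero", {
  cfg <- small_config(2, seed = 47)
  lat <- sample_cohort(cfg, n = 1)
  clean <- render_movie(lat, cfg, noise = FALSE)
  expect_gte(min(clean$movie$data), 0)
  noisy <- render_movie(lat, cfg)
  expect_gte(min(noisy$movie$data), 0)
})

test_that("lamina truth: zero probability, spans, and arc-length arithmetic", {
  cfg <- synth_config(seed = 48)
  # 60-degree gap on a circle of diameter 10 um: arc length ~ 5.24 um
  st <- render_lamina_nucleus(5, 5, gap_span_deg = 60, gap_center_deg = 0,
                              config = cfg, noise = FALSE)
  nuc <- st$dna > cfg$dna_bg + cfg$dna_base / 2
  circ <- nuclear_circularity(nuc, cfg$geometry$pixel_size_um)
  prof <- angular_intensity_profile(st$lamina, nuc)
  rp <- detect_rupture(prof, attr(circ, "perimeter_um"))
  expect_equal(rp$rupture_perimeter_um, pi * 10 * 60 / 360, tolerance = 0.1)
  expect_error(render_lamina_panel(cfg, "no_such_condition", 3),
               class = "InvalidConfig")
})

test_that("bead transits obey the width-matching rules", {
  # matched width, accumulation probability 1: ring in every inside frame
  cfg <- synth_config(geometry = default_geometry(3), seed = 49, n_frames = 60,
                      p_peribead_accumulation = 1)
  lat <- sample_cohort(cfg, n = 1, outcome = "passed")
  rb <- render_bead_transit(lat, cfg)
  fr <- rb$truth$frames
  inside <- fr$bead_x >= 42.5 & fr$bead_x < 57.5
  expect_true(all(fr$bead_ring[inside] == 1))
  expect_true(all(fr$bead_ring[!inside] == 0))
  # unmatched (3 um bead, 3.5 um constriction): never a ring
  cfg2 <- synth_config(geometry = default_geometry(3.5), seed = 50,
                       p_peribead_accumulation = 1)
  rb2 <- render_bead_transit(sample_cohort(cfg2, n = 1, outcome = "passed"), cfg2)
  expect_true(all(rb2$truth$frames$bead_ring == 0))
  # oversized bead stalls at the entrance
  cfg3 <- synth_config(geometry = default_geometry(2.5), seed = 51, n_frames = 40)
  rb3 <- render_bead_transit(sample_cohort(cfg3, n = 1, outcome = "passed"), cfg3)
  expect_lt(max(rb3$truth$frames$bead_x), 42.5)
  expect_equal(rb3$truth$events$observed_outcome, "censored")
  # bead wider than the channel is rejected
  cfg4 <- synth_config(geometry = default_geometry(3), seed = 52,
                       bead_diameter_um = 8)
  expect_error(render_bead_transit(sample_cohort(cfg4, n = 1), cfg4),
               class = "BeadTooWide")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(p_enrich_passer = 1.2), class = "InvalidConfig")
  expect_error(synth_config(speed_mean_um_min = -1), class = "InvalidConfig")
  expect_error(synth_config(n_frames = 1), class = "InvalidConfig")
})
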