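geom_ev <- channel_geometry(7, 2, 15, 50, 1)

# Build a track table directly from front/back position vectors.
mk_track <- function(cf, cb, nf, nb, dt = 2) {
  n <- length(cf)
  tr <- data.frame(frame = seq_len(n), t_min = (seq_len(n) - 1) * dt,
                   cell_com_x_um = (cf + cb) / 2, cell_com_y_um = 0,
                   nuc_com_x_um = (nf + nb) / 2, nuc_com_y_um = 0,
                   nuc_int_com_x_um = (nf + nb) / 2,
                   cell_front_x_um = cf, cell_back_x_um = cb,
                   nuc_front_x_um = nf, nuc_back_x_um = nb,
                   cell_area_um2 = 100, nuc_area_um2 = 30,
                   cell_mean_actin = 1, nuc_mean_dna = 1)
  class(tr) <- c("cc_track", "data.frame")
  tr
}

forward <- function(step = 4, n = 25, start = 20) {
  com <- start + step * (seq_len(n) - 1)
  mk_track(com + 10, com - 10, com + 2.5, com - 4.5)
}

test_that("a monotone forward transit yields four ordered times and 'passed'", {
  ev <- classify_passage(forward(), geom_ev)
  expect_equal(ev$outcome, "passed")
  times <- c(ev$t_cell_entry, ev$t_nuc_entry, ev$t_nuc_exit, ev$t_cell_exit)
  expect_true(all(diff(times) >= 0))
  expect_equal(ev$cell_passage_time_min, ev$t_cell_exit - ev$t_cell_entry)
  expect_true(ev$nuclear_entry_flag)
})

test_that("a truncated engagement is censored with no passage time", {
  tr <- forward(n = 8)                      # movie ends mid-constriction
  ev <- classify_passage(tr, geom_ev)
  expect_equal(ev$outcome, "censored")
  expect_true(is.na(ev$cell_passage_time_min))
})

test_that("never reaching the entrance raises NotEncountered", {
  com <- seq(5, 15, length.out = 5)
  tr <- mk_track(com + 10, com - 10, com + 2.5, com - 4.5)
  expect_error(classify_passage(tr, geom_ev), class = "NotEncountered")
})

test_that("retreating cells split into the two reversal classes by nuclear entry", {
  com_in <- c(20, 28, 36, 42, 42, 42, 34, 26, 18, 10)
  tr1 <- mk_track(com_in + 10, com_in - 10, com_in + 2.5, com_in - 4.5)
  ev1 <- classify_passage(tr1, geom_ev)
  expect_equal(ev1$outcome, "reversed_after_nuclear_entry")
  # direction change at the last frame still at the maximum front
  expect_equal(ev1$non_passage_time_min, (6 - 1) * 2 - ev1$t_cell_entry + 0)
  com_no <- c(20, 26, 32, 36, 36, 36, 30, 22, 14, 6)   # nuc front peaks at 38.5 < entrance
  tr2 <- mk_track(com_no + 10, com_no - 10, com_no + 2.5, com_no - 4.5)
  ev2 <- classify_passage(tr2, geom_ev)
  expect_equal(ev2$outcome, "reversed_no_nuclear_entry")
  expect_false(ev2$nuclear_entry_flag)
})

test_that("every encountered non-censored event falls in exactly one class", {
  cohorts <- list(passage_cohort(1.5, 40, 52), passage_cohort(3, 40, 53))
  for (res in cohorts) {
    ev <- res$events
    obs <- ev[!is.na(ev$outcome) & !startsWith(ev$outcome, "error"), ]
    expect_true(all(obs$outcome %in% c("passed", "reversed_after_nuclear_entry",
                                       "reversed_no_nuclear_entry", "censored")))
  }
})

test_that("classifier agrees with generator truth for at least 98% of cells", {
  ev <- rbind(passage_cohort(1.5, 40, 52)$events, passage_cohort(3, 40, 53)$events)
  ok <- !is.na(ev$outcome) & !startsWith(ev$outcome, "error")
  expect_gte(mean(ev$outcome[ok] == ev$truth_outcome[ok]), 0.98)
})

test_that("measured reversal timing matches truth within one frame interval", {
  cfg <- small_config(1.5, seed = 61)
  lat <- sample_cohort(cfg, n = 4, outcome = "reversed_after_nuclear_entry")
  for (i in 1:4) {
    rmv <- render_movie(lat[i, ], cfg)
    ms <- measure_movie(rmv$movie, cfg$geometry, metrics = character(0))
    ev <- ms$event
    tru <- rmv$truth$events
    expect_equal(ev$outcome, "reversed_after_nuclear_entry")
    truth_np <- tru$t_reversal - tru$t_cell_entry
    # entry and turn times are each quantized to the frame grid, so the
    # duration can be off by up to two frame intervals
    expect_lte(abs(ev$non_passage_time_min - truth_np), 2 * cfg$frame_interval_min)
  }
})

test_that("cohort statistics form the paper-style summary", {
  ev <- rbind(
    do.call(rbind, replicate(8, classify_passage(forward(), geom_ev),
                             simplify = FALSE)),
    classify_passage(mk_track(c(20, 28, 36, 42, 42, 42, 34, 26, 18, 10) + 10,
                              c(20, 28, 36, 42, 42, 42, 34, 26, 18, 10) - 10,
                              c(20, 28, 36, 42, 42, 42, 34, 26, 18, 10) + 2.5,
                              c(20, 28, 36, 42, 42, 42, 34, 26, 18, 10) - 4.5),
                     geom_ev),
    classify_passage(forward(n = 8), geom_ev))   # censored
  st <- cohort_passage_stats(ev)
  expect_equal(st$n_encountered, 9)              # censored excluded
  expect_equal(st$n_censored, 1)
  expect_equal(st$percentage_passage, 100 * 8 / 9)
  expect_error(cohort_passage_stats(ev[ev$outcome == "censored", , drop = FALSE]),
               class = "EmptyCohort")
})

test_that("passage percentage is invariant to time offsets", {
  tr <- forward()
  tr_shift <- tr; tr_shift$t_min <- tr$t_min + 100
  expect_equal(classify_passage(tr, geom_ev)$outcome,
               classify_passage(tr_shift, geom_ev)$outcome)
})

test_that("non-passing cells dwell at least as long as passers on average", {
  ev <- rbind(passage_cohort(1.5, 40, 52)$events, passage_cohort(3, 40, 53)$events)
  st <- cohort_passage_stats(ev[!is.na(ev$outcome) & !startsWith(ev$outcome, "error"), ])
  expect_gte(st$non_passage_time$mean, st$cell_passage_time$mean)
})
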