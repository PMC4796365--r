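geom_a <- channel_geometry(7, 2, 10, 50, 1)   # 1 um/px, constriction cols 46..55

test_that("in-constriction normalization reproduces pixel-sum arithmetic", {
  # 100-px cell, 20 px inside the constriction at 30, the other 80 at 5
  cell <- matrix(FALSE, 20, 100)
  cell[6:10, 30:45] <- TRUE                     # 80 px outside
  cell[6:10, 46:49] <- TRUE                     # 20 px inside
  img <- matrix(0, 20, 100)
  img[6:10, 30:45] <- 5; img[6:10, 46:49] <- 30
  expect_equal(normalized_actin_in_constriction(img, cell, geom_a), 3.0,
               tolerance = 1e-12)
  # uniform intensity -> exactly 1
  img2 <- matrix(7, 20, 100)
  expect_equal(normalized_actin_in_constriction(img2, cell, geom_a), 1)
  # cell entirely outside
  cell_out <- matrix(FALSE, 20, 100); cell_out[6:10, 5:20] <- TRUE
  expect_error(normalized_actin_in_constriction(img, cell_out, geom_a),
               class = "CellNotInConstriction")
})

test_that("both normalizations are scale invariant and 1 on uniform cells", {
  cell <- disk_mask(12)
  ctx <- cortex_mask(cell)
  nuc <- matrix(FALSE, nrow(cell), ncol(cell)); nuc[14:20, 14:20] <- TRUE
  pnc <- perinuclear_cortex_mask(ctx, nuc)
  img <- matrix(3.7, nrow(cell), ncol(cell))
  masks <- list(cell = cell, perinuclear_cortex = pnc)
  expect_equal(normalized_perinuclear_actin(img, masks), 1)
  set.seed(2)
  img2 <- matrix(rexp(length(cell)) + 0.1, nrow(cell))
  r1 <- normalized_perinuclear_actin(img2, masks)
  expect_equal(normalized_perinuclear_actin(img2 * 137.2, masks), r1,
               tolerance = 1e-12)
  img0 <- matrix(0, nrow(cell), ncol(cell))
  expect_error(normalized_perinuclear_actin(img0, masks), class = "NaNIntensity")
})

test_that("enrichment flag requires a real excursion above baseline and floor", {
  ev <- data.frame(t_cell_entry = 2, t_nuc_entry = 10, t_nuc_exit = 20,
                   t_cell_exit = 24, non_passage_time_min = NA_real_)
  t <- seq(0, 30, by = 2)
  flat <- rep(1, length(t))
  expect_false(enrichment_flag(flat, t, ev)$flag)
  spike <- flat; spike[t >= 12 & t <= 18] <- 1.8
  expect_true(enrichment_flag(spike, t, ev)$flag)
  # a rise below the absolute floor stays negative
  weak <- flat; weak[t >= 12 & t <= 18] <- 1.15
  expect_false(enrichment_flag(weak, t, ev)$flag)
  # too few baseline frames
  expect_error(enrichment_flag(spike[t >= 8], t[t >= 8], ev),
               class = "UndefinedBaseline")
  ev_no <- ev; ev_no$t_nuc_entry <- NA_real_
  expect_error(enrichment_flag(spike, t, ev_no), class = "UndefinedBaseline")
})

test_that("position profiles bin correctly and report empty bins with n = 0", {
  cells <- list(list(position_um = c(-5, -3, 1, 5), value = c(1, 1, 1, 1)))
  pr <- actin_vs_position_profile(cells, bin_width_um = 2)
  expect_true(all(pr$mean[pr$n > 0] == 1))
  expect_true(any(pr$n == 0))
  expect_true(all(is.na(pr$mean[pr$n == 0])))
  expect_error(actin_vs_position_profile(cells, bin_width_um = 0),
               class = "InvalidParams")
})

test_that("profile peak sits inside the constriction for enriched passers", {
  res <- cached("profile_cells", {
    cfg <- enrichment_config(2, seed = 71)
    lat <- sample_cohort(cfg, n = 6, outcome = "passed")
    lat$enriched <- TRUE
    lapply(seq_len(6), function(i) {
      rmv <- render_movie(lat[i, ], cfg)
      ms <- measure_movie(rmv$movie, cfg$geometry)
      list(position_um = ms$track$nuc_com_x_um - cfg$geometry$constriction_center_x_um,
           value = ms$series$perinuclear)
    })
  })
  pr <- actin_vs_position_profile(res, bin_width_um = 2)
  peak_bin <- pr$bin_center_um[which.max(pr$mean)]
  expect_lte(abs(peak_bin), 15 / 2 + 1)
})

test_that("circularity satisfies the closed-form identities", {
  expect_equal(as.numeric(nuclear_circularity(disk_mask(20))), 1, tolerance = 0.02)
  expect_equal(as.numeric(nuclear_circularity(square_mask(20))), pi / 4,
               tolerance = 0.02)
  line <- matrix(FALSE, 40, 40); line[20, 5:35] <- TRUE
  expect_lt(as.numeric(nuclear_circularity(line)), 0.1)
  # discretization-tolerant isoperimetric bound on assorted masks
  set.seed(4)
  for (r in c(5, 9, 14)) expect_lte(as.numeric(nuclear_circularity(disk_mask(r))), 1.02)
  # border touch warns
  full <- matrix(TRUE, 10, 10)
  expect_warning(nuclear_circularity(full), class = "BorderTouch")
})

test_that("DNA thickness / actin relation recovers constructed correlations", {
  # nucleus inside constriction cols 46..55, thickness varying by column
  ny <- 30
  nuc <- matrix(FALSE, ny, 100)
  thick <- c(9, 8, 7, 6, 5, 4, 3, 2, 2, 2)      # px = um at 1 um/px
  for (j in seq_along(thick)) nuc[15 + seq_len(thick[j]) - ceiling(thick[j] / 2), 45 + j] <- TRUE
  cortex <- matrix(TRUE, ny, 100)
  dna <- matrix(0, ny, 100); dna[nuc] <- 10
  # actin brighter where the nucleus is thinner (anti-correlation)
  actin <- matrix(0, ny, 100)
  for (j in seq_along(thick)) actin[, 45 + j] <- 20 - thick[j]
  geom_w9 <- channel_geometry(12, 9.5, 10, 50, 1)
  rel <- dna_thickness_actin_relation(nuc, dna, actin, cortex, geom_w9)
  expect_lt(rel$fit$slope, 0)
  # uniform actin -> slope ~ 0
  rel0 <- dna_thickness_actin_relation(nuc, dna, matrix(5, ny, 100), cortex, geom_w9)
  expect_equal(rel0$fit$slope, 0, tolerance = 1e-9)
  # nothing thinner than W -> InsufficientColumns
  geom_w1 <- channel_geometry(12, 1.5, 10, 50, 1)
  expect_error(dna_thickness_actin_relation(nuc, dna, actin, cortex, geom_w1),
               class = "InsufficientColumns")
})

test_that("bead annulus normalization is 1 on uniform cells and guards location", {
  cell <- matrix(FALSE, 40, 40); cell[5:35, 5:35] <- TRUE
  lab <- matrix(0L, 40, 40)
  lab[(row(lab) - 20)^2 + (col(lab) - 20)^2 <= 9] <- 1L
  img <- matrix(4, 40, 40)
  expect_equal(actin_around_bead(img, lab, 1L, cell), 1)
  outside <- matrix(0L, 40, 40)
  outside[(row(lab) - 3)^2 + (col(lab) - 3)^2 <= 4] <- 1L
  expect_error(actin_around_bead(img, outside, 1L, cell), class = "BeadOutsideCell")
})
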