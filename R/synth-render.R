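# Synthetic two-channel time-lapse generator.
#
# One cell per movie travels along the channel axis toward +x. Motion is
# piecewise-constant in speed: free speed v up to the moment the nuclear
# front reaches the constriction entrance, v * (1 - slowdown) while the
# nucleus transits, then v again. Non-passing cells advance to a sampled
# penetration depth, dwell at least as long as a matched passing cell
# would take to pass, then reverse at free speed.
#
# The actin channel paints the cell body as a wall-clipped capsule with
# a cortical rim, a rear-pole enrichment, and -- if the cell's
# enrichment flag is set and the nucleus overlaps the constriction -- a
# perinuclear ring. The DNA channel paints the nucleus as an ellipse
# whose transverse extent is clamped by the walls, with the per-column
# integrated intensity conserved so squeezing raises local density.
# Frames are PSF-blurred, then Poisson + Gaussian camera noise is
# applied and negative values clamped to zero.

# ---- latent cohort --------------------------------------------------------

#' Sample per-cell latent parameters for a synthetic cohort
#'
#' Draws, for each cell: a free-migration speed from the truncated-normal
#' speed law, a passage outcome from the width-calibrated passage
#' probability, an actin-enrichment flag conditioned on the outcome, a
#' per-cell slowdown fraction, and the nuisance quantities (penetration
#' depth, dwell factor, start position, per-cell noise seed) that fix the
#' full event schedule. Fully reproducible from the config seed.
#'
#' @param config a [synth_config()].
#' @param n number of cells (defaults to `config$n_cells`).
#' @param outcome optional forced outcome for every cell, one of
#'   `"passed"`, `"reversed_no_nuclear_entry"`,
#'   `"reversed_after_nuclear_entry"` (used to generate conditioned
#'   cohorts, e.g. passers only).
#' @param interpolate allow linear interpolation of the width maps at
#'   widths absent from the calibration tables.
#' @return data.frame of latent parameters, one row per cell.
#' @export
sample_cohort <- function(config, n = config$n_cells, outcome = NULL,
                          interpolate = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$geometry
  W <- g$constriction_width_um
  p_pass <- lookup_width_map(config$passage_prob_by_width, W, interpolate)
  s_mean <- lookup_width_map(config$slowdown_fraction_by_width, W, interpolate)
  set.seed(config$seed)
  speed <- sample_truncnorm(n, config$speed_law$mu, config$speed_law$sigma,
                            config$speed_floor_um_min)
  if (is.null(outcome)) {
    passed <- stats::runif(n) < p_pass
    entry_np <- stats::runif(n) < config$p_entry_given_nonpass
    out <- ifelse(passed, "passed",
                  ifelse(entry_np, "reversed_after_nuclear_entry",
                         "reversed_no_nuclear_entry"))
  } else {
    out <- rep(match.arg(outcome, c("passed", "reversed_no_nuclear_entry",
                                    "reversed_after_nuclear_entry")), n)
  }
  slow <- pmin(0.95, pmax(0, stats::rnorm(n, s_mean, config$slowdown_sd)))
  enrich <- stats::runif(n) < ifelse(out == "passed",
                                     config$p_enrich_passer,
                                     config$p_enrich_nonpasser)
  L <- g$constriction_length_um
  data.frame(
    cell_id = seq_len(n),
    speed_um_min = speed,
    outcome = out,
    slowdown = slow,
    enriched = enrich,
    # nuclear-front penetration depth for reversers that initiate entry,
    # and stopping gap (<= 0) for reversers that do not
    penetration_um = stats::runif(n, 1.5, max(2, 0.6 * L)),
    # no-entry reversers stop short of the entry plane by at least the
    # nuclear-entry resolution delta, so latent classes stay resolvable
    entry_gap_um = stats::runif(n, -2, -0.5),
    dwell_factor = stats::runif(n, 1.0, 1.5),
    start_com_x_um = 10.5 + stats::runif(n, 0, 1.5),
    cell_seed = sample.int(.Machine$integer.max - 1L, n),
    stringsAsFactors = FALSE
  )
}

# ---- event schedule -------------------------------------------------------

# Continuous-time schedule for one cell: breakpoints of the piecewise
# linear com trajectory plus the true event times.
cell_schedule <- function(lat, config) {
  g <- config$geometry
  if (g$migration_direction != 1L)
    cc_stop("UnsupportedGeometry", "the renderer assumes migration toward +x")
  pl <- constriction_planes(g)
  E <- pl$entrance; X <- pl$exit
  lc <- config$cell_half_length_um
  a <- config$nucleus_a_um; o <- config$nucleus_offset_um
  v <- lat$speed_um_min; vs <- v * (1 - lat$slowdown)
  x0 <- lat$start_com_x_um
  com_touch <- E - (o + a)              # nuclear front at the entrance
  t_cell_entry <- (E - lc - x0) / v
  t_touch <- (com_touch - x0) / v
  # matched passing-cell duration from cell entry to cell back exit
  t_pass_ref <- (lc - o - a) / v + (X - E + 2 * a) / vs + (lc + o - a) / v

  seg <- function(t0, x0, v) list(t0 = t0, x0 = x0, v = v)
  segs <- list(seg(0, x0, v))
  ev <- list(t_cell_entry = t_cell_entry, t_nuc_entry = NA_real_,
             t_nuc_exit = NA_real_, t_cell_exit = NA_real_,
             t_reversal = NA_real_)
  if (lat$outcome == "passed") {
    com_nexit <- X - o + a              # nuclear back at the exit
    t_nexit <- t_touch + (com_nexit - com_touch) / vs
    t_cexit <- t_nexit + (X + lc - com_nexit) / v
    t_end <- t_nexit + (X + lc + 2 - com_nexit) / v
    segs <- c(segs, list(seg(t_touch, com_touch, vs), seg(t_nexit, com_nexit, v)))
    ev$t_nuc_entry <- t_touch; ev$t_nuc_exit <- t_nexit; ev$t_cell_exit <- t_cexit
  } else if (lat$outcome == "reversed_after_nuclear_entry") {
    com_stop <- com_touch + lat$penetration_um / 1 # nuclear front at E + P
    t_stop <- t_touch + lat$penetration_um / vs
    t_rev <- t_stop + lat$dwell_factor * t_pass_ref
    com_end <- E - 2 - lc - 2           # cell front 4 um behind the entrance
    t_end <- t_rev + (com_stop - com_end) / v
    segs <- c(segs, list(seg(t_touch, com_touch, vs), seg(t_stop, com_stop, 0),
                         seg(t_rev, com_stop, -v)))
    ev$t_nuc_entry <- t_touch; ev$t_reversal <- t_rev
  } else { # reversed_no_nuclear_entry: stops with nuclear front at E + gap, gap <= 0
    com_stop <- com_touch + lat$entry_gap_um
    t_stop <- (com_stop - x0) / v
    t_rev <- t_stop + lat$dwell_factor * t_pass_ref
    com_end <- E - 2 - lc - 2
    t_end <- t_rev + (com_stop - com_end) / v
    segs <- c(segs, list(seg(t_stop, com_stop, 0), seg(t_rev, com_stop, -v)))
    ev$t_reversal <- t_rev
  }
  list(segments = segs, events = ev, t_end = t_end)
}

# Evaluate the com trajectory at times t; the final segment extrapolates
# (cells keep moving and eventually leave the field of view).
schedule_com <- function(sched, t) {
  t0s <- vapply(sched$segments, `[[`, numeric(1), "t0")
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    k <- max(which(t0s <= t[i] + 1e-12))
    s <- sched$segments[[k]]
    out[i] <- s$x0 + s$v * (t[i] - s$t0)
  }
  out
}

# ---- painting -------------------------------------------------------------

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Wall half-opening (um) for each axial coordinate x. The mouth of the
# constriction tapers linearly over taper_um so the rendered cell
# outline narrows smoothly (as funnel-mouthed devices and the cells
# themselves do), rather than stepping within one pixel.
wall_profile <- function(geometry, x, taper_um = 1.5) {
  iv <- constriction_interval(geometry)
  outside <- pmax(iv[1] - x, x - iv[2], 0)
  w2 <- geometry$constriction_width_um / 2
  d2 <- geometry$channel_width_um / 2
  w2 + (d2 - w2) * pmin(outside / taper_um, 1)
}

# Paints one frame. Returns pre-noise actin/dna images, the truth masks
# (soft coverage >= .5) and per-frame truth positions.
paint_frame <- function(com, lat, config, ring_now, bead = NULL) {
  g <- config$geometry
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  px <- g$pixel_size_um
  xs <- pixel_center_x(g, nx)
  ys <- (seq_len(ny) - 0.5) * px
  y0 <- ny / 2 * px
  dy <- abs(ys - y0)
  R <- min(3.5, g$channel_width_um / 2)
  lc <- config$cell_half_length_um
  a <- config$nucleus_a_um; b <- min(config$nucleus_b_um, g$channel_width_um / 2 - 0.1)
  xn <- com + config$nucleus_offset_um
  wall <- wall_profile(g, xs)

  act <- matrix(config$actin_bg, ny, nx)
  dna <- matrix(config$dna_bg, ny, nx)

  # cell capsule
  ax <- abs(xs - com)
  w <- ifelse(ax <= lc - R, R, sqrt(pmax(R^2 - (ax - (lc - R))^2, 0)))
  w[ax > lc] <- 0
  wclip <- pmin(w, wall)
  jc <- which(wclip > 0)
  cell_mask <- matrix(FALSE, ny, nx)
  if (length(jc)) {
    cov <- clamp01(outer(-dy, wclip[jc], `+`) / px + 0.5)
    body <- config$actin_bg + config$actin_body * cov
    # cortical rim: within rim_t of the transverse or axial boundary
    d_b <- pmin(outer(-dy, wclip[jc], `+`),
                matrix(lc - ax[jc], ny, length(jc), byrow = TRUE))
    rim <- d_b > -px & d_b < 0.65 & cov > 0.2
    # rim intensity tapers with edge coverage: in projection the signal
    # falls off at the membrane rather than stepping
    body[rim] <- config$actin_bg +
      config$actin_body * config$actin_rim_factor * cov[rim]
    rear <- rim & matrix(xs[jc] - com < -(lc - 2.5), ny, length(jc), byrow = TRUE)
    body[rear] <- config$actin_bg +
      config$actin_body * config$actin_rim_factor * config$actin_rear_factor * cov[rear]
    act[, jc] <- body
    cell_mask[, jc] <- cov >= 0.5
  }

  # nucleus: per-column clamped ellipse with conserved integrated DNA
  un <- (xs - xn) / a
  jn <- which(abs(un) < 1)
  nuc_mask <- matrix(FALSE, ny, nx)
  if (length(jn)) {
    h <- b * sqrt(1 - un[jn]^2)
    hclip <- pmin(h, wall[jn])
    dens <- config$dna_base * h / pmax(hclip, 1e-6)
    covn <- clamp01(outer(-dy, hclip, `+`) / px + 0.5)
    dna[, jn] <- config$dna_bg + covn * matrix(dens, ny, length(jn), byrow = TRUE)
    nuc_mask[, jn] <- covn >= 0.5
  }

  # perinuclear actin shell: a band straddling the clipped nuclear
  # boundary (the z-projection of a shell wrapped around the nucleus
  # overlaps the nuclear outline), restricted to the constriction
  # neighbourhood and the channel opening
  if (ring_now && any(nuc_mask)) {
    band <- as.matrix(EBImage::dilate(nuc_mask, EBImage::makeBrush(7, "disc"))) &
      !as.matrix(EBImage::erode(nuc_mask, EBImage::makeBrush(5, "disc")))
    iv <- constriction_interval(g)
    keep_col <- xs >= iv[1] - 1 & xs < iv[2] + 1
    band <- band & matrix(keep_col, ny, nx, byrow = TRUE) &
      (outer(dy, wall + px, `<`))
    act[band] <- config$actin_bg +
      config$enrichment_amplitude * config$actin_body * config$actin_rim_factor
  }

  bead_img <- NULL; bead_mask <- NULL
  if (!is.null(bead)) {
    rb <- bead$diameter_um / 2
    dist <- sqrt(outer((ys - y0)^2, (xs - bead$x)^2, `+`))
    covb <- clamp01((rb - dist) / px + 0.5)
    bead_img <- 1 + 80 * covb
    bead_mask <- covb >= 0.5
    if (isTRUE(bead$ring_now)) {
      bandb <- dist > rb & dist <= rb + 0.9 & outer(dy, wall + px, `<`)
      act[bandb] <- config$actin_bg +
        config$enrichment_amplitude * config$actin_body * config$actin_rim_factor
    }
  }

  # truth centroids of the painted (soft) masks
  cmass <- 2 * wclip; nmass <- rep(0, nx); nmass[jn] <- 2 * pmin(b * sqrt(1 - un[jn]^2), wall[jn])
  list(actin = act, dna = dna, bead = bead_img,
       cell_mask = cell_mask, nuc_mask = nuc_mask, bead_mask = bead_mask,
       truth = list(
         cell_com_x = sum(cmass * xs) / max(sum(cmass), 1e-9),
         nuc_com_x = if (length(jn)) sum(nmass * xs) / sum(nmass) else NA_real_,
         nuc_int_com_x = xn,
         cell_front_x = com + lc, cell_back_x = com - lc,
         nuc_front_x = xn + a, nuc_back_x = xn - a))
}

apply_camera <- function(img, config) {
  img <- gauss_blur(img, config$psf_sigma_um / config$geometry$pixel_size_um)
  n <- length(img)
  noisy <- stats::rpois(n, pmax(img, 0) * config$photon_scale) / config$photon_scale +
    stats::rnorm(n, 0, config$read_noise_sd)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

# ---- movie rendering ------------------------------------------------------

#' Render a synthetic two-channel movie for one cell
#'
#' @param lat one row of [sample_cohort()].
#' @param config a [synth_config()].
#' @param noise apply Poisson + Gaussian camera noise (set `FALSE` for
#'   pre-noise control movies).
#' @param return_masks keep the per-frame ground-truth cell and nucleus
#'   masks (memory heavy; off by default).
#' @param bead optional list `list(diameter_um =, offset_um =)` adding an
#'   internalized rigid bead (see [render_bead_transit()]).
#' @return list with elements `movie` (a movie object, see
#'   [as_movie()]) and `truth` (per-cell events + per-frame truth table).
#' @export
render_movie <- function(lat, config, noise = TRUE, return_masks = FALSE,
                         bead = NULL) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$geometry
  if (2 * config$nucleus_b_um > g$channel_width_um + 1e-9 ||
      2 * min(3.5, g$channel_width_um / 2) > g$channel_width_um + 1e-9)
    cc_stop("CellTooWide", "cell/nucleus transverse extent exceeds the channel width")
  if (!is.null(bead)) {
    if (bead$diameter_um > g$channel_width_um)
      cc_stop("BeadTooWide", "bead diameter exceeds the channel width")
  }
  sched <- cell_schedule(lat, config)
  dt <- config$frame_interval_min
  n_need <- ceiling(sched$t_end / dt) + 3L
  K <- min(config$n_frames, n_need)
  tk <- (seq_len(K) - 1) * dt
  com <- schedule_com(sched, tk)
  pl <- constriction_planes(g)
  iv <- constriction_interval(g)
  a <- config$nucleus_a_um; o <- config$nucleus_offset_um

  # observed-outcome label with the observer's semantics: the outcome
  # counts as resolved only if its resolving event falls on a recorded
  # frame while the relevant edge is still inside the field of view
  lc <- config$cell_half_length_um
  img_len <- config$image_shape[2] * g$pixel_size_um
  ev0 <- sched$events
  # margins of ~2 px cover the outward blur bias of measured edges, so
  # a resolve that only just happens on the final frame counts as
  # unobservable
  censored <- if (lat$outcome == "passed") {
    !any(tk >= ev0$t_cell_exit - 1e-9 & (com - lc) <= img_len - 1)
  } else {
    # reversal resolves when, after the turn, the cell front has
    # retreated 2 um behind the entrance on a recorded frame
    !any(tk >= ev0$t_reversal &
           com + lc <= constriction_planes(g)$entrance - 2 - 0.75)
  }

  # bead kinematics: the bead rides ahead of the nucleus; beads wider
  # than the constriction stall at the entrance and stall the cell too
  bead_x <- NULL
  if (!is.null(bead)) {
    rb <- bead$diameter_um / 2
    bead_x0 <- com + bead$offset_um
    if (bead$diameter_um > g$constriction_width_um + 0.25) {
      x_stall <- iv[1] - rb
      stalled <- bead_x0 >= x_stall
      bead_x <- ifelse(stalled, x_stall, bead_x0)
      com <- bead_x - bead$offset_um          # cell stalls with the bead
      censored <- TRUE
    } else bead_x <- bead_x0
  }

  nc <- if (is.null(bead)) 2L else 3L
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  dat <- array(0, c(ny, nx, nc, K))
  frames <- vector("list", K)
  masks <- if (return_masks) vector("list", K) else NULL
  set.seed(lat$cell_seed)
  match_w <- !is.null(bead) &&
    abs(bead$diameter_um - g$constriction_width_um) <= 0.25
  for (k in seq_len(K)) {
    xn <- com[k] + o
    overlap <- min(xn + a, iv[2]) - max(xn - a, iv[1])
    ring_now <- isTRUE(lat$enriched) && overlap > 0.5 &&
      g$constriction_width_um < config$enrich_max_width_um
    bk <- NULL
    if (!is.null(bead)) {
      inside_b <- bead_x[k] >= iv[1] & bead_x[k] < iv[2]
      bk <- list(diameter_um = bead$diameter_um, x = bead_x[k],
                 ring_now = isTRUE(bead$ring) && match_w && inside_b)
    }
    pf <- paint_frame(com[k], lat, config, ring_now, bead = bk)
    dat[, , 1, k] <- if (noise) apply_camera(pf$actin, config) else
      gauss_blur(pf$actin, config$psf_sigma_um / g$pixel_size_um)
    dat[, , 2, k] <- if (noise) apply_camera(pf$dna, config) else
      gauss_blur(pf$dna, config$psf_sigma_um / g$pixel_size_um)
    if (!is.null(bead))
      dat[, , 3, k] <- if (noise) apply_camera(pf$bead, config) else pf$bead
    frames[[k]] <- c(t_min = tk[k], com_x = com[k],
                     unlist(pf$truth), ring_painted = ring_now,
                     bead_x = if (is.null(bead)) NA_real_ else bead_x[k],
                     bead_ring = if (is.null(bead)) NA else isTRUE(bk$ring_now))
    if (return_masks) masks[[k]] <- list(cell = pf$cell_mask, nuc = pf$nuc_mask,
                                         bead = pf$bead_mask)
  }
  cmap <- if (is.null(bead)) c(actin = 1L, dna = 2L) else c(actin = 1L, dna = 2L, bead = 3L)
  movie <- as_movie(dat, channel_map = cmap,
                    frame_interval_min = dt, pixel_size_um = g$pixel_size_um)
  ev <- sched$events
  truth <- list(
    events = data.frame(
      cell_id = lat$cell_id, outcome = lat$outcome,
      observed_outcome = if (censored) "censored" else lat$outcome,
      speed_um_min = lat$speed_um_min, slowdown = lat$slowdown,
      enriched = lat$enriched,
      t_cell_entry = ev$t_cell_entry, t_nuc_entry = ev$t_nuc_entry,
      t_nuc_exit = ev$t_nuc_exit, t_cell_exit = ev$t_cell_exit,
      t_reversal = ev$t_reversal, stringsAsFactors = FALSE),
    frames = as.data.frame(do.call(rbind, frames)),
    masks = masks)
  list(movie = movie, truth = truth)
}

#' Render a cohort of synthetic movies
#'
#' Convenience wrapper: samples latents and renders each cell's movie.
#' For large cohorts prefer streaming with [render_movie()] per cell.
#'
#' @inheritParams sample_cohort
#' @param ... forwarded to [render_movie()].
#' @return list with `latents` and a list `cells` of render results.
#' @export
simulate_cohort <- function(config, n = config$n_cells, outcome = NULL, ...) {
  lat <- sample_cohort(config, n = n, outcome = outcome)
  cells <- lapply(seq_len(n), function(i) render_movie(lat[i, ], config, ...))
  list(latents = lat, cells = cells)
}

#' Render a synthetic transit of a cell carrying an internalized bead
#'
#' Adds a rigid circular bead (third channel) carried ahead of the
#' nucleus. When the bead diameter matches the constriction width and the
#' bead is inside the constriction, an actin ring is painted around it
#' with probability `p_peribead_accumulation`; beads wider than the
#' constriction stall at the entrance.
#'
#' @param lat one row of [sample_cohort()].
#' @param config a [synth_config()].
#' @param ... forwarded to [render_movie()].
#' @return as [render_movie()]; `truth$events$bead_ring_drawn` records
#'   whether the peribead ring was drawn for this cell.
#' @export
render_bead_transit <- function(lat, config, ...) {
  set.seed(lat$cell_seed + 1L)
  ring <- stats::runif(1) < config$p_peribead_accumulation
  out <- render_movie(lat, config, ...,
                      bead = list(diameter_um = config$bead_diameter_um,
                                  offset_um = 6, ring = ring))
  out$truth$events$bead_ring_drawn <- ring
  out
}
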