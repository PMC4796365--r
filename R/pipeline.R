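# End-to-end measurement: movie -> masks -> track -> event -> metrics.
#
# The measurement chain never sees the generator's ground truth: every
# quantity is recomputed from the rendered frames alone.

#' Pipeline analysis parameters
#'
#' All measurement tunables in one place.
#'
#' @param segment a [segment_params()].
#' @param eps_reversal_um reversal margin (um), see [classify_passage()].
#' @param delta_nuclear_um nuclear-entry threshold (um).
#' @param enrich_k,enrich_floor,min_baseline_frames enrichment-call
#'   parameters, see [enrichment_flag()].
#' @param bin_width_um profile bin width (um).
#' @param alpha,theta_min_deg lamina gap-detection parameters, see
#'   [detect_rupture()].
#' @param tip_cone_deg tip-cone half angle (deg), see [tip_localization()].
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(segment = segment_params(),
                            eps_reversal_um = 2, delta_nuclear_um = 0.5,
                            enrich_k = 2, enrich_floor = 1.2,
                            min_baseline_frames = 3L,
                            bin_width_um = 2,
                            alpha = 0.5, theta_min_deg = 15,
                            tip_cone_deg = 45) {
  structure(list(segment = segment, eps_reversal_um = eps_reversal_um,
                 delta_nuclear_um = delta_nuclear_um, enrich_k = enrich_k,
                 enrich_floor = enrich_floor,
                 min_baseline_frames = as.integer(min_baseline_frames),
                 bin_width_um = bin_width_um, alpha = alpha,
                 theta_min_deg = theta_min_deg, tip_cone_deg = tip_cone_deg),
            class = "pipeline_params")
}

#' Measure one movie blind to any ground truth
#'
#' Segments every frame, builds the track, classifies the passage event
#' and (optionally) computes kinematics and per-frame actin metrics.
#'
#' @param movie a movie object (see [as_movie()]).
#' @param geometry a [channel_geometry()].
#' @param params a [pipeline_params()].
#' @param metrics character subset of `c("kinematics", "actin")`;
#'   event classification always runs.
#' @return list with `track`, `event` (or the classification error),
#'   `kinematics` (baseline speed, mean normalized velocity variation),
#'   `series` (per-frame perinuclear and in-constriction normalized
#'   actin) and `enrichment` (the [enrichment_flag()] call).
#' @export
measure_movie <- function(movie, geometry, params = pipeline_params(),
                          metrics = c("kinematics", "actin")) {
  K <- n_frames(movie)
  masks <- vector("list", K)
  frames <- vector("list", K)
  want_actin <- "actin" %in% metrics
  peri <- rep(NA_real_, K); inc <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    fa <- movie_frame(movie, "actin", k)
    fd <- movie_frame(movie, "dna", k)
    mk <- tryCatch({
      cell <- segment_cell(fa, params$segment)
      # a frame can carry a cell without a detectable nucleus (e.g. the
      # nucleus already left the field); keep the cell-only observation
      nuc <- tryCatch(segment_nucleus(fd, cell, params$segment),
                      constrictr_error = function(e) NULL)
      list(cell = cell, nuc = nuc)
    }, constrictr_error = function(e) NULL)
    masks[k] <- list(mk)   # keep NULL placeholders for failed frames
    frames[[k]] <- list(actin = fa, dna = fd)
    if (want_actin && !is.null(mk)) {
      peri[k] <- tryCatch({
        ctx <- cortex_mask(mk$cell, params$segment)
        pnc <- perinuclear_cortex_mask(ctx, mk$nuc)
        normalized_perinuclear_actin(fa, list(cell = mk$cell, perinuclear_cortex = pnc))
      }, constrictr_error = function(e) NA_real_)
      inc[k] <- tryCatch(
        normalized_actin_in_constriction(fa, mk$cell, geometry),
        constrictr_error = function(e) NA_real_)
    }
  }
  track <- build_track(masks, geometry, movie$frame_interval_min, frames = frames)
  track <- censor_border_clipped(track, masks, geometry)
  event <- tryCatch(
    classify_passage(track, geometry, params$eps_reversal_um, params$delta_nuclear_um),
    constrictr_error = function(e) e)
  kin <- NULL
  if ("kinematics" %in% metrics) {
    v <- instantaneous_velocity(track, movie$frame_interval_min, geometry)
    nvv <- tryCatch(
      normalized_velocity_variation(track, geometry, movie$frame_interval_min),
      constrictr_error = function(e) NULL)
    kin <- list(velocity = v,
                mean_speed_um_min = mean(v, na.rm = TRUE),
                v_pre = if (!is.null(nvv)) nvv$v_pre else NA_real_,
                nvv_series = if (!is.null(nvv)) nvv$series else NULL,
                nvv_mean = if (!is.null(nvv)) nvv$mean else NA_real_)
  }
  enrich <- NULL
  if (want_actin && inherits(event, "passage_event")) {
    enrich <- tryCatch(
      enrichment_flag(peri, track$t_min, event, k = params$enrich_k,
                      floor = params$enrich_floor,
                      min_baseline_frames = params$min_baseline_frames),
      constrictr_error = function(e) e)
  }
  list(track = track, event = event, kinematics = kin,
       series = data.frame(t_min = track$t_min, perinuclear = peri,
                           in_constriction = inc),
       enrichment = enrich)
}

# QC for objects clipped by the axial field-of-view borders: an edge
# position on a clipped side (and the centroid) is biased, but the
# opposite edge remains trustworthy. Invalidate exactly the affected
# fields, per object and per frame.
censor_border_clipped <- function(track, masks, geometry) {
  dirn <- geometry$migration_direction
  for (k in seq_along(masks)) {
    mk <- masks[[k]]
    if (is.null(mk)) next
    nx <- ncol(mk$cell)
    for (obj in c("cell", "nuc")) {
      m <- mk[[obj]]
      if (is.null(m)) next
      lo <- any(m[, 1]); hi <- any(m[, nx])
      if (!lo && !hi) next
      com_cols <- paste0(obj, c("_com_x_um", "_com_y_um"))
      if (obj == "nuc") com_cols <- c(com_cols, "nuc_int_com_x_um")
      track[k, com_cols] <- NA_real_
      track[k, paste0(obj, "_area_um2")] <- NA_real_
      # the clipped side: low columns hold the back for dir +1
      if (lo) track[k, paste0(obj, if (dirn > 0) "_back_x_um" else "_front_x_um")] <- NA_real_
      if (hi) track[k, paste0(obj, if (dirn > 0) "_front_x_um" else "_back_x_um")] <- NA_real_
    }
  }
  track
}

#' Measure a bead-transit movie
#'
#' Segments the cell (actin channel) and the bead (bead channel), tracks
#' the bead centre, and applies the peribead enrichment criterion: the
#' peak normalized annulus intensity while the bead sits inside the
#' constriction against its pre-entry baseline.
#'
#' @param movie movie with `actin`, `dna` and `bead` channels.
#' @param geometry a [channel_geometry()].
#' @param bead_radius_um known bead radius (um).
#' @param params a [pipeline_params()].
#' @return list with the per-frame table (`bead_x_um`, annulus ratio)
#'   and the `flag` call (or `NA` when the baseline is undefined).
#' @export
measure_bead_movie <- function(movie, geometry, bead_radius_um,
                               params = pipeline_params()) {
  K <- n_frames(movie)
  ratio <- rep(NA_real_, K); bx <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    fa <- movie_frame(movie, "actin", k)
    fb <- movie_frame(movie, "bead", k)
    res <- tryCatch({
      cell <- segment_cell(fa, params$segment)
      lab <- segment_beads(fb, bead_radius_um, geometry)
      ctrs <- attr(lab, "centers")
      if (is.null(ctrs) || !nrow(ctrs)) NULL
      else list(r = actin_around_bead(fa, lab, 1L, cell, params$segment),
                x = ctrs[1, 2] * geometry$pixel_size_um - geometry$pixel_size_um / 2)
    }, constrictr_error = function(e) NULL)
    if (!is.null(res)) { ratio[k] <- res$r; bx[k] <- res$x }
  }
  pl <- constriction_planes(geometry)
  dirn <- geometry$migration_direction
  inside <- !is.na(bx) & classify_axial_position(geometry, ifelse(is.na(bx), 0, bx)) == "inside"
  pre <- ratio[!is.na(bx) & dirn * bx < dirn * pl$entrance & !is.na(ratio)]
  win <- ratio[inside & !is.na(ratio)]
  crossed <- any(!is.na(bx) & dirn * bx >= dirn * pl$exit)
  flag <- NA
  if (length(pre) >= params$min_baseline_frames) {
    if (!length(win)) {
      # no in-constriction sample: a bead that never advanced past the
      # entrance showed no accumulation; a fast bead that jumped the
      # constriction between frames is simply unsampled
      flag <- if (crossed) NA else FALSE
    } else {
      peak <- max(win)
      flag <- peak >= mean(pre) + params$enrich_k * stats::sd(pre) &&
        peak >= params$enrich_floor
    }
  }
  list(table = data.frame(t_min = (seq_len(K) - 1) * movie$frame_interval_min,
                          bead_x_um = bx, annulus_ratio = ratio),
       entered = any(inside),
       flag = flag)
}

#' Generate and measure a synthetic cohort, streaming cell by cell
#'
#' The workhorse behind cohort-level validation: draws the latent
#' cohort, renders each movie, runs the blind measurement chain, and
#' returns per-cell results without retaining the movies.
#'
#' @param config a [synth_config()].
#' @param n number of cells.
#' @param outcome optional forced outcome (see [sample_cohort()]).
#' @param metrics forwarded to [measure_movie()].
#' @param bead render bead transits and apply the peribead measurement.
#' @return list with `latents`, `events` (stacked classification rows,
#'   with `cell_id` and truth outcome for agreement checks), and
#'   `cells` (per-cell summary: mean speed, baseline, mean normalized
#'   velocity variation, enrichment flag, bead flag).
#' @export
run_cohort <- function(config, n = config$n_cells, outcome = NULL,
                       metrics = c("kinematics"), bead = FALSE) {
  lat <- sample_cohort(config, n = n, outcome = outcome)
  g <- config$geometry
  events <- vector("list", n)
  cells <- vector("list", n)
  params <- pipeline_params()
  for (i in seq_len(n)) {
    rm_ <- if (bead) render_bead_transit(lat[i, ], config) else render_movie(lat[i, ], config)
    row <- list(cell_id = lat$cell_id[i], truth_outcome = rm_$truth$events$observed_outcome,
                mean_speed_um_min = NA_real_, v_pre = NA_real_, nvv_mean = NA_real_,
                enrich_flag = NA, enrich_peak = NA_real_, bead_flag = NA,
                bead_entered = NA)
    if (bead) {
      mb <- measure_bead_movie(rm_$movie, g, config$bead_diameter_um / 2, params)
      row$bead_flag <- mb$flag; row$bead_entered <- mb$entered
      ev <- data.frame(outcome = NA_character_)
    } else {
      ms <- measure_movie(rm_$movie, g, params, metrics = metrics)
      ev <- if (inherits(ms$event, "passage_event")) ms$event
        else data.frame(outcome = paste0("error:", class(ms$event)[1]))
      if (!is.null(ms$kinematics)) {
        row$mean_speed_um_min <- ms$kinematics$mean_speed_um_min
        row$v_pre <- ms$kinematics$v_pre
        row$nvv_mean <- ms$kinematics$nvv_mean
      }
      if (!is.null(ms$enrichment) && !inherits(ms$enrichment, "condition")) {
        row$enrich_flag <- ms$enrichment$flag
        row$enrich_peak <- ms$enrichment$peak
      }
    }
    ev$cell_id <- lat$cell_id[i]
    ev$truth_outcome <- rm_$truth$events$observed_outcome
    events[[i]] <- ev
    cells[[i]] <- as.data.frame(row)
  }
  evd <- do.call(rbind, lapply(events, function(e) {
    # pad classification-error rows to the full event schema
    tmpl <- data.frame(t_cell_entry = NA_real_, t_nuc_entry = NA_real_,
                       t_nuc_exit = NA_real_, t_cell_exit = NA_real_,
                       outcome = NA_character_, cell_passage_time_min = NA_real_,
                       nuc_passage_time_min = NA_real_, non_passage_time_min = NA_real_,
                       nuclear_entry_flag = NA, cell_id = NA_integer_,
                       truth_outcome = NA_character_, stringsAsFactors = FALSE)
    for (nm in names(e)) tmpl[[nm]] <- e[[nm]]
    tmpl
  }))
  list(latents = lat, events = evd, cells = do.call(rbind, cells))
}
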