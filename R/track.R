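# Mask sequences -> kinematic time series.
#
# One TrackPoint per frame: centre-of-mass and front/back axial edge
# positions of cell and nucleus, areas and mean intensities. "Front" is
# the mask's extreme pixel-centre coordinate in the migration direction,
# "back" the opposite extreme. Failed frames stay as missing rows; no
# interpolation, so every number is traceable to an observed mask.

mask_axial_stats <- function(mask, geometry, weights = NULL) {
  nx <- ncol(mask)
  xc <- pixel_center_x(geometry, nx)
  colmass <- colSums(mask)
  xs <- xc[colmass > 0]
  m <- colmass[colmass > 0]
  dirn <- geometry$migration_direction
  com <- sum(xs * m) / sum(m)
  wcom <- if (!is.null(weights)) {
    wm <- colSums(mask * weights)[colmass > 0]
    sum(xs * wm) / sum(wm)
  } else NA_real_
  list(com_x = com, int_com_x = wcom,
       front_x = if (dirn > 0) max(xs) else min(xs),
       back_x = if (dirn > 0) min(xs) else max(xs))
}

mask_com_y <- function(mask, geometry) {
  ny <- nrow(mask)
  yc <- (seq_len(ny) - 0.5) * geometry$pixel_size_um
  rowmass <- rowSums(mask)
  sum(yc * rowmass) / sum(rowmass)
}

#' Build a kinematic track from per-frame masks
#'
#' @param masks_over_time list (one element per frame) of lists with
#'   logical `cell` and `nuc` masks, or `NULL` for failed frames.
#' @param geometry a [channel_geometry()].
#' @param frame_interval_min acquisition interval (min).
#' @param frames optional list of per-frame intensity images
#'   `list(actin =, dna =)` used for mean intensities and the
#'   DNA-intensity-weighted nuclear centre.
#' @return data.frame with one row per frame (class `cc_track`); failed
#'   frames hold `NA`. Errors with class `TrackTooShort` when fewer than
#'   two frames have valid masks.
#' @export
build_track <- function(masks_over_time, geometry, frame_interval_min,
                        frames = NULL) {
  n <- length(masks_over_time)
  empty <- rep(NA_real_, n)
  tr <- data.frame(
    frame = seq_len(n), t_min = (seq_len(n) - 1) * frame_interval_min,
    cell_com_x_um = empty, cell_com_y_um = empty,
    nuc_com_x_um = empty, nuc_com_y_um = empty, nuc_int_com_x_um = empty,
    cell_front_x_um = empty, cell_back_x_um = empty,
    nuc_front_x_um = empty, nuc_back_x_um = empty,
    cell_area_um2 = empty, nuc_area_um2 = empty,
    cell_mean_actin = empty, nuc_mean_dna = empty)
  px2 <- geometry$pixel_size_um^2
  valid <- 0L
  for (k in seq_len(n)) {
    mk <- masks_over_time[[k]]
    if (is.null(mk) || is.null(mk$cell)) next
    fa <- if (!is.null(frames)) frames[[k]]$actin else NULL
    fd <- if (!is.null(frames)) frames[[k]]$dna else NULL
    cs <- mask_axial_stats(mk$cell, geometry)
    tr$cell_com_x_um[k] <- cs$com_x; tr$cell_front_x_um[k] <- cs$front_x
    tr$cell_back_x_um[k] <- cs$back_x
    tr$cell_com_y_um[k] <- mask_com_y(mk$cell, geometry)
    tr$cell_area_um2[k] <- sum(mk$cell) * px2
    if (!is.null(fa)) tr$cell_mean_actin[k] <- mean(fa[mk$cell])
    if (!is.null(mk$nuc)) {   # nucleus-bearing frames only
      ns <- mask_axial_stats(mk$nuc, geometry, weights = fd)
      tr$nuc_com_x_um[k] <- ns$com_x; tr$nuc_front_x_um[k] <- ns$front_x
      tr$nuc_back_x_um[k] <- ns$back_x; tr$nuc_int_com_x_um[k] <- ns$int_com_x
      tr$nuc_com_y_um[k] <- mask_com_y(mk$nuc, geometry)
      tr$nuc_area_um2[k] <- sum(mk$nuc) * px2
      if (!is.null(fd)) tr$nuc_mean_dna[k] <- mean(fd[mk$nuc])
    }
    valid <- valid + 1L
  }
  if (valid < 2L) cc_stop("TrackTooShort", "fewer than 2 frames with valid masks")
  class(tr) <- c("cc_track", "data.frame")
  tr
}

#' Instantaneous axial velocity series
#'
#' Signed backward-difference velocity along the migration direction,
#' assigned to the later frame (um/min); missing frames propagate `NA`.
#'
#' @param track a [build_track()] result.
#' @param frame_interval_min acquisition interval (min).
#' @param source position column: the cell mask centroid (default), the
#'   nucleus mask centroid, the DNA-intensity-weighted nuclear centre, or
#'   the cell front edge.
#' @param geometry a [channel_geometry()] (migration direction sign).
#' @return numeric vector aligned with track rows (first entry `NA`).
#' @export
instantaneous_velocity <- function(track, frame_interval_min, geometry,
                                   source = c("cell_com", "nuc_com",
                                              "nuc_int_com", "cell_front")) {
  source <- match.arg(source)
  col <- switch(source, cell_com = "cell_com_x_um", nuc_com = "nuc_com_x_um",
                nuc_int_com = "nuc_int_com_x_um", cell_front = "cell_front_x_um")
  x <- track[[col]]
  if (length(x) < 2) cc_stop("TrackTooShort", "need at least 2 track points")
  v <- c(NA_real_, diff(x)) / frame_interval_min * geometry$migration_direction
  v
}

# First frame index at which the nuclear front has reached the
# constriction entrance (half-open convention), or NA.
nucleus_touch_frame <- function(track, geometry) {
  pl <- constriction_planes(geometry)
  dirn <- geometry$migration_direction
  hit <- which(!is.na(track$nuc_front_x_um) &
                 dirn * track$nuc_front_x_um >= dirn * pl$entrance)
  if (length(hit)) hit[1] else NA_integer_
}

#' Normalized velocity variation during constriction transit
#'
#' The baseline is the mean velocity over frames strictly before the
#' first frame at which the nuclear front reaches the constriction
#' entrance. For each later sample the value is
#' `(v_inst - v_pre) / v_pre`, reported only for samples whose whole
#' inter-frame interval has the nucleus engaged in the constriction
#' (nuclear front past the entrance at the earlier frame, nuclear back
#' not yet past the exit at the later frame), so entry/exit straddling
#' samples never dilute the in-constriction estimate.
#'
#' Velocities come from the DNA-intensity-weighted nuclear centre of
#' mass, the position estimate that stays unbiased while cell and
#' nucleus change shape inside the constriction (see the methods
#' vignette); set `source` for the mask-centroid variants.
#'
#' @param track a [build_track()] result.
#' @param geometry a [channel_geometry()].
#' @param frame_interval_min acquisition interval (min).
#' @param source forwarded to [instantaneous_velocity()].
#' @return list with `v_pre` (baseline, um/min), `series` (per-frame
#'   normalized variation, `NA` outside qualifying samples) and
#'   `mean` (mean over qualifying samples). Errors with class
#'   `UndefinedBaseline` when no pre-touch samples exist.
#' @export
normalized_velocity_variation <- function(track, geometry, frame_interval_min,
                                          source = "nuc_int_com") {
  touch <- nucleus_touch_frame(track, geometry)
  if (is.na(touch)) cc_stop("UndefinedBaseline", "nucleus never reached the constriction")
  v <- instantaneous_velocity(track, frame_interval_min, geometry, source = source)
  pre <- v[seq_len(touch - 1L)]
  pre <- pre[!is.na(pre)]
  if (!length(pre)) cc_stop("UndefinedBaseline", "no velocity samples before nuclear touch")
  v_pre <- mean(pre)
  if (!(v_pre > 0)) cc_stop("UndefinedBaseline", "non-positive baseline velocity")
  pl <- constriction_planes(geometry)
  dirn <- geometry$migration_direction
  n <- nrow(track)
  series <- rep(NA_real_, n)
  for (k in 2:n) {
    ok <- !is.na(v[k]) &&
      !is.na(track$nuc_front_x_um[k - 1]) && !is.na(track$nuc_back_x_um[k]) &&
      dirn * track$nuc_front_x_um[k - 1] >= dirn * pl$entrance &&
      dirn * track$nuc_back_x_um[k] < dirn * pl$exit
    if (ok) series[k] <- (v[k] - v_pre) / v_pre
  }
  list(v_pre = v_pre, series = series,
       mean = if (any(!is.na(series))) mean(series, na.rm = TRUE) else NA_real_)
}
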