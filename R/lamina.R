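# Nuclear-lamina ring-gap morphometry on fixed-cell stills.
#
# The lamina stain of an intact nucleus forms a closed band along the
# nuclear boundary. Ruptures appear as angular sectors where the band
# intensity collapses. The band is sampled on a 360-bin angular profile
# about the nuclear centroid; gaps are circular runs of bins below a
# fraction of the median profile intensity.

#' Angular intensity profile along the nuclear boundary band
#'
#' Mean lamina intensity in the boundary band (nucleus dilated once
#' minus eroded once) binned by angle about the nucleus centroid; empty
#' bins are interpolated circularly from their neighbours. Angle 0
#' points toward +x (columns), increasing counter-clockwise.
#'
#' @param lamina_frame intensity matrix.
#' @param nucleus_mask nonempty logical mask not touching the border.
#' @param n_bins number of angular bins.
#' @param params a [segment_params()] (structuring element).
#' @return numeric vector of length `n_bins`; attribute `centroid_px`
#'   holds the (row, col) centroid.
#' @export
angular_intensity_profile <- function(lamina_frame, nucleus_mask, n_bins = 360L,
                                      params = segment_params()) {
  if (!any(nucleus_mask)) cc_stop("EmptyMask", "empty nucleus mask")
  if (any(nucleus_mask[1, ]) || any(nucleus_mask[nrow(nucleus_mask), ]) ||
      any(nucleus_mask[, 1]) || any(nucleus_mask[, ncol(nucleus_mask)]))
    cc_stop("BorderTouch", "nucleus mask touches the image border")
  k <- se_brush(params)
  band <- as.matrix(EBImage::dilate(nucleus_mask, k)) &
    !as.matrix(EBImage::erode(nucleus_mask, k))
  idx <- which(band, arr.ind = TRUE)
  ctr <- colMeans(which(nucleus_mask, arr.ind = TRUE))
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) # dy (rows), dx (cols)
  bin <- 1L + ((floor((ang + pi) / (2 * pi) * n_bins)) %% n_bins)
  vals <- lamina_frame[band]
  prof <- rep(NA_real_, n_bins)
  agg <- tapply(vals, bin, mean)
  prof[as.integer(names(agg))] <- agg
  # circular interpolation of empty bins
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    if (!length(ok)) cc_stop("NoRingSignal", "boundary band produced no samples")
    for (b in which(is.na(prof))) {
      d <- pmin((ok - b) %% n_bins, (b - ok) %% n_bins)
      near <- ok[order(d)[1:min(2, length(ok))]]
      prof[b] <- mean(prof[near])
    }
  }
  # rotate so bin 1 is centred on angle 0 (toward +x)
  prof <- c(prof[(n_bins / 2 + 1):n_bins], prof[1:(n_bins / 2)])
  attr(prof, "centroid_px") <- ctr
  prof
}

#' Detect lamina rupture gaps in an angular profile
#'
#' A gap is a maximal circular run of bins whose intensity falls below
#' `alpha` times the profile median; the ring counts as ruptured when
#' the longest gap spans at least `theta_min_deg`. The rupture perimeter
#' converts angular span to arc length on the nuclear boundary.
#'
#' @param profile angular profile from [angular_intensity_profile()].
#' @param boundary_length_um nuclear boundary length (um), e.g. the
#'   perimeter attribute of [nuclear_circularity()].
#' @param alpha gap threshold as a fraction of the median intensity.
#' @param theta_min_deg minimum span (deg) for a rupture call.
#' @return list (class `lamina_ring_report`): `ruptured`, `gaps`
#'   (data.frame of span and centre angle, deg), `rupture_perimeter_um`,
#'   `angular_profile`, `boundary_length_um`. Errors with class
#'   `NoRingSignal` when the profile median is ~0.
#' @export
detect_rupture <- function(profile, boundary_length_um, alpha = 0.5,
                           theta_min_deg = 15) {
  n <- length(profile)
  med <- stats::median(profile)
  if (!is.finite(med) || med <= 1e-9)
    cc_stop("NoRingSignal", "no ring signal: profile median is ~0")
  low <- profile < alpha * med
  gaps <- data.frame(span_deg = numeric(0), center_deg = numeric(0))
  if (any(low)) {
    if (all(low)) {
      gaps <- data.frame(span_deg = 360, center_deg = 0)
    } else {
      # circular run detection: rotate so position 1 is not low
      shift <- which(!low)[1] - 1L
      lr <- low[((seq_len(n) - 1L + shift) %% n) + 1L]
      r <- rle(lr)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        span <- r$lengths[i] / n * 360
        mid0 <- (starts[i] + ends[i]) / 2          # in rotated coords
        center <- ((mid0 - 0.5 + shift) / n * 360) %% 360
        gaps <- rbind(gaps, data.frame(span_deg = span, center_deg = center))
      }
      gaps <- gaps[gaps$span_deg >= theta_min_deg, , drop = FALSE]
    }
  }
  ruptured <- nrow(gaps) > 0
  structure(list(
    ruptured = ruptured,
    gaps = gaps,
    rupture_perimeter_um = sum(gaps$span_deg) / 360 * boundary_length_um,
    angular_profile = as.numeric(profile),
    boundary_length_um = boundary_length_um,
    alpha = alpha, theta_min_deg = theta_min_deg),
    class = "lamina_ring_report")
}

#' Is the largest rupture gap at the leading nuclear pole?
#'
#' The leading pole is the nucleus boundary point of maximal axial
#' coordinate along the migration direction; the call is positive when
#' the largest gap's centre lies within the tip cone around that pole.
#'
#' @param report a [detect_rupture()] result with `ruptured = TRUE`.
#' @param nucleus_mask logical nucleus mask (defines the leading pole).
#' @param geometry a [channel_geometry()] (migration direction).
#' @param cone_half_angle_deg half-angle of the tip cone (deg).
#' @return logical.
#' @export
tip_localization <- function(report, nucleus_mask, geometry,
                             cone_half_angle_deg = 45) {
  if (!isTRUE(report$ruptured)) cc_stop("NotRuptured", "report carries no gaps")
  idx <- which(nucleus_mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ax <- idx[, 2] * geometry$migration_direction
  lead <- idx[which.max(ax), ]
  pole_deg <- (atan2(lead[1] - ctr[1], lead[2] - ctr[2]) * 180 / pi) %% 360
  g <- report$gaps
  main <- g[which.max(g$span_deg), ]
  d <- abs(((main$center_deg - pole_deg + 180) %% 360) - 180)
  d <= cone_half_angle_deg
}

#' Cohort lamina-rupture statistics
#'
#' @param reports data.frame with columns `condition`, `ruptured`,
#'   `rupture_perimeter_um` and (optionally) `tip_localized`.
#' @return data.frame per condition: n, ruptured fraction, tip-localized
#'   fraction among ruptured, mean rupture perimeter among ruptured.
#' @export
cohort_rupture_stats <- function(reports) {
  if (!nrow(reports)) cc_stop("EmptyCohort", "no reports supplied")
  conds <- unique(reports$condition)
  do.call(rbind, lapply(conds, function(cd) {
    r <- reports[reports$condition == cd, , drop = FALSE]
    rp <- r[r$ruptured, , drop = FALSE]
    data.frame(condition = cd, n = nrow(r),
               ruptured_fraction = mean(r$ruptured),
               tip_localized_fraction = if (nrow(rp) && "tip_localized" %in% names(rp))
                 mean(rp$tip_localized, na.rm = TRUE) else NA_real_,
               mean_rupture_perimeter_um = if (nrow(rp))
                 mean(rp$rupture_perimeter_um) else NA_real_)
  }))
}
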