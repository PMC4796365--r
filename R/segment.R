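# Cell / nucleus / cortex / bead segmentation.
#
# The measurement chain mirrors the assay's mask definitions: the actin
# channel yields the cell mask, the DNA channel the nucleus mask, and
# the cell cortex is the one-time-dilated minus six-times-eroded cell
# mask. Thresholding is Gaussian-smooth + Otsu (parameter free); the
# structuring element is a 3x3 square (8-connected), one iteration per
# erosion/dilation count.

#' Segmentation parameters
#'
#' @param smooth_sigma_px Gaussian pre-smoothing sigma (px).
#' @param min_area_px minimum connected-component area (px).
#' @param dilate_iter,erode_iter cortex-mask iteration counts.
#' @param brush_size structuring-element size (odd; 3 = 3x3 square).
#' @param min_contrast minimum absolute contrast for a frame to be
#'   considered segmentable.
#' @param contrast_mad_ratio robust contrast gate: the smoothed frame's
#'   `max - median` must exceed this multiple of its MAD, otherwise the
#'   frame is treated as containing no object (guards against
#'   segmenting pure camera noise).
#' @param otsu_bins histogram bins for the three-class Otsu threshold.
#' @return list of class `segment_params`.
#' @export
segment_params <- function(smooth_sigma_px = 1, min_area_px = 30,
                           dilate_iter = 1L, erode_iter = 6L,
                           brush_size = 3L, min_contrast = 1e-6,
                           contrast_mad_ratio = 10,
                           otsu_bins = 64L) {
  structure(list(smooth_sigma_px = smooth_sigma_px, min_area_px = min_area_px,
                 dilate_iter = as.integer(dilate_iter),
                 erode_iter = as.integer(erode_iter),
                 brush_size = as.integer(brush_size),
                 min_contrast = min_contrast,
                 contrast_mad_ratio = contrast_mad_ratio,
                 otsu_bins = as.integer(otsu_bins)),
            class = "segment_params")
}

se_brush <- function(params) EBImage::makeBrush(params$brush_size, "box")

# Robust Otsu threshold. The plain two-class threshold is ideal for a
# background/cell image (mask edge at half intensity), but a small very
# bright third mode (perinuclear shell, bead, condensed chromatin) can
# capture it, collapsing the mask onto the bright structure. Compute
# both the two-class threshold and the lowest threshold of the
# three-class criterion; if most foreground mass sits between them, the
# two-class split cut through the cell and the lower threshold is used.
robust_otsu <- function(v, nbins = 128L) {
  r <- range(v)
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE),
                nbins)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  W <- cumsum(h); M <- cumsum(h * mids); S2 <- cumsum(h * mids^2)
  tot <- W[nbins]; mt <- M[nbins]
  # two-class Otsu
  w0 <- W[-nbins]; m0 <- M[-nbins]
  w1 <- tot - w0; m1 <- mt - m0
  ok <- w0 > 0 & w1 > 0
  sb2 <- rep(-Inf, nbins - 1L)
  sb2[ok] <- m0[ok]^2 / w0[ok] + m1[ok]^2 / w1[ok]
  t2c <- which.max(sb2)
  # lowest threshold of the three-class criterion
  best <- -Inf; t3c <- 1L
  for (t1 in seq_len(nbins - 2L)) {
    wa <- W[t1]; ma <- M[t1]
    if (wa == 0) next
    tt <- (t1 + 1L):(nbins - 1L)
    wb <- W[tt] - wa; mb <- M[tt] - ma
    wc <- tot - W[tt]; mc <- mt - M[tt]
    okk <- wb > 0 & wc > 0
    if (!any(okk)) next
    sb <- ma^2 / wa + mb[okk]^2 / wb[okk] + mc[okk]^2 / wc[okk]
    mx <- max(sb)
    if (mx > best) { best <- mx; t3c <- t1 }
  }
  if (t3c < t2c) {
    mass_mid <- W[t2c] - W[t3c]
    mass_hi <- tot - W[t2c]
    # accept the lower threshold only when the mid class is a real
    # structure: most foreground mass and a mean well above the low
    # (background) class -- otherwise a lone small bright object plus
    # camera noise would be thresholded inside the noise
    mean_lo <- M[t3c] / W[t3c]
    sd_lo <- sqrt(pmax(S2[t3c] / W[t3c] - mean_lo^2, 0))
    mean_mid <- (M[t2c] - M[t3c]) / mass_mid
    if (mass_mid > mass_hi && mean_mid > mean_lo + 6 * sd_lo)
      return(br[t3c + 1L])
  }
  br[t2c + 1L]
}

# Otsu threshold + largest component, shared by cell and nucleus.
threshold_largest <- function(frame, params, err_class, restrict = NULL) {
  stopifnot_finite(frame, "intensity frame")
  if (any(frame < 0)) cc_stop("NegativeIntensity", "intensity frame must be nonnegative")
  sm <- gauss_blur(frame, params$smooth_sigma_px)
  r <- range(sm)
  if (diff(r) < params$min_contrast)
    cc_stop(err_class, "no contrast in frame: nothing to segment")
  sub <- sm[seq.int(1L, length(sm), by = 3L)]   # gate statistics on a stride sample
  med <- stats::median(sub)
  if (max(sm) - med <=
      params$contrast_mad_ratio * stats::mad(sub, center = med) + params$min_contrast)
    cc_stop(err_class, "no object above the noise floor")
  th <- robust_otsu(sm, params$otsu_bins)
  mask <- sm > th
  if (!is.null(restrict)) mask <- mask & restrict
  if (!any(mask)) cc_stop(err_class, "empty mask after thresholding")
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) < params$min_area_px)
    cc_stop(err_class, sprintf("no component >= %d px", params$min_area_px))
  as.matrix(lab) == which.max(sizes)
}

#' Segment the cell from an actin-reporter frame
#'
#' Gaussian-smoothed Otsu threshold, hole filling, largest connected
#' component. A pure function of `(frame, params)`.
#'
#' @param actin_frame nonnegative intensity matrix.
#' @param params a [segment_params()].
#' @return logical mask. Errors with class `NoCellDetected` when no
#'   component of at least `min_area_px` exists.
#' @export
segment_cell <- function(actin_frame, params = segment_params()) {
  threshold_largest(actin_frame, params, "NoCellDetected")
}

#' Segment the nucleus from a DNA-stain frame
#'
#' As [segment_cell()], additionally restricted to the one-px-dilated
#' cell mask (the nucleus cannot lie outside the cell).
#'
#' @param dna_frame nonnegative intensity matrix.
#' @param cell_mask logical cell mask from [segment_cell()].
#' @param params a [segment_params()].
#' @return logical mask. Errors with class `NoNucleusDetected`.
#' @export
segment_nucleus <- function(dna_frame, cell_mask, params = segment_params()) {
  restrict <- EBImage::dilate(cell_mask, se_brush(params))
  threshold_largest(dna_frame, params, "NoNucleusDetected", restrict = restrict)
}

#' Cell-cortex mask (dilate-1 minus erode-6)
#'
#' The cortex is the one-time-dilated cell mask minus the six-times-eroded
#' cell mask, using the configured structuring element: a band that
#' always contains every boundary pixel of the cell.
#'
#' @param cell_mask nonempty logical mask.
#' @param params a [segment_params()] (iteration counts, element).
#' @return logical mask.
#' @export
cortex_mask <- function(cell_mask, params = segment_params()) {
  if (!any(cell_mask)) cc_stop("EmptyMask", "cell mask is empty")
  k <- se_brush(params)
  d <- cell_mask
  for (i in seq_len(params$dilate_iter)) d <- EBImage::dilate(d, k)
  e <- cell_mask
  for (i in seq_len(params$erode_iter)) e <- EBImage::erode(e, k)
  as.matrix(d) & !as.matrix(e)
}

#' Perinuclear cortex mask
#'
#' Restricts the cortex band to the axial span of the nucleus plus a
#' one-pixel margin on each side: the cortex "around the nucleus".
#'
#' @param cortex logical cortex mask from [cortex_mask()].
#' @param nucleus_mask logical nucleus mask.
#' @param margin_px axial margin (px) added on each side of the nuclear span.
#' @return logical mask. Errors with class `EmptyPerinuclearRegion` when
#'   the restriction is empty (nucleus outside the cortex span).
#' @export
perinuclear_cortex_mask <- function(cortex, nucleus_mask, margin_px = 1L) {
  if (!any(cortex)) cc_stop("EmptyMask", "cortex mask is empty")
  if (!any(nucleus_mask)) cc_stop("EmptyMask", "nucleus mask is empty")
  cols <- which(colSums(nucleus_mask) > 0)
  lo <- max(1L, min(cols) - margin_px)
  hi <- min(ncol(cortex), max(cols) + margin_px)
  out <- cortex
  keep <- rep(FALSE, ncol(cortex)); keep[lo:hi] <- TRUE
  out <- out & matrix(keep, nrow(cortex), ncol(cortex), byrow = TRUE)
  if (!any(out))
    cc_stop("EmptyPerinuclearRegion", "no cortex pixels within the nuclear axial span")
  out
}

#' Detect beads of known radius
#'
#' Automated replacement for hand-drawn bead contours: intensity peaks in
#' the bead channel become circle centres; each detection is painted as a
#' filled circle of the known radius. Labels are assigned in decreasing
#' brightness order; [link_beads()] makes them stable across frames.
#'
#' @param bead_frame nonnegative intensity matrix.
#' @param known_radius_um bead radius (um); must exceed the pixel size.
#' @param geometry a [channel_geometry()] (pixel size).
#' @param threshold_frac detection threshold as a fraction of the frame
#'   maximum after smoothing.
#' @return integer label matrix (0 = background); attribute `centers` is
#'   a matrix of (row, col) centres in px. Zero detections give an empty
#'   (all-zero) labeling.
#' @export
segment_beads <- function(bead_frame, known_radius_um, geometry,
                          threshold_frac = 0.5) {
  if (known_radius_um <= geometry$pixel_size_um)
    cc_stop("InvalidParams", "bead radius must exceed the pixel size")
  sm <- gauss_blur(bead_frame, 1)
  r_px <- known_radius_um / geometry$pixel_size_um
  # a frame with no object above the noise floor yields an empty labeling
  if (max(sm) - stats::median(sm) <= 10 * stats::mad(sm) + 1e-6) {
    out <- matrix(0L, nrow(bead_frame), ncol(bead_frame))
    attr(out, "centers") <- NULL
    return(out)
  }
  lab0 <- EBImage::bwlabel(sm > threshold_frac * max(sm, 1e-9))
  n0 <- max(lab0)
  out <- matrix(0L, nrow(bead_frame), ncol(bead_frame))
  centers <- NULL
  if (n0 >= 1) {
    # one centre per blob: intensity-weighted centroid
    idx <- which(lab0 > 0, arr.ind = TRUE)
    labv <- lab0[lab0 > 0]; wv <- sm[lab0 > 0]
    bright <- tapply(wv, labv, sum)
    keep <- which(bright > 0.2 * max(bright))
    ord <- keep[order(bright[keep], decreasing = TRUE)]
    centers <- t(vapply(ord, function(l) {
      sel <- labv == l
      c(sum(idx[sel, 1] * wv[sel]) / sum(wv[sel]),
        sum(idx[sel, 2] * wv[sel]) / sum(wv[sel]))
    }, numeric(2)))
    rc <- row(out); cc <- col(out)
    for (i in seq_len(nrow(centers))) {
      disk <- (rc - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= r_px^2
      out[disk & out == 0L] <- i
    }
  }
  attr(out, "centers") <- centers
  out
}

#' Link bead labels across frames by nearest neighbour
#'
#' @param labels_list list of label matrices from [segment_beads()].
#' @param max_jump_px maximum allowed per-frame centre displacement.
#' @return list of relabelled matrices with track-stable labels.
#' @export
link_beads <- function(labels_list, max_jump_px = 20) {
  if (!length(labels_list)) return(labels_list)
  prev <- attr(labels_list[[1]], "centers")
  ids <- seq_len(if (is.null(prev)) 0 else nrow(prev))
  next_id <- length(ids) + 1L
  out <- labels_list
  for (k in seq_along(labels_list)[-1]) {
    cur <- attr(labels_list[[k]], "centers")
    if (is.null(cur)) { prev <- NULL; ids <- integer(0); next }
    new_ids <- integer(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      if (!is.null(prev) && nrow(prev)) {
        d <- sqrt(rowSums((prev - matrix(cur[i, ], nrow(prev), 2, byrow = TRUE))^2))
        j <- which.min(d)
        if (d[j] <= max_jump_px) { new_ids[i] <- ids[j]; next }
      }
      new_ids[i] <- next_id; next_id <- next_id + 1L
    }
    m <- labels_list[[k]]
    relab <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_len(nrow(cur))) relab[m == i] <- new_ids[i]
    attr(relab, "centers") <- cur
    out[[k]] <- relab
    prev <- cur; ids <- new_ids
  }
  out
}
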