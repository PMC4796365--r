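# Normalized actin-enrichment metrics, nuclear shape metrics, spatial
# profiles, and the DNA-thickness / actin relationship.
#
# Both normalization operations are ratios of means, so they are exactly
# invariant under global multiplicative intensity scaling and equal 1 on
# a uniform-intensity cell.

#' Normalized mean actin intensity inside the constriction
#'
#' Total actin signal over the cell pixels inside the constriction,
#' divided by that area, then divided by the mean actin intensity over
#' the whole cell mask.
#'
#' @param actin_frame intensity matrix.
#' @param cell_mask logical cell mask.
#' @param geometry a [channel_geometry()].
#' @return scalar. Errors with class `CellNotInConstriction` when the
#'   cell does not intersect the constriction.
#' @export
normalized_actin_in_constriction <- function(actin_frame, cell_mask, geometry) {
  cm <- constriction_mask(geometry, dim(actin_frame))
  sel <- cell_mask & cm
  if (!any(sel)) cc_stop("CellNotInConstriction", "cell mask does not intersect the constriction")
  whole <- mean(actin_frame[cell_mask])
  if (!is.finite(whole) || whole == 0) cc_stop("NaNIntensity", "zero mean cell intensity")
  (sum(actin_frame[sel]) / sum(sel)) / whole
}

#' Normalized perinuclear actin intensity
#'
#' Mean actin intensity over the perinuclear cortex mask divided by the
#' mean over the whole cell mask.
#'
#' @param actin_frame intensity matrix.
#' @param masks list with logical `cell` and `perinuclear_cortex` masks
#'   (see [perinuclear_cortex_mask()]).
#' @return scalar. Errors `EmptyPerinuclearRegion` / `NaNIntensity`.
#' @export
normalized_perinuclear_actin <- function(actin_frame, masks) {
  pnc <- masks$perinuclear_cortex
  if (is.null(pnc) || !any(pnc))
    cc_stop("EmptyPerinuclearRegion", "empty perinuclear cortex mask")
  whole <- mean(actin_frame[masks$cell])
  if (!is.finite(whole) || whole == 0) cc_stop("NaNIntensity", "zero mean cell intensity")
  mean(actin_frame[pnc]) / whole
}

#' Perinuclear actin-enrichment call for one cell
#'
#' The per-frame normalized perinuclear actin series is compared against
#' its own pre-entry baseline: the flag is true when the peak during the
#' nuclear engagement window (nuclear entry to nuclear exit or reversal)
#' reaches `baseline mean + k * baseline s.d.` and also an absolute
#' floor. The window and baseline come from the event classification.
#'
#' @param series numeric per-frame normalized perinuclear actin values
#'   (`NA` where unavailable).
#' @param t_min frame times (min) aligned with `series`.
#' @param event a [classify_passage()] row.
#' @param k baseline s.d. multiplier.
#' @param floor absolute minimum peak value for a positive call.
#' @param min_baseline_frames minimum pre-entry frames required.
#' @return list with `flag`, `peak`, `baseline_mean`, `baseline_sd`,
#'   `n_baseline`. Errors with class `UndefinedBaseline` when fewer than
#'   `min_baseline_frames` pre-entry values exist, or when no nuclear
#'   entry occurred.
#' @export
enrichment_flag <- function(series, t_min, event, k = 2, floor = 1.2,
                            min_baseline_frames = 3L) {
  if (is.na(event$t_nuc_entry))
    cc_stop("UndefinedBaseline", "no nuclear entry: enrichment window undefined")
  t_rev <- if (!is.na(event$non_passage_time_min))
    event$t_cell_entry + event$non_passage_time_min else NA_real_
  t_end <- suppressWarnings(min(event$t_nuc_exit, t_rev, na.rm = TRUE))
  if (!is.finite(t_end)) t_end <- max(t_min)
  base <- series[t_min < event$t_nuc_entry & !is.na(series)]
  if (length(base) < min_baseline_frames)
    cc_stop("UndefinedBaseline",
            sprintf("need >= %d pre-entry frames for the baseline", min_baseline_frames))
  win <- series[t_min >= event$t_nuc_entry & t_min <= t_end & !is.na(series)]
  peak <- if (length(win)) max(win) else NA_real_
  bm <- mean(base); bs <- stats::sd(base)
  flag <- !is.na(peak) && peak >= bm + k * bs && peak >= floor
  list(flag = flag, peak = peak, baseline_mean = bm, baseline_sd = bs,
       n_baseline = length(base))
}

#' Actin enrichment profile versus nuclear position
#'
#' Aligns per-cell normalized perinuclear actin series on the signed
#' axial distance of the nuclear centre of mass from the constriction
#' centre (positive = past the centre along the migration direction) and
#' bins them.
#'
#' @param cells list; each element has numeric `position_um` (nuclear
#'   com minus constriction centre, signed along migration) and
#'   `value` (normalized actin), equal length.
#' @param bin_width_um bin width (um).
#' @return data.frame with `bin_center_um`, `mean`, `sd`, `n` (empty
#'   bins keep `n = 0` and `NA` means).
#' @export
actin_vs_position_profile <- function(cells, bin_width_um = 2) {
  if (bin_width_um <= 0) cc_stop("InvalidParams", "bin width must be positive")
  pos <- unlist(lapply(cells, `[[`, "position_um"))
  val <- unlist(lapply(cells, `[[`, "value"))
  ok <- !is.na(pos) & !is.na(val)
  pos <- pos[ok]; val <- val[ok]
  if (!length(pos)) cc_stop("EmptyCohort", "no aligned samples")
  lo <- floor(min(pos) / bin_width_um) * bin_width_um
  hi <- ceiling(max(pos) / bin_width_um) * bin_width_um
  edges <- seq(lo, hi, by = bin_width_um)
  idx <- findInterval(pos, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  out <- data.frame(bin_center_um = edges[-length(edges)] + bin_width_um / 2,
                    mean = NA_real_, sd = NA_real_, n = 0L)
  for (b in seq_len(nb)) {
    v <- val[idx == b]
    out$n[b] <- length(v)
    if (length(v)) { out$mean[b] <- mean(v); out$sd[b] <- stats::sd(v) }
  }
  out
}

#' Nuclear circularity
#'
#' `4 * pi * A / P^2`: 1 for a disk, `pi/4` for a solid square,
#' approaching 0 with elongation. Area and perimeter are taken from a
#' sub-pixel boundary polygon: the pixel-edge outline of the mask,
#' simplified with the Ramer-Douglas-Peucker algorithm (tolerance one
#' pixel), which approximates the minimum-perimeter polygon through the
#' digitization band -- it removes the staircase bias of raw pixel-edge
#' outlines on smooth shapes while keeping true right-angle corners
#' exact. A mask touching the image border triggers a `BorderTouch`
#' warning (the outline there follows the border, so the perimeter is
#' unreliable).
#'
#' @param nucleus_mask nonempty logical mask.
#' @param pixel_size_um pixel size (um); the value is scale free, so
#'   this only matters for the returned perimeter attribute.
#' @param simplify_tol_px polygon simplification tolerance (px).
#' @return circularity scalar with attributes `perimeter_um` and
#'   `area_um2`.
#' @export
nuclear_circularity <- function(nucleus_mask, pixel_size_um = 1,
                                simplify_tol_px = 1) {
  if (!any(nucleus_mask)) cc_stop("EmptyMask", "empty nucleus mask")
  if (any(nucleus_mask[1, ]) || any(nucleus_mask[nrow(nucleus_mask), ]) ||
      any(nucleus_mask[, 1]) || any(nucleus_mask[, ncol(nucleus_mask)]))
    warning(warningCondition("mask touches the image border: perimeter unreliable",
                             class = "BorderTouch"))
  poly <- simplify_polygon(boundary_polygon(nucleus_mask), simplify_tol_px)
  P <- polygon_perimeter(poly) * pixel_size_um
  A <- polygon_area(poly) * pixel_size_um^2
  out <- 4 * pi * A / P^2
  attr(out, "perimeter_um") <- P
  attr(out, "area_um2") <- A
  out
}

# Longest closed pixel-edge boundary loop of a binary mask, as (row,
# col) vertices in pixel units (pixel i spans i +/- 0.5).
boundary_polygon <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- mask
  core <- pad[2:(n + 1), 2:(m + 1)]
  segs <- NULL
  add <- function(idx, s) if (nrow(idx)) rbind(s, cbind(
    idx[, 1] + sgn[1], idx[, 2] + sgn[2], idx[, 1] + sgn[3], idx[, 2] + sgn[4])) else s
  # exposed edges in each of the four directions; segment endpoints are
  # oriented so the mask interior stays on the same side throughout
  up <- core & !pad[1:n, 2:(m + 1)]
  dn <- core & !pad[3:(n + 2), 2:(m + 1)]
  lf <- core & !pad[2:(n + 1), 1:m]
  rt <- core & !pad[2:(n + 1), 3:(m + 2)]
  sgn <- c(-0.5, -0.5, -0.5, 0.5); segs <- add(which(up, arr.ind = TRUE), segs)
  sgn <- c(0.5, 0.5, 0.5, -0.5); segs <- add(which(dn, arr.ind = TRUE), segs)
  sgn <- c(0.5, -0.5, -0.5, -0.5); segs <- add(which(lf, arr.ind = TRUE), segs)
  sgn <- c(-0.5, 0.5, 0.5, 0.5); segs <- add(which(rt, arr.ind = TRUE), segs)
  key <- function(y, x) paste(y, x, sep = "_")
  start_of <- split(seq_len(nrow(segs)), key(segs[, 1], segs[, 2]))
  used <- rep(FALSE, nrow(segs))
  best <- NULL
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    loop <- matrix(segs[s0, 1:2], 1, 2)
    cur <- s0
    repeat {
      used[cur] <- TRUE
      endp <- segs[cur, 3:4]
      loop <- rbind(loop, endp)
      cand <- start_of[[key(endp[1], endp[2])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    if (is.null(best) || nrow(loop) > nrow(best)) best <- loop
  }
  best[-nrow(best), , drop = FALSE]
}

# Ramer-Douglas-Peucker simplification of a closed polygon: the curve is
# split at its two most distant vertices and each arc simplified.
simplify_polygon <- function(pts, eps) {
  if (eps <= 0 || nrow(pts) < 4) return(pts)
  simp <- function(p) {
    n <- nrow(p)
    if (n < 3) return(p)
    a <- p[1, ]; b <- p[n, ]
    ab <- b - a; L <- sqrt(sum(ab^2))
    d <- if (L < 1e-12) sqrt(rowSums((p - matrix(a, n, 2, byrow = TRUE))^2))
      else abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / L
    k <- which.max(d)
    if (d[k] <= eps) return(p[c(1, n), , drop = FALSE])
    left <- simp(p[1:k, , drop = FALSE])
    rbind(left[-nrow(left), , drop = FALSE], simp(p[k:n, , drop = FALSE]))
  }
  D <- as.matrix(stats::dist(pts))
  mx <- which(D == max(D), arr.ind = TRUE)[1, ]
  i1 <- min(mx); i2 <- max(mx)
  s1 <- simp(pts[i1:i2, , drop = FALSE])
  s2 <- simp(pts[c(i2:nrow(pts), 1:i1), , drop = FALSE])
  rbind(s1[-nrow(s1), , drop = FALSE], s2[-nrow(s2), , drop = FALSE])
}

polygon_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1, ])
  sum(sqrt(rowSums(diff(p2)^2)))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' DNA thickness versus actin intensity along the constriction
#'
#' For each axial column where the nucleus intersects the constriction:
#' the transverse nuclear extent (thickness, um), the mean DNA intensity
#' over the nuclear pixels of the column, and the mean actin intensity
#' over the cortex pixels of the column. An ordinary least-squares fit
#' of actin against thickness is restricted to columns thinner than the
#' constriction width.
#'
#' @param nucleus_mask,cortex logical masks.
#' @param dna_frame,actin_frame intensity matrices.
#' @param geometry a [channel_geometry()].
#' @return list with `columns` (per-column table) and `fit`
#'   (slope/intercept/n of the restricted regression, `NA` slope when
#'   degenerate). Errors with class `InsufficientColumns` when fewer
#'   than 3 qualifying columns exist.
#' @export
dna_thickness_actin_relation <- function(nucleus_mask, dna_frame, actin_frame,
                                         cortex, geometry) {
  cm <- constriction_mask(geometry, dim(nucleus_mask))
  nin <- nucleus_mask & cm
  cols <- which(colSums(nin) > 0)
  if (length(cols) < 3) cc_stop("InsufficientColumns", "fewer than 3 nucleus columns in the constriction")
  px <- geometry$pixel_size_um
  xc <- pixel_center_x(geometry, ncol(nucleus_mask))
  tab <- do.call(rbind, lapply(cols, function(j) {
    nj <- nucleus_mask[, j]
    cj <- cortex[, j]
    data.frame(x_um = xc[j],
               dna_thickness_um = sum(nj) * px,
               dna_mean_intensity = mean(dna_frame[nj, j]),
               actin_mean_intensity = if (any(cj)) mean(actin_frame[cj, j]) else NA_real_)
  }))
  W <- geometry$constriction_width_um
  sub <- tab[tab$dna_thickness_um < W & !is.na(tab$actin_mean_intensity), , drop = FALSE]
  if (nrow(sub) < 3) cc_stop("InsufficientColumns", "fewer than 3 columns thinner than W")
  fit <- stats::lm(actin_mean_intensity ~ dna_thickness_um, data = sub)
  list(columns = tab,
       fit = list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  n = nrow(sub)))
}

#' Normalized actin intensity around a bead
#'
#' Mean actin intensity in the annulus (three-times-dilated bead minus
#' bead) divided by the mean over the whole cell mask. The annulus is
#' restricted to the interior of the cell (cell mask eroded
#' `guard_erode` times): in a narrow constriction the raw annulus runs
#' straight through the cell's constitutive cortical rim, which would
#' register as spurious peribead accumulation; the guard keeps the
#' metric specific to bead-associated actin.
#'
#' @param actin_frame intensity matrix.
#' @param bead_label_mask integer label matrix from [segment_beads()].
#' @param bead_id label of the bead to measure.
#' @param cell_mask logical cell mask.
#' @param params a [segment_params()] (structuring element).
#' @param guard_erode cell-mask erosion iterations for the interior
#'   restriction of the annulus.
#' @return scalar. Errors with class `BeadOutsideCell` when the bead is
#'   not inside the cell mask.
#' @export
actin_around_bead <- function(actin_frame, bead_label_mask, bead_id, cell_mask,
                              params = segment_params(), guard_erode = 4L) {
  bead <- bead_label_mask == bead_id
  if (!any(bead)) cc_stop("EmptyMask", "bead id not present in labeling")
  if (mean(cell_mask[bead]) < 0.5)
    cc_stop("BeadOutsideCell", "bead is not inside the cell mask")
  k <- se_brush(params)
  d <- bead
  for (i in 1:3) d <- EBImage::dilate(d, k)
  interior <- cell_mask
  for (i in seq_len(guard_erode)) interior <- as.matrix(EBImage::erode(interior, k))
  ann <- as.matrix(d) & !bead & interior
  if (!any(ann)) cc_stop("EmptyMask", "empty bead annulus within the cell")
  whole <- mean(actin_frame[cell_mask])
  if (!is.finite(whole) || whole == 0) cc_stop("NaNIntensity", "zero mean cell intensity")
  mean(actin_frame[ann]) / whole
}
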