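# Microdevice coordinate frame.
#
# Axial coordinates are continuous micrometres along the channel axis
# (the x / column direction of the image). Pixel column j (1-based)
# has its centre at (j - 0.5) * pixel_size_um, i.e. the pixel-centre
# convention. The constriction occupies the half-open interval
# [center - L/2, center + L/2): a front exactly at the entry plane
# counts as having entered.

#' Channel and constriction geometry
#'
#' Defines the coordinate frame of a straight migration channel of width
#' `d` containing a single constriction of width `W` and length `L`,
#' centred at a known axial position. All downstream metrics (region
#' classification, passage events, in-constriction intensities) are
#' expressed in this frame. The geometry is always supplied by the
#' experimenter/config, never inferred from images.
#'
#' @param channel_width_um channel width `d` (um), transverse to migration.
#' @param constriction_width_um constriction width `W` (um); `0 < W < d`.
#' @param constriction_length_um constriction length `L` (um), `> 0`.
#' @param constriction_center_x_um axial coordinate of the constriction
#'   midpoint (um).
#' @param pixel_size_um physical size of one pixel (um), `> 0`.
#' @param migration_direction `+1` if cells travel toward increasing x,
#'   `-1` otherwise.
#' @param channel_height_um channel height (um); carried as metadata only
#'   (all metrics are 2-D projections).
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(channel_width_um,
                             constriction_width_um,
                             constriction_length_um,
                             constriction_center_x_um,
                             pixel_size_um,
                             migration_direction = 1L,
                             channel_height_um = NA_real_) {
  stopifnot(
    is.numeric(channel_width_um), channel_width_um > 0,
    is.numeric(constriction_width_um),
    is.numeric(constriction_length_um), constriction_length_um > 0,
    is.numeric(pixel_size_um), pixel_size_um > 0,
    migration_direction %in% c(-1, 1)
  )
  if (!(constriction_width_um > 0 && constriction_width_um < channel_width_um))
    cc_stop("InvalidGeometry", "constriction width W must satisfy 0 < W < channel width d")
  g <- structure(list(
    channel_width_um = as.numeric(channel_width_um),
    channel_height_um = as.numeric(channel_height_um),
    constriction_width_um = as.numeric(constriction_width_um),
    constriction_length_um = as.numeric(constriction_length_um),
    constriction_center_x_um = as.numeric(constriction_center_x_um),
    pixel_size_um = as.numeric(pixel_size_um),
    migration_direction = as.integer(sign(migration_direction))
  ), class = "channel_geometry")
  g
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> d=%.2f um, W=%.2f um, L=%.2f um, center=%.2f um, px=%.4g um, dir=%+d\n",
    x$channel_width_um, x$constriction_width_um, x$constriction_length_um,
    x$constriction_center_x_um, x$pixel_size_um, x$migration_direction))
  invisible(x)
}

# Half-open constriction interval [lo, hi) in um.
constriction_interval <- function(geometry) {
  c(geometry$constriction_center_x_um - geometry$constriction_length_um / 2,
    geometry$constriction_center_x_um + geometry$constriction_length_um / 2)
}

# Entrance / exit planes relative to the migration direction: the
# entrance is the upstream face of the constriction.
constriction_planes <- function(geometry) {
  iv <- constriction_interval(geometry)
  if (geometry$migration_direction > 0) list(entrance = iv[1], exit = iv[2])
  else list(entrance = iv[2], exit = iv[1])
}

# Axial coordinate (um) of pixel-column centres for an image with nx columns.
pixel_center_x <- function(geometry, nx) (seq_len(nx) - 0.5) * geometry$pixel_size_um

#' Classify an axial position relative to the constriction
#'
#' Splits the channel axis into `before` (upstream of the constriction
#' relative to the migration direction), `inside` (the half-open
#' interval `[center - L/2, center + L/2)`), and `after` (downstream).
#'
#' @param geometry a [channel_geometry()].
#' @param x axial coordinate(s) in um; must be finite.
#' @return character vector of `"before"`, `"inside"`, `"after"`.
#' @export
classify_axial_position <- function(geometry, x) {
  stopifnot(inherits(geometry, "channel_geometry"))
  stopifnot_finite(x, "axial coordinate x")
  iv <- constriction_interval(geometry)
  inside <- x >= iv[1] & x < iv[2]
  downstream <- if (geometry$migration_direction > 0) x >= iv[2] else x < iv[1]
  out <- ifelse(inside, "inside", ifelse(downstream, "after", "before"))
  out
}

#' Binary mask of the constriction region
#'
#' Marks every pixel whose axial (column) centre coordinate falls in the
#' half-open constriction interval. A constriction narrower than one
#' pixel still yields at least one marked column (the column containing
#' the constriction centre).
#'
#' @param geometry a [channel_geometry()].
#' @param image_shape integer vector `c(ny, nx)` (rows, columns).
#' @return logical matrix of dimension `image_shape`.
#' @export
constriction_mask <- function(geometry, image_shape) {
  stopifnot(inherits(geometry, "channel_geometry"), length(image_shape) == 2)
  ny <- as.integer(image_shape[1]); nx <- as.integer(image_shape[2])
  xc <- pixel_center_x(geometry, nx)
  iv <- constriction_interval(geometry)
  if (iv[1] >= nx * geometry$pixel_size_um || iv[2] <= 0)
    cc_stop("ConstrictionOutsideImage", "constriction interval lies outside the image axial extent")
  cols <- xc >= iv[1] & xc < iv[2]
  if (!any(cols)) { # sub-pixel constriction: keep the column holding the centre
    j <- min(nx, max(1L, 1L + floor(geometry$constriction_center_x_um / geometry$pixel_size_um)))
    cols[j] <- TRUE
  }
  matrix(rep(cols, each = ny), ny, nx)
}
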