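# The movie container and its TIFF + JSON-sidecar serialization.
#
# A movie is a (y, x, channel, time) array with a channel-role map,
# frame interval and pixel size. On disk: a multi-page TIFF with planes
# interleaved channel-fastest, and a JSON sidecar carrying the channel
# map and acquisition metadata plus the intensity scale used for the
# 16-bit encoding.

#' Construct a movie object
#'
#' @param data numeric array `(ny, nx, n_channels, n_frames)`.
#' @param channel_map named integer vector mapping channel roles (e.g.
#'   `actin`, `dna`, `lamina`, `bead`) to plane indices.
#' @param frame_interval_min acquisition interval (min), `> 0`.
#' @param pixel_size_um pixel size (um), `> 0`.
#' @return object of class `cc_movie`.
#' @export
as_movie <- function(data, channel_map, frame_interval_min, pixel_size_um) {
  if (length(dim(data)) != 4) cc_stop("FormatError", "movie data must be a 4-D array")
  if (anyDuplicated(names(channel_map)) || anyDuplicated(channel_map))
    cc_stop("ConfigError", "channel roles and plane indices must be unique")
  if (frame_interval_min <= 0 || pixel_size_um <= 0)
    cc_stop("ConfigError", "frame interval and pixel size must be positive")
  structure(list(data = data, channel_map = channel_map,
                 frame_interval_min = frame_interval_min,
                 pixel_size_um = pixel_size_um),
            class = "cc_movie")
}

#' @export
print.cc_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cc_movie> %d x %d px, %d channel(s) [%s], %d frame(s), dt=%.3g min, px=%.4g um\n",
              d[1], d[2], d[3], paste(names(x$channel_map), collapse = ","),
              d[4], x$frame_interval_min, x$pixel_size_um))
  invisible(x)
}

# Extract one channel frame as a plain matrix.
movie_frame <- function(movie, role, k) {
  ch <- movie$channel_map[[role]]
  if (is.null(ch)) cc_stop("ConfigError", sprintf("movie has no '%s' channel", role))
  movie$data[, , ch, k]
}

n_frames <- function(movie) dim(movie$data)[4]

#' Write a movie to a multi-page TIFF with a JSON sidecar
#'
#' Planes are stored channel-fastest as 16-bit TIFF pages; intensities
#' are scaled by `max_intensity` (recorded in the sidecar), so integer
#' data up to that bound round-trips losslessly.
#'
#' @param movie a [as_movie()] object.
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path (default: `path` + `.json`).
#' @param max_intensity full-scale intensity of the 16-bit encoding.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, sidecar = paste0(path, ".json"),
                        max_intensity = 65535) {
  d <- dim(movie$data)
  pages <- vector("list", d[3] * d[4])
  i <- 1L
  for (k in seq_len(d[4])) for (c in seq_len(d[3])) {
    pages[[i]] <- pmin(pmax(movie$data[, , c, k] / max_intensity, 0), 1)
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channel_map = as.list(movie$channel_map),
               frame_interval_min = movie$frame_interval_min,
               pixel_size_um = movie$pixel_size_um,
               max_intensity = max_intensity,
               n_channels = d[3], n_frames = d[4])
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from a multi-page TIFF with a JSON sidecar
#'
#' @param path TIFF path; plane count must be divisible by the sidecar's
#'   channel count.
#' @param sidecar JSON sidecar path.
#' @return a [as_movie()] object.
#' @export
read_movie <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (req in c("channel_map", "frame_interval_min", "pixel_size_um"))
    if (is.null(meta[[req]]))
      cc_stop("ConfigError", sprintf("sidecar lacks required field '%s'", req))
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channel_map)
  if (length(pages) %% nc != 0)
    cc_stop("FormatError", sprintf("%d planes not divisible by %d channels",
                                   length(pages), nc))
  nt <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- if (!is.null(meta$max_intensity)) meta$max_intensity else 1
  dat <- array(0, c(ny, nx, nc, nt))
  i <- 1L
  for (k in seq_len(nt)) for (c in seq_len(nc)) {
    dat[, , c, k] <- round(pages[[i]] * scale)
    i <- i + 1L
  }
  cmap <- unlist(meta$channel_map)
  as_movie(dat, channel_map = cmap,
           frame_interval_min = meta$frame_interval_min,
           pixel_size_um = meta$pixel_size_um)
}
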