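# Configuration of the synthetic two-channel time-lapse generator.
#
# The generator is calibrated so that the cohort-level statistics of the
# ground truth match the printed statistics of the dendritic-cell
# constriction-migration experiments it emulates: free-migration speeds
# with mean 4.48 and s.d. 3.93 um/min, width-dependent passage
# probabilities (4% at 1 um, 40% at 1.5 um, 78% at >= 3 um), a 41%
# velocity drop during nuclear transit of 1.5-um constrictions,
# perinuclear actin enrichment in most passers and a minority of
# non-passers, lamina-ring rupture frequencies by channel condition, and
# peribead actin accumulation at matched bead/constriction width.

# ---- truncated-normal speed law ------------------------------------------

# Moments of a normal(mu, sigma) truncated below at a.
truncnorm_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lam <- exp(stats::dnorm(alpha, log = TRUE) -
               stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + alpha * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the underlying (mu, sigma) of a below-truncated normal whose
# *realized* mean and s.d. equal the target values. The printed cohort
# speed statistics are sample moments of observed (nonnegative) speeds,
# so they are encoded as moments of the truncated law, not of the
# untruncated parent.
solve_truncnorm <- function(target_mean, target_sd, floor) {
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), floor)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Sample n speeds from the truncated law by inverse-CDF in the upper
# tail (numerically stable even when the truncation point sits far in
# the parent's tail).
sample_truncnorm <- function(n, mu, sigma, floor) {
  p_tail <- stats::pnorm(floor, mu, sigma, lower.tail = FALSE)
  u <- stats::runif(n)
  stats::qnorm(u * p_tail, mu, sigma, lower.tail = FALSE)
}

# ---- width-indexed calibration maps --------------------------------------

# Linear interpolation in a width -> value map; widths beyond the table
# take the boundary value. Exact table widths are returned exactly.
lookup_width_map <- function(map, width, interpolate = TRUE) {
  w <- as.numeric(names(map)); v <- as.numeric(map)
  o <- order(w); w <- w[o]; v <- v[o]
  hit <- which(abs(w - width) < 1e-9)
  if (length(hit)) return(v[hit[1]])
  if (!interpolate)
    cc_stop("WidthNotInMap", sprintf("width %.3g um absent from map and interpolation disabled", width))
  stats::approx(w, v, xout = width, rule = 2)$y
}

# ---- default geometry -----------------------------------------------------

#' Default microdevice geometry of the emulated assay
#'
#' A 7 x 5 um migration channel with one 15-um-long constriction of the
#' requested width, imaged at 0.325 um per pixel (20x acquisition scale)
#' on a 256 x 64 px frame, constriction centred at 50 um.
#'
#' @param constriction_width_um constriction width `W` in um.
#' @param constriction_length_um constriction length `L` in um.
#' @return a [channel_geometry()].
#' @export
default_geometry <- function(constriction_width_um = 2,
                             constriction_length_um = 15) {
  channel_geometry(
    channel_width_um = 7, channel_height_um = 5,
    constriction_width_um = constriction_width_um,
    constriction_length_um = constriction_length_um,
    constriction_center_x_um = 50,
    pixel_size_um = 0.325,
    migration_direction = 1L)
}

#' Synthetic-movie generator configuration
#'
#' All calibration constants of the generator live here; defaults encode
#' the emulated cohort statistics (see the methods vignette). Fields not
#' supplied fall back to those defaults.
#'
#' @param geometry a [channel_geometry()].
#' @param n_cells number of cells (one cell per movie).
#' @param n_frames maximum frames per movie.
#' @param frame_interval_min acquisition interval (min).
#' @param image_shape frame size `c(ny, nx)` in pixels.
#' @param speed_mean_um_min,speed_sd_um_min mean and s.d. of the
#'   free-migration speed distribution (um/min), realized moments of a
#'   below-truncated normal law.
#' @param speed_floor_um_min lower truncation of the speed law (um/min).
#' @param passage_prob_by_width named numeric map width (um) -> passage
#'   probability.
#' @param slowdown_fraction_by_width named numeric map width (um) ->
#'   fractional velocity reduction during nuclear transit.
#' @param slowdown_sd per-cell s.d. of the slowdown fraction
#'   (biological variability between cells).
#' @param p_entry_given_nonpass probability that a non-passing cell still
#'   initiates nuclear entry before reversing.
#' @param p_enrich_passer,p_enrich_nonpasser probabilities that a transit
#'   carries a perinuclear actin ring, conditioned on outcome.
#' @param enrichment_amplitude ring intensity as a multiple of the mean
#'   cell-body actin intensity.
#' @param enrich_max_width_um perinuclear rings are rendered only in
#'   constrictions narrower than this (the enrichment is specific to
#'   small constrictions).
#' @param rupture_prob_by_condition named map over
#'   `long_constriction`, `short_constriction`, `straight_channel`.
#' @param p_tip_localized probability that a rupture gap sits at the
#'   leading nuclear pole.
#' @param gap_span_range_deg range of rupture gap angular spans (deg).
#' @param bead_diameter_um bead diameter (um).
#' @param p_peribead_accumulation probability of an actin ring around a
#'   width-matched bead inside the constriction.
#' @param photon_scale Poisson photon scale (counts at unit intensity).
#' @param read_noise_sd Gaussian read-noise s.d. (counts).
#' @param psf_sigma_um PSF Gaussian sigma (um).
#' @param seed master seed; per-cell streams are derived from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(geometry = default_geometry(),
                         n_cells = 1L,
                         n_frames = 60L,
                         frame_interval_min = 2,
                         image_shape = c(64L, 256L),
                         speed_mean_um_min = 4.48,
                         speed_sd_um_min = 3.93,
                         speed_floor_um_min = 0.5,
                         passage_prob_by_width = c("1" = 0.04, "1.5" = 0.40,
                                                   "2" = 0.60, "3" = 0.78),
                         slowdown_fraction_by_width = c("1" = 0.50, "1.5" = 0.41,
                                                        "2" = 0.27, "3" = 0),
                         slowdown_sd = 0.08,
                         p_entry_given_nonpass = 0.6,
                         p_enrich_passer = 0.93,
                         p_enrich_nonpasser = 0.25,
                         enrichment_amplitude = 5,
                         enrich_max_width_um = 3,
                         rupture_prob_by_condition = c(long_constriction = 0.87,
                                                       short_constriction = 0.43,
                                                       straight_channel = 0.07),
                         p_tip_localized = 0.97,
                         gap_span_range_deg = c(30, 120),
                         bead_diameter_um = 3,
                         p_peribead_accumulation = 0.88,
                         photon_scale = 1,
                         read_noise_sd = 2,
                         psf_sigma_um = 0.3,
                         seed = 1L) {
  probs <- c(passage_prob_by_width, p_entry_given_nonpass, p_enrich_passer,
             p_enrich_nonpasser, rupture_prob_by_condition, p_tip_localized,
             p_peribead_accumulation)
  if (any(probs < 0 | probs > 1)) cc_stop("InvalidConfig", "probabilities must lie in [0, 1]")
  if (speed_mean_um_min <= 0 || speed_sd_um_min <= 0 || enrichment_amplitude <= 0 ||
      psf_sigma_um < 0 || photon_scale <= 0 || read_noise_sd < 0)
    cc_stop("InvalidConfig", "speeds, amplitudes, scales and sigmas must be positive")
  if (n_frames < 2 || frame_interval_min <= 0)
    cc_stop("InvalidConfig", "need n_frames >= 2 and a positive frame interval")
  law <- solve_truncnorm(speed_mean_um_min, speed_sd_um_min, speed_floor_um_min)
  structure(list(
    geometry = geometry,
    n_cells = as.integer(n_cells),
    n_frames = as.integer(n_frames),
    frame_interval_min = frame_interval_min,
    image_shape = as.integer(image_shape),
    speed_mean_um_min = speed_mean_um_min,
    speed_sd_um_min = speed_sd_um_min,
    speed_floor_um_min = speed_floor_um_min,
    speed_law = law,
    passage_prob_by_width = passage_prob_by_width,
    slowdown_fraction_by_width = slowdown_fraction_by_width,
    slowdown_sd = slowdown_sd,
    p_entry_given_nonpass = p_entry_given_nonpass,
    p_enrich_passer = p_enrich_passer,
    p_enrich_nonpasser = p_enrich_nonpasser,
    enrichment_amplitude = enrichment_amplitude,
    enrich_max_width_um = enrich_max_width_um,
    rupture_prob_by_condition = rupture_prob_by_condition,
    p_tip_localized = p_tip_localized,
    gap_span_range_deg = gap_span_range_deg,
    bead_diameter_um = bead_diameter_um,
    p_peribead_accumulation = p_peribead_accumulation,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    psf_sigma_um = psf_sigma_um,
    seed = as.integer(seed),
    # cell morphology (um): capsule half-length, nucleus semi-axes and
    # axial offset of the nucleus centre behind the cell centre
    cell_half_length_um = 10,
    nucleus_a_um = 3.5,
    nucleus_b_um = 2.6,
    nucleus_offset_um = -1,
    # intensity model (pre-noise counts)
    actin_body = 30, actin_rim_factor = 2, actin_rear_factor = 1.5,
    actin_bg = 3, dna_base = 60, dna_bg = 2
  ), class = "synth_config")
}

#' Configuration for a straight channel without a constriction
#'
#' Used to emulate free migration in constriction-free channels: the
#' "constriction" spans nearly the full channel width, every cell passes
#' and no slowdown is applied.
#'
#' @param channel_width_um channel width (um).
#' @param ... forwarded to [synth_config()].
#' @return a `synth_config`.
#' @export
straight_channel_config <- function(channel_width_um = 7, ...) {
  g <- channel_geometry(
    channel_width_um = channel_width_um, channel_height_um = 5,
    constriction_width_um = channel_width_um - 1e-3,
    constriction_length_um = 15, constriction_center_x_um = 50,
    pixel_size_um = 0.325, migration_direction = 1L)
  w <- as.character(g$constriction_width_um)
  synth_config(geometry = g,
               passage_prob_by_width = stats::setNames(1, w),
               slowdown_fraction_by_width = stats::setNames(0, w),
               slowdown_sd = 0, ...)
}
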