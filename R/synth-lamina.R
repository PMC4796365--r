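# Synthetic fixed-cell lamina panels.
#
# Emulates immunofluorescence stills of nuclei inside (or outside)
# constrictions: the lamina stain is a bright band along the nuclear
# boundary; with a condition-dependent probability one angular sector of
# the band is erased (the rupture gap), preferentially at the leading
# nuclear pole. A DNA channel (filled nucleus) accompanies each still so
# the nucleus can be segmented independently of the lamina signal.

lamina_shapes <- list(
  long_constriction  = c(a = 5.0, b = 1.0),
  short_constriction = c(a = 4.2, b = 1.4),
  straight_channel   = c(a = 3.2, b = 2.8)
)

#' Render one synthetic lamina-stained nucleus
#'
#' @param a,b ellipse semi-axes (um), `a` along the migration axis.
#' @param gap_span_deg angular span of the rupture gap (deg); 0 for a
#'   continuous ring.
#' @param gap_center_deg angular position of the gap centre (deg, 0 = the
#'   leading pole at +x).
#' @param config a [synth_config()] (noise/PSF settings).
#' @param shape image size `c(ny, nx)` in pixels.
#' @param noise apply camera noise.
#' @return list with `lamina` and `dna` images plus the truth geometry.
#' @export
render_lamina_nucleus <- function(a, b, gap_span_deg = 0, gap_center_deg = 0,
                                  config = synth_config(), shape = c(64L, 64L),
                                  noise = TRUE) {
  px <- config$geometry$pixel_size_um
  ny <- shape[1]; nx <- shape[2]
  xs <- (seq_len(nx) - 0.5) * px; ys <- (seq_len(ny) - 0.5) * px
  cx <- nx / 2 * px; cy <- ny / 2 * px
  DX <- matrix(xs - cx, ny, nx, byrow = TRUE); DY <- matrix(ys - cy, ny, nx)
  rho <- sqrt((DX / a)^2 + (DY / b)^2)
  # approximate signed distance (um) to the ellipse boundary, so the
  # band has constant physical thickness even on elongated nuclei
  grad <- sqrt((DX / a^2)^2 + (DY / b^2)^2) / pmax(rho, 1e-6)
  sd_um <- (rho - 1) / pmax(grad, 1e-6)
  ring <- abs(sd_um) <= 0.45
  lam <- matrix(2, ny, nx)
  lam[sd_um < -0.45] <- 8
  lam[ring] <- 80
  if (gap_span_deg > 0) {
    ang <- atan2(DY, DX) * 180 / pi
    d <- abs(((ang - gap_center_deg + 180) %% 360) - 180)
    lam[ring & d <= gap_span_deg / 2] <- 8
  }
  dna <- matrix(config$dna_bg, ny, nx)
  dna[rho <= 1] <- config$dna_bg + config$dna_base
  if (noise) {
    lam <- apply_camera_still(lam, config)
    dna <- apply_camera_still(dna, config)
  }
  list(lamina = lam, dna = dna,
       truth = list(a = a, b = b, gap_span_deg = gap_span_deg,
                    gap_center_deg = gap_center_deg,
                    center_px = c(cy / px + 0.5, cx / px + 0.5)))
}

apply_camera_still <- function(img, config) {
  img <- gauss_blur(img, config$psf_sigma_um / config$geometry$pixel_size_um)
  n <- length(img)
  noisy <- stats::rpois(n, pmax(img, 0) * config$photon_scale) / config$photon_scale +
    stats::rnorm(n, 0, config$read_noise_sd)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

#' Render a panel of synthetic lamina-stained nuclei for one condition
#'
#' For each nucleus, a rupture occurs with the condition's calibrated
#' probability; ruptured nuclei receive one angular gap whose span is
#' drawn uniformly from `config$gap_span_range_deg`. With probability
#' `config$p_tip_localized` the gap centre sits at the leading pole,
#' otherwise it is placed uniformly in [60, 300] degrees (outside the
#' tip cone).
#'
#' @param config a [synth_config()].
#' @param condition one of `"long_constriction"`, `"short_constriction"`,
#'   `"straight_channel"`.
#' @param n number of nuclei.
#' @param noise apply camera noise.
#' @return list with `stills` (list of lamina/dna image pairs) and
#'   `truth` (data.frame: ruptured, gap span/centre, tip flag).
#' @export
render_lamina_panel <- function(config, condition, n, noise = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!condition %in% names(config$rupture_prob_by_condition))
    cc_stop("InvalidConfig", sprintf("no rupture probability for condition '%s'", condition))
  p <- config$rupture_prob_by_condition[[condition]]
  sh <- lamina_shapes[[condition]]
  set.seed(config$seed)
  ruptured <- stats::runif(n) < p
  span <- stats::runif(n, config$gap_span_range_deg[1], config$gap_span_range_deg[2])
  tip <- stats::runif(n) < config$p_tip_localized
  center <- ifelse(tip, 0, stats::runif(n, 60, 300))
  span[!ruptured] <- 0
  stills <- vector("list", n)
  for (i in seq_len(n)) {
    stills[[i]] <- render_lamina_nucleus(sh["a"], sh["b"],
                                         gap_span_deg = span[i],
                                         gap_center_deg = center[i],
                                         config = config, noise = noise)
  }
  list(stills = stills,
       truth = data.frame(nucleus_id = seq_len(n), condition = condition,
                          ruptured = ruptured, gap_span_deg = span,
                          gap_center_deg = ifelse(ruptured, center, NA_real_),
                          tip_localized = ifelse(ruptured, tip, NA)))
}
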