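# Shared fixtures. Expensive synthetic cohorts are computed lazily and
# cached for the whole test run so several test files can share them.

.cc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cc_cache[[key]])) .cc_cache[[key]] <- force(expr)
  .cc_cache[[key]]
}

# A rasterized disk mask of radius r px.
disk_mask <- function(r, n = 2 * r + 9) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

square_mask <- function(s = 20, n = s + 20) {
  m <- matrix(FALSE, n, n)
  o <- floor((n - s) / 2)
  m[o + seq_len(s), o + seq_len(s)] <- TRUE
  m
}

# Small default-geometry config for rendering tests.
small_config <- function(width = 2, seed = 1, n_frames = 80, ...) {
  synth_config(geometry = default_geometry(width), n_frames = n_frames,
               seed = seed, ...)
}

# Geometry with extra upstream run-in for enrichment baselines.
enrichment_config <- function(width = 2, seed = 13, ...) {
  g <- channel_geometry(7, width, 15, 65, 0.325, 1, channel_height_um = 5)
  synth_config(geometry = g, image_shape = c(64L, 320L), n_frames = 80,
               seed = seed, ...)
}

# Cached measured cohorts at the cohort sizes used by the calibration
# recovery checks (shared between the event/kinematics tests and the
# acceptance suite).
passage_cohort <- function(width, n, seed) {
  cached(sprintf("passage_%s_%d_%d", width, n, seed),
         run_cohort(small_config(width, seed = seed), n = n,
                    metrics = "kinematics"))
}
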