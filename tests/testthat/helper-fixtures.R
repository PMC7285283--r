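# Shared fixtures: small scenes and hand-built skeletons.

small_scene_config <- function(seed = 1L, n_fibers = 6L, ...) {
  fiber_scene_config(image_shape = c(160L, 160L), cell_radius_px = 65,
                     n_fibers = n_fibers, fiber_length_px = 60,
                     seed = seed, ...)
}

# skeleton_network from a plain intensity vector (geometry irrelevant)
skeleton_from_intensities <- function(x, pixel_size_um = 0.124) {
  n <- length(x)
  skeleton_network(cbind(rep(1L, n), seq_len(n)), x,
                   pixel_size_um = pixel_size_um, dim = c(1L, max(n, 1L)))
}

# straight horizontal fiber scene rendered directly (no random walk):
# a single polyline across the middle of the image
straight_fiber_scene <- function(len = 100, width = 3, intensity = 600,
                                 shape = c(64L, 160L), psf = 1,
                                 background = 50, seed = 1L) {
  cfg <- fiber_scene_config(image_shape = shape, cell_radius_px = 75,
                            n_fibers = 1L, fiber_width_px = width,
                            fiber_length_px = len, curve_turn_sd_rad = 0,
                            fiber_intensity = intensity,
                            background_level = background,
                            psf_sigma_px = psf, seed = seed)
  sc <- generate_fiber_scene(cfg)
  r0 <- shape[1L] / 2
  c0 <- (shape[2L] - len) / 2
  pts <- cbind(rep(r0, 2), c(c0, c0 + len))
  sc$polylines <- list(pts)
  sc$backbones <- list(pts)
  sc$bundle_ids <- 1L
  sc$per_polyline_intensity <- intensity
  sc$true_total_length_um <- len * cfg$pixel_size_um
  sc$true_apparent_length_um <- len * cfg$pixel_size_um
  sc$mask <- mask_image(matrix(TRUE, shape[1L], shape[2L]))
  sc
}

# binary matrix -> skeleton_network with unit intensities
skeleton_from_binary <- function(B, pixel_size_um = 1) {
  px <- which(B, arr.ind = TRUE)
  ord <- order(px[, 2L], px[, 1L])
  px <- px[ord, , drop = FALSE]
  skeleton_network(px, rep(1, nrow(px)), pixel_size_um, dim(B))
}

# naive loop oracles for the four features
oracle_features <- function(x, pixel_size_um, n_px = length(x)) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s2 <- 0
  for (v in x) s2 <- s2 + (v - m)^2
  sig <- sqrt(s2 / length(x))
  s3 <- 0
  for (v in x) s3 <- s3 + ((v - m) / sig)^3
  list(total_length_mm = n_px * pixel_size_um * 1e-3,
       mean = m, sd = sig, cv = sig / m, skew = s3 / length(x))
}
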