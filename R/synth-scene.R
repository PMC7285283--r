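#' Configuration for a synthetic fibril scene
#'
#' Describes a synthetic fluorescence scene: a disc-shaped cell projection
#' (the top view of a protoplast) carrying a network of curvilinear fibers.
#' Fibers are grouped into bundles of `bundling_factor` fibers that share a
#' common backbone, so increasing `bundling_factor` at fixed `n_fibers`
#' concentrates the same total fluorophore into fewer, brighter lines —
#' the construct behind CV/skewness as bundling metrics.
#'
#' Defaults emulate a x100 / NA 1.30 confocal acquisition of a protoplast of
#' radius ~14 um: 256 x 256 px at 0.124 um/px, cell radius 110 px, with
#' Poisson shot noise and mild Gaussian read noise.
#'
#' @param image_shape Integer vector (rows, cols).
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param cell_radius_px Radius of the disc-shaped projection region, px.
#' @param n_fibers Number of fibers (>= 0).
#' @param bundling_factor Integer b >= 1; fibers per bundle. Must not exceed
#'   `max(n_fibers, 1)`.
#' @param fiber_intensity Expected photons per pixel of arc length per fiber.
#' @param fiber_width_px Rendered full width of a fiber, px (>= 1).
#' @param fiber_length_px Target arc length of each fiber backbone, px.
#' @param curve_step_px Step length of the random-walk backbone, px.
#' @param curve_turn_sd_rad SD of the per-step heading increment, radians.
#' @param background_level Uniform background, photons per pixel.
#' @param psf_sigma_px Gaussian PSF sigma, px (0 = no blur).
#' @param read_noise_sd SD of additive Gaussian read noise, counts.
#' @param n_dot_artifacts Number of bright dot (callose-like) artifacts.
#' @param dot_radius_px Radius of each dot artifact, px.
#' @param dot_intensity Peak added intensity of each dot, counts.
#' @param bit_depth Sensor bit depth; rendered images clip at 2^bit_depth - 1.
#' @param seed Integer seed; the scene and its rendering are fully
#'   deterministic given the config.
#' @return Object of class `fiber_scene_config`.
#' @export
fiber_scene_config <- function(image_shape = c(256L, 256L),
                               pixel_size_um = 0.124,
                               cell_radius_px = 110,
                               n_fibers = 16L,
                               bundling_factor = 1L,
                               fiber_intensity = 600,
                               fiber_width_px = 3,
                               fiber_length_px = 120,
                               curve_step_px = 4,
                               curve_turn_sd_rad = 0.25,
                               background_level = 50,
                               psf_sigma_px = 1,
                               read_noise_sd = 3,
                               n_dot_artifacts = 0L,
                               dot_radius_px = 4,
                               dot_intensity = 1500,
                               bit_depth = 16L,
                               seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape),
              pixel_size_um = pixel_size_um,
              cell_radius_px = cell_radius_px,
              n_fibers = as.integer(n_fibers),
              bundling_factor = as.integer(bundling_factor),
              fiber_intensity = fiber_intensity,
              fiber_width_px = fiber_width_px,
              fiber_length_px = fiber_length_px,
              curve_step_px = curve_step_px,
              curve_turn_sd_rad = curve_turn_sd_rad,
              background_level = background_level,
              psf_sigma_px = psf_sigma_px,
              read_noise_sd = read_noise_sd,
              n_dot_artifacts = as.integer(n_dot_artifacts),
              dot_radius_px = dot_radius_px,
              dot_intensity = dot_intensity,
              bit_depth = as.integer(bit_depth),
              seed = as.integer(seed))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    stop_cwrq("image_shape must be two integers >= 8", "cwrq_config_error")
  check_number(cfg$pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  check_number(cfg$cell_radius_px, "cell_radius_px", 0, strict = TRUE)
  check_number(cfg$n_fibers, "n_fibers", 0)
  check_number(cfg$bundling_factor, "bundling_factor", 1)
  if (cfg$bundling_factor > max(cfg$n_fibers, 1L))
    stop_cwrq("bundling_factor must be <= max(n_fibers, 1)",
              "cwrq_config_error")
  check_number(cfg$fiber_intensity, "fiber_intensity", 0, strict = TRUE)
  check_number(cfg$fiber_width_px, "fiber_width_px", 1)
  check_number(cfg$fiber_length_px, "fiber_length_px", 0, strict = TRUE)
  check_number(cfg$curve_step_px, "curve_step_px", 0, strict = TRUE)
  check_number(cfg$curve_turn_sd_rad, "curve_turn_sd_rad", 0)
  check_number(cfg$background_level, "background_level", 0)
  check_number(cfg$psf_sigma_px, "psf_sigma_px", 0)
  check_number(cfg$read_noise_sd, "read_noise_sd", 0)
  check_number(cfg$n_dot_artifacts, "n_dot_artifacts", 0)
  check_number(cfg$dot_radius_px, "dot_radius_px", 0, strict = TRUE)
  check_number(cfg$dot_intensity, "dot_intensity", 0)
  structure(cfg, class = "fiber_scene_config")
}

# Uniform random point in a disc of radius r around (0, 0).
runif_disc <- function(r) {
  a <- stats::runif(1, 0, 2 * pi)
  d <- r * sqrt(stats::runif(1))
  c(d * cos(a), d * sin(a))
}

# Bounded-curvature random-walk polyline inside a disc of radius `r_max`
# centred at the origin; reflected at the boundary. Returns n x 2 (row, col)
# offsets from the disc centre.
walk_polyline <- function(n_steps, step, turn_sd, r_max) {
  p <- runif_disc(0.9 * r_max)
  theta <- stats::runif(1, 0, 2 * pi)
  turns <- stats::rnorm(n_steps, 0, turn_sd)
  pts <- matrix(0, n_steps + 1L, 2L)
  pts[1L, ] <- p
  for (i in seq_len(n_steps)) {
    theta <- theta + turns[i]
    v <- c(cos(theta), sin(theta))
    q <- p + step * v
    if (sum(q^2) > r_max^2) {
      nhat <- p / sqrt(sum(p^2) + 1e-12)
      v <- v - 2 * sum(v * nhat) * nhat
      theta <- atan2(v[2L], v[1L])
      q <- p + step * v
      if (sum(q^2) > r_max^2) {         # grazing corner: head inward
        v <- -nhat
        theta <- atan2(v[2L], v[1L])
        q <- p + step * v
      }
    }
    pts[i + 1L, ] <- q
    p <- q
  }
  pts
}

#' Generate a synthetic fibril scene with known ground truth
#'
#' Draws `ceil(n_fibers / b)` bundle backbones as bounded-curvature random
#' walks inside the disc-shaped cell region, then lays `b` fibers on each
#' backbone with sub-pixel lateral jitter smaller than the fiber width.
#' Because each fiber carries the same photons per unit length, bundling
#' concentrates fluorophore into fewer, brighter lines while leaving the
#' total fluorophore unchanged.
#'
#' Two ground-truth lengths are recorded: `true_total_length_um` counts
#' every fiber (total fluorophore), and `true_apparent_length_um` counts
#' each bundle backbone once (the apparent network length a skeleton-based
#' measurement can recover, since co-bundled fibers are unresolvable).
#'
#' @param config A [fiber_scene_config()].
#' @return Object of class `fiber_scene`: polylines, per-polyline intensity,
#'   bundle ids, dot-artifact centres, disc mask, both ground-truth lengths,
#'   and the config.
#' @export
generate_fiber_scene <- function(config) {
  stopifnot(inherits(config, "fiber_scene_config"))
  cfg <- config
  margin <- cfg$fiber_width_px / 2 + 2
  r_eff <- cfg$cell_radius_px - margin
  n_bundles <- if (cfg$n_fibers == 0L) 0L
               else as.integer(ceiling(cfg$n_fibers / cfg$bundling_factor))
  if (cfg$n_fibers > 0L && r_eff < cfg$curve_step_px)
    stop_cwrq("cell_radius_px too small to place fibers",
              "cwrq_placement_error")
  ctr <- (cfg$image_shape + 1) / 2
  n_steps <- max(1L, as.integer(round(cfg$fiber_length_px / cfg$curve_step_px)))

  out <- with_seed(cfg$seed, {
    backbones <- vector("list", n_bundles)
    for (k in seq_len(n_bundles))
      backbones[[k]] <- walk_polyline(n_steps, cfg$curve_step_px,
                                      cfg$curve_turn_sd_rad, r_eff)
    bundle_ids <- if (cfg$n_fibers > 0L)
      rep(seq_len(n_bundles), each = cfg$bundling_factor)[seq_len(cfg$n_fibers)]
    else integer(0)
    polylines <- vector("list", cfg$n_fibers)
    for (j in seq_len(cfg$n_fibers)) {
      jmag <- stats::runif(1, 0, 0.35 * cfg$fiber_width_px)
      jang <- stats::runif(1, 0, 2 * pi)
      off <- jmag * c(cos(jang), sin(jang))
      bb <- backbones[[bundle_ids[j]]]
      polylines[[j]] <- sweep(bb, 2L, ctr + off, "+")
    }
    backbones <- lapply(backbones, function(b) sweep(b, 2L, ctr, "+"))
    dots <- if (cfg$n_dot_artifacts > 0L) {
      t(vapply(seq_len(cfg$n_dot_artifacts),
               function(i) runif_disc(0.85 * cfg$cell_radius_px) + ctr,
               numeric(2)))
    } else matrix(numeric(0), 0L, 2L)
    list(backbones = backbones, polylines = polylines,
         bundle_ids = bundle_ids, dots = dots)
  })

  rr <- matrix(seq_len(cfg$image_shape[1L]), cfg$image_shape[1L],
               cfg$image_shape[2L])
  cc <- matrix(seq_len(cfg$image_shape[2L]), cfg$image_shape[1L],
               cfg$image_shape[2L], byrow = TRUE)
  disc <- (rr - ctr[1L])^2 + (cc - ctr[2L])^2 <= cfg$cell_radius_px^2

  fiber_len_px <- vapply(out$polylines, polyline_length, numeric(1))
  backbone_len_px <- vapply(out$backbones, polyline_length, numeric(1))
  structure(list(
    polylines = out$polylines,
    backbones = out$backbones,
    bundle_ids = out$bundle_ids,
    per_polyline_intensity = rep(cfg$fiber_intensity, cfg$n_fibers),
    dots = out$dots,
    mask = mask_image(disc),
    true_total_length_um = sum(fiber_len_px) * cfg$pixel_size_um,
    true_apparent_length_um = sum(backbone_len_px) * cfg$pixel_size_um,
    config = cfg), class = "fiber_scene")
}

#' @export
print.fiber_scene <- function(x, ...) {
  cat(sprintf(paste0("<fiber_scene> %d fibers in %d bundles (b = %d), ",
                     "apparent length %.1f um, total fluorophore length %.1f um\n"),
              length(x$polylines), length(x$backbones),
              x$config$bundling_factor,
              x$true_apparent_length_um, x$true_total_length_um))
  invisible(x)
}

# Deposit polyline mass into an accumulator by densifying each segment and
# bilinearly splatting intensity * arc-length weights; exact in total mass.
splat_polylines <- function(shape, polylines, intensities, step = 0.25) {
  acc <- matrix(0, shape[1L], shape[2L])
  if (length(polylines) == 0L) return(acc)
  rs <- list(); cs <- list(); ws <- list(); n <- 0L
  for (j in seq_along(polylines)) {
    pts <- polylines[[j]]
    if (nrow(pts) < 2L) next
    seg <- diff(pts)
    len <- sqrt(rowSums(seg^2))
    for (i in seq_len(nrow(seg))) {
      if (len[i] == 0) next
      k <- max(1L, ceiling(len[i] / step))
      t <- (seq_len(k) - 0.5) / k
      n <- n + 1L
      rs[[n]] <- pts[i, 1L] + t * seg[i, 1L]
      cs[[n]] <- pts[i, 2L] + t * seg[i, 2L]
      ws[[n]] <- rep(intensities[j] * len[i] / k, k)
    }
  }
  if (n == 0L) return(acc)
  r <- unlist(rs); c <- unlist(cs); w <- unlist(ws)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  nr <- shape[1L]; nc <- shape[2L]
  dep <- function(ri, ci, wi) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & wi > 0
    if (!any(ok)) return(invisible())
    idx <- (ci[ok] - 1) * nr + ri[ok]
    tab <- rowsum(wi[ok], idx)
    acc[as.numeric(rownames(tab))] <<- acc[as.numeric(rownames(tab))] + tab[, 1L]
    invisible()
  }
  dep(r0,     c0,     w * (1 - fr) * (1 - fc))
  dep(r0 + 1, c0,     w * fr       * (1 - fc))
  dep(r0,     c0 + 1, w * (1 - fr) * fc)
  dep(r0 + 1, c0 + 1, w * fr       * fc)
  acc
}

# Normalised disc kernel of the given full width (area-sampled, sums to 1),
# used to spread centreline mass across the rendered fiber width without
# changing the total fluorophore.
disc_kernel <- function(width_px, oversample = 7L) {
  radius <- width_px / 2
  h <- ceiling(radius + 0.5)
  n <- 2L * h + 1L
  off <- seq(-h, h)
  sub <- (seq_len(oversample) - (oversample + 1) / 2) / oversample
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- off[i] + sub; dc <- off[j] + sub
    K[i, j] <- mean(outer(dr^2, dc^2, "+") <= radius^2)
  }
  K / sum(K)
}

# Anti-aliased disc (coverage in [0,1]) added at centre (r0, c0).
add_disc <- function(img, r0, c0, radius, peak) {
  h <- ceiling(radius + 1)
  rs <- max(1L, floor(r0 - h)):min(nrow(img), ceiling(r0 + h))
  cs <- max(1L, floor(c0 - h)):min(ncol(img), ceiling(c0 + h))
  d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, "+"))
  img[rs, cs] <- img[rs, cs] + peak * pmin(pmax(radius + 0.5 - d, 0), 1)
  img
}

#' Render a synthetic fibril scene to an image
#'
#' Rasterises each fiber as an anti-aliased line of width `fiber_width_px`
#' carrying `fiber_intensity` photons per pixel of arc length, adds bright
#' dot artifacts (to exercise masking), convolves with the Gaussian PSF,
#' adds uniform background, and (optionally) applies Poisson shot noise and
#' Gaussian read noise before clipping to the sensor range. The pre-noise
#' integrated fiber signal equals `fiber_intensity x total fiber arc
#' length`, independent of the bundling factor (fluorophore conservation).
#'
#' @param scene A [fiber_scene()][generate_fiber_scene()].
#' @param noise Apply the sensor noise model? `FALSE` returns the expected
#'   (pre-noise) image; useful for calibration and testing.
#' @return An [image2d()]; with `noise = TRUE` values are integer counts.
#' @export
render_scene <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "fiber_scene"))
  cfg <- scene$config
  img <- splat_polylines(cfg$image_shape, scene$polylines,
                         scene$per_polyline_intensity)
  if (cfg$fiber_width_px > 1) {
    K <- disc_kernel(cfg$fiber_width_px)
    img <- as.matrix(EBImage::filter2(img, K, boundary = 0))
  }
  if (nrow(scene$dots) > 0L)
    for (i in seq_len(nrow(scene$dots)))
      img <- add_disc(img, scene$dots[i, 1L], scene$dots[i, 2L],
                      cfg$dot_radius_px, cfg$dot_intensity)
  if (cfg$psf_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = cfg$psf_sigma_px))
  img <- img + cfg$background_level
  img <- pmax(img, 0)
  sensor_max <- 2^cfg$bit_depth - 1
  if (noise) {
    img <- with_seed(cfg$seed + 1L, {
      shot <- matrix(stats::rpois(length(img), lambda = img),
                     nrow(img), ncol(img))
      if (cfg$read_noise_sd > 0)
        shot <- shot + matrix(stats::rnorm(length(img), 0, cfg$read_noise_sd),
                              nrow(img), ncol(img))
      shot
    })
    img <- round(img)
  }
  img <- pmin(pmax(img, 0), sensor_max)
  image2d(img, pixel_size_um = cfg$pixel_size_um)
}

#' Simulate an osmotic-stability rupture count
#'
#' Models the osmotic challenge assay: `n_cells` intact protoplasts are
#' counted before the osmotic downshift (N0) and each survives the 30-min
#' incubation independently with probability `p_survive`, giving
#' N30 ~ Binomial(N0, p_survive).
#'
#' @param p_survive Per-cell survival probability in \[0, 1\].
#' @param n_cells Number of protoplasts counted before the shift (> 0).
#' @param condition Optional condition label.
#' @param seed Integer seed.
#' @return A [stability_record()].
#' @export
simulate_rupture_counts <- function(p_survive, n_cells, condition = NA_character_,
                                    seed = NULL) {
  check_number(p_survive, "p_survive", 0)
  if (p_survive > 1)
    stop_cwrq("`p_survive` must be in [0, 1]", "cwrq_config_error")
  check_number(n_cells, "n_cells", 0, strict = TRUE)
  n30 <- with_seed(seed, stats::rbinom(1L, as.integer(n_cells), p_survive))
  stability_record(n0 = as.integer(n_cells), n30 = n30, condition = condition)
}

#' Write a scene, its rendering, mask and ground truth to a directory
#'
#' Writes `image.tif` (16-bit), `mask.png` (255 = keep) and `truth.json`
#' (polylines, lengths, bundle ids, config, seed).
#'
#' @param scene A fiber scene.
#' @param dir Output directory (created if needed).
#' @param noise Passed to [render_scene()].
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, noise = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- render_scene(scene, noise = noise)
  write_image_tiff(img, file.path(dir, "image.tif"))
  write_mask_png(scene$mask, file.path(dir, "mask.png"))
  truth <- list(true_total_length_um = scene$true_total_length_um,
                true_apparent_length_um = scene$true_apparent_length_um,
                bundle_ids = scene$bundle_ids,
                polylines = lapply(scene$polylines, function(p)
                  list(row = p[, 1L], col = p[, 2L])),
                config = unclass(scene$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
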