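#' Configuration for a synthetic SEM-like fiber image
#'
#' High-resolution (nanometre-calibrated) scene of fiber ribbons whose full
#' rasterised widths are drawn from a Gaussian mixture of diameters. The
#' default mixture puts its mode in the 20-30 nm bin, the range reported as
#' most abundant for bundled cellulose microfibrils on regenerating
#' protoplast surfaces.
#'
#' @param image_shape Integer (rows, cols); default 640 x 640.
#' @param nm_per_px Nanometres per pixel (> 0), default 2 (a 512 px
#'   frame then spans ~1 um, matching high-magnification fields with a
#'   500 nm scale bar).
#' @param n_fibers Number of fiber ribbons (>= 1).
#' @param diameter_mixture List of mixture components, each
#'   `c(mean_nm, sd_nm, weight)`; weights must sum to 1.
#' @param fg_level,bg_level Foreground / background gray levels in \[0, 1\].
#' @param noise_sd SD of additive Gaussian noise on the gray levels.
#' @param curve_step_px,curve_turn_sd_rad Random-walk backbone parameters.
#' @param length_frac Fiber length as a fraction of the larger image side.
#' @param seed Integer seed.
#' @return Object of class `sem_scene_config`.
#' @export
sem_scene_config <- function(image_shape = c(640L, 640L),
                             nm_per_px = 2,
                             n_fibers = 40L,
                             diameter_mixture = list(c(25, 3.5, 0.6),
                                                     c(15, 2.5, 0.2),
                                                     c(40, 7,   0.2)),
                             fg_level = 0.8,
                             bg_level = 0.15,
                             noise_sd = 0.04,
                             curve_step_px = 8,
                             curve_turn_sd_rad = 0.12,
                             length_frac = 0.2,
                             seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape), nm_per_px = nm_per_px,
              n_fibers = as.integer(n_fibers),
              diameter_mixture = diameter_mixture,
              fg_level = fg_level, bg_level = bg_level, noise_sd = noise_sd,
              curve_step_px = curve_step_px,
              curve_turn_sd_rad = curve_turn_sd_rad,
              length_frac = length_frac,
              seed = as.integer(seed))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 16L))
    stop_cwrq("image_shape must be two integers >= 16", "cwrq_config_error")
  check_number(cfg$nm_per_px, "nm_per_px", 0, strict = TRUE)
  check_number(cfg$n_fibers, "n_fibers", 1)
  w <- vapply(cfg$diameter_mixture, function(m) m[3L], numeric(1))
  mu <- vapply(cfg$diameter_mixture, function(m) m[1L], numeric(1))
  sd <- vapply(cfg$diameter_mixture, function(m) m[2L], numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    stop_cwrq("mixture weights must sum to 1", "cwrq_config_error")
  if (any(mu <= 0) || any(sd < 0) || any(w < 0))
    stop_cwrq("mixture components must have mean > 0, sd >= 0, weight >= 0",
              "cwrq_config_error")
  check_number(cfg$fg_level, "fg_level", 0); check_number(cfg$bg_level, "bg_level", 0)
  check_number(cfg$noise_sd, "noise_sd", 0)
  check_number(cfg$curve_step_px, "curve_step_px", 0, strict = TRUE)
  check_number(cfg$curve_turn_sd_rad, "curve_turn_sd_rad", 0)
  check_number(cfg$length_frac, "length_frac", 0, strict = TRUE)
  structure(cfg, class = "sem_scene_config")
}

# Coverage-rasterise a ribbon of full width `d_px` around a polyline into
# `cov` (values in [0, 1]); edge anti-aliased over one pixel.
rasterize_ribbon <- function(cov, pts, d_px) {
  half <- d_px / 2
  pad <- half + 1.5
  nr <- nrow(cov); nc <- ncol(cov)
  seg <- diff(pts)
  for (i in seq_len(nrow(seg))) {
    p <- pts[i, ]; v <- seg[i, ]
    L2 <- sum(v^2)
    if (L2 == 0) next
    r_lo <- max(1L, floor(min(p[1L], p[1L] + v[1L]) - pad))
    r_hi <- min(nr, ceiling(max(p[1L], p[1L] + v[1L]) + pad))
    c_lo <- max(1L, floor(min(p[2L], p[2L] + v[2L]) - pad))
    c_hi <- min(nc, ceiling(max(p[2L], p[2L] + v[2L]) + pad))
    if (r_lo > r_hi || c_lo > c_hi) next
    rs <- r_lo:r_hi; cs <- c_lo:c_hi
    gr <- matrix(rs, length(rs), length(cs)) - p[1L]
    gc <- matrix(cs, length(rs), length(cs), byrow = TRUE) - p[2L]
    t <- pmin(pmax((gr * v[1L] + gc * v[2L]) / L2, 0), 1)
    d <- sqrt((gr - t * v[1L])^2 + (gc - t * v[2L])^2)
    a <- pmin(pmax(half + 0.5 - d, 0), 1)
    cov[rs, cs] <- pmax(cov[rs, cs], a)
  }
  cov
}

#' Generate a synthetic SEM-like image with known fiber diameters
#'
#' Draws `n_fibers` gently curving ribbons whose full rasterised width (in
#' pixels) equals the drawn diameter divided by `nm_per_px`, composited by
#' maximum coverage onto a uniform background, plus Gaussian noise.
#'
#' @param config A [sem_scene_config()].
#' @return List with `image` (an [image2d()], pixel size `nm_per_px / 1000`
#'   um) and `true_diameters_nm` (one diameter per fiber).
#' @export
generate_sem_image <- function(config) {
  stopifnot(inherits(config, "sem_scene_config"))
  cfg <- config
  mu <- vapply(cfg$diameter_mixture, function(m) m[1L], numeric(1))
  sdv <- vapply(cfg$diameter_mixture, function(m) m[2L], numeric(1))
  w <- vapply(cfg$diameter_mixture, function(m) m[3L], numeric(1))
  shp <- cfg$image_shape
  with_seed(cfg$seed, {
    comp <- sample.int(length(w), cfg$n_fibers, replace = TRUE, prob = w)
    diam <- stats::rnorm(cfg$n_fibers, mu[comp], sdv[comp])
    diam <- pmax(diam, 1e-6)
    if (any(diam / cfg$nm_per_px < 1))
      stop_cwrq(paste0("drawn fiber diameter below 1 px at ", cfg$nm_per_px,
                       " nm/px; unresolvable"), "cwrq_config_error")
    cov <- matrix(0, shp[1L], shp[2L])
    n_steps <- max(2L, as.integer(round(cfg$length_frac * max(shp) / cfg$curve_step_px)))
    draw_polyline <- function() {
      start <- c(stats::runif(1, 0.1, 0.9) * shp[1L],
                 stats::runif(1, 0.1, 0.9) * shp[2L])
      theta <- stats::runif(1, 0, 2 * pi)
      pts <- matrix(0, n_steps + 1L, 2L)
      pts[1L, ] <- start
      for (i in seq_len(n_steps)) {
        theta <- theta + stats::rnorm(1, 0, cfg$curve_turn_sd_rad)
        pts[i + 1L, ] <- pts[i, ] + cfg$curve_step_px * c(cos(theta), sin(theta))
      }
      pts
    }
    # the scene exists to validate width measurement, so each fiber must be
    # individually measurable: reject centrelines that mostly run on top of
    # already-placed ribbons (bounded retries keep generation deterministic)
    overlap_frac <- function(pts) {
      ri <- pmin(pmax(round(pts[, 1L]), 1L), shp[1L])
      ci <- pmin(pmax(round(pts[, 2L]), 1L), shp[2L])
      mean(cov[cbind(ri, ci)] > 0.3)
    }
    for (j in seq_len(cfg$n_fibers)) {
      best <- NULL; best_ov <- Inf
      for (try in seq_len(20L)) {
        pts <- draw_polyline()
        ov <- overlap_frac(pts)
        if (ov < best_ov) { best <- pts; best_ov <- ov }
        if (ov <= 0.15) break
      }
      cov <- rasterize_ribbon(cov, best, diam[j] / cfg$nm_per_px)
    }
    img <- cfg$bg_level + (cfg$fg_level - cfg$bg_level) * cov
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                          shp[1L], shp[2L])
    img <- pmin(pmax(img, 0), 1)
    list(image = image2d(img, pixel_size_um = cfg$nm_per_px / 1000),
         true_diameters_nm = diam)
  })
}
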