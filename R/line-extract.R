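#' Parameters for curvilinear line extraction
#'
#' Parameter vocabulary of the skeletonisation stage: iterative Gaussian
#' smoothing (`giws_iter`), directional non-maximum suppression over a short
#' segment across the ridge (`mdnms_len`), above-threshold pickup, spur
#' shaving (`shave_len`) and short-component deletion (`del_len`). Defaults
#' are the settings used for Calcofluor/immunolabel projections of
#' regenerating protoplast walls: giws_iter = 2, mdnms_len = 3,
#' pickup = "above", shave_len = 5, del_len = 5.
#'
#' `ridge_sigma_px` is the derivative scale of the Hessian ridge filter and
#' `threshold_k` sets the automatic response threshold at
#' mean + k * sd of the in-mask ridge response; both are exposed because no
#' canonical values exist for them.
#'
#' @param giws_iter Smoothing iterations (>= 0), default 2.
#' @param mdnms_len Non-maximum-suppression support length in px, default 3.
#' @param pickup Threshold mode; only `"above"` (keep responses above the
#'   automatic threshold) is defined.
#' @param shave_len Prune terminal branches shorter than this many px,
#'   default 5.
#' @param del_len Delete connected skeleton components shorter than this
#'   many px, default 5.
#' @param ridge_sigma_px Gaussian derivative scale in px, default 1.5.
#' @param threshold_k Threshold multiplier k, default 3.5; at the default
#'   the threshold sits far enough above the background ridge response that
#'   shot-noise ridges (whose tail a 2-sigma cut would admit in the tens of
#'   thousands of background pixels of a typical field) do not enter the
#'   skeleton.
#' @return Object of class `line_extract_params`.
#' @export
line_extract_params <- function(giws_iter = 2L, mdnms_len = 3L,
                                pickup = "above", shave_len = 5L,
                                del_len = 5L, ridge_sigma_px = 1.5,
                                threshold_k = 3.5) {
  if (!identical(pickup, "above"))
    stop_cwrq("only pickup = \"above\" is supported", "cwrq_config_error")
  p <- list(giws_iter = as.integer(giws_iter),
            mdnms_len = as.integer(mdnms_len), pickup = pickup,
            shave_len = as.integer(shave_len), del_len = as.integer(del_len),
            ridge_sigma_px = ridge_sigma_px, threshold_k = threshold_k)
  check_number(p$giws_iter, "giws_iter", 0)
  check_number(p$mdnms_len, "mdnms_len", 0)
  check_number(p$shave_len, "shave_len", 0)
  check_number(p$del_len, "del_len", 0)
  check_number(p$ridge_sigma_px, "ridge_sigma_px", 0, strict = TRUE)
  check_number(p$threshold_k, "threshold_k", -Inf)
  structure(p, class = "line_extract_params")
}

#' One-pixel skeleton of a curvilinear network
#'
#' Holds the skeleton pixel coordinates, the source-image intensity sampled
#' at each skeleton pixel (the per-pixel sample whose mean, CV and skewness
#' are the network features), the pixel calibration and the image shape.
#' `n_pixels` is the skeleton pixel count from which total length is
#' computed.
#'
#' @param pixels Integer n x 2 matrix of (row, col) skeleton coordinates
#'   (1-based).
#' @param intensities Numeric vector, source intensity at each pixel.
#' @param pixel_size_um Micrometres per pixel (> 0), or `NA` if unknown.
#' @param dim Integer (rows, cols) of the source image.
#' @return Object of class `skeleton_network`.
#' @export
skeleton_network <- function(pixels, intensities, pixel_size_um, dim) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (length(intensities) != nrow(pixels))
    stop_cwrq("one intensity per skeleton pixel required", "cwrq_format_error")
  structure(list(pixels = pixels, intensities = as.numeric(intensities),
                 pixel_size_um = pixel_size_um, dim = as.integer(dim),
                 n_pixels = nrow(pixels)),
            class = "skeleton_network")
}

#' @export
print.skeleton_network <- function(x, ...) {
  cat(sprintf("<skeleton_network> %d px (%d x %d image, %.4g um/px)\n",
              x$n_pixels, x$dim[1L], x$dim[2L], x$pixel_size_um))
  invisible(x)
}

#' @export
plot.skeleton_network <- function(x, image = NULL, ...) {
  if (!is.null(image)) plot(image, ...)
  else {
    graphics::plot(NA, xlim = c(1, x$dim[2L]), ylim = c(x$dim[1L], 1),
                   xlab = "col", ylab = "row", asp = 1, ...)
  }
  if (!is.null(image)) {
    nr <- x$dim[1L]; nc <- x$dim[2L]
    graphics::points((x$pixels[, "col"] - 1) / (nc - 1),
                     1 - (x$pixels[, "row"] - 1) / (nr - 1),
                     pch = ".", col = "red")
  } else {
    graphics::points(x$pixels[, "col"], x$pixels[, "row"], pch = ".",
                     col = "red")
  }
  invisible(x)
}

# Binary skeleton matrix from a skeleton_network.
skeleton_matrix <- function(sk) {
  B <- matrix(FALSE, sk$dim[1L], sk$dim[2L])
  if (sk$n_pixels > 0L) B[sk$pixels] <- TRUE
  B
}

# Hessian of a smoothed image by central differences; returns the minimum
# eigenvalue (principal curvature) and its eigenvector direction class
# (1..4 for normals ~ E, SE, S, SW in (dr, dc) terms).
ridge_response_dir <- function(sm) {
  Ixx <- shift_mat(sm, 0, -1) - 2 * sm + shift_mat(sm, 0, 1)
  Iyy <- shift_mat(sm, -1, 0) - 2 * sm + shift_mat(sm, 1, 0)
  Ixy <- (shift_mat(sm, -1, -1) + shift_mat(sm, 1, 1) -
          shift_mat(sm, -1, 1) - shift_mat(sm, 1, -1)) / 4
  tr <- Ixx + Iyy
  disc <- sqrt((Ixx - Iyy)^2 + 4 * Ixy^2)
  lam2 <- (tr - disc) / 2
  lam1 <- (tr + disc) / 2
  R <- -lam2   # signed: positive on bright ridges, negative on flanks
  # anisotropy (lineness) weight: a line has lam1 ~ 0 >> lam2, an isotropic
  # blob (dot artifact, fiber end cap) has lam1 ~ lam2 < 0; damping the
  # response by 1 - (lam1/lam2)^2 suppresses blob rims that would otherwise
  # survive NMS as short hooks
  ratio <- pmin(pmax(-lam1, 0) / pmax(-lam2, 1e-300), 1)
  pos <- R > 0
  R[pos] <- R[pos] * (1 - ratio[pos]^2)
  # eigenvector of lam2 (direction across the ridge): pick the better-
  # conditioned of the two analytic forms
  v1r <- Ixy;        v1c <- lam2 - Iyy   # (x, y) = (col, row) components
  v2r <- lam2 - Ixx; v2c <- Ixy
  use2 <- (v2r^2 + v2c^2) > (v1r^2 + v1c^2)
  vr <- ifelse(use2, v2r, v1r)  # row component
  vc <- ifelse(use2, v2c, v1c)  # col component
  ang <- atan2(vr, vc)                  # in (-pi, pi]
  ang <- ang %% pi                      # orientation, [0, pi)
  # bins centred on 0, 45, 90, 135 degrees
  dir <- as.integer(floor(((ang + pi / 8) %% pi) / (pi / 4))) + 1L
  nrm <- sqrt(vr^2 + vc^2)
  ok <- nrm > 0
  ur <- ifelse(ok, vr / pmax(nrm, 1e-300), 0)
  uc <- ifelse(ok, vc / pmax(nrm, 1e-300), 1)
  list(R = R, dir = dir, ur = ur, uc = uc)
}

# Smoothing + Hessian ridge response + tangent pooling: the linear part of
# the detector, shared between the image and the noise-reference field.
pooled_ridge_response <- function(m, params) {
  sm <- m
  if (params$giws_iter > 0L)
    for (i in seq_len(params$giws_iter))
      sm <- as.matrix(EBImage::gblur(sm, sigma = params$ridge_sigma_px))
  rd <- ridge_response_dir(sm)
  R <- rd$R
  # border pixels have one-sided stencils; drop them
  R[c(1L, nrow(R)), ] <- 0
  R[, c(1L, ncol(R))] <- 0
  half <- max(0L, (params$mdnms_len - 1L) %/% 2L)
  tang_off <- list(c(1L, 0L), c(1L, -1L), c(0L, 1L), c(1L, 1L))
  P <- matrix(0, nrow(R), ncol(R))
  for (d in 1:4) {
    sel <- rd$dir == d
    if (!any(sel)) next
    o <- tang_off[[d]]
    acc <- R
    if (half > 0L)
      for (k in seq_len(half))
        acc <- acc + shift_mat(R,  k * o[1L],  k * o[2L], 0) +
                     shift_mat(R, -k * o[1L], -k * o[2L], 0)
    P[sel] <- acc[sel] / (2L * half + 1L)
  }
  list(P = P, dir = rd$dir)
}

#' Extract a one-pixel skeleton of the curvilinear network
#'
#' Skeletonises bright curvilinear structures in a (masked) projection
#' image with a Hessian ridge detector: (1) `giws_iter` rounds of Gaussian
#' smoothing at `ridge_sigma_px`; (2) ridge response = negative principal
#' curvature of the intensity surface; (3) directional non-maximum
#' suppression across the ridge normal with a support of `mdnms_len` px;
#' (4) keep responses above mean + `threshold_k` * sd of the in-mask
#' response; (5) morphological thinning to one pixel; (6) spur shaving and
#' short-component deletion per `shave_len` / `del_len`. Skeleton-pixel
#' intensities are sampled from the original (unsmoothed) image, because
#' the endpoints are statistics of the stain's intensity distribution, not
#' of a filtered image. The whole pipeline is deterministic.
#'
#' @param image An [image2d()] or a [apply_mask()] result; in the latter
#'   case the embedded mask is used.
#' @param mask Optional [mask_image()]; combined (intersection) with any
#'   mask carried by `image`. Excluded pixels never enter the threshold
#'   statistics, the skeleton, or the intensity sample.
#' @param params A [line_extract_params()].
#' @return A [skeleton_network()]. An empty include-mask or featureless
#'   image yields an empty skeleton, not an error.
#' @export
extract_lines <- function(image, mask = NULL,
                          params = line_extract_params()) {
  stopifnot(inherits(params, "line_extract_params"))
  if (inherits(image, "masked_image")) {
    keep <- image$keep
    m <- image$pixels
    psz <- image$pixel_size_um
  } else {
    stopifnot(inherits(image, "image2d"))
    m <- image$pixels
    psz <- image$pixel_size_um
    keep <- matrix(TRUE, nrow(m), ncol(m))
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask_image"))
    if (!identical(dim(mask$keep), dim(m)))
      stop_cwrq("mask shape does not match image", "cwrq_format_error")
    keep <- keep & mask$keep
  }
  if (any(!is.finite(m)))
    stop_cwrq("image contains non-finite pixels", "cwrq_format_error")
  empty <- skeleton_network(matrix(integer(0), 0L, 2L), numeric(0),
                            pixel_size_um = psz, dim = dim(m))
  if (!any(keep)) return(empty)

  resp <- pooled_ridge_response(m, params)
  P <- resp$P
  P[!keep] <- 0

  # suppress non-maxima across the ridge normal
  norm_off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # E SE S SW
  keep_nms <- matrix(TRUE, nrow(P), ncol(P))
  for (d in 1:4) {
    sel <- resp$dir == d
    if (!any(sel)) next
    o <- norm_off[[d]]
    fwd <- shift_mat(P,  o[1L],  o[2L], 0)
    bwd <- shift_mat(P, -o[1L], -o[2L], 0)
    keep_nms <- keep_nms & (!sel | (P >= fwd & P >= bwd))
  }

  # Automatic threshold at bg_location + k * bg_scale of the ridge
  # response. The background statistics are noise-referenced: the image
  # noise sd is estimated robustly from in-mask horizontal pixel
  # differences, a matched white-noise field (fixed internal seed, so the
  # pipeline stays deterministic) is pushed through the identical response
  # operator, and the median/MAD of its in-mask response give the
  # background location and scale. Unlike statistics of the observed
  # response, this calibration cannot be contaminated by the signal tail,
  # however dense the network.
  nc2 <- ncol(m)
  dm <- m[, -1L, drop = FALSE] - m[, -nc2, drop = FALSE]
  dk <- keep[, -1L, drop = FALSE] & keep[, -nc2, drop = FALSE]
  sigma_img <- 1.4826 * stats::median(abs(dm[dk])) / sqrt(2)
  rs <- P[keep]
  # an essentially noise-free image (synthetic renders): fall back to
  # statistics of the observed response
  if (sigma_img <= 1e-8 * max(diff(range(m)), 1e-300)) sigma_img <- 0
  if (sigma_img > 0) {
    ref <- with_seed(760001L, matrix(stats::rnorm(length(m), 0, sigma_img),
                                     nrow(m), ncol(m)))
    pref <- pooled_ridge_response(ref, params)$P[keep]
    bg_loc <- stats::median(pref)
    bg_sd <- stats::mad(pref)
  } else {
    bg_loc <- stats::median(rs)
    bg_sd <- stats::mad(rs)
  }
  # a degenerate MAD (most responses identical, e.g. exactly-flat noise-free
  # background) is no scale estimate; use the plain sd instead
  if (!is.finite(bg_sd) || bg_sd < 0.01 * stats::sd(rs))
    bg_sd <- stats::sd(rs)
  thr <- bg_loc + params$threshold_k * bg_sd
  if (!is.finite(thr)) return(empty)
  B <- P > thr & keep_nms & keep
  if (!any(B)) return(empty)
  # filling holes of a few pixels prevents thinning from preserving them as
  # doubled parallel strands (genuine network pores are far larger than 9 px)
  B <- fill_small_holes(B, max_area = 9L)
  B <- B & keep
  B <- thin_binary(B)
  B <- prune_binary(B, params$shave_len, params$del_len)
  B <- B & keep
  px <- which(B, arr.ind = TRUE)
  if (nrow(px) == 0L) return(empty)
  ord <- order(px[, 2L], px[, 1L])   # fixed raster order
  px <- px[ord, , drop = FALSE]
  skeleton_network(px, m[px], pixel_size_um = psz, dim = dim(m))
}

#' Prune a skeleton
#'
#' Removes terminal branches (the path from an endpoint to the nearest
#' junction) shorter than `shave_len` pixels, iterating until no further
#' branch qualifies, then deletes 8-connected components with fewer than
#' `del_len` pixels. With both lengths zero this is the identity. The
#' operation is idempotent at fixed parameters.
#'
#' @param skeleton A [skeleton_network()].
#' @param shave_len,del_len Pruning lengths in pixels (>= 0).
#' @return A pruned [skeleton_network()].
#' @export
prune_skeleton <- function(skeleton, shave_len = 5L, del_len = 5L) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  check_number(shave_len, "shave_len", 0)
  check_number(del_len, "del_len", 0)
  B <- skeleton_matrix(skeleton)
  int_map <- matrix(NA_real_, skeleton$dim[1L], skeleton$dim[2L])
  if (skeleton$n_pixels > 0L) int_map[skeleton$pixels] <- skeleton$intensities
  B <- prune_binary(B, shave_len, del_len)
  px <- which(B, arr.ind = TRUE)
  ord <- order(px[, 2L], px[, 1L])
  px <- px[ord, , drop = FALSE]
  skeleton_network(px, int_map[px], pixel_size_um = skeleton$pixel_size_um,
                   dim = skeleton$dim)
}

#' Serialise a skeleton to JSON
#'
#' Writes pixel coordinates (1-based row/col), intensities, calibration and
#' image shape; [read_skeleton()] restores the identical object.
#'
#' @param skeleton A [skeleton_network()].
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  jsonlite::write_json(
    list(row = skeleton$pixels[, "row"], col = skeleton$pixels[, "col"],
         intensity = skeleton$intensities,
         pixel_size_um = skeleton$pixel_size_um,
         dim = skeleton$dim, index_base = 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  skeleton_network(cbind(x$row, x$col), x$intensity,
                   pixel_size_um = x$pixel_size_um, dim = x$dim)
}
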