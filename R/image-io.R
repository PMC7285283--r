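#' Calibrated 2-D grayscale image
#'
#' Lightweight container for a single grayscale image: a numeric matrix of
#' nonnegative intensities plus the lateral pixel size in micrometres.
#' Intensities are kept in native acquisition units (e.g. 16-bit detector
#' counts); nothing in the pipeline normalises them, because the bundling
#' metrics (CV, skewness) are scale-free and mean intensity is reported in
#' acquisition units.
#'
#' @param pixels Numeric matrix of finite, nonnegative intensities.
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @return An object of class `image2d` with elements `pixels` and
#'   `pixel_size_um`.
#' @export
image2d <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_cwrq("`pixels` must be a numeric matrix", "cwrq_format_error")
  if (any(!is.finite(pixels)))
    stop_cwrq("image contains non-finite pixels", "cwrq_format_error")
  if (any(pixels < 0))
    stop_cwrq("image contains negative intensities", "cwrq_format_error")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g um/px, intensity range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.image2d <- function(x, ...) {
  m <- x$pixels
  rng <- range(m)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], zlim = rng, asp = 1,
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, ...)
  invisible(x)
}

#' Confocal z-stack
#'
#' An ordered list of equal-shape 2-D slices with axial step `z_step_um`
#' (serial optical sections, typically acquired from the top of a protoplast
#' to its equator) and lateral calibration `pixel_size_um`.
#'
#' @param slices List of numeric matrices, all of the same dimension.
#' @param pixel_size_um Lateral pixel size, micrometres per pixel.
#' @param z_step_um Axial step between slices in micrometres (default 0.5).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(slices, pixel_size_um, z_step_um = 0.5) {
  if (!is.list(slices) || length(slices) < 1L)
    stop_cwrq("`slices` must be a nonempty list of matrices",
              "cwrq_format_error")
  d <- dim(slices[[1L]])
  for (s in slices) {
    if (!is.matrix(s) || !is.numeric(s) || !identical(dim(s), d))
      stop_cwrq("all slices must be numeric matrices of the same shape",
                "cwrq_format_error")
    if (any(!is.finite(s)) || any(s < 0))
      stop_cwrq("slices must contain finite nonnegative intensities",
                "cwrq_format_error")
  }
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  check_number(z_step_um, "z_step_um", min = 0, strict = TRUE)
  structure(list(slices = slices, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("<image_stack> %d slices of %d x %d px, %.4g um/px, dz = %g um\n",
              length(x$slices), d[1L], d[2L], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

# tiff::readTIFF returns values rescaled to [0, 1]; `scale` maps them back to
# detector counts (65535 for the 16-bit images the pipeline writes).
#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an [image_stack()].
#' Pages are kept in file order. RGB or mixed-shape files are rejected.
#' Pixel values are returned as `raw * scale`, i.e. in detector counts when
#' the file was written by [write_image_tiff()].
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Lateral calibration in micrometres per pixel. TIFF
#'   rarely carries trustworthy calibration, so it is a required argument.
#' @param z_step_um Axial step in micrometres (default 0.5).
#' @param scale Factor mapping the \[0, 1\] values returned by the TIFF
#'   reader back to intensity units (default 65535, 16-bit counts).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, z_step_um = 0.5, scale = 65535) {
  if (!file.exists(path))
    stop_cwrq(sprintf("file not found: %s", path), "cwrq_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop_cwrq("multi-channel (RGB) TIFF is not supported; expected grayscale",
                "cwrq_format_error")
    if (!identical(dim(p), d))
      stop_cwrq("TIFF pages have differing shapes", "cwrq_format_error")
  }
  slices <- lapply(pages, function(p) round(p * scale, 6))
  image_stack(slices, pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}

#' Write an image (or stack) as 16-bit grayscale TIFF
#'
#' @param x An [image2d()], [image_stack()], or numeric matrix.
#' @param path Output path.
#' @param max_value Full-scale intensity mapped to 65535 (default 65535, so
#'   integer detector counts round-trip exactly).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, max_value = 65535) {
  slices <- if (inherits(x, "image_stack")) x$slices
            else if (inherits(x, "image2d")) list(x$pixels)
            else list(x)
  norm <- lapply(slices, function(s) pmin(pmax(s / max_value, 0), 1))
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  invisible(path)
}

#' Inclusion mask
#'
#' Logical matrix marking pixels to include in the analysis (`TRUE` = keep).
#' In practice masks are drawn manually to exclude background and bright
#' dot-like (callose-like) artifacts before network features are computed.
#'
#' @param keep Logical matrix (`TRUE` = analyse this pixel).
#' @return Object of class `mask_image`.
#' @export
mask_image <- function(keep) {
  if (is.numeric(keep)) keep <- keep != 0
  if (!is.matrix(keep) || !is.logical(keep))
    stop_cwrq("`keep` must be a logical matrix", "cwrq_format_error")
  if (any(is.na(keep)))
    stop_cwrq("mask contains NA", "cwrq_format_error")
  structure(list(keep = keep), class = "mask_image")
}

#' Read a mask from PNG or TIFF
#'
#' Zero-valued pixels are excluded, nonzero pixels included (the labelling
#' convention of common annotation tools).
#'
#' @param path Path to a grayscale PNG or TIFF mask.
#' @return A [mask_image()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_cwrq(sprintf("file not found: %s", path), "cwrq_io_error")
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  mask_image(m != 0)
}

#' Write a mask as 8-bit PNG (255 = keep, 0 = exclude)
#'
#' @param mask A [mask_image()].
#' @param path Output path (.png).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  png::writePNG(mask$keep * 1, path)
  invisible(path)
}

#' Maximum-intensity projection
#'
#' Collapses a z-stack to a 2-D image by taking, at every (row, col), the
#' maximum intensity across slices. This is the standard projection for
#' surface-attached fibrous signal on a curved cell: each fibril is in focus
#' in some slice, and the maximum picks that slice per pixel.
#'
#' @param stack An [image_stack()].
#' @return An [image2d()] with the stack's lateral calibration.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack$slices[[1L]]
  for (s in stack$slices[-1L]) out <- pmax(out, s)
  image2d(out, pixel_size_um = stack$pixel_size_um)
}

#' Apply an exclusion mask to an image
#'
#' Pairs an image with an inclusion mask. Excluded pixels are flagged, never
#' zeroed: zeroing would inject artificial values into the intensity
#' distribution whose CV and skewness are the endpoints of the analysis.
#' Masks compose by intersection, so a second call restricts further.
#'
#' @param image An [image2d()] or an already-masked image (composition).
#' @param mask A [mask_image()] of the same shape.
#' @return An object of class `masked_image`: list with `pixels`,
#'   `pixel_size_um`, and the logical `keep` matrix.
#' @export
apply_mask <- function(image, mask) {
  stopifnot(inherits(mask, "mask_image"))
  if (inherits(image, "masked_image")) {
    if (!identical(dim(image$pixels), dim(mask$keep)))
      stop_cwrq("mask shape does not match image", "cwrq_format_error")
    image$keep <- image$keep & mask$keep
    return(image)
  }
  stopifnot(inherits(image, "image2d"))
  if (!identical(dim(image$pixels), dim(mask$keep)))
    stop_cwrq("mask shape does not match image", "cwrq_format_error")
  structure(list(pixels = image$pixels, pixel_size_um = image$pixel_size_um,
                 keep = mask$keep),
            class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  cat(sprintf("<masked_image> %d x %d px, %.4g um/px, %d/%d px included\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$keep), length(x$keep)))
  invisible(x)
}
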