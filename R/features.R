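# Population moments (1/N), exactly as the endpoints are defined: sigma and
# skewness are computed with divisor N, not the sample-corrected N - 1.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Total network length
#'
#' Converts the skeleton pixel count (N_cellulose) to millimetres:
#' `n_pixels * pixel_size_um * 1e-3`. The conversion is a pure count times
#' calibration; no diagonal-step correction is applied, so the value is the
#' apparent network length at the image's sampling.
#'
#' @param skeleton A [skeleton_network()].
#' @return Length in mm.
#' @export
total_length <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  if (is.null(skeleton$pixel_size_um) || !is.finite(skeleton$pixel_size_um))
    stop_cwrq("skeleton carries no pixel calibration", "cwrq_calibration_error")
  skeleton$n_pixels * skeleton$pixel_size_um * 1e-3
}

#' Mean skeleton-pixel intensity
#'
#' Arithmetic mean of the source-image intensity over skeleton pixels only;
#' masked-out pixels were never admitted to the skeleton, so they cannot
#' contribute.
#'
#' @param skeleton A [skeleton_network()] with at least one pixel.
#' @return Mean intensity in acquisition units.
#' @export
mean_intensity <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  if (skeleton$n_pixels < 1L)
    stop_cwrq("mean intensity is undefined for an empty skeleton",
              "cwrq_undefined_feature")
  mean(skeleton$intensities)
}

#' Coefficient of variation of skeleton-pixel intensities
#'
#' Population standard deviation divided by the mean. Bundling concentrates
#' fluorophore into fewer, brighter lines, stretching the intensity
#' distribution to the high side and raising the CV. Invariant under
#' multiplicative intensity rescaling.
#'
#' @param skeleton A [skeleton_network()] with >= 2 pixels and positive
#'   mean intensity.
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  if (skeleton$n_pixels < 2L)
    stop_cwrq("CV requires at least two skeleton pixels",
              "cwrq_undefined_feature")
  m <- mean(skeleton$intensities)
  if (m <= 0)
    stop_cwrq("CV is undefined for nonpositive mean intensity",
              "cwrq_undefined_feature")
  pop_sd(skeleton$intensities) / m
}

#' Skewness of skeleton-pixel intensities
#'
#' Third standardised population moment,
#' S = (1/N) * sum(((i_n - mean) / sigma)^3) with population sigma.
#' Like the CV it grows when bundling stretches the intensity distribution
#' toward high values; unlike the CV it is also sensitive to the overall
#' intensity regime (shot-noise skew falls as counts rise).
#'
#' @param skeleton A [skeleton_network()] with >= 2 pixels and nonzero
#'   intensity spread.
#' @return Skewness S (dimensionless).
#' @export
skewness <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  if (skeleton$n_pixels < 2L)
    stop_cwrq("skewness requires at least two skeleton pixels",
              "cwrq_undefined_feature")
  s <- pop_sd(skeleton$intensities)
  if (s == 0)
    stop_cwrq("skewness is undefined for constant intensities",
              "cwrq_undefined_feature")
  m <- mean(skeleton$intensities)
  mean(((skeleton$intensities - m) / s)^3)
}

#' Per-cell feature table
#'
#' Computes all four network features for a list of skeletons, one row per
#' cell. Cells with undefined intensity features (empty or constant
#' skeletons) are flagged in the `flags` column with `NA` features rather
#' than dropped, so batch runs never abort on a degenerate cell.
#'
#' @param skeletons List of [skeleton_network()] objects.
#' @param cell_id Optional character vector of cell identifiers.
#' @param condition Optional character vector of condition labels.
#' @return `data.frame` with columns cell_id, condition, n_pixels,
#'   total_length_mm, mean_intensity, cv, skewness, flags.
#' @export
feature_table <- function(skeletons, cell_id = NULL, condition = NULL) {
  n <- length(skeletons)
  if (is.null(cell_id)) cell_id <- sprintf("cell_%03d", seq_len(n))
  if (is.null(condition)) condition <- rep(NA_character_, n)
  if (length(cell_id) != n || length(condition) != n)
    stop_cwrq("labels must match the number of skeletons",
              "cwrq_format_error")
  one <- function(sk, id, cond) {
    safely <- function(f) tryCatch(f(sk), cwrq_undefined_feature = function(e) NA_real_)
    mi <- safely(mean_intensity)
    cv <- safely(coefficient_of_variation)
    sw <- safely(skewness)
    flags <- if (anyNA(c(mi, cv, sw))) "undefined_intensity_features" else ""
    data.frame(cell_id = id, condition = cond, n_pixels = sk$n_pixels,
               total_length_mm = total_length(sk), mean_intensity = mi,
               cv = cv, skewness = sw, flags = flags,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, skeletons, cell_id, condition))
  rownames(out) <- NULL
  out
}
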