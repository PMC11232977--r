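#' Orientation compensation factor
#'
#' An elongated target imaged at a random body angle projects a length
#' between its axial (end-on) width and its full length at normal
#' incidence. For orientation angles uniform on (-180, 180] degrees the
#' projected fraction is |cos(theta)|, whose median is sqrt(2)/2 = 0.7071 —
#' the projection at +-45 or +-135 degrees from normal incidence. A
#' non-zero axial width floors the projection at
#' `axial_width_fraction` of the full length but leaves the median
#' unchanged as long as the floor stays below sqrt(2)/2.
#'
#' @param method `"closed_form"` (exact median of |cos|) or
#'   `"monte_carlo"` (empirical median over `n` sampled angles).
#' @param axial_width_fraction Axial width as a fraction of full length, in
#'   `[0, sqrt(2)/2)`. Values at or above sqrt(2)/2 make the floor dominate
#'   the median and are rejected.
#' @param n Number of Monte-Carlo samples (monte_carlo only).
#' @param seed Integer seed (monte_carlo only).
#' @return The median projected-length fraction (dimensionless).
#' @examples
#' orientation_factor()                       # 0.70711
#' orientation_factor("monte_carlo", n = 1e5, seed = 1)
#' @export
orientation_factor <- function(method = c("closed_form", "monte_carlo"),
                               axial_width_fraction = 0,
                               n = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(axial_width_fraction >= 0)
  if (axial_width_fraction >= sqrt(2) / 2)
    stop("axial width fraction >= sqrt(2)/2: the axial floor dominates ",
         "the median and the projection model is invalid", call. = FALSE)
  if (method == "closed_form") return(sqrt(2) / 2)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::runif(n, -180, 180) * pi / 180
  stats::median(pmax(abs(cos(theta)), axial_width_fraction))
}

#' Pixel-per-millimetre conversion at the boundary range
#'
#' The imaged size of a reference-length target at the limit of the
#' resolvable volume fixes the image scale there: the boundary size is
#' first compensated for random body orientation (divided by the
#' orientation factor to recover the full normal-incidence length in
#' pixels), then divided by the physical reference length.
#'
#' @param L_boundary_px Class-division boundary size, pixels.
#' @param orientation_factor Median projected-length fraction
#'   (see [orientation_factor()]).
#' @param reference_length_mm Physical reference length, mm (conventionally
#'   the median prey length from diet samples).
#' @return Conversion factor in pixels per mm at the boundary range.
#' @examples
#' px_per_mm(34.4, sqrt(2) / 2, 42)  # ~1.16 px/mm
#' @export
px_per_mm <- function(L_boundary_px, orientation_factor, reference_length_mm) {
  vals <- c(L_boundary_px, orientation_factor, reference_length_mm)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all inputs to px_per_mm must be positive", call. = FALSE)
  (L_boundary_px / orientation_factor) / reference_length_mm
}

#' Resolvable range and pyramidal imaged volume from a size boundary
#'
#' Converts a pixel size boundary into the physical sampling volume of one
#' frame. The conversion factor at the boundary range scales the frame to
#' physical imaged width and height; the resolvable range follows from the
#' vertical field of view, `r = height_mm / (2 * tan(vfov/2))`; and the
#' imaged volume is the pyramid with apex at the camera and base
#' width x height at the resolvable range, `V = w * h * r / 3`.
#'
#' All internal lengths are millimetres and the volume is cubic metres.
#' The range is derived from the vertical field of view with the full
#' pixel height (height_mm = 0.75 * width_mm for a 4:3 frame); the
#' horizontal angle is not used for range because it is geometrically
#' inconsistent with the pixel aspect ratio for typical logger optics.
#'
#' @param L_boundary_px Boundary size, pixels.
#' @param camera A [camera_model].
#' @param prey A [prey_length_model]; its `median_mm` is the reference
#'   length.
#' @param orientation_factor Median projected-length fraction; default the
#'   closed form sqrt(2)/2.
#' @return An object of class `volume_estimate`: list with
#'   `conversion_px_per_mm`, `imaged_width_mm`, `imaged_height_mm`,
#'   `resolvable_range_mm`, `volume_m3` and the inputs used.
#' @examples
#' volume_from_boundary(34.4, camera_model(), prey_length_model())
#' @export
volume_from_boundary <- function(L_boundary_px,
                                 camera = camera_model(),
                                 prey = prey_length_model(),
                                 orientation_factor = sqrt(2) / 2) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(prey, "prey_length_model"))
  conv <- px_per_mm(L_boundary_px, orientation_factor, prey$median_mm)
  width_mm <- camera$width_px / conv
  height_mm <- camera$height_px / conv
  half_vfov <- camera$vfov_deg / 2 * pi / 180
  range_mm <- height_mm / (2 * tan(half_vfov))
  volume_m3 <- (width_mm / 1000) * (height_mm / 1000) * (range_mm / 1000) / 3
  structure(list(
    conversion_px_per_mm = conv,
    imaged_width_mm = width_mm,
    imaged_height_mm = height_mm,
    resolvable_range_mm = range_mm,
    volume_m3 = volume_m3,
    L_boundary_px = L_boundary_px,
    orientation_factor = orientation_factor,
    reference_length_mm = prey$median_mm,
    camera = camera),
    class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("Imaged volume estimate (boundary %.2f px):\n", x$L_boundary_px))
  cat(sprintf("  conversion       %.4f px/mm\n", x$conversion_px_per_mm))
  cat(sprintf("  imaged width     %.0f mm\n", x$imaged_width_mm))
  cat(sprintf("  imaged height    %.0f mm\n", x$imaged_height_mm))
  cat(sprintf("  resolvable range %.3f m\n", x$resolvable_range_mm / 1000))
  cat(sprintf("  imaged volume    %.3f m^3\n", x$volume_m3))
  invisible(x)
}

# Analytic volume (m^3) of the viewing frustum (pyramid) out to range_mm.
# Shared by the optics chain and the simulator's bookkeeping.
frustum_volume_m3 <- function(camera, range_mm) {
  half_h <- camera$hfov_deg / 2 * pi / 180
  half_v <- camera$vfov_deg / 2 * pi / 180
  w <- 2 * range_mm * tan(half_h)
  h <- 2 * range_mm * tan(half_v)
  (w / 1000) * (h / 1000) * (range_mm / 1000) / 3
}
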