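#' Camera model
#'
#' Describes the imaging geometry of a single (pinhole-approximated) camera:
#' frame size in pixels and horizontal/vertical field-of-view angles. The
#' defaults correspond to a 1280 x 960 px animal-borne video logger with a
#' 31 x 24 degree field of view recording at 30 frames per second.
#'
#' @param width_px Frame width in pixels.
#' @param height_px Frame height in pixels.
#' @param hfov_deg Horizontal field-of-view angle in degrees.
#' @param vfov_deg Vertical field-of-view angle in degrees.
#' @param frame_rate Frame rate in frames per second (informational only;
#'   no geometry depends on it).
#'
#' @return An object of class `camera_model`: a list with the five fields
#'   above.
#' @examples
#' camera_model()
#' camera_model(width_px = 1920, height_px = 1080, hfov_deg = 60, vfov_deg = 34)
#' @export
camera_model <- function(width_px = 1280, height_px = 960,
                         hfov_deg = 31, vfov_deg = 24, frame_rate = 30) {
  stopifnot(width_px > 0, height_px > 0, hfov_deg > 0, vfov_deg > 0,
            hfov_deg < 180, vfov_deg < 180, frame_rate > 0)
  structure(
    list(width_px = width_px, height_px = height_px,
         hfov_deg = hfov_deg, vfov_deg = vfov_deg, frame_rate = frame_rate),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera model: %d x %d px, FOV %g x %g deg, %g fps\n",
              x$width_px, x$height_px, x$hfov_deg, x$vfov_deg, x$frame_rate))
  invisible(x)
}

#' Reference prey-length model
#'
#' Summary of the physical length distribution of the imaged prey, taken from
#' an independent source such as predator diet samples. The defaults describe
#' Antarctic krill (*Euphausia superba*) measured from chinstrap penguin
#' stomach samples: lengths 31-60 mm, mean 43 mm (sd 4.3 mm), median 42 mm.
#' The median is the reference length used for the pixel-to-millimetre
#' conversion; the mean/sd/min/max parameterise the simulator's truncated
#' normal length distribution.
#'
#' @param mean_mm Mean total length, mm.
#' @param sd_mm Standard deviation of total length, mm.
#' @param median_mm Median total length, mm.
#' @param min_mm Minimum observed length, mm.
#' @param max_mm Maximum observed length, mm.
#'
#' @return An object of class `prey_length_model`.
#' @examples
#' prey_length_model()
#' @export
prey_length_model <- function(mean_mm = 43, sd_mm = 4.3, median_mm = 42,
                              min_mm = 31, max_mm = 60) {
  stopifnot(sd_mm > 0, min_mm > 0, min_mm <= median_mm, median_mm <= max_mm)
  structure(
    list(mean_mm = mean_mm, sd_mm = sd_mm, median_mm = median_mm,
         min_mm = min_mm, max_mm = max_mm),
    class = "prey_length_model"
  )
}

#' @export
print.prey_length_model <- function(x, ...) {
  cat(sprintf(
    "Prey length model: mean %g mm (sd %g), median %g mm, range [%g, %g] mm\n",
    x$mean_mm, x$sd_mm, x$median_mm, x$min_mm, x$max_mm))
  invisible(x)
}

#' Length-weight allometry parameters
#'
#' Power-law parameters for converting prey total length to individual wet
#' weight, w = a * L^b with L in mm and w in grams. Defaults are the
#' published Antarctic Peninsula krill relationship (a = 2.236e-6,
#' b = 3.314), which gives 0.54 g at the 42 mm median length.
#'
#' @param a Scale coefficient (g per mm^b).
#' @param b Allometric exponent (dimensionless).
#' @return An object of class `allometry_params`.
#' @examples
#' allometry_params()
#' @export
allometry_params <- function(a = 2.236e-6, b = 3.314) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "allometry_params")
}

#' Read a camera / prey configuration file
#'
#' Reads a key-value (YAML) configuration holding the camera specification
#' and prey-length model. Recognised keys: `width_px`, `height_px`,
#' `hfov_deg`, `vfov_deg`, `frame_rate`, `prey_mean_mm`, `prey_sd_mm`,
#' `prey_median_mm`, `prey_min_mm`, `prey_max_mm`, `allometry_a`,
#' `allometry_b`. Missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `camera` ([camera_model]), `prey`
#'   ([prey_length_model]) and `allometry` ([allometry_params]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) cfg <- list()
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  cam <- camera_model(
    width_px   = pick("width_px", 1280),
    height_px  = pick("height_px", 960),
    hfov_deg   = pick("hfov_deg", 31),
    vfov_deg   = pick("vfov_deg", 24),
    frame_rate = pick("frame_rate", 30)
  )
  prey <- prey_length_model(
    mean_mm   = pick("prey_mean_mm", 43),
    sd_mm     = pick("prey_sd_mm", 4.3),
    median_mm = pick("prey_median_mm", 42),
    min_mm    = pick("prey_min_mm", 31),
    max_mm    = pick("prey_max_mm", 60)
  )
  allo <- allometry_params(
    a = pick("allometry_a", 2.236e-6),
    b = pick("allometry_b", 3.314)
  )
  list(camera = cam, prey = prey, allometry = allo)
}
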