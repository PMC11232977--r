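#' Per-image numerical density and summary statistics
#'
#' Divides each image's countable-object count by the imaged volume to give
#' numerical density (animals per cubic metre), with summary statistics
#' over images. Images with zero countable objects contribute density 0.
#'
#' @param counts A data frame `(image_id, count)`, e.g. from
#'   [countable_per_image()].
#' @param volume_m3 Imaged volume per frame, cubic metres (> 0).
#' @return An object of class `density_result`: list with `per_image`
#'   (data frame `image_id, count, density_krill_per_m3`), `mean`, `sd`
#'   (sample, n-1), `median`, `min`, `max`, `n_images` and `volume_m3`.
#' @examples
#' counts <- data.frame(image_id = c("a", "b"), count = c(3, 0))
#' density_per_image(counts, 0.59)
#' @export
density_per_image <- function(counts, volume_m3) {
  stopifnot(is.data.frame(counts),
            all(c("image_id", "count") %in% names(counts)))
  if (!is.finite(volume_m3) || volume_m3 <= 0)
    stop("imaged volume must be positive", call. = FALSE)
  if (any(counts$count < 0)) stop("negative count", call. = FALSE)
  dens <- counts$count / volume_m3
  per_image <- data.frame(image_id = counts$image_id,
                          count = counts$count,
                          density_krill_per_m3 = dens,
                          stringsAsFactors = FALSE)
  structure(list(
    per_image = per_image,
    mean = mean(dens),
    sd = if (length(dens) > 1) stats::sd(dens) else NA_real_,
    median = stats::median(dens),
    min = min(dens),
    max = max(dens),
    n_images = nrow(per_image),
    volume_m3 = volume_m3),
    class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "Density over %d images (volume %.3f m^3):\n", x$n_images, x$volume_m3))
  cat(sprintf(
    "  mean %.1f, sd %.1f, median %.1f, range [%.1f, %.1f] krill/m^3\n",
    x$mean, x$sd, x$median, x$min, x$max))
  invisible(x)
}

#' Individual prey weight from length
#'
#' Length-weight allometry `w = a * L^b`, length in mm, weight in grams.
#'
#' @param L_mm Total length, mm (>= 0; vectorised).
#' @param params An [allometry_params].
#' @return Weight(s) in grams.
#' @examples
#' krill_weight_g(42)  # ~0.54 g
#' @export
krill_weight_g <- function(L_mm, params = allometry_params()) {
  stopifnot(inherits(params, "allometry_params"))
  if (any(!is.finite(L_mm) | L_mm < 0))
    stop("length must be non-negative", call. = FALSE)
  params$a * L_mm^params$b
}

#' Biomass density from numerical density
#'
#' @param density Numerical density, animals per cubic metre.
#' @param mean_weight_g Mean individual weight, grams (conventionally the
#'   weight at the median reference length).
#' @return Biomass density in g per cubic metre.
#' @export
biomass_density <- function(density, mean_weight_g) {
  stopifnot(all(density >= 0), all(mean_weight_g >= 0))
  density * mean_weight_g
}

#' Convert areal biomass density to volumetric
#'
#' Areal estimates (g per square metre of sea surface, e.g. from acoustic
#' surveys) convert to volumetric densities by dividing by the vertical
#' thickness of the aggregation.
#'
#' @param areal_g_m2 Areal biomass density, g/m^2.
#' @param thickness_m Swarm vertical thickness, m (> 0).
#' @return Volumetric biomass density, g/m^3.
#' @examples
#' areal_to_volumetric(52.9, 5)
#' @export
areal_to_volumetric <- function(areal_g_m2, thickness_m) {
  if (any(!is.finite(thickness_m) | thickness_m <= 0))
    stop("thickness must be positive", call. = FALSE)
  areal_g_m2 / thickness_m
}

#' Swarm thickness from dive/strike events
#'
#' For each dive (a `dive_start` ... `dive_end` bracket), the vertical
#' extent of the prey aggregation is proxied by the depth range spanned by
#' feeding strikes: `max(strike depths) - min(strike depths)`. Dives with
#' fewer than two strikes have thickness 0.
#'
#' @param events A data frame `(time_s, depth_m, kind)` sorted by time,
#'   with `kind` in `dive_start`, `dive_end`, `strike` and strikes occurring
#'   inside dive brackets.
#' @return A data frame `(dive_index, n_strikes, thickness_m)`.
#' @export
swarm_thickness <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "depth_m", "kind") %in% names(events)))
  if (is.unsorted(events$time_s)) stop("events must be time-sorted",
                                       call. = FALSE)
  dive <- 0L
  open <- FALSE
  strikes <- list()
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    if (kind == "dive_start") {
      if (open) stop("dive_start inside an open dive at row ", i,
                     call. = FALSE)
      dive <- dive + 1L
      open <- TRUE
      strikes[[dive]] <- numeric()
    } else if (kind == "dive_end") {
      if (!open) stop("dive_end without dive_start at row ", i, call. = FALSE)
      open <- FALSE
    } else if (kind == "strike") {
      if (!open) stop("strike outside any dive at row ", i, call. = FALSE)
      strikes[[dive]] <- c(strikes[[dive]], events$depth_m[i])
    } else {
      stop("unknown event kind '", kind, "' at row ", i, call. = FALSE)
    }
  }
  if (open) stop("unterminated dive (missing dive_end)", call. = FALSE)
  n <- vapply(strikes, length, integer(1))
  thick <- vapply(strikes, function(d)
    if (length(d) >= 2) max(d) - min(d) else 0, numeric(1))
  data.frame(dive_index = seq_along(strikes), n_strikes = n,
             thickness_m = thick)
}

#' Write per-image density results
#'
#' Writes the per-image table as CSV and the summary as a key-value block.
#'
#' @param result A `density_result`.
#' @param path Output CSV path for the per-image table; the summary goes to
#'   `<path>.summary.txt`.
#' @return `path`, invisibly.
#' @export
write_density_result <- function(result, path) {
  stopifnot(inherits(result, "density_result"))
  utils::write.csv(result$per_image, path, row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("n_images: %d", result$n_images),
    sprintf("volume_m3: %.10g", result$volume_m3),
    sprintf("mean_density_krill_per_m3: %.10g", result$mean),
    sprintf("sd_density_krill_per_m3: %.10g", result$sd),
    sprintf("median_density_krill_per_m3: %.10g", result$median),
    sprintf("min_density_krill_per_m3: %.10g", result$min),
    sprintf("max_density_krill_per_m3: %.10g", result$max)
  ), paste0(path, ".summary.txt"))
  invisible(path)
}
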