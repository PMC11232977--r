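#' End-to-end density estimation from an annotation set
#'
#' Runs the full estimation chain: select the size-fit subset, fit the
#' logistic size boundary, build the mirrored near-boundary distribution,
#' convert the boundary to resolvable range and imaged volume, count
#' countable objects per image, and compute per-image densities and
#' biomass.
#'
#' @param annotations An [annotation_set] (or a path readable by
#'   [read_annotations()]).
#' @param camera A [camera_model].
#' @param prey A [prey_length_model].
#' @param allometry An [allometry_params].
#' @param orientation_factor Median projected-length fraction.
#' @param dialect Annotation dialect when `annotations` is a path.
#' @return An object of class `density_estimate`: list with `boundary`
#'   (`logistic_boundary`), `near_boundary`
#'   (`near_boundary_distribution`), `volume` (`volume_estimate`),
#'   `density` (`density_result`), `mean_weight_g`, `biomass_g_m3` and
#'   `mean_count_per_image`.
#' @examples
#' sim <- generate_dataset(48, n_images = 10, true_r_res_mm = 1950, seed = 1)
#' est <- estimate_density(sim$annotations)
#' est$density$mean
#' @export
estimate_density <- function(annotations,
                             camera = camera_model(),
                             prey = prey_length_model(),
                             allometry = allometry_params(),
                             orientation_factor = sqrt(2) / 2,
                             dialect = "simple_csv") {
  if (is.character(annotations))
    annotations <- read_annotations(annotations, dialect)
  stopifnot(inherits(annotations, "annotation_set"))
  pairs <- boundary_fit_subset(annotations)
  boundary <- fit_logistic_boundary(pairs)
  below <- pairs$imaged_length_px[pairs$imaged_length_px <
                                    boundary$L_boundary]
  near <- if (length(below) > 0)
    mirror_near_boundary(below, boundary$L_boundary) else NULL
  vol <- volume_from_boundary(boundary$L_boundary, camera, prey,
                              orientation_factor)
  counts <- countable_per_image(annotations)
  dens <- density_per_image(counts, vol$volume_m3)
  w <- krill_weight_g(prey$median_mm, allometry)
  structure(list(
    boundary = boundary,
    near_boundary = near,
    volume = vol,
    density = dens,
    mean_weight_g = w,
    biomass_g_m3 = biomass_density(dens$mean, w),
    mean_count_per_image = mean(counts$count)),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("Density estimate\n")
  cat(sprintf("  L_boundary        %.2f px%s\n", x$boundary$L_boundary,
              if (x$boundary$degenerate) " (degenerate fit)" else ""))
  if (!is.null(x$near_boundary))
    cat(sprintf("  near-boundary sd  %.2f px\n", x$near_boundary$sd))
  cat(sprintf("  conversion        %.4f px/mm\n",
              x$volume$conversion_px_per_mm))
  cat(sprintf("  resolvable range  %.3f m\n",
              x$volume$resolvable_range_mm / 1000))
  cat(sprintf("  imaged volume     %.3f m^3\n", x$volume$volume_m3))
  cat(sprintf("  mean count/image  %.2f over %d images\n",
              x$mean_count_per_image, x$density$n_images))
  cat(sprintf("  mean density      %.2f krill/m^3 (sd %.2f)\n",
              x$density$mean, x$density$sd))
  cat(sprintf("  mean biomass      %.2f g/m^3 (at %.3f g/individual)\n",
              x$biomass_g_m3, x$mean_weight_g))
  invisible(x)
}

#' Write a density-estimate bundle to a directory
#'
#' Writes the boundary report, volume estimate, per-image densities,
#' summary block and a machine-readable provenance record (inputs digest,
#' package version).
#'
#' @param est A `density_estimate`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the provenance file (if any randomness was
#'   involved upstream).
#' @return `dir`, invisibly.
#' @export
write_estimate <- function(est, dir, seed = NA) {
  stopifnot(inherits(est, "density_estimate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_boundary_report(est$boundary, est$near_boundary,
                        file.path(dir, "boundary.txt"))
  v <- est$volume
  writeLines(c(
    sprintf("conversion_px_per_mm: %.10g", v$conversion_px_per_mm),
    sprintf("imaged_width_mm: %.10g", v$imaged_width_mm),
    sprintf("imaged_height_mm: %.10g", v$imaged_height_mm),
    sprintf("resolvable_range_mm: %.10g", v$resolvable_range_mm),
    sprintf("volume_m3: %.10g", v$volume_m3),
    sprintf("mean_weight_g: %.10g", est$mean_weight_g),
    sprintf("mean_biomass_g_per_m3: %.10g", est$biomass_g_m3)
  ), file.path(dir, "volume.txt"))
  write_density_result(est$density, file.path(dir, "density_per_image.csv"))
  prov <- list(
    package = "krillcam",
    version = as.character(utils::packageVersion("krillcam")),
    seed = seed,
    L_boundary_px = est$boundary$L_boundary,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
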