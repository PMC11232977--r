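#' Discrete boundary-grid sensitivity analysis
#'
#' Recomputes the full geometry-and-density chain at a discrete set of
#' boundary sizes describing the near-boundary distribution (mean, mean
#' +- 1 and 2 sd) and the extremes of the observed size classes (minimum
#' resolvable and minimum unresolvable object sizes). Each row is computed
#' through [volume_from_boundary()]; mean density is the fixed mean count
#' per image divided by the row's volume, and biomass multiplies by the
#' weight at the reference (median) prey length.
#'
#' @param mean_px Near-boundary mean size (the logistic boundary), px.
#' @param sd_px Near-boundary standard deviation, px.
#' @param min_res_px Minimum imaged size of resolvable objects, px.
#' @param min_unres_px Minimum imaged size of unresolvable objects, px.
#' @param camera A [camera_model].
#' @param prey A [prey_length_model].
#' @param mean_count_per_image Mean countable objects per image.
#' @param allometry An [allometry_params] for the biomass column.
#' @param orientation_factor Median projected-length fraction.
#' @return An object of class `sensitivity_grid`: a data frame with columns
#'   `label`, `boundary_px`, `range_mm`, `width_mm`, `height_mm`,
#'   `volume_m3`, `mean_density`, `biomass_g_m3`.
#' @examples
#' boundary_grid(34.4, 10.5, 14.9, 9.9, mean_count_per_image = 28.73)
#' @export
boundary_grid <- function(mean_px, sd_px, min_res_px, min_unres_px,
                          camera = camera_model(),
                          prey = prey_length_model(),
                          mean_count_per_image,
                          allometry = allometry_params(),
                          orientation_factor = sqrt(2) / 2) {
  stopifnot(mean_px > 0, sd_px >= 0, min_res_px > 0, min_unres_px > 0,
            mean_count_per_image >= 0)
  if (mean_px - 2 * sd_px <= 0)
    stop("mean - 2 sd is non-positive: nonphysical boundary", call. = FALSE)
  labels <- c("size_unres_min", "size_res_min", "boundary_mean",
              "boundary_mean-1sd", "boundary_mean+1sd",
              "boundary_mean-2sd", "boundary_mean+2sd")
  sizes <- c(min_unres_px, min_res_px, mean_px,
             mean_px - sd_px, mean_px + sd_px,
             mean_px - 2 * sd_px, mean_px + 2 * sd_px)
  w_ref <- krill_weight_g(prey$median_mm, allometry)
  rows <- lapply(seq_along(sizes), function(i) {
    v <- volume_from_boundary(sizes[i], camera, prey, orientation_factor)
    dens <- mean_count_per_image / v$volume_m3
    data.frame(label = labels[i], boundary_px = sizes[i],
               range_mm = v$resolvable_range_mm,
               width_mm = v$imaged_width_mm,
               height_mm = v$imaged_height_mm,
               volume_m3 = v$volume_m3,
               mean_density = dens,
               biomass_g_m3 = dens * w_ref,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("sensitivity_grid", "data.frame"))
}

#' Monte-Carlo propagation of boundary uncertainty
#'
#' Draws boundary sizes from Normal(mean, sd), keeps only positive values,
#' and pushes each draw through the geometry chain to obtain distributions
#' of resolvable range, imaged volume and mean density. Positivity is
#' enforced either by rejection-resampling until exactly `n` accepted draws
#' exist (default, giving a fixed sample size) or by dropping non-positive
#' draws without replacement (`keep_n = FALSE`).
#'
#' @param mean_px Boundary mean, px.
#' @param sd_px Boundary sd, px (>= 0).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param camera A [camera_model].
#' @param prey A [prey_length_model].
#' @param mean_count_per_image Fixed numerator for per-draw density.
#' @param orientation_factor Median projected-length fraction.
#' @param keep_n If `TRUE` (default) resample rejected draws so exactly `n`
#'   remain; if `FALSE` drop them.
#' @return An object of class `propagation_result`: list with `draws`
#'   (data frame `boundary_px, range_mm, volume_m3, density`), `summaries`
#'   (data frame of mean/sd/median/q25/q75 per quantity), `seed`, `n`.
#' @examples
#' propagate(34.4, 10.5, n = 1000, seed = 1, mean_count_per_image = 28.73)
#' @export
propagate <- function(mean_px, sd_px, n, seed,
                      camera = camera_model(),
                      prey = prey_length_model(),
                      mean_count_per_image,
                      orientation_factor = sqrt(2) / 2,
                      keep_n = TRUE) {
  stopifnot(n >= 1, sd_px >= 0, mean_count_per_image >= 0)
  if (sd_px > 0 && stats::pnorm(0, mean_px, sd_px, lower.tail = FALSE) < 0.01)
    stop("fewer than 1% of draws would be positive: nonphysical parameters",
         call. = FALSE)
  set.seed(seed)
  if (sd_px == 0) {
    draws_px <- rep(mean_px, n)
  } else if (keep_n) {
    draws_px <- numeric(0)
    while (length(draws_px) < n) {
      cand <- stats::rnorm(n - length(draws_px), mean_px, sd_px)
      draws_px <- c(draws_px, cand[cand > 0])
    }
  } else {
    cand <- stats::rnorm(n, mean_px, sd_px)
    draws_px <- cand[cand > 0]
    if (length(draws_px) == 0)
      stop("no positive draws", call. = FALSE)
  }
  # Vectorised geometry chain (identical to volume_from_boundary).
  conv <- (draws_px / orientation_factor) / prey$median_mm
  width_mm <- camera$width_px / conv
  height_mm <- camera$height_px / conv
  range_mm <- height_mm / (2 * tan(camera$vfov_deg / 2 * pi / 180))
  volume_m3 <- (width_mm / 1000) * (height_mm / 1000) * (range_mm / 1000) / 3
  density <- mean_count_per_image / volume_m3
  draws <- data.frame(boundary_px = draws_px, range_mm = range_mm,
                      volume_m3 = volume_m3, density = density)
  summarise <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(x), sd = stats::sd(x), median = q[2], q25 = q[1], q75 = q[3])
  }
  summaries <- t(vapply(draws, summarise, numeric(5)))
  structure(list(
    draws = draws,
    summaries = as.data.frame(summaries),
    seed = seed, n = nrow(draws)),
    class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo boundary propagation: n = %d (seed %d)\n",
              x$n, x$seed))
  print(round(x$summaries, 3))
  invisible(x)
}

#' Write sensitivity outputs
#'
#' @param grid A `sensitivity_grid` (or `NULL` to skip).
#' @param propagation A `propagation_result` (or `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @param draws Also dump the raw Monte-Carlo draws as CSV.
#' @return `dir`, invisibly.
#' @export
write_sensitivity <- function(grid = NULL, propagation = NULL, dir,
                              draws = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "sensitivity_grid"))
    utils::write.csv(as.data.frame(grid),
                     file.path(dir, "boundary_grid.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(propagation)) {
    stopifnot(inherits(propagation, "propagation_result"))
    sm <- cbind(quantity = rownames(propagation$summaries),
                propagation$summaries)
    utils::write.csv(sm, file.path(dir, "propagation_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    if (draws)
      utils::write.csv(propagation$draws,
                       file.path(dir, "propagation_draws.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
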