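#' Simulate a prey scene inside the camera frustum
#'
#' Places prey uniformly in the viewing frustum (pyramid with apex at the
#' camera, extending to `max_range_mm` along the optical axis), with count
#' drawn Poisson(true_density x frustum volume). Lengths are drawn from
#' the prey model's normal distribution truncated to its min/max; body
#' orientation angles are uniform on (-180, 180] degrees, with a fixed
#' axial width fraction of the body length.
#'
#' @param true_density True numerical density, animals per cubic metre.
#' @param max_range_mm Far limit of the simulated frustum, mm.
#' @param camera A [camera_model].
#' @param prey A [prey_length_model].
#' @param seed Integer seed.
#' @param axial_width_fraction Body width as a fraction of length
#'   (default 0.2).
#' @return A data frame of scene prey: `x_mm, y_mm, z_mm` (camera
#'   coordinates, z = range along the optical axis), `length_mm`,
#'   `orientation_deg`, `axial_width_mm`; attribute `frustum_volume_m3`.
#' @examples
#' simulate_scene(48, 5000, seed = 1)
#' @export
simulate_scene <- function(true_density, max_range_mm,
                           camera = camera_model(),
                           prey = prey_length_model(),
                           seed = NULL,
                           axial_width_fraction = 0.2) {
  stopifnot(true_density >= 0, max_range_mm > 0,
            inherits(camera, "camera_model"),
            inherits(prey, "prey_length_model"),
            axial_width_fraction >= 0, axial_width_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  vol <- frustum_volume_m3(camera, max_range_mm)
  expected <- true_density * vol
  if (expected > 1e7)
    stop("expected prey count exceeds 1e7; reduce density or range",
         call. = FALSE)
  n <- stats::rpois(1, expected)
  tan_h <- tan(camera$hfov_deg / 2 * pi / 180)
  tan_v <- tan(camera$vfov_deg / 2 * pi / 180)
  # Uniform in the pyramid via rejection from its bounding box.
  xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
  while (length(zs) < n) {
    m <- max(2 * (n - length(zs)) * 3, 100)  # pyramid fills 1/3 of the box
    z <- stats::runif(m, 0, max_range_mm)
    x <- stats::runif(m, -max_range_mm * tan_h, max_range_mm * tan_h)
    y <- stats::runif(m, -max_range_mm * tan_v, max_range_mm * tan_v)
    ok <- abs(x) <= z * tan_h & abs(y) <= z * tan_v
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok]); zs <- c(zs, z[ok])
  }
  keep <- seq_len(n)
  lengths <- rtruncnorm(n, prey$mean_mm, prey$sd_mm, prey$min_mm, prey$max_mm)
  out <- data.frame(
    x_mm = xs[keep], y_mm = ys[keep], z_mm = zs[keep],
    length_mm = lengths,
    orientation_deg = stats::runif(n, -180, 180),
    axial_width_mm = axial_width_fraction * lengths)
  attr(out, "frustum_volume_m3") <- vol
  out
}

# Truncated-normal draws by rejection; truncation bounds here are a few sd
# from the mean so acceptance is high.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(max(n - length(out), 10) * 2, mean, sd)
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Project scene prey to imaged pixel lengths
#'
#' Pinhole projection of each prey's effective length. The projected
#' physical length is `max(length * |cos(orientation)|, axial_width)` —
#' full length at normal incidence, body width when seen end-on — and the
#' imaged length in pixels follows from the range via the vertical field
#' of view: `px = projected_mm * height_px / (2 * z * tan(vfov/2))`.
#'
#' @param scene A scene data frame from [simulate_scene()].
#' @param camera A [camera_model].
#' @return A data frame `(imaged_length_px, range_mm)`.
#' @export
project_to_image <- function(scene, camera = camera_model()) {
  stopifnot(is.data.frame(scene),
            all(c("z_mm", "length_mm", "orientation_deg",
                  "axial_width_mm") %in% names(scene)))
  if (nrow(scene) > 0 && any(scene$z_mm <= 0))
    stop("non-positive range in scene", call. = FALSE)
  proj_mm <- pmax(scene$length_mm * abs(cos(scene$orientation_deg * pi / 180)),
                  scene$axial_width_mm)
  tan_v <- tan(camera$vfov_deg / 2 * pi / 180)
  px <- proj_mm * camera$height_px / (2 * scene$z_mm * tan_v)
  data.frame(imaged_length_px = px, range_mm = scene$z_mm)
}

#' Assign resolvability labels to projected objects
#'
#' Emulates the analyst's resolvable/unresolvable call as a function of
#' range. With `logistic_scale_mm = 0` the call is a hard threshold at the
#' true resolvable range; otherwise the probability of a resolvable call
#' is `plogis((true_r_res - z) / scale)`, producing a marginal region of
#' mixed calls rather than a sharp plane. Independently, a `blur_fraction`
#' of within-range objects is relabelled unresolvable, emulating motion
#' blur contaminating the unresolvable class with large, close objects.
#' Subtype flags are sampled at the given rates among resolvable records.
#'
#' @param projected A data frame from [project_to_image()] (columns
#'   `imaged_length_px`, `range_mm`), plus optional `image_id`.
#' @param true_r_res_mm True resolvable range, mm.
#' @param blur_fraction Fraction of within-range objects relabelled
#'   unresolvable, in `[0, 1)`.
#' @param logistic_scale_mm Width of the marginal region, mm (0 = hard
#'   threshold).
#' @param seed Integer seed (optional; the caller may manage the RNG).
#' @param subtype_rates Named numeric vector of rates for resolvable
#'   subtypes (`bent`, `partial`, `axial`, `motion_blurred`); the rest are
#'   `plain`.
#' @return An [annotation_set] (single image id `"img1"` unless `image_id`
#'   is present in `projected`).
#' @export
assign_resolvability <- function(projected, true_r_res_mm,
                                 blur_fraction = 0,
                                 logistic_scale_mm = 0,
                                 seed = NULL,
                                 subtype_rates = c(bent = 0, partial = 0,
                                                   axial = 0,
                                                   motion_blurred = 0)) {
  stopifnot(is.data.frame(projected), true_r_res_mm > 0,
            blur_fraction >= 0, blur_fraction < 1, logistic_scale_mm >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(projected)
  z <- projected$range_mm
  if (logistic_scale_mm == 0) {
    resolvable <- z < true_r_res_mm
  } else {
    p <- stats::plogis((true_r_res_mm - z) / logistic_scale_mm)
    resolvable <- stats::runif(n) < p
  }
  if (blur_fraction > 0) {
    blur <- stats::runif(n) < blur_fraction & z < true_r_res_mm
    resolvable <- resolvable & !blur
  }
  subtype <- rep("none", n)
  if (any(resolvable)) {
    idx <- which(resolvable)
    rates <- subtype_rates[c("bent", "partial", "axial", "motion_blurred")]
    rates[is.na(rates)] <- 0
    if (sum(rates) >= 1) stop("subtype rates must sum to < 1", call. = FALSE)
    u <- stats::runif(length(idx))
    cum <- cumsum(rates)
    pick <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
    labels <- c(names(rates), "plain")
    # findInterval returns 1..4 inside the rate bands, 5 above -> plain
    subtype[idx] <- labels[pick]
  }
  img <- if ("image_id" %in% names(projected)) projected$image_id else "img1"
  annotation_set(data.frame(
    image_id = img,
    object_id = sprintf("obj%06d", seq_len(n)),
    imaged_length_px = projected$imaged_length_px,
    resolvability = ifelse(resolvable, "resolvable", "unresolvable"),
    subtype = subtype,
    stringsAsFactors = FALSE))
}

#' Generate a full synthetic annotation dataset with ground truth
#'
#' Simulates `n_images` independent scenes at a known true density,
#' projects them to pixel lengths, assigns resolvability, and concatenates
#' the per-image annotation sets. The returned truth ledger records the
#' generator's own bookkeeping (per-image in-frustum and within-range
#' counts, analytic frustum volume, the true resolvable range) for use as
#' a recovery oracle. The simulated frustum extends beyond the true
#' resolvable range (`range_factor`, default 3x) so that unresolvable far
#' objects exist alongside resolvable ones.
#'
#' @param true_density True density, animals per cubic metre.
#' @param n_images Number of simulated frames.
#' @param true_r_res_mm True resolvable range, mm.
#' @param camera A [camera_model].
#' @param prey A [prey_length_model].
#' @param seed Integer seed.
#' @param range_factor Simulated frustum depth as a multiple of
#'   `true_r_res_mm`.
#' @param blur_fraction,logistic_scale_mm,subtype_rates Passed to
#'   [assign_resolvability()].
#' @param axial_width_fraction Passed to [simulate_scene()].
#' @return A list with `annotations` (an [annotation_set]) and `truth`
#'   (list: `true_density`, `true_r_res_mm`, `frustum_volume_m3`,
#'   `within_range_volume_m3`, `per_image_counts` data frame with
#'   `image_id`, `n_total`, `n_within_range`, `seed`).
#' @examples
#' sim <- generate_dataset(48, n_images = 5, true_r_res_mm = 1950, seed = 1)
#' sim$truth$per_image_counts
#' @export
generate_dataset <- function(true_density, n_images, true_r_res_mm,
                             camera = camera_model(),
                             prey = prey_length_model(),
                             seed = 1,
                             range_factor = 3,
                             blur_fraction = 0,
                             logistic_scale_mm = 0,
                             subtype_rates = c(bent = 0, partial = 0,
                                               axial = 0, motion_blurred = 0),
                             axial_width_fraction = 0.2) {
  stopifnot(n_images >= 1, true_r_res_mm > 0, range_factor > 1)
  set.seed(seed)
  max_range <- range_factor * true_r_res_mm
  sets <- vector("list", n_images)
  n_total <- integer(n_images)
  n_within <- integer(n_images)
  for (i in seq_len(n_images)) {
    scene <- simulate_scene(true_density, max_range, camera, prey,
                            seed = NULL,
                            axial_width_fraction = axial_width_fraction)
    proj <- project_to_image(scene, camera)
    proj$image_id <- sprintf("img%04d", i)
    n_total[i] <- nrow(scene)
    n_within[i] <- sum(scene$z_mm < true_r_res_mm)
    sets[[i]] <- as.data.frame(
      assign_resolvability(proj, true_r_res_mm, blur_fraction,
                           logistic_scale_mm, seed = NULL,
                           subtype_rates = subtype_rates))
  }
  ann <- annotation_set(do.call(rbind, sets))
  truth <- list(
    true_density = true_density,
    true_r_res_mm = true_r_res_mm,
    frustum_volume_m3 = frustum_volume_m3(camera, max_range),
    within_range_volume_m3 = frustum_volume_m3(camera, true_r_res_mm),
    per_image_counts = data.frame(
      image_id = sprintf("img%04d", seq_len(n_images)),
      n_total = n_total, n_within_range = n_within,
      stringsAsFactors = FALSE),
    seed = seed)
  list(annotations = ann, truth = truth)
}

#' Write a simulation truth ledger as JSON
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
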