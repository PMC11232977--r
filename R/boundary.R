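#' Fit the resolvable/unresolvable size boundary by logistic regression
#'
#' Fits a single-predictor binomial GLM of resolvability (resolvable coded
#' 1) on raw imaged length in pixels, and solves the fitted model at
#' predicted probability 0.5 for the class-division boundary
#' `L_boundary = -intercept / slope`. When the two classes are perfectly
#' separated in size the maximum-likelihood estimate diverges; the boundary
#' is then returned as the midpoint of the separating gap and the fit is
#' flagged `degenerate`.
#'
#' @param pairs A data frame with columns `imaged_length_px` (positive) and
#'   `resolvability` (`"resolvable"`/`"unresolvable"`, or a 0/1 numeric with
#'   resolvable = 1), e.g. from [boundary_fit_subset()].
#' @return An object of class `logistic_boundary`: list with `intercept`,
#'   `slope` (logit per pixel), `L_boundary` (px), `n_resolvable`,
#'   `n_unresolvable`, `converged`, `degenerate`, and (non-degenerate only)
#'   the `glm` fit.
#' @examples
#' set.seed(1)
#' pairs <- data.frame(
#'   imaged_length_px = c(runif(50, 10, 30), runif(50, 40, 80)),
#'   resolvability = rep(c("unresolvable", "resolvable"), each = 50))
#' fit_logistic_boundary(pairs)
#' @export
fit_logistic_boundary <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("imaged_length_px", "resolvability") %in% names(pairs)))
  x <- as.numeric(pairs$imaged_length_px)
  if (any(!is.finite(x) | x <= 0))
    stop("imaged lengths must be positive", call. = FALSE)
  y <- pairs$resolvability
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !(y %in% RESOLVABILITY)
    if (any(bad)) stop("unknown resolvability label '", y[which(bad)[1]], "'",
                       call. = FALSE)
    y <- as.integer(y == "resolvable")
  }
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 records of each resolvability class (got ",
         n1, " resolvable, ", n0, " unresolvable)", call. = FALSE)

  # Perfect size separation: every unresolvable shorter than every
  # resolvable. The MLE diverges, so report the midpoint of the gap.
  max0 <- max(x[y == 0L]); min1 <- min(x[y == 1L])
  if (max0 < min1) {
    return(structure(list(
      intercept = NA_real_, slope = NA_real_,
      L_boundary = (max0 + min1) / 2,
      n_resolvable = n1, n_unresolvable = n0,
      converged = TRUE, degenerate = TRUE, fit = NULL),
      class = "logistic_boundary"))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- stats::coef(fit)
  slope <- unname(beta[2]); intercept <- unname(beta[1])
  # Quasi-separation shows up as fitted probabilities pinned at 0/1.
  pinned <- all(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (pinned) {
    return(structure(list(
      intercept = intercept, slope = slope,
      L_boundary = (max0 + min1) / 2,
      n_resolvable = n1, n_unresolvable = n0,
      converged = fit$converged, degenerate = TRUE, fit = fit),
      class = "logistic_boundary"))
  }
  if (!is.finite(slope) || slope == 0)
    stop("logistic fit failed: zero or non-finite slope", call. = FALSE)
  structure(list(
    intercept = intercept, slope = slope,
    L_boundary = -intercept / slope,
    n_resolvable = n1, n_unresolvable = n0,
    converged = fit$converged, degenerate = FALSE, fit = fit),
    class = "logistic_boundary")
}

#' @export
print.logistic_boundary <- function(x, ...) {
  cat(sprintf("Logistic size boundary: L_boundary = %.2f px\n", x$L_boundary))
  if (x$degenerate) {
    cat("  degenerate fit (perfect separation); boundary = gap midpoint\n")
  } else {
    cat(sprintf("  intercept %.4f, slope %.4f logit/px\n",
                x$intercept, x$slope))
  }
  cat(sprintf("  n = %d resolvable, %d unresolvable; converged: %s\n",
              x$n_resolvable, x$n_unresolvable, x$converged))
  invisible(x)
}

#' Mirrored near-boundary size distribution
#'
#' The sizes below the class boundary are treated as the lower half of a
#' symmetric distribution of object sizes near the (indistinct) limit of
#' the imaged volume. Mirroring each value about the boundary —
#' `{x} U {2 * L_boundary - x}` — produces a symmetric sample whose moment
#' fit gives mean exactly `L_boundary` and a standard deviation quantifying
#' boundary uncertainty.
#'
#' @param lengths Imaged lengths in pixels, all strictly below `L_boundary`
#'   (the caller selects the sub-boundary sizes, conventionally from both
#'   resolvability classes of the size-fit subset).
#' @param L_boundary The class-division boundary in pixels.
#' @return An object of class `near_boundary_distribution`: list with
#'   `mean` (px, equals `L_boundary`), `sd` (sample sd, n-1 denominator)
#'   and `mirrored_sample`.
#' @examples
#' mirror_near_boundary(c(30, 32), 34.4)
#' @export
mirror_near_boundary <- function(lengths, L_boundary) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0) stop("empty length vector", call. = FALSE)
  stopifnot(is.finite(L_boundary), L_boundary > 0)
  if (any(lengths >= L_boundary))
    stop("all lengths must be strictly below L_boundary", call. = FALSE)
  mirrored <- c(lengths, 2 * L_boundary - lengths)
  structure(list(
    mean = L_boundary,  # exact by construction
    sd = stats::sd(mirrored),
    mirrored_sample = mirrored),
    class = "near_boundary_distribution")
}

#' @export
print.near_boundary_distribution <- function(x, ...) {
  cat(sprintf(
    "Near-boundary size distribution: N(%.2f, %.2f px), %d mirrored values\n",
    x$mean, x$sd, length(x$mirrored_sample)))
  invisible(x)
}

#' Alternative boundary estimators from the unresolvable class alone
#'
#' Instead of the logistic boundary, the centre of the unresolvable size
#' distribution can serve as a simpler boundary estimate: its median, or
#' the midpoint of the most populated histogram bin (mode).
#'
#' @param unresolvable_lengths Imaged lengths (px) of unresolvable objects.
#' @param method `"median"` or `"mode"`.
#' @param bin_width Histogram bin width in pixels for the mode (default 5);
#'   bins are centred on multiples of `bin_width`.
#' @return Boundary estimate in pixels.
#' @export
alternative_boundary <- function(unresolvable_lengths,
                                 method = c("median", "mode"),
                                 bin_width = 5) {
  method <- match.arg(method)
  x <- as.numeric(unresolvable_lengths)
  if (length(x) == 0) stop("empty length vector", call. = FALSE)
  if (method == "median") return(stats::median(x))
  stopifnot(bin_width > 0)
  # bins centred on multiples of bin_width, so a lone value maps to itself
  k <- round(x / bin_width)
  tab <- table(k)
  as.numeric(names(tab)[which.max(tab)]) * bin_width
}

#' Write a boundary report
#'
#' Serialises a fitted boundary and its near-boundary distribution as a
#' small key-value text file.
#'
#' @param boundary A `logistic_boundary`.
#' @param near A `near_boundary_distribution`, or `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_report <- function(boundary, near = NULL, path) {
  stopifnot(inherits(boundary, "logistic_boundary"))
  lines <- c(
    sprintf("intercept: %.10g", boundary$intercept),
    sprintf("slope: %.10g", boundary$slope),
    sprintf("L_boundary_px: %.10g", boundary$L_boundary),
    sprintf("n_resolvable: %d", boundary$n_resolvable),
    sprintf("n_unresolvable: %d", boundary$n_unresolvable),
    sprintf("degenerate: %s", tolower(as.character(boundary$degenerate)))
  )
  if (!is.null(near)) {
    stopifnot(inherits(near, "near_boundary_distribution"))
    lines <- c(lines,
               sprintf("near_boundary_mean_px: %.10g", near$mean),
               sprintf("near_boundary_sd_px: %.10g", near$sd))
  }
  writeLines(lines, path)
  invisible(path)
}
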