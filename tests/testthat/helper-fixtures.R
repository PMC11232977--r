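# Small in-code fixtures shared across test files.

# A hand-sized annotation data frame covering both classes and subtypes.
tiny_records <- function() {
  data.frame(
    image_id = c("img1", "img1", "img1", "img2", "img2"),
    object_id = as.character(1:5),
    imaged_length_px = c(72, 40, 15, 55, 33),
    resolvability = c("resolvable", "resolvable", "unresolvable",
                      "resolvable", "unresolvable"),
    subtype = c("plain", "partial", "none", "packed_aggregation", "plain"),
    stringsAsFactors = FALSE
  )
}

write_simple_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal VIAME detection CSV writer: one row per object.
write_viame_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- c(
    "# 1: Detection or Track-id,2: Video or Image Identifier,3: Unique Frame Identifier,4-7: Img-bbox(TL_x,TL_y,BR_x,BR_y),8: Detection confidence,9: Target Length,10-11+: Repeated Species,Confidence Pairs"
  )
  writeLines(c(header, rows), path)
  path
}

# Independent exact Bernoulli log-likelihood for the logistic model,
# used as the brute-force oracle for the boundary fit.
logistic_loglik <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  sum(y * eta - log1p(exp(eta)))
}

# Maximise the exact likelihood by general-purpose optimisation with the
# analytic score, started away from the glm solution so the check is
# independent of the fit path.
brute_force_logistic <- function(x, y) {
  nll <- function(b) -logistic_loglik(b, x, y)
  score <- function(b) {
    p <- stats::plogis(b[1] + b[2] * x)
    -c(sum(y - p), sum((y - p) * x))
  }
  fit <- stats::optim(c(0, 0.01), nll, score, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  fit$par
}
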