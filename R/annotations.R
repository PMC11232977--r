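#' @keywords internal
SUBTYPES <- c("plain", "bent", "partial", "axial", "motion_blurred",
              "packed_aggregation", "none")
RESOLVABILITY <- c("resolvable", "unresolvable")

#' Construct an annotation set
#'
#' An annotation set holds one record per imaged object: the image it was
#' seen in, an object identifier, its imaged length in pixels, the analyst's
#' resolvability call, and an optional subtype flag. Resolvable objects may
#' carry subtypes `bent`, `partial` (clipped by the frame edge), `axial`
#' (seen end-on), `motion_blurred` or `packed_aggregation`; unresolvable
#' objects are indistinct blobs and may only be `plain` or `none`.
#'
#' @param records A data frame with columns `image_id`, `object_id`,
#'   `imaged_length_px`, `resolvability`, `subtype` and optionally
#'   `timestamp_s`.
#' @return An object of class `annotation_set`: the validated records with
#'   attribute `n_images` (count of distinct `image_id`).
#' @examples
#' annotation_set(data.frame(
#'   image_id = "img1", object_id = c("a", "b"),
#'   imaged_length_px = c(72, 20),
#'   resolvability = c("resolvable", "unresolvable"),
#'   subtype = c("plain", "none")))
#' @export
annotation_set <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("image_id", "object_id", "imaged_length_px",
                "resolvability", "subtype")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!("timestamp_s" %in% names(records)))
    records$timestamp_s <- rep(NA_real_, nrow(records))
  records <- records[, c(required, "timestamp_s")]
  records$image_id <- as.character(records$image_id)
  records$object_id <- as.character(records$object_id)
  records$imaged_length_px <- as.numeric(records$imaged_length_px)
  records$resolvability <- as.character(records$resolvability)
  records$subtype <- as.character(records$subtype)

  if (nrow(records) > 0) {
    bad_len <- which(!is.finite(records$imaged_length_px) |
                       records$imaged_length_px <= 0)
    if (length(bad_len) > 0)
      stop("non-positive imaged length at row ", bad_len[1], call. = FALSE)
    bad_res <- which(!(records$resolvability %in% RESOLVABILITY))
    if (length(bad_res) > 0)
      stop("unknown resolvability class '",
           records$resolvability[bad_res[1]], "' at row ", bad_res[1],
           call. = FALSE)
    bad_sub <- which(!(records$subtype %in% SUBTYPES))
    if (length(bad_sub) > 0)
      stop("unknown subtype '", records$subtype[bad_sub[1]], "' at row ",
           bad_sub[1], call. = FALSE)
    bad_unres <- which(records$resolvability == "unresolvable" &
                         !(records$subtype %in% c("plain", "none")))
    if (length(bad_unres) > 0)
      stop("unresolvable record with subtype '",
           records$subtype[bad_unres[1]], "' at row ", bad_unres[1],
           "; unresolvable objects carry no shape subtype", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records,
            n_images = length(unique(records$image_id)),
            class = c("annotation_set", "data.frame"))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d object records over %d image(s)\n",
              nrow(x), n_images(x)))
  if (nrow(x) > 0) {
    tab <- table(x$resolvability)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of distinct images in an annotation set
#' @param a An [annotation_set].
#' @return Integer count of distinct `image_id` values.
#' @export
n_images <- function(a) {
  stopifnot(inherits(a, "annotation_set"))
  attr(a, "n_images")
}

#' Read an object-annotation table
#'
#' Two CSV dialects are supported. `simple_csv` has the header
#' `image_id,object_id,imaged_length_px,resolvability,subtype` (optionally
#' `timestamp_s`). `viame_csv` is the detection export of the VIAME
#' annotation platform: comment lines start with `#`, and data columns are
#' track id, image identifier, frame id, bounding box (TLx, TLy, BRx, BRy),
#' detection confidence, target length, then class-name/confidence pairs.
#' For `viame_csv` the imaged length is the bounding-box diagonal — the best
#' single-box proxy for an elongated target's projected length — unless the
#' target-length column holds a positive value, in which case that value is
#' used directly. The class name supplies the resolvability call (any name
#' containing "unresolvable" maps to unresolvable); a trailing attribute
#' token naming a subtype (e.g. `bent`) supplies the subtype, else
#' `plain`/`none`.
#'
#' @param path CSV file path.
#' @param dialect `"simple_csv"` (default) or `"viame_csv"`.
#' @return An [annotation_set].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("image_id,object_id,imaged_length_px,resolvability,subtype",
#'              "img1,a,72,resolvable,plain",
#'              "img1,b,20,unresolvable,none"), tmp)
#' read_annotations(tmp)
#' @export
read_annotations <- function(path, dialect = c("simple_csv", "viame_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "simple_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    required <- c("image_id", "object_id", "imaged_length_px",
                  "resolvability", "subtype")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0)
      stop("format error in ", path, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (nrow(df) > 0) {
      df$imaged_length_px <- suppressWarnings(as.numeric(df$imaged_length_px))
      if ("timestamp_s" %in% names(df))
        df$timestamp_s <- suppressWarnings(as.numeric(df$timestamp_s))
    }
    return(annotation_set(df))
  }
  read_viame_csv(path)
}

# VIAME detection CSV: comment lines start with '#'; fields 1..9 are
# track id, image id, frame id, TLx, TLy, BRx, BRy, confidence, target
# length; field 10 onward alternate class name / confidence, possibly
# followed by "(atr) ..." attribute tokens.
read_viame_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 10)
      stop("format error in ", path, ": fewer than 10 columns at data row ",
           i, call. = FALSE)
    bbox <- suppressWarnings(as.numeric(f[4:7]))
    if (any(is.na(bbox)))
      stop("format error in ", path, ": non-numeric bounding box at data row ",
           i, call. = FALSE)
    target_len <- suppressWarnings(as.numeric(f[9]))
    len <- if (is.finite(target_len) && target_len > 0) target_len else
      sqrt((bbox[3] - bbox[1])^2 + (bbox[4] - bbox[2])^2)
    cls <- tolower(f[10])
    resolv <- if (grepl("unresolvable", cls)) "unresolvable" else "resolvable"
    extra <- if (length(f) > 11) tolower(f[12:length(f)]) else character()
    sub_hit <- intersect(gsub("^\\(atr\\)\\s*", "", extra), SUBTYPES)
    subtype <- if (length(sub_hit) > 0) sub_hit[1] else
      if (resolv == "resolvable") "plain" else "none"
    data.frame(image_id = f[2], object_id = f[1], imaged_length_px = len,
               resolvability = resolv, subtype = subtype,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(), object_id = character(),
               imaged_length_px = numeric(), resolvability = character(),
               subtype = character(), stringsAsFactors = FALSE)
  annotation_set(df)
}

#' Write an annotation set to CSV
#'
#' Writes the `simple_csv` dialect; [read_annotations()] of the result
#' reproduces every field.
#'
#' @param a An [annotation_set].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  utils::write.csv(as.data.frame(a), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the records used for size-boundary fitting
#'
#' Size-based analyses (the logistic boundary fit, size histograms) exclude
#' records whose imaged length is unreliable: `partial` objects clipped by
#' the frame edge and `packed_aggregation` objects that were not
#' individually delineated. Counting analyses use a different, inclusive
#' filter — see [countable_per_image()].
#'
#' @param a An [annotation_set].
#' @return A data frame with columns `imaged_length_px` and `resolvability`,
#'   in the original record order.
#' @examples
#' a <- annotation_set(data.frame(
#'   image_id = "i", object_id = as.character(1:3),
#'   imaged_length_px = c(70, 30, 50),
#'   resolvability = c("resolvable", "unresolvable", "resolvable"),
#'   subtype = c("plain", "none", "partial")))
#' boundary_fit_subset(a)  # drops the partial record
#' @export
boundary_fit_subset <- function(a) {
  stopifnot(inherits(a, "annotation_set"))
  if (nrow(a) == 0) stop("empty annotation set", call. = FALSE)
  keep <- !(a$subtype %in% c("partial", "packed_aggregation"))
  out <- as.data.frame(a)[keep, c("imaged_length_px", "resolvability")]
  if (nrow(out) == 0)
    stop("all records excluded by the size-subset filter", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Countable objects per image
#'
#' Per-image counts of objects usable for numerical density: every record
#' classed `resolvable`, *including* subtypes `bent`, `partial`, `axial` and
#' `motion_blurred` (these are identifiable prey whose size, not existence,
#' is uncertain). Images present in the set but with zero countable objects
#' are retained with count 0.
#'
#' @param a An [annotation_set].
#' @return A data frame `(image_id, count)`, one row per distinct image.
#' @export
countable_per_image <- function(a) {
  stopifnot(inherits(a, "annotation_set"))
  if (nrow(a) == 0) stop("empty annotation set", call. = FALSE)
  ids <- unique(a$image_id)
  res <- a$image_id[a$resolvability == "resolvable"]
  counts <- vapply(ids, function(id) sum(res == id), integer(1))
  data.frame(image_id = ids, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Read a dive/strike event table
#'
#' CSV with header `time_s,depth_m,kind`, where `kind` is one of
#' `dive_start`, `dive_end`, `strike`. Depth is metres, positive downward.
#'
#' @param path CSV file path.
#' @return A data frame `(time_s, depth_m, kind)` sorted by time.
#' @export
read_dive_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "depth_m", "kind")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_kind <- which(!(df$kind %in% c("dive_start", "dive_end", "strike")))
  if (length(bad_kind) > 0)
    stop("unknown event kind '", df$kind[bad_kind[1]], "' at row ",
         bad_kind[1], call. = FALSE)
  bad_depth <- which(!is.finite(df$depth_m) | df$depth_m < 0)
  if (length(bad_depth) > 0)
    stop("negative or missing depth at row ", bad_depth[1], call. = FALSE)
  df[order(df$time_s), required]
}
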