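test_that("simple_csv annotations parse, validate, and count images", {
  path <- write_simple_csv(tiny_records())
  a <- read_annotations(path)
  expect_s3_class(a, "annotation_set")
  expect_equal(nrow(a), 5)
  expect_equal(n_images(a), 2)
  expect_equal(a$imaged_length_px[1:3], c(72, 40, 15))

  # header-only file gives an empty, valid set
  empty <- write_simple_csv(tiny_records()[0, ])
  a0 <- read_annotations(empty)
  expect_equal(nrow(a0), 0)
  expect_equal(n_images(a0), 0)

  # contract violations name the offending row
  bad <- tiny_records()
  bad$imaged_length_px[2] <- -3
  expect_error(read_annotations(write_simple_csv(bad)), "row 2")
  bad2 <- tiny_records()
  bad2$subtype[3] <- "mystery"
  expect_error(read_annotations(write_simple_csv(bad2)), "subtype")
  # missing column is a format error
  trunc <- tiny_records()[, -3]
  expect_error(read_annotations(write_simple_csv(trunc)), "missing column")
})

test_that("unresolvable records cannot carry shape subtypes", {
  rec <- tiny_records()
  rec$subtype[5] <- "bent"
  expect_error(annotation_set(rec), "unresolvable")
})

test_that("viame_csv dialect: diagonal length, target-length override, class mapping", {
  rows <- c(
    "1,frameA.png,0,0,0,30,40,0.9,0,krill,0.9",            # diagonal 50
    "2,frameA.png,0,10,10,40,40,0.8,64,krill,0.8",          # explicit length 64
    "3,frameB.png,1,5,5,8,9,0.7,0,unresolvable_object,0.7", # diag 5
    "4,frameB.png,1,0,0,6,8,0.7,0,krill,0.7,(atr) bent"     # subtype attr
  )
  a <- read_annotations(write_viame_csv(rows), dialect = "viame_csv")
  expect_equal(nrow(a), 4)
  expect_equal(n_images(a), 2)
  expect_equal(a$imaged_length_px, c(50, 64, 5, 10))
  expect_equal(a$resolvability,
               c("resolvable", "resolvable", "unresolvable", "resolvable"))
  expect_equal(a$subtype, c("plain", "plain", "none", "bent"))
})

test_that("write then read round-trips every field", {
  rec <- tiny_records()
  rec$timestamp_s <- c(1.5, 2.5, 3.5, 10, 11)
  a <- annotation_set(rec)
  path <- tempfile(fileext = ".csv")
  write_annotations(a, path)
  b <- read_annotations(path)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(n_images(a), n_images(b))
})

test_that("size-fit subset excludes partial and packed records and is idempotent", {
  a <- annotation_set(tiny_records())
  sub <- boundary_fit_subset(a)
  expect_equal(nrow(sub), 3)          # drops one partial, one packed
  expect_equal(sub$imaged_length_px, c(72, 15, 33))

  # identity on a set with no excluded subtypes
  plain <- tiny_records()
  plain$subtype <- c("plain", "plain", "none", "plain", "none")
  ap <- annotation_set(plain)
  expect_equal(boundary_fit_subset(ap)$imaged_length_px,
               ap$imaged_length_px)

  # applying the filter to an already-filtered set changes nothing
  refiltered <- annotation_set(data.frame(
    image_id = "x", object_id = as.character(seq_len(nrow(sub))),
    imaged_length_px = sub$imaged_length_px,
    resolvability = sub$resolvability,
    subtype = "plain", stringsAsFactors = FALSE))
  expect_equal(boundary_fit_subset(refiltered)$imaged_length_px,
               sub$imaged_length_px)

  all_excluded <- annotation_set(data.frame(
    image_id = "x", object_id = "1", imaged_length_px = 10,
    resolvability = "resolvable", subtype = "partial"))
  expect_error(boundary_fit_subset(all_excluded), "excluded")
})

test_that("size-fit subset count matches an independent recount on simulated flags", {
  set.seed(42)
  n <- 400
  resolvability <- sample(c("resolvable", "unresolvable"), n, replace = TRUE)
  subtype <- ifelse(resolvability == "resolvable",
                    sample(c("plain", "partial"), n, replace = TRUE,
                           prob = c(0.9, 0.1)),
                    "none")
  a <- annotation_set(data.frame(
    image_id = sprintf("img%02d", sample(1:10, n, replace = TRUE)),
    object_id = as.character(seq_len(n)),
    imaged_length_px = runif(n, 5, 100),
    resolvability = resolvability,
    subtype = subtype,
    stringsAsFactors = FALSE))
  flagged <- sum(subtype %in% c("partial", "packed_aggregation"))
  expect_equal(nrow(boundary_fit_subset(a)), n - flagged)
})

test_that("countable counts include shape subtypes and keep zero-count images", {
  rec <- tiny_records()  # img2 has 1 resolvable (packed) + 1 unresolvable
  counts <- countable_per_image(annotation_set(rec))
  expect_equal(counts$count[counts$image_id == "img1"], 2)
  expect_equal(counts$count[counts$image_id == "img2"], 1)

  # an image whose records are all unresolvable still appears, with 0
  rec2 <- rbind(rec, data.frame(
    image_id = "img3", object_id = "9", imaged_length_px = 12,
    resolvability = "unresolvable", subtype = "none"))
  counts2 <- countable_per_image(annotation_set(rec2))
  expect_equal(counts2$count[counts2$image_id == "img3"], 0)

  # total countable equals the number of resolvable-class records
  a <- annotation_set(rec2)
  expect_equal(sum(countable_per_image(a)$count),
               sum(a$resolvability == "resolvable"))
})

test_that("per-image counts match the simulator's own ledger", {
  sim <- generate_dataset(30, n_images = 8, true_r_res_mm = 1500, seed = 11)
  counts <- countable_per_image(sim$annotations)
  ledger <- sim$truth$per_image_counts
  merged <- merge(counts, ledger, by = "image_id")
  # hard boundary, no blur: countable == within-range exactly
  expect_equal(merged$count, merged$n_within_range)
})

test_that("dive event tables validate kind and depth", {
  ev <- data.frame(time_s = c(0, 10, 20), depth_m = c(0, 15, 0),
                   kind = c("dive_start", "strike", "dive_end"))
  p <- tempfile(fileext = ".csv")
  write.csv(ev, p, row.names = FALSE, quote = FALSE)
  out <- read_dive_events(p)
  expect_equal(out$kind, c("dive_start", "strike", "dive_end"))

  ev$kind[2] <- "lunge"
  write.csv(ev, p, row.names = FALSE, quote = FALSE)
  expect_error(read_dive_events(p), "unknown event kind")
})
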