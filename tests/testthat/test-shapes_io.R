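test_that("read_tps parses records, ids and scale", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=3", "0 0", "1 0", "1 1", "ID=a",
    "LM=1", "10 10", "ID=b", "SCALE=0.5"
  ), path)
  shapes <- read_tps(path, view = "trochlear")
  expect_length(shapes, 2L)
  expect_equal(shapes[[1]]$specimen_id, "a")
  expect_equal(shapes[[1]]$points, rbind(c(0, 0), c(1, 0), c(1, 1)))
  # scale multiplies stored coordinates
  expect_equal(shapes[[2]]$points, rbind(c(5, 5)))
  expect_equal(shapes[[2]]$scale_mm_per_unit, 0.5)
})

test_that("read_tps handles CURVES blocks, IMAGE fallback and flip_y", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=2", "0 0", "1 0",
    "CURVES=2", "POINTS=2", "2 1", "3 1", "POINTS=1", "4 2",
    "IMAGE=img_07.jpg"
  ), path)
  shapes <- read_tps(path, view = "medial")
  expect_equal(nrow(shapes[[1]]$points), 5L)  # curve points appended after fixed
  expect_equal(shapes[[1]]$points[3:5, 1], c(2, 3, 4))
  expect_equal(shapes[[1]]$specimen_id, "img_07.jpg")
  flipped <- read_tps(path, view = "medial", flip_y = TRUE)
  expect_equal(flipped[[1]]$points[, 2], -shapes[[1]]$points[, 2])
})

test_that("read_tps rejects malformed records with informative errors", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "ID=a"), path)  # one point short
  expect_error(read_tps(path), "record 1")
  writeLines(c("LM=2", "0 0", "1 zebra", "ID=a"), path)
  expect_error(read_tps(path), "non-numeric coordinate")
})

test_that("TPS write/read round trip preserves coordinates and order exactly", {
  sim <- small_sim(seed = 4L)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(sim$shapes, path)
  back <- read_tps(path, view = "synthetic_outline")
  expect_length(back, length(sim$shapes))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$specimen_id, sim$shapes[[i]]$specimen_id)
    expect_equal(back[[i]]$points, sim$shapes[[i]]$points, tolerance = 1e-12)
  }
  # idempotence: rewriting the re-read file changes nothing
  path2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("write_tps preserves heterogeneous point counts and record count", {
  shapes <- list(
    specimen_shape("s1", "trochlear", rand_config(3)),
    specimen_shape("s2", "trochlear", rand_config(7))
  )
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(shapes, path)
  lines <- readLines(path)
  expect_length(grep("^LM=", lines), 2L)
  back <- read_tps(path)
  expect_equal(vapply(back, function(s) nrow(s$points), integer(1)), c(3L, 7L))
  expect_equal(back[[2]]$points, shapes[[2]]$points, tolerance = 1e-12)
  expect_error(write_tps(list(), path), "non-empty")
})

test_that("slider tables validate indices and round-trip through files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("before slider after", "2 3 4", "3 4 5"), path)
  sl <- read_sliders(path, n_landmarks = 5L)
  expect_s3_class(sl, "slider_table")
  expect_equal(unclass(sl)[1, ], c(before = 2L, slider = 3L, after = 4L))

  # duplicate slider index across rows
  writeLines(c("2 3 4", "2 3 5"), path)
  expect_error(read_sliders(path), "more than once")
  # out-of-range index names the bound
  writeLines("2 3 9", path)
  expect_error(read_sliders(path, n_landmarks = 5L), "out of range")

  sl2 <- slider_table(1:3, 2:4, 3:5, n_landmarks = 6L)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_sliders(sl2, path2)
  expect_equal(unclass(read_sliders(path2)), unclass(sl2))
})

test_that("a 25-semilandmark open curve yields 23 slider rows", {
  scheme <- builtin_scheme("synthetic_outline")
  asm <- assemble_configuration(
    curves = list(outline = cbind(seq(0, 1, length.out = 40), 0.2 * sin(1:40))),
    scheme = scheme
  )
  expect_equal(nrow(asm$sliders), 23L)
  expect_equal(nrow(asm$shape$points), 25L)
})

test_that("metadata reading enforces the fossil-unassigned invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  md <- data.frame(specimen_id = c("a", "b"), taxon = c("t1", "t2"),
                   ecology_bin = c("arboreal_scansorial", "unassigned"),
                   is_fossil = c(FALSE, TRUE))
  utils::write.csv(md, path, row.names = FALSE)
  expect_silent(got <- read_metadata(path))
  expect_true(got$is_fossil[2])

  md$ecology_bin[2] <- "terrestrial_saltating"
  utils::write.csv(md, path, row.names = FALSE)
  expect_error(read_metadata(path), "fossil specimens must be unassigned")

  md$ecology_bin[2] <- "swimming"
  utils::write.csv(md, path, row.names = FALSE)
  expect_error(read_metadata(path), "unknown ecology_bin")
})

test_that("measurement reading enforces positivity and required columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_measurement_dataset(simulation_params(n_per_class = 3L, seed = 2L))
  utils::write.csv(sim$measurements, path, row.names = FALSE)
  got <- read_measurements(path)
  expect_equal(got, sim$measurements[, names(got)], tolerance = 1e-12)
  bad <- sim$measurements
  bad$WTS[2] <- -1
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_measurements(path), "WTS")
})

test_that("validate_dataset reports issues without failing", {
  sim <- small_sim(seed = 5L)
  rep0 <- validate_dataset(sim$shapes, sim$metadata, sim$params$scheme)
  expect_equal(nrow(rep0$issues), 0L)

  # drop one metadata row -> one missing-metadata issue
  md <- sim$metadata[-1L, ]
  rep1 <- validate_dataset(sim$shapes, md, sim$params$scheme)
  expect_equal(rep1$issues$type, "missing_metadata")
  expect_equal(rep1$issues$specimen_id, sim$shapes[[1]]$specimen_id)

  # fossil carrying a bin is flagged, not fatal
  md2 <- sim$metadata
  md2$ecology_bin[md2$is_fossil][1] <- "terrestrial_saltating"
  rep2 <- validate_dataset(sim$shapes, md2, sim$params$scheme)
  expect_true("fossil_labelled" %in% rep2$issues$type)

  # point-count mismatch against the scheme
  sim$shapes[[2]]$points <- sim$shapes[[2]]$points[-1, ]
  rep3 <- validate_dataset(sim$shapes, sim$metadata, sim$params$scheme)
  expect_true("point_count" %in% rep3$issues$type)
})
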