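test_that("a written TSV trio round-trips into a consistent sample", {
  s <- tiny_sample(n_row = 2, n_col = 2, n_genes = 6)
  dir <- withr::local_tempdir()
  paths <- write_sample_files(s, dir)
  got <- read_st_sample(paths$image, paths$spots, paths$counts,
                        sample_id = "tiny", patient_id = "pt1")
  expect_equal(nrow(got$spots), 4)
  expect_equal(ncol(got$expression), 6)
  expect_identical(got$spots$spot_id, s$spots$spot_id)
  expect_equal(unclass(got$expression), unclass(s$expression),
               ignore_attr = TRUE)
  expect_equal(got$spots$pixel_x, s$spots$pixel_x)
  expect_equal(load_image(got$image), s$image)
})

test_that("counts missing a spot raises an alignment error naming it", {
  s <- tiny_sample()
  dir <- withr::local_tempdir()
  paths <- write_sample_files(s, dir)
  df <- read.delim(paths$counts, check.names = FALSE)
  write.table(df[-2, ], paths$counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_st_sample(paths$image, paths$spots, paths$counts),
               "tiny_s2")
})

test_that("MatrixMarket and TSV encodings load identically", {
  set.seed(5)
  counts <- matrix(rpois(8 * 10, 3), 8, 10)
  s <- tiny_sample(n_row = 2, n_col = 4, n_genes = 10, counts = counts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_st_sample(s, d1, counts_format = "tsv")
  write_st_sample(s, d2, counts_format = "mtx")
  a <- read_st_sample(file.path(d1, "image.png"), file.path(d1, "spots.tsv"),
                      file.path(d1, "counts.tsv"))
  b <- read_st_sample(file.path(d2, "image.png"), file.path(d2, "spots.tsv"),
                      file.path(d2, "counts.mtx"))
  expect_equal(unclass(a$expression), unclass(b$expression),
               ignore_attr = TRUE)
  expect_identical(colnames(a$expression), colnames(b$expression))
})

test_that("spot table validation catches duplicates and bad coordinates", {
  df <- data.frame(spot_id = c("a", "a"), pixel_x = 1, pixel_y = 1,
                   array_row = 1:2, array_col = 1, annotation = 0)
  expect_error(spot_table(df), "duplicate spot_id")
  df$spot_id <- c("a", "b"); df$array_row <- 1
  expect_error(spot_table(df), "array_row")
  df$array_row <- 1:2; df$pixel_x <- c(-1, 1)
  expect_error(spot_table(df), "non-negative")
})

test_that("crop geometry follows the half-open centred-window convention", {
  img <- coord_image(300, 300)
  spots <- spot_table(data.frame(spot_id = "p", pixel_x = 100, pixel_y = 100,
                                 array_row = 1, array_col = 1, annotation = 0))
  s <- st_sample("g", "g", img, spots,
                 expression_matrix(matrix(1, 1, 1,
                                          dimnames = list("p", "G1")),
                                   layer = "raw_counts"))
  # window 150 centred at (100, 100): rows/cols [25, 175)
  ex <- extract_patches(s, window_px = 150, out_size_px = 150)
  expect_false(ex$boundary_mask[["p"]])
  expect_equal(ex$patches$patches[1, , , ], img[26:175, 26:175, ])
})

test_that("spots whose window exits the slide are boundary-excluded", {
  img <- coord_image(300, 300)
  spots <- spot_table(data.frame(
    spot_id = c("edge", "inner"), pixel_x = c(50, 150), pixel_y = c(50, 150),
    array_row = 1:2, array_col = 1, annotation = 0))
  s <- st_sample("g", "g", img, spots,
                 expression_matrix(matrix(1, 2, 1,
                                          dimnames = list(c("edge", "inner"), "G1")),
                                   layer = "raw_counts"))
  ex <- extract_patches(s, window_px = 150, out_size_px = 32)
  expect_true(ex$boundary_mask[["edge"]])
  expect_false(ex$boundary_mask[["inner"]])
  expect_identical(ex$patches$spot_ids, "inner")
  s$spots <- s$spots[1, ]; s$expression <- s$expression[1, , drop = FALSE]
  attr(s$expression, "layer") <- "raw_counts"
  expect_error(extract_patches(s, window_px = 150), "no spots retained")
})

test_that("boundary mask equals a brute-force window scan", {
  set.seed(42)
  H <- 97; W <- 83
  img <- coord_image(H, W)
  n <- 40
  spots <- spot_table(data.frame(
    spot_id = sprintf("s%02d", 1:n),
    pixel_x = sample(0:(W - 1), n, TRUE), pixel_y = sample(0:(H - 1), n, TRUE),
    array_row = rep(1:8, 5), array_col = rep(1:5, each = 8), annotation = 0))
  counts <- expression_matrix(matrix(1, n, 1,
                                     dimnames = list(spots$spot_id, "G1")),
                              layer = "raw_counts")
  s <- st_sample("b", "b", img, spots, counts)
  for (w in c(7, 8, 21)) {
    ex <- extract_patches(s, window_px = w, out_size_px = 8)
    lo_x <- floor(spots$pixel_x) - w %/% 2
    lo_y <- floor(spots$pixel_y) - w %/% 2
    expected <- lo_x < 0 | lo_y < 0 | lo_x + w > W | lo_y + w > H
    expect_identical(unname(ex$boundary_mask), expected)
  }
})

test_that("patch extraction is translation-consistent", {
  base <- tiny_sample(n_row = 2, n_col = 2, img_side = 240, offset = 70,
                      spacing = 50)
  dx <- 13; dy <- 7
  img <- load_image(base$image)
  big <- array(0, c(240 + dy, 240 + dx, 3))
  big[(dy + 1):(dy + 240), (dx + 1):(dx + 240), ] <- img
  shifted <- base
  shifted$image <- big
  shifted$spots$pixel_x <- base$spots$pixel_x + dx
  shifted$spots$pixel_y <- base$spots$pixel_y + dy
  a <- extract_patches(base, window_px = 40, out_size_px = 40)
  b <- extract_patches(shifted, window_px = 40, out_size_px = 40)
  expect_equal(a$patches$patches, b$patches$patches)
})

test_that("window == out size makes the resize an identity", {
  s <- tiny_sample(img_side = 200, offset = 60, spacing = 40)
  img <- load_image(s$image)
  ex <- extract_patches(s, window_px = 33, out_size_px = 33)
  x0 <- s$spots$pixel_x[1] - 16; y0 <- s$spots$pixel_y[1] - 16
  expect_identical(ex$patches$patches[1, , , ],
                   img[(y0 + 1):(y0 + 33), (x0 + 1):(x0 + 33), ])
})

test_that("patch standardization follows ((x/255) - mean) / sd", {
  ps <- structure(list(patches = array(255, c(2, 4, 4, 3)), spot_ids = c("a", "b"),
                       window_px = 4L, out_size_px = 4L, normalized = FALSE),
                  class = "patch_set")
  out <- normalize_patches(ps, c(1, 1, 1), c(1, 1, 1))
  expect_true(all(out$patches == 0))
  ps0 <- ps; ps0$patches[] <- 0
  out0 <- normalize_patches(ps0, rep(0.5, 3), rep(0.25, 3))
  expect_true(all(out0$patches == -2))
  expect_error(normalize_patches(ps, rep(0, 3), rep(0, 3)), "degenerate")
  expect_error(normalize_patches(out, c(0, 0, 0), c(1, 1, 1)),
               "already normalized")
})

test_that("standardizing with its own statistics re-centres the training set", {
  set.seed(9)
  ps <- structure(list(patches = array(runif(10 * 6 * 6 * 3, 0, 255),
                                       c(10, 6, 6, 3)),
                       spot_ids = sprintf("s%d", 1:10), window_px = 6L,
                       out_size_px = 6L, normalized = FALSE),
                  class = "patch_set")
  st <- channel_stats(ps)
  out <- normalize_patches(ps, st$mean, st$sd)
  for (ch in 1:3) {
    expect_equal(mean(out$patches[, , , ch]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(out$patches[, , , ch])), 1, tolerance = 1e-10)
  }
})

test_that("predictions TSV round-trips at float precision", {
  set.seed(2)
  pred <- matrix(rnorm(2 * 3), 2, 3)
  prob <- c(0.12345678901234, 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(c("s1", "s2"), c("GA", "GB", "GC"), pred, prob, path)
  got <- read_predictions(path)
  expect_identical(got$spot_ids, c("s1", "s2"))
  expect_identical(got$gene_names, c("GA", "GB", "GC"))
  expect_equal(unname(got$predicted), pred, tolerance = 1e-15)
  expect_equal(got$tumor_prob, prob, tolerance = 1e-15)
  expect_error(write_predictions(c("s1", "s2"), character(0),
                                 pred[, 0], prob, path), "non-empty")
  expect_error(write_predictions("s1", c("GA", "GB", "GC"), pred, prob, path),
               "shape mismatch")
})
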