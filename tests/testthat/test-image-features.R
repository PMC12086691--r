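# Patch extraction, histogram features and the feature matrix builder.

const_image <- function(h, w, rgb = c(255, 255, 255)) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("extract_patch honors geometry and the border clipping rule", {
  img <- const_image(101, 101, c(10, 20, 30))
  blk <- extract_patch(img, c(50, 50), 11)
  expect_equal(dim(blk), c(11, 11, 3))
  expect_true(all(blk[, , 2] == 20))
  # corner centre: patch clipped to the valid region
  blk0 <- extract_patch(img, c(0, 0), 11)
  expect_equal(dim(blk0), c(6, 6, 3))
  expect_error(extract_patch(img, c(200, 50), 11, barcode = "spotX"),
               "spotX")
})

test_that("histogram counts land in the right bins and are conserved", {
  img <- const_image(20, 20)
  blk <- extract_patch(img, c(10, 10), 11)
  h <- histogram_features(blk, n_bins = 10)
  # all-white patch: all mass in the last bin of each channel
  expect_equal(h, rep(c(rep(0, 9), 121), 3))
  # derived 2x2 example, checked by an explicit per-pixel binning oracle
  blk2 <- array(0, c(2, 2, 3))
  blk2[, , 1] <- c(0, 100, 200, 255)
  expect_equal(histogram_features(blk2, n_bins = 4),
               oracle_hist(blk2, n_bins = 4))
  expect_equal(histogram_features(blk2, n_bins = 4)[1:4], c(1, 1, 0, 2))
  # conservation under clipping for random patches
  set.seed(5)
  rimg <- array(sample(0:255, 30 * 40 * 3, TRUE), c(30, 40, 3))
  for (ctr in list(c(0, 0), c(29, 39), c(15, 2), c(7, 21))) {
    blk <- extract_patch(rimg, ctr, 9)
    h <- histogram_features(blk, n_bins = 7)
    npix <- prod(dim(blk)[1:2])
    expect_equal(as.vector(tapply(h, rep(1:3, each = 7), sum)),
                 rep(npix, 3))
    expect_equal(h, oracle_hist(blk, 7))
  }
  expect_error(histogram_features(array(0, c(0, 0, 3)), 5), "empty patch")
})

test_that("build_feature_matrix has the documented shape and determinism", {
  img <- const_image(80, 80)
  spots <- data.frame(barcode = c("a", "b", "c"),
                      pixel_row = c(20, 40, 60), pixel_col = c(20, 40, 60))
  fm <- build_feature_matrix(img, spots, feature_config(), 11)
  expect_equal(dim(fm$values), c(3, 3 * 3 * 10))   # scales x channels x bins
  # constant white image: every row identical
  expect_equal(fm$values[1, ], fm$values[2, ])
  expect_equal(fm$values[2, ], fm$values[3, ])
  expect_true(all(fm$values == floor(fm$values)) && min(fm$values) >= 0)
  expect_match(fm$feature_names[1], "^s0.5_R_bin1$")
  bad <- data.frame(barcode = "zz", pixel_row = 500, pixel_col = 2)
  expect_error(build_feature_matrix(img, bad, feature_config(), 11), "zz")
})

test_that("feature rows separate a two-region synthetic image perfectly", {
  coords <- data.frame(barcode = sprintf("s%02d", 1:16),
                       array_row = rep(0:3, each = 4),
                       array_col = rep(0:3, 4),
                       pixel_row = 11 + rep(0:3, each = 4) * 16,
                       pixel_col = 11 + rep(0:3, 4) * 16)
  region <- ifelse(coords$array_col < 2, 1L, 2L)
  img <- simulate_tissue_image(coords, region, 11, 5, palette_seed = 4)
  fm <- build_feature_matrix(img, coords, feature_config(scales = 1), 11)
  lab <- cluster_factors(fm$values, "kmeans", n_clusters = 2, seed = 1)
  expect_equal(unname(clustering_scores(lab, region)["ari"]), 1)
})

test_that("features are invariant to a rigid translation away from borders", {
  set.seed(9)
  base <- array(sample(0:255, 50 * 50 * 3, TRUE), c(50, 50, 3))
  big <- array(0, c(60, 60, 3))
  big[6:55, 6:55, ] <- base
  spots1 <- data.frame(barcode = "a", pixel_row = 25, pixel_col = 25)
  spots2 <- data.frame(barcode = "a", pixel_row = 30, pixel_col = 30)
  f1 <- build_feature_matrix(base, spots1, feature_config(scales = c(0.5, 1)),
                             11)
  f2 <- build_feature_matrix(big, spots2, feature_config(scales = c(0.5, 1)),
                             11)
  expect_equal(f1$values, f2$values)
})

test_that("user feature tables are validated, aligned and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  M <- matrix(abs(rnorm(12)), 4, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  df <- data.frame(barcode = c("b3", "b1", "b4", "b2"), M)
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  feats <- load_user_features(tmp, barcodes = c("b1", "b2", "b3", "b4"))
  expect_identical(feats$barcodes, c("b1", "b2", "b3", "b4"))
  expect_equal(unname(feats$values["b3" == c("b1","b2","b3","b4"), ]),
               unname(M[1, ]))
  # round trip through write_features
  out <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, out)
  again <- load_user_features(out, barcodes = feats$barcodes)
  expect_equal(again$values, feats$values)
  # negative entry rejected with row/column named
  df$f2[2] <- -1
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_user_features(tmp, c("b1", "b2", "b3", "b4")),
               "b1.*f2")
  # missing barcode listed
  expect_error(load_user_features(out, c("b1", "b9")), "b9")
})

test_that("PNG and PPM image I/O round-trips 8-bit RGB exactly", {
  set.seed(3)
  img <- array(sample(0:255, 15 * 12 * 3, TRUE), c(15, 12, 3))
  for (ext in c(".png", ".ppm")) {
    f <- withr::local_tempfile(fileext = ext)
    write_image(img, f)
    back <- read_image(f)
    expect_equal(back, img, ignore_attr = TRUE)
  }
  bad <- withr::local_tempfile(fileext = ".ppm")
  writeLines("Q9 bogus", bad)
  expect_error(read_image(bad), "PPM")
  expect_error(read_image(withr::local_tempfile(fileext = ".tiff")),
               "not found")
})
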