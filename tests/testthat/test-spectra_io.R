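test_that("spectra_set validates its inputs", {
  wl <- seq(350, 359)
  refl <- matrix(0.5, 3, 10)
  expect_s3_class(spectra_set(refl, rep("rice", 3), rep(1, 3), wl),
                  "SpectraSet")
  expect_error(spectra_set(refl[, 1:9], rep("rice", 3), rep(1, 3), wl),
               "bands")
  expect_error(spectra_set(refl, rep("rice", 2), rep(1, 3), wl), "entry")
  expect_error(spectra_set(refl, rep("weed", 3), rep(1, 3), wl), "label")
  refl[2, 4] <- NA
  expect_error(spectra_set(refl, rep("rice", 3), rep(1, 3), wl), "finite")
  expect_error(spectra_set(matrix(0.5, 2, 3), rep("rice", 2), c(1, 1),
                           c(400, 400, 410)), "increasing")
})

test_that("CSV round trip preserves the reflectance matrix", {
  data <- tiny_spectra(n = 4L, m = 2151L)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  save_spectra(data, path)
  back <- load_spectra(path)
  expect_equal(n_spectra(back), 4L)
  expect_equal(back$reflectance, data$reflectance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(data$labels))
  expect_equal(back$batch, data$batch)
  expect_equal(back$wavelengths, data$wavelengths)
})

test_that("an empty set writes a header-only file that reloads", {
  data <- tiny_spectra(n = 2L, m = 20L)
  empty <- subset_spectra(data, integer(0))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  save_spectra(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(n_spectra(load_spectra(path)), 0L)
})

test_that("malformed files are rejected", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  # one data row with a reflectance cell missing
  writeLines(c("350,351,352,label,batch", "0.1,0.2,rice,1"), path)
  expect_error(load_spectra(path), "missing|malformed")
  writeLines(c("350,351,junk,label,batch", "0.1,0.2,0.3,rice,1"), path)
  expect_error(load_spectra(path), "malformed header")
  writeLines(c("350,351,352", "0.1,0.2,0.3"), path)
  expect_error(load_spectra(path), "label")
  expect_error(load_spectra(tempfile()), "not found")
})

test_that("the full-size layout writes one row per specimen", {
  data <- generate_spectra(sim_config(seed = 3))
  expect_equal(n_spectra(data), 660L)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  save_spectra(data, path)
  expect_equal(length(readLines(path)), 661L)
})

test_that("split_by_batch partitions without loss or overlap", {
  data <- tiny_spectra(n = 30L, m = 20L, seed = 4L)
  data$batch <- sample(1:3, 30, replace = TRUE)
  sp <- split_by_batch(data, c(1, 2), 3)
  expect_equal(n_spectra(sp$train) + n_spectra(sp$test), 30L)
  expect_equal(table(sp$train$labels) + table(sp$test$labels),
               table(data$labels))
  expect_error(split_by_batch(data, c(1, 2), 2), "disjoint")
  all_train <- split_by_batch(data, 1:3, integer(0))
  expect_equal(n_spectra(all_train$test), 0L)
})
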