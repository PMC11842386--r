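test_that("the generator reproduces the three-batch study layout", {
  layout <- benchmark_layout(seed = 2)
  expect_equal(n_spectra(layout$train), 495L)
  expect_equal(n_spectra(layout$test), 165L)
  expect_equal(as.vector(table(layout$train$labels)), c(252L, 243L))
  expect_equal(as.vector(table(layout$test$labels)), c(95L, 70L))
  expect_true(all(layout$train$batch %in% 1:2))
  expect_true(all(layout$test$batch == 3L))
  full <- generate_spectra(sim_config(seed = 2))
  expect_equal(dim(full$reflectance), c(660L, 2151L))
  expect_true(all(full$reflectance >= 0 & full$reflectance <= 1))
})

test_that("generation is deterministic given the seed", {
  a <- generate_spectra(sim_config(n_rice = c(4, 4), n_barnyard = c(4, 4),
                                   seed = 9))
  b <- generate_spectra(sim_config(n_rice = c(4, 4), n_barnyard = c(4, 4),
                                   seed = 9))
  expect_identical(a$reflectance, b$reflectance)
  c <- generate_spectra(sim_config(n_rice = c(4, 4), n_barnyard = c(4, 4),
                                   seed = 10))
  expect_false(identical(a$reflectance, c$reflectance))
})

test_that("a null class effect makes the classes indistinguishable", {
  cfg <- sim_config(n_rice = c(3, 3), n_barnyard = c(3, 3),
                    red_edge_shift = 0, pigment_delta = 0, noise_sd = 0,
                    within_red_edge_sd = 0, within_depth_sd = 0,
                    amp_sd = 0, baseline_sd = 0, seed = 1)
  data <- generate_spectra(cfg)
  b1 <- data$reflectance[data$batch == 1, ]
  expect_true(all(abs(sweep(b1, 2, b1[1, ]) ) < 1e-12))
})

test_that("the class effect is learnable and vanishes when zeroed", {
  layout <- small_layout(seed = 3, per_class = 25)
  pp <- preprocess_spectra(layout$train, layout$test, method = "snv")
  fit <- e1071::svm(pp$train$reflectance, pp$train$labels, kernel = "radial")
  acc <- mean(predict(fit, pp$test$reflectance) == pp$test$labels)
  expect_gt(acc, 0.9)
  null <- small_layout(seed = 3, per_class = 25, red_edge_shift = 0,
                       pigment_delta = 0)
  np <- preprocess_spectra(thin_bands(null$train), thin_bands(null$test),
                           method = "snv")
  nfit <- e1071::svm(np$train$reflectance, np$train$labels, kernel = "radial")
  nacc <- mean(predict(nfit, np$test$reflectance) == np$test$labels)
  expect_gt(nacc, 0.25)
  expect_lt(nacc, 0.75)
})

test_that("classifier accuracy degrades as noise grows", {
  accs <- vapply(c(0.006, 0.12, 0.6), function(ns) {
    layout <- small_layout(seed = 11, per_class = 25, noise_sd = ns)
    pp <- preprocess_spectra(thin_bands(layout$train),
                             thin_bands(layout$test), method = "snv")
    fit <- e1071::svm(pp$train$reflectance, pp$train$labels,
                      kernel = "radial")
    mean(predict(fit, pp$test$reflectance) == pp$test$labels)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
})
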