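test_that("vegetation indices have the documented 163-column layout", {
  data <- tiny_spectra(n = 5L, m = 600L)   # grid 350..949 covers all bands
  vi <- vegetation_indices(data)
  expect_equal(ncol(vi), 163L)
  expect_equal(sum(startsWith(colnames(vi), "NDVI_")), 80L)
  expect_equal(sum(startsWith(colnames(vi), "RVI_")), 80L)
  expect_equal(tail(colnames(vi), 3), c("TVI", "PRI", "NPCI"))
  # normalized-difference indices are bounded for positive reflectance
  expect_true(all(abs(vi[, startsWith(colnames(vi), "NDVI_")]) <= 1))
  expect_true(all(abs(vi[, c("PRI", "NPCI")]) <= 1))
})

test_that("vegetation indices compute the defining band arithmetic", {
  wl <- seq(350L, 949L)
  refl <- matrix(0.3, 2, length(wl))
  flat <- spectra_set(refl, c("rice", "rice"), c(1, 1), wl)
  vi <- vegetation_indices(flat)
  expect_true(all(abs(vi[, startsWith(colnames(vi), "NDVI_")]) < 1e-12))
  expect_true(all(abs(vi[, startsWith(colnames(vi), "RVI_")] - 1) < 1e-12))
  expect_true(all(abs(vi[, c("TVI", "PRI", "NPCI")]) < 1e-12))
  refl2 <- refl
  refl2[1, match(724, wl)] <- 0.5
  refl2[1, match(601, wl)] <- 0.1
  two <- spectra_set(refl2, c("rice", "rice"), c(1, 1), wl)
  vi2 <- vegetation_indices(two)
  expect_equal(unname(vi2[1, "NDVI_724_601"]), 0.4 / 0.6)
  expect_equal(unname(vi2[1, "RVI_724_601"]), 5)
  short <- tiny_spectra(n = 2L, m = 100L)
  expect_error(vegetation_indices(short), "lacks")
})

test_that("SPA successive projections match a brute-force oracle", {
  # oracle: explicit orthogonal projection onto the complement of the
  # selected span, recomputed from scratch at every step
  brute_chain <- function(X, j0, k) {
    sel <- j0
    for (step in seq_len(k - 1)) {
      S <- X[, sel, drop = FALSE]
      Pc <- diag(nrow(X)) - S %*% solve(crossprod(S)) %*% t(S)
      norms <- colSums((Pc %*% X)^2)
      norms[sel] <- -Inf
      sel <- c(sel, which.max(norms))
    }
    sel
  }
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(20), 5, 4)
    y <- rnorm(5)
    fit <- spa_select(X, y, max_bands = 4, folds = 5, starts = 1L, seed = 1)
    chain <- brute_chain(X, 1L, 4)
    k <- fit$chosen_step
    expect_equal(fit$selected, chain[seq_len(k)])
  }
})

test_that("SPA with max_bands = 1 performs an exhaustive singleton scan", {
  set.seed(22)
  n <- 30
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X[, 4] + rnorm(n, 0, 0.1)
  fit <- spa_select(X, y, max_bands = 1, folds = 5, seed = 9)
  # oracle: same fold assignment, every singleton scored
  set.seed(9)
  fold_id <- sample(rep_len(1:5, n))
  rmse <- vapply(1:6, function(j) {
    deepbgs:::lm_rmsecv(X[, j, drop = FALSE], y, fold_id)
  }, numeric(1))
  expect_equal(fit$selected, which.min(rmse))
  expect_equal(fit$rmsecv, min(rmse))
})

test_that("SPA selections are linearly independent and can span fully", {
  set.seed(23)
  X <- matrix(rnorm(40), 10, 4)
  y <- rowSums(X)                       # needs all columns, no noise
  fit <- spa_select(X, y, max_bands = 4, folds = 5, seed = 1)
  expect_equal(sort(fit$selected), 1:4)
  expect_equal(qr(X[, fit$selected])$rank, length(fit$selected))
})

test_that("CARS decays the retained set and is seed-reproducible", {
  set.seed(31)
  n <- 50; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 5] - X[, 20] + rnorm(n, 0, 0.2)
  fit <- cars_select(X, y, n_runs = 20, folds = 5, seed = 4)
  tr <- fit$criterion_trace
  expect_equal(nrow(tr), 20L)
  expect_true(all(diff(tr$n_retained) <= 0))
  expect_gte(tr$n_retained[1], 0.5 * p)      # first run keeps most bands
  expect_equal(fit$chosen_step, which.min(tr$rmsecv))
  fit2 <- cars_select(X, y, n_runs = 20, folds = 5, seed = 4)
  expect_identical(fit$selected, fit2$selected)
})

test_that("internal SIMPLS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(41)
  X <- matrix(rnorm(40 * 8), 40, 8)
  colnames(X) <- paste0("b", 1:8)
  y <- X %*% rnorm(8) + rnorm(40, 0, 0.3)
  fit <- pls_fit(X, y, ncomp = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(cor(predict(fit, X), pred_ref), 1, tolerance = 1e-6)
})

test_that("PCA reduction picks its dimensionality on the training set", {
  set.seed(51)
  n <- 60
  X <- cbind(matrix(rnorm(n * 3, sd = 3), n, 3), matrix(rnorm(n * 7), n, 7))
  y <- ifelse(X[, 1] > 0, "barnyard_grass", "rice")
  out <- reduce_pca(X[1:40, ], X[41:60, ], y[1:40], max_components = 4,
                    folds = 5, seed = 1)
  expect_equal(ncol(out$train), out$n_components)
  expect_equal(ncol(out$test), out$n_components)
  expect_equal(nrow(out$trace), 4L)
  expect_equal(out$n_components, which.max(out$trace$cv_acc))
  # reconstruction error is non-increasing in the component count
  ctr <- scale(X[1:40, ], center = out$pca$center, scale = FALSE)
  errs <- vapply(1:4, function(k) {
    rec <- out$pca$x[, 1:k, drop = FALSE] %*% t(out$pca$rotation[, 1:k,
                                                                 drop = FALSE])
    sum((ctr - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # full-rank projection then back-projection recovers the data
  full <- out$pca$x %*% t(out$pca$rotation)
  expect_equal(full, unclass(ctr), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("t-SNE hook is seeded and separates distinct clusters", {
  set.seed(61)
  X <- rbind(matrix(rnorm(25 * 4, mean = 0), 25, 4),
             matrix(rnorm(25 * 4, mean = 8), 25, 4))
  emb <- reduce_tsne(X, dims = 2, seed = 5, perplexity = 10, max_iter = 300)
  expect_equal(dim(emb), c(50L, 2L))
  emb2 <- reduce_tsne(X, dims = 2, seed = 5, perplexity = 10, max_iter = 300)
  expect_identical(emb, emb2)
  grp <- rep(1:2, each = 25)
  within <- mean(dist(emb[grp == 1, ])) + mean(dist(emb[grp == 2, ]))
  between <- mean(as.matrix(dist(emb))[grp == 1, grp == 2])
  expect_gt(between, within / 2)
  expect_error(reduce_tsne(X, dims = 50), "smaller")
  # exact-gradient path for dimensionalities beyond the Barnes-Hut limit
  emb4 <- reduce_tsne(X[1:30, ], dims = 4, seed = 2, perplexity = 8,
                      max_iter = 120)
  expect_equal(dim(emb4), c(30L, 4L))
  expect_identical(emb4, reduce_tsne(X[1:30, ], dims = 4, seed = 2,
                                     perplexity = 8, max_iter = 120))
})
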