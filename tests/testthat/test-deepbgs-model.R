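# Small input geometry valid for three 2x2 poolings: 8 windows of 8 bands
tiny_wc <- function() window_config(8L, 8L, m = 64L)

tiny_array <- function(n, seed = 1L) {
  set.seed(seed)
  array(rnorm(n * 8 * 8), c(n, 8L, 8L))
}

test_that("the shape trace ends in a 25-step sequence for the canonical config", {
  sh <- forward_shapes(deepbgs_config(), window_config(200L, 150L))
  expect_equal(sh$input, c(1L, 14L, 200L))
  expect_equal(sh$stem, c(16L, 14L, 200L))
  expect_equal(sh$block1_pool, c(32L, 7L, 100L))
  expect_equal(sh$block2_pool, c(64L, 3L, 50L))
  expect_equal(sh$block3_pool, c(128L, 1L, 25L))
  expect_equal(sh$reduce2, c(64L, 1L, 25L))
  expect_equal(sh$lstm_steps, 25L)
  expect_equal(sh$lstm_features, 64L)
})

test_that("shape tracing handles other window settings and degenerate ones", {
  wc <- window_config(64L, 64L)
  expect_equal(window_count(wc), 33L)
  sh <- forward_shapes(deepbgs_config(), wc)
  expect_equal(sh$block1_pool[2], 16L)
  expect_equal(sh$block2_pool[2], 8L)
  expect_equal(sh$block3_pool[2], 4L)
  expect_equal(sh$lstm_features, 64L * 4L)
  # pooling never increases a dimension
  pools <- sh[grepl("_pool$", names(sh))]
  prev <- sh$stem[2:3]
  for (p in pools) {
    expect_true(all(p[2:3] <= prev))
    prev <- p[2:3]
  }
  # 7 windows pool to heights 3, 1, 0: invalid
  expect_error(forward_shapes(deepbgs_config(), window_config(8L, 3L, 26L)),
               "collapses")
})

test_that("CBAM preserves shape, gates in (0,1), and kills zero input", {
  set.seed(2)
  x <- array(rnorm(16 * 6 * 10), c(16, 6, 10))
  out <- cbam_block(x, seed = 3)
  expect_equal(dim(out), dim(x))
  cg <- attr(out, "channel_gate")
  sg <- attr(out, "spatial_gate")
  expect_length(cg, 16L)
  expect_equal(dim(sg), c(6L, 10L))
  expect_true(all(cg > 0 & cg < 1))
  expect_true(all(sg > 0 & sg < 1))
  # multiplicative gating: output magnitudes never exceed input magnitudes
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  zero <- cbam_block(array(0, c(8, 4, 4)), seed = 3)
  expect_true(all(zero == 0))
})

test_that("builds are deterministic and the two variants share the trunk", {
  m1 <- build_deepbgs(deepbgs_config(), tiny_wc(), seed = 11)
  m2 <- build_deepbgs(deepbgs_config(), tiny_wc(), seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_deepbgs(deepbgs_config(), tiny_wc(), seed = 12)
  expect_false(identical(m1$params, m3$params))
  nolstm <- build_deepbgs(deepbgs_config(use_lstm = FALSE), tiny_wc(),
                          seed = 11)
  trunk <- setdiff(names(m1$params),
                   c("lstm1_Wx", "lstm1_Wh", "lstm1_b",
                     "lstm2_Wx", "lstm2_Wh", "lstm2_b"))
  expect_true(all(trunk %in% names(nolstm$params)))
  for (nm in trunk) {
    expect_equal(dim(m1$params[[nm]]), dim(nolstm$params[[nm]]))
  }
})

test_that("backpropagation matches finite differences for both variants", {
  X <- tiny_array(3, seed = 21)
  xb <- aperm(X, c(2, 3, 1))
  y <- c(0L, 1L, 0L)
  cases <- list(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE),
                c(TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE))
  for (case in cases) {
    use_lstm <- case[1]; block_bn <- case[2]; frozen <- case[3]
    model <- build_deepbgs(deepbgs_config(use_lstm = use_lstm,
                                          block_batchnorm = block_bn),
                           tiny_wc(), seed = 7)
    mask <- matrix(1, length(model$params$fc2_b), 3)
    nbn <- if (block_bn) 7L else 1L
    empty <- replicate(nbn, numeric(0), simplify = FALSE)
    boot <- deepbgs:::cpp_net_grad(model$params, xb, y, use_lstm, block_bn,
                                   FALSE, empty, empty, mask)
    bn_m <- lapply(boot$bn_mean, as.numeric)
    bn_v <- lapply(boot$bn_var, as.numeric)
    res <- if (frozen) {
      deepbgs:::cpp_net_grad(model$params, xb, y, use_lstm, block_bn,
                             TRUE, bn_m, bn_v, mask)
    } else boot
    loss_at <- function(P) {
      deepbgs:::cpp_net_grad(P, xb, y, use_lstm, block_bn, frozen,
                             bn_m, bn_v, mask)$loss
    }
    set.seed(31)
    for (trial in 1:2) {
      V <- lapply(model$params, function(p) {
        array(rnorm(length(p)), dim = if (is.null(dim(p))) length(p)
              else dim(p))
      })
      an <- sum(mapply(function(g, v) sum(as.numeric(g) * as.numeric(v)),
                       res$grads[names(V)], V))
      eps <- 1e-6
      P1 <- model$params; P2 <- model$params
      for (nm in names(V)) {
        P1[[nm]] <- P1[[nm]] + eps * V[[nm]]
        P2[[nm]] <- P2[[nm]] - eps * V[[nm]]
      }
      fd <- (loss_at(P1) - loss_at(P2)) / (2 * eps)
      expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 2e-3)
    }
  }
})

test_that("softmax outputs are normalized probabilities", {
  model <- build_deepbgs(deepbgs_config(), tiny_wc(), seed = 5)
  X <- tiny_array(4, seed = 6)
  mask <- matrix(1, length(model$params$fc2_b), 4)
  empty <- replicate(7L, numeric(0), simplify = FALSE)
  res <- deepbgs:::cpp_net_grad(model$params, aperm(X, c(2, 3, 1)),
                                c(0L, 1L, 0L, 1L), TRUE, TRUE, FALSE,
                                empty, empty, mask)
  expect_true(all(res$prob_pos >= 0 & res$prob_pos <= 1))
})

test_that("training runs, records history, and is reproducible", {
  set.seed(41)
  n <- 22
  X <- tiny_array(n, seed = 42)
  cls <- rep(c("barnyard_grass", "rice"), each = n / 2)
  # plant a strong class-dependent mean shift
  X[cls == "barnyard_grass", , 1:4] <- X[cls == "barnyard_grass", , 1:4] + 2
  cfg <- train_config(learning_rate = 3e-3, epochs = 25, seed = 3)
  m1 <- deepbgs_train(build_deepbgs(deepbgs_config(), tiny_wc(), seed = 1),
                      X, cls, cfg)
  expect_equal(nrow(m1$history), 25L)
  expect_true(all(is.finite(m1$history$loss)))
  expect_gt(tail(m1$history$acc, 1), 0.8)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- deepbgs_train(build_deepbgs(deepbgs_config(), tiny_wc(), seed = 1),
                      X, cls, cfg)
  expect_identical(m1$params, m2$params)
  expect_error(deepbgs_train(build_deepbgs(deepbgs_config(), tiny_wc()),
                             X, rep("rice", n), cfg), "single class")
})

test_that("prediction is order-invariant and respects shapes", {
  n <- 10
  X <- tiny_array(n, seed = 51)
  cls <- rep(c("barnyard_grass", "rice"), each = 5)
  model <- deepbgs_train(build_deepbgs(deepbgs_config(), tiny_wc(), seed = 2),
                         X, cls,
                         train_config(learning_rate = 1e-3, epochs = 2,
                                      seed = 1))
  p <- predict_proba(model, X)
  expect_true(all(p >= 0 & p <= 1))
  perm <- sample(n)
  expect_equal(predict_proba(model, X[perm, , , drop = FALSE]), p[perm],
               tolerance = 1e-12)
  # duplicated sample gives identical probabilities
  dup <- X[c(1, 1, 3), , , drop = FALSE]
  pd <- predict_proba(model, dup)
  expect_equal(pd[1], pd[2])
  bad <- array(0, c(2, 8, 9))
  expect_error(predict_proba(model, bad), "window configuration")
  untrained <- build_deepbgs(deepbgs_config(), tiny_wc(), seed = 2)
  expect_error(predict_proba(untrained, X), "train")
  lab <- predict(model, X)
  expect_s3_class(lab, "factor")
  expect_equal(as.character(lab),
               ifelse(p >= 0.5, "barnyard_grass", "rice"))
})
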