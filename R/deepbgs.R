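#' Network architecture configuration
#'
#' Hyperparameters of the subsequence-matrix classifier: a 3x4 stem
#' convolution with 16 filters (ReLU + batch norm), three feature-extraction
#' blocks of two 3x3 convolutions, a CBAM attention layer and 2x2 max
#' pooling (32, 64, 128 filters), two 64-filter reduction convolutions, a
#' two-layer LSTM with 32 hidden units reading the final map as a width-wise
#' sequence, fully connected ReLU layers of 32 and 64 units, dropout 0.5,
#' and a 2-class softmax output. Setting `use_lstm = FALSE` swaps the LSTM
#' for a fully connected layer (the NoLSTM variant) with identical layers
#' everywhere else.
#'
#' @param stem_filters,stem_kernel Stem convolution size (16 filters, 3x4).
#' @param block_filters Filters of the three blocks (32, 64, 128).
#' @param reduce_filters Filters of the two reduction convolutions (64).
#' @param lstm_hidden,lstm_layers LSTM width (32) and depth (2).
#' @param fc_units Fully connected head widths (32 then 64).
#' @param dropout Dropout probability after the second FC layer (0.5).
#' @param cbam_reduction Channel-attention bottleneck ratio (default 8).
#' @param use_lstm `FALSE` builds the NoLSTM variant.
#' @param block_batchnorm If `TRUE` (default), batch norm follows each
#'   block convolution as well as the stem; `FALSE` normalizes only after
#'   the stem. See [train_config()] for how the batch statistics are used
#'   during training.
#' @return A `DeepBGSConfig` object.
#' @export
deepbgs_config <- function(stem_filters = 16L, stem_kernel = c(3L, 4L),
                           block_filters = c(32L, 64L, 128L),
                           reduce_filters = 64L, lstm_hidden = 32L,
                           lstm_layers = 2L, fc_units = c(32L, 64L),
                           dropout = 0.5, cbam_reduction = 8L,
                           use_lstm = TRUE, block_batchnorm = TRUE) {
  if (any(c(stem_filters, block_filters, reduce_filters, lstm_hidden,
            fc_units) <= 0L)) stop("filter/unit counts must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (length(block_filters) != 3L) stop("exactly three blocks are supported")
  structure(list(stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 block_filters = as.integer(block_filters),
                 reduce_filters = as.integer(reduce_filters),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 fc_units = as.integer(fc_units), dropout = dropout,
                 cbam_reduction = as.integer(cbam_reduction),
                 use_lstm = isTRUE(use_lstm),
                 block_batchnorm = isTRUE(block_batchnorm), n_classes = 2L),
            class = "DeepBGSConfig")
}

#' Optimizer configuration
#'
#' Defaults follow the published training protocol: Adam with learning rate
#' 5e-6, weight decay 1e-4, 150 epochs, minibatches of 11.
#'
#' `bn_mode` controls how batch normalization uses statistics during
#' training. The default `"ema"` normalizes every training batch with the
#' running (EMA) statistics, treated as constants in backpropagation: each
#' sample's output is then independent of its batchmates and inference
#' behaves exactly like training. `"batch"` is the textbook mode
#' (normalize by the current minibatch's own statistics); with minibatches
#' of 11 this lets the network learn batch-relative contrast features that
#' do not survive inference with population statistics, so it is not the
#' default (see the methods vignette). The first minibatch always
#' bootstraps the EMA from its own statistics.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coupled into the gradient.
#' @param epochs Training epochs (no early stopping).
#' @param batch_size Minibatch size.
#' @param seed Integer seed covering shuffling and dropout.
#' @param bn_mode `"ema"` (default) or `"batch"`; see Details.
#' @param clip_norm Global gradient-norm clipping threshold (`Inf`
#'   disables). Clipping is conventional for recurrent layers; a finite
#'   value guards the LSTM against destabilizing steps at higher learning
#'   rates.
#' @return A `TrainConfig` object.
#' @export
train_config <- function(learning_rate = 5e-6, weight_decay = 1e-4,
                         epochs = 150L, batch_size = 11L, seed = 1L,
                         bn_mode = c("ema", "batch"), clip_norm = Inf) {
  bn_mode <- match.arg(bn_mode)
  if (any(c(learning_rate, weight_decay, epochs, batch_size) <= 0)) {
    stop("all training parameters must be positive")
  }
  if (clip_norm <= 0) stop("clip_norm must be positive")
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 bn_mode = bn_mode, clip_norm = clip_norm),
            class = "TrainConfig")
}

#' Layer-by-layer shape trace
#'
#' Traces the feature-map shapes `(channels, height, width)` through the
#' network for a given window configuration, with same-padding convolutions
#' and floor-division 2x2 pooling. Errors when any spatial dimension would
#' collapse to zero; three poolings require at least 8 windows and window
#' length of at least 8.
#'
#' @param config A `DeepBGSConfig`.
#' @param window_config A `WindowConfig`.
#' @return Named list of `c(channels, height, width)` shapes, plus
#'   `lstm_steps` and `lstm_features` describing the sequence the LSTM sees.
#' @export
forward_shapes <- function(config, window_config) {
  stopifnot(inherits(config, "DeepBGSConfig"),
            inherits(window_config, "WindowConfig"))
  h <- window_count(window_config)
  w <- window_config$w
  shapes <- list(input = c(1L, h, w),
                 stem = c(config$stem_filters, h, w))
  for (i in 1:3) {
    shapes[[paste0("block", i, "_conv")]] <- c(config$block_filters[i], h, w)
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L) {
      stop(sprintf("spatial dimension collapses to 0 at block %d pooling", i))
    }
    shapes[[paste0("block", i, "_pool")]] <- c(config$block_filters[i], h, w)
  }
  shapes$reduce1 <- c(config$reduce_filters, h, w)
  shapes$reduce2 <- c(config$reduce_filters, h, w)
  shapes$lstm_steps <- w
  shapes$lstm_features <- config$reduce_filters * h
  shapes
}

# parameter initialization -------------------------------------------------

he_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

init_params <- function(config, window_config) {
  sh <- forward_shapes(config, window_config)
  P <- list()
  kf <- config$stem_kernel[1] * config$stem_kernel[2]
  P$stem_W <- he_mat(config$stem_filters, kf)
  P$stem_b <- numeric(config$stem_filters)
  P$stem_g <- rep(1, config$stem_filters)
  P$stem_bb <- numeric(config$stem_filters)
  cin <- config$stem_filters
  for (i in 1:3) {
    cout <- config$block_filters[i]
    P[[paste0("b", i, "c1_W")]] <- he_mat(cout, cin * 9L)
    P[[paste0("b", i, "c1_b")]] <- numeric(cout)
    P[[paste0("b", i, "c2_W")]] <- he_mat(cout, cout * 9L)
    P[[paste0("b", i, "c2_b")]] <- numeric(cout)
    if (config$block_batchnorm) {
      P[[paste0("b", i, "c1_g")]] <- rep(1, cout)
      P[[paste0("b", i, "c1_bb")]] <- numeric(cout)
      P[[paste0("b", i, "c2_g")]] <- rep(1, cout)
      P[[paste0("b", i, "c2_bb")]] <- numeric(cout)
    }
    cr <- max(1L, cout %/% config$cbam_reduction)
    P[[paste0("cb", i, "_m1_W")]] <- he_mat(cr, cout)
    P[[paste0("cb", i, "_m1_b")]] <- numeric(cr)
    P[[paste0("cb", i, "_m2_W")]] <- he_mat(cout, cr)
    P[[paste0("cb", i, "_m2_b")]] <- numeric(cout)
    P[[paste0("cb", i, "_sp_W")]] <- he_mat(1L, 18L)
    P[[paste0("cb", i, "_sp_b")]] <- numeric(1L)
    cin <- cout
  }
  P$red1_W <- he_mat(config$reduce_filters, cin * 9L)
  P$red1_b <- numeric(config$reduce_filters)
  P$red2_W <- he_mat(config$reduce_filters, config$reduce_filters * 9L)
  P$red2_b <- numeric(config$reduce_filters)
  hd <- config$lstm_hidden
  if (config$use_lstm) {
    s <- 1 / sqrt(hd)
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
    # forget-gate biases start at 1 so the cell state is initially open
    fgate <- (hd + 1L):(2L * hd)
    P$lstm1_Wx <- u(4L * hd, sh$lstm_features)
    P$lstm1_Wh <- u(4L * hd, hd)
    P$lstm1_b <- stats::runif(4L * hd, -s, s)
    P$lstm1_b[fgate] <- 1
    P$lstm2_Wx <- u(4L * hd, hd)
    P$lstm2_Wh <- u(4L * hd, hd)
    P$lstm2_b <- stats::runif(4L * hd, -s, s)
    P$lstm2_b[fgate] <- 1
  } else {
    nin <- sh$lstm_features * sh$lstm_steps
    P$flat_W <- he_mat(hd, nin)
    P$flat_b <- numeric(hd)
  }
  P$fc1_W <- he_mat(config$fc_units[1], hd)
  P$fc1_b <- numeric(config$fc_units[1])
  P$fc2_W <- he_mat(config$fc_units[2], config$fc_units[1])
  P$fc2_b <- numeric(config$fc_units[2])
  P$out_W <- he_mat(2L, config$fc_units[2])
  P$out_b <- numeric(2L)
  P
}

#' Build an untrained network
#'
#' Validates the shape chain for the given window configuration and
#' initializes all parameters (He initialization for convolutions and FC
#' layers, uniform for the LSTM, unit-gamma batch norm). Identical seeds
#' give identical initial parameters.
#'
#' @param config A `DeepBGSConfig`.
#' @param window_config A `WindowConfig`.
#' @param seed Integer seed for the initialization.
#' @return A `deepbgs_model` with untrained parameters.
#' @export
build_deepbgs <- function(config = deepbgs_config(),
                          window_config = window_config(200L, 150L),
                          seed = 1L) {
  shapes <- forward_shapes(config, window_config)
  set.seed(seed)
  params <- init_params(config, window_config)
  nbn <- if (config$block_batchnorm) 7L else 1L
  structure(list(config = config, window_config = window_config,
                 params = params, shapes = shapes,
                 bn_mean = replicate(nbn, numeric(0), simplify = FALSE),
                 bn_var = replicate(nbn, numeric(0), simplify = FALSE),
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "deepbgs_model")
}

# samples-first array [n x k x w] -> cube [k x w x n] for the C++ core
as_input_cube <- function(X, idx = seq_len(dim(X)[1])) {
  aperm(X[idx, , , drop = FALSE], c(2, 3, 1))
}

#' Train the network
#'
#' Minibatch Adam on softmax cross-entropy, with L2 weight decay coupled
#' into the gradient and batch-norm statistics tracked as running averages
#' for inference. No early stopping; given a fixed seed the whole run is
#' deterministic.
#'
#' @param model A `deepbgs_model` from [build_deepbgs()].
#' @param X Subsequence array `[n x n_windows x w]` from [batch_transform()],
#'   or a `SpectraSet` (transformed internally with the model's window
#'   configuration).
#' @param labels Class labels (ignored when `X` is a `SpectraSet`).
#' @param config A `TrainConfig`.
#' @return The model with learned parameters and a training `history`
#'   data.frame (per-epoch loss and accuracy).
#' @export
deepbgs_train <- function(model, X, labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "deepbgs_model"), inherits(config, "TrainConfig"))
  if (inherits(X, "SpectraSet")) {
    labels <- X$labels
    X <- batch_transform(X, model$window_config)
  }
  y_pos <- label_to_numeric(labels)           # 1 = barnyard_grass
  if (length(unique(y_pos)) < 2L) stop("training labels contain a single class")
  y_row <- as.integer(1L - y_pos)             # softmax row index (0-based)
  n <- dim(X)[1]
  if (dim(X)[2] != model$shapes$input[2] || dim(X)[3] != model$shapes$input[3]) {
    stop("subsequence array does not match the model's window configuration")
  }
  P <- model$params
  mom1 <- lapply(P, function(p) p * 0)
  mom2 <- mom1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  nfc2 <- length(P$fc2_b)
  keep <- 1 - model$config$dropout
  bn_mom <- 0.1
  bn_mean <- model$bn_mean; bn_var <- model$bn_var
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        acc = NA_real_)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- as_input_cube(X, idx)
      mask <- matrix(stats::rbinom(nfc2 * length(idx), 1L, keep) / keep,
                     nfc2, length(idx))
      frozen <- identical(config$bn_mode, "ema") &&
        length(bn_mean[[1]]) > 0L
      res <- cpp_net_grad(P, xb, y_row[idx], model$config$use_lstm,
                          model$config$block_batchnorm, frozen,
                          bn_mean, bn_var, mask)
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct +
        sum((res$prob_pos >= 0.5) == (y_pos[idx] == 1))
      t_step <- t_step + 1
      cor1 <- 1 - b1^t_step; cor2 <- 1 - b2^t_step
      clip_scale <- 1
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(sum(vapply(res$grads[names(P)],
                                 function(g) sum(as.numeric(g)^2),
                                 numeric(1))))
        if (gnorm > config$clip_norm) clip_scale <- config$clip_norm / gnorm
      }
      for (nm in names(P)) {
        g <- clip_scale * res$grads[[nm]] + config$weight_decay * P[[nm]]
        if (is.null(dim(P[[nm]]))) g <- as.numeric(g)
        mom1[[nm]] <- b1 * mom1[[nm]] + (1 - b1) * g
        mom2[[nm]] <- b2 * mom2[[nm]] + (1 - b2) * g^2
        P[[nm]] <- P[[nm]] - config$learning_rate *
          (mom1[[nm]] / cor1) / (sqrt(mom2[[nm]] / cor2) + eps)
      }
      for (j in seq_along(bn_mean)) {
        bm <- as.numeric(res$bn_mean[[j]]); bv <- as.numeric(res$bn_var[[j]])
        if (length(bn_mean[[j]]) == 0L) {
          bn_mean[[j]] <- bm; bn_var[[j]] <- bv
        } else {
          bn_mean[[j]] <- (1 - bn_mom) * bn_mean[[j]] + bn_mom * bm
          bn_var[[j]] <- (1 - bn_mom) * bn_var[[j]] + bn_mom * bv
        }
      }
    }
    history$loss[ep] <- ep_loss / n
    history$acc[ep] <- ep_correct / n
  }
  model$params <- P
  model$bn_mean <- bn_mean
  model$bn_var <- bn_var
  model$trained <- TRUE
  model$history <- history
  model$train_config <- config
  model
}

#' Predict barnyard-grass probabilities
#'
#' Applies the network in inference mode (running batch-norm statistics, no
#' dropout). The probability of the rice class is the complement.
#'
#' @param model A trained `deepbgs_model`.
#' @param X Subsequence array `[n x n_windows x w]` or a `SpectraSet`.
#' @param chunk Samples per forward pass (memory knob, default 64).
#' @return Numeric vector of probabilities that each sample is barnyard
#'   grass; the decision threshold is 0.5.
#' @export
predict_proba <- function(model, X, chunk = 64L) {
  stopifnot(inherits(model, "deepbgs_model"))
  if (inherits(X, "SpectraSet")) X <- batch_transform(X, model$window_config)
  if (dim(X)[2] != model$shapes$input[2] || dim(X)[3] != model$shapes$input[3]) {
    stop("subsequence array does not match the model's window configuration")
  }
  if (length(model$bn_mean[[1]]) == 0L) {
    stop("model has no batch-norm statistics; train it first")
  }
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- cpp_net_predict(model$params, as_input_cube(X, idx),
                                model$config$use_lstm,
                                model$config$block_batchnorm,
                                model$bn_mean, model$bn_var)
  }
  out
}

#' Predict class labels
#' @param object A trained `deepbgs_model`.
#' @param newdata Subsequence array or `SpectraSet`.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.deepbgs_model <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  factor(ifelse(p >= 0.5, spectra_classes()[1], spectra_classes()[2]),
         levels = spectra_classes())
}

#' Grid search over window length and sliding step
#'
#' Evaluates every `(w, s)` combination with `s <= w` by k-fold
#' cross-validation on the training set. A single stratified fold
#' assignment is drawn once from `seed` and reused for every combination,
#' so differences between cells reflect the windowing alone. The best pair
#' maximizes CV accuracy, with ties broken by higher MCC and then smaller
#' `w`.
#'
#' @param data A preprocessed training `SpectraSet`.
#' @param w_values,s_values Candidate window lengths and steps (bands).
#' @param folds CV folds (default 10).
#' @param seed Seed for the fold assignment and model builds.
#' @param config A `DeepBGSConfig`.
#' @param train_cfg A `TrainConfig` for the per-fold trainings.
#' @return List with `grid` (data.frame `w, s, acc, mcc, auc`), `best`
#'   (`w`, `s`), and `folds` (the shared fold assignment).
#' @export
grid_search_ws <- function(data, w_values, s_values, folds = 10L, seed = 1L,
                           config = deepbgs_config(),
                           train_cfg = train_config()) {
  stopifnot(inherits(data, "SpectraSet"))
  fold_id <- stratified_folds(data$labels, folds, seed)
  m <- length(data$wavelengths)
  rows <- list()
  for (w in w_values) for (s in s_values) {
    if (s > w) {
      message(sprintf("skipping (w=%d, s=%d): step exceeds window", w, s))
      next
    }
    wc <- window_config(w, s, m)
    X <- batch_transform(data, wc)
    prob <- numeric(n_spectra(data))
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      model <- build_deepbgs(config, wc, seed = seed)
      model <- deepbgs_train(model, X[tr, , , drop = FALSE],
                             data$labels[tr], train_cfg)
      prob[!tr] <- predict_proba(model, X[!tr, , , drop = FALSE])
    }
    pred <- ifelse(prob >= 0.5, spectra_classes()[1], spectra_classes()[2])
    rep <- eval_report(data$labels, pred, prob)
    rows[[length(rows) + 1L]] <- data.frame(w = w, s = s, acc = rep$acc,
                                            mcc = rep$mcc, auc = rep$auc)
  }
  grid <- do.call(rbind, rows)
  ord <- order(-grid$acc, -grid$mcc, grid$w)
  list(grid = grid, best = list(w = grid$w[ord[1]], s = grid$s[ord[1]]),
       folds = fold_id)
}

#' Apply a CBAM attention block to a feature map
#'
#' Channel attention (shared MLP over average- and max-pooled descriptors,
#' sigmoid gate) followed by spatial attention (3x3 convolution over the
#' channel-pooled average and maximum maps, sigmoid gate), both applied
#' multiplicatively. Shape is preserved; gates lie strictly in (0, 1).
#'
#' @param x Numeric feature map `[C x H x W]`.
#' @param reduction Channel bottleneck ratio (default 8).
#' @param seed Seed for the block's (random) parameters when none are given.
#' @param params Optional list with elements `m1_W`, `m1_b`, `m2_W`,
#'   `m2_b`, `sp_W`, `sp_b`.
#' @return Gated map `[C x H x W]` with attributes `channel_gate` (length
#'   C) and `spatial_gate` (`H x W`).
#' @export
cbam_block <- function(x, reduction = 8L, seed = 1L, params = NULL) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[1]
  if (is.null(params)) {
    set.seed(seed)
    cr <- max(1L, C %/% reduction)
    params <- list(m1_W = he_mat(cr, C), m1_b = numeric(cr),
                   m2_W = he_mat(C, cr), m2_b = numeric(C),
                   sp_W = he_mat(1L, 18L), sp_b = numeric(1L))
  }
  res <- cpp_cbam(aperm(x, c(2, 3, 1)), params$m1_W, params$m1_b,
                  params$m2_W, params$m2_b, params$sp_W, params$sp_b)
  out <- aperm(res$out, c(3, 1, 2))
  attr(out, "channel_gate") <- as.numeric(res$channel_gate)
  attr(out, "spatial_gate") <- res$spatial_gate
  out
}

#' @export
print.deepbgs_model <- function(x, ...) {
  cat(sprintf("deepbgs_model (%s): w=%d s=%d, %d windows, %s\n",
              if (x$config$use_lstm) "CNN-CBAM-LSTM" else "CNN-CBAM (NoLSTM)",
              x$window_config$w, x$window_config$s,
              window_count(x$window_config),
              if (x$trained) "trained" else "untrained"))
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("  %d parameters; LSTM sequence: %d steps x %d features\n",
              np, x$shapes$lstm_steps, x$shapes$lstm_features))
  invisible(x)
}
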