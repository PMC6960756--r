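# Brute-force weighted-vote oracle over explicit vote/weight vectors.
brute_fuse <- function(v, w) sum(w * v) / sum(w)

test_that("fusion implements the weighted-vote rule", {
  expect_equal(fuse(data.frame(v = rep(1, 5), w = runif(5, 0.1, 1)))$value, 1)
  expect_equal(fuse(data.frame(v = c(1, 1, 1, -1, -1), w = rep(0.7, 5)))$value,
               0.2)
  d <- data.frame(v = c(1, -1, 1, -1, 1), w = c(0.6, 0.9, 0.55, 0.8, 0.7))
  expect_equal(fuse(d)$value, 0.15 / 3.55)

  expect_error(fuse(data.frame(v = c(1, -1), w = c(0, 0))),
               class = "degenerate_fusion")
  expect_error(fuse(data.frame(v = numeric(0), w = numeric(0))),
               class = "invalid_argument")
  expect_error(fuse(data.frame(v = c(1, 0.5), w = c(0.5, 0.5))),
               class = "invalid_argument")
})

test_that("fusion matches the brute-force oracle on all vote patterns", {
  set.seed(8)
  for (k in 1:5) {
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    for (rep_i in 1:20) {
      w <- runif(k, 0.05, 1)
      for (p in seq_len(nrow(patterns))) {
        v <- patterns[p, ]
        f <- fuse(data.frame(v = v, w = w))
        expect_equal(f$value, brute_fuse(v, w))
        # weighted-mean bound and permutation invariance
        expect_gte(f$value, min(v))
        expect_lte(f$value, max(v))
        perm <- sample(k)
        expect_equal(fuse(data.frame(v = v[perm], w = w[perm]))$value,
                     f$value)
      }
    }
  }
})

test_that("flipping one vote moves the fused value monotonically", {
  set.seed(13)
  for (i in 1:20) {
    k <- 5
    w <- runif(k, 0.05, 1)
    v <- sample(c(-1, 1), k, replace = TRUE)
    v_lo <- v; v_lo[1] <- -1
    v_hi <- v; v_hi[1] <- 1
    expect_lt(fuse(data.frame(v = v_lo, w = w))$value,
              fuse(data.frame(v = v_hi, w = w))$value)
  }
})

test_that("column construction is sized and seeded", {
  cfg <- train_config(k = 5, seed = 9)
  m1 <- build_columns(cfg, column_arch())
  expect_length(m1$axes$valence, 5)
  expect_length(m1$axes$arousal, 5)
  m2 <- build_columns(cfg, column_arch())
  expect_identical(m1$axes$valence[[3]]$kernels, m2$axes$valence[[3]]$kernels)
  # columns are independent: different filterbanks
  expect_false(identical(m1$axes$valence[[1]]$kernels,
                         m1$axes$valence[[2]]$kernels))
  expect_error(train_config(k = 0), class = "config_error")
})

test_that("training learns separable band-power structure", {
  ws <- fixture_separable_windows()
  model <- fixture_trained_model()

  # the independent band-power oracle is itself strong on these windows
  alpha <- apply(ws$val$x, 3, window_alpha_power)
  labs <- ws$val$meta$valence_label
  thr <- mean(c(mean(alpha[labs > 0]), mean(alpha[labs < 0])))
  oracle_acc <- mean((alpha > thr) == (labs > 0))
  expect_gt(oracle_acc, 0.9)

  fv <- score_windows(model, ws$val)
  acc_val <- mean(sign(fv$valence) == ws$val$meta$valence_label)
  expect_gt(acc_val, 0.85)

  # history is recorded per axis, column and epoch
  h <- model$history
  expect_true(all(c("epoch", "lr", "train_error", "val_error",
                    "axis", "column") %in% names(h)))
  expect_true(all(h$lr <= 0.3))
})

test_that("training on permuted labels stays at chance", {
  ws <- fixture_separable_windows()
  perm_train <- ws$train
  set.seed(99)
  perm_train$meta$valence_label <- sample(perm_train$meta$valence_label)
  perm_train$meta$arousal_label <- sample(perm_train$meta$arousal_label)
  tcfg <- train_config(k = 2, learning_rate = 0.3, max_epochs = 6, seed = 5)
  model <- train_recognizer(build_columns(tcfg, column_arch()),
                            perm_train, ws$val)
  fv <- score_windows(model, ws$val)
  acc <- mean(sign(fv$valence) == ws$val$meta$valence_label)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("training is deterministic given the seed", {
  ws <- fixture_separable_windows()
  tcfg <- train_config(k = 2, learning_rate = 0.3, max_epochs = 4, seed = 31)
  m1 <- train_recognizer(build_columns(tcfg, column_arch()),
                         ws$train, ws$val)
  m2 <- train_recognizer(build_columns(tcfg, column_arch()),
                         ws$train, ws$val)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$axes$valence[[1]]$readout, m2$axes$valence[[1]]$readout)
})

test_that("train/validation participant overlap is rejected", {
  ws <- fixture_separable_windows()
  tcfg <- train_config(k = 1, seed = 1)
  expect_error(
    train_recognizer(build_columns(tcfg, column_arch()),
                     ws$train, ws$train),
    class = "invalid_argument"
  )
})

test_that("per-window prediction respects the fusion contract", {
  model <- fixture_trained_model()
  ws <- fixture_separable_windows()$val
  pred <- predict_window(model, ws$x[, , 1])
  for (axis in c("valence", "arousal")) {
    expect_equal(nrow(pred[[axis]]$columns), 2)
    expect_true(all(pred[[axis]]$columns$v %in% c(-1, 1)))
    expect_true(all(pred[[axis]]$columns$w >= 0 &
                      pred[[axis]]$columns$w <= 1))
    expect_gte(pred[[axis]]$fused$value, -1)
    expect_lte(pred[[axis]]$fused$value, 1)
    # fused value is reproduced by the standalone fusion rule
    expect_equal(pred[[axis]]$fused$value, fuse(pred[[axis]]$columns)$value)
  }
  expect_error(predict_window(model, matrix(0, 16, 32)),
               class = "shape_error")
})

test_that("trial scores are the mean of the fused window values", {
  model <- fixture_trained_model()
  ws <- fixture_separable_windows()$val
  small <- list(x = ws$x[, , 1:5, drop = FALSE], meta = ws$meta[1:5, ])
  class(small) <- "window_set"
  sc <- score_trial(model, small)
  by_hand <- rowMeans(vapply(1:5, function(i) {
    p <- predict_window(model, small$x[, , i])
    c(p$valence$fused$value, p$arousal$fused$value)
  }, numeric(2)))
  expect_equal(sc$valence, by_hand[1])
  expect_equal(sc$arousal, by_hand[2])
  expect_gte(sc$valence, -1)
  expect_lte(sc$valence, 1)

  empty <- list(x = array(0, c(32, 32, 0)), meta = ws$meta[0, ])
  class(empty) <- "window_set"
  expect_error(score_trial(model, empty), class = "invalid_argument")
})
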