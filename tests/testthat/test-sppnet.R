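test_that("spp_pool yields the fixed-length pyramid vector", {
  x <- array(rnorm(37 * 18 * 200), c(37, 18, 200))
  expect_length(spp_pool(x, c(4, 2, 1)), 4200)
  # level [1] is the global per-channel max
  expect_equal(spp_pool(x, 1L), apply(x, 3, max))
  expect_error(spp_pool(array(rnorm(3 * 3 * 2), c(3, 3, 2)), 4L),
               "exceeds")
})

test_that("spp_pool matches a brute-force windowed-max oracle", {
  brute <- function(m, n) {
    win <- function(a) {
      w <- ceiling(a / n); s <- floor(a / n)
      cbind((0:(n - 1)) * s + 1, pmin((0:(n - 1)) * s + w, a))
    }
    wr <- win(nrow(m)); wc <- win(ncol(m))
    sapply(1:n, function(j) sapply(1:n, function(i)
      max(m[wr[i, 1]:wr[i, 2], wc[j, 1]:wc[j, 2]])))
  }
  # the worked example: a = 13, n = 4 -> win 4, str 3
  set.seed(2)
  m <- matrix(rnorm(13 * 13), 13)
  expect_equal(spp_pool(m, 4L), as.vector(brute(m, 4)))
  for (rep in 1:10) {
    H <- sample(20:700, 1); W <- sample(5:21, 1)
    n <- sample(1:4, 1)
    m <- matrix(rnorm(H * W), H)
    expect_equal(spp_pool(m, n), as.vector(brute(m, n)))
  }
})

test_that("pooled vector length is size invariant; bins are max invariant", {
  set.seed(3)
  lens <- sapply(c(20, 45, 120, 700), function(H)
    length(spp_pool(matrix(rnorm(H * 21), H), c(4, 2, 1))))
  expect_true(all(lens == lens[1]))

  # permuting rows inside one level-1 pooling bin leaves the pool unchanged
  m <- matrix(rnorm(16 * 8), 16)
  v1 <- spp_pool(m, 4L)
  rows <- 1:4                                 # first bin at level 4 (str 4)
  m2 <- m; m2[rows, ] <- m[rev(rows), ]
  expect_equal(spp_pool(m2, 4L), v1)
})

test_that("convolution shapes reproduce the published architecture", {
  w1 <- array(rnorm(10 * 4 * 1 * 10), c(10, 4, 1, 10))
  out <- conv_forward(matrix(rnorm(610 * 21), 610), w1, stride = c(5, 1))
  expect_equal(dim(out), c(121L, 18L, 10L))   # (610 - 10)/5 + 1 = 121

  w2 <- array(rnorm(5 * 2 * 10 * 200), c(5, 2, 10, 200))
  out2 <- conv_forward(out, w2, stride = c(1, 1), pad_w = 1)
  expect_equal(dim(out2), c(117L, 18L, 200L))

  zero <- conv_forward(matrix(0, 40, 21), w1, stride = c(5, 1))
  expect_true(all(zero == 0))
  expect_error(conv_forward(matrix(rnorm(5 * 21), 5), w1, stride = c(5, 1)),
               "kernel larger")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_spp_config()
  set.seed(4)
  ws <- deemd:::init_weights(cfg)
  # perturb the zero-initialized output layer so its gradient test is
  # non-trivial
  ws$fc[[2]]$W[] <- rnorm(length(ws$fc[[2]]$W), sd = 0.1)
  x0 <- array(rnorm(12 * 4), c(12, 4, 1))
  fw <- deemd:::net_forward(x0, ws, cfg, keep = TRUE)
  g <- deemd:::net_backward(fw, ws, cfg, c(1, 0))
  eps <- 1e-6
  loss_at <- function() -log(deemd:::net_forward(x0, ws, cfg)$prob[1])
  check <- function(get, set, analytic) {
    w0 <- get(); set(w0 + eps); l1 <- loss_at()
    set(w0 - eps); l2 <- loss_at(); set(w0)
    expect_lt(abs(analytic - (l1 - l2) / (2 * eps)), 1e-5)
  }
  for (rep in 1:6) {
    l <- sample(1:2, 1); i <- sample(length(ws$conv[[l]]$W), 1)
    check(function() ws$conv[[l]]$W[i],
          function(v) ws$conv[[l]]$W[i] <<- v, g$conv[[l]]$dW[i])
  }
  for (rep in 1:4) {
    l <- sample(1:2, 1); i <- sample(length(ws$fc[[l]]$W), 1)
    check(function() ws$fc[[l]]$W[i],
          function(v) ws$fc[[l]]$W[i] <<- v, g$fc[[l]]$dW[i])
  }
})

test_that("training handles variable heights, rejects degenerate input", {
  cfg <- tiny_spp_config()
  set.seed(5)
  mk <- function(lab, h) {
    m <- matrix(rnorm(h * 21), h)
    if (lab == 1) m[, 2] <- m[, 2] + 3
    list(map = m, label = lab)
  }
  ds <- c(lapply(sample(12:40, 10, TRUE), mk, lab = 0),
          lapply(sample(12:40, 10, TRUE), mk, lab = 1))
  model <- spp_train(ds, cfg)
  expect_s3_class(model, "spp_model")
  # maps of different heights flow through a single predict call
  pr <- predict(model, list(matrix(rnorm(15 * 21), 15),
                            matrix(rnorm(60 * 21), 60)))
  expect_equal(nrow(pr), 2)
  expect_true(all(abs(rowSums(as.matrix(pr[, -1])) - 1) < 1e-9))

  expect_error(spp_train(lapply(rep(1L, 6), mk, h = 20), cfg),
               "two classes")
  # training is deterministic under a fixed seed
  m2 <- spp_train(ds, cfg)
  expect_identical(model$loss_log, m2$loss_log)
})

test_that("models serialize and round-trip predictions", {
  cfg <- tiny_spp_config()
  set.seed(6)
  ds <- lapply(rep(0:1, each = 6), function(lab) {
    m <- matrix(rnorm(20 * 21), 20)
    if (lab == 1) m[, 5] <- m[, 5] + 2
    list(map = m, label = lab)
  })
  model <- spp_train(ds, cfg)
  path <- tempfile(fileext = ".json")
  write_spp_model(model, path)
  back <- read_spp_model(path)
  batch <- lapply(1:4, function(i) matrix(rnorm(25 * 21), 25))
  p1 <- predict(model, batch); p2 <- predict(back, batch)
  expect_identical(p1$class, p2$class)
  expect_equal(as.matrix(p1[, -1]), as.matrix(p2[, -1]), tolerance = 1e-12)
})

test_that("accuracy and fold construction follow their definitions", {
  expect_equal(accuracy_counts(3, 2, 1, 2), 0.625)
  expect_equal(accuracy_counts(10, 10, 0, 0), 1)
  expect_error(accuracy_counts(0, 0, 0, 0), "zero total")
  expect_error(accuracy_counts(-1, 2, 0, 0), "nonnegative")

  # 1,373 trials in 5 folds -> sizes 275, 275, 275, 274, 274
  labels <- rep(c("a", "b"), c(687, 686))
  fold <- deemd:::stratified_folds(labels, 5L, seed = 1L)
  expect_equal(sort(tabulate(fold, 5), decreasing = TRUE),
               c(275, 275, 275, 274, 274))
  # stratification: class counts per fold differ by at most one
  tab <- table(labels, fold)
  expect_lte(max(tab) - min(tab), 1)
})

test_that("cross_validate tests every trial exactly once", {
  cfg <- tiny_spp_config(epochs = 2L)
  set.seed(7)
  ds <- lapply(rep(0:1, each = 8), function(lab) {
    m <- matrix(rnorm(18 * 21), 18)
    if (lab == 1) m[, 3] <- m[, 3] + 2.5
    list(map = m, label = lab)
  })
  cv <- cross_validate(ds, cfg, k = 4L, seed = 2L)
  expect_length(cv$fold_accuracy, 4)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_equal(sort(unique(cv$fold)), 1:4)
  expect_equal(tabulate(cv$fold, 4), rep(4L, 4))
  expect_error(cross_validate(ds, cfg, k = 20L), "k must lie")
})
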