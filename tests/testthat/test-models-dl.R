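# separable toy set: Gaussian bump at one of two positions
bump_problem <- function(n = 20, L = 64, seed = 42, noise = 0.02) {
  set.seed(seed)
  x <- matrix(0, n, L)
  y <- rep(c(0L, 1L), each = n / 2)
  for (i in seq_len(n)) {
    ctr <- if (y[i] == 1L) round(0.7 * L) else round(0.3 * L)
    x[i, ] <- exp(-((seq_len(L) - ctr)^2) / 18) + rnorm(L, 0, noise)
  }
  list(x = x, y = y)
}

test_that("the CNN layer stack matches its printed architecture", {
  m <- build_cnn1d(128, seed = 1)
  s <- summary(m)
  expect_equal(s$type, c("conv1d", "relu", "bn", "dropout", "conv1d", "relu",
                         "bn", "dropout", "avgpool", "flatten", "dense"))
  expect_equal(s$channels[c(1, 5)], c(10, 25))
  expect_equal(s$size[c(1, 5)], c(3, 3))     # kernel sizes
  expect_equal(s$size[9], 8)                 # pool size
  # first conv: 3 (kernel) x 1 (input channel) x 10 (filters) weights + 10 biases
  expect_equal(s$n_params[1], 30 + 10)
  expect_equal(length(m$net$layers[[1]]$params$W), 30)
  expect_error(build_cnn1d(16), ">= 32")
})

test_that("the residual network records 3 blocks with 16/32/64 channels", {
  m <- build_resnet1d(128, seed = 1)
  s <- summary(m)
  blocks <- which(s$type == "resblock")
  expect_length(blocks, 3L)
  expect_equal(s$channels[blocks], c(16, 32, 64))
  expect_equal(s$type[length(s$type) - 1], "gap")
  expect_error(build_resnet1d(32), ">= 64")
})

test_that("forward passes produce probabilities strictly inside (0, 1)", {
  set.seed(9)
  x <- matrix(rnorm(6 * 128), 6, 128)
  for (builder in list(build_cnn1d, build_resnet1d)) {
    m <- builder(128, seed = 2)
    p <- predict_prob(m, x)
    expect_true(all(p > 0 & p < 1))
    expect_length(p, 6)
  }
})

test_that("the default training recipe echoes 40 epochs at lr 0.001", {
  r <- dl_recipe()
  expect_equal(r$epochs, 40L)
  expect_equal(r$learning_rate, 0.001)
})

test_that("a tiny separable problem is learned to 100% training accuracy", {
  tp <- bump_problem()
  m <- train_dl(build_cnn1d(64, seed = 1), tp$x, tp$y,
                recipe = dl_recipe(epochs = 30, batch_size = 8))
  expect_equal(mean((predict_prob(m, tp$x) >= 0.5) == tp$y), 1)
  expect_length(m$history, 30L)  # one loss per epoch
  expect_lt(m$history[30], m$history[1])

  m2 <- train_dl(build_resnet1d(64, dropout = 0, seed = 1), tp$x, tp$y,
                 recipe = dl_recipe(epochs = 30, batch_size = 8))
  expect_equal(mean((predict_prob(m2, tp$x) >= 0.5) == tp$y), 1)
})

test_that("training is reproducible for a fixed seed", {
  tp <- bump_problem()
  ma <- train_dl(build_cnn1d(64, seed = 3), tp$x, tp$y,
                 recipe = dl_recipe(epochs = 5, batch_size = 8))
  mb <- train_dl(build_cnn1d(64, seed = 3), tp$x, tp$y,
                 recipe = dl_recipe(epochs = 5, batch_size = 8))
  expect_lt(max(abs(predict_prob(ma, tp$x) - predict_prob(mb, tp$x))), 1e-5)
})

test_that("a residual block with zeroed conv path passes its input through", {
  blk <- ramantissue:::nn_layer_resblock(16L, 16L)  # no projection shortcut
  for (nm in c("conv1", "conv2")) {
    blk$sub[[nm]]$params$W[] <- 0
    blk$sub[[nm]]$params$b[] <- 0
  }
  blk$sub$bn2$params$gamma[] <- 1
  x <- array(abs(rnorm(2 * 40 * 16)), c(2, 40, 16))  # non-negative input
  out <- ramantissue:::.resblock_forward(blk, x, training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-9)
})

test_that("deep models reject mismatched input lengths", {
  tp <- bump_problem()
  m <- build_cnn1d(64, seed = 1)
  expect_error(train_dl(m, tp$x[, 1:50], tp$y), "input_length")
  m <- train_dl(m, tp$x, tp$y, recipe = dl_recipe(epochs = 1, batch_size = 8))
  expect_error(build_model(model_spec("cnn1d")), "input_length")
})

test_that("gradients match finite differences through every layer type", {
  set.seed(11)
  x <- matrix(rnorm(4 * 64), 4, 64)
  y <- c(0, 1, 0, 1)
  loss_of <- function(net) {
    f <- ramantissue:::nn_forward(net, x, training = TRUE)
    p <- stats::plogis(f$logit)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  for (builder in list(function() build_cnn1d(64, dropout = 0, seed = 5),
                       function() build_resnet1d(64, dropout = 0, seed = 5))) {
    m <- builder()
    net <- m$net
    f <- ramantissue:::nn_forward(net, x, training = TRUE)
    p <- stats::plogis(f$logit)
    b <- ramantissue:::nn_backward(f$net, f, (p - y) / 4)
    # probe one coordinate of each parameterized top-level layer
    for (li in seq_along(net$layers)) {
      ly <- net$layers[[li]]
      if (is.null(ly$params) && is.null(ly$sub)) next
      if (!is.null(ly$sub)) {
        g_an <- b$grads[[li]]$conv1$W[2] -
          2 * ly$sub$conv1$l2 * ly$sub$conv1$params$W[2]
        n1 <- net; n2 <- net
        n1$layers[[li]]$sub$conv1$params$W[2] <-
          n1$layers[[li]]$sub$conv1$params$W[2] + 1e-5
        n2$layers[[li]]$sub$conv1$params$W[2] <-
          n2$layers[[li]]$sub$conv1$params$W[2] - 1e-5
      } else {
        nm <- names(ly$params)[1]
        pen <- if (nm == "W" && !is.null(ly$l2)) 2 * ly$l2 * ly$params[[nm]][1]
               else 0
        g_an <- b$grads[[li]][[nm]][1] - pen
        n1 <- net; n2 <- net
        n1$layers[[li]]$params[[nm]][1] <- n1$layers[[li]]$params[[nm]][1] + 1e-5
        n2$layers[[li]]$params[[nm]][1] <- n2$layers[[li]]$params[[nm]][1] - 1e-5
      }
      g_fd <- (loss_of(n1) - loss_of(n2)) / 2e-5
      expect_equal(g_an, g_fd, tolerance = 1e-4)
    }
  }
})
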