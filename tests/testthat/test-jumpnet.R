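test_that("initialization is seed-deterministic and within the Glorot bounds", {
  p1 <- jumpnet_params(M = 10, L = 4, seed = 7)
  p2 <- jumpnet_params(M = 10, L = 4, seed = 7)
  expect_identical(p1, p2)
  p3 <- jumpnet_params(M = 10, L = 4, seed = 8)
  expect_false(isTRUE(all.equal(p1$IOW, p3$IOW)))
  expect_true(all(abs(p1$IHW) <= sqrt(6 / 14)))
  expect_true(all(abs(p1$HOW) <= sqrt(6 / 5)))
  expect_true(all(abs(p1$IOW) <= sqrt(6 / 11)))
  expect_identical(p1$hidden_bias, numeric(4))
  expect_identical(p1$output_bias, 0)
})

test_that("forward pass isolates the linear jump path", {
  p <- jumpnet_params(M = 10, L = 4, seed = 1)
  p$IHW[] <- 0; p$HOW[] <- 0; p$IOW[] <- 0
  expect_equal(jumpnet_forward(p, runif(10, 60, 300)), 0)
  # persistence through the jump connection: last input passes straight through
  p$IOW <- c(rep(0, 9), 1)
  p2 <- jumpnet_params(M = 10, L = 4, seed = 2)  # arbitrary hidden weights
  p$IHW <- p2$IHW
  expect_equal(jumpnet_forward(p, c(runif(9, 60, 300), 137)), 137)
  expect_error(jumpnet_forward(p, runif(7)), "width")
})

test_that("vectorized forward pass equals the per-neuron loop oracle", {
  set.seed(31)
  for (i in 1:100) {
    M <- sample(2:12, 1); L <- sample(1:6, 1)
    p <- jumpnet_params(M, L, seed = i)
    if (i %% 3 == 0) {  # exercise the bias terms too
      p$hidden_bias <- rnorm(L); p$output_bias <- rnorm(1)
    }
    x <- runif(M, 40, 400)
    expect_equal(jumpnet_forward(p, x), loop_forward(p, x), tolerance = 1e-12)
  }
})

test_that("gradients vanish for zero weights and reduce to MSE for unit weights", {
  p <- jumpnet_params(10, 4, seed = 5)
  X <- matrix(runif(50, 80, 200), ncol = 10)
  y <- runif(5, 80, 200)
  g0 <- jumpnet_gradients(p, X, y, sample_weights = 0)
  expect_equal(max(abs(c(g0$IHW, g0$HOW, g0$IOW, g0$hidden_bias, g0$output_bias))), 0)
  g1 <- jumpnet_gradients(p, X, y, sample_weights = 1)
  gm <- jumpnet_gradients(p, X, y)
  expect_identical(g1[names(g1) != "loss"], gm[names(gm) != "loss"])
})

test_that("analytic gradients match central finite differences for both losses", {
  set.seed(77)
  for (i in 1:20) {
    M <- sample(2:8, 1); L <- sample(1:4, 1); n <- sample(1:6, 1)
    p <- jumpnet_params(M, L, seed = 100 + i)
    p$hidden_bias <- rnorm(L, sd = 0.1); p$output_bias <- rnorm(1, sd = 0.1)
    X <- matrix(runif(n * M, -2, 2), ncol = M)
    y <- runif(n, -2, 2)
    # plain MSE, and penalty weights frozen at the current errors
    for (w in list(rep(1, n),
                   penalty(10 * (y - jumpnet_forward(p, X))))) {
      if (all(w == 0)) w <- w + 1
      ga <- jumpnet_gradients(p, X, y, sample_weights = w)
      gn <- fd_gradients(p, X, y, w)
      for (s in names(gn)) {
        denom <- pmax(abs(gn[[s]]), 1e-8)
        expect_lt(max(abs(ga[[s]] - gn[[s]]) / denom), 1e-4)
      }
    }
  }
})

test_that("clipping clamps elementwise and never increases magnitudes", {
  g <- list(IHW = matrix(c(-1, 0, 1, 0.7), 2), HOW = c(0.7, -0.1),
            IOW = c(-0.1, 0.05), hidden_bias = c(0, 2), output_bias = -5)
  c1 <- clip_gradients(g, 0.3)
  expect_equal(c1$HOW, c(0.3, -0.1))
  expect_equal(c1$IOW, c(-0.1, 0.05))
  expect_equal(as.vector(c1$IHW), c(-0.3, 0, 0.3, 0.3))
  expect_equal(c1$output_bias, -0.3)
  for (s in names(g)) expect_true(all(abs(c1[[s]]) <= abs(g[[s]]) + 1e-15))
  # norm mode rescales without changing direction
  cn <- clip_gradients(g, 0.3, mode = "norm")
  nrm <- sqrt(sum(unlist(g[names(g)])^2))
  expect_equal(unlist(cn), unlist(g) * 0.3 / nrm)
})

test_that("a gradient step moves parameters by -lr * grad and respects bias flags", {
  p <- jumpnet_params(3, 2, seed = 1)
  g <- jumpnet_gradients(p, matrix(runif(6, 80, 200), ncol = 3), runif(2, 80, 200))
  same <- sgd_step(p, g, 0)
  expect_identical(same, p)
  stepped <- sgd_step(p, g, 0.1)
  expect_equal(stepped$IOW, p$IOW - 0.1 * g$IOW)
  expect_equal(stepped$IHW, p$IHW - 0.1 * g$IHW)
  expect_identical(stepped$output_bias, 0)  # biases frozen by default
  pb <- jumpnet_params(3, 2, seed = 1, train_bias = TRUE)
  expect_equal(sgd_step(pb, g, 0.1)$output_bias, -0.1 * g$output_bias)
  # scalar arithmetic: w = 1, g = 0.5, lr = 0.1 -> 0.95
  p1 <- jumpnet_params(1, 1, seed = 1)
  p1$IOW <- 1
  expect_equal(sgd_step(p1, list(IHW = matrix(0, 1, 1), HOW = 0, IOW = 0.5,
                                 hidden_bias = 0, output_bias = 0), 0.1)$IOW, 0.95)
})

test_that("training on a noiseless linear process recovers the jump weights", {
  set.seed(11)
  M <- 10; n <- 1200
  X <- matrix(runif(n * M, 80, 180), ncol = M)
  iow_true <- c(-0.2, 0.1, 0, 0.05, -0.1, 0.2, 0.1, -0.05, 0.3, 0.6)
  y <- drop(X %*% iow_true)
  Xv <- matrix(runif(300 * M, 80, 180), ncol = M)
  tr <- structure(list(inputs = X, targets = y), class = "windowed_dataset")
  va <- structure(list(inputs = Xv, targets = drop(Xv %*% iow_true)),
                  class = "windowed_dataset")
  p <- jumpnet_params(M, 4, seed = 3)
  p$HOW[] <- 0; p$IHW[] <- 0   # zero nonlinear path stays zero (its gradient vanishes)
  fit <- train_offline(p, tr, va,
                       training_hyperparams(learning_rate = 3e-6,
                                            max_epochs = 6000, clip_value = NULL))
  expect_lt(max(abs(fit$params$IOW - iow_true)), 0.05)
  expect_lt(rmse(y - jumpnet_forward(fit$params, X)), 1)
  expect_equal(max(abs(fit$params$HOW)), 0)
})

test_that("early stopping keeps the best-validation snapshot", {
  # a single train pair pulls IOW upward while validation truth stays at 0,
  # so the validation MSE worsens monotonically after the first check
  p <- jumpnet_params(1, 1, seed = 1)
  p$IOW <- 0; p$HOW <- 0; p$IHW[] <- 0
  tr <- structure(list(inputs = matrix(1), targets = 1), class = "windowed_dataset")
  va <- structure(list(inputs = matrix(1), targets = 0), class = "windowed_dataset")
  fit <- train_offline(p, tr, va,
                       training_hyperparams(learning_rate = 0.01, max_epochs = 100,
                                            clip_value = NULL,
                                            validation_check_every = 1,
                                            patience_checks = 1))
  expect_true(fit$stopped_early)
  expect_equal(nrow(fit$history), 2)     # stopped after the second check
  expect_equal(fit$best_epoch, 1)
  expect_equal(fit$params$IOW, 0.02)     # one step of lr * 2e * x from 0
})

test_that("training is reproducible bit for bit and rejects bad inputs", {
  vals <- smooth_signal(1440)
  ds <- build_supervised_windows(make_group(vals), M = 10, PH = 30)
  sp <- chronological_split(ds)
  hy <- training_hyperparams(learning_rate = 0.05, max_epochs = 40)
  f1 <- train_offline(jumpnet_params(10, 4, seed = 9), sp$train, sp$validation, hy)
  f2 <- train_offline(jumpnet_params(10, 4, seed = 9), sp$train, sp$validation, hy)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_error(training_hyperparams(max_epochs = 0), "counts")
  expect_error(training_hyperparams(learning_rate = 0), "learning_rate")
})

test_that("parameter checkpoints round-trip through flat JSON", {
  p <- jumpnet_params(10, 4, seed = 13)
  p$hidden_bias <- rnorm(4)
  path <- withr::local_tempfile(fileext = ".json")
  save_jumpnet(p, path)
  q <- load_jumpnet(path)
  expect_equal(q, p)
  x <- runif(10, 80, 200)
  expect_equal(jumpnet_forward(q, x), jumpnet_forward(p, x))
})
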