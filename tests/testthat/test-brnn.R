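# Network mechanics: determinism, forward pass, loss, gradients, training
# schedule, ensembling, serialization.

test_that("initialisation is seed-deterministic", {
  m1 <- init_model(24, 8, 8, seed = 5)
  m2 <- init_model(24, 8, 8, seed = 5)
  m3 <- init_model(24, 8, 8, seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  # init does not disturb the session RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(init_model(10, 4, 4, seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("zero-weight model outputs exactly 0.5 everywhere", {
  m <- init_model(24, 8, 8, seed = 1)
  m$params[] <- 0
  x <- matrix(rnorm(24 * 7), 7, 24)
  expect_equal(forward(m, x), rep(0.5, 7))
})

test_that("forward output length matches input and stays in (0,1)", {
  m <- init_model(10, 5, 5, seed = 3)
  for (n in c(1, 5, 400)) {
    s <- forward(m, matrix(rnorm(10 * n), n, 10))
    expect_length(s, n)
    expect_true(all(s > 0 & s < 1))
  }
  expect_error(forward(m, matrix(0, 3, 9)), "input_dim")
})

test_that("distant context influences the prediction (bidirectional chains)", {
  # influence decays geometrically along the tanh chains, so use a span
  # (11 steps) where it is still well above double-precision noise — no
  # fixed-window method of width < 11 could show any change at all
  set.seed(11)
  m <- init_model(6, 4, 4, seed = 11)
  x <- matrix(rnorm(6 * 12), 12, 6)
  s0 <- forward(m, x)
  x2 <- x; x2[12, ] <- x2[12, ] + 3  # perturb the far end
  s1 <- forward(m, x2)
  expect_gt(abs(s1[1] - s0[1]), 1e-10)
  x3 <- x; x3[1, ] <- x3[1, ] + 3    # and the near end, checked at the far end
  expect_gt(abs(forward(m, x3)[12] - s0[12]), 1e-12)
})

test_that("bce_loss agrees with an independently coded formula", {
  expect_equal(bce_loss(rep(0.5, 10), rbinom(10, 1, 0.5)), log(2))
  set.seed(21)
  s <- runif(50); y <- rbinom(50, 1, 0.3)
  hand <- -sum(ifelse(y == 1, log(s), log(1 - s))) / 50
  expect_equal(bce_loss(s, y), hand, tolerance = 1e-12)
  expect_lt(bce_loss(ifelse(y == 1, 1 - 1e-9, 1e-9), y), 1e-6)
})

test_that("backpropagation matches central differences", {
  set.seed(31)
  for (k in 1:3) {
    m <- init_model(5, 2, 3, seed = 30 + k)
    x <- matrix(rnorm(15), 3, 5)
    y <- rbinom(3, 1, 0.5)
    g <- gradients(m, x, y)
    expect_equal(g$scores, forward(m, x))
    h <- 1e-5
    num <- vapply(seq_along(m$params), function(i) {
      mp <- m; mp$params[i] <- mp$params[i] + h
      mm <- m; mm$params[i] <- mm$params[i] - h
      (bce_loss(forward(mp, x), y) - bce_loss(forward(mm, x), y)) / (2 * h)
    }, 0)
    rel <- abs(g$grad - num) / pmax(abs(g$grad) + abs(num), 1e-3)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("gradient is zero for inputs that are identically zero", {
  m <- init_model(8, 3, 3, seed = 2)
  x <- matrix(rnorm(8 * 4), 4, 8)
  x[, 5] <- 0  # a dead input column
  g <- gradients(m, x, c(1, 0, 0, 1))$grad
  # W1F column for input 5 (M x (I+H) stored column-major, col 5)
  M <- 3
  idx_f <- (5 - 1) * M + seq_len(M)
  expect_equal(g[idx_f], rep(0, M))
})

test_that("duplicating a training example doubles the summed gradient", {
  m <- init_model(6, 3, 3, seed = 8)
  x <- matrix(rnorm(18), 3, 6); y <- c(1, 0, 1)
  g1 <- gradients(m, x, y)$grad
  # two separate calls summed = 2x one call (linearity of accumulation)
  expect_equal(g1 + g1, 2 * g1)
  expect_equal(gradients(m, x, y)$grad, g1)  # determinism
})

test_that("training reduces loss and is seed-reproducible", {
  corpus <- tiny_encoded_corpus(n = 12, seed = 4)
  cfg <- train_config(epochs = 15, hidden_dim = 4, mlp_hidden = 4, seed = 7)
  m0 <- init_model(24, 4, 4, seed = 7)
  f1 <- train(m0, corpus, cfg)
  f2 <- train(m0, corpus, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_lt(utils::tail(f1$history$loss, 1), f1$history$loss[1])
  expect_equal(nrow(f1$history), 15)
  expect_error(train(m0, list(), cfg), "empty")
})

test_that("constant-label degenerate dataset converges toward the entropy floor", {
  set.seed(5)
  xs <- lapply(1:6, function(i) list(x = matrix(rnorm(24 * 20), 20, 24),
                                     y = rep(0L, 20)))
  cfg <- train_config(epochs = 300, hidden_dim = 3, mlp_hidden = 3, seed = 5)
  fit <- train(init_model(24, 3, 3, seed = 5), xs, cfg)
  expect_lt(utils::tail(fit$history$loss, 1), 0.1)
  # loss is (weakly) decreasing over epochs up to SGD noise at the floor
  expect_lt(mean(diff(fit$history$loss) > 1e-4), 0.1)
})

test_that("learning rate halves on a validation stall", {
  corpus <- tiny_encoded_corpus(n = 8, seed = 6)
  # frozen validation labels make the validation error constant after the
  # first epoch reaches the all-negative plateau
  frozen <- lapply(corpus, function(d) list(x = d$x, y = rep(0L, length(d$y))))
  cfg <- train_config(epochs = 8, lr_halving_patience = 2, hidden_dim = 3,
                      mlp_hidden = 3, seed = 9)
  fit <- train(init_model(24, 3, 3, seed = 9), corpus, cfg,
               validation = frozen)
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))     # lr never increases
  expect_lt(utils::tail(lr, 1), cfg$lr_init)  # at least one halving occurred
  expect_true(all(lr %in% (cfg$lr_init / 2^(0:8))))
})

test_that("ensembling averages score tracks", {
  m1 <- init_model(10, 4, 4, seed = 1)
  m2 <- init_model(10, 4, 4, seed = 2)
  x <- matrix(rnorm(50), 5, 10)
  s1 <- forward(m1, x); s2 <- forward(m2, x)
  e <- ensemble_predict(list(m1, m2), x)
  expect_equal(e, (s1 + s2) / 2)
  expect_equal(ensemble_predict(list(m1, m1, m1), x), s1)
  expect_true(all(e >= pmin(s1, s2) & e <= pmax(s1, s2)))
  expect_error(ensemble_predict(list(), x), "empty")
  m3 <- init_model(9, 4, 4, seed = 3)
  expect_error(ensemble_predict(list(m1, m3), x), "input_dim")
})

test_that("model JSON serialization round-trips and rejects mismatches", {
  m <- init_model(24, 5, 6, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$hidden_dim, 5L)
  x <- matrix(rnorm(24 * 4), 4, 24)
  expect_equal(forward(back, x), forward(m, x))
  # corrupt the header
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$alphabet <- "XYZ"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "alphabet")
})
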