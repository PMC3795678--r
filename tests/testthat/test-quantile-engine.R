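test_that("wsad_loss computes the asymmetric deviation criterion", {
  expect_equal(wsad_loss(c(1, 2, 3), c(2, 2, 2), tau = 0.9), 1.0)
  expect_equal(wsad_loss(c(0, 10), c(5, 5), tau = 0.5), 5.0)
  y <- rnorm(20)
  expect_equal(wsad_loss(y, y, tau = 0.7), 0)
  # agrees with the independent pmax formulation on random data
  set.seed(4)
  for (tau in c(0.1, 0.5, 0.9)) {
    q <- rnorm(20)
    expect_equal(wsad_loss(y, q, tau), pinball(y, q, tau))
  }
  expect_error(wsad_loss(1:3, 1:2, 0.9), "same length")
  expect_error(wsad_loss(1:3, 1:3, 1), "tau")
})

test_that("intercept-only fits land on the lower vertex of flat optima", {
  d <- list(X = cbind(intercept = rep(1, 10)), y = as.numeric(1:10))
  fit <- qr_fit(d, tau = 0.9)
  # n * tau = 9 is an integer: any value in [9, 10] minimizes the loss;
  # the grid oracle and the engine must both report the lower end
  expect_equal(unname(fit$coefficients), 9)
  expect_equal(grid_quantile_oracle(d$y, 0.9), 9)
  expect_equal(fit$train_wsad, pinball(d$y, 9, 0.9))
})

test_that("unconditional_quantile matches the intercept-only engine fit", {
  expect_equal(unconditional_quantile(c(5, 5, 5), 0.42), 5)
  expect_equal(unconditional_quantile(1:10, 0.9), 9)
  set.seed(11)
  for (i in 1:20) {
    y <- sample(rpois(sample(5:40, 1), 14))
    tau <- runif(1, 0.05, 0.95)
    fit <- qr_fit(list(X = cbind(intercept = rep(1, length(y))), y = y),
                  tau = tau)
    expect_equal(unconditional_quantile(y, tau), unname(fit$coefficients))
    expect_equal(unconditional_quantile(y, tau),
                 unconditional_quantile(rev(y), tau))
  }
  expect_error(unconditional_quantile(numeric(0), 0.9), "non-empty")
})

test_that("noise-free linear data is interpolated exactly at any tau", {
  x <- seq(-3, 3, length.out = 25)
  X <- cbind(intercept = 1, x = x)
  y <- 2 + 3 * x
  for (tau in c(0.1, 0.5, 0.9)) {
    fit <- qr_fit(list(X = X, y = y), tau = tau)
    expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-9)
    expect_equal(fit$train_wsad, 0, tolerance = 1e-9)
  }
})

test_that("fitted values agree with quantreg on unique-optimum instances", {
  skip_if_not_installed("quantreg")
  for (seed in 1:25) {
    inst <- random_instance(seed)
    fit <- qr_fit(list(X = inst$X, y = inst$y), tau = inst$tau)
    ref <- quantreg::rq.fit.br(inst$X, inst$y, tau = inst$tau)
    expect_lt(max(abs(fit$fitted - (inst$y - ref$residuals))), 1e-6)
  }
})

test_that("objective matches exhaustive vertex enumeration for tiny n", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    p <- sample(1:3, 1)
    tau <- sample(c(0.5, 0.9), 1)
    X <- cbind(intercept = 1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", seq_len(p))
    y <- as.numeric(rpois(n, 10))
    fit <- qr_fit(list(X = X, y = y), tau = tau)
    expect_equal(fit$train_wsad, vertex_enum_oracle(X, y, tau),
                 tolerance = 1e-9)
    # the solution is itself an interpolating vertex
    expect_length(fit$basis, p)
    expect_lt(max(abs(y[fit$basis] - fit$fitted[fit$basis])), 1e-8)
  }
})

test_that("engine matches quantreg objectives on heavily tied count data", {
  skip_if_not_installed("quantreg")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(c(60, 150, 400), 1)
    p <- sample(2:6, 1)
    X <- cbind(intercept = 1, matrix(round(rnorm(n * (p - 1)), 1), n))
    colnames(X) <- paste0("c", seq_len(p))
    y <- as.numeric(rpois(n, 8))
    tau <- sample(c(0.5, 0.8, 0.9), 1)
    fit <- qr_fit(list(X = X, y = y), tau = tau)
    ref <- suppressWarnings(quantreg::rq.fit.br(X, y, tau = tau))
    expect_equal(fit$train_wsad, pinball(y, y - ref$residuals, tau),
                 tolerance = 1e-7)
  }
})

test_that("every fit satisfies the quantile sign property", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    p <- sample(1:5, 1)
    tau <- runif(1, 0.1, 0.95)
    X <- cbind(intercept = 1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", seq_len(p))
    y <- as.numeric(rpois(n, 12))
    fit <- qr_fit(list(X = X, y = y), tau = tau)
    expect_true(sign_property_ok(y, fit$fitted, tau))
  }
})

test_that("fits are location and positive-scale equivariant", {
  set.seed(8)
  X <- cbind(intercept = 1, x1 = rnorm(60), x2 = rnorm(60))
  y <- as.numeric(rpois(60, 10))
  fit <- qr_fit(list(X = X, y = y), tau = 0.9)
  shifted <- qr_fit(list(X = X, y = y + 7.5), tau = 0.9)
  expect_equal(unname(shifted$coefficients - fit$coefficients),
               c(7.5, 0, 0), tolerance = 1e-8)
  scaled <- qr_fit(list(X = X, y = 3 * y), tau = 0.9)
  expect_equal(unname(scaled$coefficients), unname(3 * fit$coefficients),
               tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  X <- cbind(intercept = 1, a = 1:20, twice_a = 2 * (1:20))
  expect_error(qr_fit(list(X = X, y = rnorm(20)), tau = 0.9), "twice_a")
})

test_that("predict applies frozen coefficients and checks column names", {
  set.seed(9)
  X <- cbind(intercept = 1, x = rnorm(40))
  y <- as.numeric(rpois(40, 15))
  fit <- qr_fit(list(X = X, y = y), tau = 0.9)
  # training-design predictions reproduce the fitted values and train WSAD
  expect_equal(predict(fit, list(X = X)), fit$fitted)
  expect_equal(wsad_loss(y, predict(fit, list(X = X)), 0.9),
               fit$train_wsad)
  # constant model predicts its constant anywhere
  cfit <- qr_fit(list(X = cbind(intercept = rep(1, 40)), y = y), tau = 0.9)
  newX <- cbind(intercept = rep(1, 7))
  expect_equal(predict(cfit, list(X = newX)),
               rep(unname(cfit$coefficients), 7))
  bad <- X
  colnames(bad) <- c("intercept", "renamed")
  expect_error(predict(fit, list(X = bad)), "do not match")
})

test_that("jittering the response perturbs coefficients only slightly", {
  set.seed(10)
  X <- cbind(intercept = 1, x = rnorm(300))
  y <- as.numeric(rpois(300, 14))
  plain <- qr_fit(list(X = X, y = y), tau = 0.9)
  jit <- qr_fit(list(X = X, y = y), tau = 0.9,
                jitter = list(amount = 0.1, seed = 42))
  expect_true(jit$jitter$applied)
  expect_false(plain$jitter$applied)
  expect_lt(max(abs(jit$coefficients - plain$coefficients)), 0.5)
  # identical jitter seed reproduces the fit exactly
  jit2 <- qr_fit(list(X = X, y = y), tau = 0.9,
                 jitter = list(amount = 0.1, seed = 42))
  expect_identical(jit$coefficients, jit2$coefficients)
})
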