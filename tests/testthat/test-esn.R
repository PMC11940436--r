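test_that("reservoir initialisation honours sparsity, radius and seed", {
  m <- esnInit(100, 8, sparsity = 0.5, rho = 0.9, seed = 7)
  expect_equal(Matrix::nnzero(m@Wres), 5000L)
  expect_equal(mcdecode:::spectralRadius(m@Wres), 0.9, tolerance = 1e-9)
  m2 <- esnInit(100, 8, sparsity = 0.5, rho = 0.9, seed = 7)
  expect_identical(m@Win, m2@Win)
  expect_identical(m@Wres, m2@Wres)
  expect_error(esnInit(100, 8, rho = 1.0), "below 1")
})

test_that("reservoir update follows the leaky-tanh recurrence", {
  m <- esnInit(20, 4, a = 1, sparsity = 0.5, rho = 0.5, seed = 1)
  m@Wres@x[] <- 0
  inp <- rnorm(4)
  m1 <- esnStep(m, inp)
  expect_equal(m1@R, as.numeric(tanh(m@Win %*% inp)))

  m <- esnInit(20, 4, a = 0.5, sparsity = 0.5, rho = 0.5, seed = 1)
  m@a <- 1e-12   # a -> 0: state frozen (a = 0 itself is outside (0,1])
  m@R <- rnorm(20)
  m2 <- esnStep(m, inp)
  expect_equal(m2@R, m@R, tolerance = 1e-9)

  # general step equals the explicit formula
  m <- esnInit(20, 4, a = 0.3, sparsity = 0.5, rho = 0.8, seed = 2)
  m@R <- rnorm(20)
  expected <- (1 - 0.3) * m@R +
    0.3 * tanh(as.numeric(m@Win %*% inp) + as.numeric(m@Wres %*% m@R))
  expect_equal(esnStep(m, inp)@R, expected)
  expect_error(esnStep(m, rnorm(3)), "length")
})

test_that("the echo-state property holds: initial conditions wash out", {
  for (s in 1:10) {
    m <- esnInit(200, 10, a = 0.5, sparsity = 0.5, rho = 0.95, seed = s)
    set.seed(1000 + s)
    inp <- matrix(rnorm(100 * 10), 100, 10)
    m1 <- m; m2 <- m
    m1@R <- runif(200, -1, 1)
    m2@R <- runif(200, -1, 1)
    d0 <- sqrt(sum((m1@R - m2@R)^2))
    for (t in 1:100) {
      m1 <- esnStep(m1, inp[t, ])
      m2 <- esnStep(m2, inp[t, ])
      expect_lte(max(abs(m1@R)), 1)
    }
    d1 <- sqrt(sum((m1@R - m2@R)^2))
    expect_lt(d1, 1e-3 * d0)
  }
})

test_that("readout is the advertised linear map of [R; in]", {
  m <- esnInit(15, 5, seed = 3)
  m <- addHead(m, "state", 3)
  inp <- rnorm(5)
  m <- esnStep(m, inp)
  expect_equal(esnOutput(m, "state", inp), rep(0, 3))   # Wout = 0
  W <- matrix(rnorm(3 * 20), 3, 20)
  m@heads$state@Wout <- W
  expect_equal(esnOutput(m, "state", inp),
               as.numeric(W %*% c(m@R, inp)))
  # selecting the input block as identity returns the input
  m <- addHead(m, "probe", 5)
  m@heads$probe@Wout[, 16:20] <- diag(5)
  expect_equal(esnOutput(m, "probe", inp), inp)
  expect_error(esnOutput(m, "nothere", inp), "unknown head")
})

test_that("RLS keeps a perfect prediction fixed and matches scalar theory", {
  h <- readoutHead(2, 6, epsilon = 1e-2)
  h@Wout <- matrix(rnorm(12), 2, 6)
  x <- rnorm(6)
  target <- as.numeric(h@Wout %*% x)
  h2 <- rlsUpdate(h, x, target)
  expect_equal(h2@Wout, h@Wout)        # zero innovation
  expect_false(isTRUE(all.equal(h2@P, h@P)))

  # scalar RLS with forgetting 1 equals the ridge estimate at every step
  eps <- 0.5
  h <- readoutHead(1, 1, epsilon = eps)
  obs <- c(2, 2, 2, 2, 2)              # x = 1 each time, y = 2
  for (n in seq_along(obs)) {
    h <- rlsUpdate(h, 1, obs[n])
    expect_equal(h@Wout[1, 1], sum(obs[1:n]) / (n + eps),
                 tolerance = 1e-12)
  }
  expect_error(rlsUpdate(h, NaN, 1), "non-finite")
})

test_that("RLS converges to batch ridge regression and is order-invariant", {
  set.seed(20)
  d <- 40; n <- 200; eps <- 1e-2
  X <- matrix(rnorm(n * d), n, d)
  Y <- matrix(rnorm(n * 2), n, 2)
  ridge <- t(solve(crossprod(X) + eps * diag(d), crossprod(X, Y)))
  h <- readoutHead(2, d, epsilon = eps)
  for (i in 1:n) h <- rlsUpdate(h, X[i, ], Y[i, ])
  expect_lt(max(abs(h@Wout - ridge)), 1e-6)
  # any order gives the same endpoint
  perm <- sample.int(n)
  h2 <- readoutHead(2, d, epsilon = eps)
  for (i in perm) h2 <- rlsUpdate(h2, X[i, ], Y[i, ])
  expect_lt(max(abs(h2@Wout - h@Wout)), 1e-6)
})

test_that("reinforcement rule gates on satisfaction and builds its trace", {
  h <- readoutHead(2, 5, alpha = 0.1, delta = 0)
  h@Wout <- matrix(rnorm(10), 2, 5)
  x <- rnorm(5); out <- rnorm(2)
  # satisfaction = 1: weights unchanged, trace still updated
  h1 <- rlUpdate(h, x, out, 1)
  expect_equal(h1@Wout, h@Wout)
  expect_equal(h1@E, tcrossprod(out, x))
  # delta = 0, satisfaction = 0: weight change is exactly -alpha * out x'
  h0 <- rlUpdate(h, x, out, 0)
  expect_equal(h0@Wout - h@Wout, -0.1 * tcrossprod(out, x))
  expect_error(rlUpdate(h, x, out, 0.5), "satisfaction")

  # constant out (x) product: E converges geometrically at rate delta
  h <- readoutHead(2, 5, alpha = 0, delta = 0.8)
  target <- tcrossprod(out, x)
  for (k in 1:5) {
    h <- rlUpdate(h, x, out, 1)
    expect_equal(h@E, (1 - 0.8^k) * target, tolerance = 1e-12)
  }
})

test_that("argmax decoding breaks ties toward the lowest index", {
  expect_equal(decodeState(c(0.1, 0.9)), 2L)
  expect_equal(decodeState(c(0.5, 0.5)), 1L)
  expect_equal(decodeState(c(0, 1, 2, 9, 3)), 4L)
  expect_error(decodeState(numeric()), "empty")
  expect_equal(decodeSatisfaction(c(0.2, 0.8)), 1L)
  expect_equal(decodeSatisfaction(c(0.8, 0.2)), 0L)
  expect_equal(decodeSatisfaction(c(0.5, 0.5)), 0L)
})
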