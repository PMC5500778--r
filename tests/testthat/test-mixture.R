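test_that("components are canonicalized by ascending sd", {
  m <- mixture_model(c(0.2, 0.5, 0.3), c(0, 5, 10), c(300, 20, 60))
  expect_equal(m$sds, c(20, 60, 300))
  expect_equal(m$means, c(5, 10, 0))
  expect_equal(m$weights, c(0.5, 0.3, 0.2))
  expect_error(mixture_model(c(0.5, 0.4), c(0, 1), c(1, 2)), "sum to 1")
})

test_that("K=1 EM is the closed-form Gaussian fit", {
  set.seed(5)
  x <- rnorm(200, 4, 7)
  f <- em_fit(x, K = 1L)
  expect_equal(f$model$means, mean(x), tolerance = 1e-12)
  expect_equal(f$model$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-9)
  expect_equal(f$model$weights, 1)
})

test_that("log-likelihood matches direct summation and the standard normal value", {
  m1 <- mixture_model(1, 0, 1)
  expect_equal(log_likelihood(m1, 0), -0.5 * log(2 * pi), tolerance = 1e-14)
  set.seed(8)
  m <- mixture_model(c(0.5, 0.3, 0.2), c(5, 10, 0), c(20, 60, 300))
  x <- rnorm(10, 0, 100)
  expect_equal(log_likelihood(m, x), oracle_loglik(m, x), tolerance = 1e-10)
  # a point at the heavy component's mean raises mean loglik more than a
  # point 10 sigma out
  base <- log_likelihood(m, x)
  near <- (log_likelihood(m, c(x, 5)) ) / 11
  far <- (log_likelihood(m, c(x, 5 + 10 * 300))) / 11
  expect_gt(near, far)
})

test_that("EM log-likelihood trace is non-decreasing and responsibilities normalize", {
  set.seed(13)
  for (i in 1:5) {
    d <- rmix(600, c(0.5, 0.3, 0.2), c(5, 10, 0), c(20, 60, 300))
    f <- em_fit(d$x, 3)
    expect_true(all(diff(f$loglik_trace) >= -1e-9))
    expect_equal(rowSums(f$responsibilities), rep(1, 600), tolerance = 1e-9)
    expect_true(f$converged)
  }
})

test_that("EM errors on insufficient data and handles degenerate input", {
  expect_error(em_fit(1:5, 3), "insufficient data")
  expect_warning(f <- em_fit(rep(7, 20), 3), "variance clamped")
  expect_equal(f$model$means, rep(7, 3))
  expect_equal(f$model$sds, rep(sqrt(1e-6), 3))
})

test_that("MAP assignment follows the weighted density argmax with first-index ties", {
  # identical components: tie goes to the lowest canonical index
  m <- mixture_model(c(0.5, 0.5), c(0, 0), c(10, 10))
  expect_equal(unique(map_assign(m, seq(-30, 30, by = 0.5))), 1L)
  # equal means: the small-sd component wins at the mean iff pi1/sd1 > pi2/sd2
  m2 <- mixture_model(c(0.5, 0.5), c(0, 0), c(10, 50))
  expect_equal(map_assign(m2, 0), 1L)
  m3 <- mixture_model(c(0.05, 0.95), c(0, 0), c(10, 11))
  expect_equal(map_assign(m3, 0), 2L)
})

test_that("equal-mean decision boundaries match the closed form", {
  p1 <- 0.6; p2 <- 0.4; s1 <- 15; s2 <- 120; mu <- 3
  m <- mixture_model(c(p1, p2), c(mu, mu), c(s1, s2))
  b <- sqrt(2 * s1^2 * s2^2 / (s2^2 - s1^2) * log(p1 * s2 / (p2 * s1)))
  reg <- assignment_regions(m, c(mu - 1000, mu + 1000))
  inner <- reg[reg$cluster == 1L, ]
  expect_equal(nrow(inner), 1L)
  expect_equal(inner$lower, mu - b, tolerance = 1e-8)
  expect_equal(inner$upper, mu + b, tolerance = 1e-8)
})

test_that("assignment regions partition the domain and agree with grid scan", {
  set.seed(17)
  models <- list(
    mixture_model(1, 2, 5),
    mixture_model(c(1, 1, 1) / 3, c(0, 0, 0), c(30, 100, 400)),
    mixture_model(c(0.5, 0.3, 0.2), c(5, 10, 0), c(20, 60, 300)),
    mixture_model(c(0.45, 0.55), c(-20, 35), c(25, 40)))
  for (m in models) {
    dom <- c(-1300, 1550)
    reg <- assignment_regions(m, dom)
    # partition: contiguous, no gaps or overlaps
    expect_equal(reg$lower[1], dom[1])
    expect_equal(reg$upper[nrow(reg)], dom[2])
    if (nrow(reg) > 1) {
      expect_equal(reg$lower[-1], reg$upper[-nrow(reg)])
    }
    grid <- seq(dom[1], dom[2], length.out = 10000)
    expect_equal(region_assign(reg, grid), map_assign(m, grid))
  }
})

test_that("K=1 yields a single region covering the domain", {
  reg <- assignment_regions(mixture_model(1, 0, 10), c(-50, 50))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$cluster, 1L)
})

test_that("converged solution agrees with an independent reference EM", {
  set.seed(99)
  d <- rmix(2000, c(0.5, 0.3, 0.2), c(5, 10, 0), c(20, 60, 300))
  f <- em_fit(d$x, 3, tol = 1e-12, max_iter = 5000)
  ours <- f$loglik_trace[length(f$loglik_trace)]
  par <- list(pro = f$model$weights, mean = f$model$means,
              variance = list(modelName = "V", d = 1, G = 3,
                              sigmasq = f$model$sds^2))
  ref <- mclust::emV(data = d$x, parameters = par,
                     control = mclust::emControl(tol = c(1e-12, 1e-12)))
  expect_equal(ours, ref$loglik, tolerance = 1e-6)
})

test_that("supervised per-class fit reproduces class statistics", {
  set.seed(23)
  x <- c(rnorm(300, 10, 30), rnorm(700, 0, 200))
  lab <- rep(c("ADR", "OTHER"), c(300, 700))
  m <- fit_supervised(x, lab)
  expect_equal(m$K, 2L)
  expect_equal(m$weights[1], 0.3)
  expect_equal(m$means[1], mean(x[1:300]))
})
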