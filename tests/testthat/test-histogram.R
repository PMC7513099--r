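test_that("binning follows the half-open convention and validates input", {
  b <- bin_counts(c(0, 0.5, 1.0), K = 2)
  expect_identical(b$v, c(1L, 2L)) # 0.5 belongs to the upper bin, 1.0 is kept
  expect_equal(b$R, 1)
  expect_equal(b$h, 0.5)
  expect_equal(b$edges, c(0, 0.5, 1))

  b1 <- bin_counts(c(0, 1), K = 1)
  expect_identical(b1$v, 2L)
  expect_equal(b1$R, 1)

  expect_error(bin_counts(c(0, 0, 0), 3), "zero range")
  expect_error(bin_counts(c(0, 1), 0), "positive integer")
  expect_error(bin_counts(c(0, NA, 1), 2), "missing")
  expect_error(bin_counts(0.5, 2), "at least 2")

  # explicit support override
  bo <- bin_counts(c(0.2, 0.4, 0.9), K = 2, range = c(0, 1))
  expect_identical(bo$v, c(2L, 1L))
  expect_equal(bo$R, 1)
  expect_error(bin_counts(c(0.2, 1.4), 2, range = c(0, 1)), "outside")
})

test_that("bin counts satisfy their structural invariants", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1))
    K <- sample(1:25, 1)
    b <- bin_counts(x, K)
    expect_identical(sum(b$v), length(x))
    expect_equal(b$h * b$K, b$R)
    expect_equal(b$edges[1], min(x))
    expect_equal(b$edges[b$K + 1], max(x))
  }
})

test_that("sphere MLE lands on the radius-sqrt(K/R) sphere", {
  # single bin: u = 1, lambda = N
  b <- bin_counts(c(rep(0, 3), 1), 1)
  m <- sphere_mle(b)
  expect_equal(m$u_hat, 1)
  expect_equal(m$lambda_hat, 4)

  # equal counts
  b2 <- bin_counts(c(0, 0.2, 0.6, 1), 2)
  m2 <- sphere_mle(b2)
  expect_equal(m2$u_hat, c(1, 1))
  expect_equal(sum(m2$u_hat^2), b2$K / b2$R)

  # v = (3, 0, 1), N = 4, K = 3, R = 2: u = sqrt(v K / (N R))
  b3 <- bin_counts(c(0, 0.1, 0.2, 2), 3)
  expect_identical(b3$v, c(3L, 0L, 1L))
  m3 <- sphere_mle(b3)
  expect_equal(m3$u_hat, c(sqrt(9 / 8), 0, sqrt(3 / 8)))
  expect_equal(sum(m3$u_hat^2), 3 / 2)
  expect_equal(m3$lambda_hat, 4 * 2 / 3)

  # random cases: constraint and density normalization
  set.seed(7)
  for (i in 1:20) {
    x <- rt(sample(20:150, 1), df = 3)
    K <- sample(1:20, 1)
    b <- bin_counts(x, K)
    u <- sphere_mle(b)$u_hat
    expect_equal(sum(u^2), b$K / b$R, tolerance = 1e-10)
    expect_equal(sum(u^2 * b$h), 1, tolerance = 1e-12)
  }
})

test_that("negative log-likelihood handles empty bins and matches closed forms", {
  # uniform counts on unit range: all u = 1, likelihood term vanishes
  b <- bin_counts(equal_count_data(60, 4), 4, range = c(0, 1))
  expect_identical(b$v, rep(15L, 4))
  expect_equal(neg_log_likelihood(b), 0)
  expect_equal(neg_log_likelihood(bin_counts(c(0, 1), 1)), 0)

  # v = (3, 1), N = 4, R = 1: hand-evaluated -3 ln(3/2) + ln 2
  b2 <- bin_counts(c(0, 0.1, 0.2, 1), 2)
  expect_identical(b2$v, c(3L, 1L))
  expect_equal(neg_log_likelihood(b2), -3 * log(3 / 2) + log(2))

  # cross-check against the multinomial histogram likelihood -sum v log(p/h)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(80)
    K <- sample(2:25, 1) # large K gives empty bins; 0 log 0 := 0
    b <- bin_counts(x, K)
    pos <- b$v > 0
    expect_equal(neg_log_likelihood(b),
                 -sum(b$v[pos] * log((b$v[pos] / b$N) / b$h)))
    expect_true(is.finite(neg_log_likelihood(b)))
  }
})

test_that("Hessian diagonal is 4h and matches the Lagrange assembly", {
  expect_equal(hessian_diagonal(bin_counts(runif(10), 4, range = c(0, 1))), 1)
  expect_equal(hessian_diagonal(bin_counts(runif(10, 0, 2), 2, range = c(0, 2))), 4)
  # (2/N) v_k / u_k^2 + 2 lambda / N = 4h at every non-empty bin
  set.seed(3)
  for (i in 1:10) {
    b <- bin_counts(rnorm(70), sample(1:15, 1))
    m <- sphere_mle(b)
    pos <- b$v > 0
    assembled <- (2 / b$N) * b$v[pos] / m$u_hat[pos]^2 + 2 * m$lambda_hat / b$N
    expect_equal(assembled, rep(hessian_diagonal(b), sum(pos)))
    expect_true(hessian_diagonal(b) > 0)
  }
})

test_that("Fisher log sqrt determinant is (K/2) log(4R/K)", {
  expect_equal(fisher_log_det_sqrt(4, 1), 0)
  expect_equal(fisher_log_det_sqrt(1, 1), log(2))
  expect_equal(fisher_log_det_sqrt(2, 3), log(6))
})

test_that("fit term is shift invariant and shifts by N log a under rescaling", {
  set.seed(19)
  x <- rnorm(60)
  a <- 3.7
  for (K in 1:10) {
    nll <- neg_log_likelihood(bin_counts(x, K))
    expect_equal(neg_log_likelihood(bin_counts(x + 5, K)), nll)
    expect_equal(neg_log_likelihood(bin_counts(a * x, K)),
                 nll + length(x) * log(a))
  }
})

test_that("MLE recovers a bin-aligned piecewise-constant density", {
  set.seed(101)
  n <- 1e5
  p1 <- 0.25 # mass of the left half, density heights 0.5 and 1.5 on [0, 1]
  left <- runif(n) < p1
  x <- ifelse(left, runif(n, 0, 0.5), runif(n, 0.5, 1))
  b <- bin_counts(x, 2, range = c(0, 1))
  u2 <- sphere_mle(b)$u_hat^2
  se <- sqrt(p1 * (1 - p1) / n) / 0.5
  expect_lt(abs(u2[1] - 0.5), 3 * se)
  expect_lt(abs(u2[2] - 1.5), 3 * se)
})

test_that("sample reader accepts clean files and rejects blanks and text", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.5", "-2", "3e-1"), path)
  expect_equal(read_sample(path), c(1.5, -2, 0.3))

  writeLines(c("1.5", "", "3"), path)
  expect_error(read_sample(path), "blank line 2")

  writeLines(c("1.5", "abc"), path)
  expect_error(read_sample(path), "not a number")
})
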