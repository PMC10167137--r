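test_that("Ex-Gaussian density is a proper density with mean mu + nu", {
  for (th in list(c(1, 0.2, 0.5), c(0, 0.1, 0.02), c(2, 1, 3))) {
    intg <- integrate(function(x) dexgauss(x, th[1], th[2], th[3]),
                      th[1] - 9 * th[2], th[1] + 12 * (th[2] + th[3]))
    expect_equal(intg$value, 1, tolerance = 1e-5)
  }
  set.seed(11)
  expect_equal(mean(rexgauss(1e6, 1, 0.2, 0.5)), 1.5, tolerance = 5e-3)
})

test_that("Ex-Gaussian density degenerates to the Normal as nu -> 0", {
  x <- seq(-1, 2, by = 0.25)
  expect_equal(dexgauss(x, 0.5, 0.3, 1e-7, log = TRUE),
               dnorm(x, 0.5, 0.3, log = TRUE), tolerance = 1e-5)
  # no overflow when nu << sigma
  expect_true(all(is.finite(dexgauss(x, 0.5, 0.3, 1e-12, log = TRUE))))
})

test_that("Ex-Gaussian cdf, quantiles and scores are mutually consistent", {
  expect_equal(pexgauss(qexgauss(c(0.1, 0.5, 0.9), 1, 0.2, 0.5), 1, 0.2, 0.5),
               c(0.1, 0.5, 0.9), tolerance = 1e-8)
  # analytic scores against central differences
  x <- c(0.6, 1.4, 3.0); th <- c(1, 0.2, 0.5)
  an <- vsmulti:::exgauss_score(x, th[1], th[2], th[3])
  for (j in 1:3) {
    h <- 1e-6; tp <- th; tp[j] <- th[j] + h; tm <- th; tm[j] <- th[j] - h
    num <- (dexgauss(x, tp[1], tp[2], tp[3], log = TRUE) -
              dexgauss(x, tm[1], tm[2], tm[3], log = TRUE)) / (2 * h)
    expect_equal(unname(an[, j]), num, tolerance = 1e-4)
  }
})

test_that("GB1 nests the Beta distribution and is a proper density", {
  # Beta(2,2) arises at mu = .5, sigma = 1/sqrt(5), nu = tau = 1
  expect_equal(dgb1(0.5, 0.5, 1 / sqrt(5), 1, 1, log = TRUE),
               dbeta(0.5, 2, 2, log = TRUE), tolerance = 1e-12)
  x <- seq(0.05, 0.95, by = 0.15)
  expect_equal(dgb1(x, 0.5, 1 / sqrt(5), 1, 1, log = TRUE),
               dbeta(x, 2, 2, log = TRUE), tolerance = 1e-12)
  for (th in list(c(0.6, 0.4, 1.5, 2), c(0.3, 0.6, 0.5, 0.8))) {
    intg <- integrate(function(v) dgb1(v, th[1], th[2], th[3], th[4]),
                      1e-10, 1 - 1e-10)
    expect_equal(intg$value, 1, tolerance = 1e-4)
  }
  # symmetric member: logpdf(x) = logpdf(1 - x)
  xs <- c(0.1, 0.25, 0.4)
  expect_equal(dgb1(xs, 0.5, 0.4, 1, 1, log = TRUE),
               dgb1(1 - xs, 0.5, 0.4, 1, 1, log = TRUE), tolerance = 1e-12)
  expect_error(dgb1(1, 0.5, 0.4, 1, 1), "inside")
  # analytic score against central differences
  th <- c(0.6, 0.4, 1.5, 2); x <- c(0.3, 0.8, 0.95)
  an <- vsmulti:::gb1_score(x, th[1], th[2], th[3], th[4])
  for (j in 1:4) {
    h <- 1e-6; tp <- th; tp[j] <- th[j] + h; tm <- th; tm[j] <- th[j] - h
    num <- (dgb1(x, tp[1], tp[2], tp[3], tp[4], log = TRUE) -
              dgb1(x, tm[1], tm[2], tm[3], tm[4], log = TRUE)) / (2 * h)
    expect_equal(unname(an[, j]), num, tolerance = 1e-4)
  }
})

test_that("ML fitting recovers parameters and reports honest convergence", {
  set.seed(42)
  x <- rexgauss(5000, 0.8, 0.15, 0.6)
  f <- fit_mle(x, dist_family("exgaussian"))
  expect_true(f$converged)
  expect_lt(max(abs(f$theta_hat - c(0.8, 0.15, 0.6)) / c(0.8, 0.15, 0.6)),
            0.05)
  # mean per-observation score vanishes at an interior optimum
  expect_lt(max(abs(colMeans(f$score_matrix))), 1e-4 / sqrt(f$n) * 100)
  expect_equal(f$loglik, sum(dexgauss(x, f$theta_hat[1], f$theta_hat[2],
                                      f$theta_hat[3], log = TRUE)))

  # Normal family: closed-form ML solution
  set.seed(2)
  y <- rnorm(200, 3, 2)
  fn <- fit_mle(y, dist_family("normal"))
  expect_equal(unname(fn$theta_hat["mu"]), mean(y), tolerance = 1e-5)
  expect_equal(unname(fn$theta_hat["sigma"]),
               sd(y) * sqrt(199 / 200), tolerance = 1e-4)

  # degenerate constant sample: flagged, no crash
  fc <- fit_mle(rep(1, 100), dist_family("exgaussian"))
  expect_false(fc$converged && !fc$boundary)

  expect_error(fit_mle(rexgauss(10, 1, .2, .5), dist_family("exgaussian")),
               "at least")
})

test_that("optimizer never loses to its method-of-moments start", {
  set.seed(13)
  for (i in 1:8) {
    x <- rexgauss(300, runif(1, 0.5, 2), runif(1, 0.05, 0.4),
                  runif(1, 0.1, 1.5))
    spec <- dist_family("exgaussian")
    st <- spec$start(x)
    f <- fit_mle(x, spec)
    expect_gte(f$loglik, sum(spec$logpdf(x, st)) - 1e-6)
  }
  set.seed(14)
  b <- rbeta(400, 3, 1.5)
  spec <- dist_family("gb1")
  st <- spec$start(b)
  fg <- fit_mle(b, spec)
  expect_gte(fg$loglik, sum(spec$logpdf(b, st)) - 1e-6)
})

test_that("squeeze_unit compresses the closed interval monotonically", {
  expect_equal(squeeze_unit(1, 0.005), 0.995)
  expect_equal(squeeze_unit(0, 0.005), 0.005)
  expect_equal(squeeze_unit(0.5, 0.3), 0.5)
  set.seed(3)
  for (i in 1:5) {
    v <- runif(50)
    expect_equal(order(squeeze_unit(v, 0.01)), order(v))
  }
  expect_error(squeeze_unit(c(0.5, 1.2)), "0, 1")
  expect_error(squeeze_unit(0.5, 0.7), "epsilon")
})

test_that("fitted models serialize to JSON", {
  set.seed(4)
  f <- fit_mle(rexgauss(200, 1, 0.2, 0.4), dist_family("exgaussian"))
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$family, "exgaussian")
  expect_equal(js$n, 200)
  expect_equal(js$theta_hat$mu, unname(f$theta_hat["mu"]))
})
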