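test_that("median CI follows the binomial order-statistic formula", {
  r <- median_ci(1:100)
  expect_equal(r$median, 50.5)
  # ranks floor((100 - 1.96*10)/2) = 40 and ceiling((100 + 1.96*10)/2) = 60
  expect_equal(r$lo, 40)
  expect_equal(r$hi, 60)
  expect_false(r$wide)

  rc <- median_ci(rep(3, 20))
  expect_equal(rc$lo, rc$hi)

  rs <- median_ci(c(2, 5, 1))
  expect_true(rs$wide)
  expect_equal(c(rs$lo, rs$hi), c(1, 5))
})

test_that("instability test handles degenerate covariates by convention", {
  set.seed(1)
  f <- fit_mle(rnorm(80), dist_family("normal"))
  expect_equal(instability_test(f$score_matrix, rep(1, 80))$p.value, 1)
  expect_equal(instability_test(f$score_matrix,
                                factor(rep("a", 80)))$p.value, 1)
})

test_that("instability test separates null from shifted covariates", {
  set.seed(2)
  # null: covariate independent of the scores
  f <- fit_mle(rexgauss(150, 1, 0.2, 0.5), dist_family("exgaussian"))
  p_null <- instability_test(f$score_matrix,
                             factor(rep(c("a", "b"), 75)))$p.value
  expect_gt(p_null, 0.001)
  # planted location shift of 3 pooled SDs
  z <- rep(0:1, each = 100)
  sdp <- sqrt(0.2^2 + 0.5^2)
  x <- rexgauss(200, 1 + 3 * sdp * z, 0.2, 0.5)
  fs <- fit_mle(x, dist_family("exgaussian"))
  expect_lt(instability_test(fs$score_matrix, factor(z))$p.value, 1e-4)
  # numeric covariate tracking the shift
  expect_lt(instability_test(fs$score_matrix,
                             z + runif(200, 0, 0.1))$p.value, 1e-3)
})

test_that("select_split Bonferroni-adjusts and can abstain", {
  set.seed(3)
  f <- fit_mle(rexgauss(200, 1, 0.2, 0.5), dist_family("exgaussian"))
  expect_null(select_split(f, data.frame(x = numeric(200))[, 0]))
  # one strong covariate among nulls is selected
  z <- rep(c("a", "b"), each = 100)
  x <- rexgauss(200, ifelse(z == "a", 1, 2.5), 0.2, 0.5)
  fs <- fit_mle(x, dist_family("exgaussian"))
  cov <- data.frame(z = factor(z), u1 = rnorm(200), u2 = rnorm(200),
                    u3 = factor(sample(c("p", "q"), 200, TRUE)))
  sel <- select_split(fs, cov)
  expect_equal(sel$covariate, "z")
  expect_lt(sel$adjusted_p, 0.05)
  expect_equal(unname(sel$adjusted_p), min(sel$all_adjusted))
})

test_that("partition search maximizes the children's joint likelihood", {
  set.seed(4)
  # ordinal set size with a shift between {4} and {16, 24}
  s <- factor(sample(c(4, 16, 24), 300, TRUE), levels = c(4, 16, 24),
              ordered = TRUE)
  y <- rexgauss(300, ifelse(s == "4", 0.9, 2.4), 0.15, 0.5)
  part <- find_partition(y, s, dist_family("exgaussian"), min_node = 20)
  expect_equal(part$left_levels, "4")
  # children jointly beat the parent fit
  parent <- fit_mle(y, dist_family("exgaussian"))
  expect_gte(part$loglik, parent$loglik)

  # numeric threshold agrees with exhaustive enumeration under the
  # closed-form Gaussian ML log-likelihood
  set.seed(5)
  u <- runif(30)
  yn <- rnorm(30, ifelse(u < 0.45, 0, 2), 1)
  pn <- find_partition(yn, u, dist_family("normal"), min_node = 10)
  vals <- sort(unique(u))
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  lls <- vapply(cand, function(tt) {
    if (sum(u <= tt) < 10 || sum(u > tt) < 10) return(-Inf)
    norm_ml_loglik(yn[u <= tt]) + norm_ml_loglik(yn[u > tt])
  }, numeric(1))
  expect_equal(pn$threshold, cand[which.max(lls)])

  # no admissible partition when min_node cannot be honoured
  expect_null(find_partition(yn, u, dist_family("normal"), min_node = 20))
})

test_that("tree growth stops correctly and reports depth-first ids", {
  set.seed(6)
  z <- factor(rep(c("a", "b"), each = 200))
  y <- rexgauss(400, ifelse(z == "a", 1, 2), 0.2, 0.4)
  tr <- disttree(y, data.frame(z = z),
                 control = disttree_control(max_depth = 0))
  expect_null(tr$root$split)

  tr2 <- disttree(y, data.frame(z = z),
                  control = disttree_control(max_depth = 2))
  expect_equal(tr2$root$split$covariate, "z")
  expect_equal(tr2$root$id, 1)
  ids <- vapply(vsmulti:::tree_nodes(tr2), `[[`, integer(1), "id")
  expect_equal(ids, seq_along(ids))  # preorder numbering
  kids_n <- vapply(tr2$root$kids, `[[`, integer(1), "n")
  expect_equal(sum(kids_n), tr2$root$n)
})

test_that("identical data, config and seed give identical trees", {
  set.seed(7)
  z <- factor(rep(c("a", "b"), each = 150))
  u <- runif(300)
  y <- rexgauss(300, ifelse(z == "a", 1, 1.9), 0.2, 0.4)
  t1 <- disttree(y, data.frame(z = z, u = u),
                 control = disttree_control(seed = 5))
  t2 <- disttree(y, data.frame(z = z, u = u),
                 control = disttree_control(seed = 5))
  expect_identical(tree_to_json(t1), tree_to_json(t2))
})

test_that("refitting a leaf on its own data reproduces the stored fit", {
  set.seed(8)
  z <- factor(rep(c("a", "b"), each = 150))
  y <- rexgauss(300, ifelse(z == "a", 1, 2.2), 0.2, 0.4)
  tr <- disttree(y, data.frame(z = z))
  leaf <- tr$root$kids[[1]]
  refit <- fit_mle(y[leaf$idx], dist_family("exgaussian"))
  expect_equal(refit$theta_hat, leaf$model$theta_hat, tolerance = 1e-5)
})

test_that("permuting covariates destroys the structure", {
  set.seed(9)
  hits <- 0
  for (i in 1:5) {
    z <- factor(rep(c("a", "b"), each = 150))
    u <- runif(300)
    y <- rexgauss(300, ifelse(z == "a", 1, 2.2), 0.2, 0.4)
    perm <- sample(300)
    tr <- disttree(y, data.frame(z = z[perm], u = u[perm]),
                   control = disttree_control(max_depth = 2))
    hits <- hits + is.null(tr$root$split)
  }
  expect_gte(hits, 4)
})

test_that("tree serializations carry the reporting format", {
  set.seed(10)
  z <- factor(rep(c("a", "b"), each = 150))
  y <- rexgauss(300, ifelse(z == "a", 1, 2.2), 0.2, 0.4)
  tr <- disttree(y, data.frame(z = z))
  js <- jsonlite::fromJSON(tree_to_json(tr))
  expect_equal(js$family, "exgaussian")
  expect_equal(js$root$n, 300)
  expect_true(!is.null(js$root$summary$median))
  dot <- tree_to_dot(tr)
  expect_match(dot, "digraph")
  expect_match(dot, "n = 300, ")
  expect_match(dot, "\\[")
})
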