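make_cond_data <- function(seed = 1, n_imp = 14, n_ctl = 12) {
  pre <- preprocess_trials(
    simulate_experiment(sim_config(seed = seed, n_impaired = n_imp,
                                   n_control = n_ctl))$trials)
  cond <- pre$conditions
  cond <- cond[!cond$excluded & !is.na(cond$median_rt), ]
  cond$acc_sq <- squeeze_unit(cond$accuracy)
  cond
}

test_that("design matrix is reproducible, hash-stable, with fixed coding", {
  cond <- make_cond_data()
  d1 <- build_design(cond, "median_rt")
  d2 <- build_design(cond, "median_rt")
  expect_identical(d1$hash, d2$hash)
  expect_true(all(c("(Intercept)", "groupi", "set_size16", "set_size24",
                    "targetp", "nystagmus", "age", "genderm") %in%
                    colnames(d1$X)))
  expect_equal(ncol(d1$X), 15)
  expect_equal(d1$var_map[["groupi:set_size16"]], c("G", "S"))
  # aliased column detection
  cond2 <- cond
  cond2$nystagmus <- as.integer(cond2$group == "i")
  expect_error(build_design(cond2, "median_rt"), "rank deficient")
})

test_that("median regression recovers medians and exact linear data", {
  d0 <- list(y = c(1, 2, 3, 4, 100),
             X = matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)")))
  tab <- fit_quantile(d0, boot = 50, seed = 1)
  expect_equal(tab$estimate, 3, tolerance = 1e-6)

  set.seed(2)
  x <- runif(60)
  yl <- 1 + 2 * x
  dl <- list(y = yl, X = cbind("(Intercept)" = 1, x = x))
  tabl <- fit_quantile(dl, boot = 50, seed = 1)
  expect_equal(tabl$estimate, c(1, 2), tolerance = 1e-4)
  expect_equal(attr(tabl, "inference"), "bootstrap")
})

test_that("Huber regression matches least squares on clean Gaussian data
           and resists gross outliers", {
  set.seed(3)
  x <- runif(500)
  y <- 1 + 3 * x + rnorm(500, 0, 0.2)
  des <- list(y = y, X = cbind("(Intercept)" = 1, x = x))
  rb <- fit_robust(des)
  ls <- coef(lm(y ~ x))
  expect_lt(max(abs(rb$estimate - ls) / abs(ls)), 0.01)

  # intercept-only symmetric data: intercept ~ mean
  des0 <- list(y = rnorm(300, 5),
               X = matrix(1, 300, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(fit_robust(des0)$estimate, mean(des0$y), tolerance = 0.02)

  # 10% wild outliers: robust slope stays near truth, OLS does not
  yo <- y; idx <- sample(500, 50); yo[idx] <- yo[idx] + 40
  deso <- list(y = yo, X = des$X)
  rb_o <- fit_robust(deso)
  ls_o <- coef(lm(yo ~ x))
  expect_lt(abs(rb_o$estimate[2] - 3), 0.2 * abs(ls_o[2] - 3) + 0.3)
})

test_that("intercept-only distributional fit reproduces fit_mle", {
  set.seed(4)
  y <- rexgauss(400, 1, 0.2, 0.5)
  des <- list(y = y,
              X = matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)")))
  fd <- fit_distributional(des, "exgaussian")
  fm <- fit_mle(y, dist_family("exgaussian"))
  est <- vapply(fd$tables, function(tb) tb$estimate[1], numeric(1))
  expect_equal(unname(est["mu"]), unname(fm$theta_hat["mu"]),
               tolerance = 1e-4)
  expect_equal(unname(exp(est["sigma"])), unname(fm$theta_hat["sigma"]),
               tolerance = 1e-3)
  expect_equal(unname(exp(est["nu"])), unname(fm$theta_hat["nu"]),
               tolerance = 1e-3)
  expect_equal(fd$loglik, fm$loglik, tolerance = 1e-6)
})

test_that("distributional regression localizes a scale-only effect", {
  set.seed(5)
  n <- 500
  z <- rep(0:1, each = n / 2)
  y <- rnorm(n, 0, exp(0.1 + 0.5 * z))
  des <- list(y = y, X = cbind("(Intercept)" = 1, z = z))
  fd <- fit_distributional(des, "normal", full_for = c("mu", "sigma"))
  expect_true(fd$converged)
  expect_lt(fd$tables$sigma$p[fd$tables$sigma$term == "z"], 0.01)
  expect_gt(fd$tables$mu$p[fd$tables$mu$term == "z"], 0.01)
})

test_that("the multiverse shares one design and summarizes agreement", {
  cond <- make_cond_data()
  mv <- run_multiverse(cond, "median_rt", family = "exgaussian", seed = 1)
  expect_setequal(mv$universes,
                  c("quantile", "robust", "distributional"))
  expect_equal(nrow(mv$agreement), 15)
  expect_true(all(mv$agreement$n_significant <= length(mv$universes)))
  # group effect is unmissable at these effect sizes
  g <- mv$agreement[mv$agreement$term == "groupi", ]
  expect_gte(g$n_significant, 2)
  expect_true(g$sign_consistent)
})

test_that("model reduction combines screening and corroboration", {
  fake_mv <- function(sig_terms) {
    terms <- c("(Intercept)", "groupi", "set_size16", "targetp",
               "nystagmus", "age", "genderm")
    var_map <- list("(Intercept)" = character(0), groupi = "G",
                    set_size16 = "S", targetp = "T", nystagmus = "n",
                    age = "a", genderm = "g")
    structure(list(
      agreement = data.frame(term = terms,
                             n_significant = ifelse(terms %in% sig_terms,
                                                    3L, 0L),
                             sign_consistent = TRUE, sign = 1),
      var_map = var_map,
      universes = c("quantile", "robust", "distributional")),
      class = "multiverse_result")
  }
  fake_imp <- function(confirmed) {
    vars <- c("group", "set_size", "target", "gender", "nystagmus", "age")
    dec <- ifelse(vars %in% confirmed, "confirmed", "rejected")
    structure(list(decision = factor(stats::setNames(dec, vars),
                                     levels = c("confirmed", "tentative",
                                                "rejected"))),
              class = "importance_result")
  }
  mv <- fake_mv(c("groupi", "set_size16", "targetp", "genderm"))
  imp <- fake_imp(c("group", "set_size", "target", "gender", "nystagmus"))
  red <- reduce_model(mv, imp)
  # nystagmus confirmed by the screen but vetoed by the regressions
  expect_setequal(red$retained, c("G", "S", "T", "g"))
  expect_true(red$all_categorical)

  red_or <- reduce_model(mv, imp, rule = "or")
  expect_setequal(red_or$retained, c("G", "S", "T", "g", "n"))

  # all-null: intercept-only with warning
  expect_warning(red0 <- reduce_model(fake_mv(character(0)),
                                      fake_imp(character(0))),
                 "intercept-only")
  expect_length(red0$retained, 0)

  # age retained makes the reduced model non-categorical
  mv_a <- fake_mv(c("set_size16", "targetp", "age"))
  imp_a <- fake_imp(c("set_size", "target", "age"))
  red_a <- reduce_model(mv_a, imp_a)
  expect_setequal(red_a$retained, c("S", "T", "a"))
  expect_false(red_a$all_categorical)
})

test_that("reduction degrades gracefully when a universe is missing", {
  cond <- make_cond_data()
  mv2 <- run_multiverse(cond, "median_rt", family = "exgaussian",
                        universes = c("quantile", "robust"), seed = 1)
  expect_length(mv2$universes, 2)
  Xc <- cond[, c("group", "set_size", "target", "gender", "nystagmus",
                 "age")]
  Xc$nystagmus <- factor(Xc$nystagmus)
  b <- boruta(Xc, cond$median_rt, max_iter = 12, num_trees = 80, seed = 1)
  expect_no_error(reduce_model(mv2, b))
})
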