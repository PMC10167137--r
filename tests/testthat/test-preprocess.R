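test_that("practice trials (first eight presentations) are dropped", {
  tr <- make_trials(80)
  out <- drop_practice(validate_trials(tr))
  expect_equal(nrow(out), 72)
  expect_equal(out$order, 9:80)

  expect_equal(nrow(drop_practice(validate_trials(tr)[0, ])), 0)
  test_only <- validate_trials(tr)[9:80, ]
  expect_identical(drop_practice(test_only), test_only)

  tr_bad <- tr; tr_bad$order[3] <- NA
  expect_error(drop_practice(tr_bad), "order")
})

test_that("RT cutoff excludes strictly above the bound", {
  tr <- make_trials(3, rt = c(9.9, 10.0, 10.1))
  out <- apply_rt_cutoff(tr)
  expect_equal(out$rt_s, c(9.9, 10.0))

  below <- make_trials(5, rt = rep(2, 5))
  expect_identical(apply_rt_cutoff(below), below)
  above <- make_trials(5, rt = rep(11, 5))
  expect_equal(nrow(apply_rt_cutoff(above)), 0)

  bad <- make_trials(2, rt = c(1, -1))
  expect_error(apply_rt_cutoff(bad), "positive")
})

test_that("practice drop and RT cutoff commute", {
  set.seed(31)
  for (i in 1:5) {
    tr <- make_trials(40, rt = runif(40, 0.2, 12))
    tr$practice <- tr$order <= 8
    a <- apply_rt_cutoff(drop_practice(tr))
    b <- drop_practice(apply_rt_cutoff(tr))
    expect_identical(a, b)
  }
})

test_that("condition summary reproduces the worked accuracy example", {
  # 10 correct out of 12 presentations -> 83%
  tr <- make_trials(12, rt = rep(1, 12),
                    correct = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 1, 1),
                    set_size = rep(4L, 12), target = rep("p", 12))
  s <- summarize_condition(tr)
  expect_equal(s$accuracy, 10 / 12)
  expect_equal(round(100 * s$accuracy), 83)
  expect_false(s$excluded)
  expect_length(s$retained_rts, 8)

  # all correct: accuracy 1, exactly eight retained
  s2 <- summarize_condition(make_trials(8, set_size = rep(4L, 8),
                                        target = rep("p", 8)))
  expect_equal(s2$accuracy, 1)
  expect_length(s2$retained_rts, 8)

  # 6 of 12: at chance, excluded
  s3 <- summarize_condition(make_trials(12, correct = rep(c(1L, 0L), 6),
                                        set_size = rep(4L, 12),
                                        target = rep("p", 12)))
  expect_equal(s3$accuracy, 0.5)
  expect_true(s3$excluded)

  # no presentations: empty flag, no exception
  s4 <- summarize_condition(make_trials(1)[0, ])
  expect_true(s4$empty)
})

test_that("alternative eight-over-trials accuracy rule is available", {
  # eighth correct response arrives on presentation 10
  corr <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 1, 1)
  tr <- make_trials(12, correct = corr, set_size = rep(4L, 12),
                    target = rep("p", 12))
  s <- summarize_condition(tr, accuracy_rule = "eight_over_trials")
  expect_equal(s$accuracy, 8 / 10)
  # never reaching eight correct gives NA accuracy
  s2 <- summarize_condition(make_trials(6, set_size = rep(4L, 6),
                                        target = rep("p", 6)),
                            accuracy_rule = "eight_over_trials")
  expect_true(is.na(s2$accuracy))
})

test_that("retained RTs are the first eight correct, cutoff-surviving", {
  rt <- c(1, 12, 2, 3, 4, 5, 6, 7, 8, 9, 1.5, 2.5)
  corr <- c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1, 1)
  tr <- make_trials(12, rt = rt, correct = corr,
                    set_size = rep(4L, 12), target = rep("p", 12))
  s <- summarize_condition(tr)
  # the 12 s trial is removed by the cutoff, the rt = 3 trial is incorrect
  expect_equal(s$retained_rts, c(1, 2, 4, 5, 6, 7, 8, 9))
  expect_equal(length(s$retained_rts),
               min(8, sum(corr == 1 & rt <= 10)))
})

test_that("per-condition exclusion fires exactly at accuracy <= 50%", {
  for (k in c(5, 6, 7)) {
    tr <- make_trials(12, correct = rep(c(1L, 0L), c(k, 12 - k)),
                      set_size = rep(4L, 12), target = rep("p", 12))
    s <- summarize_condition(tr)
    expect_equal(s$excluded, k / 12 <= 0.5)
  }
})

test_that("visual angles match the study's stimulus geometry", {
  expect_equal(round(visual_angle(0.8, 40), 2), 1.15)
  expect_equal(round(visual_angle(0.7, 40), 2), 1.00)
  expect_equal(round(visual_angle(1.0, 40), 2), 1.43)
  expect_equal(visual_angle(0, 40), 0)
  expect_error(visual_angle(1, 0), "distance")
  expect_error(visual_angle(-1, 10), "extent")

  # strictly increasing in extent, decreasing in distance
  ext <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(visual_angle(ext, 40)) > 0))
  dst <- seq(20, 100, by = 5)
  expect_true(all(diff(visual_angle(1, dst)) < 0))

  # small-angle approximation within 0.5% below 2 degrees
  e <- c(0.2, 0.5, 1.0, 1.3)
  exact <- visual_angle(e, 40)
  approx <- e / 40 * 180 / pi
  expect_true(all(abs(exact - approx) / exact < 0.005))
})

test_that("full preprocessing builds consistent analysis tables", {
  sim <- simulate_experiment(sim_config(seed = 8, n_impaired = 10,
                                        n_control = 8))
  pre <- preprocess_trials(sim$trials)
  expect_s3_class(pre, "vs_preprocessed")
  expect_equal(nrow(pre$conditions), 18 * 6)
  expect_true(all(pre$conditions$n_retained <= 8))
  expect_true(all(pre$conditions$accuracy > 0 & pre$conditions$accuracy <= 1))
  expect_true(all(pre$conditions$excluded ==
                    (pre$conditions$accuracy <= 0.5)))
  kept <- pre$conditions[!pre$conditions$excluded, ]
  expect_equal(nrow(pre$rt_long), sum(kept$n_retained))
  expect_true(all(pre$rt_long$rt_s <= 10))
})

test_that("trial table CSV round-trips through read_trials", {
  sim <- simulate_experiment(sim_config(seed = 9, n_impaired = 4,
                                        n_control = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(sim$trials))
  expect_equal(levels(back$group), c("c", "i"))
  expect_equal(levels(back$set_size), c("4", "16", "24"))
  expect_true(file.exists(paste0(path, ".truth.json")))
})
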