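#' Configuration for the synthetic visual-search experiment generator
#'
#' Builds the configuration for [simulate_experiment()]. Defaults emulate a
#' two-cohort school-age feature-search study: 39 vision-impaired
#' participants (82% with nystagmus, binocular acuity ~0.63 LogMAR) and 33
#' controls, 80 presentations each (8 practice + 72 test) over the six
#' set-size x target conditions, Ex-Gaussian reaction times whose medians
#' are calibrated cell-by-cell to the node medians of the reference
#' analysis (seconds), and per-trial accuracy driven by set size, target
#' and age band.
#'
#' `effect_scale` interpolates all RT cell medians toward their geometric
#' grand mean on the log scale (1 = full published effects, 0 = a null
#' experiment with no covariate effects); `accuracy_effect_scale` does the
#' same for correctness probabilities on the logit scale. `acuity_slope`
#' optionally adds a linear acuity term (seconds per LogMAR) to the
#' Ex-Gaussian location.
#'
#' @param n_impaired,n_control cohort sizes.
#' @param nystagmus_prev prevalence of nystagmus among impaired.
#' @param male_prop_impaired,male_prop_control male proportions.
#' @param age_mean_impaired,age_mean_control,age_sd_impaired,age_sd_control
#'   age distributions in years (Normal, truncated to `age_range`). The SD
#'   defaults reconstruct the cohort SD from the reported standard errors
#'   (SD = SEM * sqrt(n)).
#' @param age_range inclusion range in years.
#' @param acuity_mean,acuity_sd impaired-group binocular acuity (LogMAR),
#'   truncated to `acuity_range`; controls are drawn near 0.
#' @param acuity_range impaired acuity truncation bounds (LogMAR).
#' @param rt_medians named RT median map (seconds); see
#'   [rt_median_map_default()].
#' @param sigma_frac,nu_frac Ex-Gaussian sigma and nu as fractions of each
#'   cell's median; the location is then solved numerically so the implied
#'   median matches the map.
#' @param effect_scale,accuracy_effect_scale effect attenuation in `[0,1]`.
#' @param acuity_slope seconds of RT location per LogMAR, within group.
#' @param participant_sd SD of an optional participant-level random
#'   intercept on RT location (seconds); 0 (default) matches the reference
#'   models, which carry none.
#' @param n_practice,n_test presentations per participant.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_impaired = 39L, n_control = 33L,
                       nystagmus_prev = 0.82,
                       male_prop_impaired = 0.56, male_prop_control = 0.61,
                       age_mean_impaired = 11.6, age_mean_control = 13.0,
                       age_sd_impaired = 0.5 * sqrt(39),
                       age_sd_control = 0.5 * sqrt(33),
                       age_range = c(5, 18),
                       acuity_mean = 0.63, acuity_sd = 0.05 * sqrt(39),
                       acuity_range = c(0.2, 1.5),
                       rt_medians = rt_median_map_default(),
                       sigma_frac = 0.12, nu_frac = 0.35,
                       effect_scale = 1, accuracy_effect_scale = 1,
                       acuity_slope = 0, participant_sd = 0,
                       n_practice = 8L, n_test = 72L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nystagmus_prev >= 0, nystagmus_prev <= 1,
            male_prop_impaired >= 0, male_prop_impaired <= 1,
            effect_scale >= 0, effect_scale <= 1,
            accuracy_effect_scale >= 0, accuracy_effect_scale <= 1,
            sigma_frac > 0, nu_frac > 0, n_practice >= 0, n_test >= 6)
  structure(cfg, class = "sim_config")
}

#' Default reaction-time median map
#'
#' Cell medians (seconds) over group x set-size band x target x gender used
#' to calibrate the Ex-Gaussian generator, taken from the node medians of
#' the reference tree: at set size 4, controls 0.91 s (target present) and
#' 1.08 s (absent), impaired 1.59 s; at set sizes 16/24 target-absent,
#' controls 2.43 s, impaired females 4.37 s and males 3.10 s; at 16/24
#' target-present, impaired 2.15 s, control males 1.51 s and females
#' 1.38 s. Within the 16/24 band, set size 16 is scaled by 0.95 and 24 by
#' 1.05 so search time still grows with display size while the pooled band
#' median stays on target.
#'
#' @return a `data.frame` with columns `group, set_size, target, gender,
#'   median_s` covering all 24 cells.
#' @export
rt_median_map_default <- function() {
  band <- function(group, target, gender, m) {
    data.frame(group = group,
               set_size = rep(c(16L, 24L), each = 1L),
               target = target, gender = gender,
               median_s = m * c(0.95, 1.05))
  }
  s4 <- expand.grid(group = c("c", "i"), set_size = 4L,
                    target = c("ab", "p"), gender = c("f", "m"),
                    stringsAsFactors = FALSE)
  s4$median_s <- ifelse(s4$group == "i", 1.59,
                        ifelse(s4$target == "p", 0.91, 1.08))
  big <- rbind(
    band("c", "ab", "f", 2.43), band("c", "ab", "m", 2.43),
    band("i", "ab", "f", 4.37), band("i", "ab", "m", 3.10),
    band("i", "p", "f", 2.15), band("i", "p", "m", 2.15),
    band("c", "p", "f", 1.38), band("c", "p", "m", 1.51))
  out <- rbind(s4[, c("group", "set_size", "target", "gender", "median_s")],
               big)
  rownames(out) <- NULL
  out
}

#' Default per-trial correctness probability map
#'
#' Correctness probabilities chosen so expected condition accuracies
#' reproduce the reference pattern: ~0.97 at set size 4; at set sizes
#' 16/24, target-present accuracy 0.88 for participants under 14 years and
#' 0.98 at 14 or older, with target-absent slightly higher (0.93 / 0.99).
#'
#' @param set_size 4, 16 or 24 (vectorized).
#' @param target `"ab"` or `"p"` (vectorized).
#' @param age age in years (vectorized).
#' @return correctness probabilities in `[0.5, 1]`.
#' @examples
#' accuracy_map_default(24, "p", 10)  # 0.88
#' accuracy_map_default(24, "p", 16)  # 0.98
#' @export
accuracy_map_default <- function(set_size, target, age) {
  young <- age < 14
  p <- ifelse(set_size == 4, 0.97,
              ifelse(target == "p",
                     ifelse(young, 0.88, 0.98),
                     ifelse(young, 0.93, 0.99)))
  pmin(pmax(p, 0.5), 1)
}

#' Sample a 72-trial condition schedule
#'
#' Draws the test-trial schedule of one participant: a uniformly random
#' composition of the six set-size x target conditions over 72 trials,
#' resampled until every condition appears between 8 and 15 times
#' (12 on average), then uniformly shuffled.
#'
#' @param seed optional integer; when given, the schedule is drawn in an
#'   isolated RNG stream seeded with it (the caller's RNG state is left
#'   untouched).
#' @param n_test number of test trials (default 72).
#' @return a `data.frame` with 72 rows, columns `set_size`, `target`.
#' @export
sample_schedule <- function(seed = NULL, n_test = 72L) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  conds <- expand.grid(set_size = c(4L, 16L, 24L), target = c("ab", "p"),
                       stringsAsFactors = FALSE)
  lo <- max(1L, floor(n_test / 6) - 4L)
  hi <- floor(n_test / 6) + 3L
  for (it in seq_len(1e5)) {
    counts <- as.vector(stats::rmultinom(1, n_test, rep(1 / 6, 6)))
    if (all(counts >= lo & counts <= hi)) {
      idx <- sample(rep(seq_len(6), counts))
      return(conds[idx, , drop = FALSE])
    }
  }
  stop("sample_schedule: no admissible schedule found (iteration cap hit)")
}

rtnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# solve the Ex-Gaussian location so the implied median equals m, given
# sigma and nu; the family is a location family so the offset is exact
exgauss_mu_for_median <- function(m, sigma, nu)
  m - qexgauss(0.5, 0, sigma, nu)

# attenuate the median map toward its grand geometric mean (log scale)
scale_medians <- function(map, effect_scale) {
  if (effect_scale == 1) return(map)
  gm <- exp(mean(base::log(map$median_s)))
  map$median_s <- exp(base::log(gm) +
                        effect_scale * (base::log(map$median_s) - base::log(gm)))
  map
}

#' Simulate a complete visual-search experiment
#'
#' Draws participants (group, gender, nystagmus, age, acuity), per-
#' participant trial schedules, per-trial correctness (Bernoulli from the
#' accuracy map) and reaction times (Ex-Gaussian from the calibrated cell
#' parameter map; draws above 10 s occur naturally so the cutoff rule is
#' exercised), and returns a trial table in the exact schema of
#' [read_trials()] together with the ground-truth parameter maps.
#'
#' @param config a [sim_config()].
#' @return a list of class `vs_simulation` with elements `trials` (the
#'   trial `data.frame`) and `truth` (cell parameter map, accuracy map
#'   function, participant table, config).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_impaired + config$n_control
  grp <- c(rep("i", config$n_impaired), rep("c", config$n_control))
  male_p <- ifelse(grp == "i", config$male_prop_impaired,
                   config$male_prop_control)
  gender <- ifelse(stats::runif(n) < male_p, "m", "f")
  nyst <- ifelse(grp == "i",
                 as.integer(stats::runif(n) < config$nystagmus_prev), 0L)
  age <- ifelse(grp == "i",
                rtnorm(n, config$age_mean_impaired, config$age_sd_impaired,
                       config$age_range[1], config$age_range[2]),
                rtnorm(n, config$age_mean_control, config$age_sd_control,
                       config$age_range[1], config$age_range[2]))
  acuity <- ifelse(grp == "i",
                   rtnorm(n, config$acuity_mean, config$acuity_sd,
                          config$acuity_range[1], config$acuity_range[2]),
                   rtnorm(n, 0, 0.05, -0.1, 0.1))
  pid <- sprintf("P%03d", seq_len(n))
  participants <- data.frame(participant_id = pid, group = grp,
                             gender = gender, nystagmus = nyst,
                             age = round(age, 2),
                             acuity_logmar = round(acuity, 3),
                             stringsAsFactors = FALSE)

  map <- scale_medians(config$rt_medians, config$effect_scale)
  map$sigma <- config$sigma_frac * map$median_s
  map$nu <- config$nu_frac * map$median_s
  map$mu <- mapply(exgauss_mu_for_median, map$median_s, map$sigma, map$nu)
  key <- function(g, s, t, gen) paste(g, s, t, gen, sep = "|")
  rownames(map) <- key(map$group, map$set_size, map$target, map$gender)

  acc_base <- mean(accuracy_map_default(
    rep(c(4, 16, 24), 4), rep(rep(c("ab", "p"), each = 3), 2),
    rep(c(10, 16), each = 6)))
  acc_fun <- function(set_size, target, age) {
    p <- accuracy_map_default(set_size, target, age)
    if (config$accuracy_effect_scale == 1) return(p)
    stats::plogis(stats::qlogis(acc_base) + config$accuracy_effect_scale *
                    (stats::qlogis(p) - stats::qlogis(acc_base)))
  }

  rand_int <- if (config$participant_sd > 0)
    stats::rnorm(n, 0, config$participant_sd) else numeric(n)

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- sample_schedule(n_test = config$n_test)
    prac_idx <- sample(seq_len(nrow(sched)), config$n_practice,
                       replace = TRUE)
    prac <- sched[prac_idx, , drop = FALSE]
    all_tr <- rbind(prac, sched)
    ntr <- nrow(all_tr)
    k <- key(grp[i], all_tr$set_size, all_tr$target, gender[i])
    mu <- map[k, "mu"] + rand_int[i] +
      config$acuity_slope * acuity[i]
    rt <- stats::rnorm(ntr, mu, map[k, "sigma"]) +
      stats::rexp(ntr, rate = 1 / map[k, "nu"])
    rt <- pmax(rt, 0.15)  # motor floor; no non-positive RTs
    pcorr <- acc_fun(all_tr$set_size, all_tr$target, age[i])
    correct <- as.integer(stats::runif(ntr) < pcorr)
    trials[[i]] <- data.frame(
      participant_id = pid[i], group = grp[i], gender = gender[i],
      age = participants$age[i], nystagmus = nyst[i],
      acuity_logmar = participants$acuity_logmar[i],
      set_size = all_tr$set_size, target = all_tr$target,
      rt_s = round(rt, 4), correct = correct, order = seq_len(ntr),
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 truth = list(rt_map = map, accuracy_map = acc_fun,
                              participants = participants,
                              config = config)),
            class = "vs_simulation")
}

#' @export
print.vs_simulation <- function(x, ...) {
  p <- x$truth$participants
  cat(sprintf(paste0("Synthetic visual search experiment: %d participants",
                     " (%d impaired, %d control), %d trials\n"),
              nrow(p), sum(p$group == "i"), sum(p$group == "c"),
              nrow(x$trials)))
  invisible(x)
}

#' Write a simulated experiment to CSV
#'
#' @param sim a `vs_simulation`.
#' @param path output CSV path; ground truth is written alongside as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "vs_simulation"))
  utils::write.csv(sim$trials, path, row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(rt_map = truth$rt_map, participants = truth$participants,
         config = truth$config[setdiff(names(truth$config), "rt_medians")]),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(path)
}
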