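#' Run the full four-step analysis pipeline
#'
#' Orchestrates the complete analysis on a trial table (real or
#' simulated): preprocessing (practice drop, RT cutoff, first-eight-correct
#' retention, 50% exclusion), Step 1 variable screening (Boruta + One
#' Rule), Step 2 regression multiverse (quantile, robust, distributional),
#' Step 3 reduced model testing — via the rank-based ANOVA-type statistic
#' when every retained covariate is categorical, else via median quantile
#' regression — and Step 4 distributional regression trees (Ex-Gaussian
#' for reaction times at the retained-trial level; GB1 for squeezed
#' accuracies at the condition level), plus Kendall tau-b and percentage
#' bend correlations between binocular acuity and participant median RT.
#'
#' Steps 1-3 operate on the condition-level table (one row per participant
#' x set-size x target: median retained RT, accuracy); the RT tree uses
#' every retained reaction time.
#'
#' @param trials a trial `data.frame` in the [read_trials()] schema, or a
#'   [sim_config()] (an experiment is then simulated from it).
#' @param seed integer seed governing every stochastic stage.
#' @param max_depth tree depth cap for Step 4. Default 3.
#' @param boruta_iter,num_trees Boruta settings (see [boruta()]).
#' @param reduce_rule reduction rule, see [reduce_model()].
#' @param out_dir optional directory; when given, all stage outputs are
#'   serialized there (CSV/JSON/DOT) and a report hash over the serialized
#'   artifacts is computed.
#' @return an object of class `vs_pipeline`: list with `preprocessed`,
#'   `screening` (per response: boruta + one_rule), `multiverse` (per
#'   response), `reduced` (per response), `step3` (per response: `ats` or
#'   quantile table with a `method` tag), `trees` (rt, accuracy),
#'   `correlations`, `seed`, and `report_hash` when `out_dir` is used.
#' @export
run_pipeline <- function(trials, seed = 1L, max_depth = 3L,
                         boruta_iter = 50L, num_trees = 500L,
                         reduce_rule = "screen_and_regression",
                         out_dir = NULL) {
  if (inherits(trials, "sim_config"))
    trials <- simulate_experiment(trials)$trials
  set.seed(seed)
  pre <- preprocess_trials(trials)
  cond <- pre$conditions
  cond <- cond[!cond$excluded & !is.na(cond$median_rt), ]
  cond$acc_sq <- squeeze_unit(cond$accuracy)
  Xc <- cond[, c("group", "set_size", "target", "gender", "nystagmus",
                 "age")]
  Xc$nystagmus <- factor(Xc$nystagmus)
  responses <- c(rt = "median_rt", accuracy = "acc_sq")
  families <- c(rt = "exgaussian", accuracy = "gb1")

  # Step 2 data: reaction times at the retained-trial level (every
  # retained RT is an observation); accuracy at the condition level (its
  # natural unit). Step 1 screening always runs on the condition table.
  mv_data <- list(rt = pre$rt_long, accuracy = cond)
  mv_resp <- c(rt = "rt_s", accuracy = "acc_sq")
  screening <- list(); mv <- list(); reduced <- list(); step3 <- list()
  for (nm in names(responses)) {
    y <- cond[[responses[nm]]]
    screening[[nm]] <- list(
      boruta = boruta(Xc, y, max_iter = boruta_iter,
                      num_trees = num_trees, seed = seed),
      one_rule = one_rule(Xc, y))
    mv[[nm]] <- run_multiverse(mv_data[[nm]], mv_resp[nm],
                               family = families[nm], seed = seed)
    reduced[[nm]] <- reduce_model(mv[[nm]], screening[[nm]]$boruta,
                                  rule = reduce_rule)
    step3[[nm]] <- fit_step3(cond, responses[nm], reduced[[nm]],
                             seed = seed)
  }

  col_of <- c(G = "group", S = "set_size", T = "target", n = "nystagmus",
              a = "age", g = "gender")
  tree_covars <- function(d, retained) {
    cols <- unname(col_of[retained])
    if (!length(cols)) cols <- "set_size"  # degenerate: still a valid frame
    cv <- d[, cols, drop = FALSE]
    if ("nystagmus" %in% names(cv)) cv$nystagmus <- factor(cv$nystagmus)
    cv
  }
  trees <- list(
    rt = disttree(pre$rt_long$rt_s,
                  tree_covars(pre$rt_long, reduced$rt$retained),
                  family = "exgaussian",
                  control = disttree_control(max_depth = max_depth,
                                             seed = seed)),
    accuracy = disttree(cond$acc_sq,
                        tree_covars(cond, reduced$accuracy$retained),
                        family = "gb1",
                        control = disttree_control(max_depth = max_depth,
                                                   seed = seed)))

  per_part <- stats::aggregate(median_rt ~ participant_id + acuity_logmar,
                               data = cond, FUN = stats::median)
  correlations <- list(
    kendall_tau = kendall_tau(per_part$acuity_logmar, per_part$median_rt),
    percentage_bend = percentage_bend_cor(per_part$acuity_logmar,
                                          per_part$median_rt))

  out <- structure(list(preprocessed = pre, screening = screening,
                        multiverse = mv, reduced = reduced, step3 = step3,
                        trees = trees, correlations = correlations,
                        seed = seed),
                   class = "vs_pipeline")
  if (!is.null(out_dir)) out$report_hash <- write_report(out, out_dir)
  out
}

# Step 3 dispatch: ATS iff every retained covariate is categorical,
# else a median quantile model on the reduced design
fit_step3 <- function(cond, response, reduced, seed = 1L) {
  col_of <- c(G = "group", S = "set_size", T = "target", n = "nystagmus",
              a = "age", g = "gender")
  vars <- unname(col_of[reduced$retained])
  if (!length(vars))
    return(list(method = "none", result = NULL))
  if (reduced$all_categorical) {
    res <- ats(cond, vars, response)
    list(method = "ats", result = res)
  } else {
    d <- cond
    d[vars] <- lapply(d[vars], function(v)
      if (is.numeric(v)) v else factor(v))
    fml <- stats::as.formula(paste("~", paste(vars, collapse = " * ")))
    X <- stats::model.matrix(fml, d)
    tab <- fit_quantile(list(y = d[[response]], X = X), seed = seed)
    list(method = "quantile", result = tab)
  }
}

#' @export
print.vs_pipeline <- function(x, ...) {
  cat("Visual search multiverse pipeline (seed ", x$seed, ")\n\n", sep = "")
  print(x$preprocessed)
  for (nm in names(x$reduced)) {
    cat("\n== ", nm, " ==\n", sep = "")
    print(x$reduced[[nm]])
    cat("Step 3 method: ", x$step3[[nm]]$method, "\n", sep = "")
  }
  cat("\nRT tree:\n"); print(x$trees$rt)
  cat("\nAccuracy tree:\n"); print(x$trees$accuracy)
  cat(sprintf("\nAcuity-RT correlation: Kendall tau-b = %.3f, percentage bend = %.3f\n",
              x$correlations$kendall_tau, x$correlations$percentage_bend))
  invisible(x)
}

write_report <- function(pipe, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pipe$preprocessed$conditions,
                   file.path(out_dir, "conditions.csv"), row.names = FALSE)
  for (nm in names(pipe$multiverse)) {
    mvr <- pipe$multiverse[[nm]]
    jsonlite::write_json(
      list(universes = mvr$universes, design_hash = mvr$design_hash,
           tables = mvr$tables, agreement = mvr$agreement),
      file.path(out_dir, paste0("multiverse_", nm, ".json")),
      auto_unbox = TRUE, digits = 10, force = TRUE)
    jsonlite::write_json(
      list(decision = as.list(stats::setNames(
             as.character(pipe$screening[[nm]]$boruta$decision),
             names(pipe$screening[[nm]]$boruta$hits))),
           one_rule = as.list(pipe$screening[[nm]]$one_rule),
           retained = pipe$reduced[[nm]]$retained),
      file.path(out_dir, paste0("screening_", nm, ".json")),
      auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  tree_to_json(pipe$trees$rt, file.path(out_dir, "tree_rt.json"))
  tree_to_dot(pipe$trees$rt, file.path(out_dir, "tree_rt.dot"))
  tree_to_json(pipe$trees$accuracy, file.path(out_dir, "tree_accuracy.json"))
  tree_to_dot(pipe$trees$accuracy, file.path(out_dir, "tree_accuracy.dot"))
  jsonlite::write_json(pipe$correlations,
                       file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = 10)
  files <- sort(list.files(out_dir, full.names = TRUE))
  unname(tools::md5sum(files))
}
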