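#' Boruta all-relevant variable screening
#'
#' Shadow-feature importance screening: at each iteration every covariate
#' is copied and within-column permuted ("shadow" features), a random
#' forest is fit on the augmented table with permutation importance, and a
#' covariate scores a *hit* when its importance exceeds the maximum shadow
#' importance. Two-sided binomial tests on the accumulated hit counts
#' (level 0.01, Bonferroni-corrected across candidate covariates) drive
#' the confirmed / rejected decisions; covariates still undecided after
#' `max_iter` iterations remain tentative.
#'
#' @param X `data.frame` of candidate covariates (no missing values).
#' @param y numeric response (reaction time or squeezed accuracy) or a
#'   factor for classification.
#' @param max_iter maximum number of iterations, at least 10. Default 50.
#' @param num_trees trees per forest. Default 500.
#' @param p_level decision level for the binomial tests. Default 0.01.
#' @param seed integer seed; the procedure is seed-deterministic.
#' @return an object of class `importance_result`: list with `decision`
#'   (named factor: confirmed / tentative / rejected), `hits`, `n_iter`,
#'   `history` (iterations x covariates importance matrix) and
#'   `shadow_max` (per-iteration max shadow importance).
#' @export
boruta <- function(X, y, max_iter = 50L, num_trees = 500L, p_level = 0.01,
                   seed = 1L) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  if (max_iter < 10) stop("boruta: max_iter must be at least 10")
  if (anyNA(X) || anyNA(y)) stop("boruta: missing values are not allowed")
  set.seed(seed)
  vars <- names(X)
  k <- length(vars)
  decision <- stats::setNames(rep("tentative", k), vars)
  hits <- stats::setNames(rep(0L, k), vars)
  tested <- 0L
  history <- matrix(NA_real_, max_iter, k, dimnames = list(NULL, vars))
  shadow_max <- numeric(max_iter)
  df <- as.data.frame(X)
  for (it in seq_len(max_iter)) {
    sh <- as.data.frame(lapply(df, sample))
    names(sh) <- paste0("shadow_", vars)
    dat <- cbind(df, sh, .y = y)
    rf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                         num.trees = num_trees, importance = "permutation",
                         num.threads = 1L,
                         seed = seed * 1000L + it)
    imp <- rf$variable.importance
    smax <- max(imp[startsWith(names(imp), "shadow_")])
    shadow_max[it] <- smax
    history[it, ] <- imp[vars]
    hits <- hits + as.integer(imp[vars] > smax)
    tested <- tested + 1L
    # two-sided binomial decisions, Bonferroni over the k candidates
    p_hi <- stats::pbinom(hits - 1L, tested, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits, tested, 0.5)
    newly_conf <- decision == "tentative" & p_hi * k < p_level
    newly_rej <- decision == "tentative" & p_lo * k < p_level
    decision[newly_conf] <- "confirmed"
    decision[newly_rej] <- "rejected"
    if (!any(decision == "tentative")) break
  }
  structure(list(decision = factor(decision,
                                   levels = c("confirmed", "tentative",
                                              "rejected")),
                 hits = hits, n_iter = tested,
                 history = history[seq_len(tested), , drop = FALSE],
                 shadow_max = shadow_max[seq_len(tested)]),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Boruta screening (", x$n_iter, " iterations):\n", sep = "")
  for (lv in levels(x$decision)) {
    v <- names(x$decision)[x$decision == lv]
    if (length(v)) cat("  ", lv, ": ", paste(v, collapse = ", "), "\n",
                       sep = "")
  }
  invisible(x)
}

#' One Rule per-variable accuracy
#'
#' The One Rule baseline: for each covariate, build the single rule that
#' maps each of its (discretized) levels to the majority class of the
#' binned response, and report the rule's training accuracy. The accuracy
#' ranking is the screening output. Numeric inputs are discretized by
#' quartiles.
#'
#' @param X `data.frame` of covariates.
#' @param y response; numeric responses are binned into quartile classes,
#'   factors are used as-is.
#' @return named numeric vector of per-variable training accuracies (each
#'   at least the majority-class baseline, which is returned as the
#'   `"baseline"` attribute).
#' @export
one_rule <- function(X, y) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  bin <- function(v) {
    if (is.numeric(v) && length(unique(v)) > 4) {
      q <- unique(stats::quantile(v, c(0.25, 0.5, 0.75)))
      cut(v, c(-Inf, q, Inf))
    } else factor(v)
  }
  yb <- bin(y)
  baseline <- max(table(yb)) / length(yb)
  out <- vapply(X, function(v) {
    vb <- bin(v)
    tab <- table(vb, yb)
    sum(apply(tab, 1, max)) / length(yb)
  }, numeric(1))
  attr(out, "baseline") <- baseline
  out
}
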