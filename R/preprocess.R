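#' Read a trial-level visual search table
#'
#' Reads a CSV with one row per stimulus presentation. Required columns
#' (exactly): `participant_id, group, gender, age, nystagmus, acuity_logmar,
#' set_size, target, rt_s, correct, order`, with `group` in `{c, i}`,
#' `gender` in `{m, f}`, `target` in `{ab, p}`, `set_size` in
#' `{4, 16, 24}`, booleans coded 0/1, reaction times in seconds.
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` of trials with `practice` flag added
#'   (`TRUE` iff `order <= 8`), factors coded with fixed reference levels
#'   (group `c`, set size `4`, target `ab`, gender `f`).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
}

#' @rdname read_trials
#' @param trials a raw trial `data.frame` with the schema above.
#' @export
validate_trials <- function(trials) {
  req <- c("participant_id", "group", "gender", "age", "nystagmus",
           "acuity_logmar", "set_size", "target", "rt_s", "correct", "order")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!trials$group %in% c("c", "i")))
    stop("group must be 'c' (control) or 'i' (impaired)")
  if (any(!trials$target %in% c("ab", "p")))
    stop("target must be 'ab' (absent) or 'p' (present)")
  if (any(!trials$gender %in% c("m", "f")))
    stop("gender must be 'm' or 'f'")
  if (any(!trials$set_size %in% c(4L, 16L, 24L)))
    stop("set_size must be 4, 16 or 24")
  if (any(!is.finite(trials$rt_s)) || any(trials$rt_s <= 0))
    stop("rt_s must be positive and finite")
  if (any(is.na(trials$order)))
    stop("order is required for every trial")
  dup <- tapply(trials$order, trials$participant_id,
                function(o) anyDuplicated(o) > 0)
  if (any(dup))
    stop("order must be unique within participant: ",
         paste(names(dup)[dup], collapse = ", "))
  trials$group <- factor(trials$group, levels = c("c", "i"))
  trials$gender <- factor(trials$gender, levels = c("f", "m"))
  trials$target <- factor(trials$target, levels = c("ab", "p"))
  trials$set_size <- factor(trials$set_size, levels = c(4L, 16L, 24L),
                            ordered = TRUE)
  trials$nystagmus <- as.integer(trials$nystagmus)
  trials$correct <- as.integer(trials$correct)
  trials$practice <- trials$order <= 8L
  trials
}

#' Drop practice trials
#'
#' Removes the practice presentations (the first eight of each
#' participant's session, `order <= 8`), preserving input order.
#'
#' @param trials a trial `data.frame` (see [read_trials()]); must carry an
#'   `order` column.
#' @return the test trials only.
#' @export
drop_practice <- function(trials) {
  if (is.null(trials$order) || any(is.na(trials$order)))
    stop("drop_practice: order is required for every trial")
  practice <- if (!is.null(trials$practice)) as.logical(trials$practice)
              else trials$order <= 8L
  trials[!practice, , drop = FALSE]
}

#' Apply the reaction-time cutoff
#'
#' Excludes trials whose reaction time is strictly greater than the cutoff
#' (default 10 s); a trial at exactly the cutoff is retained.
#'
#' @param trials a trial `data.frame` with an `rt_s` column, seconds.
#' @param cutoff positive cutoff in seconds. Default 10.
#' @return trials with `rt_s <= cutoff`, input order preserved.
#' @export
apply_rt_cutoff <- function(trials, cutoff = 10) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  if (any(!is.finite(trials$rt_s)) || any(trials$rt_s <= 0))
    stop("apply_rt_cutoff: rt_s must be positive and finite")
  trials[trials$rt_s <= cutoff, , drop = FALSE]
}

#' Summarize one participant x set-size x target condition
#'
#' Computes the retained reaction times (the first eight correct,
#' cutoff-surviving RTs in presentation order) and the accuracy of a
#' condition, and flags it for exclusion when accuracy is at or below
#' chance (50%).
#'
#' Two accuracy rules are available. The default, `"prop_correct"`, is the
#' proportion of correct responses among all test presentations of the
#' condition (10 correct of 12 presentations gives 83%). The alternative
#' `"eight_over_trials"` divides 8 by the number of presentations needed to
#' reach the eighth correct response (NA when eight correct are never
#' reached).
#'
#' @param trials test trials of a single participant and condition (already
#'   practice-dropped), in presentation order. RT-cutoff filtering affects
#'   which RTs are retained but not the accuracy denominator.
#' @param cutoff RT cutoff in seconds for retention. Default 10.
#' @param accuracy_rule `"prop_correct"` (default) or `"eight_over_trials"`.
#' @return a list of class `condition_summary`: `participant_id`,
#'   `set_size`, `target`, `retained_rts` (<= 8 values), `n_presented`,
#'   `n_correct`, `accuracy`, `excluded`, `reason`, `empty`.
#' @export
summarize_condition <- function(trials, cutoff = 10,
                                accuracy_rule = c("prop_correct",
                                                  "eight_over_trials")) {
  accuracy_rule <- match.arg(accuracy_rule)
  if (nrow(trials) == 0) {
    return(structure(list(participant_id = NA, set_size = NA, target = NA,
                          retained_rts = numeric(0), n_presented = 0L,
                          n_correct = 0L, accuracy = NA_real_,
                          excluded = TRUE, reason = "no_presentations",
                          empty = TRUE),
                     class = "condition_summary"))
  }
  trials <- trials[base::order(trials$order), , drop = FALSE]
  n_pres <- nrow(trials)
  n_corr <- sum(trials$correct == 1L)
  ok <- trials$correct == 1L & trials$rt_s <= cutoff
  retained <- utils::head(trials$rt_s[ok], 8L)
  accuracy <- switch(accuracy_rule,
    prop_correct = n_corr / n_pres,
    eight_over_trials = {
      idx <- which(cumsum(trials$correct == 1L) == 8L)[1]
      if (is.na(idx)) NA_real_ else 8 / idx
    })
  excluded <- !is.na(accuracy) && accuracy <= 0.5
  structure(list(participant_id = trials$participant_id[1],
                 set_size = trials$set_size[1], target = trials$target[1],
                 retained_rts = retained, n_presented = n_pres,
                 n_correct = n_corr, accuracy = accuracy,
                 excluded = excluded,
                 reason = if (excluded) "accuracy_le_50pct" else NA_character_,
                 empty = FALSE),
            class = "condition_summary")
}

#' Preprocess a full trial table
#'
#' Applies the complete inclusion pipeline — drop practice trials, then
#' summarize every participant x set-size x target condition (retaining the
#' first eight correct RTs at or under the cutoff and computing accuracy) —
#' and returns analysis tables for the downstream steps.
#'
#' @param trials a validated trial `data.frame` ([read_trials()] /
#'   [validate_trials()]).
#' @inheritParams summarize_condition
#' @return a list of class `vs_preprocessed`:
#' \describe{
#'   \item{`conditions`}{one row per participant x condition:
#'     covariates, `n_presented`, `n_correct`, `accuracy`, `median_rt`
#'     (of retained RTs), `n_retained`, `excluded`.}
#'   \item{`rt_long`}{one row per retained RT (excluded conditions
#'     dropped), with all covariates — the reaction-time analysis table.}
#'   \item{`n_excluded`}{number of condition observations excluded by the
#'     50% rule.}
#' }
#' @export
preprocess_trials <- function(trials, cutoff = 10,
                              accuracy_rule = "prop_correct") {
  trials <- validate_trials(trials)
  test <- drop_practice(trials)
  key <- interaction(test$participant_id, test$set_size, test$target,
                     drop = TRUE)
  sums <- lapply(split(test, key), summarize_condition, cutoff = cutoff,
                 accuracy_rule = accuracy_rule)
  meta <- unique(trials[, c("participant_id", "group", "gender", "age",
                            "nystagmus", "acuity_logmar")])
  rownames(meta) <- as.character(meta$participant_id)
  cond <- do.call(rbind, lapply(sums, function(s) {
    data.frame(participant_id = s$participant_id,
               set_size = s$set_size, target = s$target,
               n_presented = s$n_presented, n_correct = s$n_correct,
               accuracy = s$accuracy,
               median_rt = if (length(s$retained_rts)) stats::median(s$retained_rts) else NA_real_,
               n_retained = length(s$retained_rts),
               excluded = s$excluded, stringsAsFactors = FALSE)
  }))
  cond <- cbind(cond,
                meta[as.character(cond$participant_id),
                     c("group", "gender", "age", "nystagmus", "acuity_logmar")])
  rownames(cond) <- NULL
  cond <- cond[base::order(cond$participant_id, cond$set_size, cond$target), ]
  keep <- !cond$excluded & cond$n_retained > 0
  rt_long <- do.call(rbind, lapply(sums, function(s) {
    if (s$excluded || length(s$retained_rts) == 0) return(NULL)
    data.frame(participant_id = s$participant_id, set_size = s$set_size,
               target = s$target, rt_s = s$retained_rts,
               stringsAsFactors = FALSE)
  }))
  rt_long <- cbind(rt_long,
                   meta[as.character(rt_long$participant_id),
                        c("group", "gender", "age", "nystagmus",
                          "acuity_logmar")])
  rownames(rt_long) <- NULL
  structure(list(conditions = cond, rt_long = rt_long,
                 n_excluded = sum(cond$excluded)),
            class = "vs_preprocessed")
}

#' @export
print.vs_preprocessed <- function(x, ...) {
  cat(sprintf(paste0("Preprocessed visual search data: %d condition",
                     " observations (%d excluded at <=50%% accuracy), %d",
                     " retained RTs\n"),
              nrow(x$conditions), x$n_excluded, nrow(x$rt_long)))
  invisible(x)
}

#' Visual angle subtended by a stimulus
#'
#' Full visual angle of an object of extent `extent_cm` viewed at
#' `distance_cm`, `2 atan(extent / (2 distance))`, in degrees. At the study
#' geometry (40 cm viewing distance) a 0.8 cm circle subtends 1.15 degrees
#' and the 0.7 x 1.0 cm ellipse 1.00 x 1.43 degrees.
#'
#' @param extent_cm object extent in cm, >= 0 (vectorized).
#' @param distance_cm viewing distance in cm, > 0.
#' @return visual angle in degrees.
#' @examples
#' visual_angle(0.8, 40)
#' @export
visual_angle <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("visual_angle: distance must be positive")
  if (any(extent_cm < 0)) stop("visual_angle: extent must be non-negative")
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}
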