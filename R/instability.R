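# Score-based parameter instability tests (M-fluctuation tests).
#
# At a fitted node the per-observation score contributions have mean ~0;
# systematic drift of their cumulative sum along a covariate signals that
# the fitted parameters are unstable in that covariate. Categorical
# covariates use a Pearson-type chi-square functional over level-wise score
# sums; numeric covariates use the supLM functional over ordered cutpoints
# within a trimmed range, referred to the supremum of a squared, tied-down
# Bessel process (null distribution simulated once and cached).

.vsm_cache <- new.env(parent = emptyenv())

# decorrelate score columns: S %*% J^{-1/2} with J = crossprod(S)/n,
# dropping near-null directions (e.g. boundary fits)
decorrelate_scores <- function(S) {
  S <- as.matrix(S)
  if (!all(is.finite(S))) return(NULL)  # degenerate fit: no usable scores
  S <- sweep(S, 2, colMeans(S))  # center: exact mean-zero fluctuation
  J <- crossprod(S) / nrow(S)
  e <- eigen(J, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  if (!any(keep)) return(NULL)
  W <- S %*% e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  W
}

# simulated null distribution of sup_{t in [trim, 1-trim]} ||B(t)||^2/(t(1-t))
# for a p-dimensional Brownian bridge B; cached, fixed internal seed
suplm_null <- function(p, trim, reps = 40000L, grid = 1000L) {
  key <- sprintf("suplm_p%d_t%0.3f", p, trim)
  if (!is.null(.vsm_cache[[key]])) return(.vsm_cache[[key]])
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20240L + p * 7L + as.integer(round(trim * 1000)))
  tt <- seq_len(grid) / grid
  use <- tt >= trim & tt <= 1 - trim
  denom <- tt[use] * (1 - tt[use])
  out <- numeric(reps)
  chunk <- 2000L
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    q <- matrix(0, sum(use), m)
    for (j in seq_len(p)) {
      inc <- matrix(stats::rnorm(grid * m, 0, sqrt(1 / grid)), grid, m)
      W <- apply(inc, 2, cumsum)
      B <- W - outer(tt, W[grid, ])  # bridge
      q <- q + B[use, , drop = FALSE]^2
    }
    out[done + seq_len(m)] <- apply(q / denom, 2, max)
    done <- done + m
  }
  .vsm_cache[[key]] <- sort(out)
  .vsm_cache[[key]]
}

suplm_pvalue <- function(stat, p, trim) {
  null <- suplm_null(p, trim)
  R <- length(null)
  k <- sum(null >= stat)
  if (k > 0) return((k + 1) / (R + 1))
  # beyond the simulated range: exponential tail in the statistic
  (1 / (R + 1)) * exp(-(stat - null[R]) / 2)
}

#' Parameter instability test along a covariate
#'
#' Tests whether the per-observation score contributions of a converged ML
#' fit drift systematically along a covariate. For nominal and ordinal
#' covariates the statistic is a Pearson-type chi-square over level-wise
#' sums of decorrelated scores (df = p * (k - 1)); for numeric covariates
#' it is the supLM statistic over ordered cutpoints within the trimmed
#' range `[trim, 1 - trim]`, with p-value from a simulated null
#' distribution of the limiting trimmed squared Bessel-process supremum
#' (fixed internal seed, so p-values are deterministic).
#'
#' @param score_matrix n x p matrix of per-observation scores at the fitted
#'   optimum (see [fit_mle()]).
#' @param covariate length-n vector; factors are treated as categorical,
#'   numerics as numeric unless `type` overrides.
#' @param type `"auto"` (default), `"nominal"`, `"ordinal"` or `"numeric"`.
#' @param trim trimming fraction for the numeric scan. Default 0.1.
#' @return a list with `statistic`, `p.value`, `type`, and `df` (categorical
#'   case only). A covariate with a single observed level returns
#'   `p.value = 1` by convention.
#' @export
instability_test <- function(score_matrix, covariate,
                             type = c("auto", "nominal", "ordinal",
                                      "numeric"),
                             trim = 0.1) {
  type <- match.arg(type)
  n <- nrow(score_matrix)
  stopifnot(length(covariate) == n)
  if (type == "auto")
    type <- if (is.ordered(covariate)) "ordinal"
            else if (is.factor(covariate) || is.character(covariate) ||
                     is.logical(covariate)) "nominal"
            else "numeric"
  if (length(unique(covariate[!is.na(covariate)])) < 2)
    return(list(statistic = 0, p.value = 1, type = type))
  W <- decorrelate_scores(score_matrix)
  if (is.null(W)) return(list(statistic = 0, p.value = 1, type = type))
  p <- ncol(W)

  if (type %in% c("nominal", "ordinal")) {
    f <- factor(covariate)
    k <- nlevels(f)
    sums <- rowsum(W, f)                     # k x p level-wise score sums
    nl <- as.vector(table(f))
    stat <- sum(sums^2 / nl)
    df <- p * (k - 1)
    return(list(statistic = stat, p.value = stats::pchisq(stat, df,
                                                          lower.tail = FALSE),
                type = type, df = df))
  }
  # numeric: supLM over ordered cutpoints, ties pooled
  o <- base::order(covariate)
  Wo <- W[o, , drop = FALSE]
  cs <- apply(Wo, 2, cumsum) / sqrt(n)
  xo <- covariate[o]
  cut_ok <- xo[-n] != xo[-1]                 # cutpoint after position k
  tt <- seq_len(n - 1) / n
  use <- cut_ok & tt >= trim & tt <= 1 - trim
  if (!any(use)) return(list(statistic = 0, p.value = 1, type = type))
  lm_t <- rowSums(cs[-n, , drop = FALSE]^2)[use] / (tt[use] * (1 - tt[use]))
  stat <- max(lm_t)
  list(statistic = stat, p.value = suplm_pvalue(stat, p, trim),
       type = type)
}
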