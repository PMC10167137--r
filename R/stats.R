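#' Rank-based ANOVA-type statistic for factorial designs
#'
#' The nonparametric ANOVA-type statistic (ATS) of Brunner, Dette and
#' Munk for crossed factorial between-subject designs: the pooled response
#' is mid-ranked, relative treatment effects are estimated per cell, and
#' for every main effect and interaction an F-type statistic is formed
#' with a Box-type approximation for the (possibly non-integer) numerator
#' df and the standard Brunner denominator-df approximation. Being
#' rank-based, the statistic is invariant to strictly monotone transforms
#' of the response.
#'
#' @param data a `data.frame`.
#' @param factors character vector of factor column names (each with >= 2
#'   levels present).
#' @param response numeric response column name.
#' @param denominator `"finite"` (default; F(df1, df2) reference) or
#'   `"infinite"` (F(df1, Inf), i.e. the chi-square/df1 reference).
#' @return an object of class `ats_result`: a `data.frame` with one row
#'   per effect (`effect`, `statistic`, `df1`, `df2`, `p`), plus the cell
#'   table as an attribute.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rep(c("a", "b"), each = 30),
#'                 y = c(rnorm(30), rnorm(30, 1)))
#' ats(d, "g", "y")
#' @export
ats <- function(data, factors, response,
                denominator = c("finite", "infinite")) {
  denominator <- match.arg(denominator)
  stopifnot(all(factors %in% names(data)), response %in% names(data))
  y <- data[[response]]
  fs <- lapply(factors, function(f) factor(data[[f]]))
  names(fs) <- factors
  levs <- lapply(fs, levels)
  nlev <- vapply(levs, length, integer(1))
  # cell index: first factor varies slowest (lex order), so cells align
  # with the Kronecker-product contrast blocks below
  cell_of <- interaction(as.data.frame(fs), lex.order = TRUE, drop = FALSE)
  grid <- rev(expand.grid(rev(levs), stringsAsFactors = FALSE))
  names(grid) <- factors
  counts <- as.vector(table(cell_of))
  if (any(counts < 2)) {
    empty <- levels(cell_of)[counts < 2]
    stop("ats: cells with fewer than 2 observations: ",
         paste(empty, collapse = ", "))
  }
  N <- length(y)
  r <- rank(y)  # mid-ranks
  rbar <- tapply(r, cell_of, mean)
  s2 <- tapply(r, cell_of, stats::var) / N^2
  phat <- (rbar - 0.5) / N
  d <- length(phat)
  Sigma <- N * diag(as.vector(s2) / counts, d)

  # projection blocks: centering matrix for factors in the effect,
  # averaging matrix for the others
  P <- function(k) diag(k) - matrix(1 / k, k, k)
  J <- function(k) matrix(1 / k, k, k)
  effects <- unlist(lapply(seq_along(factors), function(ord)
    utils::combn(factors, ord, simplify = FALSE)), recursive = FALSE)
  out <- do.call(rbind, lapply(effects, function(eff) {
    Tm <- Reduce(`%x%`, lapply(factors, function(f)
      if (f %in% eff) P(nlev[f]) else J(nlev[f])))
    TS <- Tm %*% Sigma
    tr1 <- sum(diag(TS))
    if (tr1 <= 0) return(NULL)
    stat <- N * drop(phat %*% Tm %*% phat) / tr1
    df1 <- tr1^2 / sum(diag(TS %*% TS))
    df2 <- tr1^2 / sum((diag(Tm) * diag(Sigma))^2 / (counts - 1))
    pval <- if (denominator == "finite")
      stats::pf(stat, df1, df2, lower.tail = FALSE)
    else stats::pf(stat, df1, Inf, lower.tail = FALSE)
    data.frame(effect = paste(eff, collapse = ":"), statistic = stat,
               df1 = df1, df2 = if (denominator == "finite") df2 else Inf,
               p = pval, row.names = NULL)
  }))
  cells <- cbind(grid, n = counts, mean_rank = as.vector(rbar),
                 rel_effect = as.vector(phat))
  structure(out, class = c("ats_result", "data.frame"), cells = cells)
}

#' @export
print.ats_result <- function(x, ...) {
  cat("ANOVA-type statistic (rank-based factorial test)\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 3)
  df$df1 <- round(df$df1, 2); df$df2 <- round(df$df2, 1)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Percentage bend correlation
#'
#' Wilcox's robust correlation estimator: deviations from a robust
#' location estimate are scaled by the `(1 - beta)` empirical quantile of
#' absolute deviations from the median (the percentage bend measure of
#' scale) and bent through the clipping psi function
#' `psi(u) = max(-1, min(1, u))` before forming the normalized
#' cross-product. With `beta = 0` it reduces to Pearson correlation around
#' medians; `beta = 0.2` (default) downweights the most extreme 20%.
#'
#' @param x,y numeric vectors of equal length, `n >= 5`.
#' @param beta bend fraction in `[0, 0.5)`. Default 0.2.
#' @return correlation in `[-1, 1]`.
#' @export
percentage_bend_cor <- function(x, y, beta = 0.2) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            beta >= 0, beta < 0.5)
  pb_psi_dev <- function(v) {
    n <- length(v)
    m <- floor((1 - beta) * n + 0.5)
    w <- sort(abs(v - stats::median(v)))[m]
    if (w <= 0)
      stop("percentage_bend_cor: zero percentage bend scale (constant input)")
    u <- (v - stats::median(v)) / w
    i1 <- sum(u < -1); i2 <- sum(u > 1)
    sv <- sum(v[abs(u) <= 1])
    theta <- (w * (i2 - i1) + sv) / (length(v) - i1 - i2)
    pmin(pmax((v - theta) / w, -1), 1)
  }
  a <- pb_psi_dev(x)
  b <- pb_psi_dev(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation from concordant/discordant pair
#' counts (tau-b).
#'
#' @param x,y numeric vectors of equal length, `n >= 2`.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("kendall_tau: undefined for an all-tied vector")
  stats::cor(x, y, method = "kendall")
}
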