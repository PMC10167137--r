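#' Build the full-model design matrix
#'
#' Constructs the treatment-coded design matrix for the full model
#' `DV ~ G * S * T + n + a + g` (group x set-size x target interactions
#' plus nystagmus, age and gender main effects) with fixed reference
#' levels: control, set size 4, target absent, female. The same matrix is
#' consumed byte-identically by every universe (hash-exposed).
#'
#' @param data a `data.frame` with columns `group`, `set_size`, `target`,
#'   `gender`, `nystagmus`, `age` and the response column.
#' @param response name of the response column (e.g. `"median_rt"`,
#'   `"rt_s"` or `"accuracy"`).
#' @return list of class `model_design`: `y`, `X` (named columns),
#'   `var_map` (which of G/S/T/n/a/g each column involves), `hash`.
#' @export
build_design <- function(data, response) {
  stopifnot(response %in% names(data))
  d <- data
  d$group <- factor(d$group, levels = c("c", "i"))
  d$gender <- factor(d$gender, levels = c("f", "m"))
  d$target <- factor(d$target, levels = c("ab", "p"))
  d$set_size <- factor(as.character(d$set_size), levels = c("4", "16", "24"))
  d$nystagmus <- as.numeric(d$nystagmus)
  X <- stats::model.matrix(
    ~ group * set_size * target + nystagmus + age + gender, data = d,
    contrasts.arg = list(group = "contr.treatment",
                         set_size = "contr.treatment",
                         target = "contr.treatment",
                         gender = "contr.treatment"))
  y <- d[[response]]
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  var_map <- lapply(colnames(X), function(cn) {
    v <- character(0)
    if (grepl("group", cn)) v <- c(v, "G")
    if (grepl("set_size", cn)) v <- c(v, "S")
    if (grepl("target", cn)) v <- c(v, "T")
    if (grepl("nystagmus", cn)) v <- c(v, "n")
    if (grepl("age", cn)) v <- c(v, "a")
    if (grepl("gender", cn)) v <- c(v, "g")
    v
  })
  names(var_map) <- colnames(X)
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  saveRDS(list(y, X), tf)
  structure(list(y = y, X = X, var_map = var_map,
                 hash = unname(tools::md5sum(tf))),
            class = "model_design")
}

#' Median (quantile) regression
#'
#' Quantile regression by iteratively reweighted least squares on the
#' check loss (epsilon-smoothed), with bootstrap standard errors. At
#' `tau = 0.5` this is median regression; an intercept-only design returns
#' the sample median.
#'
#' @param design a [build_design()] object, or a list with `y` and `X`.
#' @param tau quantile in (0, 1). Default 0.5 (the median).
#' @param boot number of bootstrap resamples for SEs. Default 200.
#' @param seed bootstrap seed.
#' @return a `data.frame` coefficient table (`term`, `estimate`, `se`,
#'   `p`), with attribute `inference = "bootstrap"`.
#' @export
fit_quantile <- function(design, tau = 0.5, boot = 200L, seed = 1L) {
  stopifnot(tau > 0, tau < 1)
  y <- design$y; X <- design$X
  beta <- qr_irls_quantile(y, X, tau)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(y)
  bs <- replicate(boot, {
    i <- sample.int(n, n, replace = TRUE)
    tryCatch(qr_irls_quantile(y[i], X[i, , drop = FALSE], tau,
                              beta0 = beta, maxit = 25L),
             error = function(e) rep(NA_real_, ncol(X)))
  })
  if (is.null(dim(bs))) bs <- matrix(bs, nrow = 1)
  se <- apply(bs, 1, stats::sd, na.rm = TRUE)
  z <- beta / se
  out <- data.frame(term = colnames(X), estimate = beta, se = se,
                    p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  attr(out, "inference") <- "bootstrap"
  attr(out, "tau") <- tau
  out
}

qr_irls_quantile <- function(y, X, tau, eps = 1e-6, maxit = 100L,
                             beta0 = NULL) {
  beta <- if (is.null(beta0)) stats::lm.fit(X, y)$coefficients else beta0
  beta[is.na(beta)] <- 0
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    r_new <- y - drop(X %*% beta_new)
    obj <- sum(ifelse(r_new > 0, tau * r_new, (tau - 1) * r_new))
    if (is.finite(obj_old) && abs(obj_old - obj) < 1e-10 * (abs(obj) + 1e-10))
      { beta <- beta_new; break }
    beta <- beta_new; obj_old <- obj
  }
  beta
}

#' Robust (Huber M-estimation) regression
#'
#' Huber M-estimation with tuning constant 1.345 (95% Gaussian
#' efficiency), iteratively reweighted via [MASS::rlm()].
#'
#' @param design a [build_design()] object.
#' @param k Huber tuning constant. Default 1.345.
#' @return coefficient table (`term`, `estimate`, `se`, `p`) with a
#'   `converged` attribute.
#' @export
fit_robust <- function(design, k = 1.345) {
  y <- design$y; X <- design$X
  fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = k, maxit = 100)
  sm <- summary(fit)$coefficients
  z <- sm[, "Value"] / sm[, "Std. Error"]
  out <- data.frame(term = colnames(X), estimate = sm[, "Value"],
                    se = sm[, "Std. Error"], p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL)
  attr(out, "converged") <- fit$converged
  out
}

#' Distributional regression (all parameters on covariates)
#'
#' Joint maximum likelihood of a full distributional regression model: for
#' every parameter of the family, a linear predictor on the same design
#' matrix through that parameter's link (identity / log / logit). Standard
#' errors come from the observed information (numerical Hessian at the
#' optimum); diverged or separated fits are flagged and their coefficient
#' tables withheld.
#'
#' @param design a [build_design()] object.
#' @param family a [dist_family()] or name. Default Ex-Gaussian.
#' @param full_for distribution parameters that receive the full linear
#'   predictor; the remaining parameters get an intercept only. Default
#'   `"mu"` (the usual distributional-regression default, which keeps the
#'   observed information well conditioned); use
#'   `family$parameters` to put the covariates on every parameter.
#' @return list of class `distreg_fit`: `tables` (one coefficient
#'   `data.frame` per distribution parameter), `loglik`, `converged`.
#' @export
fit_distributional <- function(design, family = dist_family("exgaussian"),
                               full_for = "mu") {
  if (is.character(family)) family <- dist_family(family)
  y <- design$y; X <- design$X
  n <- nrow(X); p <- length(family$parameters)
  links <- family$links
  stopifnot(all(full_for %in% family$parameters))
  Xs <- lapply(family$parameters, function(pm)
    if (pm %in% full_for) X else X[, 1, drop = FALSE])
  qs <- vapply(Xs, ncol, integer(1))
  off <- c(0L, cumsum(qs))

  theta_mat <- function(coefs) {
    th <- matrix(0, n, p)
    for (j in seq_len(p)) {
      eta <- drop(Xs[[j]] %*% coefs[(off[j] + 1):off[j + 1]])
      th[, j] <- link_fun(links[j])$from(eta)
    }
    th
  }
  negll <- function(coefs) {
    th <- theta_mat(coefs)
    if (!all(is.finite(th))) return(1e10)
    if (any(th[, links == "log"] <= 0)) return(1e10)
    if (p > 2 && any(links == "logit") &&
        any(th[, links == "logit"] <= 0 | th[, links == "logit"] >= 1))
      return(1e10)
    ll <- sum(logpdf_rowwise(y, th, family))
    if (!is.finite(ll)) 1e10 else -ll
  }
  npar <- off[p + 1]
  grad <- function(coefs) {
    th <- theta_mat(coefs)
    if (!all(is.finite(th))) return(rep(0, npar))
    sc <- tryCatch(score_rowwise(y, th, family), error = function(e) NULL)
    if (is.null(sc) || !all(is.finite(sc))) return(rep(0, npar))
    g <- numeric(npar)
    for (j in seq_len(p)) {
      dthdeta <- switch(links[j], identity = rep(1, n), log = th[, j],
                        logit = th[, j] * (1 - th[, j]))
      g[(off[j] + 1):off[j + 1]] <- -crossprod(Xs[[j]], sc[, j] * dthdeta)
    }
    g
  }
  start_theta <- family$start(y)
  start_eta <- theta_to_link(start_theta, family)
  coefs0 <- numeric(npar)
  coefs0[off[seq_len(p)] + 1L] <- start_eta
  opt <- stats::optim(coefs0, negll, gr = grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
  conv <- opt$convergence == 0 && opt$value < 1e9 &&
    all(abs(opt$par) < 50)
  if (!conv)
    return(structure(list(tables = NULL, loglik = -opt$value,
                          converged = FALSE, family = family$family),
                     class = "distreg_fit"))
  H <- stats::optimHess(opt$par, negll)
  V <- tryCatch(solve(H), error = function(e) NULL)
  se <- rep(NA_real_, npar)
  if (!is.null(V)) {
    dg <- diag(V)
    ok <- is.finite(dg) & dg > 0
    se[ok] <- sqrt(dg[ok])
  }
  tables <- lapply(seq_len(p), function(j) {
    i <- (off[j] + 1):off[j + 1]
    z <- opt$par[i] / se[i]
    data.frame(term = colnames(Xs[[j]]), estimate = opt$par[i],
               se = se[i], p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  })
  names(tables) <- family$parameters
  structure(list(tables = tables, loglik = -opt$value, converged = TRUE,
                 family = family$family),
            class = "distreg_fit")
}

logpdf_rowwise <- function(y, th, family) {
  switch(family$family,
    exgaussian = dexgauss(y, th[, 1], th[, 2], th[, 3], log = TRUE),
    normal = stats::dnorm(y, th[, 1], th[, 2], log = TRUE),
    gb1 = {
      a <- th[, 1] * (1 - th[, 2]^2) / th[, 2]^2
      b <- (1 - th[, 1]) * (1 - th[, 2]^2) / th[, 2]^2
      xt <- y^th[, 4]
      base::log(th[, 4]) + b * base::log(th[, 3]) +
        (th[, 4] * a - 1) * base::log(y) + (b - 1) * log1p(-xt) -
        lbeta(a, b) - (a + b) * base::log(th[, 3] + (1 - th[, 3]) * xt)
    })
}

score_rowwise <- function(y, th, family) {
  switch(family$family,
    exgaussian = exgauss_score(y, th[, 1], th[, 2], th[, 3]),
    normal = {
      r <- (y - th[, 1]) / th[, 2]
      cbind(r / th[, 2], (r^2 - 1) / th[, 2])
    },
    gb1 = gb1_score(y, th[, 1], th[, 2], th[, 3], th[, 4]))
}

#' Run the regression multiverse
#'
#' Fits the full model under the three analytic lenses — median quantile
#' regression, Huber robust regression, and distributional regression —
#' on a byte-identical design matrix, and summarizes per-term agreement
#' (sign consistency and significance counts) across universes. For the
#' distributional universe, agreement is assessed on the location (`mu`)
#' submodel.
#'
#' @param data condition- or trial-level analysis table.
#' @param response response column name.
#' @param family distributional-universe family (name or
#'   [dist_family()]); `"exgaussian"` for RT, `"gb1"` for accuracy.
#' @param universes character subset of
#'   `c("quantile", "robust", "distributional")`.
#' @param alpha significance level for the agreement summary. Default 0.05.
#' @param seed bootstrap seed for the quantile universe.
#' @return list of class `multiverse_result`: `tables` (per universe),
#'   `distributional` (full per-parameter fit), `agreement` (per-term
#'   `data.frame`: `n_significant`, `sign_consistent`, `sign`),
#'   `design_hash`, `universes`.
#' @export
run_multiverse <- function(data, response, family = "exgaussian",
                           universes = c("quantile", "robust",
                                         "distributional"),
                           alpha = 0.05, seed = 1L) {
  universes <- match.arg(universes, several.ok = TRUE)
  design <- build_design(data, response)
  tables <- list()
  dist_fit <- NULL
  if ("quantile" %in% universes)
    tables$quantile <- fit_quantile(design, seed = seed)
  if ("robust" %in% universes)
    tables$robust <- fit_robust(design)
  if ("distributional" %in% universes) {
    dist_fit <- fit_distributional(design, family)
    if (isTRUE(dist_fit$converged))
      tables$distributional <- dist_fit$tables$mu
  }
  terms <- colnames(design$X)
  agreement <- do.call(rbind, lapply(terms, function(tm) {
    est <- vapply(tables, function(tb) tb$estimate[tb$term == tm],
                  numeric(1))
    pv <- vapply(tables, function(tb) tb$p[tb$term == tm], numeric(1))
    sig <- !is.na(pv) & pv < alpha
    sgn <- sign(est[sig])
    data.frame(term = tm, n_significant = sum(sig),
               sign_consistent = length(sgn) == 0 ||
                 all(sgn == sgn[1]),
               sign = if (length(sgn) && all(sgn == sgn[1])) sgn[1]
                      else NA_real_,
               row.names = NULL)
  }))
  structure(list(tables = tables, distributional = dist_fit,
                 agreement = agreement, design_hash = design$hash,
                 var_map = design$var_map,
                 universes = names(tables), alpha = alpha),
            class = "multiverse_result")
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat("Multiverse fit (", paste(x$universes, collapse = ", "), "), ",
      nrow(x$agreement), " terms\n", sep = "")
  sig <- x$agreement[x$agreement$n_significant >= 2 &
                       x$agreement$sign_consistent, ]
  if (nrow(sig)) {
    cat("terms significant (p <", x$alpha,
        ") with consistent sign in >= 2 universes:\n")
    print(sig[, c("term", "n_significant", "sign")], row.names = FALSE)
  }
  invisible(x)
}

#' Reduce the full model using screening and multiverse agreement
#'
#' Step 3 of the pipeline: propose the explainable reduced model. The
#' default rule (`"screen_and_regression"`) retains a variable when the
#' Boruta screen confirms it *and* the multiverse corroborates it — some
#' design-matrix term involving the variable is significant with a
#' consistent sign in at least 2 of the 3 universes (the regression step
#' can thereby veto screen hits that are mere proxies of retained
#' variables, e.g. a nystagmus flag concentrated in the impaired group).
#' `rule = "or"` instead retains anything confirmed by the screen or
#' corroborated by the multiverse.
#'
#' @param multiverse a [run_multiverse()] result.
#' @param importance a [boruta()] result on the same data.
#' @param rule `"screen_and_regression"` (default) or `"or"`.
#' @param min_universes universes that must agree for corroboration;
#'   default 2, degraded to the number available when fewer ran.
#' @return list of class `reduced_model`: `retained` (character vector of
#'   variable symbols among G, S, T, n, a, g), `audit` (per-variable
#'   `data.frame` with the screen decision and corroboration), `rule`.
#' @export
reduce_model <- function(multiverse, importance,
                         rule = c("screen_and_regression", "or"),
                         min_universes = 2L) {
  rule <- match.arg(rule)
  symbol_of <- c(group = "G", set_size = "S", target = "T",
                 nystagmus = "n", age = "a", gender = "g")
  dec <- importance$decision
  names(dec) <- unname(symbol_of[names(importance$decision)])
  vars <- unname(symbol_of)
  m_avail <- length(multiverse$universes)
  need <- min(min_universes, max(m_avail, 1L))
  if (m_avail < min_universes)
    message("reduce_model: only ", m_avail,
            " universes available; corroboration threshold degraded to ",
            need)
  ag <- multiverse$agreement
  corroborated <- vapply(vars, function(v) {
    involves <- vapply(ag$term, function(tm)
      v %in% multiverse$var_map[[tm]], logical(1))
    any(involves & ag$n_significant >= need & ag$sign_consistent)
  }, logical(1))
  confirmed <- vars %in% names(dec)[dec == "confirmed"]
  retained <- switch(rule,
    screen_and_regression = vars[confirmed & corroborated],
    or = vars[confirmed | corroborated])
  audit <- data.frame(variable = vars, screen = as.character(dec[vars]),
                      corroborated = corroborated,
                      retained = vars %in% retained, row.names = NULL)
  if (!length(retained))
    warning("reduce_model: no variable retained; intercept-only model")
  structure(list(retained = retained, audit = audit, rule = rule,
                 all_categorical = !("a" %in% retained)),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("Reduced model (rule: ", x$rule, "): DV ~ ",
      if (length(x$retained)) paste(x$retained, collapse = " * ") else "1",
      "\n", sep = "")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
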