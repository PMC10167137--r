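#' Control parameters for distributional regression trees
#'
#' @param alpha significance level for splitting (Bonferroni-adjusted
#'   instability p-value must fall below it). Default 0.05.
#' @param min_node minimum number of observations to fit a node and for
#'   each child of a split. Default 20; must be at least five times the
#'   family's parameter count.
#' @param max_depth maximum tree depth (root = depth 0). Default 5.
#' @param trim trimming fraction for numeric instability scans. Default 0.1.
#' @param seed integer seed forwarded to node fits (restart jitter).
#' @return a list of class `disttree_control`.
#' @export
disttree_control <- function(alpha = 0.05, min_node = 20L, max_depth = 5L,
                             trim = 0.1, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_node >= 5, max_depth >= 0,
            trim > 0, trim < 0.5)
  structure(list(alpha = alpha, min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth), trim = trim,
                 seed = as.integer(seed)),
            class = "disttree_control")
}

#' Median with approximate 95% confidence interval
#'
#' Order-statistic (binomial method) interval: ranks
#' `floor((n - z sqrt(n)) / 2)` and `ceiling((n + z sqrt(n)) / 2)` with
#' `z = 1.96`, clamped to the sample range. For `n < 6` the interval is the
#' sample range and a width warning is flagged.
#'
#' @param sample numeric vector, `n >= 1`.
#' @param conf confidence level (default 0.95).
#' @return list with `median`, `lo`, `hi`, `n`, `wide` (TRUE when the
#'   range fallback was used).
#' @export
median_ci <- function(sample, conf = 0.95) {
  x <- sort(as.numeric(sample))
  n <- length(x)
  stopifnot(n >= 1)
  med <- stats::median(x)
  if (n < 6)
    return(list(median = med, lo = x[1], hi = x[n], n = n, wide = TRUE))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo_r <- max(1L, floor((n - z * sqrt(n)) / 2))
  hi_r <- min(n, ceiling((n + z * sqrt(n)) / 2))
  list(median = med, lo = x[lo_r], hi = x[hi_r], n = n, wide = FALSE)
}

covariate_type <- function(v) {
  if (is.ordered(v)) "ordinal"
  else if (is.factor(v) || is.character(v) || is.logical(v)) "nominal"
  else "numeric"
}

#' Select the splitting covariate at a node
#'
#' Runs the parameter [instability_test()] for every covariate with
#' variation, Bonferroni-adjusts the p-values across the tested covariates,
#' and returns the minimizing covariate iff its adjusted p-value falls
#' below `alpha`.
#'
#' @param fit a converged [fit_mle()] node fit.
#' @param covars `data.frame` of covariates (rows aligned with the fit's
#'   sample).
#' @param alpha significance level.
#' @param trim numeric-scan trimming fraction.
#' @return `NULL` when no covariate qualifies, else a list with
#'   `covariate`, `statistic`, `p.value` (nominal) and `adjusted_p`.
#' @export
select_split <- function(fit, covars, alpha = 0.05, trim = 0.1) {
  if (ncol(covars) == 0) return(NULL)
  tests <- lapply(names(covars), function(nm)
    instability_test(fit$score_matrix, covars[[nm]], trim = trim))
  names(tests) <- names(covars)
  varying <- vapply(covars, function(v)
    length(unique(v[!is.na(v)])) > 1, logical(1))
  m <- sum(varying)
  if (m == 0) return(NULL)
  pv <- vapply(tests, `[[`, numeric(1), "p.value")
  adj <- pmin(pv * m, 1)
  best <- which.min(adj)
  if (adj[best] >= alpha) return(NULL)
  list(covariate = names(covars)[best],
       statistic = tests[[best]]$statistic,
       p.value = pv[best], adjusted_p = adj[best],
       all_adjusted = adj)
}

# enumerate candidate bipartitions of a covariate as logical left-side masks
candidate_partitions <- function(v) {
  type <- covariate_type(v)
  if (type == "numeric") {
    vals <- sort(unique(v))
    if (length(vals) < 2) return(list())
    thr <- (vals[-1] + vals[-length(vals)]) / 2
    lapply(thr, function(tt) list(kind = "numeric", threshold = tt,
                                  left = v <= tt))
  } else if (type == "ordinal") {
    lev <- levels(factor(v))
    lapply(seq_len(length(lev) - 1), function(k)
      list(kind = "ordinal", left_levels = lev[1:k],
           left = as.character(v) %in% lev[1:k]))
  } else {
    lev <- unique(as.character(v))
    k <- length(lev)
    if (k < 2) return(list())
    out <- list()
    for (code in seq_len(2^(k - 1) - 1)) {
      sel <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
      out[[length(out) + 1]] <- list(kind = "nominal",
                                     left_levels = lev[sel],
                                     left = as.character(v) %in% lev[sel])
    }
    out
  }
}

#' Find the best binary partition of a selected covariate
#'
#' Enumerates the admissible bipartitions of the covariate (threshold
#' midway between adjacent observed values for numeric; contiguous level
#' blocks for ordinal; all level bipartitions for nominal) and returns the
#' one maximizing the sum of the two children's maximized log-likelihoods,
#' subject to both children holding at least `min_node` observations.
#'
#' @param y node response vector.
#' @param v the selected covariate vector.
#' @param family a [dist_family()].
#' @param min_node minimum child size.
#' @param seed fit seed.
#' @return `NULL` when no admissible partition exists, else a list with the
#'   partition description (`kind`, `threshold` or `left_levels`), `left`
#'   mask, child fits and `loglik` (sum over children).
#' @export
find_partition <- function(y, v, family, min_node = 20L, seed = 1L) {
  cands <- candidate_partitions(v)
  best <- NULL
  for (cd in cands) {
    nl <- sum(cd$left); nr <- length(y) - nl
    if (nl < min_node || nr < min_node) next
    fl <- tryCatch(fit_mle(y[cd$left], family, seed = seed),
                   error = function(e) NULL)
    fr <- tryCatch(fit_mle(y[!cd$left], family, seed = seed),
                   error = function(e) NULL)
    if (is.null(fl) || is.null(fr)) next
    ll <- fl$loglik + fr$loglik
    if (is.null(best) || ll > best$loglik) {
      best <- cd
      best$loglik <- ll
      best$fit_left <- fl
      best$fit_right <- fr
    }
  }
  best
}

#' Grow a distributional regression tree
#'
#' Recursive partitioning of a response by maximum-likelihood distribution
#' fits: each node fits the family to its own observations
#' (intercept-only — covariates act only through splits), tests every
#' covariate for parameter instability via the per-observation scores,
#' Bonferroni-adjusts across covariates, and, while the minimum adjusted
#' p-value stays below `alpha`, splits on the binary partition of the
#' selected covariate that maximizes the children's joint log-likelihood.
#' Growth stops at `max_depth`, `min_node`, or when no covariate shows
#' significant instability. Node ids are assigned depth-first in reporting
#' order; every node carries its sample size, median and approximate 95%
#' CI of the median.
#'
#' @param y numeric response (e.g. retained reaction times in seconds, or
#'   squeezed accuracies).
#' @param covars `data.frame` of covariates; ordered factors are scanned
#'   over contiguous level blocks, unordered factors over all level
#'   bipartitions, numerics over observed thresholds.
#' @param family a [dist_family()] or family name. Default Ex-Gaussian.
#' @param control a [disttree_control()].
#' @return an object of class `disttree`: nested node list (`id`, `depth`,
#'   `n`, `model`, `summary`, `split`, `kids`) plus the growing
#'   configuration.
#' @examples
#' set.seed(1)
#' z <- factor(rep(c("a", "b"), each = 150))
#' y <- rexgauss(300, ifelse(z == "a", 1, 2), 0.2, 0.4)
#' tr <- disttree(y, data.frame(z = z))
#' print(tr)
#' @export
disttree <- function(y, covars, family = dist_family("exgaussian"),
                     control = disttree_control()) {
  if (is.character(family)) family <- dist_family(family)
  stopifnot(is.data.frame(covars), nrow(covars) == length(y))
  if (anyNA(y) || anyNA(covars))
    stop("disttree: missing values in response or covariates")
  min_fit <- max(control$min_node, 5L * length(family$parameters))

  grow_node <- function(idx, depth) {
    yy <- y[idx]
    fit <- tryCatch(fit_mle(yy, family, seed = control$seed),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      if (depth == 0)
        stop("disttree: the root fit failed; cannot grow a tree")
      warning("disttree: child fit failed at depth ", depth,
              "; node kept as leaf")
      fit <- fit %||% list(family = family$family, theta_hat = NULL,
                           loglik = NA_real_, n = length(yy),
                           converged = FALSE)
    }
    ci <- median_ci(yy)
    node <- list(id = NA_integer_, depth = depth, n = length(yy),
                 idx = idx,
                 model = fit[c("family", "theta_hat", "loglik", "n",
                               "converged")],
                 summary = ci, split = NULL, kids = NULL)
    node$model$score_matrix <- fit$score_matrix
    if (depth >= control$max_depth || length(yy) < 2L * min_fit ||
        !isTRUE(fit$converged))
      return(node)
    sel <- select_split(fit, covars[idx, , drop = FALSE],
                        alpha = control$alpha, trim = control$trim)
    if (is.null(sel)) return(node)
    part <- find_partition(yy, covars[idx, , drop = FALSE][[sel$covariate]],
                           family, min_node = min_fit, seed = control$seed)
    if (is.null(part)) return(node)
    node$split <- list(covariate = sel$covariate, kind = part$kind,
                       threshold = part$threshold,
                       left_levels = part$left_levels,
                       statistic = sel$statistic,
                       adjusted_p = sel$adjusted_p)
    node$kids <- list(grow_node(idx[part$left], depth + 1L),
                      grow_node(idx[!part$left], depth + 1L))
    node
  }

  root <- grow_node(seq_along(y), 0L)
  # depth-first preorder reporting ids
  counter <- 0L
  assign_ids <- function(node) {
    counter <<- counter + 1L
    node$id <- counter
    if (!is.null(node$kids))
      node$kids <- lapply(node$kids, assign_ids)
    node
  }
  root <- assign_ids(root)
  structure(list(root = root, family = family$family,
                 control = control, n = length(y),
                 covariates = names(covars)),
            class = "disttree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    if (!is.null(node$kids)) lapply(node$kids, walk)
    invisible(NULL)
  }
  walk(tree$root)
  out
}

sig_glyph <- function(p) if (p < 0.001) "♦" else if (p < 0.05) "●" else ""

#' @export
print.disttree <- function(x, digits = 2, ...) {
  cat(sprintf("Distributional regression tree (%s family), n = %d\n",
              x$family, x$n))
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    s <- node$summary
    lab <- sprintf("n = %d, %s [%s, %s]", node$n,
                   format(round(s$median, digits), nsmall = digits),
                   format(round(s$lo, digits), nsmall = digits),
                   format(round(s$hi, digits), nsmall = digits))
    if (is.null(node$split)) {
      cat(sprintf("%s[%d] leaf: %s\n", pad, node$id, lab))
    } else {
      desc <- if (node$split$kind == "numeric")
        sprintf("%s <= %.3g", node$split$covariate, node$split$threshold)
      else sprintf("%s in {%s}", node$split$covariate,
                   paste(node$split$left_levels, collapse = ","))
      cat(sprintf("%s[%d] %s: split %s %s (adj. p = %.3g)\n", pad, node$id,
                  lab, desc, sig_glyph(node$split$adjusted_p),
                  node$split$adjusted_p))
      walk(node$kids[[1]], indent + 1)
      walk(node$kids[[2]], indent + 1)
    }
  }
  walk(x$root, 0)
  invisible(x)
}

#' Serialize a distributional tree
#'
#' `tree_to_json` renders the tree as nested JSON (ids, node fits,
#' summaries, splits); `tree_to_dot` renders Graphviz DOT with node labels
#' in the reporting format `n = xx, median [lo, hi]` and significance
#' glyphs on split edges (filled circle p < .05, filled diamond p < .001).
#'
#' @param tree a [disttree()].
#' @param path optional file to write to.
#' @return the JSON or DOT string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    node$idx <- NULL
    node$model$score_matrix <- NULL
    node$model$theta_hat <- as.list(node$model$theta_hat)
    if (!is.null(node$kids)) node$kids <- lapply(node$kids, strip)
    node
  }
  obj <- list(family = tree$family, n = tree$n,
              covariates = tree$covariates, root = strip(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname tree_to_json
#' @export
tree_to_dot <- function(tree, path = NULL) {
  lines <- c("digraph disttree {", "  node [shape=box];")
  walk <- function(node) {
    s <- node$summary
    lab <- sprintf("n = %d, %.2f [%.2f, %.2f]", node$n, s$median, s$lo, s$hi)
    if (!is.null(node$split))
      lab <- sprintf("%s\\n%s %s", lab, node$split$covariate,
                     sig_glyph(node$split$adjusted_p))
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", node$id, lab))
    if (!is.null(node$kids)) {
      edge_lab <- if (node$split$kind == "numeric")
        sprintf(c("<= %.3g", "> %.3g"), node$split$threshold)
      else c(paste(node$split$left_levels, collapse = ","),
             "otherwise")
      for (i in 1:2) {
        lines <<- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];",
                                   node$id, node$kids[[i]]$id, edge_lab[i]))
        walk(node$kids[[i]])
      }
    }
  }
  walk(tree$root)
  lines <- c(lines, "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
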