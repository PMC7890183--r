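# Paired statistics for pre/post comparisons: paired t, one-sample
# (paired) Hotelling's T-squared with Wilks' lambda, and the Simes
# multiple-testing procedure for post-hoc control.

#' Matched pre/post sample
#'
#' @param pre,post subjects x variables matrices with matched rows (same
#'   subject order) and identical shape.
#' @param labels variable labels.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(pre, post, labels = NULL) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (!all(dim(pre) == dim(post)))
    abort_param("`pre` and `post` must have identical shape")
  if (is.null(labels)) labels <- colnames(pre)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(pre)))
  structure(list(pre = pre, post = post, labels = labels),
            class = "paired_sample")
}

#' Paired t-test
#'
#' Classical two-sided paired t on the differences `post - pre`. The
#' degenerate case of identical constant shift (zero difference
#' variance) is handled explicitly: a zero shift gives `t = 0, p = 1`, a
#' non-zero shift an infinite statistic with `p = 0`.
#'
#' @param pre,post numeric vectors of matched observations.
#' @return list of class `test_result`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `method`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) abort_param("unmatched pair lengths")
  n <- length(pre)
  if (n < 2L) abort_param("at least 2 matched pairs required")
  d <- post - pre
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    md <- mean(d)
    res <- list(statistic = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1L, p_value = if (md == 0) 1 else 0,
                mean_difference = md, method = "paired t")
    return(structure(res, class = "test_result"))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = unname(tt$estimate),
                 method = "paired t"),
            class = "test_result")
}

#' Paired Hotelling's T-squared test
#'
#' One-sample Hotelling's test on the difference vectors:
#' `T2 = n * dbar' S^-1 dbar` with `S` the sample covariance of the
#' differences; `Wilks' lambda = (1 + T2 / (n - 1))^-1`;
#' `F = T2 (n - p) / (p (n - 1))` on `(p, n - p)` degrees of freedom.
#'
#' @param s a [paired_sample()].
#' @return list of class `test_result`: `statistic` (T2),
#'   `wilks_lambda`, `f_value`, `df` (`c(p, n - p)`), `p_value`, `n`,
#'   `p`, `method`.
#' @export
paired_hotelling <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$post - s$pre
  n <- nrow(d)
  p <- ncol(d)
  if (n <= p)
    abort_param("Hotelling's test needs more subjects than variables")
  if (max(abs(d)) == 0) {
    return(structure(list(statistic = 0, wilks_lambda = 1, f_value = 0,
                          df = c(p, n - p), p_value = 1, n = n, p = p,
                          labels = s$labels, method = "paired Hotelling T2"),
                     class = "test_result"))
  }
  dbar <- colMeans(d)
  cv <- stats::cov(d)
  sol <- tryCatch(solve(cv, dbar), error = function(e) NULL)
  if (is.null(sol) || rcond(cv) < 1e-12)
    abort_param("singular difference covariance; reduce the variable set")
  t2 <- n * sum(dbar * sol)
  lambda <- 1 / (1 + t2 / (n - 1))
  fval <- t2 * (n - p) / (p * (n - 1))
  pval <- stats::pf(fval, p, n - p, lower.tail = FALSE)
  structure(list(statistic = t2, wilks_lambda = lambda, f_value = fval,
                 df = c(p, n - p), p_value = pval, n = n, p = p,
                 labels = s$labels, method = "paired Hotelling T2"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (x$method == "paired Hotelling T2") {
    cat(sprintf("%s: T2 = %.4g, Wilks' lambda = %.3f, F(%d, %d) = %.4g, p = %.4g\n",
                x$method, x$statistic, x$wilks_lambda, x$df[1], x$df[2],
                x$f_value, x$p_value))
  } else {
    cat(sprintf("%s: t(%g) = %.4g, p = %.4g\n",
                x$method, x$df, x$statistic, x$p_value))
  }
  invisible(x)
}

#' Simes multiple-testing procedure
#'
#' Orders the unadjusted p-values `p_(1) <= ... <= p_(m)` and rejects
#' the global null iff `p_(i) <= i * alpha / m` for some `i`; the
#' elementary hypothesis at rank `i` is rejected iff its ordered
#' p-value satisfies the same inequality. Exact level-`alpha` under
#' independence, and less conservative than Bonferroni.
#'
#' @param pvals numeric vector of unadjusted p-values in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @return list of class `simes_result`: `global_reject`, `alpha`, and a
#'   data frame `decisions` in the input order with columns `p`, `rank`,
#'   `threshold`, `reject`.
#' @export
simes <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (m < 1L) abort_param("at least one p-value required")
  if (any(pvals < 0 | pvals > 1)) abort_param("p-values must lie in [0, 1]")
  ord <- order(pvals)
  thresholds <- seq_len(m) * alpha / m
  rej_sorted <- pvals[ord] <= thresholds
  decisions <- data.frame(p = pvals,
                          rank = order(ord),
                          threshold = thresholds[order(ord)],
                          reject = rej_sorted[order(ord)])
  structure(list(global_reject = any(rej_sorted), alpha = alpha,
                 decisions = decisions),
            class = "simes_result")
}

#' @export
print.simes_result <- function(x, ...) {
  cat(sprintf("Simes (alpha = %g): global %s\n", x$alpha,
              if (x$global_reject) "REJECT" else "retain"))
  print(x$decisions)
  invisible(x)
}

#' One Hotelling family with Simes post-hoc tests
#'
#' Runs a paired Hotelling's T-squared over a family of variables, then
#' per-variable paired t-tests with Simes control at `alpha` across the
#' family. Mirrors the layout of a pre/post outcome table: one
#' multivariate row and one post-hoc row per variable.
#'
#' @param pre,post subjects x variables matrices (matched rows).
#' @param labels variable labels.
#' @param family family name carried into the output.
#' @param alpha level of the Simes procedure.
#' @return list with the `test_result` in `hotelling`, the
#'   `simes_result` in `simes`, and a tidy data frame `table` (family,
#'   variable, statistic, wilks_lambda, df1, df2, p, simes_threshold,
#'   reject).
#' @export
paired_family_test <- function(pre, post, labels = NULL, family = "family",
                               alpha = 0.05) {
  s <- paired_sample(pre, post, labels)
  ht <- paired_hotelling(s)
  tt <- lapply(seq_len(ncol(s$pre)), function(k)
    paired_t(s$pre[, k], s$post[, k]))
  pv <- vapply(tt, `[[`, numeric(1L), "p_value")
  sm <- simes(pv, alpha)
  tab <- rbind(
    data.frame(family = family, variable = "(multivariate)",
               statistic = ht$statistic, wilks_lambda = ht$wilks_lambda,
               df1 = ht$df[1], df2 = ht$df[2], p = ht$p_value,
               simes_threshold = NA_real_, reject = ht$p_value <= alpha),
    data.frame(family = family, variable = s$labels,
               statistic = vapply(tt, `[[`, numeric(1L), "statistic"),
               wilks_lambda = NA_real_,
               df1 = vapply(tt, function(z) z$df, numeric(1L)),
               df2 = NA_real_, p = pv,
               simes_threshold = sm$decisions$threshold,
               reject = sm$decisions$reject)
  )
  list(hotelling = ht, simes = sm, table = tab)
}
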