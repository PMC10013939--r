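#' Complete-case prevalence cell
#'
#' Computes the `n (%)` cell of a stratified prevalence table. The
#' denominator is the complete-case count: respondents in the stratum with
#' a non-missing answer to the variable. Percentages are rounded half away
#' from zero to one decimal, the convention used in printed tables.
#'
#' @param count Integer vector of category counts.
#' @param denominator Integer vector of complete-case denominators (> 0).
#' @return Tibble with columns `count`, `denominator`, `pct`.
#' @export
#' @examples
#' prevalence_cell(62, 133)   # 46.6%
prevalence_cell <- function(count, denominator) {
  if (any(denominator <= 0)) abort("prevalence_cell: denominator must be > 0")
  if (any(count < 0 | count > denominator)) {
    abort("prevalence_cell: count must be in [0, denominator]")
  }
  tibble::tibble(count = as.integer(count),
                 denominator = as.integer(denominator),
                 pct = round_half_up(100 * count / denominator, 1))
}

#' Pooled two-proportion z-test
#'
#' Two-sided normal-approximation test of equal proportions using the
#' pooled estimate in the standard error, without continuity correction.
#' The statistic carries the sign of `x1/n1 - x2/n2`. When the pooled
#' proportion is degenerate (0 or 1) the statistic is 0 and p = 1.
#' Vectorized over all four arguments.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return Tibble with columns `statistic`, `p` and `method`.
#' @export
#' @examples
#' two_proportion_z(54, 201, 92, 522)   # p ~ .006
two_proportion_z <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0 | n2 <= 0)) abort("two_proportion_z: denominators must be > 0")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (p1 - p2) / se)
  p <- ifelse(se == 0, 1, 2 * pnorm(-abs(z)))
  tibble::tibble(statistic = z, p = p,
                 method = "two-proportion pooled z-test")
}

#' Bonferroni adjustment
#'
#' Multiplies each raw p-value by the family size and caps at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
#' @examples
#' bonferroni(c(0.02, 0.5), m = 4)
bonferroni <- function(p, m = length(p)) {
  if (m < 1) abort("bonferroni: family size m must be >= 1")
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("bonferroni: p-values must be in [0, 1]")
  pmin(1, m * p)
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `(a d) / (b c)` with the 95% Wald interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Cell layout:
#' `a` exposed cases, `b` exposed controls, `c` unexposed cases,
#' `d` unexposed controls. A zero cell is an error unless
#' `haldane = TRUE`, which adds 0.5 to every cell (Haldane-Anscombe).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param haldane Apply the +0.5 continuity correction when a cell is zero.
#' @param conf_level Confidence level for the Wald interval.
#' @return Tibble with `or`, `ci_low`, `ci_high`, `n_used`, `method`.
#' @export
#' @examples
#' crude_or(20, 10, 10, 20)   # OR 4
crude_or <- function(a, b, c, d, haldane = FALSE, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("crude_or: cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!haldane) {
      abort("crude_or: zero cell; use haldane = TRUE for the +0.5 correction")
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells[["a"]]) + log(cells[["d"]]) -
    log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - zq * se),
    ci_high = exp(log_or + zq * se),
    n_used = as.integer(a + b + c + d),
    method = if (any(c(a, b, c, d) == 0)) "crude (Haldane-Anscombe +0.5)" else "crude"
  )
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit used for the crude and adjusted odds
#' ratio models. Rows with a missing outcome or any missing design entry
#' are dropped (complete-case) and the retained sample size is reported.
#' Iteration stops when the largest absolute score component falls below
#' `1e-8` or the relative deviance change falls below `1e-10`, with at most
#' 50 iterations; coefficients diverging beyond +/-30 on the logit scale
#' are reported as perfect separation.
#'
#' @param outcome Binary (0/1 or logical) response vector.
#' @param design Numeric design matrix including the intercept column, or a
#'   data frame passed through [stats::model.matrix()].
#' @return An object of class `hbsr_logit` with coefficients, standard
#'   errors, the variance-covariance matrix, deviance and iteration info.
#'   Use [generics::tidy()] for per-term odds ratios with Wald intervals.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(-0.5 + x))
#' fit <- fit_logistic(y, cbind(`(Intercept)` = 1, x = x))
#' tidy(fit, exponentiate = TRUE)
fit_logistic <- function(outcome, design) {
  y <- as.numeric(outcome)
  X <- if (is.data.frame(design)) model.matrix(~ ., design) else as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n < ncol(X)) abort("fit_logistic: fewer complete rows than parameters")
  if (!all(y %in% c(0, 1))) abort("fit_logistic: outcome must be binary 0/1")
  if (length(unique(y)) < 2) abort("fit_logistic: outcome is constant")

  p <- ncol(X)
  beta <- rep(0, p)
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  XtWX <- NULL
  for (iter in seq_len(50L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    dev_new <- -2 * sum(ifelse(y == 1, log(pmax(mu, 1e-300)),
                               log(pmax(1 - mu, 1e-300))))
    if (max(abs(score)) < 1e-8 ||
        abs(dev - dev_new) / (abs(dev_new) + 0.1) < 1e-10) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
    z <- eta + (y - mu) / pmax(w, 1e-10)
    XtWX <- crossprod(X, X * w)
    beta <- drop(solve(XtWX, crossprod(X, w * z)))
    if (any(abs(beta) > 30)) {
      abort("fit_logistic: perfect separation detected (diverging coefficients)")
    }
  }
  if (!converged) abort("fit_logistic: IRLS did not converge in 50 iterations")

  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  vcov <- solve(crossprod(X, X * w))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))

  structure(list(
    coefficients = setNames(beta, colnames(X)),
    std_error = setNames(se, colnames(X)),
    vcov = vcov,
    deviance = dev,
    n_used = n,
    iterations = iter,
    converged = converged
  ), class = "hbsr_logit")
}

#' @export
print.hbsr_logit <- function(x, ...) {
  cat("<hbsr_logit> logistic fit (IRLS), n =", x$n_used,
      "| deviance =", format(x$deviance, digits = 6),
      "|", x$iterations, "iterations\n")
  print(round(rbind(coef = x$coefficients, se = x$std_error), 4))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x An `hbsr_logit` object.
#' @param exponentiate Report odds ratios (`exp(coef)`) instead of log-odds.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   Wald z statistic, p-value and confidence bounds.
#' @method tidy hbsr_logit
#' @export
tidy.hbsr_logit <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  se <- x$std_error
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - zq * se),
    conf.high = unname(est + zq * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a logistic fit
#'
#' @param x An `hbsr_logit` object.
#' @param ... Unused.
#' @return One-row tibble with deviance, sample size and convergence info.
#' @method glance hbsr_logit
#' @export
glance.hbsr_logit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, n_used = x$n_used,
                 iterations = x$iterations, converged = x$converged)
}

#' Compare mean HBSR scores between two groups
#'
#' Two-sided t-test on the complete scores of two groups (Welch by
#' default, Student's pooled-variance test as an option), together with
#' each group's mean, SD and normal-approximation 95% CI
#' (mean +/- 1.96 sd/sqrt(n)).
#'
#' @param scores1,scores2 Numeric score vectors; missing values dropped.
#' @param var_equal Use the pooled-variance (Student) test.
#' @return One-row tibble: per-group `n`, `mean`, `sd`, CI bounds, then
#'   `statistic` (t), `df`, `p` and `method`.
#' @export
#' @examples
#' mean_score_ttest(c(0, 0, 2, 2), c(1, 1, 1, 1))   # equal means, p = 1
mean_score_ttest <- function(scores1, scores2, var_equal = FALSE) {
  s1 <- scores1[!is.na(scores1)]
  s2 <- scores2[!is.na(scores2)]
  if (length(s1) < 2 || length(s2) < 2) {
    abort("mean_score_ttest: each group needs at least 2 complete scores")
  }
  if (stats::sd(s1) == 0 && stats::sd(s2) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(s1) + length(s2) - 2),
               p.value = if (mean(s1) == mean(s2)) 1 else 0)
  } else {
    tt <- stats::t.test(s1, s2, var.equal = var_equal)
  }
  ci <- function(x) mean(x) + c(-1, 1) * 1.96 * stats::sd(x) / sqrt(length(x))
  c1 <- ci(s1); c2 <- ci(s2)
  tibble::tibble(
    n1 = length(s1), mean1 = mean(s1), sd1 = stats::sd(s1),
    ci1_low = c1[1], ci1_high = c1[2],
    n2 = length(s2), mean2 = mean(s2), sd2 = stats::sd(s2),
    ci2_low = c2[1], ci2_high = c2[2],
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    method = if (var_equal) "two-sided t-test (pooled variance)" else "two-sided t-test (Welch)"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
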