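#' Two-sample test of proportions
#'
#' Pooled two-sample z-test, \eqn{z = (p_1-p_2)/\sqrt{\hat p(1-\hat p)(1/n_1
#' + 1/n_2)}} with \eqn{\hat p = (k_1+k_2)/(n_1+n_2)}, without continuity
#' correction by default. Per-group 95% confidence intervals are Wilson score
#' intervals (well behaved at small n).
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param conf_level confidence level of the per-group intervals.
#' @param correct apply the continuity correction to z.
#' @return list of class `allonet_proptest`: `p1`, `p2`, `ci1`, `ci2`, `z`,
#'   `p_value`, `alternative`.
#' @export
test_proportions <- function(k1, n1, k2, n2,
                             alternative = c("two.sided", "greater", "less"),
                             conf_level = 0.95, correct = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  num <- p1 - p2
  if (correct) num <- sign(num) * max(0, abs(num) - 0.5 * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else num / se
  p_value <- switch(alternative,
                    two.sided = 2 * stats::pnorm(-abs(z)),
                    greater = stats::pnorm(z, lower.tail = FALSE),
                    less = stats::pnorm(z))
  structure(list(p1 = p1, p2 = p2,
                 ci1 = wilson_ci(k1, n1, conf_level),
                 ci2 = wilson_ci(k2, n2, conf_level),
                 z = z, p_value = min(p_value, 1),
                 alternative = alternative),
            class = "allonet_proptest")
}

#' Wilson score confidence interval for a proportion
#' @param k,n successes and total.
#' @param conf_level confidence level.
#' @return numeric length-2 interval.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, center - half), min(1, center + half))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with tie correction. For `min(n) <= 8` (and a feasible
#' enumeration size) the p-value is exact, computed by enumerating all
#' assignments of the pooled ranks to the first sample, which remains valid
#' under ties; larger samples use the tie-corrected normal approximation
#' (no continuity correction).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max_n exact path is used when `min(n)` is at most this.
#' @return list of class `allonet_wilcoxon`: `statistic` (Mann-Whitney U of
#'   `x`), `p_value`, `method` ("exact" or "normal"), `alternative`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max_n = 8) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  exact_ok <- min(nx, ny) <= exact_max_n &&
    choose(nx + ny, min(nx, ny)) <= 2e6
  if (exact_ok) {
    idx <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    tol <- 1e-9
    p_ge <- mean(u_all >= u_obs - tol)
    p_le <- mean(u_all <= u_obs + tol)
    p_value <- switch(alternative,
                      greater = p_ge,
                      less = p_le,
                      two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_sizes <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 *
      (n + 1 - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p_value <- switch(alternative,
                      greater = stats::pnorm(z, lower.tail = FALSE),
                      less = stats::pnorm(z),
                      two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = u_obs, p_value = min(p_value, 1),
                 method = method, alternative = alternative),
            class = "allonet_wilcoxon")
}

#' ANCOVA with one covariate and a binary group factor
#'
#' Ordinary least squares `y ~ x + g` with an F-test on the group term
#' (single factor, so the type-II and sequential tests coincide). Rows can be
#' excluded up front via `exclude` (e.g. inhibitor-bound structures).
#'
#' @param y response.
#' @param x continuous covariate.
#' @param g binary group (factor, character or 0/1); the reported offset is
#'   the effect of the second level relative to the first.
#' @param exclude logical mask of rows to drop before fitting.
#' @return list of class `allonet_ancova`: `coefficients` (intercept,
#'   covariate slope, group offset), `F`, `p_value`, `n`, `excluded_rows`,
#'   `fit` (the `lm` object).
#' @export
ancova <- function(y, x, g, exclude = NULL) {
  if (is.null(exclude)) exclude <- rep(FALSE, length(y))
  stopifnot(length(y) == length(x), length(y) == length(g),
            length(y) == length(exclude))
  keep <- !exclude & !is.na(y) & !is.na(x) & !is.na(g)
  y <- y[keep]; x <- x[keep]; g <- factor(g[keep])
  if (length(y) < 4) stop("fewer than 4 rows after exclusion")
  if (nlevels(g) != 2) stop("group factor must have exactly 2 levels")
  if (stats::var(x) == 0 && nlevels(g) < 2) stop("singular design")
  fit <- stats::lm(y ~ x + g)
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  dr <- stats::drop1(fit, scope = ~g, test = "F")
  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("intercept", "slope",
                                                  "group_offset")),
                 F = dr[["F value"]][2], p_value = dr[["Pr(>F)"]][2],
                 n = length(y), excluded_rows = sum(exclude),
                 group_levels = levels(g), fit = fit),
            class = "allonet_ancova")
}

#' @export
print.allonet_proptest <- function(x, ...) {
  cat(sprintf("two-sample test of proportions: p1 = %.3f, p2 = %.3f, z = %.3f, p = %.3g (%s)\n",
              x$p1, x$p2, x$z, x$p_value, x$alternative))
  invisible(x)
}

#' @export
print.allonet_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA (n = %d, %d excluded): group offset = %.4f, F = %.3f, p = %.3g\n",
              x$n, x$excluded_rows, x$coefficients["group_offset"], x$F,
              x$p_value))
  invisible(x)
}
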