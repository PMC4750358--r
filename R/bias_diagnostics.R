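# Publication-bias diagnostics: Egger regression, Begg rank correlation,
# funnel-plot export.

new_bias_test <- function(method, statistic, dispersion, p_value, k, note = NULL) {
  structure(list(method = method, statistic = statistic,
                 dispersion = dispersion, p_value = p_value, k = k,
                 note = note), class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  name <- c(egger = "Egger regression asymmetry test",
            begg = "Begg rank-correlation test")[x$method]
  stat <- c(egger = "intercept", begg = "Kendall tau")[x$method]
  cat(sprintf("%s (k = %d)\n  %s = %.4f, p = %.4f\n",
              name, x$k, stat, x$statistic, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Classic formulation: ordinary least-squares regression of the
#' standardized effect `y_i/se_i` on the precision `1/se_i`; the intercept
#' estimates small-study asymmetry and is tested two-sided against a t
#' distribution on k - 2 df. The weighted variant (`weighted = TRUE`)
#' regresses `y_i` on `se_i` with weights `1/se_i^2` and tests the
#' coefficient of `se_i`.
#'
#' @inheritParams fixed_effect_pool
#' @param weighted Use the weighted variant (default `FALSE`, the classic
#'   unweighted regression).
#' @return A `bias_test` with `method = "egger"`, the asymmetry
#'   `statistic`, its standard error (`dispersion`) and two-sided
#'   `p_value`.
#' @export
egger_test <- function(y, se, weighted = FALSE) {
  k <- check_estimates(y, se, 3L)
  if (weighted) {
    x <- se
    z <- y
    wts <- 1 / se^2
  } else {
    x <- 1 / se
    z <- y / se
    wts <- NULL
  }
  if (stats::var(x) == 0) {
    if (stats::var(z) == 0)
      return(new_bias_test("egger", 0, NA_real_, 1, k,
                           "degenerate: identical estimates"))
    stop("Egger regressor degenerate: all precisions equal with unequal effects")
  }
  fit <- if (weighted) stats::lm(z ~ x, weights = wts) else stats::lm(z ~ x)
  coefs <- summary(fit)$coefficients
  target <- if (weighted) "x" else "(Intercept)"
  est <- coefs[target, "Estimate"]
  se_est <- coefs[target, "Std. Error"]
  p <- 2 * stats::pt(abs(est / se_est), df = k - 2, lower.tail = FALSE)
  new_bias_test("egger", est, se_est, p, k)
}

# Kendall S statistic (concordant minus discordant pairs) and its null
# variance with tie correction, as used by the rank-correlation bias test.
kendall_s <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(a[-seq_len(i)] - a[i]) * sign(b[-seq_len(i)] - b[i]))
  }
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) * (2 * t + 5))
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term(a) - tie_term(b)) / 18
  list(s = s, var_s = var_s)
}

#' Begg and Mazumdar's rank-correlation test for publication bias
#'
#' Kendall rank correlation between the variance-stabilized standardized
#' deviates `(y_i - y_fixed)/sqrt(se_i^2 - se_fixed^2)` and the sampling
#' variances `se_i^2`. The default p-value uses the normal approximation to
#' Kendall's S with tie correction and a continuity correction; for
#' k <= 8 an exact permutation p-value is available.
#'
#' @inheritParams fixed_effect_pool
#' @param correction Apply the continuity correction (default `TRUE`).
#' @param exact Exact permutation p-value (only for k <= 8; default
#'   `FALSE`).
#' @return A `bias_test` with `method = "begg"`, Kendall `statistic` (tau,
#'   in \[-1, 1\]), the null variance of S (`dispersion`) and two-sided
#'   `p_value`.
#' @export
begg_test <- function(y, se, correction = TRUE, exact = FALSE) {
  k <- check_estimates(y, se, 3L)
  v <- se^2
  if (length(unique(v)) == 1L) {
    message("all sampling variances equal: Begg tau undefined, p = 1")
    return(new_bias_test("begg", 0, NA_real_, 1, k,
                         "degenerate: equal variances"))
  }
  fe <- fixed_effect_pool(y, se)
  v_pooled <- fe$se_pooled^2
  t_i <- (y - fe$y_pooled) / sqrt(v - v_pooled)
  ks <- kendall_s(t_i, v)
  n_pairs <- k * (k - 1) / 2
  tau <- ks$s / n_pairs
  if (exact) {
    if (k > 8) stop("exact permutation p-value limited to k <= 8")
    perms <- permutations_of(k)
    s_obs <- abs(ks$s)
    s_perm <- apply(perms, 1, function(idx) abs(kendall_s(t_i[idx], v)$s))
    p <- mean(s_perm >= s_obs)
  } else {
    z <- if (correction) max(0, abs(ks$s) - 1) / sqrt(ks$var_s) else
      abs(ks$s) / sqrt(ks$var_s)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
  }
  new_bias_test("begg", tau, ks$var_s, p, k)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

#' Funnel-plot data export
#'
#' One row per unit (OR-scale effect, standard error, precision) together
#' with the pooled reference line and pseudo-95% funnel boundaries
#' `exp(y_pooled +/- 1.96 se)` evaluated on a standard-error grid.
#'
#' @param effects An `effect_table`.
#' @param pooled Optional `pooled_result` giving the centre line; computed
#'   by [pool_effects()] when omitted.
#' @return A `funnel_data` data.frame (`label`, `or`, `y`, `se`,
#'   `precision`) with attributes `center` (pooled OR) and `boundaries`
#'   (data.frame `se`, `lower`, `upper`).
#' @export
funnel_data <- function(effects, pooled = NULL) {
  stopifnot(nrow(effects) >= 1L)
  if (is.null(pooled)) pooled <- pool_effects(effects)
  out <- data.frame(label = effects$label, or = effects$or, y = effects$y,
                    se = effects$se, precision = 1 / effects$se,
                    stringsAsFactors = FALSE)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = 50)
  attr(out, "center") <- pooled$or
  attr(out, "boundaries") <- data.frame(
    se = se_grid,
    lower = exp(pooled$y_pooled - 1.96 * se_grid),
    upper = exp(pooled$y_pooled + 1.96 * se_grid))
  class(out) <- c("funnel_data", "data.frame")
  out
}
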