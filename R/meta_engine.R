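# Pooling engine: inverse-variance fixed effect, DerSimonian-Laird random
# effects, heterogeneity statistics, subgroups, leave-one-out, Galbraith.

check_estimates <- function(y, se, k_min = 1L) {
  stopifnot(length(y) == length(se), length(y) >= k_min,
            all(is.finite(y)), all(is.finite(se)), all(se > 0))
  invisible(length(y))
}

resolve_labels <- function(labels, k) {
  if (is.null(labels)) paste0("study_", seq_len(k)) else as.character(labels)
}

new_pooled_result <- function(k, y_pooled, se_pooled, q, df, tau2, weights,
                              labels, method) {
  p_het <- if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  structure(list(
    k = k, y_pooled = y_pooled, se_pooled = se_pooled,
    or = exp(y_pooled),
    ci_lower = exp(y_pooled - 1.96 * se_pooled),
    ci_upper = exp(y_pooled + 1.96 * se_pooled),
    q = q, df = df, p_heterogeneity = p_het,
    tau2 = tau2, i2 = i_squared(q, df),
    weights = stats::setNames(weights, labels),
    labels = labels, method = method), class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s pool of %d units\n",
              if (x$method == "DL") "DerSimonian-Laird random-effects"
              else "Inverse-variance fixed-effect",
              x$k))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f)\n", x$or, x$ci_lower, x$ci_upper))
  cat(sprintf("  Q = %.2f on %d df (p = %s), tau2 = %.4f, I2 = %.1f%%\n",
              x$q, x$df,
              if (is.na(x$p_heterogeneity)) "NA" else
                sprintf("%.3f", x$p_heterogeneity),
              x$tau2, x$i2))
  invisible(x)
}

#' Inverse-variance fixed-effect pool
#'
#' Pools log odds ratios with weights `w_i = 1/se_i^2`:
#' `y = sum(w y) / sum(w)`, `se = 1/sqrt(sum(w))`. Also the internal first
#' pass of the DerSimonian-Laird estimator.
#'
#' @param y Log odds ratios.
#' @param se Their standard errors (positive).
#' @param labels Optional unit labels.
#' @return A `pooled_result` (with `tau2 = 0` by construction).
#' @export
fixed_effect_pool <- function(y, se, labels = NULL) {
  k <- check_estimates(y, se, 1L)
  labels <- resolve_labels(labels, k)
  w <- 1 / se^2
  y_pooled <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_pooled)^2)
  new_pooled_result(k, y_pooled, 1 / sqrt(sum(w)), q, k - 1L, 0, w,
                    labels, "fixed")
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (y_i - y_fixed)^2)` with fixed-effect weights, referred to
#' a chi-square distribution on k - 1 df.
#'
#' @inheritParams fixed_effect_pool
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(y, se) {
  k <- check_estimates(y, se, 2L)
  w <- 1 / se^2
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  list(q = q, df = k - 1L, p = stats::pchisq(q, k - 1L, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - df)/Q) * 100`; 0% means no observed heterogeneity,
#' values around 25/50/75% are conventionally read as low/moderate/high.
#'
#' @param q Cochran's Q.
#' @param df Its degrees of freedom (k - 1).
#' @return Percentage in \[0, 100\].
#' @export
i_squared <- function(q, df) {
  if (q <= 0) return(0)
  max(0, (q - df) / q) * 100
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator `tau2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)` and fixed-effect weights `w = 1/se^2`.
#'
#' @inheritParams fixed_effect_pool
#' @return Non-negative `tau2` (0 when `Q <= df`).
#' @export
dl_tau2 <- function(y, se) {
  check_estimates(y, se, 2L)
  w <- 1 / se^2
  q <- cochran_q(y, se)$q
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(y) - 1)) / C)
}

#' DerSimonian-Laird random-effects pool
#'
#' Re-weights each unit by `w*_i = 1/(se_i^2 + tau2)` with the
#' method-of-moments `tau2` from [dl_tau2()], and reports the Wald 95% CI
#' `exp(y +/- 1.96 se)` together with Q, its p-value, tau-squared and
#' I-squared. A single unit degenerates to that estimate; a homogeneous set
#' (`Q <= df`) reduces exactly to [fixed_effect_pool()].
#'
#' @inheritParams fixed_effect_pool
#' @return A `pooled_result` with `method = "DL"`.
#' @export
random_effects_pool <- function(y, se, labels = NULL) {
  k <- check_estimates(y, se, 1L)
  labels <- resolve_labels(labels, k)
  if (k == 1L)
    return(new_pooled_result(1L, y, se, 0, 0L, 0, 1 / se^2, labels, "DL"))
  tau2 <- dl_tau2(y, se)
  q <- cochran_q(y, se)$q
  w_star <- 1 / (se^2 + tau2)
  y_pooled <- sum(w_star * y) / sum(w_star)
  new_pooled_result(k, y_pooled, 1 / sqrt(sum(w_star)), q, k - 1L, tau2,
                    w_star, labels, "DL")
}

#' Pool an effect table
#'
#' Convenience wrapper dispatching an `effect_table` (from
#' [study_effects()]) to the fixed- or random-effects engine.
#'
#' @param effects An `effect_table`.
#' @param method `"random"` (default) or `"fixed"`.
#' @return A `pooled_result`.
#' @export
pool_effects <- function(effects, method = c("random", "fixed")) {
  method <- match.arg(method)
  if (method == "random") {
    random_effects_pool(effects$y, effects$se, effects$label)
  } else {
    fixed_effect_pool(effects$y, effects$se, effects$label)
  }
}

#' Stratified (subgroup) meta-analysis
#'
#' Splits one SNP's studies by a stratification factor and pools each level
#' independently with [random_effects_pool()] (tau-squared re-estimated per
#' stratum). Shared-control strata are aggregated first, except when
#' stratifying by tumour site, where the shared-control rows are distinct
#' strata by construction. Levels with a single unit are pooled degenerately
#' and flagged.
#'
#' @param records A `study_table`.
#' @param factor One of `"design"`, `"ethnicity"`, `"sample_size"`,
#'   `"tumour_site"`.
#' @param snp_id Optional SNP filter; required when `records` spans several
#'   SNPs.
#' @param model Optional genetic-model override passed to [study_effects()].
#' @return Named list of `pooled_result`s (one per level, level order by
#'   first appearance), each with attribute `degenerate` when k = 1;
#'   attribute `factor` on the list.
#' @export
subgroup_analysis <- function(records, factor = c("design", "ethnicity",
                                                  "sample_size",
                                                  "tumour_site"),
                              snp_id = NULL, model = NULL) {
  factor <- match.arg(factor)
  if (!is.null(snp_id)) records <- records[records$snp_id == snp_id, ,
                                           drop = FALSE]
  stopifnot(nrow(records) > 0L, length(unique(records$snp_id)) == 1L)
  effects <- study_effects(records, model = model)
  if (factor != "tumour_site")
    effects <- aggregate_shared_controls(effects)
  level_of <- effects[[factor]]
  out <- list()
  for (lev in unique(level_of[!is.na(level_of)])) {
    sub <- effects[!is.na(level_of) & level_of == lev, , drop = FALSE]
    pooled <- random_effects_pool(sub$y, sub$se, sub$label)
    if (pooled$k == 1L) attr(pooled, "degenerate") <- TRUE
    out[[lev]] <- pooled
  }
  attr(out, "factor") <- factor
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the random-effects pool omitting each unit in turn; tau-squared
#' is re-estimated in every iteration. Identifies units whose removal
#' materially shifts the pooled estimate or collapses the heterogeneity.
#'
#' @inheritParams fixed_effect_pool
#' @return Data frame with one row per omitted unit: `omitted`, `k`, `or`,
#'   `ci_lower`, `ci_upper`, `q`, `tau2`, `i2`.
#' @export
leave_one_out <- function(y, se, labels = NULL) {
  k <- check_estimates(y, se, 3L)
  labels <- resolve_labels(labels, k)
  rows <- lapply(seq_len(k), function(i) {
    p <- random_effects_pool(y[-i], se[-i], labels[-i])
    data.frame(omitted = labels[i], k = p$k, or = p$or,
               ci_lower = p$ci_lower, ci_upper = p$ci_upper,
               q = p$q, tau2 = p$tau2, i2 = p$i2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Galbraith (radial) outlier diagnostics
#'
#' For each unit, the standardized effect `y_i/se_i` is compared with the
#' fixed-effect regression line through the origin (slope = fixed-effect
#' pooled log OR), giving the residual `(y_i - y_fixed)/se_i`. Units with
#' `|residual|` above the conventional +/-2 band contribute
#' disproportionately to Cochran's Q and are flagged as outliers.
#'
#' @inheritParams fixed_effect_pool
#' @param threshold Outlier band half-width on the residual scale
#'   (default 2).
#' @return Data frame with `label`, `precision` (1/se),
#'   `standardized_effect` (y/se), `residual`, `outlier`.
#' @export
galbraith <- function(y, se, labels = NULL, threshold = 2) {
  k <- check_estimates(y, se, 3L)
  labels <- resolve_labels(labels, k)
  y_fixed <- fixed_effect_pool(y, se)$y_pooled
  residual <- (y - y_fixed) / se
  data.frame(label = labels, precision = 1 / se,
             standardized_effect = y / se, residual = residual,
             outlier = abs(residual) > threshold,
             stringsAsFactors = FALSE)
}

#' Forest-plot data export
#'
#' One row per unit (OR, CI bounds, percentage random-effects weight) plus
#' a final pooled row, in the shape used to draw a forest plot.
#'
#' @param effects An `effect_table`.
#' @param pooled Optional `pooled_result`; computed by [pool_effects()]
#'   when omitted.
#' @return Data frame with `label`, `or`, `ci_lower`, `ci_upper`,
#'   `weight_pct`, `pooled` (logical marker for the summary row).
#' @export
forest_data <- function(effects, pooled = NULL) {
  if (is.null(pooled)) pooled <- pool_effects(effects)
  w <- 100 * pooled$weights / sum(pooled$weights)
  rbind(
    data.frame(label = effects$label, or = effects$or,
               ci_lower = effects$lcl, ci_upper = effects$ucl,
               weight_pct = as.numeric(w), pooled = FALSE,
               stringsAsFactors = FALSE),
    data.frame(label = sprintf("RE pool (k = %d)", pooled$k),
               or = pooled$or, ci_lower = pooled$ci_lower,
               ci_upper = pooled$ci_upper, weight_pct = 100, pooled = TRUE,
               stringsAsFactors = FALSE))
}
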