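# Per-study effect extraction: 2x2 odds ratios, genotype collapsing,
# CI back-transformation, genetic-model selection, HWE screening.

new_effect_estimate <- function(y, se, label = NULL) {
  y <- unname(y)
  se <- unname(se)
  stopifnot(is.finite(y), is.finite(se), se > 0)
  structure(list(y = y, se = se, or = exp(y),
                 lcl = exp(y - 1.96 * se), ucl = exp(y + 1.96 * se),
                 label = label),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%sOR %.2f (95%% CI %.2f-%.2f)  logOR %.4f  SE %.4f\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$or, x$lcl, x$ucl, x$y, x$se))
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' Computes the log odds ratio `ln[(a d)/(b c)]` for the table
#' (a = exposed cases, b = unexposed cases, c = exposed controls,
#' d = unexposed controls) with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero the
#' Haldane-Anscombe continuity `correction` is added to all four cells
#' (with a message); tables left with a zero cell after correction are an
#' error.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative cell counts.
#' @param correction Non-negative value added to every cell when any cell
#'   is zero (default 0.5).
#' @param label Optional provenance label.
#' @return An `effect_estimate` (log OR `y`, standard error `se`, OR-scale
#'   `or`/`lcl`/`ucl`).
#' @export
#' @examples
#' odds_ratio_from_2x2(20, 80, 10, 90)  # OR 2.25
odds_ratio_from_2x2 <- function(exposed_cases, unexposed_cases,
                                exposed_controls, unexposed_controls,
                                correction = 0.5, label = NULL) {
  cells <- as.numeric(c(exposed_cases, unexposed_cases,
                        exposed_controls, unexposed_controls))
  stopifnot(all(cells >= 0), correction >= 0)
  if (any(cells == 0)) {
    cells <- cells + correction
    message("zero cell: continuity correction ", correction,
            " added to all cells",
            if (!is.null(label)) paste0(" (", label, ")") else "")
  }
  if (any(cells == 0)) stop("odds ratio undefined: zero cell after correction")
  y <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  new_effect_estimate(y, se, label)
}

#' Collapse genotype counts under a genetic model
#'
#' Recessive: exposed = homozygous mutant (mtmt), unexposed = wild-type
#' carriers (wtwt + wtmt). Dominant: exposed = mutant carriers
#' (wtmt + mtmt), unexposed = wtwt. Applied identically to cases and
#' controls.
#'
#' @param counts Named numeric vector (or one-row data.frame/list) with
#'   `cases_wtwt`, `cases_wtmt`, `cases_mtmt`, `controls_wtwt`,
#'   `controls_wtmt`, `controls_mtmt`.
#' @param model `"recessive"` or `"dominant"`.
#' @return Numeric vector `c(exposed_cases, unexposed_cases,
#'   exposed_controls, unexposed_controls)`.
#' @export
collapse_genotypes <- function(counts, model = c("recessive", "dominant")) {
  model <- match.arg(model)
  counts <- unlist(counts)[genotype_columns]
  stopifnot(all(!is.na(counts)), all(counts >= 0))
  if (model == "recessive") {
    out <- c(exposed_cases = counts[["cases_mtmt"]],
             unexposed_cases = counts[["cases_wtwt"]] + counts[["cases_wtmt"]],
             exposed_controls = counts[["controls_mtmt"]],
             unexposed_controls = counts[["controls_wtwt"]] +
               counts[["controls_wtmt"]])
  } else {
    out <- c(exposed_cases = counts[["cases_wtmt"]] + counts[["cases_mtmt"]],
             unexposed_cases = counts[["cases_wtwt"]],
             exposed_controls = counts[["controls_wtmt"]] +
               counts[["controls_mtmt"]],
             unexposed_controls = counts[["controls_wtwt"]])
  }
  out
}

#' Recover a log odds ratio and SE from a reported OR and 95% CI
#'
#' Inverts the Wald interval: `y = ln(or)` and
#' `se = (ln(ucl) - ln(lcl)) / (2 * 1.96)`, so that
#' `exp(y +/- 1.96 se)` reproduces the bounds. Published tables print ORs
#' to two decimals; the recovered `y` therefore carries that rounding.
#'
#' @param or,lcl,ucl Reported odds ratio and its 95% confidence bounds
#'   (`0 < lcl < ucl`).
#' @param label Optional provenance label.
#' @return An `effect_estimate`.
#' @export
#' @examples
#' effect_from_reported(2.0, 1.0, 4.0)  # y = ln 2, se = ln(4)/3.92
effect_from_reported <- function(or, lcl, ucl, label = NULL) {
  stopifnot(is.finite(or), is.finite(lcl), is.finite(ucl), or > 0)
  if (!(lcl > 0 && lcl < ucl))
    stop("invalid confidence interval: need 0 < lcl < ucl")
  new_effect_estimate(log(or), (log(ucl) - log(lcl)) / (2 * 1.96), label)
}

#' Choose between the recessive and dominant genetic model
#'
#' Compares the crude heterozygote contrast OR1 (wtmt vs wtwt) with the
#' homozygote contrast OR2 (mtmt vs wtwt). "Different from 1" is read as
#' the 95% CI excluding 1. The decision rules are: recessive when OR2
#' differs from 1 but OR1 does not; dominant when both differ from 1.
#' When neither pattern holds the tie-break picks recessive iff
#' `|log OR2| >= |log OR1|`, else dominant.
#'
#' @param or1,or2 `effect_estimate`s for the heterozygote and homozygote
#'   contrasts.
#' @return A `model_selection` list: `or1`, `or2`, `chosen`
#'   (`"recessive"` / `"dominant"`) and `rule` (which rule fired).
#' @export
select_genetic_model <- function(or1, or2) {
  stopifnot(inherits(or1, "effect_estimate"), inherits(or2, "effect_estimate"))
  excludes_1 <- function(e) e$lcl > 1 || e$ucl < 1
  sel <- if (excludes_1(or2) && !excludes_1(or1)) {
    list(chosen = "recessive", rule = "OR2 != 1 and OR1 = 1")
  } else if (excludes_1(or2) && excludes_1(or1)) {
    list(chosen = "dominant", rule = "OR2 = OR1 != 1")
  } else {
    list(chosen = if (abs(or2$y) >= abs(or1$y)) "recessive" else "dominant",
         rule = "tie-break on |log OR|")
  }
  structure(list(or1 = or1, or2 = or2, chosen = sel$chosen, rule = sel$rule),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Genetic model selection\n")
  cat(sprintf("  OR1 (wtmt vs wtwt): %.2f (%.2f-%.2f)\n",
              x$or1$or, x$or1$lcl, x$or1$ucl))
  cat(sprintf("  OR2 (mtmt vs wtwt): %.2f (%.2f-%.2f)\n",
              x$or2$or, x$or2$lcl, x$or2$ucl))
  cat("  chosen:", x$chosen, "| rule:", x$rule, "\n")
  invisible(x)
}

#' Hardy-Weinberg equilibrium test on a control series
#'
#' Pearson goodness-of-fit test (1 df) of the observed control genotype
#' counts against the HWE expectations p^2, 2pq, q^2 at the observed allele
#' frequency, or the exact conditional test on the heterozygote count when
#' `exact = TRUE`. Monomorphic series return chi-square 0 and p 1 by
#' convention (with a message). Series with `p <= alpha` are marked for
#' exclusion (the boundary p = alpha is excluded).
#'
#' @param controls_wtwt,controls_wtmt,controls_mtmt Control genotype counts.
#' @param alpha Exclusion threshold (default 0.01).
#' @param exact Use the exact conditional test instead of the asymptotic
#'   chi-square (default `FALSE`).
#' @return An `hwe_result` list: `chi_square`, `p_value`, `excluded`,
#'   `allele_freq`, `method`.
#' @export
#' @examples
#' hwe_test(30, 40, 30)  # chi-square 4, p ~ 0.0455
hwe_test <- function(controls_wtwt, controls_wtmt, controls_mtmt,
                     alpha = 0.01, exact = FALSE) {
  obs <- c(controls_wtwt, controls_wtmt, controls_mtmt)
  stopifnot(all(obs >= 0), sum(obs) >= 1, alpha > 0, alpha < 1)
  n <- sum(obs)
  q <- (obs[2] + 2 * obs[3]) / (2 * n)  # mutant allele frequency
  if (q == 0 || q == 1) {
    message("monomorphic control series: HWE test degenerate, p = 1")
    return(structure(list(chi_square = 0, p_value = 1, excluded = FALSE,
                          allele_freq = q, method = "chi-square"),
                     class = "hwe_result"))
  }
  if (exact) {
    p_val <- hwe_exact_p(obs[1], obs[2], obs[3])
    chi <- NA_real_
    method <- "exact"
  } else {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi <- sum((obs - expected)^2 / expected)
    p_val <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(chi_square = chi, p_value = p_val,
                 excluded = p_val <= alpha, allele_freq = q, method = method),
            class = "hwe_result")
}

# Exact HWE p-value: probability, conditional on the allele counts, of a
# heterozygote count at least as improbable as the observed one.
hwe_exact_p <- function(aa, ab, bb) {
  n <- aa + ab + bb
  n_b <- ab + 2 * bb          # mutant allele count; symmetric in the allele
  het_parity <- n_b %% 2
  hets <- seq(het_parity, min(n_b, 2 * n - n_b), by = 2)
  # conditional distribution of the heterozygote count given allele counts
  log_prob <- hets * log(2) + lfactorial(n) -
    lfactorial((n_b - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_b + hets) / 2) +
    lfactorial(n_b) + lfactorial(2 * n - n_b) - lfactorial(2 * n)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[hets == ab] * (1 + 1e-12)])
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test: chi2 = %s, p = %.4g, allele freq = %.3f -> %s\n",
              x$method,
              if (is.na(x$chi_square)) "NA" else sprintf("%.3f", x$chi_square),
              x$p_value, x$allele_freq,
              if (x$excluded) "EXCLUDE" else "keep"))
  invisible(x)
}

#' Screen a study table for Hardy-Weinberg disequilibrium in controls
#'
#' Applies [hwe_test()] to every row carrying control genotype counts and
#' removes rows with `p <= alpha`. Rows without genotype counts (e.g.
#' literature rows that only print an OR/CI and whose source asserts HWE
#' compliance) pass through untested.
#'
#' @param records A `study_table`.
#' @inheritParams hwe_test
#' @return List with `records` (kept rows), `excluded` (removed rows) and
#'   `log` (one row per tested study: label, chi-square, p, decision).
#' @export
hwe_filter <- function(records, alpha = 0.01, exact = FALSE) {
  n <- nrow(records)
  drop <- logical(n)
  logs <- list()
  for (i in seq_len(n)) {
    ctl <- unlist(records[i, c("controls_wtwt", "controls_wtmt",
                               "controls_mtmt")])
    if (any(is.na(ctl))) next
    res <- hwe_test(ctl[1], ctl[2], ctl[3], alpha = alpha, exact = exact)
    drop[i] <- res$excluded
    logs[[length(logs) + 1L]] <- data.frame(
      label = study_label(records[i, ]),
      chi_square = res$chi_square, p_value = res$p_value,
      excluded = res$excluded, stringsAsFactors = FALSE)
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(label = character(), chi_square = numeric(),
               p_value = numeric(), excluded = logical(),
               stringsAsFactors = FALSE)
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, excluded = records[drop, , drop = FALSE], log = log_df)
}
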