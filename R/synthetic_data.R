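# Genotype-level simulator: case-control studies under HWE with a
# configurable genetic model, between-study heterogeneity and
# publication-bias censoring.

#' Simulation configuration
#'
#' Describes a synthetic collection of case-control genotype studies.
#' Controls are drawn multinomially under Hardy-Weinberg proportions at the
#' mutant-allele frequency; each study's log odds ratio is
#' `ln(true_or) + N(0, tau2)`; case genotype probabilities tilt the exposed
#' class (per the genetic model) by that study's odds ratio. When explicit
#' study sizes are not given, case counts are drawn log-uniformly in
#' \[100, 2000\] with controls = cases x Uniform(0.8, 1.5), echoing the
#' spread of published study sizes. With `bias_severity > 0`, studies whose
#' collapsed-OR 95% CI contains 1 are censored with that probability
#' (publication-bias emulation).
#'
#' @param allele_freq Mutant-allele frequency in controls, in (0, 1).
#' @param true_or Odds ratio of the exposed genotype class (> 0).
#' @param model `"recessive"` or `"dominant"`.
#' @param n_cases,n_controls Optional fixed per-study sizes (recycled to
#'   `k_studies`); drawn from the size distribution when `NULL`.
#' @param tau2 Between-study variance of the log odds ratio (>= 0).
#' @param k_studies Number of studies to generate.
#' @param bias_severity Censoring probability for non-significant studies,
#'   in \[0, 1\].
#' @param seed Optional integer seed; fully determines the output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(allele_freq = 0.3, true_or = 1.5,
                              model = c("recessive", "dominant"),
                              n_cases = NULL, n_controls = NULL,
                              tau2 = 0, k_studies = 10L,
                              bias_severity = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(allele_freq > 0, allele_freq < 1, true_or > 0, tau2 >= 0,
            k_studies >= 1, bias_severity >= 0, bias_severity <= 1)
  if (!is.null(n_cases)) stopifnot(all(n_cases >= 1))
  if (!is.null(n_controls)) stopifnot(all(n_controls >= 1))
  structure(list(allele_freq = allele_freq, true_or = true_or, model = model,
                 n_cases = n_cases, n_controls = n_controls, tau2 = tau2,
                 k_studies = as.integer(k_studies),
                 bias_severity = bias_severity, seed = seed),
            class = "simulation_config")
}

# Genotype class probabilities (wtwt, wtmt, mtmt) for controls and for
# cases at a given study log OR, under the configured model.
genotype_probs <- function(allele_freq, log_or, model) {
  q <- allele_freq
  ctl <- c(wtwt = (1 - q)^2, wtmt = 2 * q * (1 - q), mtmt = q^2)
  exposed <- if (model == "recessive") c(FALSE, FALSE, TRUE) else
    c(FALSE, TRUE, TRUE)
  p_exp <- sum(ctl[exposed])
  odds_case <- (p_exp / (1 - p_exp)) * exp(log_or)
  p_exp_case <- odds_case / (1 + odds_case)
  cas <- ctl
  cas[exposed] <- ctl[exposed] / p_exp * p_exp_case
  cas[!exposed] <- ctl[!exposed] / (1 - p_exp) * (1 - p_exp_case)
  list(controls = ctl, cases = cas)
}

simulate_study_impl <- function(config, index = 1L) {
  n_cases <- if (is.null(config$n_cases)) {
    round(exp(stats::runif(1, log(100), log(2000))))
  } else {
    rep_len(config$n_cases, config$k_studies)[index]
  }
  n_controls <- if (is.null(config$n_controls)) {
    round(n_cases * stats::runif(1, 0.8, 1.5))
  } else {
    rep_len(config$n_controls, config$k_studies)[index]
  }
  theta <- log(config$true_or) +
    if (config$tau2 > 0) stats::rnorm(1, 0, sqrt(config$tau2)) else 0
  pr <- genotype_probs(config$allele_freq, theta, config$model)
  if (any(n_controls * pr$controls < 1) || any(n_cases * pr$cases < 1))
    warning("expected genotype cell count < 1; counts may be degenerate")
  ctl <- as.integer(stats::rmultinom(1, n_controls, pr$controls))
  cas <- as.integer(stats::rmultinom(1, n_cases, pr$cases))
  out <- data.frame(
    snp_id = "rs0000000",
    author = sprintf("Sim%03d", index), year = 2000L + (index %% 26L),
    tumour_site = "lung", country = "Simulated", ethnicity = "Mixed",
    design = "population", n_cases = n_cases, n_controls = n_controls,
    cases_wtwt = cas[1], cases_wtmt = cas[2], cases_mtmt = cas[3],
    controls_wtwt = ctl[1], controls_wtmt = ctl[2], controls_mtmt = ctl[3],
    reported_or = NA_real_, reported_lcl = NA_real_, reported_ucl = NA_real_,
    reported_model = config$model, shared_control_group = "",
    true_log_or = theta,  # hidden truth for recovery tests
    stringsAsFactors = FALSE)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Simulate one case-control genotype study
#'
#' See [simulation_config()] for the generative model. The returned row
#' carries the study's true log odds ratio in the non-schema column
#' `true_log_or` (dropped by [write_study_table()] unless
#' `include_truth = TRUE`).
#'
#' @param config A `simulation_config`. Its `seed`, when non-`NULL`, is set
#'   before drawing, so equal configs give identical counts.
#' @return A one-row `study_table` with genotype counts.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_study_impl(config, 1L)
}

#' Simulate a collection of case-control genotype studies
#'
#' Draws `k_studies` independent studies per [simulate_study()]; when
#' `bias_severity > 0`, each study whose collapsed-OR 95% CI contains 1 is
#' dropped with that probability, emulating the censoring of
#' non-significant results. No refilling: censoring reduces the returned
#' study count.
#'
#' @param config A `simulation_config`.
#' @return A `study_table` with up to `k_studies` rows (hidden
#'   `true_log_or` column included).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- vector("list", config$k_studies)
  for (i in seq_len(config$k_studies)) {
    st <- simulate_study_impl(config, i)
    if (config$bias_severity > 0) {
      tab <- collapse_genotypes(unlist(st[1, genotype_columns]), config$model)
      est <- suppressMessages(
        odds_ratio_from_2x2(tab[1], tab[2], tab[3], tab[4]))
      nonsig <- est$lcl <= 1 && est$ucl >= 1
      if (nonsig && stats::runif(1) < config$bias_severity) next
    }
    rows[[i]] <- st
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- simulate_study_impl(config, 1L)[0, ]
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("study_table", "data.frame")
  out
}
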