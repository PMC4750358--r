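test_that("2x2 odds ratios: arithmetic, continuity correction, errors", {
  bal <- odds_ratio_from_2x2(10, 10, 10, 10)
  expect_equal(bal$y, 0)
  expect_equal(bal$or, 1)

  est <- odds_ratio_from_2x2(20, 80, 10, 90)
  expect_equal(est$or, 2.25)
  expect_equal(est$se, sqrt(1/20 + 1/80 + 1/10 + 1/90))

  # zero cell: all four cells shifted by the correction, direct arithmetic
  expect_message(cor_est <- odds_ratio_from_2x2(0, 50, 10, 40), "zero cell")
  expect_equal(cor_est$y, log((0.5 * 40.5) / (50.5 * 10.5)))
  expect_equal(cor_est$se, sqrt(1/0.5 + 1/50.5 + 1/10.5 + 1/40.5))

  expect_error(
    suppressMessages(odds_ratio_from_2x2(0, 50, 0, 40, correction = 0)),
    "zero cell")
})

test_that("genotype collapsing matches the model definitions", {
  counts <- c(cases_wtwt = 10, cases_wtmt = 20, cases_mtmt = 30,
              controls_wtwt = 30, controls_wtmt = 20, controls_mtmt = 10)
  expect_equal(unname(collapse_genotypes(counts, "recessive")),
               c(30, 30, 10, 50))
  expect_equal(unname(collapse_genotypes(counts, "dominant")),
               c(50, 10, 30, 30))
  # degenerate: no homozygous mutants -> zero exposed cells, correction fires
  none <- counts
  none[c("cases_mtmt", "controls_mtmt")] <- 0
  tab <- collapse_genotypes(none, "recessive")
  expect_equal(unname(tab[c(1, 3)]), c(0, 0))
  expect_message(odds_ratio_from_2x2(tab[1], tab[2], tab[3], tab[4]),
                 "zero cell")
})

test_that("collapse + OR equals the OR of the hand-built 2x2 (property)", {
  set.seed(42)
  for (rep in 1:50) {
    counts <- c(cases_wtwt = sample(1:50, 1), cases_wtmt = sample(1:50, 1),
                cases_mtmt = sample(1:50, 1), controls_wtwt = sample(1:50, 1),
                controls_wtmt = sample(1:50, 1),
                controls_mtmt = sample(1:50, 1))
    for (model in c("recessive", "dominant")) {
      tab <- collapse_genotypes(counts, model)
      est <- odds_ratio_from_2x2(tab[1], tab[2], tab[3], tab[4])
      # hand-built 2x2 straight from the genotype definition
      if (model == "recessive") {
        a <- counts[["cases_mtmt"]]
        b <- counts[["cases_wtwt"]] + counts[["cases_wtmt"]]
        c_ <- counts[["controls_mtmt"]]
        d <- counts[["controls_wtwt"]] + counts[["controls_wtmt"]]
      } else {
        a <- counts[["cases_wtmt"]] + counts[["cases_mtmt"]]
        b <- counts[["cases_wtwt"]]
        c_ <- counts[["controls_wtmt"]] + counts[["controls_mtmt"]]
        d <- counts[["controls_wtwt"]]
      }
      expect_equal(est$y, log(a * d / (b * c_)))
    }
  }
})

test_that("reported OR/CI back-transform and its round-trip", {
  est <- effect_from_reported(2.0, 1.0, 4.0)
  expect_equal(est$y, log(2))
  expect_equal(est$se, log(4) / 3.92)

  figueroa <- effect_from_reported(0.80, 0.62, 1.04)
  expect_equal(figueroa$y, -0.2231, tolerance = 1e-3)
  expect_equal(figueroa$se, 0.1320, tolerance = 1e-3)

  expect_error(effect_from_reported(1.0, 1.0, 1.0), "lcl < ucl")
  expect_error(effect_from_reported(1.0, -1, 2), "0 < lcl")

  # log-symmetric inputs round-trip exactly
  set.seed(8)
  for (rep in 1:25) {
    y0 <- rnorm(1); s0 <- runif(1, 0.05, 0.6)
    e <- effect_from_reported(exp(y0), exp(y0 - 1.96 * s0),
                              exp(y0 + 1.96 * s0))
    expect_equal(e$lcl, exp(y0 - 1.96 * s0), tolerance = 1e-12)
    expect_equal(e$ucl, exp(y0 + 1.96 * s0), tolerance = 1e-12)
  }
  # printed fixture rows reproduce the CI ratio exactly; the bounds only to
  # input precision, since a printed OR need not be the geometric midpoint
  # of its printed bounds (worst fixture row: a 0.04 lower bound, whose
  # 2-decimal granularity is 12.5% of its value)
  studies <- read_study_table(snpmeta_fixture())
  for (i in seq_len(nrow(studies))) {
    e <- effect_from_reported(studies$reported_or[i], studies$reported_lcl[i],
                              studies$reported_ucl[i])
    expect_equal(e$ucl / e$lcl,
                 studies$reported_ucl[i] / studies$reported_lcl[i],
                 tolerance = 1e-10)
    expect_equal(e$lcl, studies$reported_lcl[i], tolerance = 0.06)
    expect_equal(e$ucl, studies$reported_ucl[i], tolerance = 0.06)
  }
})

test_that("genetic-model selection rules and tie-break", {
  mk <- function(or, lcl, ucl) effect_from_reported(or, lcl, ucl)
  # published rs762551 crude contrasts: both CIs contain 1 -> tie-break
  sel <- select_genetic_model(mk(1.03, 0.98, 1.07), mk(1.06, 0.97, 1.16))
  expect_equal(sel$chosen, "recessive")
  expect_match(sel$rule, "tie-break")
  # both exclude 1 -> dominant
  expect_equal(select_genetic_model(mk(1.5, 1.2, 1.8),
                                    mk(1.5, 1.2, 1.8))$chosen, "dominant")
  # OR2 excludes, OR1 does not -> recessive
  expect_equal(select_genetic_model(mk(1.0, 0.9, 1.1),
                                    mk(1.6, 1.3, 2.0))$chosen, "recessive")
  # swap invariance: relabelling the contrasts and re-reading the patterns
  # accordingly gives the mirrored decision
  a <- mk(1.01, 0.9, 1.1); b <- mk(1.3, 0.95, 1.7)
  expect_equal(select_genetic_model(a, b)$chosen,
               ifelse(select_genetic_model(b, a)$chosen == "recessive",
                      "dominant", "recessive"))
})

test_that("HWE chi-square test: exact proportions, known value, boundary", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chi_square, 0)
  expect_equal(perfect$p_value, 1)
  expect_false(perfect$excluded)

  dev <- hwe_test(30, 40, 30)
  expect_equal(dev$chi_square, 4)
  expect_equal(dev$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_false(dev$excluded)  # 0.0455 > 0.01

  # boundary: p equal to alpha is excluded
  at_boundary <- hwe_test(30, 40, 30, alpha = dev$p_value)
  expect_true(at_boundary$excluded)

  expect_message(mono <- hwe_test(100, 0, 0), "monomorphic")
  expect_equal(mono$p_value, 1)
  expect_false(mono$excluded)
})

test_that("exact HWE test agrees with chi-square at moderate counts", {
  ex <- hwe_test(57, 14, 50, exact = TRUE)
  as <- hwe_test(57, 14, 50)
  expect_lt(ex$p_value, 0.01)   # grossly out of HWE either way
  expect_lt(as$p_value, 0.01)
  near <- hwe_test(240, 250, 80, exact = TRUE)
  near_chi <- hwe_test(240, 250, 80)
  expect_equal(near$p_value, near_chi$p_value, tolerance = 0.2)
  expect_true(ex$p_value >= 0 && ex$p_value <= 1)
})

test_that("HWE filter removes violating control series and logs them", {
  cfg <- simulation_config(allele_freq = 0.3, true_or = 1, k_studies = 4,
                           n_cases = 500, n_controls = 500, seed = 7)
  st <- simulate_collection(cfg)
  # plant one grossly disequilibrated control series
  st$controls_wtwt[2] <- 250; st$controls_wtmt[2] <- 0
  st$controls_mtmt[2] <- 250
  st$n_controls[2] <- 500
  res <- hwe_filter(st)
  expect_equal(nrow(res$records), 3)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(sum(res$log$excluded), 1)
  expect_true(all(res$log$p_value[!res$log$excluded] > 0.01))
})
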