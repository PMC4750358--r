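test_that("fixed-effect pool: identity, closed forms, brute-force oracle", {
  one <- fixed_effect_pool(0.3, 0.1)
  expect_equal(one$y_pooled, 0.3)
  expect_equal(one$se_pooled, 0.1)
  expect_equal(one$q, 0)
  expect_equal(one$df, 0L)

  two <- fixed_effect_pool(c(0.5, 0.5), c(0.2, 0.2))
  expect_equal(two$y_pooled, 0.5)
  expect_equal(two$se_pooled, 0.2 / sqrt(2))

  set.seed(11)
  for (k in c(2, 5, 9)) {
    est <- random_estimates(k)
    p <- fixed_effect_pool(est$y, est$se)
    o <- brute_fixed(est$y, est$se)
    expect_equal(p$y_pooled, o$y)
    expect_equal(p$se_pooled, o$se)
  }
  expect_error(fixed_effect_pool(numeric(0), numeric(0)))
})

test_that("Cochran's Q: null case, permutation symmetry, fixture value", {
  same <- cochran_q(rep(0.4, 4), rep(0.2, 4))
  expect_equal(same$q, 0)
  expect_equal(same$p, 1)

  set.seed(12)
  est <- random_estimates(7)
  perm <- sample(7)
  expect_equal(cochran_q(est$y, est$se)$q,
               cochran_q(est$y[perm], est$se[perm])$q)

  # the four rs2472304 units are homogeneous: Q < df, hence I2 = 0
  ef <- fixture_effects("rs2472304")
  q4 <- cochran_q(ef$y, ef$se)
  expect_lt(q4$q, q4$df)
  expect_equal(i_squared(q4$q, q4$df), 0)
})

test_that("I-squared closed forms", {
  expect_equal(i_squared(0, 3), 0)
  expect_equal(i_squared(8, 4), 50)
  expect_equal(i_squared(2, 5), 0)  # truncation at zero
})

test_that("DL tau2: truncation, homogeneity, bladder value, oracle", {
  set.seed(13)
  est <- random_estimates(4)
  expect_equal(dl_tau2(rep(0.2, 5), rep(0.3, 5)), 0)
  expect_equal(dl_tau2(est$y, est$se), brute_tau2(est$y, est$se))

  ef <- fixture_effects("rs762551")
  bladder <- ef[!is.na(ef$tumour_site) & ef$tumour_site == "bladder", ]
  expect_equal(nrow(bladder), 5)
  t2 <- dl_tau2(bladder$y, bladder$se)
  expect_equal(t2, brute_tau2(bladder$y, bladder$se))
  expect_equal(t2, 0.014, tolerance = 0.05)
})

test_that("random-effects pool: published subgroups and homogeneous limit", {
  ef <- fixture_effects("rs762551")
  bladder <- ef[!is.na(ef$tumour_site) & ef$tumour_site == "bladder", ]
  p <- random_effects_pool(bladder$y, bladder$se, bladder$label)
  expect_equal(round(p$or, 2), 0.84)

  ef4 <- fixture_effects("rs2472304")
  cauc <- ef4[ef4$ethnicity == "Caucasian", ]
  p2 <- random_effects_pool(cauc$y, cauc$se)
  expect_equal(round(p2$or, 2), 0.72)
  expect_equal(round(p2$ci_lower, 2), 0.52)
  expect_equal(round(p2$ci_upper, 2), 0.99)

  # tau2 = 0 reduces exactly to the fixed-effect pool
  hom <- random_effects_pool(ef4$y, ef4$se)
  fix <- fixed_effect_pool(ef4$y, ef4$se)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$y_pooled, fix$y_pooled)
  expect_equal(hom$se_pooled, fix$se_pooled)

  # homogeneous limit: common y with se/sqrt(k), all statistics null
  lim <- random_effects_pool(rep(0.25, 6), rep(0.3, 6))
  expect_equal(lim$y_pooled, 0.25)
  expect_equal(lim$se_pooled, 0.3 / sqrt(6))
  expect_equal(lim$q, 0)
  expect_equal(lim$i2, 0)
})

test_that("appending a unit at the pooled value never widens the CI", {
  set.seed(14)
  for (rep in 1:20) {
    est <- random_estimates(sample(3:10, 1))
    p <- random_effects_pool(est$y, est$se)
    p2 <- random_effects_pool(c(est$y, p$y_pooled),
                              c(est$se, runif(1, 0.05, 0.8)))
    expect_lte(p2$ci_upper - p2$ci_lower, p$ci_upper - p$ci_lower + 1e-12)
  }
})

test_that("subgroup analysis: published strata, degenerate levels, errors", {
  studies <- read_study_table(snpmeta_fixture())
  eth <- subgroup_analysis(studies, "ethnicity", snp_id = "rs2470890")
  mixed <- eth$Mixed
  expect_equal(round(mixed$or, 2), 1.44)
  expect_equal(mixed$i2, 0)
  expect_equal(mixed$k, 2)

  size <- subgroup_analysis(studies, "sample_size", snp_id = "rs2472304")
  expect_equal(round(size$large$or, 2), 0.79)

  # single-level factor equals the overall pool
  e526 <- studies[studies$snp_id == "rs2069526", ]
  eth1 <- subgroup_analysis(e526, "ethnicity")
  expect_equal(names(eth1), "Caucasian")
  ef <- study_effects(e526)
  expect_equal(eth1$Caucasian$y_pooled, random_effects_pool(ef$y, ef$se)$y_pooled)

  # k = 1 levels carry the degenerate flag
  site <- subgroup_analysis(studies, "tumour_site", snp_id = "rs2472304")
  expect_true(attr(site$lung, "degenerate"))

  expect_error(subgroup_analysis(studies, "country", snp_id = "rs2472304"))
})

test_that("leave-one-out: restoration property, symmetry, k guard", {
  set.seed(15)
  est <- random_estimates(6)
  loo <- leave_one_out(est$y, est$se)
  expect_equal(nrow(loo), 6)
  full <- random_effects_pool(est$y, est$se)
  for (i in 1:6) {
    refit <- random_effects_pool(c(est$y[-i], est$y[i]),
                                 c(est$se[-i], est$se[i]))
    expect_equal(refit$y_pooled, full$y_pooled)
  }
  sym <- leave_one_out(rep(0.2, 4), rep(0.3, 4))
  expect_equal(length(unique(round(sym$or, 12))), 1)
  expect_error(leave_one_out(c(0.1, 0.2), c(0.1, 0.1)))
})

test_that("Galbraith residuals: homogeneous null and a planted outlier", {
  none <- galbraith(rep(0.3, 5), runif(5, 0.1, 0.5))
  expect_false(any(none$outlier))

  # tight cluster plus one unit 5 SEs away
  y <- c(rep(0, 10), 5 * 0.2)
  se <- c(rep(0.04, 10), 0.2)
  g <- galbraith(y, se, labels = c(paste0("s", 1:10), "planted"))
  expect_equal(g$label[g$outlier], "planted")
  expect_equal(g$residual, (y - fixed_effect_pool(y, se)$y_pooled) / se)
  expect_error(galbraith(c(0, 1), c(1, 1)))
})

test_that("forest export carries per-unit weights plus a pooled row", {
  ef <- fixture_effects("rs2472304")
  fd <- forest_data(ef)
  expect_equal(nrow(fd), 5)
  expect_true(fd$pooled[5])
  expect_equal(sum(fd$weight_pct[!fd$pooled]), 100)
  expect_equal(fd$or[5], random_effects_pool(ef$y, ef$se)$or)
})
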