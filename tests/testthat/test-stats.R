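test_that("ANOVA denominator df match the two design scales", {
  # 2 x 2 x 3 design, 5 reps, no three-way term: N - 1 - 9 = 50
  tab5 <- make_credit_table(reps = 5, sd = 0.2, seed = 1)
  fit5 <- fit_effects_model(tab5, model = "no_threeway")
  expect_equal(unique(fit5$anova$df_den), 50)
  expect_equal(sum(fit5$anova$df_num), 9)
  # 100 reps, full factorial: N - 12 = 1188
  tab100 <- make_credit_table(reps = 100, sd = 0.2, seed = 2)
  fit100 <- fit_effects_model(tab100, model = "full")
  expect_equal(unique(fit100$anova$df_den), 1188)
  expect_equal(sum(fit100$anova$df_num), 11)
})

test_that("degenerate responses are handled as documented", {
  tab <- make_credit_table(reps = 3, sd = 0, seed = 1)  # constant response
  fit <- suppressWarnings(fit_effects_model(tab))       # perfect-fit lm note
  expect_true(all(fit$anova$F == 0))
  # exact injected effect with zero noise: that term's F is Inf
  tab2 <- make_credit_table(effects = list(number = 1), reps = 3, sd = 0)
  fit2 <- suppressWarnings(fit_effects_model(tab2))
  expect_equal(fit2$anova$F[fit2$anova$term == "number"], Inf)
})

test_that("marginal-mean predictions agree with emmeans", {
  skip_if_not_installed("emmeans")
  tab <- make_credit_table(effects = list(number = 0.5, location = -0.3,
                                          community = c(0, -0.4, -0.8)),
                           reps = 8, sd = 0.25, seed = 42)
  fit <- fit_effects_model(tab, model = "full")
  for (f in c("number", "location", "community")) {
    em <- as.data.frame(suppressMessages(emmeans::emmeans(fit$fit, f)))
    pr <- fit$predictions[fit$predictions$factor == f, ]
    expect_equal(pr$fit, em$emmean, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(pr$se, em$SE, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(pr$lwr, em$lower.CL, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("predictions respect non-alphabetical factor level order", {
  # catalogue order is not alphabetical (e.g. "2A" precedes "1A-1P"); the
  # marginal means must track the data's level order, not re-sort it
  tab <- make_credit_table(effects = list(community = c(0, -0.5, -1, -1.5)),
                           communities = c("1A", "2A", "1A-1P", "2A-1P"),
                           reps = 6, sd = 0.1, seed = 13)
  fit <- fit_effects_model(tab, model = "full")
  raw <- tapply(tab$credit_ln1p, tab$community, mean)
  pr <- fit$predictions[fit$predictions$factor == "community", ]
  expect_equal(pr$fit, as.vector(raw[pr$level]), tolerance = 1e-10)
})

test_that("percent change follows the stated arithmetic and sign convention", {
  tab <- make_credit_table(effects = list(number = 0.6), grand_mean = 4,
                           reps = 200, sd = 0.01, seed = 3)
  fit <- fit_effects_model(tab, model = "full")
  # m_from = 4.0, m_to = 4.6 -> +15%
  expect_equal(percent_change(fit, "number", "1", "4"), 15, tolerance = 0.5)
  # identical predictions -> 0; decrease -> negative
  tab0 <- make_credit_table(reps = 50, sd = 0.01, seed = 4)
  fit0 <- fit_effects_model(tab0, model = "full")
  expect_equal(percent_change(fit0, "number", "1", "4"), 0, tolerance = 0.5)
  tabn <- make_credit_table(effects = list(location = -0.4), reps = 50,
                            sd = 0.01, seed = 5)
  fitn <- fit_effects_model(tabn, model = "full")
  expect_lt(percent_change(fitn, "location", "central", "peripheral"), 0)
})

test_that("unbalanced tables are refused unless forced", {
  tab <- make_credit_table(reps = 4, sd = 0.2, seed = 6)
  tab <- tab[-1, ]
  expect_error(fit_effects_model(tab), "unbalanced")
  skip_if_not_installed("car")
  fit <- fit_effects_model(tab, force = TRUE)
  expect_false(fit$balanced)
  expect_true(all(is.finite(fit$anova$F)))
})

test_that("post hoc simple effects reduce to the main effect without interaction", {
  tab <- make_credit_table(effects = list(number = 0.5), reps = 100,
                           sd = 0.05, seed = 7)
  fit <- fit_effects_model(tab, model = "full")
  ph <- posthoc_interaction(fit, "number", "location")
  # additive data: the number effect is ~0.5 within both locations
  expect_equal(ph$estimate, rep(0.5, 2), tolerance = 0.05)
  expect_true(all(ph$p_adj < 0.05))
  # with a pure interaction the effect appears only in one stratum
  tabx <- make_credit_table(effects = list(number_location = 0.8),
                            reps = 100, sd = 0.05, seed = 8)
  fitx <- fit_effects_model(tabx, model = "full")
  phx <- posthoc_interaction(fitx, "number", "location")
  expect_equal(phx$estimate[phx$within == "central"], 0, tolerance = 0.05)
  expect_equal(phx$estimate[phx$within == "peripheral"], 0.8, tolerance = 0.05)
})

test_that("post hoc contrasts hold their size under the null", {
  # on null tables no contrast should be significant in most simulations
  set.seed(9)
  n_sig <- 0
  for (i in 1:60) {
    tab <- make_credit_table(reps = 5, sd = 0.3, seed = i)
    fit <- fit_effects_model(tab, model = "full")
    ph <- posthoc_interaction(fit, "number", "location")
    if (any(ph$p_adj < 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 60, 0.15)
})
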