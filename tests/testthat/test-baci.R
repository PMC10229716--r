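test_that("BACI table reproduces the balanced-design df and source layout", {
  cfg <- simulation_config(seed = 1, n_taxa = 2)
  sim <- simulate_experiment(cfg)
  an <- fit_baci_anova(response_table(derive_responses(sim$abundance)$detritus))
  expect_equal(an$source,
               c("Treatment", "River", "Treatment x River",
                 "Between sites (within Treatment x River)", "Time",
                 "Time x Treatment", "Time x River",
                 "Time x Treatment x River", "Residual"))
  expect_equal(an$df, c(1, 5, 5, 24, 1, 1, 5, 5, 24))
  # reconstruction property: F ratios recomputable from the printed MS
  ms <- setNames(an$MS, an$source)
  expect_equal(an$F[an$source == "Treatment"],
               ms["Treatment"] /
                 ms["Between sites (within Treatment x River)"],
               ignore_attr = TRUE)
  expect_equal(an$F[an$source == "Time x Treatment"],
               ms["Time x Treatment"] / ms["Residual"], ignore_attr = TRUE)
})

test_that("sums of squares match an independent balanced decomposition", {
  for (seed in 1:6) {
    d <- make_response(n_rivers = 3, n_sites = 2, effect = seed %% 3,
                       noise_sd = 2, seed = seed)
    an <- fit_baci_anova(response_table(d, transform = "none"))
    oracle <- oracle_baci_ss(d)
    expect_equal(setNames(an$SS, an$source), oracle, tolerance = 1e-8)
    # additivity against the total corrected SS
    expect_equal(sum(an$SS), sum((d$value - mean(d$value))^2),
                 tolerance = 1e-8)
  }
})

test_that("degenerate responses are rejected or reported as missing", {
  d <- make_response(seed = 2)
  d$value <- 7
  an <- fit_baci_anova(response_table(d, transform = "none"))
  expect_true(all(an$SS == 0))
  expect_true(all(is.na(an$F)))
  # unbalanced data refuse to fit
  expect_error(response_table(make_response(seed = 1)[-1, ]), "unbalanced")
})

test_that("a priori contrast matches the least-squares oracle", {
  for (seed in 7:11) {
    d <- make_response(n_rivers = 3, n_sites = 3, effect = (seed %% 2) * 3,
                       noise_sd = 1.5, seed = seed)
    an <- fit_baci_anova(response_table(d, transform = "none"))
    ct <- apriori_contrast(an)
    orc <- oracle_contrast(d)
    expect_equal(ct$estimate, orc$L, tolerance = 1e-8)
    expect_equal(ct$F, orc$F, tolerance = 1e-6)
    expect_equal(ct$P, orc$P, tolerance = 1e-6)
    # per-river scope against the oracle too
    ct1 <- apriori_contrast(an, "R2")
    orc1 <- oracle_contrast(d, "R2")
    expect_equal(ct1$F, orc1$F, tolerance = 1e-6)
  }
})

test_that("equal cell means give a zero contrast with P = 1", {
  d <- make_response(n_rivers = 2, n_sites = 3, seed = 3, noise_sd = 0)
  # add site-level noise that cancels within every cell
  d$value <- d$value + rep(c(-1, 0, 1), length.out = nrow(d))
  an <- fit_baci_anova(response_table(d, transform = "none"))
  ct <- apriori_contrast(an)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$F, 0)
  expect_equal(ct$P, 1)
})

test_that("contrast is invariant to river relabelling (pooled scope)", {
  d <- make_response(n_rivers = 3, n_sites = 2, effect = 2, seed = 12)
  an <- fit_baci_anova(response_table(d, transform = "none"))
  ct <- apriori_contrast(an)
  d2 <- d
  d2$river <- c(R1 = "Zed", R2 = "Alba", R3 = "Mira")[d2$river]
  ct2 <- apriori_contrast(fit_baci_anova(response_table(d2,
                                                        transform = "none")))
  expect_equal(ct$F, ct2$F)
  expect_equal(ct$estimate, ct2$estimate)
})

test_that("effect size follows the baseline-relative percentage formula", {
  cm <- list(BC = 10, BM = 12, AC = 14, AM = 24, n_cell = 3)
  expect_equal(riverbaci:::effect_size_from_means(cm, "none")$es, 100)
  expect_equal(riverbaci:::effect_size_from_means(cm, "none")$Y, 12)
  cm0 <- list(BC = 10, BM = 12, AC = 14, AM = 12, n_cell = 3)
  expect_equal(riverbaci:::effect_size_from_means(cm0, "none")$es, 0)
  # via the public interface with exact cell means
  d <- make_response(n_rivers = 2, n_sites = 3, seed = 1, noise_sd = 0)
  d$value <- c(-0.5, 0, 0.5)[match(sub("_.*", "", d$site),
                                   c("S1", "S2", "S3"))] +
    with(d, ifelse(period == "before" & treatment == "control", 10,
            ifelse(period == "before" & treatment == "manipulation", 12,
            ifelse(period == "after" & treatment == "control", 14, 24))))
  an <- fit_baci_anova(response_table(d, transform = "none"))
  expect_equal(effect_size(an), 100)
  expect_equal(effect_size(an, "R1"), 100)
})

test_that("per-river contrasts drop the smallest-|ES| river", {
  d <- make_response(n_rivers = 6, n_sites = 3, seed = 30, noise_sd = 0.5)
  # make river R4 respond strongly
  d$value[d$river == "R4" & d$treatment == "manipulation" &
            d$period == "after"] <- 25
  an <- fit_baci_anova(response_table(d, transform = "none"))
  pr <- per_river_contrasts(an)
  expect_equal(nrow(pr), 5)
  expect_false(attr(pr, "excluded_river") %in% pr$scope)
  expect_equal(pr$scope[which.min(pr$P)], "R4")
  # identical rivers: deterministic alphabetical exclusion
  d2 <- make_response(n_rivers = 3, n_sites = 2, seed = 5, noise_sd = 0)
  d2$value <- rep(c(-1, 1), length.out = nrow(d2)) + 10
  an2 <- fit_baci_anova(response_table(d2, transform = "none"))
  expect_message(pr2 <- per_river_contrasts(an2), "alphabetically first")
  expect_equal(attr(pr2, "excluded_river"), "R1")
})

test_that("the auto log rule reacts to cell-variance heterogeneity", {
  d <- make_response(n_rivers = 3, n_sites = 3, seed = 40, noise_sd = 0.01)
  expect_equal(attr(response_table(d), "transform"), "none")
  ma <- d$treatment == "manipulation" & d$period == "after"
  d$value[ma] <- 10 * exp(stats::rnorm(sum(ma), 0, 1))
  expect_equal(attr(response_table(d), "transform"), "log")
  expect_equal(attr(response_table(d, transform = "none"), "transform"),
               "none")
  # back-transformed ES on log-analysed data stays on the data scale
  an <- fit_baci_anova(response_table(d, transform = "log"))
  es <- effect_size(an)
  expect_true(is.finite(es))
})
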