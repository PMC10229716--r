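test_that("design has the stratified BACI layout and is seed-reproducible", {
  cfg <- simulation_config(seed = 3)
  des <- generate_design(cfg)
  expect_equal(nrow(des), 42)
  tab <- table(des$river, des$treatment)
  expect_true(all(tab[, "control"] == 3))
  expect_true(all(tab[, "manipulation"] == 3))
  expect_true(all(tab[, "reference"] == 1))
  expect_false(any(duplicated(paste(des$river, des$site))))
  expect_identical(des, generate_design(cfg))

  # stratification: every consecutive site pair holds one of each treatment
  for (sd_ in 1:100) {
    d <- generate_design(simulation_config(seed = sd_, n_rivers = 2))
    d <- d[d$treatment != "reference", ]
    for (rv in unique(d$river)) {
      trt <- d$treatment[d$river == rv][order(d$position_km[d$river == rv])]
      for (k in seq(1, length(trt), by = 2))
        expect_setequal(trt[k:(k + 1)], c("control", "manipulation"))
    }
  }
  expect_error(generate_design(simulation_config(n_control = 2)),
               "equal numbers")
})

test_that("config validation rejects malformed parameter sets", {
  expect_error(simulation_config(responder_fractions =
    c(increaser = 0.5, new_colonist = 0, decreaser = 0, lost = 0,
      non_responder = 0.4)), "sum to 1")
  expect_error(simulation_config(river_sd = -1), "nonnegative")
  expect_error(simulation_config(n_taxa = -2), "nonnegative integer")
})

test_that("abundance generation is deterministic and honours taxon classes", {
  cfg <- simulation_config(seed = 5, treatment_multiplier = 5, n_taxa = 40)
  des <- generate_design(cfg)
  ab1 <- simulate_abundances(des, cfg)
  ab2 <- simulate_abundances(des, cfg)
  expect_identical(ab1$counts, ab2$counts)
  expect_identical(ab1$detritus, ab2$detritus)

  cls <- attr(ab1, "taxon_classes")
  cnt <- ab1$counts
  mb <- cnt$treatment == "manipulation" & cnt$period == "before"
  ma <- cnt$treatment == "manipulation" & cnt$period == "after"
  new_taxa <- names(cls)[cls == "new_colonist"]
  lost_taxa <- names(cls)[cls == "lost"]
  expect_true(all(cnt$count[mb & cnt$taxon %in% new_taxa] == 0))
  expect_true(all(cnt$count[ma & cnt$taxon %in% lost_taxa] == 0))
})

test_that("unit multiplier is null: manipulation and control means agree", {
  ratios <- vapply(1:200, function(i) {
    cfg <- simulation_config(seed = i, n_taxa = 6, treatment_multiplier = 1,
      responder_fractions = c(increaser = 0, new_colonist = 0,
                              decreaser = 0, lost = 0, non_responder = 1))
    ab <- simulate_abundances(generate_design(cfg), cfg)
    cnt <- ab$counts[ab$counts$period == "after", ]
    mean(cnt$count[cnt$treatment == "manipulation"]) /
      mean(cnt$count[cnt$treatment == "control"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("multiplier 3 for increasers is realised in the group means", {
  ratios <- vapply(1:500, function(i) {
    cfg <- simulation_config(seed = i, n_taxa = 6, treatment_multiplier = 3,
      responder_fractions = c(increaser = 1, new_colonist = 0,
                              decreaser = 0, lost = 0, non_responder = 0))
    ab <- simulate_abundances(generate_design(cfg), cfg)
    cnt <- ab$counts[ab$counts$period == "after", ]
    mean(cnt$count[cnt$treatment == "manipulation"]) /
      mean(cnt$count[cnt$treatment == "control"])
  }, numeric(1))
  # Monte-Carlo band: mean of 500 replicate ratios around 3
  expect_lt(abs(mean(ratios) - 3), 3 * 1.96 * stats::sd(ratios) / sqrt(500))
})

test_that("infinite dispersion approaches the Poisson variance/mean limit", {
  vm_of <- function(dispersion) {
    cfg <- simulation_config(seed = 9, n_taxa = 200,
                             dispersion = dispersion, river_sd = 0,
                             site_sd = 0, period_sd = 0,
                             treatment_multiplier = 1)
    ab <- simulate_abundances(generate_design(cfg), cfg)
    cnt <- ab$counts[ab$counts$treatment != "reference", ]  # flat means
    vm <- tapply(seq_len(nrow(cnt)), cnt$taxon, function(ix) {
      x <- cnt$count[ix]
      if (mean(x) == 0) NA else stats::var(x) / mean(x)
    })
    mean(vm, na.rm = TRUE)
  }
  expect_lt(abs(vm_of(Inf) - 1), 0.05)
  expect_gt(vm_of(2), 1.5)  # clearly overdispersed at small size parameter
})

test_that("transect surveys respect truncation and the coverage-TE link", {
  cfg <- simulation_config(seed = 21, n_rivers = 1, n_transects = 400)
  des <- generate_design(cfg)
  tr <- simulate_transects(des, cfg)
  expect_true(all(tr$intercept_m <= tr$transect_length + 1e-12))
  expect_true(all(tr$detritus_m[tr$intercept_m == 0] == 0))
  # estimated TE converges to the generating TE
  te_gen <- attr(tr, "generating_te")
  te_est <- trapping_efficiency(tr, scope = "global")
  te_est <- stats::setNames(te_est$te, te_est$element_type)
  expect_lt(max(abs(te_est[names(te_gen)] - te_gen) / te_gen), 0.15)
})

test_that("null_dataset is reproducible and forces the null configuration", {
  cfg <- simulation_config(seed = 13, treatment_multiplier = 4, n_taxa = 10)
  n1 <- null_dataset(cfg)
  n2 <- null_dataset(cfg)
  expect_identical(n1$abundance$counts, n2$abundance$counts)
  expect_identical(n1$transects, n2$transects)
  expect_equal(n1$config$treatment_multiplier, 1)
  expect_equal(unname(n1$config$responder_fractions["non_responder"]), 1)
})

test_that("experiment tables round-trip through CSV", {
  cfg <- simulation_config(seed = 2, n_taxa = 5, n_rivers = 2)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment(sim, dir)
  back <- read_experiment(dir)
  expect_equal(back$design$treatment, sim$design$treatment)
  expect_equal(back$abundance$counts$count, sim$abundance$counts$count)
  expect_equal(back$transects$intercept_m, sim$transects$intercept_m)
  expect_true(file.exists(file.path(dir, "config.txt")))
})
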