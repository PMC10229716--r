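test_that("LCI is the mean over transects of intercept per metre", {
  # one 10 m transect with 2 m of wood -> 0.2 m/m
  s1 <- transect_rows("R1", "S1", 1, 10, "wood", 2, 0.5)
  lci <- linear_coverage_index(s1)
  expect_equal(lci$by_element$lci[lci$by_element$element_type == "wood"], 0.2)
  expect_equal(lci$by_site$detritus_lci, 0.05)

  # two transects, 2 m and 4 m -> mean of ratios 0.3
  s2 <- rbind(s1, transect_rows("R1", "S1", 2, 10, "wood", 4, 1))
  lci2 <- linear_coverage_index(s2)
  expect_equal(lci2$by_site$lci_total, 0.3)

  # element absent from a site contributes zero, not NA
  s3 <- rbind(s2, transect_rows("R1", "S2", 1, 10, "cobble", 1, 0))
  lci3 <- linear_coverage_index(s3)
  wood_s2 <- lci3$by_element$lci[lci3$by_element$site == "S2" &
                                   lci3$by_element$element_type == "wood"]
  expect_equal(wood_s2, 0)
  # and lci_total is always the sum of the per-element indices
  sums <- tapply(lci3$by_element$lci,
                 paste(lci3$by_element$river, lci3$by_element$site), sum)
  expect_equal(as.numeric(sums[paste(lci3$by_site$river,
                                     lci3$by_site$site)]),
               lci3$by_site$lci_total)

  expect_error(linear_coverage_index(
    transect_rows("R1", "S1", 1, 0, "wood", 0, 0)), "transect")
  expect_error(linear_coverage_index(
    transect_rows("R1", "S1", 1, 10, "wood", -1, 0)), "nonnegative")
})

test_that("trapping efficiency is the across-site mean of per-site ratios", {
  # every metre of wood holds 0.5 m of detritus everywhere
  s <- rbind(transect_rows("R1", "S1", 1, 10, "wood", 2, 1),
             transect_rows("R1", "S2", 1, 10, "wood", 4, 2))
  te <- trapping_efficiency(s, scope = "global")
  expect_equal(te$te[te$element_type == "wood"], 0.5)

  # per-site ratios 0.2 and 0.6 -> TE 0.4
  s2 <- rbind(transect_rows("R1", "S1", 1, 10, "wood", 5, 1),
              transect_rows("R1", "S2", 1, 10, "wood", 5, 3))
  te2 <- trapping_efficiency(s2, scope = "global")
  expect_equal(te2$te[te2$element_type == "wood"], 0.4)

  # intercepted but detritus-free element: TE 0, never observed: TE NA
  s3 <- rbind(s2, transect_rows("R1", "S1", 1, 10, "cobble", 3, 0),
              transect_rows("R1", "S2", 1, 10, "log_jam", 0, 0))
  te3 <- trapping_efficiency(s3, scope = "global")
  expect_equal(te3$te[te3$element_type == "cobble"], 0)
  expect_true(is.na(te3$te[te3$element_type == "log_jam"]))
})

test_that("effective retentiveness is the TE-weighted LCI sum", {
  # single element: LCI 0.3 x TE 0.4 = 0.12
  s <- rbind(transect_rows("R1", "S1", 1, 10, "wood", 3, 1.2))
  lci <- linear_coverage_index(s)
  te <- trapping_efficiency(s, scope = "global")
  er <- effective_retentiveness(lci, te)
  expect_equal(er$effective_retentiveness, 0.3 * 0.4)

  # all TE = 1 -> equals lci_total
  te1 <- te
  te1$te <- 1
  expect_equal(effective_retentiveness(lci, te1)$effective_retentiveness,
               lci$by_site$lci_total)

  # random 10-element fixture matches a brute-force dot product
  cfg <- simulation_config(seed = 8, n_rivers = 2)
  tr <- simulate_transects(generate_design(cfg), cfg)
  lci_r <- linear_coverage_index(tr)
  te_r <- trapping_efficiency(tr, scope = "global")
  er_r <- effective_retentiveness(lci_r, te_r)
  for (k in sample(nrow(er_r), 4)) {
    rows <- lci_r$by_element$river == er_r$river[k] &
      lci_r$by_element$site == er_r$site[k]
    w <- te_r$te[match(lci_r$by_element$element_type[rows],
                       te_r$element_type)]
    expect_equal(er_r$effective_retentiveness[k],
                 sum(lci_r$by_element$lci[rows] * w))
  }

  # element present at a site but with undefined TE must raise
  te_na <- te
  te_na$te <- NA_real_
  expect_error(effective_retentiveness(lci, te_na), "wood")
})

test_that("detritus standing stock divides pooled mass by the Surber area", {
  expect_equal(surber_pooled_area(), 1.485)
  det <- data.frame(river = "R1", site = "S1", treatment = "control",
                    period = "before", mass_g = 14.85, area_m2 = 1.485)
  expect_equal(detritus_standing_stock(det)$detritus_gm2, 10)
  det0 <- transform(det, mass_g = 0)
  expect_equal(detritus_standing_stock(det0)$detritus_gm2, 0)
  expect_error(detritus_standing_stock(transform(det, mass_g = -1)),
               "negative")
})

test_that("indices are invariant to row order and common rescaling", {
  cfg <- simulation_config(seed = 15, n_rivers = 2)
  tr <- simulate_transects(generate_design(cfg), cfg)
  shuf <- tr[sample(nrow(tr)), ]
  a <- retentiveness_summary(tr)
  b <- retentiveness_summary(shuf)
  expect_equal(a, b[order(match(paste(b$river, b$site),
                                paste(a$river, a$site))), ],
               ignore_attr = TRUE)
  # scaling intercepts and transect lengths together leaves LCI unchanged
  sc <- tr
  sc$intercept_m <- sc$intercept_m * 3
  sc$transect_length <- sc$transect_length * 3
  expect_equal(linear_coverage_index(sc)$by_element$lci,
               linear_coverage_index(tr)$by_element$lci)
})
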