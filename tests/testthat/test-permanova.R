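euclid_dist_with_info <- function(d) {
  v <- matrix(d$value, ncol = 1)
  rownames(v) <- paste(d$river, d$site, d$period, sep = "|")
  dm <- as.matrix(stats::dist(v))
  info <- data.frame(river = d$river, site = d$site,
                     treatment = as.character(d$treatment),
                     period = as.character(d$period))
  rownames(info) <- rownames(v)
  attr(dm, "info") <- info
  dm
}

test_that("PERMANOVA df follow the repeated-measures source structure", {
  cfg <- simulation_config(seed = 2, n_taxa = 12)
  sim <- simulate_experiment(cfg)
  dm <- bray_curtis_matrix(transform_abundance(
    abundance_matrix(sim$abundance)))
  pt <- permanova(dm, sim$design, n_perm = 99, seed = 1,
                  terms = "Time x Treatment")
  expect_equal(pt$source,
               c("River", "Treatment", "River x Treatment",
                 "Between sites within (River x Treatment)", "Time",
                 "Time x Treatment", "Time x River",
                 "Time x River x Treatment", "Residual"))
  expect_equal(pt$df, c(5, 1, 5, 24, 1, 1, 5, 5, 24))
  # SS additivity against the trace of the Gower-centred matrix
  G <- riverbaci:::gower_centred(dm[rownames(attr(dm, "info")),
                                    rownames(attr(dm, "info"))][
    attr(dm, "info")$treatment != "reference",
    attr(dm, "info")$treatment != "reference"])
  expect_equal(sum(pt$SS), sum(diag(G)), tolerance = 1e-8)
  expect_true(all(pt$P_perm > 0 & pt$P_perm <= 1, na.rm = TRUE))
})

test_that("Euclidean PERMANOVA equals the classical ANOVA term by term", {
  for (seed in 1:10) {
    d <- make_response(n_rivers = 3, n_sites = 2, effect = seed %% 4,
                       noise_sd = 1 + seed / 10, seed = 100 + seed)
    rt <- response_table(d, transform = "none")
    an <- fit_baci_anova(rt)
    dm <- euclid_dist_with_info(rt)
    pt <- permanova(dm, n_perm = 99, seed = 1, terms = "Time")
    key_a <- riverbaci:::normalize_source(an$source)
    key_p <- riverbaci:::normalize_source(pt$source)
    ord <- match(key_a, key_p)
    expect_equal(pt$SS[ord], an$SS, tolerance = 1e-6)
    expect_equal(pt$pseudo_F[ord], an$F, tolerance = 1e-6)
  }
})

test_that("pairwise test obeys t^2 = pseudo-F and detects separation", {
  # duplicated communities across groups: zero between-group SS
  m <- rbind(c(5, 1, 0, 2), c(0, 3, 4, 1), c(5, 1, 0, 2), c(0, 3, 4, 1),
             c(2, 2, 2, 2), c(1, 0, 5, 1))
  rownames(m) <- paste("R1", paste0("S", 1:6), "after", sep = "|")
  info <- data.frame(river = "R1", site = paste0("S", 1:6),
                     treatment = rep(c("control", "manipulation",
                                       "control"), each = 2),
                     period = "after")
  rownames(info) <- rownames(m)
  dm <- bray_curtis_matrix(m)
  attr(dm, "info") <- info
  res <- pairwise_permanova(dm, period = "after", n_perm = 199, seed = 1)
  expect_equal(res$t^2, res$pseudo_F, tolerance = 1e-10)

  # identical groups: t ~ 0, P ~ 1
  m2 <- m[c(1, 2, 1, 2), ]
  rownames(m2) <- paste("R1", paste0("S", 1:4), "after", sep = "|")
  info2 <- data.frame(river = "R1", site = paste0("S", 1:4),
                      treatment = rep(c("control", "manipulation"),
                                      each = 2), period = "after")
  rownames(info2) <- rownames(m2)
  dm2 <- bray_curtis_matrix(m2)
  attr(dm2, "info") <- info2
  res2 <- pairwise_permanova(dm2, period = "after", n_perm = 199, seed = 1)
  expect_lt(res2$t, 1e-6)
  expect_gt(res2$P_perm, 0.95)

  # strongly separated groups (disjoint taxon sets) reach the smallest
  # attainable P
  cm <- make_community(n_per_group = 8, n_taxa = 10, shift = 0, seed = 3)
  cm$mat[1:8, 1:5] <- 0
  cm$mat[9:16, 6:10] <- 0
  rownames(cm$mat) <- paste("R1", paste0("S", 1:16), "after", sep = "|")
  info3 <- data.frame(river = "R1", site = paste0("S", 1:16),
                      treatment = rep(c("control", "manipulation"),
                                      each = 8), period = "after")
  rownames(info3) <- rownames(cm$mat)
  dm3 <- bray_curtis_matrix(transform_abundance(cm$mat))
  attr(dm3, "info") <- info3
  res3 <- pairwise_permanova(dm3, period = "after", n_perm = 999, seed = 1)
  expect_lte(res3$P_perm, 0.002)
})

test_that("label mismatches and size-one groups are rejected", {
  cfg <- simulation_config(seed = 2, n_taxa = 6, n_rivers = 2)
  sim <- simulate_experiment(cfg)
  dm <- bray_curtis_matrix(transform_abundance(
    abundance_matrix(sim$abundance)))
  attr(dm, "info") <- NULL
  bad_design <- sim$design
  bad_design$site <- paste0("X", bad_design$site)
  expect_error(permanova(dm, bad_design, n_perm = 99), "do not match")
  expect_error(permanova(dm, sim$design, n_perm = 99, terms = "Nope"),
               "untestable")
})

test_that("a strong Time x Treatment effect is detected by permutation", {
  cfg <- simulation_config(seed = 31, n_taxa = 30, treatment_multiplier = 6)
  sim <- simulate_experiment(cfg)
  dm <- bray_curtis_matrix(transform_abundance(
    abundance_matrix(sim$abundance)))
  pt <- permanova(dm, sim$design, n_perm = 199, seed = 4,
                  terms = "Time x Treatment")
  expect_lte(pt$P_perm[pt$source == "Time x Treatment"], 0.01)
})
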