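#' Configuration for a synthetic detritus-supplementation experiment
#'
#' Builds and validates the parameter set used by [generate_design()],
#' [simulate_abundances()] and [simulate_transects()]. Defaults emulate a
#' six-river staked-site experiment: each river carries one upstream
#' reference site plus three control and three manipulation sites sampled
#' before and after the manipulation, with macroinvertebrate counts pooled
#' over 15 Surber samples per site and channel retentiveness surveyed along
#' eight cross-sectional transects per site.
#'
#' @param n_rivers number of rivers (replicate ecosystems).
#' @param n_control,n_manipulation treatment sites per river. Must be equal,
#'   because treatments are allocated in stratified pairs along the channel.
#' @param n_reference reference sites per river (unreplicated in the field,
#'   hence default 1).
#' @param n_taxa number of macroinvertebrate taxa simulated.
#' @param n_transects line-intercept transects per site.
#' @param transect_length transect length in metres (approximate wetted
#'   channel width).
#' @param baseline_abundance mean pooled count per taxon per site sample;
#'   per-taxon baselines are drawn lognormally around this value.
#' @param dispersion negative-binomial size parameter of the count model;
#'   `Inf` gives Poisson counts.
#' @param river_sd,site_sd,period_sd standard deviations (natural-log scale)
#'   of the taxon-by-river, site and river-by-period random effects.
#' @param treatment_multiplier multiplicative density boost applied to
#'   responding taxa (and detritus) in manipulation sites after treatment;
#'   1 gives a null experiment.
#' @param responder_fractions named numeric vector of taxon-class
#'   proportions over `increaser`, `new_colonist`, `decreaser`, `lost`,
#'   `non_responder`; must sum to 1.
#' @param detritus_params list with components `mean_gm2` (mean standing
#'   stock, g m^-2), `sd_log` (lognormal residual sd), `te_mean`, `te_sd`
#'   (mean/sd of per-element trapping efficiencies, m detritus per m
#'   element) and `reference_uplift` (multiplier on detritus and taxon
#'   densities at reference sites).
#' @param seed integer root seed. All generator randomness flows from this
#'   seed through named substreams, so each table can be regenerated
#'   independently.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' des <- generate_design(cfg)
#' table(des$treatment)
simulation_config <- function(n_rivers = 6, n_control = 3, n_manipulation = 3,
                              n_reference = 1, n_taxa = 80, n_transects = 8,
                              transect_length = 8,
                              baseline_abundance = 15, dispersion = 5,
                              river_sd = 0.3, site_sd = 0.2, period_sd = 0.15,
                              treatment_multiplier = 1,
                              responder_fractions = c(increaser = 0.25,
                                                      new_colonist = 0.075,
                                                      decreaser = 0.05,
                                                      lost = 0.025,
                                                      non_responder = 0.6),
                              detritus_params = list(mean_gm2 = 30,
                                                     sd_log = 0.3,
                                                     te_mean = 0.3,
                                                     te_sd = 0.15,
                                                     reference_uplift = 1.5),
                              seed = 1L) {
  cfg <- list(n_rivers = n_rivers, n_control = n_control,
              n_manipulation = n_manipulation, n_reference = n_reference,
              n_taxa = n_taxa, n_transects = n_transects,
              transect_length = transect_length,
              baseline_abundance = baseline_abundance, dispersion = dispersion,
              river_sd = river_sd, site_sd = site_sd, period_sd = period_sd,
              treatment_multiplier = treatment_multiplier,
              responder_fractions = responder_fractions,
              detritus_params = detritus_params, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

responder_classes <- c("increaser", "new_colonist", "decreaser", "lost",
                       "non_responder")

validate_sim_config <- function(cfg) {
  counts <- c("n_rivers", "n_control", "n_manipulation", "n_reference",
              "n_taxa", "n_transects")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.numeric(v) || v < 0 || v != round(v))
      stop(sprintf("'%s' must be a single nonnegative integer", nm))
  }
  pos <- c("transect_length", "baseline_abundance", "dispersion")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be positive", nm))
  }
  for (nm in c("river_sd", "site_sd", "period_sd", "treatment_multiplier")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("'%s' must be nonnegative", nm))
  }
  fr <- cfg$responder_fractions
  if (!all(responder_classes %in% names(fr)))
    stop("responder_fractions must be named over: ",
         paste(responder_classes, collapse = ", "))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("responder_fractions must be nonnegative and sum to 1")
  dp <- cfg$detritus_params
  need <- c("mean_gm2", "sd_log", "te_mean", "te_sd", "reference_uplift")
  if (!all(need %in% names(dp)))
    stop("detritus_params must contain: ", paste(need, collapse = ", "))
  invisible(cfg)
}

# Named substreams off the root seed so that design, abundances and
# transects can each be regenerated independently and deterministically.
substream_seed <- function(seed, name) {
  off <- c(design = 101L, abundance = 211L, transects = 307L,
           analysis = 401L)
  (as.integer(seed) + off[[name]]) %% .Machine$integer.max
}

#' Generate the site-by-treatment design of the experiment
#'
#' Each river receives `n_reference` upstream reference sites plus an equal
#' number of control and manipulation sites placed at ~1 km intervals
#' downstream. Treatments are allocated in a stratified-random way: within
#' each consecutive pair of treatment sites (upstream, middle, downstream
#' pairs), one site is control and one manipulation, with the order
#' randomised by the seed. This spreads both treatments along the channel.
#'
#' @param config a [simulation_config()] object.
#' @return A `data.frame` (class `"design_table"`) with columns `river`,
#'   `site`, `treatment` (`reference`/`control`/`manipulation`) and
#'   `position_km`.
#' @export
generate_design <- function(config) {
  validate_sim_config(config)
  if (config$n_control != config$n_manipulation)
    stop("stratified allocation requires equal numbers of control and ",
         "manipulation sites per river (odd total is undefined)")
  set.seed(substream_seed(config$seed, "design"))
  rivers <- sprintf("R%d", seq_len(config$n_rivers))
  out <- lapply(rivers, function(rv) {
    ref <- if (config$n_reference > 0)
      data.frame(river = rv,
                 site = sprintf("REF%d", seq_len(config$n_reference)),
                 treatment = "reference",
                 position_km = -(seq_len(config$n_reference) - 1))
    n_pair <- config$n_control
    trt <- unlist(lapply(seq_len(n_pair), function(k)
      sample(c("control", "manipulation"))))
    trt_rows <- data.frame(river = rv,
                           site = sprintf("S%d", seq_len(2 * n_pair)),
                           treatment = trt,
                           position_km = seq_len(2 * n_pair))
    rbind(ref, trt_rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("design_table", "data.frame")
  out
}

#' Simulate macroinvertebrate abundances and detritus standing stocks
#'
#' Pooled Surber counts are drawn from a negative-binomial model whose
#' log-scale mean is the sum of a per-taxon baseline, a taxon-by-river
#' effect, a site effect, a river-by-period effect and a treatment term
#' confined to manipulation-after cells. Taxa are pre-assigned to response
#' classes: `increaser` taxa gain `log(treatment_multiplier)`, `decreaser`
#' taxa lose it, `new_colonist` taxa are structurally absent at
#' manipulation sites before treatment, and `lost` taxa are structurally
#' absent after. Detritus mass is simulated analogously on a continuous
#' lognormal scale; reference sites get an uplift on both detritus and
#' taxon densities so equivalence tests have a meaningful target.
#'
#' @param design a design table from [generate_design()].
#' @param config the matching [simulation_config()].
#' @return An object of class `"abundance_table"`: a list with elements
#'   `counts` (long `data.frame`: river, site, treatment, period, taxon,
#'   count) and `detritus` (per site-by-period pooled detritus mass in
#'   grams with the pooled sampled area in m^2). The generating taxon
#'   classes are stored in `attr(, "taxon_classes")`.
#' @export
simulate_abundances <- function(design, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "abundance"))
  n_taxa <- config$n_taxa
  taxa <- sprintf("T%03d", seq_len(n_taxa))
  taxon_sd <- 0.8  # between-taxon spread of baseline abundances (log scale)
  log_base <- stats::rnorm(n_taxa, log(config$baseline_abundance) -
                             taxon_sd^2 / 2, taxon_sd)
  classes <- sample(responder_classes, n_taxa, replace = TRUE,
                    prob = config$responder_fractions[responder_classes])
  names(classes) <- taxa

  rivers <- unique(design$river)
  river_eff <- matrix(stats::rnorm(n_taxa * length(rivers), 0, config$river_sd),
                      n_taxa, length(rivers), dimnames = list(taxa, rivers))
  usite <- paste(design$river, design$site, sep = ":")
  site_eff <- stats::rnorm(nrow(design), 0, config$site_sd)
  names(site_eff) <- usite
  period_eff <- stats::rnorm(length(rivers), 0, config$period_sd)
  names(period_eff) <- rivers

  grid <- design[rep(seq_len(nrow(design)), each = 2), ]
  grid$period <- rep(c("before", "after"), nrow(design))
  cells <- grid[rep(seq_len(nrow(grid)), times = n_taxa), ]
  cells$taxon <- rep(taxa, each = nrow(grid))

  lmu <- log_base[match(cells$taxon, taxa)] +
    river_eff[cbind(match(cells$taxon, taxa), match(cells$river, rivers))] +
    site_eff[paste(cells$river, cells$site, sep = ":")] +
    ifelse(cells$period == "after", period_eff[cells$river], 0)

  manip_after <- cells$treatment == "manipulation" & cells$period == "after"
  manip_before <- cells$treatment == "manipulation" & cells$period == "before"
  cls <- classes[cells$taxon]
  lmult <- log(config$treatment_multiplier)
  lmu <- lmu + lmult * manip_after * (cls %in% c("increaser", "new_colonist")) -
    lmult * manip_after * (cls == "decreaser")
  lmu <- lmu + log(config$detritus_params$reference_uplift) *
    (cells$treatment == "reference")
  mu <- exp(lmu)
  # structural presence/absence switches for colonising and lost taxa;
  # inert at multiplier 1 so that a unit multiplier is null in distribution
  if (config$treatment_multiplier != 1) {
    mu[manip_before & cls == "new_colonist"] <- 0
    mu[manip_after & cls == "lost"] <- 0
  }

  count <- if (is.finite(config$dispersion)) {
    stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
  } else {
    stats::rpois(length(mu), mu)
  }
  counts <- data.frame(river = cells$river, site = cells$site,
                       treatment = cells$treatment, period = cells$period,
                       taxon = cells$taxon, count = count)
  rownames(counts) <- NULL

  # detritus: lognormal standing stock with its own river/site/period effects
  dp <- config$detritus_params
  d_river <- stats::rnorm(length(rivers), 0, config$river_sd)
  names(d_river) <- rivers
  d_site <- stats::rnorm(nrow(design), 0, config$site_sd)
  names(d_site) <- usite
  d_period <- stats::rnorm(length(rivers), 0, config$period_sd)
  names(d_period) <- rivers
  dg <- grid
  d_lmu <- log(dp$mean_gm2) + d_river[dg$river] +
    d_site[paste(dg$river, dg$site, sep = ":")] +
    ifelse(dg$period == "after", d_period[dg$river], 0) +
    lmult * (dg$treatment == "manipulation" & dg$period == "after") +
    log(dp$reference_uplift) * (dg$treatment == "reference")
  gm2 <- exp(d_lmu + stats::rnorm(nrow(dg), 0, dp$sd_log))
  area <- surber_pooled_area()
  detritus <- data.frame(river = dg$river, site = dg$site,
                         treatment = dg$treatment, period = dg$period,
                         mass_g = gm2 * area, area_m2 = area)
  rownames(detritus) <- NULL

  out <- list(counts = counts, detritus = detritus)
  class(out) <- "abundance_table"
  attr(out, "taxon_classes") <- classes
  out
}

#' Ten retentive-element types surveyed by the line-intercept method
#' @export
retentive_elements <- function() {
  c("log_jam", "debris_dam", "wood", "root_mass", "depositional_zone",
    "macrophyte", "trailing_plant", "leaf_pack", "cobble", "boulder")
}

#' Simulate line-intercept transect surveys of retentive elements
#'
#' For every site, `n_transects` cross-sectional transects are generated.
#' Each transect records the intercepted length of each of the ten
#' retentive-element types (truncated at the transect length) and the
#' length of detritus retained on that element, drawn so that the expected
#' detritus equals the intercepted length times that element type's
#' trapping efficiency. The generating trapping efficiencies are stored in
#' `attr(, "generating_te")` for consistency checks.
#'
#' @inheritParams simulate_abundances
#' @return A `data.frame` (class `"transect_survey"`) with columns `river`,
#'   `site`, `transect`, `transect_length`, `element_type`, `intercept_m`,
#'   `detritus_m`.
#' @export
simulate_transects <- function(design, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "transects"))
  elems <- retentive_elements()
  dp <- config$detritus_params
  # per-element trapping efficiency, gamma so TE >= 0 with given mean/sd
  te <- if (dp$te_sd > 0) {
    shp <- (dp$te_mean / dp$te_sd)^2
    stats::rgamma(length(elems), shape = shp, rate = shp / dp$te_mean)
  } else rep(dp$te_mean, length(elems))
  names(te) <- elems

  rivers <- unique(design$river)
  # river-by-element mean coverage (m per transect), lognormal across rivers
  cov_mean <- matrix(exp(stats::rnorm(length(rivers) * length(elems),
                                      log(0.04 * config$transect_length), 0.5)),
                     length(rivers), length(elems),
                     dimnames = list(rivers, elems))
  n_t <- config$n_transects
  rows <- design[rep(seq_len(nrow(design)), each = n_t * length(elems)), ]
  rows$transect <- rep(rep(seq_len(n_t), each = length(elems)), nrow(design))
  rows$element_type <- rep(elems, n_t * nrow(design))
  m <- cov_mean[cbind(match(rows$river, rivers),
                      match(rows$element_type, elems))]
  intercept <- stats::rgamma(nrow(rows), shape = 2, rate = 2 / m)
  # zero-inflate: patchy elements are absent from many transects
  intercept[stats::runif(nrow(rows)) < 0.15] <- 0
  intercept <- pmin(intercept, config$transect_length)
  det_mean <- intercept * te[rows$element_type]
  detritus <- ifelse(det_mean > 0,
                     stats::rgamma(nrow(rows), shape = 3, rate = 3 /
                                     pmax(det_mean, 1e-12)), 0)
  out <- data.frame(river = rows$river, site = rows$site,
                    transect = rows$transect,
                    transect_length = config$transect_length,
                    element_type = rows$element_type,
                    intercept_m = intercept, detritus_m = detritus)
  rownames(out) <- NULL
  class(out) <- c("transect_survey", "data.frame")
  attr(out, "generating_te") <- te
  out
}

#' Generate a complete null dataset (no treatment effect)
#'
#' Convenience wrapper forcing `treatment_multiplier = 1` and placing all
#' responder mass on `non_responder`, so every treatment-related term is
#' null in distribution. Used for type-I-error calibration.
#'
#' @param config a [simulation_config()]; its multiplier and responder
#'   fractions are overridden.
#' @return list with elements `design`, `abundance`, `transects`, `config`.
#' @export
null_dataset <- function(config) {
  config$treatment_multiplier <- 1
  config$responder_fractions <- c(increaser = 0, new_colonist = 0,
                                  decreaser = 0, lost = 0, non_responder = 1)
  simulate_experiment(config)
}

#' Simulate a full experiment (design, abundances, transects)
#' @inheritParams generate_design
#' @return list with elements `design`, `abundance`, `transects`, `config`.
#' @export
simulate_experiment <- function(config) {
  design <- generate_design(config)
  list(design = design,
       abundance = simulate_abundances(design, config),
       transects = simulate_transects(design, config),
       config = config)
}

#' Write the simulated experiment as plain CSV tables
#'
#' Writes `design.csv`, `abundance.csv` (long format), `detritus.csv`,
#' `transects.csv` and the resolved configuration as `config.txt`
#' (`key: value` lines) into `dir`.
#'
#' @param sim result of [simulate_experiment()] or [null_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$design, file.path(dir, "design.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$abundance$counts, file.path(dir, "abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$abundance$detritus, file.path(dir, "detritus.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$transects, file.path(dir, "transects.csv"),
                   row.names = FALSE)
  cfg <- sim$config
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    if (is.list(v))
      v <- paste(names(v), unlist(v), sep = "=", collapse = "; ")
    else if (!is.null(names(v)))
      v <- paste(names(v), v, sep = "=", collapse = "; ")
    else v <- paste(v, collapse = ", ")
    sprintf("%s: %s", nm, v)
  }, character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
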