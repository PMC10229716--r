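#' Univariate responses from the abundance table
#'
#' Derives the per site-by-period response values analysed univariately:
#' detritus standing stock (g m^-2), taxon richness (number of taxa with
#' a nonzero pooled count) and total invertebrate density (individuals
#' m^-2 over the pooled Surber area).
#'
#' @param abundance an `"abundance_table"`.
#' @return named list of data.frames (river, site, treatment, period,
#'   value), including reference sites.
#' @export
derive_responses <- function(abundance) {
  counts <- abundance$counts
  key <- interaction(counts$river, counts$site, counts$period, drop = TRUE)
  meta <- counts[!duplicated(key), c("river", "site", "treatment", "period")]
  richness <- as.numeric(tapply(counts$count > 0, key, sum)[as.character(
    key[!duplicated(key)])])
  total <- as.numeric(tapply(counts$count, key, sum)[as.character(
    key[!duplicated(key)])])
  det <- detritus_standing_stock(abundance)
  mk <- function(v) {
    out <- cbind(meta, value = v)
    rownames(out) <- NULL
    out
  }
  list(detritus = data.frame(river = det$river, site = det$site,
                             treatment = det$treatment, period = det$period,
                             value = det$detritus_gm2),
       richness = mk(richness),
       density = mk(total / surber_pooled_area()))
}

#' Per-river similarities to the reference site and among controls
#'
#' From a Bray-Curtis dissimilarity matrix that includes the reference
#' sites, extracts for each river (after treatment) the similarity of
#' each manipulation site to the reference site and the pairwise
#' similarities among control sites — the ingredients of
#' [composition_equivalence()].
#'
#' @param dm dissimilarity matrix with sample metadata (built from
#'   `abundance_matrix(ab, include_reference = TRUE)`).
#' @param period sampling period to use (default `"after"`).
#' @return named list per river: list(manip_to_ref, among_controls),
#'   similarities on the 0-100 scale.
#' @export
reference_similarities <- function(dm, period = "after") {
  info <- attr(dm, "info")
  if (is.null(info)) stop("dissimilarity matrix lacks sample metadata")
  sim <- 100 - dm
  out <- lapply(split(seq_len(nrow(info)), info$river), function(ix) {
    here <- info[ix, ]
    ref <- ix[here$treatment == "reference" & here$period == period]
    man <- ix[here$treatment == "manipulation" & here$period == period]
    ctl <- ix[here$treatment == "control" & here$period == period]
    if (length(ref) < 1) stop("river without reference site: ",
                              here$river[1])
    pairs <- utils::combn(ctl, 2)
    list(manip_to_ref = sim[man, ref[1]],
         among_controls = sim[cbind(pairs[1, ], pairs[2, ])])
  })
  out
}

#' Validate experiment input tables
#'
#' Structural diagnostics for the design, abundance and transect tables:
#' balance of the BACI layout, label consistency across tables and
#' nonnegativity of counts, masses and lengths. Returns issues rather
#' than failing, so callers can report all problems at once.
#'
#' @param design,abundance,transects the three input tables (the latter
#'   two optional).
#' @return data.frame with columns `issue` and `detail` (zero rows when
#'   everything is well-formed).
#' @export
validate_inputs <- function(design, abundance = NULL, transects = NULL) {
  issues <- list()
  add <- function(issue, detail)
    issues[[length(issues) + 1]] <<- data.frame(issue = issue,
                                                detail = detail)
  tab <- table(design$river, design$treatment)
  if ("reference" %in% colnames(tab) && any(tab[, "reference"] != 1))
    add("reference_sites", "rivers without exactly one reference site")
  if (all(c("control", "manipulation") %in% colnames(tab)) &&
      any(tab[, "control"] != tab[, "manipulation"]))
    add("unbalanced", "unequal control and manipulation sites in a river")
  dup <- duplicated(paste(design$river, design$site))
  if (any(dup))
    add("duplicate_site", paste(design$river[dup], design$site[dup],
                                collapse = "; "))
  dkey <- paste(design$river, design$site)
  if (!is.null(abundance)) {
    counts <- if (inherits(abundance, "abundance_table")) abundance$counts
    else abundance
    neg <- which(counts$count < 0)
    if (length(neg))
      add("negative value", paste("abundance rows:",
                                  paste(utils::head(neg, 5),
                                        collapse = ", ")))
    akey <- unique(paste(counts$river, counts$site))
    if (!all(akey %in% dkey))
      add("label_mismatch", paste("abundance sites not in design:",
                                  paste(setdiff(akey, dkey),
                                        collapse = ", ")))
    cell <- table(paste(counts$river, counts$site), counts$period)
    if (length(unique(as.vector(cell))) != 1)
      add("unbalanced", paste("site-period cells with missing counts:",
                              paste(utils::head(rownames(cell)[apply(
                                cell, 1, function(x)
                                  length(unique(x)) != 1 ||
                                  any(x != max(cell)))], 5),
                                collapse = ", ")))
  }
  if (!is.null(transects)) {
    if (any(transects$intercept_m < 0) || any(transects$detritus_m < 0))
      add("negative value", "negative intercept or detritus length")
    tkey <- unique(paste(transects$river, transects$site))
    if (!all(tkey %in% dkey))
      add("label_mismatch", paste("transect sites not in design:",
                                  paste(setdiff(tkey, dkey),
                                        collapse = ", ")))
  }
  if (!length(issues))
    return(data.frame(issue = character(), detail = character()))
  do.call(rbind, issues)
}

#' Read experiment tables written by [write_experiment()]
#' @param dir directory holding design.csv, abundance.csv, detritus.csv
#'   and transects.csv.
#' @return list with `design`, `abundance` (`"abundance_table"`),
#'   `transects`.
#' @export
read_experiment <- function(dir) {
  design <- utils::read.csv(file.path(dir, "design.csv"))
  class(design) <- c("design_table", "data.frame")
  ab <- list(counts = utils::read.csv(file.path(dir, "abundance.csv")),
             detritus = utils::read.csv(file.path(dir, "detritus.csv")))
  class(ab) <- "abundance_table"
  transects <- utils::read.csv(file.path(dir, "transects.csv"))
  class(transects) <- c("transect_survey", "data.frame")
  list(design = design, abundance = ab, transects = transects)
}

# Small deterministic fingerprint of the resolved configuration (not
# cryptographic; used to tie a report to its inputs).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%010d", h)
}

#' Run the complete analysis pipeline
#'
#' Executes every stage on one experiment: input validation,
#' retentiveness indices, univariate BACI ANOVA with pooled and per-river
#' a priori contrasts and effect sizes for detritus, richness and
#' density, bio-equivalence against the reference sites (pooled and per
#' river), and the community analyses (fourth-root Bray-Curtis PERMANOVA,
#' pairwise tests before/after, NMDS with centroid trajectories, SIMPER,
#' and per-river compositional equivalence).
#'
#' @param sim a simulated experiment from [simulate_experiment()] /
#'   [null_dataset()], or `NULL` to simulate from `config`.
#' @param config a [simulation_config()] used when `sim` is `NULL`.
#' @param input_dir optionally, a directory of CSV tables from
#'   [write_experiment()] (exactly one of the three input modes applies).
#' @param alpha significance level.
#' @param R_l bio-equivalence margin.
#' @param n_perm permutations for the community tests.
#' @param n_boot bootstrap resamples for compositional equivalence.
#' @param transform transform policy for the univariate responses
#'   (`"auto"`, `"none"`, `"log"`).
#' @param nmds_restarts random starts for the ordination.
#' @return A `"report_bundle"`: list with `validation`, `retentiveness`,
#'   `univariate` (per response: anova, pooled contrast, per-river
#'   contrasts, effect sizes), `equivalence`, `community` and `manifest`.
#' @export
run_full_analysis <- function(sim = NULL, config = NULL, input_dir = NULL,
                              alpha = 0.05, R_l = 0.8, n_perm = 999,
                              n_boot = 999,
                              transform = c("auto", "none", "log"),
                              nmds_restarts = 20) {
  transform <- match.arg(transform)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 99)
  if (is.null(sim)) {
    if (!is.null(input_dir)) sim <- read_experiment(input_dir)
    else if (!is.null(config)) sim <- simulate_experiment(config)
    else stop("provide one of: sim, config, input_dir")
  }
  seed <- if (!is.null(sim$config)) sim$config$seed else 1L
  aseed <- substream_seed(seed, "analysis")

  validation <- validate_inputs(sim$design, sim$abundance, sim$transects)
  if (nrow(validation))
    warning("input diagnostics reported ", nrow(validation), " issue(s)")
  retent <- retentiveness_summary(sim$transects)

  responses <- derive_responses(sim$abundance)
  univariate <- lapply(responses, function(resp) {
    rt <- response_table(resp, transform = transform)
    an <- fit_baci_anova(rt)
    list(anova = an,
         pooled_contrast = apriori_contrast(an, "pooled"),
         per_river = per_river_contrasts(an),
         transform = attr(an, "transform"))
  })

  # bio-equivalence on raw-scale responses
  equivalence <- lapply(responses, function(resp) {
    after <- resp[resp$period == "after", ]
    ref <- after[after$treatment == "reference", ]
    ref_vals <- tapply(ref$value, ref$river, mean)
    man <- after[after$treatment == "manipulation", ]
    pooled <- equivalence_test(man$value, as.numeric(ref_vals), R_l = R_l)
    per_river <- do.call(rbind, lapply(split(man, man$river), function(d)
      cbind(river = d$river[1],
            equivalence_test(d$value, as.numeric(ref_vals), R_l = R_l))))
    rownames(per_river) <- NULL
    list(pooled = pooled, per_river = per_river)
  })

  # community analyses
  mat <- transform_abundance(abundance_matrix(sim$abundance))
  dm <- bray_curtis_matrix(mat)
  perm <- permanova(dm, sim$design, n_perm = n_perm, seed = aseed)
  pairwise <- rbind(
    pairwise_permanova(dm, sim$design, "before", n_perm, seed = aseed),
    pairwise_permanova(dm, sim$design, "after", n_perm, seed = aseed + 1))
  ord <- nmds(dm, n_restarts = nmds_restarts, seed = aseed)
  traj <- centroid_trajectories(ord, attr(dm, "info"))
  info <- attr(dm, "info")
  after_rows <- info$period == "after"
  smp <- simper(mat[after_rows, , drop = FALSE],
                info$treatment[after_rows])
  mat_ref <- transform_abundance(
    abundance_matrix(sim$abundance, include_reference = TRUE))
  dm_ref <- bray_curtis_matrix(mat_ref)
  sims <- reference_similarities(dm_ref)
  comp_equiv <- do.call(rbind, lapply(names(sims), function(rv)
    cbind(river = rv,
          composition_equivalence(sims[[rv]]$manip_to_ref,
                                  sims[[rv]]$among_controls,
                                  n_boot = n_boot, seed = aseed))))

  manifest <- list(
    package_version = as.character(utils::packageVersion("riverbaci")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    alpha = alpha, R_l = R_l, n_perm = n_perm,
    config_hash = config_hash(list(sim$config, alpha, R_l, n_perm, seed)),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))

  out <- list(validation = validation, retentiveness = retent,
              univariate = univariate, equivalence = equivalence,
              community = list(permanova = perm, pairwise = pairwise,
                               nmds = ord, trajectories = traj,
                               simper = smp,
                               composition_equivalence = comp_equiv),
              manifest = manifest)
  class(out) <- "report_bundle"
  out
}

#' Write a report bundle as CSV tables
#'
#' Emits the inferential tables of [run_full_analysis()] as plain CSV
#' files plus a `manifest.txt`, ready for plotting or archiving.
#'
#' @param bundle a `"report_bundle"`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, nm) utils::write.csv(x, file.path(dir, nm),
                                        row.names = FALSE)
  w(bundle$retentiveness, "retentiveness.csv")
  for (nm in names(bundle$univariate)) {
    u <- bundle$univariate[[nm]]
    w(u$anova, paste0("anova_", nm, ".csv"))
    w(rbind(u$pooled_contrast, u$per_river), paste0("contrasts_", nm, ".csv"))
  }
  for (nm in names(bundle$equivalence)) {
    e <- bundle$equivalence[[nm]]
    w(cbind(river = "pooled", e$pooled)[names(e$per_river)],
      paste0("equivalence_", nm, ".csv"))
  }
  w(bundle$community$permanova, "permanova.csv")
  w(bundle$community$pairwise, "pairwise_permanova.csv")
  pts <- data.frame(sample = rownames(bundle$community$nmds$points),
                    bundle$community$nmds$points)
  w(pts, "nmds_coordinates.csv")
  w(bundle$community$trajectories, "nmds_trajectories.csv")
  w(bundle$community$simper, "simper.csv")
  w(bundle$community$composition_equivalence,
    "composition_equivalence.csv")
  mf <- bundle$manifest
  writeLines(sprintf("%s: %s", names(mf), unlist(mf)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
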