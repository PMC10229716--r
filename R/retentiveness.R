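#' Surber sampling area pooled per site
#'
#' Fifteen Surber samples with a 0.30 x 0.33 m frame are pooled per site,
#' so per-site standing stocks divide pooled mass by 15 * 0.30 * 0.33 m^2.
#' @return pooled area in m^2 (1.485).
#' @export
surber_pooled_area <- function(n_samples = 15, frame_w = 0.30,
                               frame_l = 0.33) {
  n_samples * frame_w * frame_l
}

check_transect_survey <- function(survey) {
  need <- c("river", "site", "transect", "transect_length", "element_type",
            "intercept_m", "detritus_m")
  miss <- setdiff(need, names(survey))
  if (length(miss))
    stop("transect survey lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(survey$transect_length <= 0)
  if (length(bad))
    stop("zero or negative transect_length in transect(s): ",
         paste(unique(paste(survey$river[bad], survey$site[bad],
                            survey$transect[bad], sep = ":")),
               collapse = ", "))
  if (any(survey$intercept_m < 0) || any(survey$detritus_m < 0))
    stop("intercepted and detritus lengths must be nonnegative")
  invisible(survey)
}

site_key <- function(x) paste(x$river, x$site, sep = ":")

#' Linear Coverage Index from line-intercept surveys
#'
#' For each site and retentive-element type, the Linear Coverage Index
#' (LCI) is the mean over transects of intercepted metres per metre of
#' transect. The detritus LCI is computed identically from the detritus
#' lengths (summed over element types within each transect). Element types
#' never recorded at a site contribute 0.
#'
#' @param survey a transect survey `data.frame` (see
#'   [simulate_transects()] for the column layout).
#' @return list with `by_element` (data.frame: river, site, element_type,
#'   lci in m/m) and `by_site` (data.frame: river, site, lci_total,
#'   detritus_lci).
#' @export
linear_coverage_index <- function(survey) {
  check_transect_survey(survey)
  sk <- site_key(survey)
  tk <- paste(sk, survey$transect, sep = ":")
  n_transects <- tapply(survey$transect, sk,
                        function(x) length(unique(x)))
  ratio <- survey$intercept_m / survey$transect_length
  elems <- sort(unique(survey$element_type))
  sites <- unique(survey[c("river", "site")])
  sites <- sites[order(sites$river, sites$site), ]
  by_el <- expand.grid(element_type = elems,
                       idx = seq_len(nrow(sites)),
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  by_el <- data.frame(river = sites$river[by_el$idx],
                      site = sites$site[by_el$idx],
                      element_type = by_el$element_type)
  sums <- tapply(ratio, list(sk, survey$element_type), sum, default = 0)
  key <- site_key(by_el)
  by_el$lci <- sums[cbind(key, by_el$element_type)] / n_transects[key]
  by_el$lci[is.na(by_el$lci)] <- 0

  det_ratio <- survey$detritus_m / survey$transect_length
  det_by_transect <- tapply(det_ratio, tk, sum)
  t_site <- sub(":[^:]*$", "", names(det_by_transect))
  det_lci <- tapply(det_by_transect, t_site, mean)
  by_site <- data.frame(river = sites$river, site = sites$site)
  skey <- site_key(by_site)
  by_site$lci_total <- as.numeric(tapply(by_el$lci, key, sum)[skey])
  by_site$detritus_lci <- as.numeric(det_lci[skey])
  list(by_element = by_el, by_site = by_site)
}

#' Trapping Efficiency of retentive-element types
#'
#' The trapping efficiency (TE) of an element type is the mean amount (m)
#' of detritus retained per metre of that element. Within each site, the
#' ratio of summed detritus length to summed intercepted length is taken
#' (ratio of sums, so zero-intercept transects are harmless); sites where
#' the element was never intercepted are excluded; the per-site ratios are
#' then averaged across sites. With `scope = "river"` (the default) the
#' average runs over the sites of each river separately; `scope = "global"`
#' pools all sites.
#'
#' @param survey transect survey data.frame.
#' @param scope `"river"` or `"global"`.
#' @return data.frame with columns `river` (`NA` for global scope),
#'   `element_type`, `te`. Element types intercepted nowhere in a scope are
#'   reported with `te = NA` (undefined, not zero).
#' @export
trapping_efficiency <- function(survey, scope = c("river", "global")) {
  scope <- match.arg(scope)
  check_transect_survey(survey)
  elems <- sort(unique(survey$element_type))
  one_scope <- function(sv, river_label) {
    sk <- site_key(sv)
    num <- tapply(sv$detritus_m, list(sk, sv$element_type), sum, default = 0)
    den <- tapply(sv$intercept_m, list(sk, sv$element_type), sum, default = 0)
    te <- vapply(elems, function(e) {
      if (!e %in% colnames(den)) return(NA_real_)
      ok <- den[, e] > 0
      if (!any(ok)) return(NA_real_)
      mean(num[ok, e] / den[ok, e])
    }, numeric(1))
    data.frame(river = river_label, element_type = elems, te = unname(te))
  }
  if (scope == "global") {
    out <- one_scope(survey, NA_character_)
  } else {
    out <- do.call(rbind, lapply(split(survey, survey$river),
                                 function(sv) one_scope(sv, sv$river[1])))
  }
  rownames(out) <- NULL
  out
}

#' Effective retentiveness per site
#'
#' Weights each element type's Linear Coverage Index by that type's
#' Trapping Efficiency and sums over element types, converting structural
#' coverage into the expected metres of detritus retained per metre of
#' transect.
#'
#' @param lci result of [linear_coverage_index()].
#' @param te result of [trapping_efficiency()].
#' @return data.frame: river, site, effective_retentiveness (m/m).
#' @export
effective_retentiveness <- function(lci, te) {
  by_el <- lci$by_element
  global <- all(is.na(te$river))
  key <- if (global) by_el$element_type
  else paste(by_el$river, by_el$element_type)
  te_key <- if (global) te$element_type else paste(te$river, te$element_type)
  w <- te$te[match(key, te_key)]
  bad <- by_el$lci > 0 & (is.na(w))
  if (any(bad))
    stop("no trapping efficiency available for element type(s) present: ",
         paste(unique(by_el$element_type[bad]), collapse = ", "))
  contrib <- by_el$lci * ifelse(is.na(w), 0, w)
  sk <- site_key(by_el)
  er <- tapply(contrib, sk, sum)
  sites <- unique(by_el[c("river", "site")])
  sites$effective_retentiveness <- as.numeric(er[site_key(sites)])
  rownames(sites) <- NULL
  sites
}

#' Detritus standing stock per site and period
#'
#' Converts pooled dried detritus mass to areal standing stock by dividing
#' by the pooled sampled area (by default 15 Surber samples of a
#' 0.30 x 0.33 m frame, 1.485 m^2).
#'
#' @param abundance an `"abundance_table"` (or its `detritus` data.frame
#'   with columns `mass_g` and optionally `area_m2`).
#' @return data.frame: river, site, treatment, period, detritus_gm2.
#' @export
detritus_standing_stock <- function(abundance) {
  det <- if (inherits(abundance, "abundance_table")) abundance$detritus
  else abundance
  if (!all(c("mass_g") %in% names(det)))
    stop("detritus table must contain a 'mass_g' column")
  if (any(det$mass_g < 0)) stop("negative detritus mass")
  area <- if ("area_m2" %in% names(det)) det$area_m2 else surber_pooled_area()
  out <- det[intersect(c("river", "site", "treatment", "period"), names(det))]
  out$detritus_gm2 <- det$mass_g / area
  out
}

#' Per-site retentiveness summary
#'
#' Convenience wrapper joining LCI totals, detritus LCI and effective
#' retentiveness into one table per site.
#'
#' @inheritParams trapping_efficiency
#' @return data.frame: river, site, lci_total, detritus_lci,
#'   effective_retentiveness.
#' @export
retentiveness_summary <- function(survey, scope = c("river", "global")) {
  lci <- linear_coverage_index(survey)
  te <- trapping_efficiency(survey, scope)
  er <- effective_retentiveness(lci, te)
  out <- merge(lci$by_site, er, by = c("river", "site"), sort = TRUE)
  out[order(out$river, out$site), ]
}
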