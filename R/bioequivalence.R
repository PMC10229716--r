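#' Reference target for bio-equivalence tests
#'
#' The equivalence target for a response is the arithmetic mean of the
#' per-river reference-site values. Reference sites are unreplicated
#' within rivers, so the target's sampling variance is taken across
#' rivers.
#'
#' @param reference_values named numeric vector, one value per river.
#' @return the target mean.
#' @export
reference_target <- function(reference_values) {
  if (anyNA(reference_values))
    stop("missing reference value for river(s): ",
         paste(names(reference_values)[is.na(reference_values)],
               collapse = ", "))
  mean(reference_values)
}

#' Bio-equivalence test of manipulation sites against a reference target
#'
#' Computes the ratio `R` of the mean of manipulation-site values (after
#' treatment) to the mean of the reference-site values, with a Fieller
#' confidence interval for the ratio of two independent means (the
#' reference mean carries its own sampling variance across rivers). The
#' one-tailed null hypothesis `R <= R_l` is rejected at level
#' `(1 - conf) / 2` exactly when the lower bound of the two-sided
#' `conf`-level interval exceeds `R_l`; with the defaults this is a
#' one-tailed test at alpha = 0.05 using a 90% interval. The interval also
#' reports whether full equivalence (R = 1) is covered.
#'
#' @param manip_values numeric, manipulation-site values (>= 2).
#' @param reference_values numeric, per-river reference-site values.
#' @param R_l lower equivalence margin (default 0.8).
#' @param conf two-sided confidence level of the interval (default 0.90).
#' @return object of class `"equivalence_result"`: one-row data.frame with
#'   `R`, `ci_low`, `ci_high`, `R_l`, `decision` (`equivalent` /
#'   `not_shown`) and `includes_full_equivalence`.
#' @export
equivalence_test <- function(manip_values, reference_values, R_l = 0.8,
                             conf = 0.90) {
  if (length(manip_values) < 2)
    stop("need at least two manipulation values")
  if (length(reference_values) < 2)
    stop("need at least two reference values")
  a <- mean(manip_values)
  b <- mean(reference_values)
  if (b <= 0) stop("reference target must be positive")
  va <- stats::var(manip_values) / length(manip_values)
  vb <- stats::var(reference_values) / length(reference_values)
  df <- length(manip_values) + length(reference_values) - 2
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  R <- a / b
  if (va == 0 && vb == 0) {
    lo <- hi <- R
  } else {
    # roots of (a - R b)^2 = t^2 (va + R^2 vb)
    A <- b^2 - tq^2 * vb
    B <- -2 * a * b
    C <- a^2 - tq^2 * va
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      out <- data.frame(R = R, ci_low = -Inf, ci_high = Inf, R_l = R_l,
                        decision = "not_shown",
                        includes_full_equivalence = NA)
      class(out) <- c("equivalence_result", "data.frame")
      attr(out, "note") <- "reference mean not significantly > 0; Fieller interval unbounded"
      return(out)
    }
    lo <- (-B - sqrt(disc)) / (2 * A)
    hi <- (-B + sqrt(disc)) / (2 * A)
  }
  out <- data.frame(R = R, ci_low = lo, ci_high = hi, R_l = R_l,
                    decision = ifelse(lo > R_l, "equivalent", "not_shown"),
                    includes_full_equivalence = lo <= 1 & hi >= 1)
  class(out) <- c("equivalence_result", "data.frame")
  out
}

#' Bootstrap cross-check of the equivalence interval
#'
#' Percentile-bootstrap confidence interval for the ratio of means, used
#' as an independent check on the Fieller interval.
#'
#' @inheritParams equivalence_test
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
equivalence_bootstrap_ci <- function(manip_values, reference_values,
                                     conf = 0.90, n_boot = 9999, seed = 1) {
  set.seed(seed)
  n1 <- length(manip_values); n2 <- length(reference_values)
  r <- vapply(seq_len(n_boot), function(i) {
    mean(sample(manip_values, n1, replace = TRUE)) /
      mean(sample(reference_values, n2, replace = TRUE))
  }, numeric(1))
  unname(stats::quantile(r, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Compositional equivalence: similarity to the reference vs among controls
#'
#' Tests whether manipulation sites became more similar to the reference
#' site than control sites are to each other. The statistic is the mean
#' Bray-Curtis similarity between each manipulation site and the reference
#' site (after treatment) divided by the mean pairwise similarity among
#' control sites (after). The one-tailed hypothesis that this ratio is
#' <= 1 is tested by a stratified bootstrap over sites: both similarity
#' sets are resampled with replacement and the P value is the proportion
#' of bootstrap ratios at or below 1. Rejection means the manipulation
#' sites are significantly more similar to the reference than controls
#' are.
#'
#' @param sim_manip_to_ref similarities (0-100) of each manipulation site
#'   to the reference site.
#' @param sim_among_controls pairwise similarities (0-100) among control
#'   sites (needs >= 2 control sites, i.e. >= 1 pair).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return one-row data.frame: `ratio`, `P`, `significant` (at 0.05).
#' @export
composition_equivalence <- function(sim_manip_to_ref, sim_among_controls,
                                    n_boot = 9999, seed = 1) {
  if (length(sim_among_controls) < 1)
    stop("need at least two control sites (one among-control pair)")
  vals <- c(sim_manip_to_ref, sim_among_controls)
  if (any(vals < 0 | vals > 100))
    stop("similarities must lie in [0, 100]")
  if (mean(sim_among_controls) <= 0)
    stop("mean among-control similarity must be positive")
  ratio <- mean(sim_manip_to_ref) / mean(sim_among_controls)
  set.seed(seed)
  n1 <- length(sim_manip_to_ref); n2 <- length(sim_among_controls)
  boot <- vapply(seq_len(n_boot), function(i) {
    m <- mean(sample(sim_manip_to_ref, n1, replace = TRUE))
    cc <- mean(sample(sim_among_controls, n2, replace = TRUE))
    if (cc <= 0) NA_real_ else m / cc
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  P <- (sum(boot <= 1) + 1) / (length(boot) + 1)
  data.frame(ratio = ratio, P = P, significant = P <= 0.05)
}
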