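#' Build a response table for the BACI analysis
#'
#' Assembles one univariate response (one value per site and period) into
#' the balanced layout required by [fit_baci_anova()]: Treatment (control
#' vs manipulation) crossed with River, Site nested in Treatment x River,
#' and the repeated measure Time (before vs after). Reference sites are
#' excluded here; they enter the analysis only through the bio-equivalence
#' tests.
#'
#' A log10(x + 1) transform is applied when `transform = "log"`, or under
#' `"auto"` when a variance-heterogeneity diagnostic triggers: the ratio of
#' the largest to the smallest among-site cell variance (cells being
#' river x treatment x period combinations with positive variance) exceeds
#' `hetero_ratio`.
#'
#' @param data data.frame with columns `river`, `treatment`, `site`,
#'   `period`, `value`.
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @param hetero_ratio trigger threshold for the auto log rule.
#' @return A `data.frame` of class `"response_table"` with attribute
#'   `"transform"` (`"none"` or `"log"`).
#' @export
response_table <- function(data, transform = c("auto", "none", "log"),
                           hetero_ratio = 4) {
  transform <- match.arg(transform)
  need <- c("river", "treatment", "site", "period", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("response data lacks columns: ", paste(miss, collapse = ", "))
  data <- data[data$treatment != "reference", need]
  data$river <- factor(data$river)
  data$treatment <- factor(data$treatment,
                           levels = c("control", "manipulation"))
  data$period <- factor(data$period, levels = c("before", "after"))
  if (anyNA(data$treatment) || anyNA(data$period))
    stop("treatment must be control/manipulation and period before/after")
  check_balance(data)
  applied <- "none"
  if (transform == "log" ||
      (transform == "auto" && hetero_triggered(data, hetero_ratio))) {
    if (any(data$value < 0)) stop("log transform needs nonnegative values")
    data$value <- log10(data$value + 1)
    applied <- "log"
  }
  out <- data[order(data$river, data$treatment, data$site, data$period), ]
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  attr(out, "transform") <- applied
  out
}

check_balance <- function(data) {
  tab <- table(data$river, data$treatment, data$period)
  if (length(unique(as.vector(tab))) != 1 || tab[1] < 1)
    stop("unbalanced design: every river x treatment x period cell must ",
         "hold the same number of sites")
  per_site <- table(paste(data$river, data$site), data$period)
  if (any(per_site != 1))
    stop("unbalanced design: every site needs exactly one value per period")
  invisible(data)
}

# Variance heterogeneity is judged across the four Time x Treatment cells
# (pooled over rivers and sites, so each variance is well supported); the
# finer river-level cells have too few sites for a stable ratio.
hetero_triggered <- function(data, hetero_ratio) {
  cells <- interaction(data$treatment, data$period, drop = TRUE)
  v <- tapply(data$value, cells, stats::var)
  v <- v[!is.na(v) & v > 0]
  length(v) > 1 && max(v) / min(v) > hetero_ratio
}

baci_sources <- c("Treatment", "River", "Treatment x River",
                  "Between sites (within Treatment x River)",
                  "Time", "Time x Treatment", "Time x River",
                  "Time x Treatment x River", "Residual")

#' Error-term (denominator) mapping for the repeated-measures BACI table
#'
#' Applies the fixed denominator mapping of the three-factor
#' repeated-measures design to a table of mean squares: the
#' between-subject terms (Treatment, River, Treatment x River) are tested
#' over the Between-sites mean square, and the within-subject terms (Time
#' and all Time interactions) over the Residual mean square. Useful both
#' inside [fit_baci_anova()] and for reconstructing F ratios from a
#' published table of mean squares.
#'
#' @param tbl data.frame with columns `source` and `MS` (or `SS` and `df`,
#'   from which MS is computed), and optionally `df` for P values. Source
#'   names are matched loosely ("River x Treatment" and
#'   "Treatment x River" are both understood, as are "Between sites ..."
#'   variants).
#' @return the table with `MS`, `F`, `P` and `denominator_source` filled
#'   in. Error-term rows get `NA` F.
#' @export
apply_denominator_mapping <- function(tbl) {
  src <- normalize_source(tbl$source)
  if (is.null(tbl$MS)) tbl$MS <- tbl$SS / tbl$df
  between <- c("treatment", "river", "treatment:river")
  within <- c("time", "time:treatment", "time:river", "time:treatment:river")
  ms_bs <- tbl$MS[src == "between_sites"]
  ms_res <- tbl$MS[src == "residual"]
  if (!length(ms_bs) || !length(ms_res))
    stop("table must contain Between-sites and Residual rows")
  denom_ms <- ifelse(src %in% between, ms_bs,
                     ifelse(src %in% within, ms_res, NA_real_))
  tbl$F <- tbl$MS / denom_ms
  tbl$denominator_source <- ifelse(
    src %in% between, "Between sites (within Treatment x River)",
    ifelse(src %in% within, "Residual", NA))
  if (!is.null(tbl$df)) {
    df_bs <- tbl$df[src == "between_sites"]
    df_res <- tbl$df[src == "residual"]
    denom_df <- ifelse(src %in% between, df_bs,
                       ifelse(src %in% within, df_res, NA_real_))
    tbl$P <- stats::pf(tbl$F, tbl$df, denom_df, lower.tail = FALSE)
  }
  tbl
}

normalize_source <- function(x) {
  s <- tolower(gsub("[^a-z]+", " ", tolower(x)))
  s <- trimws(gsub("\\s+", " ", s))
  out <- character(length(s))
  out[grepl("between sites", s)] <- "between_sites"
  out[grepl("^residual", s)] <- "residual"
  plain <- !(grepl("between sites", s) | grepl("^residual", s))
  norm1 <- function(z) {
    parts <- strsplit(z, " x | ")[[1]]
    parts[parts == "period"] <- "time"
    paste(sort(parts), collapse = ":")
  }
  out[plain] <- vapply(s[plain], norm1, character(1))
  # canonical order-insensitive labels
  out[out == "river:treatment"] <- "treatment:river"
  out[out %in% c("time:treatment", "treatment:time")] <- "time:treatment"
  out[out == "river:time"] <- "time:river"
  out[out == "river:time:treatment"] <- "time:treatment:river"
  out
}

#' Fit the three-factor repeated-measures BACI ANOVA
#'
#' Treatment (fixed: control vs manipulation) is crossed with River
#' (fixed) and with the repeated measure Time (before vs after); Site is
#' nested within Treatment x River and carries the between-subject error.
#' Sums of squares follow the balanced-design decomposition (computed via
#' [stats::aov()] with an error stratum per site); F ratios use the fixed
#' denominator mapping of [apply_denominator_mapping()].
#'
#' @param data a [response_table()] (or a data.frame coercible to one;
#'   coercion uses `transform = "auto"`).
#' @return data.frame of class `"baci_anova"`: source, df, SS, MS, F, P,
#'   denominator_source, in the standard source order. The response table
#'   and its transform tag are kept as attributes for downstream
#'   contrasts.
#' @export
fit_baci_anova <- function(data) {
  if (!inherits(data, "response_table")) data <- response_table(data)
  d <- as.data.frame(data)
  d$usite <- interaction(d$river, d$site, drop = TRUE)
  fit <- stats::aov(value ~ treatment * river * period + Error(usite),
                    data = d)
  s <- summary(fit)
  btw <- s[["Error: usite"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  pick <- function(stratum, label) {
    i <- match(label, trimws(rownames(stratum)))
    c(df = stratum$Df[i], SS = stratum$`Sum Sq`[i])
  }
  rows <- rbind(pick(btw, "treatment"), pick(btw, "river"),
                pick(btw, "treatment:river"), pick(btw, "Residuals"),
                pick(wth, "period"), pick(wth, "treatment:period"),
                pick(wth, "river:period"),
                pick(wth, "treatment:river:period"),
                pick(wth, "Residuals"))
  tbl <- data.frame(source = baci_sources, df = rows[, "df"],
                    SS = rows[, "SS"])
  tbl$MS <- tbl$SS / tbl$df
  ss_total <- sum((d$value - mean(d$value))^2)
  if (ss_total == 0) {
    # constant response: every SS is zero and F is undefined
    tbl$SS <- tbl$MS <- 0
    tbl <- apply_denominator_mapping(tbl)
    tbl$F <- tbl$P <- NA_real_
  } else {
    if (tbl$MS[tbl$source == "Residual"] == 0)
      stop("zero Residual mean square: within-site variation is degenerate")
    tbl <- apply_denominator_mapping(tbl)
  }
  class(tbl) <- c("baci_anova", "data.frame")
  attr(tbl, "data") <- data
  attr(tbl, "transform") <- attr(data, "transform")
  tbl
}

baci_cell_means <- function(d, scope = "pooled") {
  if (!identical(scope, "pooled")) {
    if (!scope %in% levels(d$river)) stop("unknown river: ", scope)
    d <- d[d$river == scope, ]
  }
  cell <- interaction(d$period, d$treatment, drop = FALSE)
  m <- tapply(d$value, cell, mean)
  n <- tapply(d$value, cell, length)
  list(BC = m[["before.control"]], BM = m[["before.manipulation"]],
       AC = m[["after.control"]], AM = m[["after.manipulation"]],
       n_cell = unname(n[1]))
}

#' A priori treatment contrast of the BACI design
#'
#' Tests the planned contrast `(xBC + xBM + xAC) - 3 * xAM = 0`, where the
#' subscripts denote cell means of Before/After crossed with
#' Control/Manipulation. A treatment effect makes the manipulation-after
#' mean depart from the other three cells, so the contrast estimate is
#' negative for an increase. The single-degree-of-freedom F uses the
#' Residual mean square of the full repeated-measures fit as its error
#' term; the P value is the (two-sided) upper tail of F(1, df_res), with
#' the sign of the estimate carried separately for direction.
#'
#' @param anova a fitted [fit_baci_anova()] table.
#' @param scope `"pooled"` for all rivers, or a river label for a
#'   single-river contrast within the Time x Treatment x River stratum.
#' @return object of class `"baci_contrast"`: a one-row data.frame with
#'   the scope, the four cell means, the contrast estimate, F, P, the
#'   direction, the baseline mean `Y` and the effect size (%).
#' @export
apriori_contrast <- function(anova, scope = "pooled") {
  stopifnot(inherits(anova, "baci_anova"))
  d <- attr(anova, "data")
  cm <- baci_cell_means(d, scope)
  L <- cm$BC + cm$BM + cm$AC - 3 * cm$AM
  ms_res <- anova$MS[anova$source == "Residual"]
  df_res <- anova$df[anova$source == "Residual"]
  se2 <- ms_res * sum(c(1, 1, 1, -3)^2) / cm$n_cell
  Fv <- if (se2 > 0) L^2 / se2 else NA_real_
  P <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
  es <- effect_size_from_means(cm, attr(anova, "transform"))
  out <- data.frame(scope = scope, mean_BC = cm$BC, mean_BM = cm$BM,
                    mean_AC = cm$AC, mean_AM = cm$AM, estimate = L,
                    F = Fv, P = P,
                    direction = ifelse(L < 0, "increase", "decrease"),
                    Y = es$Y, effect_size_pct = es$es)
  rownames(out) <- NULL
  class(out) <- c("baci_contrast", "data.frame")
  out
}

# ES on the data scale: cell means are back-transformed first when the
# analysis ran on log10(x + 1).
effect_size_from_means <- function(cm, transform) {
  back <- function(x) if (identical(transform, "log")) 10^x - 1 else x
  Y <- (back(cm$BC) + back(cm$BM) + back(cm$AC)) / 3
  es <- if (abs(Y) < .Machine$double.eps) NA_real_
  else (back(cm$AM) - Y) / Y * 100
  list(Y = Y, es = es)
}

#' Percentage effect size of the manipulation
#'
#' `ES = (xAM - Y) / Y * 100` with `Y = (xBC + xBM + xAC) / 3`, the mean
#' of the three baseline cells. When the analysis was run on
#' log10(x + 1)-transformed data, cell means are back-transformed first so
#' the effect size stays a percentage on the raw data scale.
#'
#' @inheritParams apriori_contrast
#' @return effect size in percent (`NA` when `Y` is zero).
#' @export
effect_size <- function(anova, scope = "pooled") {
  stopifnot(inherits(anova, "baci_anova"))
  cm <- baci_cell_means(attr(anova, "data"), scope)
  effect_size_from_means(cm, attr(anova, "transform"))$es
}

#' Per-river a priori contrasts with smallest-effect-size exclusion
#'
#' Computes the effect size for every river, excludes the river with the
#' smallest absolute effect size (to preserve the independence of the
#' contrasts within the Time x Treatment x River stratum; ties are broken
#' towards the alphabetically first river, with a message), and runs the
#' a priori contrast for each remaining river against the pooled Residual
#' mean square.
#'
#' @inheritParams apriori_contrast
#' @return data.frame of per-river `"baci_contrast"` rows (one per tested
#'   river) with attribute `"excluded_river"`.
#' @export
per_river_contrasts <- function(anova) {
  stopifnot(inherits(anova, "baci_anova"))
  d <- attr(anova, "data")
  rivers <- levels(d$river)
  if (length(rivers) < 2) stop("need at least two rivers")
  es <- vapply(rivers, function(rv) effect_size(anova, rv), numeric(1))
  aes <- abs(es)
  aes[is.na(aes)] <- -Inf  # undefined ES counts as smallest
  drop_candidates <- rivers[aes == min(aes)]
  excluded <- sort(drop_candidates)[1]
  if (length(drop_candidates) > 1)
    message("tie for smallest |ES|; excluding alphabetically first: ",
            excluded)
  keep <- setdiff(rivers, excluded)
  out <- do.call(rbind, lapply(keep, function(rv) apriori_contrast(anova, rv)))
  attr(out, "excluded_river") <- excluded
  attr(out, "effect_sizes") <- es
  class(out) <- c("baci_contrast", "data.frame")
  out
}
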