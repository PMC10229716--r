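# Orthogonal projection matrices for the balanced three-factor
# repeated-measures design. Each term's block uses centred (Helmert-style)
# contrast columns, so on a balanced design the blocks are mutually
# orthogonal and the distance-based sums of squares partition additively.
baci_term_projections <- function(info) {
  trt <- factor(info$treatment, levels = c("control", "manipulation"))
  riv <- factor(info$river)
  per <- factor(info$period, levels = c("before", "after"))
  site <- interaction(info$river, info$site, drop = TRUE)
  cell <- interaction(riv, trt, drop = TRUE)

  contr_cols <- function(f) {
    stats::model.matrix(~f, contrasts.arg =
                          list(f = "contr.helmert"))[, -1, drop = FALSE]
  }
  Xt <- contr_cols(trt)
  Xr <- contr_cols(riv)
  Xp <- contr_cols(per)
  cross <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(A) * ncol(B))
    k <- 0
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      k <- k + 1
      out[, k] <- A[, i] * B[, j]
    }
    out
  }
  # site-within-(river x treatment): Helmert over sites, per cell
  site_cols <- list()
  for (cl in levels(cell)) {
    rows <- cell == cl
    s_here <- factor(as.character(site[rows]))
    H <- stats::contr.helmert(nlevels(s_here))
    for (j in seq_len(ncol(H))) {
      v <- numeric(nrow(info))
      v[rows] <- H[as.integer(s_here), j]
      site_cols[[length(site_cols) + 1]] <- v
    }
  }
  Xs <- do.call(cbind, site_cols)

  proj <- function(X) X %*% solve(crossprod(X), t(X))
  list(
    "River" = proj(Xr),
    "Treatment" = proj(Xt),
    "River x Treatment" = proj(cross(Xr, Xt)),
    "Between sites within (River x Treatment)" = proj(Xs),
    "Time" = proj(Xp),
    "Time x Treatment" = proj(cross(Xp, Xt)),
    "Time x River" = proj(cross(Xp, Xr)),
    "Time x River x Treatment" = proj(cross(Xp, cross(Xr, Xt)))
  )
}

permanova_sources <- c("River", "Treatment", "River x Treatment",
                       "Between sites within (River x Treatment)",
                       "Time", "Time x Treatment", "Time x River",
                       "Time x River x Treatment", "Residual")

gower_centred <- function(dm) {
  A <- -0.5 * dm^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

resolve_info <- function(dm, design) {
  info <- attr(dm, "info")
  if (is.null(info)) {
    if (is.null(design)) stop("no sample metadata: pass a design table")
    parts <- strsplit(rownames(dm), "|", fixed = TRUE)
    if (any(lengths(parts) != 3))
      stop("distance labels must be 'river|site|period'")
    info <- data.frame(river = vapply(parts, `[`, "", 1),
                       site = vapply(parts, `[`, "", 2),
                       period = vapply(parts, `[`, "", 3))
    key <- paste(info$river, info$site)
    dkey <- paste(design$river, design$site)
    if (!all(key %in% dkey))
      stop("distance labels do not match the design table: ",
           paste(unique(key[!key %in% dkey]), collapse = ", "))
    info$treatment <- design$treatment[match(key, dkey)]
    rownames(info) <- rownames(dm)
  }
  info
}

#' PERMANOVA for the three-factor repeated-measures BACI design
#'
#' Partitions a (Bray-Curtis) dissimilarity matrix by the same balanced
#' Treatment x River x Time model with sites nested in Treatment x River
#' as the univariate BACI ANOVA, using the Gower-centred inner-product
#' matrix, so the degrees of freedom match the univariate table exactly.
#' Pseudo-F ratios use the same denominator mapping (between-subject terms
#' over the Between-sites mean square, within-subject terms over the
#' Residual). Significance is assessed by permutation, with the strategy
#' chosen per term and reported per source row. Terms involving Treatment
#' (Treatment, River x Treatment, Time x Treatment and the three-way) are
#' tested by re-randomising the treatment allocation: whole-site blocks
#' (both periods together) are permuted among the treatment sites of each
#' river, exactly mirroring the design's stratified randomisation, which
#' makes the test exact under the no-treatment-effect null. The
#' non-randomisable terms (River, Time, Time x River) are tested by
#' permutation of residuals under the reduced model, with exchangeable
#' units from the term's error stratum: whole-site blocks across rivers
#' for River; site blocks plus random before/after swaps within sites for
#' the within-subject terms.
#'
#' @param dm dissimilarity matrix from [bray_curtis_matrix()] (or any
#'   symmetric dissimilarity matrix with sample metadata).
#' @param design design table, used when `dm` carries no metadata.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @param terms sources to test by permutation (default: all testable
#'   terms); others get `NA` P values. Useful when only one term is of
#'   interest.
#' @return data.frame of class `"permanova_table"`: source, df, SS, MS,
#'   pseudo_F, P_perm, n_unique_perms, permutation (strategy label).
#' @export
permanova <- function(dm, design = NULL, n_perm = 9999, seed = 1,
                      terms = NULL) {
  if (anyNA(dm)) stop("dissimilarity matrix contains NA")
  info <- resolve_info(dm, design)
  info <- droplevels(info[info$treatment != "reference", ])
  keep <- rownames(info)
  dm <- dm[keep, keep]
  G <- gower_centred(dm)
  P <- baci_term_projections(info)

  r <- length(unique(info$river))
  t_ <- length(unique(info$treatment))
  s <- length(unique(paste(info$river, info$site))) / (r * t_)
  dfs <- c(r - 1, t_ - 1, (r - 1) * (t_ - 1), r * t_ * (s - 1),
           1, t_ - 1, r - 1, (r - 1) * (t_ - 1), r * t_ * (s - 1))
  names(dfs) <- permanova_sources
  SS <- vapply(names(P), function(nm) sum(P[[nm]] * G), numeric(1))
  SS["Residual"] <- sum(diag(G)) - sum(SS)
  SS <- SS[permanova_sources]
  MS <- SS / dfs

  between <- c("River", "Treatment", "River x Treatment")
  within <- c("Time", "Time x Treatment", "Time x River",
              "Time x River x Treatment")
  bs <- "Between sites within (River x Treatment)"
  pseudoF <- rep(NA_real_, length(permanova_sources))
  names(pseudoF) <- permanova_sources
  pseudoF[between] <- MS[between] / MS[bs]
  pseudoF[within] <- MS[within] / MS["Residual"]

  site_f <- factor(paste(info$river, info$site))
  n <- nrow(info)
  I <- diag(n)
  P_full <- Reduce(`+`, P)
  set.seed(seed)
  Pp <- rep(NA_real_, length(permanova_sources))
  names(Pp) <- permanova_sources
  n_unique <- rep(NA_real_, length(permanova_sources))
  names(n_unique) <- permanova_sources
  trt_terms <- c("Treatment", "River x Treatment", "Time x Treatment",
                 "Time x River x Treatment")
  strategy <- c("residuals: whole sites",
                "treatment re-randomisation within rivers",
                "treatment re-randomisation within rivers", NA,
                "residuals: site blocks + period swaps",
                "treatment re-randomisation within rivers",
                "residuals: site blocks + period swaps",
                "treatment re-randomisation within rivers", NA)
  names(strategy) <- permanova_sources

  # rows of each site, ordered by period so that permuting whole sites
  # keeps before/after aligned across site positions
  site_rows <- lapply(split(seq_len(n), site_f), function(ix)
    ix[order(info$period[ix])])
  n_site <- length(site_rows)
  testable <- c(between, within)
  if (is.null(terms)) terms <- testable
  if (!all(terms %in% testable))
    stop("untestable term(s): ",
         paste(setdiff(terms, testable), collapse = ", "))
  river_of_site <- vapply(split(as.character(info$river), site_f),
                          `[`, "", 1)
  block_idx <- function(pm, swap = NULL) {
    idx <- integer(n)
    for (bb in seq_len(n_site)) {
      src <- site_rows[[pm[bb]]]
      if (!is.null(swap) && swap[bb]) src <- rev(src)
      idx[site_rows[[bb]]] <- src
    }
    idx
  }
  for (nm in terms) {
    is_between <- nm %in% between
    randomise <- nm %in% trt_terms
    P_den <- if (is_between) P[[bs]] else I - P_full
    df_den <- if (is_between) dfs[bs] else dfs["Residual"]
    f_of <- function(Gm) {
      (sum(P[[nm]] * Gm) / dfs[nm]) / (sum(P_den * Gm) / df_den)
    }
    if (randomise) {
      # exact re-randomisation of the treatment allocation on the raw
      # distance matrix: whole sites shuffled within their river
      Guse <- G
    } else {
      reduced <- setdiff(names(P), nm)
      if (is_between) reduced <- setdiff(reduced, bs)
      Rm <- I - Reduce(`+`, P[reduced])
      Guse <- Rm %*% G %*% Rm
    }
    f_obs <- f_of(Guse)
    keys <- character(n_perm)
    f_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      if (randomise) {
        pm <- seq_len(n_site)
        for (rv in unique(river_of_site)) {
          ix <- which(river_of_site == rv)
          pm[ix] <- ix[sample(length(ix))]
        }
        idx <- block_idx(pm)
      } else if (is_between) {
        idx <- block_idx(sample(n_site))
      } else {
        # site blocks permuted plus random before/after swaps: within-site
        # residual differences are exchangeable across sites and symmetric
        # in sign under the reduced model
        idx <- block_idx(sample(n_site), stats::runif(n_site) < 0.5)
      }
      keys[b] <- paste(idx, collapse = ",")
      f_perm[b] <- f_of(Guse[idx, idx])
    }
    Pp[nm] <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_unique[nm] <- length(unique(keys))
  }
  out <- data.frame(source = permanova_sources, df = as.numeric(dfs),
                    SS = as.numeric(SS), MS = as.numeric(MS),
                    pseudo_F = as.numeric(pseudoF),
                    P_perm = as.numeric(Pp),
                    n_unique_perms = as.numeric(n_unique),
                    permutation = as.character(strategy), row.names = NULL)
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Pairwise two-group PERMANOVA (control vs manipulation within a period)
#'
#' One-way permutational test between the control and manipulation
#' communities of a single period, pooled over rivers. Reports
#' `t = sqrt(pseudo-F)` as in pairwise PRIMER-style output. Group labels
#' are permuted over sites within each river (or freely when all samples
#' share one river), mirroring the stratified treatment randomisation.
#'
#' @inheritParams permanova
#' @param period `"before"` or `"after"`.
#' @return one-row data.frame: period, t, pseudo_F, P_perm, df.
#' @export
pairwise_permanova <- function(dm, design = NULL,
                               period = c("after", "before"),
                               n_perm = 9999, seed = 1) {
  period <- match.arg(period)
  info <- resolve_info(dm, design)
  keep <- info$treatment %in% c("control", "manipulation") &
    info$period == period
  info <- info[keep, ]
  dm <- dm[rownames(info), rownames(info)]
  g <- factor(info$treatment)
  if (any(table(g) < 2)) stop("each group needs at least two samples")
  G <- gower_centred(dm)
  x <- as.numeric(g == levels(g)[2])
  x <- x - mean(x)
  Pg <- outer(x, x) / sum(x^2)
  n <- nrow(G)
  f_of <- function(Gm, ord) {
    ss_b <- sum(Pg * Gm[ord, ord])
    ss_w <- sum(diag(Gm)) - ss_b
    (ss_b / 1) / (ss_w / (n - 2))
  }
  f_obs <- f_of(G, seq_len(n))
  set.seed(seed)
  strata <- split(seq_len(n), info$river)
  shuffle <- function() {
    ord <- seq_len(n)
    for (ix in strata) ord[ix] <- ix[sample(length(ix))]
    ord
  }
  f_perm <- vapply(seq_len(n_perm), function(b) f_of(G, shuffle()),
                   numeric(1))
  P <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  data.frame(period = period, t = sqrt(f_obs), pseudo_F = f_obs,
             P_perm = P, df = n - 2)
}
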