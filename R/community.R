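#' Sample-by-taxon abundance matrix
#'
#' Reshapes the long abundance table into a samples (site-by-period) by
#' taxa count matrix for the multivariate analyses. Sample metadata travel
#' in `attr(, "info")`.
#'
#' @param abundance an `"abundance_table"` or its long `counts` data.frame.
#' @param include_reference keep reference sites (needed for the
#'   similarity-to-reference analyses)?
#' @return numeric matrix, rows labelled `river|site|period`.
#' @export
abundance_matrix <- function(abundance, include_reference = FALSE) {
  counts <- if (inherits(abundance, "abundance_table")) abundance$counts
  else abundance
  if (!include_reference) counts <- counts[counts$treatment != "reference", ]
  counts$period <- factor(counts$period, levels = c("before", "after"))
  lab <- paste(counts$river, counts$site, counts$period, sep = "|")
  m <- as.matrix(stats::xtabs(count ~ lab + taxon,
                              data = cbind(counts, lab = lab)))
  names(dimnames(m)) <- NULL
  info <- counts[!duplicated(lab), c("river", "site", "treatment", "period")]
  rownames(info) <- lab[!duplicated(lab)]
  attr(m, "info") <- info[rownames(m), ]
  m
}

#' Fourth-root transform of abundances
#'
#' The standard down-weighting transform for community data before
#' Bray-Curtis: elementwise `x^0.25`.
#'
#' @param counts nonnegative numeric matrix or vector.
#' @return transformed object (attributes preserved).
#' @export
transform_abundance <- function(counts) {
  if (any(counts < 0)) stop("abundances must be nonnegative")
  out <- counts^0.25
  attributes(out) <- attributes(counts)
  out
}

#' Bray-Curtis dissimilarity matrix on the 0-100 scale
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' `100 * sum|x - y| / sum(x + y)` between sample rows (via
#' [vegan::vegdist]). Pairs in which both samples are entirely zero have
#' no defined dissimilarity and are returned as `NA` with a warning.
#'
#' @param mat samples-by-taxa matrix (usually fourth-root transformed).
#' @return symmetric matrix with zero diagonal, values in \[0, 100\],
#'   `attr(, "metric") = "bray_curtis"`; sample metadata (`attr "info"`)
#'   are carried through if present.
#' @export
bray_curtis_matrix <- function(mat) {
  if (nrow(mat) < 2) stop("need at least two samples")
  empty <- rowSums(mat) == 0
  d <- suppressWarnings(vegan::vegdist(mat, method = "bray"))
  dm <- 100 * as.matrix(d)
  if (sum(empty) >= 2) {
    dm[empty, empty] <- NA_real_
    warning("dissimilarity undefined for pairs of all-zero samples; ",
            "returned as NA")
  }
  diag(dm) <- 0
  attr(dm, "metric") <- "bray_curtis"
  attr(dm, "info") <- attr(mat, "info")
  dm
}

#' Bray-Curtis similarities (100 - dissimilarity)
#' @param dm a dissimilarity matrix from [bray_curtis_matrix()].
#' @return matrix of similarities on the 0-100 scale.
#' @export
similarity_matrix <- function(dm) {
  s <- 100 - dm
  attr(s, "info") <- attr(dm, "info")
  s
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Two-dimensional NMDS minimising Kruskal's stress-1, via
#' [vegan::monoMDS]. The first start uses metric scaling, the remaining
#' `n_restarts - 1` use seeded random configurations; the lowest-stress
#' solution is returned, centred and rotated to its principal axes.
#'
#' @param dm dissimilarity matrix (0-100 scale) or `dist`.
#' @param k dimensions (default 2).
#' @param n_restarts number of starts (default 20).
#' @param seed integer seed.
#' @param maxit,tol iteration cap and convergence tolerance passed to the
#'   optimiser.
#' @return object of class `"nmds_result"`: list with `points` (n x k),
#'   `stress` (final stress-1), `n_restarts`, `converged` (did the best
#'   start converge?) and `restart_stress` (stress per start).
#' @export
nmds <- function(dm, k = 2, n_restarts = 20, seed = 1, maxit = 500,
                 tol = 1e-6) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  if (n < 4) stop("need at least four samples")
  if (anyNA(d)) stop("dissimilarity matrix contains NA; drop empty samples")
  fits <- vector("list", n_restarts)
  set.seed(seed)
  for (i in seq_len(n_restarts)) {
    fits[[i]] <- if (i == 1) {
      vegan::monoMDS(d, k = k, model = "global", maxit = maxit,
                     smin = 1e-7, sratmax = 1 - tol)
    } else {
      y0 <- matrix(stats::rnorm(n * k), n, k)
      vegan::monoMDS(d, y = y0, k = k, model = "global", maxit = maxit,
                     smin = 1e-7, sratmax = 1 - tol)
    }
  }
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  best <- fits[[which.min(stresses)]]
  converged <- best$icause != 1  # 1 = stopped only by the iteration cap
  if (!converged)
    warning("no restart converged; returning the best solution found")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pr <- stats::prcomp(pts, center = FALSE)
  pts <- pr$x[, seq_len(k), drop = FALSE]
  dimnames(pts) <- list(labels(d), paste0("NMDS", seq_len(k)))
  out <- list(points = pts, stress = best$stress,
              n_restarts = n_restarts, converged = converged,
              restart_stress = stresses)
  class(out) <- "nmds_result"
  out
}

#' SIMPER: taxon contributions to between-group dissimilarity
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for every between-group sample pair, taxon
#' `k` contributes `100 |x_k - y_k| / sum(x + y)`; contributions are
#' averaged over pairs, so they sum exactly to the average between-group
#' dissimilarity. The ratio of mean contribution to its standard
#' deviation over pairs flags consistent discriminators.
#'
#' @param mat samples-by-taxa matrix (transformed scale).
#' @param groups two-level factor over the rows of `mat`.
#' @return data.frame of class `"simper_result"`, one row per taxon
#'   ordered by decreasing contribution: `taxon`, `average` (contribution
#'   to dissimilarity, 0-100 scale), `sd`, `ratio`, `cumulative_pct`;
#'   `attr(, "average_dissimilarity")` holds the total.
#' @export
simper <- function(mat, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("simper needs exactly two groups")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  if (!length(g1) || !length(g2)) stop("each group needs >= 1 sample")
  pairs <- expand.grid(i = g1, j = g2)
  contrib <- matrix(NA_real_, nrow(pairs), ncol(mat),
                    dimnames = list(NULL, colnames(mat)))
  skipped <- 0L
  for (p in seq_len(nrow(pairs))) {
    x <- mat[pairs$i[p], ]; y <- mat[pairs$j[p], ]
    den <- sum(x + y)
    if (den == 0) { skipped <- skipped + 1L; next }
    contrib[p, ] <- 100 * abs(x - y) / den
  }
  if (skipped > 0)
    warning(skipped, " all-zero sample pair(s) skipped")
  ok <- stats::complete.cases(contrib)
  avg <- colMeans(contrib[ok, , drop = FALSE])
  sdv <- apply(contrib[ok, , drop = FALSE], 2, stats::sd)
  out <- data.frame(taxon = colnames(mat), average = avg, sd = sdv,
                    ratio = ifelse(sdv > 0, avg / sdv, NA_real_))
  out <- out[order(-out$average), ]
  total <- sum(out$average)
  out$cumulative_pct <- if (total > 0) cumsum(out$average) / total * 100
  else NA_real_
  rownames(out) <- NULL
  class(out) <- c("simper_result", "data.frame")
  attr(out, "average_dissimilarity") <- total
  out
}

#' Centroid trajectories of community change
#'
#' For each river-by-treatment group, the centroid of the before samples
#' and of the after samples in ordination space, and the displacement
#' between them (arrow start and end for trajectory plots).
#'
#' @param ord an `"nmds_result"` or a coordinate matrix with sample
#'   metadata in `attr(, "info")`.
#' @param info optional data.frame (river, treatment, period) aligned with
#'   the coordinate rows; defaults to the attached metadata.
#' @return data.frame: river, treatment, x_before, y_before, x_after,
#'   y_after, dx, dy, length.
#' @export
centroid_trajectories <- function(ord, info = NULL) {
  pts <- if (inherits(ord, "nmds_result")) ord$points else ord
  if (is.null(info)) info <- attr(pts, "info")
  if (is.null(info))
    stop("sample metadata needed: pass `info` with river/treatment/period")
  stopifnot(nrow(info) == nrow(pts))
  grp <- interaction(info$river, info$treatment, drop = TRUE)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    rows <- grp == g
    b <- rows & info$period == "before"
    a <- rows & info$period == "after"
    cb <- colMeans(pts[b, , drop = FALSE])
    ca <- colMeans(pts[a, , drop = FALSE])
    data.frame(river = info$river[rows][1],
               treatment = info$treatment[rows][1],
               x_before = cb[1], y_before = cb[2],
               x_after = ca[1], y_after = ca[2],
               dx = ca[1] - cb[1], dy = ca[2] - cb[2],
               length = sqrt(sum((ca - cb)^2)), row.names = NULL)
  }))
  out[order(out$river, out$treatment), ]
}
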