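#' One-way ANOVA with Tukey HSD letter display
#'
#' Compares group means (e.g. detritus densities across rivers before the
#' manipulation) with a one-way ANOVA followed by Tukey's Honestly
#' Significant Difference test, and summarises the pairwise outcomes as a
#' compact letter display: groups that do not differ significantly share a
#' letter.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level for the pairwise tests.
#' @return list with `anova` (the [stats::aov] summary table), `means`
#'   (data.frame: group, n, mean, letters, ordered by decreasing mean) and
#'   `tukey` (pairwise comparisons from [stats::TukeyHSD]).
#' @export
one_way_anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2))
    stop("each group needs at least two values for Tukey's HSD")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  sig <- tk[, "p adj"] < alpha
  means <- tapply(values, groups, mean)
  ord <- names(sort(means, decreasing = TRUE))
  letters <- compact_letter_display(ord, pairs, sig)
  out <- data.frame(group = ord, n = as.integer(table(groups)[ord]),
                    mean = as.numeric(means[ord]), letters = letters[ord])
  rownames(out) <- NULL
  list(anova = summary(fit)[[1]], means = out,
       tukey = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                          diff = tk[, "diff"], p_adj = tk[, "p adj"],
                          significant = sig, row.names = NULL))
}

# Insert-and-absorb compact letter display. `order` lists groups by
# decreasing mean; `pairs` is a 2-column matrix of group labels with the
# logical `sig` marking significantly different pairs. Returns a named
# character vector of letter strings.
compact_letter_display <- function(order, pairs, sig) {
  cols <- list(order)  # each column = set of groups sharing a letter
  sig_pairs <- pairs[sig, , drop = FALSE]
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[k, 1]; b <- sig_pairs[k, 2]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb: drop duplicates, then columns that are subsets of another
    new_cols <- unique(lapply(new_cols, sort))
    new_cols <- new_cols[lengths(new_cols) > 0]
    keep <- vapply(seq_along(new_cols), function(i) {
      !any(vapply(seq_along(new_cols), function(j)
        i != j && all(new_cols[[i]] %in% new_cols[[j]]), logical(1)))
    }, logical(1))
    cols <- new_cols[keep]
  }
  # order columns by the highest-ranked group they contain
  rank1 <- vapply(cols, function(col) min(match(col, order)), numeric(1))
  cols <- cols[order(rank1)]
  out <- vapply(order, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col,
                               logical(1)))], collapse = "")
  }, character(1))
  names(out) <- order
  out
}
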