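# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# Balanced BACI response data with controllable structure.
# `effect` is added to manipulation-after values; `noise_sd` gaussian.
make_response <- function(n_rivers = 3, n_sites = 2, effect = 0,
                          noise_sd = 1, seed = 1, base = 10) {
  set.seed(seed)
  g <- expand.grid(site = paste0("S", seq_len(n_sites)),
                   treatment = c("control", "manipulation"),
                   river = paste0("R", seq_len(n_rivers)),
                   period = c("before", "after"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$site <- paste0(g$site, "_", substr(g$treatment, 1, 1))
  g$value <- base + stats::rnorm(nrow(g), 0, noise_sd) +
    effect * (g$treatment == "manipulation" & g$period == "after")
  g
}

# Independent balanced-decomposition oracle for the BACI sums of squares,
# computed straight from marginal means (no aov, no projections).
oracle_baci_ss <- function(d) {
  d$treatment <- factor(d$treatment)
  d$river <- factor(d$river)
  d$period <- factor(d$period)
  usite <- interaction(d$river, d$site)
  N <- nrow(d)
  g <- mean(d$value)
  m_t <- tapply(d$value, d$treatment, mean)
  m_r <- tapply(d$value, d$river, mean)
  m_p <- tapply(d$value, d$period, mean)
  m_tr <- tapply(d$value, list(d$treatment, d$river), mean)
  m_tp <- tapply(d$value, list(d$treatment, d$period), mean)
  m_rp <- tapply(d$value, list(d$river, d$period), mean)
  m_trp <- tapply(d$value, list(d$treatment, d$river, d$period), mean)
  m_s <- tapply(d$value, usite, mean)
  t_ <- nlevels(d$treatment); r <- nlevels(d$river); p <- 2
  s <- N / (t_ * r * p)
  ss_t <- (N / t_) * sum((m_t - g)^2)
  ss_r <- (N / r) * sum((m_r - g)^2)
  ss_tr <- (N / (t_ * r)) * sum((m_tr - outer(m_t, rep(1, r)) -
                                   outer(rep(1, t_), m_r) + g)^2)
  ss_p <- (N / p) * sum((m_p - g)^2)
  ss_tp <- (N / (t_ * p)) * sum((m_tp - outer(m_t, rep(1, p)) -
                                   outer(rep(1, t_), m_p) + g)^2)
  ss_rp <- (N / (r * p)) * sum((m_rp - outer(m_r, rep(1, p)) -
                                  outer(rep(1, r), m_p) + g)^2)
  trp_dev <- m_trp
  for (i in seq_len(t_)) for (j in seq_len(r)) for (k in seq_len(p))
    trp_dev[i, j, k] <- m_trp[i, j, k] - m_tr[i, j] - m_tp[i, k] -
      m_rp[j, k] + m_t[i] + m_r[j] + m_p[k] - g
  ss_trp <- (N / (t_ * r * p)) * sum(trp_dev^2)
  # between sites: site means around their treatment x river cell mean
  cellf <- interaction(d$treatment, d$river)
  ss_bs <- 0
  for (u in levels(usite)) {
    rows <- usite == u
    cm <- mean(d$value[cellf == unique(cellf[rows])])
    ss_bs <- ss_bs + p * (mean(d$value[rows]) - cm)^2
  }
  ss_tot <- sum((d$value - g)^2)
  ss_res <- ss_tot - ss_t - ss_r - ss_tr - ss_bs - ss_p - ss_tp - ss_rp -
    ss_trp
  c(Treatment = ss_t, River = ss_r, `Treatment x River` = ss_tr,
    `Between sites (within Treatment x River)` = ss_bs, Time = ss_p,
    `Time x Treatment` = ss_tp, `Time x River` = ss_rp,
    `Time x Treatment x River` = ss_trp, Residual = ss_res)
}

# Independent least-squares oracle for the a priori contrast: fits the
# full model by lm (site fixed effects + treatment x river x period
# cells), then tests L = BC + BM + AC - 3 AM from the cell means with the
# lm residual variance.
oracle_contrast <- function(d, scope = "pooled") {
  d$usite <- interaction(d$river, d$site)
  d$cell <- interaction(d$treatment, d$river, d$period)
  fit <- stats::lm(value ~ usite + cell, data = d)
  sig2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  dd <- if (identical(scope, "pooled")) d else d[d$river == scope, ]
  m <- tapply(dd$value, list(dd$treatment, dd$period), mean)
  n_cell <- nrow(dd) / 4
  L <- m["control", "before"] + m["manipulation", "before"] +
    m["control", "after"] - 3 * m["manipulation", "after"]
  Fv <- L^2 / (sig2 * 12 / n_cell)
  list(L = L, F = Fv,
       P = stats::pf(Fv, 1, fit$df.residual, lower.tail = FALSE),
       df_res = fit$df.residual)
}

# Hand-built transect survey rows.
transect_rows <- function(river, site, transect, length, element,
                          intercept, detritus) {
  data.frame(river = river, site = site, transect = transect,
             transect_length = length, element_type = element,
             intercept_m = intercept, detritus_m = detritus)
}

# Tiny community fixture: two groups of samples drawn around distinct
# taxon profiles.
make_community <- function(n_per_group = 4, n_taxa = 12, shift = 0,
                           seed = 1) {
  set.seed(seed)
  base <- exp(stats::rnorm(n_taxa, 2, 0.5))
  other <- base * exp(shift * stats::rnorm(n_taxa, 1, 0.2))
  m <- rbind(
    t(replicate(n_per_group, stats::rpois(n_taxa, base))),
    t(replicate(n_per_group, stats::rpois(n_taxa, other))))
  rownames(m) <- paste0("s", seq_len(2 * n_per_group))
  colnames(m) <- paste0("T", seq_len(n_taxa))
  list(mat = m, groups = rep(c("g1", "g2"), each = n_per_group))
}
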