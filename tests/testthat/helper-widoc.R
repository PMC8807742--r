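# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / grid search) and never reuse package internals.

# Exhaustive pairwise win-fraction AUC (ties count 1/2).
oracle_auc <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  wins <- 0
  for (x in cs) wins <- wins + sum(x > ct) + 0.5 * sum(x == ct)
  wins / (length(cs) * length(ct))
}

# Single-beta maximum likelihood by two-stage 2-D grid search on log shapes.
oracle_single_beta_mle <- function(x, steps = 60) {
  nll <- function(a, b) -mean(dbeta(x, a, b, log = TRUE))
  ctr <- log(c(2, 2))
  width <- log(400)
  for (level in 1:3) {
    la <- seq(ctr[1] - width, ctr[1] + width, length.out = steps)
    lb <- seq(ctr[2] - width, ctr[2] + width, length.out = steps)
    grid <- expand.grid(la = la, lb = lb)
    vals <- mapply(function(u, v) nll(exp(u), exp(v)), grid$la, grid$lb)
    best <- grid[which.min(vals), ]
    ctr <- c(best$la, best$lb)
    width <- width / (steps / 6)
  }
  list(a = exp(ctr[1]), b = exp(ctr[2]), nll = nll(exp(ctr[1]), exp(ctr[2])))
}

# Constrained least-squares deconvolution by simplex grid search.
oracle_fractions_grid <- function(centroid, d, step = 0.02) {
  k <- ncol(centroid)
  fr <- seq(0, 1, by = step)
  best <- NULL
  best_rss <- Inf
  grid3 <- expand.grid(f1 = fr, f2 = fr, f3 = fr)
  grid3 <- grid3[rowSums(grid3) <= 1 + 1e-9, ]
  for (i in seq_len(nrow(grid3))) {
    f <- c(unlist(grid3[i, ]), 1 - sum(grid3[i, ]))
    rss <- sum((centroid %*% f - d)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- f
    }
  }
  setNames(best, colnames(centroid))
}

# Small planted-signal world shared across tests.
make_world <- function(n_cpgs = 300, n_cases = 40, n_controls = 60,
                       n_informative = 20, delta = 0.1, noise_sd = 0.02,
                       seed = 42, fractions = fraction_model("ic_uniform"),
                       ...) {
  pr <- generate_profiles(n_cpgs, seed = seed)
  pool <- subset(pr$profiles, cell_type == "epithelial" & is.na(marker_for))
  ok <- pool$a / (pool$a + pool$b) + delta
  inf <- head(pool$cpg_id[ok > 0.05 & ok < 0.95], n_informative)
  eff <- if (n_informative > 0) effect_spec(inf, delta) else NULL
  ch <- generate_cohort(pr, n_cases, n_controls, effect = eff,
                        fractions = fractions,
                        noise_sd = noise_sd, seed = seed + 1, ...)
  list(profiles = pr, cohort = ch, effect = eff)
}
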