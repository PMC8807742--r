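# Evaluation layer: rank-based AUC, median-unbiased (mid-p) odds ratios,
# quartile tables, region enrichment, PRS, PMR.

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (all(labels %in% c("case", "control"))) return(labels == "case")
  abort("labels must be logical, 0/1, or 'case'/'control'.")
}

# Mann-Whitney AUC with ties counted 1/2.
roc_auc <- function(scores, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong-type confidence interval
#'
#' The AUC is the Mann-Whitney U statistic scaled by the number of
#' case/control pairs, with ties counted one half. The confidence interval
#' uses the asymptotic rank-based (DeLong) variance built from per-sample
#' placement values.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case/control labels (logical, 0/1, or `"case"`/`"control"`).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `conf_lo`, `conf_hi`, `n_case`,
#'   `n_control`.
#' @examples
#' roc_auc_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc_ci <- function(scores, labels, conf_level = 0.95) {
  is_case <- as_case_logical(labels)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  auc <- roc_auc(scores, is_case)
  x <- scores[is_case]; y <- scores[!is_case]
  # placement values: fraction of opposite-class scores beaten (ties = 1/2)
  v10 <- vapply(x, function(s) (sum(s > y) + 0.5 * sum(s == y)) / n0, numeric(1))
  v01 <- vapply(y, function(s) (sum(x > s) + 0.5 * sum(x == s)) / n1, numeric(1))
  v <- var(v10) / n1 + var(v01) / n0
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(v, 0))
  tibble(auc = auc, conf_lo = max(0, auc - half), conf_hi = min(1, auc + half),
         n_case = n1, n_control = n0)
}

# log-pmf weights of Fisher's noncentral hypergeometric distribution over
# the support of the exposed-case cell, given margins and odds ratio psi.
nchg_weights <- function(a, b, c, d, psi) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  xs <- max(0L, n1 - m2):min(m1, n1)
  lw <- lchoose(m1, xs) + lchoose(m2, n1 - xs) + xs * log(psi)
  w <- exp(lw - max(lw))
  list(xs = xs, p = w / sum(w))
}

#' Mid-p tail probability of a 2x2 table at a given odds ratio
#'
#' The upper mid-p tail \eqn{P(X > a) + \frac12 P(X = a)} of Fisher's
#' noncentral hypergeometric distribution for the exposed-case cell,
#' conditioning on both margins. The median-unbiased OR estimate is the
#' `psi` at which this equals 0.5.
#'
#' @param a,b,c,d Exposed-case, exposed-control, reference-case,
#'   reference-control counts.
#' @param psi Odds ratio at which to evaluate.
#' @return The upper mid-p tail probability.
#' @export
midp_tail_probability <- function(a, b, c, d, psi) {
  w <- nchg_weights(a, b, c, d, psi)
  sum(w$p[w$xs > a]) + 0.5 * sum(w$p[w$xs == a])
}

midp_root <- function(a, b, c, d, target, lower_tail = FALSE) {
  f <- function(lpsi) {
    up <- midp_tail_probability(a, b, c, d, exp(lpsi))
    (if (lower_tail) 1 - up else up) - target
  }
  exp(uniroot(f, c(-40, 40), tol = 1e-12)$root)
}

#' Median-unbiased (mid-p) odds ratio with exact mid-p confidence interval
#'
#' The point estimate is the odds-ratio value at which the one-sided mid-p
#' tail probability of the conditional (noncentral hypergeometric)
#' distribution of the 2x2 table equals one half; the confidence bounds
#' invert the mid-p tails at `(1 - conf_level) / 2`. With a zero cell the
#' estimate sits on the boundary (0 or `Inf`) and the affected bound is
#' reported as unbounded.
#'
#' @param a,b,c,d Non-negative counts: exposed-case, exposed-control,
#'   reference-case, reference-control. The odds ratio estimated is
#'   `(a * d) / (b * c)`-oriented. All four margins must be positive.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf_lo`, `conf_hi`.
#' @examples
#' midp_odds_ratio(57, 74, 3, 75)  # ~18.2
#' @export
midp_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort("counts must be non-negative integers.")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    abort("all margins of the 2x2 table must be positive.")
  }
  alpha <- 1 - conf_level
  sup <- range(max(0, (a + c) - (c + d)), min(a + b, a + c))
  at_min <- a == sup[1]; at_max <- a == sup[2]
  est <- if (at_min) 0 else if (at_max) Inf else midp_root(a, b, c, d, 0.5)
  lo <- if (at_min) 0 else midp_root(a, b, c, d, alpha / 2)
  hi <- if (at_max) Inf else midp_root(a, b, c, d, alpha / 2, lower_tail = TRUE)
  tibble(estimate = est, conf_lo = lo, conf_hi = hi)
}

#' Quartile odds-ratio table against a control-derived reference
#'
#' Cutpoints are the 25/50/75 percentiles (linear interpolation between
#' order statistics) of `reference_scores` — typically the control scores of
#' the internal validation set, so that control counts differ by at most one
#' across quartiles. Quartile intervals are closed on the right. Unadjusted
#' odds ratios compare each quartile to the first via
#' [midp_odds_ratio()]; when covariates are supplied, adjusted ORs come from
#' a logistic regression of case status on quartile indicators plus the
#' covariates, with Wald intervals, and non-convergence is reported rather
#' than silently dropped.
#'
#' @param scores Index values of the evaluated samples.
#' @param labels Case/control labels aligned with `scores`.
#' @param reference_scores Control score distribution defining the
#'   cutpoints.
#' @param covariates Optional data frame of covariates (one row per
#'   sample).
#' @param conf_level Confidence level.
#' @return A `wid_quartile_table` tibble: `quartile`, `interval`,
#'   `n_control`, `n_case`, `or`, `or_conf_lo`, `or_conf_hi` (and `or_adj*`
#'   columns when adjusted); attributes `cutpoints`, `adj_converged`.
#' @export
quartile_odds_table <- function(scores, labels, reference_scores,
                                covariates = NULL, conf_level = 0.95) {
  is_case <- as_case_logical(labels)
  if (length(unique(reference_scores)) < 4L) {
    abort("degenerate reference scores: cannot derive quartile cutpoints.")
  }
  cuts <- quantile(reference_scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(diff(cuts) <= 0)) abort("degenerate reference scores: tied cutpoints.")
  q <- cut(scores, breaks = c(-Inf, cuts, Inf),
           labels = paste0("Q", 1:4), right = TRUE)
  tab <- tibble(
    quartile = paste0("Q", 1:4),
    interval = c(sprintf("(-Inf, %.2f]", cuts[1]),
                 sprintf("(%.2f, %.2f]", cuts[1], cuts[2]),
                 sprintf("(%.2f, %.2f]", cuts[2], cuts[3]),
                 sprintf("(%.2f, Inf)", cuts[3])),
    n_control = as.integer(table(q[!is_case])),
    n_case = as.integer(table(q[is_case]))
  )
  ors <- purrr::map_dfr(1:4, function(i) {
    if (i == 1L) return(tibble(estimate = 1, conf_lo = NA_real_, conf_hi = NA_real_))
    tryCatch(
      midp_odds_ratio(tab$n_case[i], tab$n_control[i],
                      tab$n_case[1], tab$n_control[1], conf_level),
      error = function(e) {
        warn(sprintf("quartile %d odds ratio unavailable: %s", i,
                     conditionMessage(e)))
        tibble(estimate = NA_real_, conf_lo = NA_real_, conf_hi = NA_real_)
      })
  })
  tab$or <- ors$estimate
  tab$or_conf_lo <- ors$conf_lo
  tab$or_conf_hi <- ors$conf_hi

  adj_converged <- NA
  if (!is.null(covariates)) {
    df <- data.frame(y = is_case, q = q, covariates)
    fit <- withCallingHandlers(
      glm(y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("converge|fitted probabilities", conditionMessage(w))) {
          warn(paste("adjusted OR model:", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      })
    adj_converged <- isTRUE(fit$converged)
    z <- qnorm(1 - (1 - conf_level) / 2)
    co <- summary(fit)$coefficients
    qn <- paste0("qQ", 2:4)
    est <- se <- rep(NA_real_, 3)
    hit <- qn %in% rownames(co)
    est[hit] <- co[qn[hit], "Estimate"]
    se[hit] <- co[qn[hit], "Std. Error"]
    tab$or_adj <- c(1, exp(est))
    tab$or_adj_conf_lo <- c(NA, exp(est - z * se))
    tab$or_adj_conf_hi <- c(NA, exp(est + z * se))
  }
  structure(tab, class = c("wid_quartile_table", class(tab)),
            cutpoints = cuts, adj_converged = adj_converged)
}

#' Genomic-region enrichment of a CpG set
#'
#' For each relation-to-island class, compares the composition of the
#' selected CpGs with the background via a 2x2 table (in class vs not, by
#' selected vs not) and the median-unbiased mid-p odds ratio. Classes absent
#' from the background are skipped with a message.
#'
#' @param selected_cpgs CpG ids (must be a subset of the background).
#' @param annotation Annotation tibble with `cpg_id` and `region_class`.
#' @param background CpG ids forming the comparison universe; defaults to
#'   all annotated CpGs.
#' @param conf_level Confidence level.
#' @return Tibble: `region_class`, `n_selected`, `n_background`, `or`,
#'   `conf_lo`, `conf_hi`.
#' @export
region_enrichment <- function(selected_cpgs, annotation, background = NULL,
                              conf_level = 0.95) {
  background <- background %||% annotation$cpg_id
  if (!all(selected_cpgs %in% background)) {
    abort("`selected_cpgs` must be a subset of `background`.")
  }
  cls <- setNames(annotation$region_class, annotation$cpg_id)[background]
  sel <- background %in% selected_cpgs
  purrr::map_dfr(c("Island", "Shore", "Shelf", "OpenSea"), function(rc) {
    inc <- cls == rc
    if (!any(inc)) {
      rlang::inform(sprintf("region_enrichment: class %s absent from background; skipped.", rc))
      return(tibble())
    }
    est <- midp_odds_ratio(sum(inc & sel), sum(inc & !sel),
                           sum(!inc & sel), sum(!inc & !sel), conf_level)
    tibble(region_class = rc, n_selected = sum(inc & sel),
           n_background = sum(inc), or = est$estimate,
           conf_lo = est$conf_lo, conf_hi = est$conf_hi)
  })
}

#' Polygenic risk score from effect-allele dosages
#'
#' \eqn{PRS_j = \sum_i \hat\beta_i x_{ij}} with \eqn{x_{ij}} the effect-allele
#' dosage in \[0, 2\] and \eqn{\hat\beta_i} published log odds ratios.
#' Missing dosages are imputed at twice the effect-allele frequency when
#' frequencies are supplied, otherwise they are an error.
#'
#' @param dosages Sample x SNP matrix with sample rownames and SNP colnames.
#' @param weights Tibble: `snp_id`, `effect_allele`, `beta`.
#' @param allele_freq Optional named effect-allele frequencies for
#'   imputation.
#' @return Tibble: `sample_id`, `prs`.
#' @export
compute_prs <- function(dosages, weights, allele_freq = NULL) {
  if (!is.matrix(dosages) || is.null(colnames(dosages))) {
    abort("`dosages` must be a matrix with SNP colnames.")
  }
  unmatched <- setdiff(colnames(dosages), weights$snp_id)
  if (length(unmatched)) {
    abort(paste("SNPs without weights:", paste(unmatched, collapse = ", ")))
  }
  vals <- dosages[, , drop = FALSE]
  if (any(vals < 0 | vals > 2, na.rm = TRUE)) abort("dosages must lie in [0, 2].")
  if (anyNA(vals)) {
    if (is.null(allele_freq)) abort("missing dosages and no allele frequencies for imputation.")
    for (snp in colnames(vals)) {
      miss <- is.na(vals[, snp])
      if (any(miss)) {
        if (is.na(allele_freq[snp])) abort(paste("no allele frequency for", snp))
        vals[miss, snp] <- 2 * allele_freq[[snp]]
      }
    }
  }
  w <- setNames(weights$beta, weights$snp_id)[colnames(vals)]
  tibble(sample_id = rownames(vals) %||% as.character(seq_len(nrow(vals))),
         prs = unname(drop(vals %*% w)))
}

#' MethyLight percentage of methylated reference (PMR)
#'
#' \eqn{PMR = 100 \cdot} (target:reference ratio of the sample) / (the same
#' ratio in fully-methylated SssI-treated control DNA).
#'
#' @param sample_ratio Target:reference ratio(s) of the sample(s).
#' @param sssi_ratio Target:reference ratio of the fully-methylated control
#'   (> 0).
#' @return PMR in percent (vectorized over `sample_ratio`).
#' @export
compute_pmr <- function(sample_ratio, sssi_ratio) {
  check_scalar_number(sssi_ratio, "sssi_ratio")
  if (sssi_ratio <= 0) abort("`sssi_ratio` must be positive.")
  100 * sample_ratio / sssi_ratio
}
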