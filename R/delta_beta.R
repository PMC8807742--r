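get_group_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$type, labels$sample_id)[sample_ids]
  }
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids) || anyNA(labels) ||
      !all(labels %in% c("case", "control"))) {
    abort("labels must assign 'case' or 'control' to every sample.")
  }
  labels
}

#' Cell-type-resolved delta-beta by the intercept method
#'
#' Immune-cell contamination dilutes epithelial case/control differences, so
#' per CpG the beta values are regressed linearly on the immune-cell (IC)
#' fraction within cases and controls separately. The difference of the two
#' regression lines at IC = 0 estimates the delta-beta in a pure epithelial
#' population (`epithelial_delta`); their difference at IC = 1 estimates the
#' immune-cell delta-beta (`immune_delta`).
#'
#' @param beta CpG x sample matrix.
#' @param fractions Tibble with `sample_id` and `ic` (immune fraction), as
#'   returned by [estimate_fractions()], or a numeric IC vector aligned with
#'   the columns of `beta`.
#' @param labels `"case"`/`"control"` per sample (vector, or tibble with
#'   `sample_id` and `type`).
#' @return Tibble: `cpg_id`, group intercepts and slopes, `epithelial_delta`
#'   (= case intercept - control intercept), `immune_delta` (difference of
#'   fitted values at IC = 1), and `available` (FALSE when a group has zero
#'   IC spread, in which case estimates are NA rather than silently zero).
#' @examples
#' pr <- generate_profiles(40, 1)
#' ch <- generate_cohort(pr, 20, 20, effect_spec(pr$annotation$cpg_id[1:4], 0.1),
#'                       fractions = fraction_model("ic_uniform"), seed = 3)
#' db <- estimate_delta_betas(ch$beta, ch$truth$fractions$immune, ch$sheet)
#' head(db)
#' @export
estimate_delta_betas <- function(beta, fractions, labels) {
  check_beta_matrix(beta)
  ic <- if (is.data.frame(fractions)) {
    setNames(fractions$ic, fractions$sample_id)[colnames(beta)]
  } else {
    setNames(as.numeric(fractions), colnames(beta))
  }
  if (anyNA(ic)) abort("every sample needs an IC fraction.")
  labels <- get_group_labels(labels, colnames(beta))
  if (sum(labels == "case") < 3L || sum(labels == "control") < 3L) {
    abort("need at least 3 cases and 3 controls.")
  }

  group_fit <- function(group) {
    u <- ic[labels == group]
    B <- beta[, labels == group, drop = FALSE]
    su <- sum((u - mean(u))^2)
    if (su <= .Machine$double.eps * length(u)) {
      return(list(intercept = rep(NA_real_, nrow(B)),
                  slope = rep(NA_real_, nrow(B)), ok = FALSE))
    }
    slope <- drop(B %*% (u - mean(u))) / su
    intercept <- rowMeans(B) - slope * mean(u)
    list(intercept = intercept, slope = slope, ok = TRUE)
  }
  fc <- group_fit("case")
  f0 <- group_fit("control")
  if (!fc$ok || !f0$ok) {
    warn("zero IC variance in a group; delta-beta records flagged unavailable.")
  }

  tibble(
    cpg_id = rownames(beta),
    case_intercept = unname(fc$intercept), case_slope = unname(fc$slope),
    control_intercept = unname(f0$intercept), control_slope = unname(f0$slope),
    epithelial_delta = unname(fc$intercept - f0$intercept),
    immune_delta = unname((fc$intercept + fc$slope) - (f0$intercept + f0$slope)),
    available = fc$ok && f0$ok
  )
}

#' Rank CpGs by absolute delta-beta
#'
#' Descending by the absolute delta of the chosen compartment; the combined
#' mode uses the larger of the two absolute deltas. Ties break
#' lexicographically by CpG id.
#'
#' @param records Tibble from [estimate_delta_betas()].
#' @param mode `"epithelial"`, `"immune"`, or `"combined"`.
#' @return Character vector of CpG ids, best first.
#' @export
rank_cpgs <- function(records, mode = c("epithelial", "immune", "combined")) {
  mode <- match.arg(mode)
  if (!nrow(records)) abort("`records` is empty.")
  key <- switch(mode,
    epithelial = abs(records$epithelial_delta),
    immune = abs(records$immune_delta),
    combined = pmax(abs(records$epithelial_delta), abs(records$immune_delta))
  )
  records$cpg_id[order(-key, records$cpg_id)]
}

#' Covariate-adjusted differential-methylation scan
#'
#' Per CpG, an ordinary least-squares fit of beta on case/control status plus
#' covariates (immune-cell fraction and age); the two-sided p-value of the
#' status coefficient is reported together with its Bonferroni adjustment
#' (multiplier = number of CpGs tested). CpGs with no residual variance
#' (e.g. constant betas) are flagged unavailable.
#'
#' @param beta CpG x sample matrix.
#' @param labels `"case"`/`"control"` per sample.
#' @param covariates Data frame of numeric covariates (one row per sample,
#'   aligned with the columns of `beta`), typically `ic` and `age`.
#' @return Tibble: `cpg_id`, `estimate`, `p`, `p_bonferroni`, `available`.
#' @export
dmp_association_test <- function(beta, labels, covariates) {
  check_beta_matrix(beta)
  labels <- get_group_labels(labels, colnames(beta))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(beta) || anyNA(covariates)) {
    abort("`covariates` must be complete, one row per sample.")
  }
  X <- cbind(intercept = 1, status = as.numeric(labels == "case"),
             as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) abort("collinear design (status + covariates).")

  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi
  coefs <- beta %*% H
  resid <- beta - coefs %*% t(X)
  df <- ncol(beta) - ncol(X)
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi["status", "status"])
  tstat <- coefs[, "status"] / se
  p <- 2 * pt(-abs(tstat), df)
  bad <- sigma2 <= .Machine$double.eps
  p[bad] <- NA_real_

  tibble(
    cpg_id = rownames(beta),
    estimate = unname(coefs[, "status"]),
    p = unname(p),
    p_bonferroni = unname(pmin(1, p * nrow(beta))),
    available = unname(!bad)
  )
}
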