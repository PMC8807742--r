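# Two-component beta mixture with known immune mixing weights: per CpG,
# beta_i ~ (1 - rho_i) Beta(a0, b0) + rho_i Beta(a1, b1), rho_i observed.

beta_moment_shapes <- function(x, fallback = c(2, 2)) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) {
    return(fallback)
  }
  s <- max(m * (1 - m) / v - 1, 0.1)
  c(m * s, (1 - m) * s)
}

mixture_nll <- function(logpar, betas, rhos) {
  p <- exp(logpar)
  dens <- (1 - rhos) * dbeta(betas, p[1], p[2]) +
    rhos * dbeta(betas, p[3], p[4])
  -mean(log(pmax(dens, 1e-300)))
}

single_nll <- function(logpar, betas) {
  -mean(dbeta(betas, exp(logpar[1]), exp(logpar[2]), log = TRUE))
}

#' Fit the per-CpG epithelial/immune beta mixture
#'
#' Minimizes the negative average log-likelihood
#' \deqn{L(a_0,b_0,a_1,b_1) = -\frac{1}{N}\sum_i \log[(1-\rho_i)
#'   Beta(\beta_i|a_0,b_0) + \rho_i Beta(\beta_i|a_1,b_1)]}
#' over log-parameterized shapes, where \eqn{\rho_i} is the known immune
#' fraction of sample \eqn{i}. Optimization is multi-start Nelder-Mead from
#' method-of-moments seeds (low-rho subset, high-rho subset, global). The
#' epithelial and immune beta-distribution variances are the per-compartment
#' variance estimates. Betas are clipped to \[1e-6, 1 - 1e-6\] since the beta
#' density is unbounded or undefined at the boundary. With all \eqn{\rho_i = 0}
#' the immune component is unidentifiable: the fit reduces to a single beta
#' and the immune shapes are flagged `NA`.
#'
#' @param betas Beta values of one CpG across samples (N >= 20).
#' @param rhos Immune proportions per sample, in \[0, 1\].
#' @param cpg_id Optional id carried into the result.
#' @return A `wid_mixture_fit` list: `cpg_id`, `a0`, `b0`, `a1`, `b1`,
#'   `var_epi`, `var_imm`, `nll`, `converged`, `immune_identifiable`.
#' @export
fit_beta_mixture <- function(betas, rhos, cpg_id = NA_character_) {
  if (length(betas) < 20L) abort("need at least 20 samples per CpG.")
  if (length(rhos) != length(betas) || any(rhos < 0 | rhos > 1)) {
    abort("`rhos` must match `betas` and lie in [0, 1].")
  }
  betas <- clip01(betas, eps = 1e-6)

  if (all(rhos == 0)) {
    st <- log(beta_moment_shapes(betas))
    opt <- optim(st, single_nll, betas = betas, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    p <- exp(opt$par)
    return(structure(list(
      cpg_id = cpg_id, a0 = p[1], b0 = p[2], a1 = NA_real_, b1 = NA_real_,
      var_epi = beta_var(p[1], p[2]), var_imm = NA_real_,
      nll = opt$value, converged = opt$convergence == 0,
      immune_identifiable = FALSE), class = "wid_mixture_fit"))
  }

  lo <- rhos <= median(rhos)
  starts <- list(
    c(beta_moment_shapes(betas[lo]), beta_moment_shapes(betas[!lo])),
    c(beta_moment_shapes(betas[rhos < 0.5], beta_moment_shapes(betas)),
      beta_moment_shapes(betas[rhos >= 0.5], beta_moment_shapes(betas))),
    c(beta_moment_shapes(betas), beta_moment_shapes(betas))
  )
  fits <- lapply(starts, function(st) {
    optim(log(pmax(st, 1e-3)), mixture_nll, betas = betas, rhos = rhos,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- exp(best$par)
  structure(list(
    cpg_id = cpg_id, a0 = p[1], b0 = p[2], a1 = p[3], b1 = p[4],
    var_epi = beta_var(p[1], p[2]), var_imm = beta_var(p[3], p[4]),
    nll = best$value, converged = best$convergence == 0,
    immune_identifiable = TRUE), class = "wid_mixture_fit")
}

#' @export
print.wid_mixture_fit <- function(x, ...) {
  cat(sprintf("<wid_mixture_fit> a0=%.3g b0=%.3g a1=%.3g b1=%.3g nll=%.4g (%s)\n",
              x$a0, x$b0, x$a1, x$b1, x$nll,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Fit the beta mixture across a matrix of CpGs
#'
#' @param beta CpG x sample matrix.
#' @param rhos Immune fractions per sample (aligned with columns), or a
#'   fractions tibble with `sample_id` and `ic`.
#' @param ratio Variance-ratio threshold forwarded to
#'   [classify_cpg_origin()].
#' @return Tibble with one row per CpG: shapes, variances, `nll`,
#'   `converged`, `origin_class`.
#' @export
fit_beta_mixtures <- function(beta, rhos, ratio = 2) {
  check_beta_matrix(beta)
  if (is.data.frame(rhos)) {
    rhos <- setNames(rhos$ic, rhos$sample_id)[colnames(beta)]
  }
  fits <- purrr::map(rownames(beta), function(cg) {
    fit_beta_mixture(beta[cg, ], rhos, cpg_id = cg)
  })
  out <- purrr::map_dfr(fits, function(f) tibble::as_tibble(unclass(f)))
  out$origin_class <- purrr::map_chr(fits, classify_cpg_origin, ratio = ratio)
  out
}

#' Classify a CpG as epithelial, shared, or immune
#'
#' Compares the fitted compartment variances: `"epithelial"` when
#' `var_epi > ratio * var_imm`, `"immune"` when `var_imm > ratio * var_epi`,
#' otherwise `"shared"`. Unconverged or immune-unidentifiable fits return
#' `NA`.
#'
#' @param fit A `wid_mixture_fit` (or any list/row with `var_epi`,
#'   `var_imm`, `converged`).
#' @param ratio Threshold ratio (>= 1).
#' @return A single class string, or `NA_character_`.
#' @export
classify_cpg_origin <- function(fit, ratio = 2) {
  check_scalar_number(ratio, "ratio", lower = 1)
  if (!isTRUE(fit$converged) || !is.finite(fit$var_imm) ||
      !is.finite(fit$var_epi)) {
    return(NA_character_)
  }
  if (fit$var_epi > ratio * fit$var_imm) return("epithelial")
  if (fit$var_imm > ratio * fit$var_epi) return("immune")
  "shared"
}
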