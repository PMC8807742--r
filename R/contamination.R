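# In-silico tumour-DNA contamination of control methylomes.

#' Mix tumour DNA into control beta values
#'
#' Simulated beta values are the element-wise convex combination
#' \eqn{\beta = (1 - \rho)\beta_c + \rho\beta_t} of each control sample with
#' a single tumour profile.
#'
#' @param controls CpG x sample matrix of control betas.
#' @param tumour_profile Named per-CpG tumour betas covering the control
#'   CpGs.
#' @param rho Tumour proportion in \[0, 1\].
#' @return Matrix of mixed betas with the dimensions of `controls`.
#' @export
mix_betas <- function(controls, tumour_profile, rho) {
  check_beta_matrix(controls)
  check_scalar_number(rho, "rho")
  if (rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  if (is.null(names(tumour_profile)) ||
      !all(rownames(controls) %in% names(tumour_profile))) {
    abort("`tumour_profile` must be named and cover the control CpGs.")
  }
  bt <- tumour_profile[rownames(controls)]
  if (any(bt < 0 | bt > 1)) abort("tumour profile betas must lie in [0, 1].")
  (1 - rho) * controls + rho * bt
}

#' Index shift as a function of tumour contamination
#'
#' For each \eqn{\rho} on the grid, mixes the tumour profile into every
#' control sample and reports the mean index shift of the mixed cohort in
#' SD units of the unmixed controls:
#' \eqn{shift(\rho) = (\bar{I}_\rho - \bar{I}_0) / sd(I_0)}. Because the
#' index is linear in beta, \eqn{shift(\rho) = \rho \cdot shift(1)} exactly.
#' The contamination \eqn{\rho^*} reaching `target_shift_sd` is the smallest
#' grid value whose shift meets the target, linearly interpolated between
#' grid points; an unreachable target is reported as such, never
#' extrapolated.
#'
#' @param model A `wid_index_model`.
#' @param controls CpG x sample matrix of unmixed controls.
#' @param tumour_profile Named per-CpG tumour betas.
#' @param rho_grid Grid of tumour proportions in \[0, 1\].
#' @param target_shift_sd Target shift in control-SD units (default 1.25, a
#'   case/control separation typical of this index family).
#' @return A `wid_shift_curve` tibble (`rho`, `shift`) with attributes
#'   `rho_star`, `target_shift_sd`, `reachable`.
#' @export
contamination_shift_curve <- function(model, controls, tumour_profile,
                                      rho_grid = seq(0, 1, by = 0.05),
                                      target_shift_sd = 1.25) {
  if (any(rho_grid < 0 | rho_grid > 1)) abort("`rho_grid` must lie in [0, 1].")
  rho_grid <- sort(unique(rho_grid))
  idx0 <- compute_index(model, controls)$index
  sd0 <- sd(idx0)
  if (!is.finite(sd0) || sd0 <= 0) abort("controls' index SD must be positive.")
  shifts <- vapply(rho_grid, function(r) {
    m <- compute_index(model, mix_betas(controls, tumour_profile, r))$index
    (mean(m) - mean(idx0)) / sd0
  }, numeric(1))

  reachable <- any(shifts >= target_shift_sd)
  rho_star <- NA_real_
  if (reachable) {
    i <- which(shifts >= target_shift_sd)[1L]
    if (i == 1L) {
      rho_star <- rho_grid[1L]
    } else {
      rho_star <- rho_grid[i - 1L] +
        (target_shift_sd - shifts[i - 1L]) *
          (rho_grid[i] - rho_grid[i - 1L]) / (shifts[i] - shifts[i - 1L])
    }
  }
  structure(tibble(rho = rho_grid, shift = shifts),
            class = c("wid_shift_curve", class(tibble())),
            rho_star = rho_star, target_shift_sd = target_shift_sd,
            reachable = reachable)
}

#' @method glance wid_shift_curve
#' @export
glance.wid_shift_curve <- function(x, ...) {
  tibble(rho_star = attr(x, "rho_star"),
         target_shift_sd = attr(x, "target_shift_sd"),
         reachable = attr(x, "reachable"))
}
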