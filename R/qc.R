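#' Detection-failure masking, failure-rate filtering, and kNN imputation
#'
#' Entries whose detection p-value exceeds `p_thresh` are regarded as failed
#' and masked. Samples with more than `sample_fail_frac` failed probes are
#' removed first, then probes with more than `probe_fail_frac` failures among
#' the retained samples; remaining masked entries are imputed from the `k`
#' nearest probes by Euclidean distance over the samples where the target
#' probe is observed. The intensity-level sample filter used on raw arrays
#' needs intensities, not betas, and is recorded in the report as not applied.
#'
#' @param beta CpG x sample beta matrix.
#' @param detection_p Detection p-value matrix, conformable with `beta`.
#' @param p_thresh Detection p-value threshold (default 0.01).
#' @param sample_fail_frac Maximum tolerated failed-probe fraction per sample.
#' @param probe_fail_frac Maximum tolerated failure rate per probe.
#' @param k Number of neighbour probes for imputation.
#' @return List with `beta` (no masked entries) and `report`, a `wid_qc_report`
#'   with `removed_samples`, `removed_probes` (tibbles: id, reason) and
#'   `imputed_count`.
#' @examples
#' ch <- generate_cohort(generate_profiles(30, 1), 5, 5, seed = 2,
#'                       detection_fail_rate = 0.02)
#' qc <- qc_filter_impute(ch$beta, ch$detection_p, k = 5)
#' qc$report$imputed_count
#' @export
qc_filter_impute <- function(beta, detection_p, p_thresh = 0.01,
                             sample_fail_frac = 0.10, probe_fail_frac = 0.10,
                             k = 10) {
  check_beta_matrix(beta)
  check_scalar_number(p_thresh, "p_thresh", 0, 1)
  if (p_thresh <= 0 || p_thresh >= 1) abort("`p_thresh` must lie in (0, 1).")
  if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(beta))) {
    abort("`detection_p` must be a matrix conformable with `beta`.")
  }
  check_scalar_number(k, "k", lower = 1)

  failed <- detection_p > p_thresh
  drop_samples <- colMeans(failed) > sample_fail_frac
  if (all(drop_samples)) abort("all samples removed by the failure-rate filter.")

  beta2 <- beta[, !drop_samples, drop = FALSE]
  failed2 <- failed[, !drop_samples, drop = FALSE]
  drop_probes <- rowMeans(failed2) > probe_fail_frac

  beta3 <- beta2[!drop_probes, , drop = FALSE]
  failed3 <- failed2[!drop_probes, , drop = FALSE]
  beta3[failed3] <- NA_real_

  if (k >= nrow(beta3)) abort("`k` is not smaller than the number of retained probes.")

  imp <- knn_impute(beta3, k = k)
  report <- structure(list(
    removed_samples = tibble(sample_id = colnames(beta)[drop_samples],
                             reason = "failed-probe fraction above threshold"),
    removed_probes = tibble(cpg_id = rownames(beta2)[drop_probes],
                            reason = "failure rate above threshold"),
    imputed_count = imp$count,
    not_applied = "intensity-based sample filter (requires raw intensities)"
  ), class = "wid_qc_report")
  list(beta = imp$beta, report = report)
}

#' @export
print.wid_qc_report <- function(x, ...) {
  cat(sprintf("<wid_qc_report> %d samples removed, %d probes removed, %d values imputed\n",
              nrow(x$removed_samples), nrow(x$removed_probes), x$imputed_count))
  cat("not applied:", x$not_applied, "\n")
  invisible(x)
}

# kNN imputation: for each probe with masked entries, the k nearest
# fully-observed probes (Euclidean over the probe's observed samples)
# supply the mean value at the masked samples. Squared distances over each
# probe's observed samples are assembled from three matrix products so the
# whole missing block is handled with BLAS calls rather than an R loop:
# sum_c w_ic (m_ic - c_jc)^2 = sum w m^2 - 2 (M0 C')_ij + (W C^2')_ij.
knn_impute <- function(M, k) {
  na_mask <- is.na(M)
  miss_rows <- which(rowSums(na_mask) > 0L)
  if (!length(miss_rows)) return(list(beta = M, count = 0L))
  complete_rows <- which(rowSums(na_mask) == 0L)
  if (length(complete_rows) < k) {
    abort("fewer fully-observed probes than `k`; cannot impute.")
  }
  C <- M[complete_rows, , drop = FALSE]
  Mm <- M[miss_rows, , drop = FALSE]
  W <- 1 - na_mask[miss_rows, , drop = FALSE]
  M0 <- Mm
  M0[is.na(M0)] <- 0
  D2 <- rowSums(M0^2) - 2 * M0 %*% t(C) + W %*% t(C^2)
  count <- 0L
  for (r in seq_along(miss_rows)) {
    nb <- order(D2[r, ])[seq_len(k)]
    mis <- which(na_mask[miss_rows[r], ])
    M[miss_rows[r], mis] <- colMeans(C[nb, mis, drop = FALSE])
    count <- count + length(mis)
  }
  list(beta = M, count = count)
}

#' Remove blocklisted probes
#'
#' Drops every probe named in any of the supplied blocklists (e.g. non-CpG
#' probes, SNP-related probes, trimodal probes); ids absent from the matrix
#' are ignored. Probe order is preserved.
#'
#' @param beta CpG x sample matrix.
#' @param blocklists Named list of character vectors of CpG ids.
#' @return The filtered matrix. A fully-emptied matrix triggers a warning.
#' @export
exclude_probes <- function(beta, blocklists = list()) {
  check_beta_matrix(beta, allow_na = TRUE)
  if (!is.list(blocklists)) abort("`blocklists` must be a list of id vectors.")
  drop <- unique(unlist(blocklists, use.names = FALSE))
  missing_ids <- setdiff(drop, rownames(beta))
  if (length(missing_ids)) {
    rlang::inform(sprintf("exclude_probes: %d blocklisted ids not in the matrix.",
                          length(missing_ids)))
  }
  out <- beta[!(rownames(beta) %in% drop), , drop = FALSE]
  if (nrow(out) == 0L) warn("exclude_probes: all probes removed.")
  out
}

#' Split samples into training and internal-validation sets
#'
#' The split is random given `seed` and intended to be performed once and
#' persisted; rerunning with the same seed reproduces it. An optional
#' stratified variant balances the case proportion.
#'
#' @param sheet Sample sheet tibble with `sample_id` (and `type` when
#'   stratifying).
#' @param train_frac Training fraction in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @param stratify Stratify by the `type` column.
#' @return List with `train` and `validation` character vectors of sample ids
#'   (disjoint, exhaustive).
#' @export
split_discovery <- function(sheet, train_frac = 2 / 3, seed = 1L,
                            stratify = FALSE) {
  if (!is.data.frame(sheet) || !"sample_id" %in% names(sheet)) {
    abort("`sheet` must be a data frame with a `sample_id` column.")
  }
  check_scalar_number(train_frac, "train_frac")
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must lie in (0, 1).")
  n <- nrow(sheet)
  if (n < 3L) abort("need at least 3 samples to split.")
  set.seed(as.integer(seed))
  if (stratify) {
    if (!"type" %in% names(sheet)) abort("stratified split needs a `type` column.")
    train <- unlist(lapply(split(sheet$sample_id, sheet$type), function(ids) {
      sample(ids, round(length(ids) * train_frac))
    }), use.names = FALSE)
  } else {
    train <- sample(sheet$sample_id, round(n * train_frac))
  }
  list(train = sort(train),
       validation = sort(setdiff(sheet$sample_id, train)))
}
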