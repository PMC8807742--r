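#' Build a marker-CpG reference panel from pure cell-type samples
#'
#' For each cell type, every CpG is tested one-vs-rest with a two-sided
#' Wilcoxon rank-sum test; p-values are Benjamini-Hochberg adjusted per cell
#' type. Markers must satisfy `p_adj < p_adj_max` and an absolute group mean
#' difference above the per-type delta threshold. When `target_count_per_type`
#' is supplied the delta threshold is instead auto-tuned per type to the
#' smallest value yielding at most that many markers. Each marker is
#' attributed to exactly one cell type (the one with the largest absolute
#' delta if several qualify). The centroid holds the per-type mean beta at
#' every selected marker.
#'
#' @param beta CpG x sample matrix of pure-sample betas.
#' @param labels Tibble with `sample_id`, `cell_type`, or a named character
#'   vector keyed by sample id.
#' @param p_adj_max FDR-adjusted p-value ceiling (default 0.01).
#' @param delta_min Minimum absolute mean difference: a single number or a
#'   named per-type vector.
#' @param target_count_per_type Optional marker-count cap per type; overrides
#'   `delta_min`.
#' @return A `wid_ref_panel`: `markers` (tibble: cpg_id, cell_type, delta,
#'   p_adj), `centroid` (marker x cell-type matrix), `thresholds` used.
#' @examples
#' pr <- generate_profiles(200, seed = 1)
#' ref <- generate_reference_samples(pr, n_per_type = 10, seed = 2)
#' panel <- build_reference_panel(ref$beta, ref$labels, delta_min = 0.5)
#' dplyr::count(panel$markers, cell_type)
#' @export
build_reference_panel <- function(beta, labels, p_adj_max = 0.01,
                                  delta_min = 0.5,
                                  target_count_per_type = NULL) {
  check_beta_matrix(beta)
  if (is.data.frame(labels)) {
    labels <- setNames(labels$cell_type, labels$sample_id)[colnames(beta)]
  }
  if (anyNA(labels) || length(labels) != ncol(beta)) {
    abort("`labels` must assign a cell type to every sample.")
  }
  types <- unique(labels)
  if (length(types) < 2L) abort("need at least two cell types to contrast.")
  counts <- table(labels)
  if (any(counts < 2)) abort("need at least 2 pure samples per cell type.")
  if (is.null(names(delta_min))) {
    delta_min <- setNames(rep(delta_min[[1]], length(types)), types)
  }

  per_type <- purrr::map(types, function(ct) {
    own <- labels == ct
    delta <- rowMeans(beta[, own, drop = FALSE]) -
      rowMeans(beta[, !own, drop = FALSE])
    p <- apply(beta, 1L, function(v) {
      suppressWarnings(wilcox.test(v[own], v[!own])$p.value)
    })
    p_adj <- p.adjust(p, method = "BH")
    sig <- which(p_adj < p_adj_max)
    thr <- delta_min[[ct]]
    if (!is.null(target_count_per_type)) {
      ad <- sort(abs(delta[sig]), decreasing = TRUE)
      thr <- if (length(ad) > target_count_per_type) {
        ad[target_count_per_type + 1L]
      } else 0
    }
    keep <- sig[abs(delta[sig]) > thr]
    list(tab = tibble(cpg_id = rownames(beta)[keep], cell_type = ct,
                      delta = delta[keep], p_adj = p_adj[keep]),
         threshold = thr)
  })
  names(per_type) <- types

  markers <- dplyr::bind_rows(purrr::map(per_type, "tab")) |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::slice_max(abs(.data$delta), n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$cell_type, types), dplyr::desc(abs(.data$delta)))

  empty <- setdiff(types, unique(markers$cell_type))
  if (length(empty)) {
    abort(sprintf("no markers selected for cell type(s): %s",
                  paste(empty, collapse = ", ")))
  }

  centroid <- vapply(types, function(ct) {
    rowMeans(beta[markers$cpg_id, labels == ct, drop = FALSE])
  }, numeric(nrow(markers)))
  rownames(centroid) <- markers$cpg_id

  structure(list(markers = markers, centroid = centroid,
                 thresholds = list(p_adj_max = p_adj_max,
                                   delta = purrr::map_dbl(per_type, "threshold"))),
            class = "wid_ref_panel")
}

#' @export
print.wid_ref_panel <- function(x, ...) {
  cat(sprintf("<wid_ref_panel> %d markers over %d cell types\n",
              nrow(x$markers), ncol(x$centroid)))
  print(table(x$markers$cell_type))
  invisible(x)
}

#' @method tidy wid_ref_panel
#' @export
tidy.wid_ref_panel <- function(x, ...) x$markers

#' Estimate per-sample cell-type fractions
#'
#' Solves, per sample, a non-negative least-squares fit of the sample's
#' marker betas on the panel centroid columns, then renormalizes to sum to
#' one. Markers missing from `beta` are dropped before fitting; at least half
#' of the panel must be present. `ic` aliases the immune fraction; cell types
#' absent from the panel are reported as 0.
#'
#' @param beta CpG x sample matrix.
#' @param panel A `wid_ref_panel`.
#' @return Tibble: `sample_id`, `epithelial`, `fibroblast`, `immune`,
#'   `tumour`, `ic`.
#' @export
estimate_fractions <- function(beta, panel) {
  check_beta_matrix(beta)
  if (!inherits(panel, "wid_ref_panel")) abort("`panel` must be a wid_ref_panel.")
  shared <- intersect(rownames(panel$centroid), rownames(beta))
  if (length(shared) < 0.5 * nrow(panel$centroid)) {
    abort("fewer than 50% of panel markers present in `beta`.")
  }
  C <- panel$centroid[shared, , drop = FALSE]
  fits <- apply(beta[shared, , drop = FALSE], 2L, function(d) {
    x <- pracma::lsqnonneg(C, d)$x
    if (sum(x) <= 0) rep(1 / ncol(C), ncol(C)) else x / sum(x)
  })
  fits <- t(fits)
  colnames(fits) <- colnames(C)
  out <- tibble(sample_id = colnames(beta))
  for (ct in cell_types()) {
    out[[ct]] <- if (ct %in% colnames(fits)) unname(fits[, ct]) else rep(0, nrow(out))
  }
  out$ic <- out$immune
  out
}

#' Residual-correct the tumour-DNA fraction against epithelial content
#'
#' The raw tumour fraction co-varies with epithelial content in healthy
#' samples. A local polynomial (loess) smooth of tumour on epithelial is
#' fitted on controls only, and `tumour_corrected` is the residual of every
#' sample from that smooth; it may be slightly negative and is deliberately
#' left unnormalized. Samples with epithelial values outside the controls'
#' fitted range are extrapolated linearly from the boundary slope and
#' flagged.
#'
#' @param fractions Tibble from [estimate_fractions()].
#' @param control_ids Sample ids of the controls (>= 20 required).
#' @param span Loess span.
#' @return `fractions` with `tumour_corrected` and `extrapolated` columns.
#' @export
correct_tumour_fraction <- function(fractions, control_ids, span = 0.75) {
  if (!all(c("sample_id", "tumour", "epithelial") %in% names(fractions))) {
    abort("`fractions` must contain sample_id, tumour and epithelial columns.")
  }
  ctrl <- fractions[fractions$sample_id %in% control_ids, ]
  if (nrow(ctrl) < 20L) abort("need at least 20 controls for the loess fit.")
  fit <- loess(tumour ~ epithelial, data = ctrl, span = span,
               degree = 2, surface = "direct")
  rng <- range(ctrl$epithelial)
  x <- fractions$epithelial
  inside <- x >= rng[1] & x <= rng[2]
  pred <- rep(NA_real_, length(x))
  pred[inside] <- predict(fit, newdata = data.frame(epithelial = x[inside]))
  if (any(!inside)) {
    h <- 1e-4 * diff(rng)
    for (side in 1:2) {
      b <- rng[side]
      probe <- if (side == 1) c(b, b + h) else c(b - h, b)
      pb <- predict(fit, newdata = data.frame(epithelial = probe))
      slope <- diff(pb) / h
      sel <- if (side == 1) !inside & x < b else !inside & x > b
      pred[sel] <- pb[side] + slope * (x[sel] - b)
    }
    warn(sprintf("correct_tumour_fraction: %d sample(s) outside the control range; extrapolated linearly.",
                 sum(!inside)))
  }
  fractions$tumour_corrected <- fractions$tumour - pred
  fractions$extrapolated <- !inside
  fractions
}
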