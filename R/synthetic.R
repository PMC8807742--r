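#' Generate per-cell-type beta-distribution profiles and CpG annotation
#'
#' Creates the ground-truth statistical structure a synthetic cervical-smear
#' cohort is built from: for every CpG one beta distribution
#' \eqn{Beta(\beta | a, b)} per cell type (epithelial, fibroblast, immune,
#' tumour), plus an array-style annotation table assigning each CpG a
#' relation-to-island class. A designated subset of CpGs per cell type are
#' *markers*: their mean beta is separated from every other cell type by at
#' least 0.5, so that reference-panel construction and deconvolution have a
#' recoverable signal.
#'
#' Non-marker CpGs share a common baseline mean across cell types with small
#' type-specific deviations; the epithelial compartment is given lower
#' beta-precision (higher biological variance) than the immune compartment,
#' mirroring the variance structure the variance-attribution model probes.
#'
#' @param n_cpgs Number of CpGs (>= 10).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param annotation_spec Named proportions over region classes
#'   `Island`, `Shore`, `Shelf`, `OpenSea`; defaults to an EPIC-like mix.
#' @param marker_frac Fraction of CpGs reserved as markers *per cell type*.
#' @return A list of class `wid_profiles` with elements `profiles` (tibble:
#'   `cpg_id`, `cell_type`, `a`, `b`, `marker_for`) and `annotation` (tibble:
#'   `cpg_id`, `chr`, `pos`, `region_class`, `gene`).
#' @examples
#' pr <- generate_profiles(n_cpgs = 50, seed = 1)
#' dplyr::count(pr$profiles, cell_type)
#' @export
generate_profiles <- function(n_cpgs, seed,
                              annotation_spec = c(Island = 0.20, Shore = 0.25,
                                                  Shelf = 0.10, OpenSea = 0.45),
                              marker_frac = 0.05) {
  check_scalar_number(n_cpgs, "n_cpgs", lower = 10)
  check_scalar_number(seed, "seed")
  if (is.null(names(annotation_spec)) ||
      !setequal(names(annotation_spec), c("Island", "Shore", "Shelf", "OpenSea"))) {
    abort("`annotation_spec` must be named proportions for Island/Shore/Shelf/OpenSea.")
  }
  annotation_spec <- annotation_spec / sum(annotation_spec)
  n_cpgs <- as.integer(n_cpgs)
  set.seed(as.integer(seed))

  cpg_id <- sprintf("cg%08d", seq_len(n_cpgs))
  types <- cell_types()

  n_marker <- max(1L, as.integer(round(marker_frac * n_cpgs)))
  if (4L * n_marker > n_cpgs) n_marker <- n_cpgs %/% 4L
  marker_idx <- sample.int(n_cpgs, 4L * n_marker)
  marker_for <- rep(NA_character_, n_cpgs)
  marker_for[marker_idx] <- rep(types, each = n_marker)

  # Baseline means and per-type precisions for non-marker CpGs.
  base_mean <- runif(n_cpgs, 0.10, 0.90)
  prec <- list(
    epithelial = runif(n_cpgs, 8, 30),    # broad: epithelial variance dominates
    fibroblast = runif(n_cpgs, 20, 80),
    immune     = runif(n_cpgs, 60, 150),  # tight: immune betas are stable
    tumour     = runif(n_cpgs, 10, 40)
  )

  means <- lapply(types, function(ct) clip01(base_mean + rnorm(n_cpgs, 0, 0.02),
                                             eps = 0.03))
  names(means) <- types

  # Markers: own type far from all others (separation >= 0.7 by construction),
  # half hyper- and half hypo-methylated in the owning type, tight precision.
  marker_high <- runif(n_cpgs) < 0.5
  for (ct in types) {
    idx <- which(marker_for == ct)
    for (other in types) {
      own <- other == ct
      hi <- runif(length(idx), 0.85, 0.90)
      lo <- runif(length(idx), 0.10, 0.15)
      means[[other]][idx] <- ifelse(xor(marker_high[idx], !own), hi, lo)
      prec[[other]][idx] <- 100
    }
  }

  profiles <- purrr::map_dfr(types, function(ct) {
    sh <- beta_shapes(means[[ct]], prec[[ct]])
    tibble(cpg_id = cpg_id, cell_type = ct, a = sh$a, b = sh$b,
           marker_for = marker_for)
  })

  annotation <- tibble(
    cpg_id = cpg_id,
    chr = paste0("chr", sample(1:22, n_cpgs, replace = TRUE)),
    pos = sample.int(2.4e8, n_cpgs, replace = TRUE),
    region_class = sample(names(annotation_spec), n_cpgs, replace = TRUE,
                          prob = annotation_spec),
    gene = paste0("GENE", seq_len(n_cpgs))
  )

  structure(list(profiles = profiles, annotation = annotation),
            class = "wid_profiles")
}

#' Specify the planted case/control effect
#'
#' @param informative_cpgs Character vector of CpG ids carrying the effect.
#' @param epithelial_delta Signed shift of the mean beta in the affected
#'   compartment (|delta| < 1); shifted means must stay inside (0, 1).
#' @param compartment Cell type carrying the case effect.
#' @param tumour_delta Signed mean shift of the *tumour* compartment at the
#'   same CpGs, emulating a tumour methylome that carries the case signature
#'   in amplified form (tumour delta-betas are typically several-fold larger
#'   than the risk signal in normal tissue). Defaults to three times
#'   `epithelial_delta`; shifted tumour means saturate at \[0.05, 0.95\].
#' @return A list of class `wid_effect`.
#' @export
effect_spec <- function(informative_cpgs, epithelial_delta,
                        compartment = "epithelial", tumour_delta = NULL) {
  check_scalar_number(epithelial_delta, "epithelial_delta", lower = -1, upper = 1)
  compartment <- match.arg(compartment, cell_types())
  tumour_delta <- tumour_delta %||%
    (sign(epithelial_delta) * min(0.95, 3 * abs(epithelial_delta)))
  check_scalar_number(tumour_delta, "tumour_delta", lower = -1, upper = 1)
  structure(list(informative_cpgs = as.character(informative_cpgs),
                 epithelial_delta = epithelial_delta,
                 compartment = compartment,
                 tumour_delta = tumour_delta),
            class = "wid_effect")
}

# Shift the tumour-profile means at the informative CpGs, saturating so the
# shifted means stay away from the boundary.
shift_tumour_profiles <- function(prof_tumour, effect) {
  idx <- match(effect$informative_cpgs, prof_tumour$cpg_id)
  s <- prof_tumour$a[idx] + prof_tumour$b[idx]
  m <- clip01(beta_mean(prof_tumour$a[idx], prof_tumour$b[idx]) +
                effect$tumour_delta, eps = 0.05)
  prof_tumour$a[idx] <- m * s
  prof_tumour$b[idx] <- (1 - m) * s
  prof_tumour
}

#' Specify the per-sample cell-fraction model
#'
#' Three models are available: `"dirichlet"` (default) draws
#' (epithelial, fibroblast, immune) from a Dirichlet with concentration
#' `alpha`, giving an immune marginal spanning \[0, 1\]; `"ic_uniform"` draws
#' the immune fraction uniformly on `ic_range` with a small fibroblast
#' fraction, the configuration used for index-development cohorts; `"fixed"`
#' uses the supplied fractions for every sample.
#'
#' @param type Model type.
#' @param alpha Dirichlet concentration for (epithelial, fibroblast, immune).
#' @param ic_range Range of the uniform immune fraction.
#' @param fibroblast_shape Beta shapes for the fibroblast share of the
#'   non-immune remainder under `"ic_uniform"`.
#' @param fractions Length-3 fractions (epithelial, fibroblast, immune) for
#'   `"fixed"`; must be non-negative and sum to 1.
#' @return A list of class `wid_fraction_model`.
#' @export
fraction_model <- function(type = c("dirichlet", "ic_uniform", "fixed"),
                           alpha = c(3, 0.5, 2.5),
                           ic_range = c(0, 0.8),
                           fibroblast_shape = c(2, 18),
                           fractions = NULL) {
  type <- match.arg(type)
  if (type == "fixed") {
    if (is.null(fractions) || length(fractions) != 3L ||
        any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
      abort("`fractions` must be 3 non-negative values summing to 1.")
    }
  }
  structure(list(type = type, alpha = alpha, ic_range = ic_range,
                 fibroblast_shape = fibroblast_shape, fractions = fractions),
            class = "wid_fraction_model")
}

draw_fractions <- function(model, n) {
  f <- switch(model$type,
    dirichlet = rdirichlet(n, model$alpha),
    ic_uniform = {
      ic <- runif(n, model$ic_range[1], model$ic_range[2])
      fib <- (1 - ic) * rbeta(n, model$fibroblast_shape[1], model$fibroblast_shape[2])
      cbind(1 - ic - fib, fib, ic)
    },
    fixed = matrix(rep(model$fractions, each = n), nrow = n)
  )
  colnames(f) <- c("epithelial", "fibroblast", "immune")
  f
}

#' Simulate a case/control cervical-smear cohort
#'
#' Each observed beta value is a convex combination of sample-specific draws
#' from the per-cell-type beta distributions,
#' \eqn{\beta = \sum_{ct} f_{ct} \beta_{ct}}, optionally mixed with a tumour
#' compartment at per-sample proportion \eqn{\rho}, plus Gaussian measurement
#' noise truncated to \[0, 1\]. Cases receive a mean shift confined to the
#' effect compartment at the informative CpGs. A detection-p matrix flags
#' simulated probe failures at the stated rate.
#'
#' @param profiles A `wid_profiles` object (or its `profiles` tibble).
#' @param n_cases,n_controls Sample counts per group.
#' @param effect A [effect_spec()] or `NULL` for a null cohort.
#' @param fractions A [fraction_model()].
#' @param tumour_contamination Per-sample tumour proportions in \[0, 1\]
#'   (recycled), or `NULL` for none. When all zero, the tumour compartment is
#'   never drawn and the output matches a run without it.
#' @param noise_sd Measurement noise SD on the beta scale (>= 0).
#' @param detection_fail_rate Probability a probe fails detection.
#' @param seed Integer seed.
#' @param age_effect Optional list(`cpgs`, `slope`): per-year beta trend added
#'   at the listed CpGs, centred at age 50.
#' @param keep_components Keep the per-compartment draws in the truth object
#'   (memory-heavy; used to verify mixing convexity).
#' @return A list of class `wid_cohort`: `beta` (CpG x sample matrix), `sheet`
#'   (tibble: sample_id, type, age, menopause, centre), `detection_p`
#'   (matrix), `truth` (true fractions, per-CpG deltas, seed), `annotation`.
#' @examples
#' pr <- generate_profiles(60, seed = 1)
#' eff <- effect_spec(pr$annotation$cpg_id[1:5], 0.1)
#' ch <- generate_cohort(pr, n_cases = 10, n_controls = 10, effect = eff, seed = 2)
#' dim(ch$beta)
#' @export
generate_cohort <- function(profiles, n_cases, n_controls, effect = NULL,
                            fractions = fraction_model(),
                            tumour_contamination = NULL,
                            noise_sd = 0.01, detection_fail_rate = 0,
                            seed = 1L, age_effect = NULL,
                            keep_components = FALSE) {
  prof <- if (inherits(profiles, "wid_profiles")) profiles$profiles else profiles
  annotation <- if (inherits(profiles, "wid_profiles")) profiles$annotation else NULL
  check_scalar_number(n_cases, "n_cases", lower = 0)
  check_scalar_number(n_controls, "n_controls", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(detection_fail_rate, "detection_fail_rate", 0, 1)
  if (!inherits(fractions, "wid_fraction_model")) {
    abort("`fractions` must be created with fraction_model().")
  }

  prof_split <- split(prof, prof$cell_type)
  cpg_id <- prof_split[[1]]$cpg_id
  n_cpg <- length(cpg_id)
  n <- as.integer(n_cases + n_controls)
  sample_id <- sprintf("S%04d", seq_len(n))
  type <- rep(c("case", "control"), c(n_cases, n_controls))

  rho <- rep(0, n)
  if (!is.null(tumour_contamination)) {
    rho <- rep_len(tumour_contamination, n)
    if (any(rho < 0 | rho > 1)) abort("tumour proportions must lie in [0, 1].")
  }

  # Validate the planted effect before consuming any random numbers.
  inf_idx <- integer(0)
  if (!is.null(effect)) {
    if (!inherits(effect, "wid_effect")) abort("`effect` must be an effect_spec().")
    inf_idx <- match(effect$informative_cpgs, cpg_id)
    if (anyNA(inf_idx)) abort("effect names CpGs absent from the profiles.")
    pe <- prof_split[[effect$compartment]]
    m_shift <- beta_mean(pe$a[inf_idx], pe$b[inf_idx]) + effect$epithelial_delta
    if (any(m_shift <= 0 | m_shift >= 1)) {
      abort("infeasible effect: shifted compartment means leave (0, 1).")
    }
  }

  set.seed(as.integer(seed))
  base_frac <- draw_fractions(fractions, n)
  frac <- cbind(base_frac * (1 - rho), tumour = rho)
  age <- pmin(75, pmax(25, round(rnorm(n, 45, 10))))

  draw_type <- function(ct) {
    p <- prof_split[[ct]]
    matrix(rbeta(n_cpg * n, p$a, p$b), nrow = n_cpg,
           dimnames = list(cpg_id, sample_id))
  }
  comp <- list(
    epithelial = draw_type("epithelial"),
    fibroblast = draw_type("fibroblast"),
    immune     = draw_type("immune")
  )

  if (!is.null(effect) && length(inf_idx) && n_cases > 0) {
    pe <- prof_split[[effect$compartment]]
    s <- pe$a[inf_idx] + pe$b[inf_idx]
    m_shift <- beta_mean(pe$a[inf_idx], pe$b[inf_idx]) + effect$epithelial_delta
    case_cols <- which(type == "case")
    comp[[effect$compartment]][inf_idx, case_cols] <-
      rbeta(length(inf_idx) * length(case_cols), m_shift * s, (1 - m_shift) * s)
  }

  beta <- comp$epithelial * rep(frac[, "epithelial"], each = n_cpg) +
    comp$fibroblast * rep(frac[, "fibroblast"], each = n_cpg) +
    comp$immune * rep(frac[, "immune"], each = n_cpg)
  if (any(rho > 0)) {
    pt <- prof_split[["tumour"]]
    if (!is.null(effect)) pt <- shift_tumour_profiles(pt, effect)
    comp$tumour <- matrix(rbeta(n_cpg * n, pt$a, pt$b), nrow = n_cpg,
                          dimnames = list(cpg_id, sample_id))
    beta <- beta + comp$tumour * rep(frac[, "tumour"], each = n_cpg)
  }

  if (!is.null(age_effect)) {
    ai <- match(age_effect$cpgs, cpg_id)
    beta[ai, ] <- beta[ai, , drop = FALSE] +
      age_effect$slope * rep(age - 50, each = length(ai))
  }
  if (noise_sd > 0) beta <- beta + rnorm(n_cpg * n, 0, noise_sd)
  beta <- clip01(beta)

  fail <- matrix(runif(n_cpg * n) < detection_fail_rate, nrow = n_cpg)
  detection_p <- matrix(runif(n_cpg * n, 0, 0.005), nrow = n_cpg,
                        dimnames = list(cpg_id, sample_id))
  detection_p[fail] <- runif(sum(fail), 0.02, 0.8)

  deltas <- tibble(cpg_id = cpg_id, epithelial_delta = 0, immune_delta = 0)
  if (!is.null(effect)) deltas$epithelial_delta[inf_idx] <- effect$epithelial_delta

  truth <- list(
    fractions = tibble(sample_id = sample_id,
                       epithelial = frac[, "epithelial"],
                       fibroblast = frac[, "fibroblast"],
                       immune = frac[, "immune"],
                       tumour = frac[, "tumour"]),
    deltas = deltas,
    informative_cpgs = cpg_id[inf_idx],
    seed = as.integer(seed)
  )
  if (keep_components) truth$components <- comp

  sheet <- tibble(
    sample_id = sample_id, type = type, age = as.numeric(age),
    menopause = ifelse(age >= 51, "post", "pre"),
    centre = sample(c("A", "B", "C"), n, replace = TRUE)
  )

  structure(list(beta = beta, sheet = sheet, detection_p = detection_p,
                 truth = truth, annotation = annotation),
            class = "wid_cohort")
}

#' @export
print.wid_cohort <- function(x, ...) {
  cat(sprintf("<wid_cohort> %d CpGs x %d samples (%d cases / %d controls)\n",
              nrow(x$beta), ncol(x$beta),
              sum(x$sheet$type == "case"), sum(x$sheet$type == "control")))
  invisible(x)
}

#' Simulate pure cell-type reference samples
#'
#' Draws `n_per_type` samples per cell type, each composed entirely of that
#' type, standing in for purified-cell / cell-line arrays used to build
#' deconvolution reference panels.
#'
#' @param profiles A `wid_profiles` object.
#' @param n_per_type Samples per cell type (>= 2; rank tests need two).
#' @param seed Integer seed.
#' @param noise_sd Measurement noise SD.
#' @param effect Optional [effect_spec()]: tumour reference samples (e.g.
#'   cancer cell lines) then carry the amplified tumour-compartment shift at
#'   the informative CpGs, as real tumour references would.
#' @return List with `beta` (matrix) and `labels` (tibble: sample_id,
#'   cell_type).
#' @export
generate_reference_samples <- function(profiles, n_per_type, seed,
                                       noise_sd = 0.02, effect = NULL) {
  prof <- if (inherits(profiles, "wid_profiles")) profiles$profiles else profiles
  check_scalar_number(n_per_type, "n_per_type", lower = 2)
  n_per_type <- as.integer(n_per_type)
  set.seed(as.integer(seed))
  prof_split <- split(prof, prof$cell_type)[cell_types()]
  if (!is.null(effect)) {
    prof_split[["tumour"]] <- shift_tumour_profiles(prof_split[["tumour"]], effect)
  }
  cpg_id <- prof_split[[1]]$cpg_id
  n_cpg <- length(cpg_id)

  mats <- purrr::map(cell_types(), function(ct) {
    p <- prof_split[[ct]]
    matrix(rbeta(n_cpg * n_per_type, p$a, p$b), nrow = n_cpg)
  })
  beta <- do.call(cbind, mats)
  if (noise_sd > 0) beta <- beta + rnorm(length(beta), 0, noise_sd)
  beta <- clip01(beta)
  labels <- tibble(
    sample_id = sprintf("REF_%s_%02d", rep(cell_types(), each = n_per_type),
                        rep(seq_len(n_per_type), 4)),
    cell_type = rep(cell_types(), each = n_per_type)
  )
  dimnames(beta) <- list(cpg_id, labels$sample_id)
  list(beta = beta, labels = labels)
}
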