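# Penalized-logistic index: training, size sweep, finalization, scoring.

stratified_foldid <- function(y, folds, seed) {
  folds <- min(folds, min(table(y)))
  if (folds < 2L) abort("both classes must appear at least twice.")
  set.seed(as.integer(seed))
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Train a penalized logistic classifier on top-ranked CpGs
#'
#' Fits a binomial glmnet model (ridge `alpha = 0` or lasso `alpha = 1`) on
#' the top `n` CpGs of a ranked list, choosing the regularization strength by
#' stratified 10-fold cross-validated deviance over a geometric grid of 100
#' lambdas down to 1e-4 of the data-driven maximum. Deterministic given
#' `seed`.
#'
#' @param beta CpG x sample training matrix.
#' @param labels `"case"`/`"control"` per sample.
#' @param ranked_cpgs Ranked CpG ids (best first), e.g. from [rank_cpgs()].
#' @param n Number of top CpGs to use (`n <= length(ranked_cpgs)`).
#' @param penalty `"ridge"` or `"lasso"`.
#' @param folds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @return A `wid_classifier`: `cpgs`, `weights`, `intercept`, `lambda`,
#'   `penalty`, `seed`.
#' @export
train_penalized_classifier <- function(beta, labels, ranked_cpgs, n,
                                       penalty = c("ridge", "lasso"),
                                       folds = 10, seed = 1L) {
  penalty <- match.arg(penalty)
  check_beta_matrix(beta)
  if (n > length(ranked_cpgs)) abort("`n` exceeds the ranked CpG list.")
  cpgs <- ranked_cpgs[seq_len(n)]
  if (!all(cpgs %in% rownames(beta))) abort("ranked CpGs missing from `beta`.")
  labels <- get_group_labels(labels, colnames(beta))
  y <- as.numeric(labels == "case")
  x <- t(beta[cpgs, , drop = FALSE])
  foldid <- stratified_foldid(y, folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          alpha = if (penalty == "ridge") 0 else 1,
                          foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4,
                          type.measure = "deviance")
  co <- as.numeric(coef(cv, s = "lambda.min"))
  structure(list(cpgs = cpgs, weights = setNames(co[-1], cpgs),
                 intercept = co[1], lambda = cv$lambda.min,
                 penalty = penalty, seed = as.integer(seed)),
            class = "wid_classifier")
}

classifier_scores <- function(clf, beta) {
  shared <- intersect(clf$cpgs, rownames(beta))
  drop(crossprod(beta[shared, , drop = FALSE], clf$weights[shared]))
}

#' Sweep the index size over a grid of CpG counts
#'
#' Trains one classifier per `n` on the training set and evaluates each on a
#' disjoint validation set by AUC. The optimal `n` maximizes validation AUC;
#' ties go to the smallest `n`.
#'
#' @param train_beta,train_labels Training data.
#' @param val_beta,val_labels Validation data (disjoint samples).
#' @param ranked_cpgs Ranked CpG ids.
#' @param n_grid Candidate CpG counts (each `<= length(ranked_cpgs)`).
#' @param penalty,folds,seed Passed to [train_penalized_classifier()].
#' @return A `wid_sweep` tibble (`n`, `auc`, `lambda`) with attributes
#'   `optimal_n` and `penalty`; see [tidy()] / [glance()] / [autoplot()].
#' @export
sweep_index_size <- function(train_beta, train_labels, val_beta, val_labels,
                             ranked_cpgs, n_grid,
                             penalty = c("ridge", "lasso"),
                             folds = 10, seed = 1L) {
  penalty <- match.arg(penalty)
  if (!length(n_grid)) abort("`n_grid` is empty.")
  if (length(intersect(colnames(train_beta), colnames(val_beta)))) {
    abort("training and validation samples overlap.")
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > length(ranked_cpgs)) {
    abort("`n_grid` exceeds the ranked CpG list.")
  }
  val_y <- get_group_labels(val_labels, colnames(val_beta))
  rows <- purrr::map_dfr(n_grid, function(n) {
    clf <- train_penalized_classifier(train_beta, train_labels, ranked_cpgs,
                                      n, penalty, folds, seed)
    s <- classifier_scores(clf, val_beta)
    tibble(n = n, auc = roc_auc(s, val_y == "case"), lambda = clf$lambda)
  })
  optimal_n <- rows$n[which.max(rows$auc)]  # ties: smallest n (grid sorted)
  structure(rows, class = c("wid_sweep", class(rows)),
            optimal_n = optimal_n, penalty = penalty)
}

#' @method tidy wid_sweep
#' @export
tidy.wid_sweep <- function(x, ...) tibble::as_tibble(unclass(x)[c("n", "auc", "lambda")])

#' @method glance wid_sweep
#' @export
glance.wid_sweep <- function(x, ...) {
  i <- which(x$n == attr(x, "optimal_n"))
  tibble(optimal_n = x$n[i], auc = x$auc[i], lambda = x$lambda[i],
         penalty = attr(x, "penalty"))
}

#' Finalize the index model on the full discovery set
#'
#' Refits the classifier on all discovery samples with the penalty and
#' `lambda` fixed from the sweep, then anchors the index scale: `mu` and
#' `sigma` are the mean and SD of \eqn{\sum_i w_i x_i} over the discovery
#' samples, so the index is zero-mean unit-SD on its training data. The
#' classifier intercept is excluded from the index (it cancels under the
#' scaling). Per-CpG training means are stored for scoring-time imputation.
#'
#' @param beta CpG x sample discovery matrix (train + internal validation).
#' @param labels `"case"`/`"control"` per sample.
#' @param ranked_cpgs Ranked CpG ids.
#' @param n Index size chosen by the sweep.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param lambda Regularization strength fixed from the sweep.
#' @param seed Integer seed (recorded; the refit itself is deterministic).
#' @return A `wid_index_model`: `cpgs`, `weights`, `mu`, `sigma`,
#'   `train_means`, `n`, `penalty`, `lambda`, `seed`.
#' @export
finalize_index <- function(beta, labels, ranked_cpgs, n,
                           penalty = c("ridge", "lasso"), lambda, seed = 1L) {
  penalty <- match.arg(penalty)
  check_beta_matrix(beta)
  if (n > length(ranked_cpgs)) abort("`n` exceeds the ranked CpG list.")
  cpgs <- ranked_cpgs[seq_len(n)]
  labels <- get_group_labels(labels, colnames(beta))
  y <- as.numeric(labels == "case")
  x <- t(beta[cpgs, , drop = FALSE])
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        alpha = if (penalty == "ridge") 0 else 1,
                        lambda = lambda * c(8, 4, 2, 1))
  co <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  w <- setNames(co[-1], cpgs)
  s <- drop(x %*% w)
  sigma <- sd(s)
  if (!is.finite(sigma) || sigma <= 0) abort("degenerate index: sigma is 0.")
  structure(list(cpgs = cpgs, weights = w, mu = mean(s), sigma = sigma,
                 train_means = rowMeans(beta[cpgs, , drop = FALSE]),
                 n = as.integer(n), penalty = penalty, lambda = lambda,
                 seed = as.integer(seed)),
            class = "wid_index_model")
}

#' @export
print.wid_index_model <- function(x, ...) {
  cat(sprintf("<wid_index_model> %d CpGs, %s penalty (lambda = %.4g), mu = %.4g, sigma = %.4g\n",
              x$n, x$penalty, x$lambda, x$mu, x$sigma))
  invisible(x)
}

#' @method tidy wid_index_model
#' @export
tidy.wid_index_model <- function(x, ...) {
  tibble(cpg_id = x$cpgs, weight = unname(x$weights),
         train_mean = unname(x$train_means))
}

#' @method glance wid_index_model
#' @export
glance.wid_index_model <- function(x, ...) {
  tibble(n = x$n, penalty = x$penalty, lambda = x$lambda,
         mu = x$mu, sigma = x$sigma)
}

#' Score samples with an index model
#'
#' Computes \eqn{(\sum_i w_i x_i - \mu) / \sigma} per sample, in SD units of
#' the training distribution. The score is exactly linear in the beta values.
#' At least 95% of the model's CpGs must be present; missing CpGs are imputed
#' at their training mean and reported via a message.
#'
#' @param model A `wid_index_model`.
#' @param beta CpG x sample matrix.
#' @return Tibble: `sample_id`, `index`.
#' @export
compute_index <- function(model, beta) {
  if (!inherits(model, "wid_index_model")) abort("`model` must be a wid_index_model.")
  check_beta_matrix(beta)
  present <- model$cpgs %in% rownames(beta)
  if (mean(present) < 0.95) {
    abort("fewer than 95% of the model's CpGs are present.")
  }
  X <- matrix(model$train_means, length(model$cpgs), ncol(beta),
              dimnames = list(model$cpgs, colnames(beta)))
  X[present, ] <- beta[model$cpgs[present], , drop = FALSE]
  if (any(!present)) {
    rlang::inform(sprintf("compute_index: %d CpG(s) imputed at the training mean.",
                          sum(!present)))
  }
  s <- drop(crossprod(X, model$weights))
  tibble(sample_id = colnames(beta),
         index = unname((s - model$mu) / model$sigma))
}

#' Serialize / restore an index model as JSON
#'
#' @param model A `wid_index_model`.
#' @param path File path.
#' @return `write_index_model()` returns `path` invisibly; `read_index_model()`
#'   the restored model, scoring identically to the original.
#' @export
write_index_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$cpgs <- as.character(m$cpgs)
  m$weights <- setNames(as.numeric(m$weights), m$cpgs)
  m$train_means <- setNames(as.numeric(m$train_means), m$cpgs)
  m$n <- as.integer(m$n)
  structure(m[c("cpgs", "weights", "mu", "sigma", "train_means", "n",
                "penalty", "lambda", "seed")],
            class = "wid_index_model")
}

#' Sub-classifier analysis of an index model
#'
#' Ranks the model's CpGs by absolute weight and retrains fresh classifiers
#' on (i) the top-n CpGs retained, (ii) the top-n removed, and (iii)
#' consecutive bins of `bin_size` CpGs, evaluating each on the validation
#' set. This probes how concentrated versus redundant the predictive signal
#' is across the index.
#'
#' @param model A `wid_index_model`.
#' @param train_beta,train_labels Training data.
#' @param val_beta,val_labels Validation data.
#' @param top_n Grid of top-n values.
#' @param bin_size Bin width (a bin larger than the model yields one bin).
#' @param folds,seed Passed to [train_penalized_classifier()].
#' @return Tibble: `condition` (`"retained"`, `"removed"`, `"bin"`), `which`
#'   (n or bin index), `n_cpgs`, `auc`.
#' @export
subclassifier_analysis <- function(model, train_beta, train_labels,
                                   val_beta, val_labels,
                                   top_n = c(50, 100, 200), bin_size = 500,
                                   folds = 10, seed = 1L) {
  if (!inherits(model, "wid_index_model")) abort("`model` must be a wid_index_model.")
  ranked <- model$cpgs[order(-abs(model$weights))]
  val_y <- get_group_labels(val_labels, colnames(val_beta)) == "case"
  eval_subset <- function(cpgs) {
    clf <- train_penalized_classifier(train_beta, train_labels, cpgs,
                                      length(cpgs), model$penalty, folds, seed)
    roc_auc(classifier_scores(clf, val_beta), val_y)
  }
  top_n <- top_n[top_n <= length(ranked)]
  rows <- list()
  for (n in top_n) {
    rows[[length(rows) + 1L]] <- tibble(condition = "retained", which = n,
                                        n_cpgs = n,
                                        auc = eval_subset(ranked[seq_len(n)]))
    rest <- ranked[-seq_len(n)]
    if (length(rest) >= 2L) {
      rows[[length(rows) + 1L]] <- tibble(condition = "removed", which = n,
                                          n_cpgs = length(rest),
                                          auc = eval_subset(rest))
    }
  }
  if (bin_size >= length(ranked)) {
    bins <- list(seq_along(ranked))
  } else {
    bins <- split(seq_along(ranked), ceiling(seq_along(ranked) / bin_size))
  }
  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    if (length(idx) < 2L) next
    rows[[length(rows) + 1L]] <- tibble(condition = "bin", which = b,
                                        n_cpgs = length(idx),
                                        auc = eval_subset(ranked[idx]))
  }
  dplyr::bind_rows(rows)
}
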