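toy_model <- function(w, mu, sigma, cpgs = paste0("cg", seq_along(w)),
                      train_means = rep(0.5, length(w))) {
  structure(list(cpgs = cpgs, weights = setNames(w, cpgs), mu = mu,
                 sigma = sigma, train_means = setNames(train_means, cpgs),
                 n = length(w), penalty = "ridge", lambda = 0.1, seed = 1L),
            class = "wid_index_model")
}

sep_data <- function(n_per = 30, seed = 1) {
  set.seed(seed)
  beta <- cbind(matrix(runif(2 * n_per, 0.7, 0.9), 2),
                matrix(runif(2 * n_per, 0.1, 0.3), 2))
  dimnames(beta) <- list(c("cg1", "cg2"), sprintf("S%03d", seq_len(2 * n_per)))
  labels <- setNames(rep(c("case", "control"), each = n_per), colnames(beta))
  list(beta = beta, labels = labels)
}

test_that("perfectly separating CpGs give training AUC 1 under ridge", {
  d <- sep_data()
  clf <- train_penalized_classifier(d$beta, d$labels, rownames(d$beta), 2,
                                    "ridge", folds = 5, seed = 1)
  s <- widoc:::classifier_scores(clf, d$beta)
  expect_equal(widoc:::roc_auc(s, d$labels == "case"), 1.0)
  expect_error(train_penalized_classifier(d$beta, d$labels, rownames(d$beta),
                                          5, "ridge"), "exceeds")
})

test_that("pure-noise CpGs give a chance-level validation AUC", {
  set.seed(9)
  n <- 300
  beta <- matrix(runif(100 * n), 100, n,
                 dimnames = list(paste0("cg", 1:100), sprintf("S%03d", 1:n)))
  labels <- setNames(rep(c("case", "control"), each = n / 2), colnames(beta))
  tr <- sample(colnames(beta), 150)
  va <- setdiff(colnames(beta), tr)
  sw <- sweep_index_size(beta[, tr], labels[tr], beta[, va], labels[va],
                         rownames(beta), n_grid = 100, folds = 5, seed = 3)
  expect_gte(sw$auc, 0.4)
  expect_lte(sw$auc, 0.6)
  expect_equal(attr(sw, "optimal_n"), 100L)
})

test_that("lasso concentrates its support on the informative CpGs", {
  w <- make_world(n_cpgs = 1000, n_cases = 100, n_controls = 100,
                  n_informative = 20, delta = 0.25, seed = 13,
                  fractions = fraction_model("fixed",
                                             fractions = c(0.9, 0.05, 0.05)))
  # fixed fractions: zero IC spread, so ranking is uninformative and the
  # lasso must find the support among all 1000 CpGs on its own
  db <- suppressWarnings(
    estimate_delta_betas(w$cohort$beta, w$cohort$truth$fractions$immune,
                         w$cohort$sheet))
  ranked <- rank_cpgs(db)
  clf <- train_penalized_classifier(w$cohort$beta, w$cohort$sheet, ranked,
                                    1000, "lasso", folds = 5, seed = 2)
  nz <- names(clf$weights)[clf$weights != 0]
  expect_gt(length(nz), 0)
  expect_gte(mean(nz %in% w$effect$informative_cpgs), 0.5)
})

test_that("wider coverage of a planted signal does not hurt the sweep", {
  w <- make_world(n_cpgs = 600, n_cases = 120, n_controls = 120,
                  n_informative = 100, delta = 0.12, seed = 17)
  sheet <- w$cohort$sheet
  sp <- split_discovery(sheet, seed = 5)
  ic <- setNames(w$cohort$truth$fractions$immune,
                 w$cohort$truth$fractions$sample_id)
  db <- estimate_delta_betas(w$cohort$beta[, sp$train], ic[sp$train], sheet)
  ranked <- rank_cpgs(db)
  sw <- sweep_index_size(w$cohort$beta[, sp$train],
                         sheet[match(sp$train, sheet$sample_id), ],
                         w$cohort$beta[, sp$validation],
                         sheet[match(sp$validation, sheet$sample_id), ],
                         ranked, n_grid = c(10, 100), folds = 5, seed = 6)
  expect_gte(sw$auc[sw$n == 100], sw$auc[sw$n == 10])
  expect_s3_class(tidy(sw), "tbl_df")
  expect_equal(nrow(glance(sw)), 1)
  expect_error(sweep_index_size(w$cohort$beta[, sp$train], sheet,
                                w$cohort$beta[, sp$train], sheet,
                                ranked, c(10)), "overlap")
})

test_that("finalized models are deterministic, scaled, and serializable", {
  d <- sep_data(n_per = 25, seed = 3)
  m1 <- finalize_index(d$beta, d$labels, rownames(d$beta), 2, "ridge",
                       lambda = 0.05)
  m2 <- finalize_index(d$beta, d$labels, rownames(d$beta), 2, "ridge",
                       lambda = 0.05)
  expect_identical(m1$weights, m2$weights)

  sc <- compute_index(m1, d$beta)
  expect_lt(abs(mean(sc$index)), 1e-8)
  expect_lt(abs(sd(sc$index) - 1), 1e-8)

  path <- withr::local_tempfile(fileext = ".json")
  write_index_model(m1, path)
  m3 <- read_index_model(path)
  expect_equal(compute_index(m3, d$beta)$index, sc$index, tolerance = 1e-12)
  expect_equal(glance(m3)$n, 2L)
  expect_equal(nrow(tidy(m1)), 2)
})

test_that("the index formula is exact hand arithmetic and linear in beta", {
  m <- toy_model(w = c(1, -1), mu = 0, sigma = 0.5)
  x <- matrix(c(0.8, 0.3), 2, 1, dimnames = list(m$cpgs, "S1"))
  expect_equal(compute_index(m, x)$index, 1.0)

  set.seed(4)
  bc <- matrix(runif(2 * 5), 2, 5, dimnames = list(m$cpgs, paste0("S", 1:5)))
  bt <- c(cg1 = 0.9, cg2 = 0.1)
  rho <- 0.3
  mixed <- (1 - rho) * bc + rho * bt
  lhs <- compute_index(m, mixed)$index
  rhs <- (1 - rho) * compute_index(m, bc)$index +
    rho * compute_index(m, matrix(bt, 2, 5, dimnames = dimnames(bc)))$index
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("scoring imputes sparse missing CpGs and refuses heavy loss", {
  m <- toy_model(w = rep(0.1, 40), mu = 0.2, sigma = 0.5,
                 train_means = rep(0.4, 40))
  set.seed(5)
  full <- matrix(runif(40 * 3), 40, 3, dimnames = list(m$cpgs, paste0("S", 1:3)))
  part <- full[-1, , drop = FALSE]   # 97.5% present
  expect_message(sc <- compute_index(m, part), "imputed")
  manual <- (colSums(rbind(cg1 = 0.4, part) * 0.1) - 0.2) / 0.5
  expect_equal(sc$index, unname(manual))
  expect_error(compute_index(m, full[-(1:3), ]), "95%")
})

test_that("subclassifier analysis spans retained, removed, and binned subsets", {
  w <- make_world(n_cpgs = 300, n_cases = 80, n_controls = 80,
                  n_informative = 40, delta = 0.2, seed = 19)
  sheet <- w$cohort$sheet
  sp <- split_discovery(sheet, seed = 7)
  ic <- setNames(w$cohort$truth$fractions$immune,
                 w$cohort$truth$fractions$sample_id)
  db <- estimate_delta_betas(w$cohort$beta[, sp$train], ic[sp$train], sheet)
  ranked <- rank_cpgs(db)
  model <- finalize_index(w$cohort$beta[, sp$train],
                          sheet[match(sp$train, sheet$sample_id), ],
                          ranked, 60, "ridge", lambda = 0.1)
  res <- subclassifier_analysis(model,
                                w$cohort$beta[, sp$train],
                                sheet[match(sp$train, sheet$sample_id), ],
                                w$cohort$beta[, sp$validation],
                                sheet[match(sp$validation, sheet$sample_id), ],
                                top_n = c(20, 60), bin_size = 500,
                                folds = 5, seed = 8)
  expect_setequal(unique(res$condition), c("retained", "removed", "bin"))
  # a bin wider than the model collapses to a single bin over all CpGs
  expect_equal(sum(res$condition == "bin"), 1)
  expect_equal(res$n_cpgs[res$condition == "bin"], 60)

  # retaining every CpG reproduces a fresh full-model fit exactly
  full_clf <- train_penalized_classifier(
    w$cohort$beta[, sp$train], sheet[match(sp$train, sheet$sample_id), ],
    model$cpgs[order(-abs(model$weights))], 60, "ridge", folds = 5, seed = 8)
  full_auc <- widoc:::roc_auc(
    widoc:::classifier_scores(full_clf, w$cohort$beta[, sp$validation]),
    sheet$type[match(sp$validation, sheet$sample_id)] == "case")
  expect_equal(res$auc[res$condition == "retained" & res$which == 60],
               full_auc)
})
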