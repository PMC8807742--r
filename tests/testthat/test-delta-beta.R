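line_cohort <- function(ic_case, ic_control, f_case, f_control, n_cpgs = 3) {
  n <- length(ic_case) + length(ic_control)
  ids <- sprintf("S%02d", seq_len(n))
  labels <- rep(c("case", "control"), c(length(ic_case), length(ic_control)))
  ic <- c(ic_case, ic_control)
  beta <- t(sapply(seq_len(n_cpgs), function(i) {
    ifelse(labels == "case", f_case(ic), f_control(ic))
  }))
  dimnames(beta) <- list(sprintf("cg%02d", seq_len(n_cpgs)), ids)
  list(beta = beta, ic = setNames(ic, ids), labels = setNames(labels, ids))
}

test_that("noiseless regression lines give exact intercept-method deltas", {
  lc <- line_cohort(ic_case = c(0.1, 0.3, 0.5, 0.7),
                    ic_control = c(0.2, 0.4, 0.6, 0.8),
                    f_case = function(u) 0.4 + 0.1 * u,
                    f_control = function(u) 0.2 + 0.3 * u)
  db <- estimate_delta_betas(lc$beta, lc$ic, lc$labels)
  expect_equal(db$epithelial_delta, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(db$immune_delta, rep(0.0, 3), tolerance = 1e-12)
  expect_equal(db$case_intercept - db$control_intercept,
               db$epithelial_delta)
  expect_equal((db$case_intercept + db$case_slope) -
                 (db$control_intercept + db$control_slope),
               db$immune_delta)
})

test_that("identical groups give zero deltas and label swap negates them", {
  lc <- line_cohort(ic_case = c(0.1, 0.4, 0.6, 0.8),
                    ic_control = c(0.1, 0.4, 0.6, 0.8),
                    f_case = function(u) 0.3 + 0.2 * u,
                    f_control = function(u) 0.3 + 0.2 * u)
  db <- estimate_delta_betas(lc$beta, lc$ic, lc$labels)
  expect_lt(max(abs(db$epithelial_delta)), 1e-12)
  expect_lt(max(abs(db$immune_delta)), 1e-12)

  lc2 <- line_cohort(ic_case = c(0.1, 0.3, 0.5, 0.7),
                     ic_control = c(0.2, 0.4, 0.6, 0.8),
                     f_case = function(u) 0.45 + 0.05 * u,
                     f_control = function(u) 0.25 + 0.28 * u)
  db_fwd <- estimate_delta_betas(lc2$beta, lc2$ic, lc2$labels)
  swapped <- ifelse(lc2$labels == "case", "control", "case")
  db_rev <- estimate_delta_betas(lc2$beta, lc2$ic,
                                 setNames(swapped, names(lc2$labels)))
  expect_equal(db_rev$epithelial_delta, -db_fwd$epithelial_delta)
  expect_equal(db_rev$immune_delta, -db_fwd$immune_delta)
})

test_that("two distinct IC values per group reproduce the two-point fit", {
  lc <- line_cohort(ic_case = c(0.2, 0.2, 0.6, 0.6),
                    ic_control = c(0.1, 0.1, 0.7, 0.7),
                    f_case = function(u) 0.5 + 0.2 * u,
                    f_control = function(u) 0.1 + 0.4 * u, n_cpgs = 1)
  db <- estimate_delta_betas(lc$beta, lc$ic, lc$labels)
  # closed form from the two support points of each line
  expect_equal(db$case_slope, (0.62 - 0.54) / 0.4, tolerance = 1e-12)
  expect_equal(db$control_slope, (0.38 - 0.14) / 0.6, tolerance = 1e-12)
  expect_equal(db$epithelial_delta, 0.5 - 0.1, tolerance = 1e-12)
})

test_that("zero IC spread in a group flags records instead of silently zeroing", {
  lc <- line_cohort(ic_case = c(0.3, 0.3, 0.3, 0.3),
                    ic_control = c(0.2, 0.4, 0.6, 0.8),
                    f_case = function(u) 0.4 + 0 * u,
                    f_control = function(u) 0.2 + 0.3 * u)
  expect_warning(db <- estimate_delta_betas(lc$beta, lc$ic, lc$labels),
                 "zero IC variance")
  expect_true(all(is.na(db$epithelial_delta)))
  expect_false(any(db$available))

  expect_error(estimate_delta_betas(lc$beta[, 1:5], lc$ic[1:5],
                                    lc$labels[1:5]), "3 cases")
})

test_that("planted epithelial deltas are recovered against the true-IC oracle", {
  w <- make_world(n_cpgs = 1000, n_cases = 200, n_controls = 200,
                  n_informative = 100, delta = 0.15, noise_sd = 0.02,
                  seed = 77)
  db <- estimate_delta_betas(w$cohort$beta, w$cohort$truth$fractions$immune,
                             w$cohort$sheet)
  est <- db$epithelial_delta[match(w$effect$informative_cpgs, db$cpg_id)]
  expect_lt(abs(mean(est) - 0.15), 0.02)
  null_est <- db$epithelial_delta[!db$cpg_id %in% w$effect$informative_cpgs]
  expect_lt(abs(mean(null_est)), 0.01)
})

test_that("ranking follows absolute deltas with lexicographic tie-breaks", {
  rec <- tibble::tibble(cpg_id = c("c1", "c2", "c3"),
                        epithelial_delta = c(0.3, -0.5, 0.1),
                        immune_delta = c(0.0, 0.4, 0.0))
  expect_equal(rank_cpgs(rec, "epithelial"), c("c2", "c1", "c3"))
  expect_equal(rank_cpgs(rec, "immune"), c("c2", "c1", "c3"))

  rec2 <- tibble::tibble(cpg_id = c("b", "c", "a"),
                         epithelial_delta = c(0.2, 0.2, 0.2),
                         immune_delta = 0)
  expect_equal(rank_cpgs(rec2, "epithelial"), c("a", "b", "c"))

  rec3 <- tibble::tibble(cpg_id = c("c1", "c2"),
                         epithelial_delta = c(0.2, 0.05),
                         immune_delta = c(0.0, 0.4))
  expect_equal(rank_cpgs(rec3, "combined"), c("c2", "c1"))

  expect_error(rank_cpgs(rec[0, ], "epithelial"), "empty")
  expect_error(rank_cpgs(rec, "everything"), "arg")
})

test_that("the covariate-adjusted scan holds its size and finds planted CpGs", {
  null_w <- make_world(n_cpgs = 2000, n_cases = 100, n_controls = 100,
                       n_informative = 0, seed = 55)
  cov <- data.frame(ic = null_w$cohort$truth$fractions$immune,
                    age = null_w$cohort$sheet$age)
  res <- dmp_association_test(null_w$cohort$beta, null_w$cohort$sheet, cov)
  frac_sig <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(frac_sig, 0.03)
  expect_lte(frac_sig, 0.07)

  sig_w <- make_world(n_cpgs = 500, n_cases = 200, n_controls = 200,
                      n_informative = 20, delta = 0.2, seed = 56)
  cov2 <- data.frame(ic = sig_w$cohort$truth$fractions$immune,
                     age = sig_w$cohort$sheet$age)
  res2 <- dmp_association_test(sig_w$cohort$beta, sig_w$cohort$sheet, cov2)
  planted <- res2[match(sig_w$effect$informative_cpgs, res2$cpg_id), ]
  expect_true(all(planted$p_bonferroni < 0.05))
})

test_that("degenerate scan inputs are flagged or rejected", {
  w <- make_world(n_cpgs = 20, n_cases = 10, n_controls = 10, seed = 58)
  beta <- w$cohort$beta
  beta[1, ] <- 0.5
  cov <- data.frame(ic = w$cohort$truth$fractions$immune,
                    age = w$cohort$sheet$age)
  res <- dmp_association_test(beta, w$cohort$sheet, cov)
  expect_true(is.na(res$p[1]))
  expect_false(res$available[1])

  cov_bad <- data.frame(ic = cov$ic, ic2 = 2 * cov$ic)
  expect_error(dmp_association_test(beta, w$cohort$sheet, cov_bad),
               "collinear")
})
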