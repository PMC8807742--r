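test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  res <- roc_auc_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$auc, 0.75)

  sep <- roc_auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1.0)

  set.seed(201)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc_ci(scores, labels)$auc,
                 oracle_auc(scores, labels))
  }
  expect_error(roc_auc_ci(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the DeLong interval matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(202)
  scores <- c(rnorm(60, 0.5), rnorm(40))
  labels <- rep(c(1, 0), c(60, 40))
  ours <- roc_auc_ci(scores, labels)
  ref <- suppressMessages(
    as.numeric(pROC::ci.auc(labels, scores, method = "delong")))
  expect_equal(ours$auc, ref[2], tolerance = 1e-10)
  expect_equal(ours$conf_lo, ref[1], tolerance = 1e-6)
  expect_equal(ours$conf_hi, ref[3], tolerance = 1e-6)
})

test_that("random labels give a chance-level AUC at n = 2000", {
  set.seed(203)
  scores <- rnorm(2000)
  labels <- sample(rep(c(1, 0), 1000))
  auc <- roc_auc_ci(scores, labels)$auc
  expect_gte(auc, 0.47)
  expect_lte(auc, 0.53)
})

test_that("mid-p odds ratios are median-unbiased and attenuated", {
  sym <- midp_odds_ratio(20, 20, 20, 20)
  expect_equal(sym$estimate, 1.0, tolerance = 1e-8)
  expect_lt(sym$conf_lo, 1)
  expect_gt(sym$conf_hi, 1)

  # attenuation relative to the cross-product ratio
  est <- midp_odds_ratio(57, 74, 3, 75)$estimate
  expect_lt(est, (57 * 75) / (74 * 3))
  expect_gt(est, 1)

  # defining identity: mid-p tail at the estimate is exactly one half,
  # and the CI endpoints invert the tails at alpha/2
  tabs <- list(c(10, 74, 3, 75), c(57, 74, 3, 75), c(18, 16, 12, 41),
               c(7, 5, 3, 11))
  for (tb in tabs) {
    or <- midp_odds_ratio(tb[1], tb[2], tb[3], tb[4])
    expect_equal(midp_tail_probability(tb[1], tb[2], tb[3], tb[4],
                                       or$estimate), 0.5, tolerance = 1e-6)
    expect_equal(midp_tail_probability(tb[1], tb[2], tb[3], tb[4],
                                       or$conf_lo), 0.025, tolerance = 1e-6)
    expect_equal(1 - midp_tail_probability(tb[1], tb[2], tb[3], tb[4],
                                           or$conf_hi), 0.025,
                 tolerance = 1e-6)
  }

  # large balanced tables approach the cross-product ratio
  big <- midp_odds_ratio(300, 250, 220, 280)
  cp <- (300 * 280) / (250 * 220)
  expect_lt(abs(big$estimate - cp) / cp, 0.02)
})

test_that("zero cells sit on the boundary and zero margins error", {
  z <- midp_odds_ratio(0, 20, 10, 20)
  expect_equal(z$estimate, 0)
  expect_equal(z$conf_lo, 0)
  expect_true(is.finite(z$conf_hi))
  zi <- midp_odds_ratio(10, 20, 0, 20)
  expect_equal(zi$estimate, Inf)
  expect_true(is.finite(zi$conf_lo))
  expect_error(midp_odds_ratio(0, 0, 5, 5), "margins")
  expect_error(midp_odds_ratio(3.5, 1, 1, 1), "integers")
})

test_that("control-derived cutpoints split 297 controls as 75/74/74/74", {
  set.seed(204)
  ctrl <- rnorm(297)
  cases <- rnorm(83, mean = 1)
  qt <- quartile_odds_table(c(ctrl, cases),
                            rep(c("control", "case"), c(297, 83)), ctrl)
  expect_equal(qt$n_control, c(75L, 74L, 74L, 74L))
  expect_equal(sum(qt$n_case), 83L)
  expect_equal(qt$or[1], 1)
  expect_true(all(qt$or[2:4] > 0))
})

test_that("null quartile tables cover an odds ratio of one", {
  set.seed(205)
  ctrl <- rnorm(400)
  cases <- rnorm(400)
  qt <- quartile_odds_table(c(ctrl, cases),
                            rep(c("control", "case"), each = 400), ctrl)
  expect_true(all(qt$or_conf_lo[2:4] < 1 & qt$or_conf_hi[2:4] > 1))
  expect_error(quartile_odds_table(cases, rep("case", 400), rep(1, 400)),
               "degenerate")
})

test_that("covariate adjustment produces Wald intervals per quartile", {
  set.seed(206)
  n <- 600
  score <- rnorm(n)
  age <- rnorm(n, 50, 8)
  p <- plogis(-1 + 0.8 * score + 0.02 * (age - 50))
  y <- ifelse(rbinom(n, 1, p) == 1, "case", "control")
  ctrl_scores <- score[y == "control"]
  qt <- quartile_odds_table(score, y, ctrl_scores,
                            covariates = data.frame(age = age))
  expect_true(all(c("or_adj", "or_adj_conf_lo", "or_adj_conf_hi") %in%
                    names(qt)))
  expect_true(attr(qt, "adj_converged"))
  expect_equal(qt$or_adj[1], 1)
  expect_gt(qt$or_adj[4], qt$or_adj[2])
})

test_that("region enrichment matches hand-built tables and boundary cases", {
  ann <- tibble::tibble(
    cpg_id = sprintf("cg%02d", 1:8),
    region_class = rep(c("Island", "OpenSea"), each = 4)
  )
  sel <- c("cg01", "cg06", "cg07", "cg08")   # 1 Island + 3 OpenSea
  res <- region_enrichment(sel, ann)
  open <- res[res$region_class == "OpenSea", ]
  hand <- midp_odds_ratio(3, 1, 1, 3)
  expect_equal(open$or, hand$estimate)
  expect_gt(open$or, 1)   # direction agrees with cross-product 9.0
  expect_lt(res$or[res$region_class == "Island"], 1)

  all_open <- ann$cpg_id[ann$region_class == "OpenSea"]
  res2 <- region_enrichment(all_open, ann)
  expect_equal(res2$or[res2$region_class == "OpenSea"], Inf)
  expect_equal(res2$or[res2$region_class == "Island"], 0)

  expect_error(region_enrichment("cgZZ", ann), "subset")
})

test_that("a random 10% selection is unenriched in every region class", {
  pr <- generate_profiles(20000, seed = 207)
  set.seed(209)
  sel <- sample(pr$annotation$cpg_id, 2000)
  res <- region_enrichment(sel, pr$annotation)
  expect_equal(nrow(res), 4)
  expect_true(all(res$conf_lo < 1 & res$conf_hi > 1))
})

test_that("polygenic scores are exact weighted dosage sums", {
  w <- tibble::tibble(snp_id = c("rs1", "rs2"), effect_allele = c("A", "G"),
                      beta = c(0.1, -0.2))
  d <- matrix(c(2, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("rs1", "rs2")))
  prs <- compute_prs(d, w)
  expect_equal(prs$prs, c(0.2 - 0.2, 0))
  expect_equal(compute_prs(d, dplyr::mutate(w, beta = 2 * beta))$prs,
               2 * prs$prs)

  d_na <- d
  d_na["P1", "rs2"] <- NA
  expect_error(compute_prs(d_na, w), "allele frequencies")
  imp <- compute_prs(d_na, w, allele_freq = c(rs1 = 0.3, rs2 = 0.25))
  expect_equal(imp$prs[1], 0.1 * 2 - 0.2 * (2 * 0.25))

  colnames(d)[2] <- "rsX"
  expect_error(compute_prs(d, w), "rsX")
})

test_that("PMR is the percentage of the fully-methylated reference", {
  expect_equal(compute_pmr(0.08, 0.08), 100)
  expect_equal(compute_pmr(0, 0.08), 0)
  expect_equal(compute_pmr(0.02, 0.08), 25.0)
  expect_equal(compute_pmr(c(0.02, 0.04), 0.08), c(25, 50))
  expect_error(compute_pmr(0.02, 0), "positive")
})
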