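#' Published per-quartile case/control counts for the cervical-smear index
#'
#' Per-quartile control and case counts from the published multi-cohort
#' validation of the cervical-smear methylation index, with quartiles
#' defined on the internal-validation control distribution: internal and
#' external ovarian-cancer validation sets, an endometrial-cancer set, a
#' poor-prognosis breast-cancer set, and a BRCA1 mutation-carrier set.
#' These counts are the inputs from which the unadjusted quartile odds
#' ratios are recomputed with [midp_odds_ratio()].
#'
#' @return Tibble: `cohort`, `quartile` (`Q1`-`Q4`), `n_control`, `n_case`.
#' @examples
#' counts <- published_quartile_counts()
#' q4 <- subset(counts, cohort == "internal_ovarian" & quartile %in% c("Q1", "Q4"))
#' midp_odds_ratio(q4$n_case[2], q4$n_control[2], q4$n_case[1], q4$n_control[1])
#' @export
published_quartile_counts <- function() {
  tibble(
    cohort = rep(c("internal_ovarian", "external_ovarian", "endometrial",
                   "breast", "brca1"), each = 4L),
    quartile = rep(paste0("Q", 1:4), 5L),
    n_control = c(75, 74, 74, 74,
                  59, 57, 49, 60,
                  75, 74, 74, 74,
                  75, 74, 74, 74,
                  41, 26, 31, 16),
    n_case = c(3, 10, 13, 57,
               2, 6, 6, 33,
               4, 6, 15, 192,
               28, 49, 91, 161,
               12, 15, 12, 18)
  )
}

#' Recompute the published unadjusted quartile odds ratios
#'
#' Applies the median-unbiased mid-p estimator to the 2x2 tables formed by
#' each quartile against the first, for every cohort in
#' [published_quartile_counts()].
#'
#' @param conf_level Confidence level.
#' @return Tibble: `cohort`, `quartile`, counts, `or`, `conf_lo`, `conf_hi`.
#' @export
published_quartile_ors <- function(conf_level = 0.95) {
  counts <- published_quartile_counts()
  counts |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_modify(function(g, key) {
      ors <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
        if (i == 1L) return(tibble(estimate = 1, conf_lo = NA_real_,
                                   conf_hi = NA_real_))
        midp_odds_ratio(g$n_case[i], g$n_control[i],
                        g$n_case[1], g$n_control[1], conf_level)
      })
      dplyr::bind_cols(g, dplyr::rename(ors, or = "estimate"))
    }) |>
    dplyr::ungroup()
}
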