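#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: given the allele counts, the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (two-sided, the usual exact HWE formulation).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(is.na(c(n_AA, n_Aa, n_aa)))) {
    abort("genotype counts must be non-negative.",
          class = "cardiotrio_input_error")
  }
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("need at least one genotype.", class = "cardiotrio_input_error")
  n_a <- 2L * n_aa + n_Aa
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0L) return(1)
  h_all <- seq(rare %% 2L, rare, by = 2L)
  hom_rare <- (rare - h_all) %/% 2L
  hom_common <- n - h_all - hom_rare
  logp <- h_all * log(2) + lfactorial(n) -
    lfactorial(hom_rare) - lfactorial(h_all) - lfactorial(hom_common)
  logp <- logp - max(logp)
  p_all <- exp(logp) / sum(exp(logp))
  h_obs <- n_Aa
  p_obs <- p_all[match(h_obs, h_all)]
  if (is.na(p_obs)) {
    abort("heterozygote count inconsistent with allele counts.",
          class = "cardiotrio_input_error")
  }
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-9)]))
}

gt_alt_count <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% "1/1"] <- 2L
  out
}

#' Site and genotype quality control for trio records
#'
#' Applies the hard filters of the processing pipeline: genotypes with
#' GQ < 20 or DP < 8 are first set to missing; then sites are removed
#' when site quality < 30, mapping quality < 20, the parental genotypes
#' violate Hardy-Weinberg equilibrium (exact p < 1e-5), or the genotype
#' missing rate exceeds 10%. Records are sparse: (trio, site) rows absent
#' from the table are implicit clean homozygous-reference calls, so
#' `n_trios` sets the denominator for the missing-rate and HWE
#' evaluations. A record missing a QC field fails closed.
#'
#' @param records Trio genotype tibble (one row per trio per variant,
#'   columns `child_gt`, `child_dp`, `child_gq`, ... for each member,
#'   plus `qual`, `mapq`).
#' @param n_trios Number of trios in the cohort; defaults to the number
#'   of distinct `trio_id` values in `records`.
#' @param qual_min,mapq_min,hwe_p_min,max_missing Filter thresholds.
#' @param gq_min,dp_min Genotype masking thresholds.
#' @return The filtered records, genotype columns masked to `NA` where
#'   applicable; dropped sites and reasons in `attr(, "qc_removed")`.
#' @export
apply_site_qc <- function(records, n_trios = NULL,
                          qual_min = 30, mapq_min = 20,
                          hwe_p_min = 1e-5, max_missing = 0.1,
                          gq_min = 20, dp_min = 8) {
  n_trios <- n_trios %||% dplyr::n_distinct(records$trio_id)
  for (m in c("child", "father", "mother")) {
    gt <- paste0(m, "_gt"); gq <- paste0(m, "_gq"); dp <- paste0(m, "_dp")
    bad <- is.na(records[[gq]]) | is.na(records[[dp]]) |
      records[[gq]] < gq_min | records[[dp]] < dp_min
    records[[gt]][bad] <- NA_character_
  }

  site <- records |>
    group_by(variant_key) |>
    summarise(
      qual = qual[1], mapq = mapq[1],
      n_rows = dplyr::n(),
      n_missing = sum(is.na(child_gt)) + sum(is.na(father_gt)) +
        sum(is.na(mother_gt)),
      p_AA = sum(c(father_gt, mother_gt) %in% "0/0"),
      p_Aa = sum(c(father_gt, mother_gt) %in% c("0/1", "1/0")),
      p_aa = sum(c(father_gt, mother_gt) %in% "1/1"),
      .groups = "drop"
    ) |>
    mutate(
      denom = 3 * pmax(n_trios, n_rows),
      implicit = pmax(n_trios - n_rows, 0L),
      missing_rate = n_missing / denom,
      hwe_p = purrr::pmap_dbl(
        list(p_AA + 2L * implicit, p_Aa, p_aa),
        hwe_exact_test
      ),
      reason = case_when(
        is.na(qual) | is.na(mapq) ~ "missing QC field",
        qual < qual_min ~ "site quality",
        mapq < mapq_min ~ "mapping quality",
        hwe_p < hwe_p_min ~ "HWE violation in parents",
        missing_rate > max_missing ~ "missing rate",
        TRUE ~ NA_character_
      )
    )

  removed <- site |> filter(!is.na(reason)) |> select(variant_key, reason)
  if (nrow(removed) > 0) {
    inform(sprintf("apply_site_qc: removed %d of %d sites.",
                   nrow(removed), nrow(site)))
  }
  out <- records |> filter(!variant_key %in% removed$variant_key)
  attr(out, "qc_removed") <- removed
  out
}
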