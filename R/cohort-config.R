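#' Cohort simulation configuration
#'
#' Bundles and validates the parameters of the synthetic trio cohort.
#'
#' @param n_trios Number of trios (>= 1).
#' @param n_genes Number of genes in the toy genome (>= 1).
#' @param dnm_fold_enrichment Multiplier applied to the expected de novo
#'   mutation rate inside the designated enriched gene set (> 0).
#' @param recessive_carrier_freq Per-parent heterozygous carrier
#'   frequency for planted recessive loci, in (0, 0.5).
#' @param seq_error_rate Per-read error rate in \[0, 0.1\]. At exactly 0
#'   the generator emits noise-free read support: depth equals
#'   `mean_depth` and allele depths are the rounded expectation, so
#'   classifier output is deterministic given the genotypes.
#' @param mean_depth Mean sequencing depth (positive integer).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_trios, n_genes, dnm_fold_enrichment = 1,
                          recessive_carrier_freq = 0.2,
                          seq_error_rate = 0, mean_depth = 40, seed = 1) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "cardiotrio_config_error")
  chk(is.numeric(n_trios) && length(n_trios) == 1 && n_trios >= 1,
      "`n_trios` must be a positive integer.")
  chk(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1,
      "`n_genes` must be a positive integer.")
  chk(is.numeric(dnm_fold_enrichment) && dnm_fold_enrichment > 0,
      "`dnm_fold_enrichment` must be positive.")
  chk(is.numeric(recessive_carrier_freq) && recessive_carrier_freq > 0 &&
        recessive_carrier_freq < 0.5,
      "`recessive_carrier_freq` must lie in (0, 0.5).")
  chk(is.numeric(seq_error_rate) && seq_error_rate >= 0 && seq_error_rate <= 0.1,
      "`seq_error_rate` must lie in [0, 0.1].")
  chk(is.numeric(mean_depth) && mean_depth >= 1,
      "`mean_depth` must be a positive integer.")
  chk(is.numeric(seed) && length(seed) == 1 && !is.na(seed),
      "`seed` must be an integer.")
  structure(
    list(n_trios = as.integer(n_trios), n_genes = as.integer(n_genes),
         dnm_fold_enrichment = dnm_fold_enrichment,
         recessive_carrier_freq = recessive_carrier_freq,
         seq_error_rate = seq_error_rate,
         mean_depth = as.integer(mean_depth), seed = as.integer(seed)),
    class = "cohort_config"
  )
}
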