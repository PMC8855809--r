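test_that("cohort simulation is deterministic under a fixed config", {
  gm <- make_gene_models(6, seed = 2)
  rates <- make_rate_table(seed = 2)
  cfg <- cohort_config(n_trios = 25, n_genes = 6, seed = 5)
  a <- simulate_trio_cohort(cfg, gm, rates)
  b <- simulate_trio_cohort(cfg, gm, rates)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations, b$annotations)
})

test_that("config validation enforces the stated parameter ranges", {
  expect_error(cohort_config(0, 5), class = "cardiotrio_config_error")
  expect_error(cohort_config(5, 5, recessive_carrier_freq = 0.6),
               class = "cardiotrio_config_error")
  expect_error(cohort_config(5, 5, seq_error_rate = 0.5),
               class = "cardiotrio_config_error")
  expect_error(cohort_config(5, 5, dnm_fold_enrichment = -1),
               class = "cardiotrio_config_error")
})

test_that("noise-free planted de novo variants have clean hom-ref parents", {
  fix <- shared_cohort()
  coh <- fix$cohort
  dn_keys <- paste(coh$truth$planted_dnms$trio_id,
                   coh$truth$planted_dnms$variant_key)
  rows <- coh$records[paste(coh$records$trio_id, coh$records$variant_key)
                      %in% dn_keys, ]
  expect_equal(nrow(rows), nrow(coh$truth$planted_dnms))
  expect_true(all(rows$father_gt == "0/0" & rows$mother_gt == "0/0"))
  expect_true(all(rows$father_ad_alt == 0 & rows$mother_ad_alt == 0))
  # conservation: every emitted de novo record has a ground-truth entry
  emitted_dn <- coh$records |>
    dplyr::filter(child_gt != "0/0", father_gt == "0/0", mother_gt == "0/0")
  expect_setequal(paste(emitted_dn$trio_id, emitted_dn$variant_key), dn_keys)
})

test_that("planted de novo counts follow the Poisson null of the rate model", {
  gm <- make_gene_models(30, seed = 3)
  rates <- make_rate_table(seed = 3)
  cfg <- cohort_config(n_trios = 2000, n_genes = 30, seed = 23)
  coh <- simulate_trio_cohort(cfg, gm, rates,
                              truth_spec = list(n_background_per_gene = 0))
  snv_mass <- sum(coh$expectation$protein_altering +
                    coh$expectation$synonymous)
  mean_total <- 2 * cfg$n_trios * snv_mass
  observed <- nrow(coh$truth$planted_dnms)
  expect_lt(abs(observed - mean_total) / sqrt(mean_total), 4)
})

test_that("planted fold enrichment is recovered through the full pipeline", {
  gm <- make_gene_models(40, seed = 19)
  rates <- make_rate_table(seed = 19)
  cfg <- cohort_config(n_trios = 1500, n_genes = 40,
                       dnm_fold_enrichment = 3, seed = 29)
  coh <- simulate_trio_cohort(cfg, gm, rates,
                              truth_spec = list(n_background_per_gene = 0))
  dn <- call_de_novo(coh$records, coh$annotations)
  res <- poisson_burden(dn, coh$expectation, cfg$n_trios,
                        "protein_altering", gene_set = coh$truth$enriched_genes)
  mc_sd <- sqrt(3 / res$expected)
  expect_lt(abs(res$fold - 3), 3 * mc_sd)
  comp <- poisson_burden(dn, coh$expectation, cfg$n_trios, "protein_altering",
                         gene_set = setdiff(coh$expectation$gene_id,
                                            coh$truth$enriched_genes))
  expect_lt(abs(comp$fold - 1), 3 * sqrt(1 / comp$expected))
})

test_that("sequencing noise perturbs read support but not genotypes", {
  gm <- make_gene_models(5, seed = 6)
  rates <- make_rate_table(seed = 6)
  cfg <- cohort_config(n_trios = 30, n_genes = 5, seq_error_rate = 0.01,
                       mean_depth = 40, seed = 9)
  coh <- simulate_trio_cohort(cfg, gm, rates)
  expect_true(any(coh$records$child_dp != 40))
  hom_ref_alt <- coh$records$father_ad_alt[coh$records$father_gt == "0/0"]
  expect_true(mean(hom_ref_alt > 0) < 0.5) # errors are rare, not absent
  expect_true(all(coh$records$child_gq <= 99))
})

test_that("the CNV callset plants de novo, mosaic, and CVR structure as stated", {
  cfg <- cohort_config(n_trios = 10, n_genes = 5, seed = 4)
  cs <- simulate_cnv_callset(cfg)

  # the planted de novo CNVs are absent from the parental set
  dn_truth <- cs$truth[cs$truth$is_de_novo, ]
  for (i in seq_len(nrow(dn_truth))) {
    par_same_trio <- cs$parents[cs$parents$trio_id == dn_truth$trio_id[i], ]
    if (nrow(par_same_trio) == 0) next
    ro <- reciprocal_overlap(dn_truth[i, c("contig", "start", "end")],
                             par_same_trio[1, c("contig", "start", "end")])
    expect_false(ro$highly_overlapping)
  }

  # the mosaic deletion's depth ratio lies strictly between single-copy
  # (0.5) and diploid (1.0) expectations
  mos <- cs$case[cs$case$cnv_id %in% cs$truth$cnv_id[cs$truth$is_mosaic], ]
  expect_true(all(mos$depth_ratio > 0.5 & mos$depth_ratio < 1.0))

  # classification and mosaic flagging recover the planted truth exactly
  dn <- classify_de_novo_cnv(cs$case, cs$parents, cs$gold)
  expect_setequal(dn$cnv_id, cs$truth$cnv_id[cs$truth$is_de_novo])
  dels <- cs$case[cs$case$type == "deletion", ]
  flags <- flag_mosaic(dels)
  expect_setequal(dels$cnv_id[flags], cs$truth$cnv_id[cs$truth$is_mosaic])

  # exactly one reference deletion highly overlaps all deletions at the
  # planted CVR locus (exhaustive pairwise check), and it is returned
  locus_dels <- cs$case[cs$case$start < 20000 & cs$case$type == "deletion", ]
  ref_dels <- cs$reference[cs$reference$type == "deletion", ]
  qualifies <- vapply(seq_len(nrow(ref_dels)), function(j) {
    all(vapply(seq_len(nrow(locus_dels)), function(i) {
      reciprocal_overlap(ref_dels[j, c("contig", "start", "end")],
                         locus_dels[i, c("contig", "start", "end")]
                         )$highly_overlapping
    }, logical(1)))
  }, logical(1))
  expect_equal(sum(qualifies), 1)
  expect_equal(ref_dels$cnv_id[qualifies], cs$cvr_reference_id)
  cvr <- copy_number_variable_region(locus_dels, ref_dels)
  expect_equal(cvr$reference_id[cvr$locus == 1], cs$cvr_reference_id)
})

test_that("expression simulation is deterministic and respects the no-noise limit", {
  cfg <- cohort_config(n_trios = 5, n_genes = 5, seed = 8)
  a <- simulate_expression_modules(cfg)
  b <- simulate_expression_modules(cfg)
  expect_identical(a$expression, b$expression)
  s0 <- simulate_expression_modules(cfg, noise = 0, n_modules = 2,
                                    n_stages = 2)
  expect_true(all(s0$expression >= 0))
  for (m in unique(s0$module_membership$module)) {
    g <- s0$module_membership$gene_id[s0$module_membership$module == m]
    expect_true(all(s0$expression[, g] == s0$expression[, g[1]]))
  }
  expect_error(simulate_expression_modules(cfg, n_stages = 1),
               class = "cardiotrio_config_error")
})
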