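test_that("de novo calls honour parental, frequency and allele-ratio criteria", {
  ann <- make_annotation("c:100:A:T")
  ok <- call_de_novo(make_record(child_ad = c(10, 10)), ann)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$category, "de_novo")

  # alternate allele ratio 0.20 < 25% in a het proband
  low_ratio <- call_de_novo(make_record(child_ad = c(16, 4)), ann)
  expect_equal(nrow(low_ratio), 0)

  # population frequency 2% >= 1%
  common <- call_de_novo(make_record(), make_annotation("c:100:A:T", af = 0.02))
  expect_equal(nrow(common), 0)

  # parent with 2 supporting reads exceeds the default max of 1
  leaky <- call_de_novo(make_record(father_ad = c(18, 2)), ann)
  expect_equal(nrow(leaky), 0)
  leaky_ok <- call_de_novo(make_record(father_ad = c(18, 2)), ann,
                           max_parent_alt = 2)
  expect_equal(nrow(leaky_ok), 1)

  # a missing parental genotype is not evidence of absence
  miss <- make_record(); miss$father_gt <- NA_character_
  expect_equal(nrow(call_de_novo(miss, ann)), 0)
})

test_that("homozygous recessive calls enforce the four genotype criteria", {
  ann <- make_annotation("c:100:A:T")
  hom_rec <- function(child_ad = c(2, 18), father_ad = c(10, 10),
                      mother_ad = c(10, 10)) {
    make_record(child = "1/1", father = "0/1", mother = "0/1",
                child_ad = child_ad, father_ad = father_ad,
                mother_ad = mother_ad)
  }
  ok <- call_recessive(hom_rec(), ann, mode = "strict")
  expect_equal(ok$category, "homozygous_recessive")

  # proband allele ratio 0.60 < 75%
  expect_equal(nrow(call_recessive(hom_rec(child_ad = c(8, 12)), ann,
                                   mode = "strict")), 0)
  # parental allele ratio 0.20 < 25%
  expect_equal(nrow(call_recessive(hom_rec(father_ad = c(16, 4)), ann,
                                   mode = "strict")), 0)
  # strict mode requires MAF < 0.001
  expect_equal(nrow(call_recessive(hom_rec(),
                                   make_annotation("c:100:A:T", af = 0.005),
                                   mode = "strict")), 0)
  # ... which the relaxed CADD>20 rule accepts (MAF < 0.01)
  relaxed <- call_recessive(hom_rec(),
                            make_annotation("c:100:A:T", af = 0.005,
                                            damaging = FALSE, cadd = 25),
                            mode = "relaxed")
  expect_equal(nrow(relaxed), 1)
})

test_that("compound heterozygotes require trans configuration", {
  ann <- dplyr::bind_rows(make_annotation("c:100:A:T"),
                          make_annotation("c:200:G:C"))
  trans <- dplyr::bind_rows(
    make_record(key = "c:100:A:T", father = "0/1", father_ad = c(10, 10)),
    make_record(key = "c:200:G:C", mother = "0/1", mother_ad = c(10, 10))
  )
  pairs <- call_recessive(trans, ann, mode = "strict")
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$category, "compound_het")
  expect_setequal(pairs$partner_key, c("c:100:A:T", "c:200:G:C"))

  # both variants inherited from the father: cis, no pair
  cis <- dplyr::bind_rows(
    make_record(key = "c:100:A:T", father = "0/1", father_ad = c(10, 10)),
    make_record(key = "c:200:G:C", father = "0/1", father_ad = c(10, 10))
  )
  expect_equal(nrow(call_recessive(cis, ann, mode = "strict")), 0)

  # one member failing the damaging rule disqualifies the pair
  ann_benign <- dplyr::bind_rows(
    make_annotation("c:100:A:T"),
    make_annotation("c:200:G:C", damaging = FALSE, cadd = 5))
  expect_equal(nrow(call_recessive(trans, ann_benign, mode = "strict")), 0)
})

test_that("ultra-rare damaging calls apply absence and deleteriousness rules", {
  panel <- "g1"
  stopgain <- make_record(key = "c:100:A:T")
  expect_equal(
    call_ultra_rare_damaging(stopgain,
                             make_annotation("c:100:A:T", consequence = "stopgain"),
                             panel)$category,
    "ultra_rare_damaging")
  # missense needs CADD > 20, strictly
  expect_equal(nrow(call_ultra_rare_damaging(
    stopgain, make_annotation("c:100:A:T", cadd = 19.9), panel)), 0)
  expect_equal(nrow(call_ultra_rare_damaging(
    stopgain, make_annotation("c:100:A:T", cadd = 20), panel)), 0)
  # presence in the internal disease-control set disqualifies
  expect_equal(nrow(call_ultra_rare_damaging(
    stopgain, make_annotation("c:100:A:T", consequence = "stopgain",
                              in_controls = TRUE), panel)), 0)
  # AF of exactly 0 with the presence flag set still counts as present
  expect_equal(nrow(call_ultra_rare_damaging(
    stopgain, make_annotation("c:100:A:T", consequence = "stopgain",
                              present = TRUE), panel)), 0)
  # outside the panel
  expect_equal(nrow(call_ultra_rare_damaging(
    stopgain, make_annotation("c:100:A:T", consequence = "stopgain"),
    "other_gene")), 0)
})

test_that("pseudocontrols are the untransmitted parental alleles", {
  cases <- list(
    list(f = "0/1", m = "0/0", c = "0/1", pseudo = "0/0"),
    list(f = "0/1", m = "0/1", c = "1/1", pseudo = "0/0"),
    list(f = "0/1", m = "0/1", c = "0/0", pseudo = "1/1"),
    list(f = "0/1", m = "0/1", c = "0/1", pseudo = "0/1"), # ambiguous tie-break
    list(f = "1/1", m = "0/0", c = "0/1", pseudo = "0/1"),
    list(f = "1/1", m = "0/1", c = "1/1", pseudo = "0/1")
  )
  for (cs in cases) {
    rec <- make_record(child = cs$c, father = cs$f, mother = cs$m)
    out <- build_pseudocontrols(rec)
    expect_equal(out$pseudo_gt, cs$pseudo,
                 info = paste(cs$f, cs$m, cs$c))
  }
  # Mendelian-inconsistent site skipped with a log entry
  bad <- make_record(child = "1/1", father = "0/0", mother = "0/0")
  out <- suppressMessages(build_pseudocontrols(bad))
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "skipped")), 1)
})

test_that("pseudocontrol allele conservation holds at every consistent site", {
  gts <- c("0/0", "0/1", "1/1")
  cnt <- c(`0/0` = 0, `0/1` = 1, `1/1` = 2)
  for (f in gts) for (m in gts) for (ch in gts) {
    rec <- make_record(child = ch, father = f, mother = m)
    out <- suppressMessages(build_pseudocontrols(rec))
    if (nrow(out) == 1) {
      expect_equal(cnt[[out$pseudo_gt]] + cnt[[ch]], cnt[[f]] + cnt[[m]],
                   info = paste(f, m, ch))
    } else {
      # skipped combinations must be genuinely Mendelian-impossible
      t_lo <- (f == "1/1") + (m == "1/1")
      t_hi <- (f != "0/0") + (m != "0/0")
      expect_true(cnt[[ch]] < t_lo || cnt[[ch]] > t_hi,
                  info = paste(f, m, ch))
    }
  }
})

test_that("the cascade reproduces planted truth on a noise-free cohort", {
  fix <- shared_cohort()
  coh <- fix$cohort
  rec <- apply_site_qc(coh$records, n_trios = fix$cfg$n_trios)

  dn <- call_de_novo(rec, coh$annotations)
  expect_setequal(paste(dn$trio_id, dn$variant_key),
                  paste(coh$truth$planted_dnms$trio_id,
                        coh$truth$planted_dnms$variant_key))

  rcv <- call_recessive(rec, coh$annotations, mode = "strict")
  expect_setequal(
    paste(rcv$trio_id, rcv$variant_key, rcv$category == "compound_het"),
    paste(coh$truth$planted_recessive$trio_id,
          coh$truth$planted_recessive$variant_key,
          coh$truth$planted_recessive$mechanism == "compound_het"))

  ur <- call_ultra_rare_damaging(rec, coh$annotations, coh$truth$panel_genes)
  expect_setequal(paste(ur$trio_id, ur$variant_key),
                  paste(coh$truth$planted_ultra_rare$trio_id,
                        coh$truth$planted_ultra_rare$variant_key))
})
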