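# Inheritance classification of trio variants: de novo, homozygous
# recessive, compound heterozygous, ultra-rare damaging, and
# pseudocontrol construction from untransmitted parental alleles.

LOF_CLASSES <- c("nonsense", "stopgain", "frameshift",
                 "essential_splice", "splicing")

max_pop_af <- function(annotations) {
  af_cols <- intersect(c("af_kg", "af_exac", "af_gnomad"), names(annotations))
  if (length(af_cols) == 0) {
    abort("annotations must carry population frequency columns (af_kg, af_exac, af_gnomad).",
          class = "cardiotrio_input_error")
  }
  do.call(pmax, c(lapply(annotations[af_cols], function(x) tidyr::replace_na(x, 0)),
                  list(na.rm = TRUE)))
}

join_annotations <- function(records, annotations) {
  ann <- annotations |> mutate(max_af = max_pop_af(annotations))
  records |> inner_join(ann, by = "variant_key",
                        suffix = c("", ".ann"), relationship = "many-to-one")
}

alt_ratio <- function(ad_alt, dp) ifelse(dp > 0, ad_alt / dp, NA_real_)

#' Call de novo variants in trios
#'
#' A variant is de novo when (i) the alternate allele is present in the
#' child but both parents are confidently homozygous reference (at most
#' `max_parent_alt` supporting reads each), (ii) its maximum population
#' allele frequency across the annotation databases is below `af_max`
#' (1% by default), and (iii) a heterozygous child carries the alternate
#' allele on at least `min_alt_ratio` (25%) of reads.
#'
#' @param records QC-passed trio genotype tibble.
#' @param annotations Annotation tibble keyed by `variant_key` with
#'   population frequency columns, `consequence`, `cadd`,
#'   `damaging_missense`.
#' @param af_max,min_alt_ratio,max_parent_alt Thresholds as above.
#' @return Classified-variant tibble: `trio_id`, `variant_key`,
#'   `gene_id`, `consequence`, `damaging_missense`, `category`,
#'   `partner_key`.
#' @export
call_de_novo <- function(records, annotations, af_max = 0.01,
                         min_alt_ratio = 0.25, max_parent_alt = 1) {
  join_annotations(records, annotations) |>
    filter(
      child_gt %in% c("0/1", "1/0", "1/1"),
      father_gt %in% "0/0", mother_gt %in% "0/0",
      tidyr::replace_na(father_ad_alt, 0) <= max_parent_alt,
      tidyr::replace_na(mother_ad_alt, 0) <= max_parent_alt,
      max_af < af_max,
      child_gt %in% "1/1" |
        alt_ratio(child_ad_alt, child_dp) >= min_alt_ratio
    ) |>
    transmute(trio_id, variant_key, gene_id, consequence, damaging_missense,
              category = "de_novo", partner_key = NA_character_)
}

recessive_params <- function(mode) {
  switch(match.arg(mode, c("strict", "relaxed")),
    strict = list(af_max = 0.001, damaging = function(d) d$damaging_missense |
                    d$consequence %in% LOF_CLASSES),
    relaxed = list(af_max = 0.01, damaging = function(d) d$cadd > 20 |
                    d$consequence %in% LOF_CLASSES)
  )
}

#' Call recessive genotypes: homozygous and compound heterozygous
#'
#' Homozygous-recessive calls require both parents heterozygous with
#' alternate allele ratio >= 25%, the child homozygous alternate with
#' allele ratio >= 75%, population frequency below the active threshold,
#' and the variant damaging under the active rule. Compound-heterozygous
#' pairs are two distinct qualifying heterozygous child variants in one
#' gene in trans: each heterozygous in exactly one parent, one per
#' parent; both members must pass the damaging rule.
#'
#' The `strict` mode mirrors MAF < 0.001 plus an ensemble
#' damaging-missense call; `relaxed` mirrors MAF < 0.01 plus CADD > 20.
#' Loss-of-function consequences qualify as damaging under either rule.
#'
#' @inheritParams call_de_novo
#' @param mode `"strict"` or `"relaxed"`.
#' @param min_het_ratio,min_hom_ratio Allele-ratio thresholds for
#'   heterozygous carriers and the homozygous proband.
#' @return Classified-variant tibble; compound-het members appear as
#'   paired rows with `partner_key` set.
#' @export
call_recessive <- function(records, annotations, mode = "strict",
                           min_het_ratio = 0.25, min_hom_ratio = 0.75) {
  par <- recessive_params(mode)
  ann <- join_annotations(records, annotations)
  ann$damaging <- par$damaging(ann)

  hom <- ann |>
    filter(
      father_gt %in% c("0/1", "1/0"), mother_gt %in% c("0/1", "1/0"),
      child_gt %in% "1/1",
      alt_ratio(father_ad_alt, father_dp) >= min_het_ratio,
      alt_ratio(mother_ad_alt, mother_dp) >= min_het_ratio,
      alt_ratio(child_ad_alt, child_dp) >= min_hom_ratio,
      max_af < par$af_max, damaging
    ) |>
    transmute(trio_id, variant_key, gene_id, consequence, damaging_missense,
              category = "homozygous_recessive", partner_key = NA_character_)

  members <- ann |>
    filter(
      child_gt %in% c("0/1", "1/0"),
      alt_ratio(child_ad_alt, child_dp) >= min_het_ratio,
      max_af < par$af_max, damaging,
      xor(father_gt %in% c("0/1", "1/0"), mother_gt %in% c("0/1", "1/0")),
      father_gt %in% c("0/0", "0/1", "1/0"),
      mother_gt %in% c("0/0", "0/1", "1/0")
    ) |>
    mutate(
      origin = ifelse(father_gt %in% c("0/1", "1/0"), "father", "mother"),
      het_parent_ratio = ifelse(origin == "father",
                                alt_ratio(father_ad_alt, father_dp),
                                alt_ratio(mother_ad_alt, mother_dp))
    ) |>
    filter(het_parent_ratio >= min_het_ratio)

  side <- function(d, which) {
    d |>
      filter(origin == which) |>
      select(trio_id, gene_id, variant_key, consequence, damaging_missense)
  }
  pairs <- inner_join(
    side(members, "father"), side(members, "mother"),
    by = c("trio_id", "gene_id"), suffix = c("_a", "_b"),
    relationship = "many-to-many")
  comphet <- bind_rows(
    pairs |> transmute(trio_id, variant_key = variant_key_a, gene_id,
                       consequence = consequence_a,
                       damaging_missense = damaging_missense_a,
                       category = "compound_het",
                       partner_key = variant_key_b),
    pairs |> transmute(trio_id, variant_key = variant_key_b, gene_id,
                       consequence = consequence_b,
                       damaging_missense = damaging_missense_b,
                       category = "compound_het",
                       partner_key = variant_key_a)
  ) |>
    distinct()

  bind_rows(hom, comphet) |> arrange(trio_id, gene_id, variant_key)
}

#' Call ultra-rare damaging variants in panel genes
#'
#' Keeps child-carried variants that are (i) absent from every public
#' frequency database (all frequency columns zero and no presence flag),
#' (ii) absent from the internal disease-control cohort, and (iii)
#' loss-of-function (stopgain, frameshift, splicing) or missense with a
#' scaled deleteriousness score above `cadd_min`.
#'
#' @inheritParams call_de_novo
#' @param panel_genes Character vector of genes to restrict to.
#' @param cadd_min Missense score threshold (exclusive).
#' @return Classified-variant tibble with category
#'   `"ultra_rare_damaging"`.
#' @export
call_ultra_rare_damaging <- function(records, annotations, panel_genes,
                                     cadd_min = 20) {
  join_annotations(records, annotations) |>
    filter(
      gene_id %in% panel_genes,
      child_gt %in% c("0/1", "1/0", "1/1"),
      max_af == 0,
      !tidyr::replace_na(present_any_db, FALSE),
      !tidyr::replace_na(in_disease_controls, FALSE),
      consequence %in% LOF_CLASSES |
        (consequence == "missense" & cadd > cadd_min)
    ) |>
    transmute(trio_id, variant_key, gene_id, consequence, damaging_missense,
              category = "ultra_rare_damaging", partner_key = NA_character_)
}

#' Build pseudocontrol genotypes from untransmitted parental alleles
#'
#' For each trio and biallelic site, the pseudocontrol genotype consists
#' of the two parental alleles not transmitted to the child, so its
#' alternate-allele count is `father + mother - child` (in allele
#' counts) at every Mendelian-consistent site. When all three members
#' are heterozygous the transmission is ambiguous but both phasings give
#' the same unordered pseudocontrol genotype (0/1). Inconsistent or
#' partially missing sites are skipped and logged.
#'
#' @param records Trio genotype tibble.
#' @return Tibble `trio_id`, `variant_key`, `pseudo_gt`; skipped rows in
#'   `attr(, "skipped")`.
#' @export
build_pseudocontrols <- function(records) {
  f <- gt_alt_count(records$father_gt)
  m <- gt_alt_count(records$mother_gt)
  c_ <- gt_alt_count(records$child_gt)
  # transmitted alt alleles from a parent with alt count p: 1 if p == 2,
  # 0 or 1 if p == 1, 0 if p == 0
  t_lo <- as.integer(f == 2) + as.integer(m == 2)
  t_hi <- as.integer(f >= 1) + as.integer(m >= 1)
  consistent <- !is.na(f) & !is.na(m) & !is.na(c_) & c_ >= t_lo & c_ <= t_hi
  idx <- f + m - c_ + 1L
  idx[!consistent | is.na(idx)] <- NA_integer_ # avoid 0/negative indexing
  gt_str <- c("0/0", "0/1", "1/1")[idx]
  out <- tibble(
    trio_id = records$trio_id[consistent],
    variant_key = records$variant_key[consistent],
    pseudo_gt = gt_str[consistent]
  )
  skipped <- records[!consistent, c("trio_id", "variant_key")]
  if (nrow(skipped) > 0) {
    inform(sprintf(
      "build_pseudocontrols: skipped %d Mendelian-inconsistent or missing sites.",
      nrow(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}
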