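#' Simulate a trio cohort with planted ground truth
#'
#' Generates per-trio variant records emulating a jointly called trio
#' VCF, together with the exact list of planted events:
#'
#' * De novo SNVs: per gene and variant class, counts are drawn
#'   Poisson(2 * n_trios * p_class(gene) * fold(gene)), where p comes
#'   from the mutational model over the supplied rate table and fold is
#'   `dnm_fold_enrichment` inside the designated enriched gene set and 1
#'   elsewhere. Sites are drawn within a class proportionally to their
#'   baseline rate. Frameshift de novo events are planted as 1-bp
#'   insertions at rate 1.25 x the nonsense rate.
#' * Recessive loci: designated genes where parents are heterozygous
#'   carriers at frequency `recessive_carrier_freq` and children draw
#'   genotypes by Mendelian transmission; homozygous and trans
#'   compound-heterozygous outcomes are recorded as truth. One event of
#'   each mechanism is forced so small cohorts always carry truth.
#' * Ultra-rare damaging variants in a 3-gene panel, inherited from a
#'   single carrier parent, absent from all population databases.
#' * Background polymorphic sites (common, allele frequency 0.05-0.4)
#'   that exercise the frequency filters; records are sparse -- trios in
#'   which no member carries the alternate allele are implicit
#'   homozygous-reference rows.
#'
#' Read support follows DP ~ Poisson(mean_depth), alt depth ~
#' Binomial(DP, f) with f = `seq_error_rate`, 0.5, or 1 by genotype, and
#' GQ = min(99, 3 * DP * (1 - 2|ab - E(ab)|)); with `seq_error_rate = 0`
#' read support collapses to its noise-free expectation.
#'
#' @param config A [cohort_config()].
#' @param gene_models A `gene_models` object.
#' @param rates Trinucleotide rate table; a missing context raises an
#'   input error.
#' @param truth_spec Optional list overriding the planting layout:
#'   `enriched_genes`, `recessive_hom_genes`, `comphet_genes`,
#'   `panel_genes`, `n_background_per_gene` (default 2; 0 gives a pure
#'   de novo cohort).
#' @return A list of class `trio_cohort`: `records` (trio genotype
#'   tibble), `annotations` (variant annotation tibble), `truth`
#'   (planted ground truth), `expectation` (the per-gene expectation
#'   table used for planting), `config`.
#' @export
simulate_trio_cohort <- function(config, gene_models, rates,
                                 truth_spec = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  expectation <- gene_expectation_table(gene_models, rates)
  lookup <- rate_lookup(rates)
  gene_ids <- gene_models$genes$gene_id

  with_seed(config$seed, {
    spec <- truth_spec %||% list()
    n_special <- min(length(gene_ids), 7L)
    pool <- sample(gene_ids)
    enriched <- spec$enriched_genes %||%
      pool[seq_len(max(1L, ceiling(length(gene_ids) / 10)))]
    rest <- setdiff(pool, enriched)
    hom_genes <- spec$recessive_hom_genes %||% head(rest, 2)
    comphet_genes <- spec$comphet_genes %||% head(setdiff(rest, hom_genes), 2)
    panel_genes <- spec$panel_genes %||%
      head(setdiff(rest, c(hom_genes, comphet_genes)), 3)
    n_bg <- spec$n_background_per_gene %||% 2L

    subs <- lapply(setNames(gene_ids, gene_ids), function(g) {
      st <- substitution_table(gene_models, g)
      st$rate <- lookup(st$context, st$alt)
      st$variant_key <- make_variant_key(st$contig, st$pos, st$ref, st$alt)
      st
    })

    reserved <- character() # keys not available to the de novo sampler
    rec_rows <- list(); rec_truth <- list(); ann_rows <- list()

    pick_site <- function(g, exclude_pos = integer()) {
      st <- subs[[g]]
      st <- st[!st$pos %in% exclude_pos, , drop = FALSE]
      st[sample.int(nrow(st), 1L), , drop = FALSE]
    }

    emit_inherited <- function(site, gene, f_cnt, m_cnt, c_cnt, trios) {
      tibble(
        trio_id = trios,
        contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
        variant_key = site$variant_key, gene_id = gene,
        f = f_cnt, m = m_cnt, c = c_cnt
      )
    }

    # --- planted recessive loci -------------------------------------------
    q <- config$recessive_carrier_freq
    n <- config$n_trios
    trio_ids <- sprintf("trio%05d", seq_len(n))
    # parents drawn from Hardy-Weinberg at allele frequency q/2 (carrier
    # frequency ~ q) so planted sites survive the parental HWE filter
    a_freq <- q / 2
    transmit <- function(cnt) {
      ifelse(cnt == 2L, 1L, ifelse(cnt == 1L, rbinom(n, 1L, 0.5), 0L))
    }
    for (g in hom_genes) {
      cand <- subs[[g]][subs[[g]]$class == "missense", , drop = FALSE]
      site <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      reserved <- c(reserved, site$variant_key)
      f_cnt <- rbinom(n, 2L, a_freq); m_cnt <- rbinom(n, 2L, a_freq)
      f_cnt[1] <- 1L; m_cnt[1] <- 1L # force one informative trio
      tf <- transmit(f_cnt); tm <- transmit(m_cnt)
      tf[1] <- 1L; tm[1] <- 1L       # forced homozygous child in trio 1
      keep <- f_cnt + m_cnt > 0
      rec_rows[[length(rec_rows) + 1L]] <-
        emit_inherited(site, g, f_cnt[keep], m_cnt[keep],
                       (tf + tm)[keep], trio_ids[keep])
      hom_trios <- trio_ids[f_cnt == 1 & m_cnt == 1 & tf + tm == 2]
      if (length(hom_trios) > 0) {
        rec_truth[[length(rec_truth) + 1L]] <- tibble(
          trio_id = hom_trios, gene_id = g, mechanism = "homozygous",
          variant_key = site$variant_key, partner_key = NA_character_)
      }
      ann_rows[[length(ann_rows) + 1L]] <- tibble(
        variant_key = site$variant_key, gene_id = g, consequence = "missense",
        af_kg = 2e-4, af_exac = 2e-4, af_gnomad = 2e-4,
        cadd = 28, damaging_missense = TRUE,
        present_any_db = TRUE, in_disease_controls = FALSE)
    }
    for (g in comphet_genes) {
      cand <- subs[[g]][subs[[g]]$class == "missense", , drop = FALSE]
      i2 <- sample.int(nrow(cand), 2L)
      siteA <- cand[i2[1], , drop = FALSE]; siteB <- cand[i2[2], , drop = FALSE]
      reserved <- c(reserved, siteA$variant_key, siteB$variant_key)
      fA <- rbinom(n, 2L, a_freq); mB <- rbinom(n, 2L, a_freq)
      fA[2] <- 1L; mB[2] <- 1L
      tfA <- transmit(fA); tmB <- transmit(mB)
      tfA[2] <- 1L; tmB[2] <- 1L     # forced compound het in trio 2
      keepA <- fA > 0; keepB <- mB > 0
      rec_rows[[length(rec_rows) + 1L]] <-
        emit_inherited(siteA, g, fA[keepA], 0L, tfA[keepA], trio_ids[keepA])
      rec_rows[[length(rec_rows) + 1L]] <-
        emit_inherited(siteB, g, 0L, mB[keepB], tmB[keepB], trio_ids[keepB])
      ch_trios <- trio_ids[fA == 1 & mB == 1 & tfA == 1 & tmB == 1]
      if (length(ch_trios) > 0) {
        rec_truth[[length(rec_truth) + 1L]] <- bind_rows(
          tibble(trio_id = ch_trios, gene_id = g, mechanism = "compound_het",
                 variant_key = siteA$variant_key, partner_key = siteB$variant_key),
          tibble(trio_id = ch_trios, gene_id = g, mechanism = "compound_het",
                 variant_key = siteB$variant_key, partner_key = siteA$variant_key))
      }
      ann_rows[[length(ann_rows) + 1L]] <- tibble(
        variant_key = c(siteA$variant_key, siteB$variant_key), gene_id = g,
        consequence = "missense",
        af_kg = 2e-4, af_exac = 2e-4, af_gnomad = 2e-4,
        cadd = 28, damaging_missense = TRUE,
        present_any_db = TRUE, in_disease_controls = FALSE)
    }

    # --- planted ultra-rare damaging panel variants -----------------------
    ur_truth <- list()
    for (g in panel_genes) {
      cand <- subs[[g]][subs[[g]]$class == "nonsense", , drop = FALSE]
      if (nrow(cand) == 0) cand <- subs[[g]][subs[[g]]$class == "missense", ,
                                             drop = FALSE]
      site <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      reserved <- c(reserved, site$variant_key)
      f_het <- rbinom(n, 1L, 0.02)
      if (g == panel_genes[1]) f_het[3] <- 1L
      tf <- f_het * rbinom(n, 1L, 0.5)
      if (g == panel_genes[1]) tf[3] <- 1L # forced carrier child in trio 3
      keep <- f_het > 0
      rec_rows[[length(rec_rows) + 1L]] <-
        emit_inherited(site, g, f_het[keep], 0L, tf[keep], trio_ids[keep])
      carriers <- trio_ids[tf == 1]
      if (length(carriers) > 0) {
        ur_truth[[length(ur_truth) + 1L]] <- tibble(
          trio_id = carriers, gene_id = g, variant_key = site$variant_key)
      }
      ann_rows[[length(ann_rows) + 1L]] <- tibble(
        variant_key = site$variant_key, gene_id = g,
        consequence = site$class,
        af_kg = 0, af_exac = 0, af_gnomad = 0,
        cadd = ifelse(site$class == "missense", 28, 40),
        damaging_missense = site$class == "missense",
        present_any_db = FALSE, in_disease_controls = FALSE)
    }

    # --- common background polymorphisms ----------------------------------
    if (n_bg > 0) {
      for (g in gene_ids) {
        st <- subs[[g]][!subs[[g]]$variant_key %in% reserved, , drop = FALSE]
        take <- st[sample.int(nrow(st), min(n_bg, nrow(st))), , drop = FALSE]
        for (j in seq_len(nrow(take))) {
          site <- take[j, , drop = FALSE]
          reserved <- c(reserved, site$variant_key)
          af <- runif(1, 0.05, 0.4)
          f_cnt <- rbinom(n, 2L, af); m_cnt <- rbinom(n, 2L, af)
          tf <- ifelse(f_cnt == 2L, 1L, ifelse(f_cnt == 1L, rbinom(n, 1L, 0.5), 0L))
          tm <- ifelse(m_cnt == 2L, 1L, ifelse(m_cnt == 1L, rbinom(n, 1L, 0.5), 0L))
          keep <- f_cnt + m_cnt > 0
          rec_rows[[length(rec_rows) + 1L]] <-
            emit_inherited(site, g, f_cnt[keep], m_cnt[keep],
                           (tf + tm)[keep], trio_ids[keep])
          ann_rows[[length(ann_rows) + 1L]] <- tibble(
            variant_key = site$variant_key, gene_id = g,
            consequence = site$class,
            af_kg = af, af_exac = af, af_gnomad = af,
            cadd = ifelse(site$class %in% c("nonsense", "essential_splice"),
                          35, 5),
            damaging_missense = FALSE,
            present_any_db = TRUE, in_disease_controls = FALSE)
        }
      }
    }

    # --- de novo mutations -------------------------------------------------
    fold <- ifelse(gene_ids %in% enriched, config$dnm_fold_enrichment, 1)
    names(fold) <- gene_ids
    snv_classes <- c("synonymous", "missense", "nonsense",
                     "essential_splice", "start_loss", "stop_loss")
    dnm_rows <- list(); dnm_truth <- list()
    for (g in gene_ids) {
      st <- subs[[g]]
      st_open <- st[!st$variant_key %in% reserved, , drop = FALSE]
      for (cl in snv_classes) {
        st_cl <- st_open[st_open$class == cl, , drop = FALSE]
        mass <- sum(st[st$class == cl, ]$rate)
        if (mass <= 0 || nrow(st_cl) == 0) next
        k <- rpois(1L, 2 * n * mass * fold[[g]])
        if (k == 0) next
        idx <- sample.int(nrow(st_cl), k, replace = TRUE,
                          prob = st_cl$rate)
        ev_trios <- sample(trio_ids, k, replace = TRUE)
        dnm_rows[[length(dnm_rows) + 1L]] <- tibble(
          trio_id = ev_trios,
          contig = st_cl$contig[idx], pos = st_cl$pos[idx],
          ref = st_cl$ref[idx], alt = st_cl$alt[idx],
          variant_key = st_cl$variant_key[idx], gene_id = g,
          class = cl,
          damaging_missense = cl == "missense" &
            default_damaging_predictor(st_cl[idx, , drop = FALSE])
        )
      }
      # frameshift: 1-bp insertions at 1.25 x the nonsense rate
      fs_mean <- 2 * n * 1.25 * sum(st[st$class == "nonsense", ]$rate) * fold[[g]]
      k_fs <- if (fs_mean > 0) rpois(1L, fs_mean) else 0L
      if (k_fs > 0) {
        cds <- st_open[st_open$class != "essential_splice", , drop = FALSE]
        idx <- sample.int(nrow(cds), k_fs, replace = TRUE)
        ins_base <- sample(c("A", "C", "G", "T"), k_fs, replace = TRUE)
        dnm_rows[[length(dnm_rows) + 1L]] <- tibble(
          trio_id = sample(trio_ids, k_fs, replace = TRUE),
          contig = cds$contig[idx], pos = cds$pos[idx],
          ref = cds$ref[idx], alt = paste0(cds$ref[idx], ins_base),
          variant_key = make_variant_key(cds$contig[idx], cds$pos[idx],
                                         cds$ref[idx],
                                         paste0(cds$ref[idx], ins_base)),
          gene_id = g, class = "frameshift", damaging_missense = FALSE
        )
      }
    }
    dnms <- bind_rows(dnm_rows)
    if (nrow(dnms) > 0) {
      # at most one de novo record per (trio, site)
      dnms <- dnms |> distinct(trio_id, variant_key, .keep_all = TRUE)
      dnm_truth <- dnms |>
        select(trio_id, variant_key, class, gene_id)
      ann_rows[[length(ann_rows) + 1L]] <- dnms |>
        distinct(variant_key, .keep_all = TRUE) |>
        transmute(
          variant_key, gene_id, consequence = class,
          af_kg = 0, af_exac = 0, af_gnomad = 0,
          cadd = case_when(
            class %in% c("nonsense", "essential_splice", "frameshift") ~ 40,
            class == "missense" & damaging_missense ~ 28,
            class %in% c("start_loss", "stop_loss") ~ 24,
            class == "missense" ~ 12,
            TRUE ~ 3),
          damaging_missense = tidyr::replace_na(damaging_missense, FALSE),
          present_any_db = FALSE, in_disease_controls = FALSE)
    } else {
      dnm_truth <- tibble(trio_id = character(), variant_key = character(),
                          class = character(), gene_id = character())
    }

    # --- assemble genotype rows -------------------------------------------
    inherited <- bind_rows(rec_rows)
    dnm_gt <- if (nrow(dnms) > 0) {
      dnms |> transmute(trio_id, contig, pos, ref, alt, variant_key, gene_id,
                        f = 0L, m = 0L, c = 1L)
    } else NULL
    all_rows <- bind_rows(inherited, dnm_gt) |>
      distinct(trio_id, variant_key, .keep_all = TRUE)

    gt_str <- c("0/0", "0/1", "1/1")
    records <- all_rows |>
      mutate(qual = 1000, mapq = 60,
             child_gt = gt_str[c + 1L],
             father_gt = gt_str[f + 1L],
             mother_gt = gt_str[m + 1L])
    for (mem in c("child", "father", "mother")) {
      cnt <- switch(mem, child = records$c, father = records$f,
                    mother = records$m)
      rs <- simulate_read_support(cnt, config)
      records[[paste0(mem, "_dp")]] <- rs$dp
      records[[paste0(mem, "_ad_ref")]] <- rs$ad_ref
      records[[paste0(mem, "_ad_alt")]] <- rs$ad_alt
      records[[paste0(mem, "_gq")]] <- rs$gq
    }
    records <- records |>
      select(-f, -m, -c) |>
      arrange(contig, pos, alt, trio_id)

    annotations <- bind_rows(ann_rows) |>
      distinct(variant_key, .keep_all = TRUE)

    # ultra-rare ground truth includes qualifying de novo events that
    # happen to land in panel genes
    dnm_ur <- dnm_truth |>
      filter(gene_id %in% panel_genes) |>
      left_join(annotations |> select(variant_key, cadd), by = "variant_key") |>
      filter(class %in% c("nonsense", "essential_splice", "frameshift") |
               (class == "missense" & cadd > 20)) |>
      select(trio_id, gene_id, variant_key)
    ultra_rare_truth <- bind_rows(bind_rows(ur_truth), dnm_ur) |>
      distinct()

    truth <- list(
      planted_dnms = dnm_truth,
      planted_recessive = bind_rows(rec_truth),
      planted_ultra_rare = ultra_rare_truth,
      enriched_genes = enriched,
      panel_genes = panel_genes,
      recessive_hom_genes = hom_genes,
      comphet_genes = comphet_genes
    )

    structure(
      list(records = records, annotations = annotations, truth = truth,
           expectation = expectation, config = config),
      class = "trio_cohort"
    )
  })
}

# DP, allele depths and GQ for a vector of alt-allele counts (0/1/2).
# GQ is min(99, 3 * DP * (1 - 2|ab - E(ab)|)): a deterministic monotone
# function of depth and allele balance so the GQ >= 20 mask is
# exercisable.
simulate_read_support <- function(alt_count, config) {
  n <- length(alt_count)
  f_exp <- c(config$seq_error_rate, 0.5, 1)[alt_count + 1L]
  if (config$seq_error_rate == 0) {
    dp <- rep(config$mean_depth, n)
    ad_alt <- as.integer(round(dp * f_exp))
  } else {
    dp <- pmax(rpois(n, config$mean_depth), 1L)
    ad_alt <- rbinom(n, dp, f_exp)
  }
  ab <- ad_alt / dp
  gq <- pmin(99L, as.integer(round(3 * dp * pmax(0, 1 - 2 * abs(ab - f_exp)))))
  list(dp = as.integer(dp), ad_ref = as.integer(dp - ad_alt),
       ad_alt = as.integer(ad_alt), gq = gq)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(
    "<trio_cohort> %d trios, %d genotype rows, %d planted DNMs, %d recessive, %d ultra-rare\n",
    x$config$n_trios, nrow(x$records), nrow(x$truth$planted_dnms),
    nrow(x$truth$planted_recessive), nrow(x$truth$planted_ultra_rare)))
  invisible(x)
}
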