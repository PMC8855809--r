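# Hand-built fixtures and independent oracles shared across test files.

# A minimal gene_models object built by hand (no generator involved):
# one plus-strand single-exon gene, CDS = ATG GCT TAA, flanked by TT pads.
toy_gene_models <- function() {
  cds <- "ATGGCTTAA"
  structure(
    list(
      genes = tibble::tibble(gene_id = "toy1", contig = "ctgT",
                             strand = "+", start = 3L, end = 11L, n_tx = 1L),
      exons = tibble::tibble(gene_id = "toy1", tx_id = "toy1.t1",
                             contig = "ctgT", strand = "+",
                             start = 3L, end = 11L, exon_rank = 1L),
      contig_seq = c(ctgT = paste0("TT", cds, "TT"))
    ),
    class = "gene_models"
  )
}

# uniform rate table: every context-substitution pair at rate r
uniform_rate_table <- function(r = 1e-6) {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = bases, ref = c("A", "C"), p3 = bases, alt = bases,
                   stringsAsFactors = FALSE)
  g <- g[g$alt != g$ref, ]
  tibble::tibble(context = paste0(g$p5, g$ref, g$p3), alt = g$alt,
                 methyl_level = "none", rate = r)
}

no_damaging <- function(subs) rep(FALSE, nrow(subs))

# ---- independent consequence oracle -----------------------------------

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# classify one substitution against one transcript by rebuilding and
# translating the whole coding sequence with Biostrings
oracle_tx_classify <- function(contig_seq, exons_tx, pos, alt) {
  ex <- exons_tx[order(exons_tx$start), ]
  strand <- ex$strand[1]
  k <- nrow(ex)
  splice <- integer()
  if (k >= 2) {
    splice <- c(unlist(lapply(seq_len(k - 1), function(i) ex$end[i] + 1:2)),
                unlist(lapply(2:k, function(i) ex$start[i] - 2:1)))
  }
  if (pos %in% splice) return("essential_splice")
  covered <- any(pos >= ex$start & pos <= ex$end)
  if (!covered) return(NA_character_)
  build_cds <- function(seq_chr) {
    chunks <- vapply(seq_len(k), function(i)
      substring(seq_chr, ex$start[i], ex$end[i]), character(1))
    s <- paste(chunks, collapse = "")
    if (strand == "-") s <- oracle_revcomp(s)
    s
  }
  seq_ref <- contig_seq
  seq_alt <- contig_seq
  substr(seq_alt, pos, pos) <- alt
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(build_cds(seq_ref)), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(build_cds(seq_alt)), no.init.codon = TRUE))
  diff_at <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  n_aa <- nchar(aa_ref)
  # locate the codon index of the substitution
  cds_pos <- unlist(lapply(seq_len(k), function(i) ex$start[i]:ex$end[i]))
  if (strand == "-") cds_pos <- rev(cds_pos)
  idx <- match(pos, cds_pos)
  codon_idx <- (idx - 1) %/% 3 + 1
  if (codon_idx == 1) return("start_loss")
  if (codon_idx == n_aa) {
    if (length(diff_at) == 0) return("synonymous") else return("stop_loss")
  }
  if (length(diff_at) == 0) return("synonymous")
  if (substring(aa_alt, codon_idx, codon_idx) == "*") return("nonsense")
  "missense"
}

oracle_severity <- c(nonsense = 1, essential_splice = 2, start_loss = 3,
                     stop_loss = 4, missense = 5, synonymous = 6)

# most damaging class across transcripts, oracle route
oracle_classify <- function(gene_models, gene_id, pos, alt) {
  ex_all <- gene_models$exons[gene_models$exons$gene_id == gene_id, ]
  seq_chr <- gene_models$contig_seq[[ex_all$contig[1]]]
  cls <- vapply(split(ex_all, ex_all$tx_id), function(ex)
    oracle_tx_classify(seq_chr, ex, pos, alt), character(1))
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) return(NA_character_)
  names(sort(oracle_severity[cls]))[1]
}

# independent rate lookup straight off the rate-table tibble
oracle_rate <- function(rates, context, alt, methyl = "high") {
  hit <- rates[rates$context == context & rates$alt == alt, ]
  rc <- rates[rates$context == oracle_revcomp(context) &
                rates$alt == chartr("ACGT", "TGCA", alt), ]
  rows <- rbind(hit, rc)
  lv <- if (any(rows$methyl_level != "none")) methyl else "none"
  rows <- rows[rows$methyl_level == lv, ]
  mean(rows$rate)
}

# brute-force per-gene class probabilities: enumerate every site and alt
oracle_gene_expectation <- function(gene_models, gene_id, rates,
                                    damaging_predictor = no_damaging,
                                    masked_pos = integer()) {
  ex_all <- gene_models$exons[gene_models$exons$gene_id == gene_id, ]
  seq_chr <- gene_models$contig_seq[[ex_all$contig[1]]]
  pos_all <- sort(unique(unlist(lapply(split(ex_all, ex_all$tx_id),
    function(ex) {
      ex <- ex[order(ex$start), ]
      k <- nrow(ex)
      cds <- unlist(lapply(seq_len(k), function(i) ex$start[i]:ex$end[i]))
      spl <- integer()
      if (k >= 2) {
        spl <- c(unlist(lapply(seq_len(k - 1), function(i) ex$end[i] + 1:2)),
                 unlist(lapply(2:k, function(i) ex$start[i] - 2:1)))
      }
      c(cds, spl)
    }))))
  pos_all <- setdiff(pos_all, masked_pos)
  out <- setNames(numeric(8),
                  c("synonymous", "missense", "damaging_missense", "nonsense",
                    "essential_splice", "frameshift", "start_loss", "stop_loss"))
  for (p in pos_all) {
    ref <- substring(seq_chr, p, p)
    ctx <- substring(seq_chr, p - 1, p + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cls <- oracle_classify(gene_models, gene_id, p, alt)
      if (is.na(cls)) next
      r <- oracle_rate(rates, ctx, alt)
      out[cls] <- out[cls] + r
      if (cls == "missense" &&
          damaging_predictor(tibble::tibble(pos = p, alt = alt))) {
        out["damaging_missense"] <- out["damaging_missense"] + r
      }
    }
  }
  out["frameshift"] <- 1.25 * out["nonsense"]
  out
}

# ---- trio record constructor ------------------------------------------

make_record <- function(trio_id = "t1", key = "c:100:A:T", gene = "g1",
                        child = "0/1", father = "0/0", mother = "0/0",
                        child_ad = c(10, 10), father_ad = c(20, 0),
                        mother_ad = c(20, 0), gq = 99, qual = 1000,
                        mapq = 60) {
  parts <- strsplit(key, ":")[[1]]
  tibble::tibble(
    trio_id = trio_id, contig = parts[1], pos = as.integer(parts[2]),
    ref = parts[3], alt = parts[4], variant_key = key, gene_id = gene,
    qual = qual, mapq = mapq,
    child_gt = child, child_ad_ref = child_ad[1], child_ad_alt = child_ad[2],
    child_dp = sum(child_ad), child_gq = gq,
    father_gt = father, father_ad_ref = father_ad[1],
    father_ad_alt = father_ad[2], father_dp = sum(father_ad), father_gq = gq,
    mother_gt = mother, mother_ad_ref = mother_ad[1],
    mother_ad_alt = mother_ad[2], mother_dp = sum(mother_ad), mother_gq = gq
  )
}

make_annotation <- function(key, gene = "g1", consequence = "missense",
                            af = 0, cadd = 25, damaging = TRUE,
                            present = FALSE, in_controls = FALSE) {
  tibble::tibble(
    variant_key = key, gene_id = gene, consequence = consequence,
    af_kg = af, af_exac = af, af_gnomad = af, cadd = cadd,
    damaging_missense = damaging, present_any_db = present,
    in_disease_controls = in_controls
  )
}

# shared small simulated cohort (built once per test run)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gm <- make_gene_models(12, seed = 7)
      rates <- make_rate_table(seed = 2)
      cfg <- cohort_config(n_trios = 60, n_genes = 12, seed = 11)
      cache <<- list(gm = gm, rates = rates, cfg = cfg,
                     cohort = simulate_trio_cohort(cfg, gm, rates))
    }
    cache
  }
})

# case/control toy tables shared by unit and acceptance tests
toy_samples <- function(n_cases = 146, n_controls = 590) {
  tibble::tibble(
    sample_id = c(sprintf("case%03d", seq_len(n_cases)),
                  sprintf("ctrl%03d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls))
  )
}

# 7 qualifying case variants in 6 individuals (one carries two), and
# 13 control variants in 12 individuals (one carries two)
toy_panel_variants <- function() {
  dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("case%03d", 1:6),
                   gene_id = c("KDR", "KDR", "FLT4", "NOTCH1",
                               "NOTCH1", "NOTCH1"),
                   variant_key = paste0("v", 1:6)),
    tibble::tibble(sample_id = "case001", gene_id = "FLT4",
                   variant_key = "v7"),
    tibble::tibble(sample_id = sprintf("ctrl%03d", c(1:12, 1)),
                   gene_id = c(rep("NOTCH1", 9), "KDR", "KDR", "FLT4", "KDR"),
                   variant_key = paste0("w", 1:13))
  )
}

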