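VARIANT_CLASSES <- c("synonymous", "missense", "damaging_missense",
                     "nonsense", "essential_splice", "frameshift",
                     "start_loss", "stop_loss")

# severity used when transcripts disagree (most damaging wins)
SEVERITY_ORDER <- c("nonsense", "essential_splice", "start_loss",
                    "stop_loss", "missense", "synonymous")

#' Coding consequence of a single-nucleotide substitution
#'
#' Classifies a substitution against every transcript of a gene and
#' returns the most damaging annotation across transcripts, using the
#' severity order nonsense > essential splice > start loss > stop loss >
#' missense > synonymous. Essential splice sites are the two intronic
#' bases flanking each internal coding-exon junction.
#'
#' @param gene_models A `gene_models` object.
#' @param gene_id Gene identifier.
#' @param pos 1-based genomic position on the gene's contig.
#' @param alt Alternate base (reference strand).
#' @return A single class string.
#' @export
classify_consequence <- function(gene_models, gene_id, pos, alt) {
  tab <- substitution_table(gene_models, gene_id)
  hit <- tab[tab$pos == pos & tab$alt == alt, ]
  if (nrow(hit) == 0) {
    if (!pos %in% tab$pos) {
      abort(sprintf("position %d is outside the coding/splice span of %s.",
                    pos, gene_id),
            class = "cardiotrio_range_error")
    }
    abort(sprintf("alt '%s' equals the reference base at %d.", alt, pos),
          class = "cardiotrio_input_error")
  }
  hit$class[1]
}

# classify one transcript's CDS substitutions in coding space
classify_tx_cds <- function(coding_seq, cds_index, alt_coding) {
  n_codons <- nchar(coding_seq) / 3L
  codon_idx <- (cds_index - 1L) %/% 3L + 1L
  within <- (cds_index - 1L) %% 3L + 1L
  codon_start <- (codon_idx - 1L) * 3L + 1L
  old_codon <- substring(coding_seq, codon_start, codon_start + 2L)
  new_codon <- old_codon
  substr(new_codon, within, within) <- alt_coding
  gc <- Biostrings::GENETIC_CODE
  old_aa <- unname(gc[old_codon])
  new_aa <- unname(gc[new_codon])
  dplyr::case_when(
    codon_idx == 1L ~ "start_loss",
    codon_idx == n_codons & new_aa == "*" ~ "synonymous",
    codon_idx == n_codons ~ "stop_loss",
    new_aa == "*" ~ "nonsense",
    new_aa == old_aa ~ "synonymous",
    TRUE ~ "missense"
  )
}

#' Enumerate all single-nucleotide substitutions of a gene
#'
#' Lists every (site, alternate base) pair in the union of the gene's
#' transcript CDS and essential splice positions, with the most damaging
#' consequence across transcripts and the reference-strand trinucleotide
#' context. This enumeration is the basis of the per-gene expectation
#' model and of de novo variant planting in the simulator.
#'
#' @inheritParams classify_consequence
#' @return Tibble: `contig`, `pos`, `ref`, `alt`, `context`, `class`.
#' @export
substitution_table <- function(gene_models, gene_id) {
  ex_all <- gene_models$exons[gene_models$exons$gene_id == gene_id, ]
  if (nrow(ex_all) == 0) {
    abort(sprintf("unknown gene '%s'.", gene_id),
          class = "cardiotrio_input_error")
  }
  contig <- ex_all$contig[1]
  strand <- ex_all$strand[1]
  seq_ctg <- gene_models$contig_seq[[contig]]
  bases <- c("A", "C", "G", "T")

  per_tx <- lapply(split(ex_all, ex_all$tx_id), function(ex) {
    pos_map <- tx_cds_positions(ex)
    genome_ref <- substring(seq_ctg, pos_map, pos_map)
    coding_ref <- if (strand == "+") genome_ref else unname(comp_base(genome_ref))
    coding_seq <- paste(coding_ref, collapse = "")
    idx <- rep(seq_along(pos_map), each = 3L)
    galt <- unlist(lapply(genome_ref, function(r) setdiff(bases, r)),
                   use.names = FALSE)
    calt <- if (strand == "+") galt else unname(comp_base(galt))
    cds <- tibble(
      pos = pos_map[idx], ref = genome_ref[idx], alt = galt,
      class = classify_tx_cds(coding_seq, idx, calt)
    )
    spl_pos <- tx_splice_positions(ex)
    spl_ref <- if (length(spl_pos) == 0) character() else
      substring(seq_ctg, spl_pos, spl_pos)
    sidx <- rep(seq_along(spl_pos), each = 3L)
    spl <- tibble(
      pos = spl_pos[sidx], ref = spl_ref[sidx],
      alt = unlist(lapply(spl_ref, function(r) setdiff(bases, r)),
                   use.names = FALSE),
      class = "essential_splice"
    )
    bind_rows(cds, spl)
  })

  bind_rows(per_tx) |>
    mutate(severity = match(class, SEVERITY_ORDER)) |>
    group_by(pos, ref, alt) |>
    summarise(class = SEVERITY_ORDER[min(severity)], .groups = "drop") |>
    mutate(contig = contig,
           context = substring(seq_ctg, pos - 1L, pos + 1L)) |>
    select(contig, pos, ref, alt, context, class) |>
    arrange(pos, alt)
}

#' Default damaging-missense predictor
#'
#' A deterministic stand-in for an ensemble missense deleteriousness
#' classifier: a fixed pseudo-random but reproducible function of the
#' site and alternate base, flagging roughly 40% of missense
#' substitutions as damaging. Supply a real predictor (a function of a
#' substitution tibble returning a logical vector) for real data.
#'
#' @param subs Tibble with columns `pos` and `alt`.
#' @return Logical vector.
#' @export
default_damaging_predictor <- function(subs) {
  (subs$pos * 7L + match(subs$alt, c("A", "C", "G", "T")) * 3L) %% 5L < 2L
}

#' Per-gene expected de novo mutation probabilities by variant class
#'
#' For every gene, sums the context-specific baseline substitution rate
#' over all unmasked coding and essential-splice sites and all three
#' alternate bases, grouped by coding consequence. The frameshift class
#' is then set to 1.25 x the nonsense probability. Sites flagged by the
#' coverage mask (intended for positions where more than 10% of samples
#' have fewer than 8 reads) contribute zero; no other read-depth
#' adjustment is applied. Aggregate columns: `lof` = nonsense +
#' essential splice + frameshift, and `protein_altering` = everything
#' except synonymous (damaging missense is a subset of missense and is
#' not double counted).
#'
#' @param gene_models A `gene_models` object.
#' @param rates Rate-table tibble (see [make_rate_table()]).
#' @param coverage_mask Optional tibble of low-coverage sites with
#'   columns `contig`, `pos`.
#' @param damaging_predictor Function mapping a substitution tibble to a
#'   logical damaging flag for missense rows; defaults to
#'   [default_damaging_predictor()].
#' @param methyl_level Methylation level used for CpG contexts when no
#'   methylation track is supplied.
#' @return Tibble, one row per gene, with one probability column per
#'   variant class plus `lof` and `protein_altering`.
#' @export
gene_expectation_table <- function(gene_models, rates,
                                   coverage_mask = NULL,
                                   damaging_predictor = default_damaging_predictor,
                                   methyl_level = "high") {
  lookup <- rate_lookup(rates)
  masked <- if (is.null(coverage_mask)) character() else {
    paste(coverage_mask$contig, coverage_mask$pos)
  }
  rows <- lapply(gene_models$genes$gene_id, function(g) {
    subs <- substitution_table(gene_models, g)
    subs <- subs[!(paste(subs$contig, subs$pos) %in% masked), , drop = FALSE]
    out <- setNames(numeric(length(VARIANT_CLASSES)), VARIANT_CLASSES)
    if (nrow(subs) > 0) {
      subs$rate <- lookup(subs$context, subs$alt, methyl_level)
      by_class <- tapply(subs$rate, subs$class, sum)
      out[names(by_class)] <- by_class
      is_mis <- subs$class == "missense"
      if (any(is_mis)) {
        dmg <- damaging_predictor(subs[is_mis, , drop = FALSE])
        out["damaging_missense"] <- sum(subs$rate[is_mis][dmg])
      }
    }
    out["frameshift"] <- 1.25 * out["nonsense"]
    tibble(gene_id = g, !!!as.list(out))
  })
  bind_rows(rows) |>
    mutate(
      lof = nonsense + essential_splice + frameshift,
      protein_altering = missense + nonsense + essential_splice +
        frameshift + start_loss + stop_loss
    )
}

#' @rdname gene_expectation_table
#' @param expectation Expectation tibble as returned above.
#' @param path TSV path; written long (gene, class, probability).
#' @export
write_expectation_table <- function(expectation, path) {
  expectation |>
    tidyr::pivot_longer(-gene_id, names_to = "class",
                        values_to = "probability") |>
    readr::write_tsv(path)
  invisible(expectation)
}

#' @rdname gene_expectation_table
#' @export
read_expectation_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "probability")
}
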