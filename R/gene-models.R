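#' Generate a toy genome with gene models
#'
#' Builds a small synthetic genome of non-overlapping protein-coding genes
#' for exercising the mutation model and trio simulator. Each gene carries
#' 1--3 transcripts of 1--10 coding exons on a randomly assigned strand.
#' Exon lengths are multiples of 3 so that every transcript (including
#' exon-skipping isoforms) stays in frame; the coding sequence starts with
#' ATG, ends with a stop codon, and contains no internal stop in any
#' isoform. Introns carry canonical GT..AG splice dinucleotides.
#'
#' @param n_genes Number of genes to generate (>= 1).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param genes_per_contig Genes placed per synthetic contig.
#' @return An object of class `gene_models`: a list with
#'   * `genes`: tibble of per-gene spans (`gene_id`, `contig`, `strand`,
#'     `start`, `end`, `n_tx`), 1-based inclusive coordinates,
#'   * `exons`: tibble of per-transcript coding exons (`gene_id`, `tx_id`,
#'     `contig`, `strand`, `start`, `end`, `exon_rank`), rank in
#'     transcription order,
#'   * `contig_seq`: named character vector of contig sequences.
#' @export
make_gene_models <- function(n_genes, seed = 1, genes_per_contig = 10) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || is.na(n_genes) ||
      n_genes < 1) {
    abort("`n_genes` must be a single integer >= 1.", class = "cardiotrio_config_error")
  }
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                            c("TAA", "TAG", "TGA"))
    stop_codons <- c("TAA", "TAG", "TGA")
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

    exon_rows <- vector("list", n_genes)
    gene_rows <- vector("list", n_genes)
    contig_parts <- list()
    cur_contig <- 0L
    cursor <- 0L
    contig_seqs <- character()

    flush_contig <- function() {
      if (cur_contig > 0L) {
        contig_seqs[[paste0("chrS", cur_contig)]] <<-
          paste(unlist(contig_parts), collapse = "")
      }
    }

    for (g in seq_len(n_genes)) {
      if ((g - 1L) %% genes_per_contig == 0L) {
        flush_contig()
        cur_contig <- cur_contig + 1L
        contig_parts <- list(rand_seq(80L))
        cursor <- 80L
      }
      contig <- paste0("chrS", cur_contig)
      gene_id <- sprintf("gene%04d", g)
      strand <- sample(c("+", "-"), 1L)
      n_exons <- sample.int(10L, 1L)
      codons_per_exon <- sample(3:20, n_exons, replace = TRUE)
      n_codons <- sum(codons_per_exon)
      codons <- c("ATG",
                  sample(sense_codons, n_codons - 2L, replace = TRUE),
                  sample(stop_codons, 1L))
      mrna <- paste(codons, collapse = "")
      # split mRNA into transcription-order exon chunks
      ends <- cumsum(codons_per_exon) * 3L
      starts <- c(1L, head(ends, -1L) + 1L)
      chunks <- substring(mrna, starts, ends)
      # genome order: plus strand keeps transcription order; minus strand
      # lays exons down reverse-complemented right-to-left
      if (strand == "+") {
        genome_chunks <- chunks
        ranks <- seq_len(n_exons)
      } else {
        genome_chunks <- rev(vapply(chunks, revcomp_chr, character(1)))
        ranks <- rev(seq_len(n_exons))
      }
      ex_start <- integer(n_exons)
      ex_end <- integer(n_exons)
      for (j in seq_len(n_exons)) {
        if (j > 1L) {
          ilen <- sample(40:120, 1L)
          intron <- rand_seq(ilen)
          if (strand == "+") {
            substr(intron, 1L, 2L) <- "GT"
            substr(intron, ilen - 1L, ilen) <- "AG"
          } else {
            substr(intron, 1L, 2L) <- "CT"
            substr(intron, ilen - 1L, ilen) <- "AC"
          }
          contig_parts[[length(contig_parts) + 1L]] <- intron
          cursor <- cursor + ilen
        }
        ex_start[j] <- cursor + 1L
        ex_end[j] <- cursor + nchar(genome_chunks[j])
        contig_parts[[length(contig_parts) + 1L]] <- genome_chunks[j]
        cursor <- cursor + nchar(genome_chunks[j])
      }

      # transcripts: tx1 has all exons; extra isoforms skip internal exons
      n_tx <- if (n_exons >= 3L) sample.int(3L, 1L) else 1L
      tx_list <- list(seq_len(n_exons))
      if (n_tx > 1L) {
        internal <- 2:(n_exons - 1L)
        for (t in 2:n_tx) {
          drop_n <- sample.int(length(internal), 1L)
          dropped <- sample(internal, drop_n)
          tx_list[[t]] <- setdiff(seq_len(n_exons), dropped)
        }
        tx_list <- unique(tx_list)
        n_tx <- length(tx_list)
      }

      ex <- purrr::imap_dfr(tx_list, function(keep_ranks, t) {
        idx <- which(ranks %in% keep_ranks)
        tibble(
          gene_id = gene_id,
          tx_id = sprintf("%s.t%d", gene_id, t),
          contig = contig, strand = strand,
          start = ex_start[idx], end = ex_end[idx],
          exon_rank = match(ranks[idx], sort(keep_ranks))
        )
      })
      exon_rows[[g]] <- ex
      gene_rows[[g]] <- tibble(
        gene_id = gene_id, contig = contig, strand = strand,
        start = min(ex_start), end = max(ex_end), n_tx = n_tx
      )
      contig_parts[[length(contig_parts) + 1L]] <- rand_seq(sample(100:250, 1L))
      cursor <- nchar(paste(unlist(contig_parts), collapse = ""))
    }
    flush_contig()

    structure(
      list(
        genes = bind_rows(gene_rows),
        exons = bind_rows(exon_rows),
        contig_seq = contig_seqs
      ),
      class = "gene_models"
    )
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes, %d transcripts on %d contigs (%s bp)\n",
    nrow(x$genes), length(unique(x$exons$tx_id)), length(x$contig_seq),
    format(sum(nchar(x$contig_seq)), big.mark = ",")
  ))
  invisible(x)
}

# reverse complement for a plain character scalar
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

# genome positions of a transcript's CDS in translation order
tx_cds_positions <- function(exons_tx) {
  ex <- exons_tx[order(exons_tx$exon_rank), ]
  unlist(purrr::pmap(list(ex$start, ex$end, ex$strand), function(s, e, st) {
    if (st == "+") s:e else e:s
  }), use.names = FALSE)
}

# essential splice positions (2 intronic bases each side of each internal
# junction) for one transcript, in genome coordinates
tx_splice_positions <- function(exons_tx) {
  ex <- exons_tx[order(exons_tx$start), ]
  k <- nrow(ex)
  if (k < 2L) return(integer())
  donor <- unlist(lapply(seq_len(k - 1L), function(i) ex$end[i] + 1:2))
  accept <- unlist(lapply(2:k, function(i) ex$start[i] - 2:1))
  sort(unique(c(donor, accept)))
}

contig_base <- function(gene_models, contig, pos) {
  substring(gene_models$contig_seq[[contig]], pos, pos)
}

#' Trinucleotide context at a position (reference strand)
#' @keywords internal
site_context <- function(gene_models, contig, pos) {
  substring(gene_models$contig_seq[[contig]], pos - 1L, pos + 1L)
}

#' Write / read gene models as TSV
#'
#' The on-disk form is the exon table plus a sequence table, both plain TSV.
#' @param gene_models A `gene_models` object.
#' @param dir Directory to write `exons.tsv` and `contigs.tsv` into.
#' @export
write_gene_models <- function(gene_models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(gene_models$exons, file.path(dir, "exons.tsv"))
  readr::write_tsv(
    tibble(contig = names(gene_models$contig_seq),
           sequence = unname(gene_models$contig_seq)),
    file.path(dir, "contigs.tsv")
  )
  invisible(gene_models)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(dir) {
  exons <- readr::read_tsv(
    file.path(dir, "exons.tsv"), show_col_types = FALSE,
    col_types = readr::cols(start = "i", end = "i", exon_rank = "i",
                            .default = "c"))
  ctg <- readr::read_tsv(file.path(dir, "contigs.tsv"), show_col_types = FALSE)
  genes <- exons |>
    group_by(gene_id, contig, strand) |>
    summarise(start = min(start), end = max(end),
              n_tx = dplyr::n_distinct(tx_id), .groups = "drop")
  structure(
    list(genes = genes, exons = exons,
         contig_seq = setNames(ctg$sequence, ctg$contig)),
    class = "gene_models"
  )
}
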