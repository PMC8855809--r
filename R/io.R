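# VCF 4.2 and TSV interchange. Trio records are sparse: a (trio, site)
# row absent from the table is an implicit clean homozygous-reference
# call, written as plain 0/0 genotypes.

#' Write trio genotype records as VCF 4.2
#'
#' One joint multi-sample VCF with three columns per trio
#' (`<trio>_child`, `<trio>_father`, `<trio>_mother`), FORMAT
#' `GT:AD:DP:GQ`. Trios with no emitted row at a site are written as
#' homozygous reference with missing read-support subfields.
#'
#' @param records Trio genotype tibble.
#' @param path Output path (plain text).
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @export
write_trio_vcf <- function(records, path, contig_lengths = NULL) {
  trios <- sort(unique(records$trio_id))
  samples <- as.vector(t(outer(trios, c("_child", "_father", "_mother"),
                               paste0)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cardiotrio",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))

  fmt_member <- function(d, mem) {
    gt <- d[[paste0(mem, "_gt")]]
    gt[is.na(gt)] <- "./."
    sprintf("%s:%s,%s:%s:%s", gt,
            d[[paste0(mem, "_ad_ref")]], d[[paste0(mem, "_ad_alt")]],
            d[[paste0(mem, "_dp")]], d[[paste0(mem, "_gq")]])
  }

  sites <- records |>
    distinct(contig, pos, ref, alt, variant_key, gene_id, qual, mapq) |>
    arrange(contig, pos, alt)
  by_site <- split(records, records$variant_key)
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    d <- by_site[[s$variant_key]]
    cells <- setNames(rep("0/0:.,.:.:.", length(samples)), samples)
    for (mem in c("child", "father", "mother")) {
      cells[paste0(d$trio_id, "_", mem)] <- fmt_member(d, mem)
    }
    paste(c(s$contig, s$pos, s$variant_key, s$ref, s$alt,
            format(s$qual, trim = TRUE), "PASS",
            sprintf("GENE=%s;MQ=%s", s$gene_id, format(s$mapq, trim = TRUE)),
            "GT:AD:DP:GQ", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a trio VCF back into sparse trio records
#'
#' Parses a VCF written by [write_trio_vcf()] (or any VCF with
#' `<trio>_child/_father/_mother` sample naming and GT:AD:DP:GQ
#' genotypes) via the vcfR package, keeping only (trio, site) rows in
#' which some member carries an alternate allele or a missing genotype.
#'
#' @param path VCF path.
#' @return Trio genotype tibble.
#' @export
read_trio_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0(key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  samples <- colnames(gt)
  trios <- unique(sub("_(child|father|mother)$", "", samples))

  base <- tibble(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_key = make_variant_key(fix$CHROM, as.integer(fix$POS),
                                   fix$REF, fix$ALT),
    gene_id = info_field(fix$INFO, "GENE"),
    qual = as.numeric(fix$QUAL),
    mapq = as.numeric(info_field(fix$INFO, "MQ"))
  )

  per_trio <- lapply(trios, function(tr) {
    out <- base
    out$trio_id <- tr
    for (mem in c("child", "father", "mother")) {
      s <- paste0(tr, "_", mem)
      g <- gt[, s]
      g[g %in% c("./.", ".")] <- NA_character_
      adr <- suppressWarnings(
        as.integer(vapply(strsplit(ad[, s], ","), `[`, character(1), 1)))
      ada <- suppressWarnings(
        as.integer(vapply(strsplit(ad[, s], ","), function(x)
          if (length(x) >= 2) x[2] else NA_character_, character(1))))
      out[[paste0(mem, "_gt")]] <- unname(g)
      out[[paste0(mem, "_ad_ref")]] <- adr
      out[[paste0(mem, "_ad_alt")]] <- ada
      out[[paste0(mem, "_dp")]] <- as.integer(dp[, s])
      out[[paste0(mem, "_gq")]] <- as.integer(gq[, s])
    }
    keep <- is.na(out$child_gt) | is.na(out$father_gt) | is.na(out$mother_gt) |
      out$child_gt != "0/0" | out$father_gt != "0/0" | out$mother_gt != "0/0"
    out[keep, , drop = FALSE]
  })
  bind_rows(per_trio) |> arrange(contig, pos, alt, trio_id)
}

#' Read / write classified variants as TSV
#' @param classified Classified-variant tibble.
#' @param path File path.
#' @export
write_classified_variants <- function(classified, path) {
  readr::write_tsv(classified, path)
  invisible(classified)
}

#' @rdname write_classified_variants
#' @export
read_classified_variants <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(partner_key = "c",
                                          damaging_missense = "l",
                                          .default = readr::col_guess()))
}

#' Read a two-column gene-set TSV (set id, gene id)
#' @param path File path (columns `set_id`, `gene_id`, no header
#'   required).
#' @return Named list of gene-id vectors.
#' @export
read_gene_sets <- function(path) {
  d <- readr::read_tsv(path, col_names = c("set_id", "gene_id"),
                       show_col_types = FALSE)
  if (identical(unlist(d[1, ], use.names = FALSE),
                c("set_id", "gene_id"))) d <- d[-1, ]
  split(d$gene_id, d$set_id)
}
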