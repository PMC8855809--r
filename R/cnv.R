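# CNV interval algebra. Coordinates are 0-based half-open throughout
# (BED dialect); conversion from 1-based VCF-style coordinates happens
# at the I/O boundary.

check_cnv <- function(cnvs, arg = "cnvs") {
  req <- c("contig", "start", "end")
  if (!all(req %in% names(cnvs))) {
    abort(sprintf("`%s` needs columns contig, start, end.", arg),
          class = "cardiotrio_input_error")
  }
  if (any(cnvs$end <= cnvs$start)) {
    abort(sprintf("`%s` has degenerate intervals (end <= start).", arg),
          class = "cardiotrio_input_error")
  }
  invisible(cnvs)
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Reciprocal overlap of two CNV intervals
#'
#' Returns the overlap as a fraction of each interval's own length; the
#' pair is "highly overlapping" when both fractions strictly exceed 50%
#' (a boundary of exactly one half fails).
#'
#' @param a,b One-row tibbles (or lists) with `contig`, `start`, `end`,
#'   0-based half-open.
#' @return One-row tibble: `fraction_a`, `fraction_b`,
#'   `highly_overlapping`.
#' @export
reciprocal_overlap <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  check_cnv(a, "a"); check_cnv(b, "b")
  ov <- if (a$contig != b$contig) 0 else
    overlap_len(a$start, a$end, b$start, b$end)
  fa <- ov / (a$end - a$start)
  fb <- ov / (b$end - b$start)
  tibble(fraction_a = fa, fraction_b = fb,
         highly_overlapping = fa > 0.5 & fb > 0.5)
}

# vectorized: for each row of x, does any row of y (same contig, and same
# type when both carry one) highly overlap it (>50% reciprocal)?
any_high_overlap <- function(x, y, match_type = TRUE) {
  vapply(seq_len(nrow(x)), function(i) {
    cand <- y[y$contig == x$contig[i], , drop = FALSE]
    if (match_type && "type" %in% names(x) && "type" %in% names(y)) {
      cand <- cand[cand$type == x$type[i], , drop = FALSE]
    }
    if (nrow(cand) == 0) return(FALSE)
    ov <- overlap_len(x$start[i], x$end[i], cand$start, cand$end)
    any(ov / (x$end[i] - x$start[i]) > 0.5 &
          ov / (cand$end - cand$start) > 0.5)
  }, logical(1))
}

#' Classify de novo CNVs in probands
#'
#' A child CNV is de novo when no same-type parental CNV of the same
#' trio highly overlaps it (>50% reciprocal overlap -- breakpoint jitter
#' makes exact-coordinate matching inappropriate) and no gold-standard
#' population CNV highly overlaps it.
#'
#' @param child_cnvs,parent_cnvs CNV tibbles with `contig`, `start`,
#'   `end`, `type`, `sample_id`, `trio_id`.
#' @param gold_standard_cnvs CNV tibble of common population variants.
#' @return The de novo subset of `child_cnvs`.
#' @export
classify_de_novo_cnv <- function(child_cnvs, parent_cnvs, gold_standard_cnvs) {
  check_cnv(child_cnvs, "child_cnvs")
  if (nrow(parent_cnvs) > 0) check_cnv(parent_cnvs, "parent_cnvs")
  if (nrow(gold_standard_cnvs) > 0) check_cnv(gold_standard_cnvs, "gold_standard_cnvs")
  inherited <- vapply(seq_len(nrow(child_cnvs)), function(i) {
    par_i <- parent_cnvs[parent_cnvs$trio_id == child_cnvs$trio_id[i], ,
                         drop = FALSE]
    any_high_overlap(child_cnvs[i, , drop = FALSE], par_i)
  }, logical(1))
  in_gold <- any_high_overlap(child_cnvs, gold_standard_cnvs,
                              match_type = FALSE)
  child_cnvs[!inherited & !in_gold, , drop = FALSE]
}

# connected components of deletions under any-overlap, per contig
cnv_loci <- function(dels) {
  dels$locus <- NA_integer_
  nxt <- 0L
  for (ctg in unique(dels$contig)) {
    idx <- which(dels$contig == ctg)
    d <- dels[idx, ]
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir)
    comp <- IRanges::findOverlaps(ir, red, select = "first")
    dels$locus[idx] <- nxt + as.integer(comp)
    nxt <- nxt + length(red)
  }
  dels
}

#' Copy-number variable region from a reference deletion catalogue
#'
#' For each locus (connected component of cohort deletions under any
#' overlap), finds the reference deletions having more than 50%
#' reciprocal overlap with every cohort deletion at that locus and
#' returns the shortest (ties broken by leftmost start). Loci with no
#' qualifying reference deletion yield no row; the reasons are attached
#' as an attribute.
#'
#' @param cohort_deletions,reference_deletions Deletion tibbles
#'   (`contig`, `start`, `end`, plus an id column `cnv_id` if
#'   available).
#' @return Tibble of regions: `region`, `locus`, `contig`, `start`,
#'   `end`, `reference_id`, `n_supporting`.
#' @export
copy_number_variable_region <- function(cohort_deletions, reference_deletions) {
  check_cnv(cohort_deletions, "cohort_deletions")
  if (nrow(reference_deletions) == 0) {
    abort("reference deletion set is empty.", class = "cardiotrio_input_error")
  }
  check_cnv(reference_deletions, "reference_deletions")
  ref <- reference_deletions
  if (!"cnv_id" %in% names(ref)) ref$cnv_id <- paste0("ref", seq_len(nrow(ref)))
  dels <- cnv_loci(cohort_deletions)
  out <- list(); misses <- character()
  for (loc in sort(unique(dels$locus))) {
    d <- dels[dels$locus == loc, ]
    cand <- ref[ref$contig == d$contig[1], , drop = FALSE]
    ok <- vapply(seq_len(nrow(cand)), function(j) {
      ov <- overlap_len(cand$start[j], cand$end[j], d$start, d$end)
      all(ov / (cand$end[j] - cand$start[j]) > 0.5 &
            ov / (d$end - d$start) > 0.5)
    }, logical(1))
    if (!any(ok)) {
      misses <- c(misses, sprintf(
        "locus %d (%s:%d-%d): no reference deletion with >50%% reciprocal overlap with all %d cohort deletions",
        loc, d$contig[1], min(d$start), max(d$end), nrow(d)))
      next
    }
    q <- cand[ok, , drop = FALSE]
    q <- q[order(q$end - q$start, q$start), , drop = FALSE]
    out[[length(out) + 1L]] <- tibble(
      region = "copy_number_variable_region", locus = loc,
      contig = q$contig[1], start = q$start[1], end = q$end[1],
      reference_id = q$cnv_id[1], n_supporting = nrow(d)
    )
  }
  res <- bind_rows(out)
  attr(res, "unresolved") <- misses
  res
}

#' Minimal critical region of same-type CNVs
#'
#' The interval intersection of all input CNVs; candidate genes for the
#' phenotype are sought inside it. All CNVs must share one type and one
#' contig, and the intersection must be non-empty.
#'
#' @param cnvs_same_type CNV tibble (`contig`, `start`, `end`, `type`).
#' @return One-row tibble: `region`, `contig`, `start`, `end`,
#'   `n_supporting`.
#' @export
minimal_critical_region <- function(cnvs_same_type) {
  check_cnv(cnvs_same_type, "cnvs_same_type")
  if ("type" %in% names(cnvs_same_type) &&
      length(unique(cnvs_same_type$type)) > 1) {
    abort("minimal critical region requires a single CNV type.",
          class = "cardiotrio_input_error")
  }
  if (length(unique(cnvs_same_type$contig)) > 1) {
    abort("minimal critical region requires a single contig.",
          class = "cardiotrio_input_error")
  }
  s <- max(cnvs_same_type$start)
  e <- min(cnvs_same_type$end)
  if (e <= s) {
    abort("the CNVs have an empty common intersection; no critical region exists.",
          class = "cardiotrio_no_region_error")
  }
  tibble(region = "minimal_critical_region",
         contig = cnvs_same_type$contig[1], start = s, end = e,
         n_supporting = nrow(cnvs_same_type))
}

#' Flag mosaic deletions from depth and allelic ratios
#'
#' A constitutive heterozygous deletion halves read depth (ratio ~0.5)
#' and drives spanned heterozygous-SNP allelic ratios to 0 or 1; a
#' diploid region has ratio ~1 and balanced SNPs. A deletion present in
#' only a fraction of cells sits between the two: it is flagged mosaic
#' when its depth ratio lies inside `(depth_lo, depth_hi)` and, when SNP
#' allelic ratios are supplied, their mean deviation from 1/2 lies
#' strictly between `dev_min` and `dev_max` (i.e. shifted but not to the
#' full-deletion extreme). The margins are configurable conventions, not
#' estimates.
#'
#' @param cnv CNV tibble with `type`, `depth_ratio`, and optionally a
#'   list-column `het_allelic_ratios`.
#' @param depth_lo,depth_hi Mosaic window for the depth ratio.
#' @param dev_min,dev_max Mosaic window for the mean |ratio - 1/2| of
#'   spanned heterozygous SNPs.
#' @return Logical vector, one flag per row.
#' @export
flag_mosaic <- function(cnv, depth_lo = 0.6, depth_hi = 0.9,
                        dev_min = 0.05, dev_max = 0.45) {
  if (any(cnv$type != "deletion")) {
    abort("mosaic flagging is defined for deletions only.",
          class = "cardiotrio_input_error")
  }
  depth_ok <- cnv$depth_ratio >= depth_lo & cnv$depth_ratio <= depth_hi
  if (!"het_allelic_ratios" %in% names(cnv)) return(depth_ok)
  ratio_ok <- vapply(seq_len(nrow(cnv)), function(i) {
    r <- cnv$het_allelic_ratios[[i]]
    if (is.null(r) || length(r) == 0) return(TRUE)
    dev <- mean(abs(r - 0.5))
    dev > dev_min & dev < dev_max
  }, logical(1))
  depth_ok & ratio_ok
}

#' Annotate CNVs against gene models
#'
#' Flags each CNV as genic (overlapping any gene span) and exonic
#' (overlapping any coding exon), lists the genes hit, and emits the
#' validation-window flag used for confirmatory PCR design (exonic, and
#' size strictly between 250 bp and 1 Mb).
#'
#' @param cnvs CNV tibble, 0-based half-open.
#' @param gene_models A `gene_models` object (1-based inclusive
#'   coordinates; converted internally).
#' @return `cnvs` with added `genic`, `exonic`, `genes` (list-column),
#'   `validation_candidate`.
#' @export
intersect_exons <- function(cnvs, gene_models) {
  check_cnv(cnvs, "cnvs")
  genes <- gene_models$genes
  exons <- gene_models$exons
  res <- purrr::map_dfr(seq_len(nrow(cnvs)), function(i) {
    s1 <- cnvs$start[i] + 1L; e1 <- cnvs$end[i] # to 1-based inclusive
    g <- genes[genes$contig == cnvs$contig[i] &
                 genes$start <= e1 & genes$end >= s1, , drop = FALSE]
    ex <- exons[exons$contig == cnvs$contig[i] &
                  exons$start <= e1 & exons$end >= s1, , drop = FALSE]
    tibble(genic = nrow(g) > 0, exonic = nrow(ex) > 0,
           genes = list(sort(unique(g$gene_id))))
  })
  size <- cnvs$end - cnvs$start
  bind_cols(cnvs, res) |>
    mutate(validation_candidate = exonic & size > 250 & size < 1e6)
}

#' Read / write CNV call sets as BED-like TSV
#'
#' Columns: contig, start, end (0-based half-open), type, sample_id and
#' any further columns present.
#' @param cnvs CNV tibble.
#' @param path File path.
#' @export
write_cnv_bed <- function(cnvs, path) {
  drop <- intersect("het_allelic_ratios", names(cnvs))
  readr::write_tsv(cnvs[setdiff(names(cnvs), drop)], path)
  invisible(cnvs)
}

#' @rdname write_cnv_bed
#' @export
read_cnv_bed <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
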