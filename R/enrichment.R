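#' Hypergeometric enrichment of a target set in a module
#'
#' Upper-tail hypergeometric test of the overlap between a coexpression
#' module and a target gene set inside a stated universe: with universe
#' size N, K target genes, module size n and overlap k, p = P(X >= k)
#' for X ~ Hypergeometric(N, K, n) (equivalently 1 - CDF(k - 1)), with
#' expected successes n*K/N and fold enrichment k/expected. Genes
#' outside the universe are logged and clipped before counting.
#'
#' @param module_genes Character vector of module members.
#' @param target_set Character vector of target genes.
#' @param universe Character vector, the background gene universe.
#' @param module_id,target_id Labels for the output row.
#' @return One-row `enrichment_result` tibble: `module`, `target_set`,
#'   `N`, `K`, `n`, `k`, `expected`, `fold`, `p_value`.
#' @export
hypergeometric_enrichment <- function(module_genes, target_set, universe,
                                      module_id = "module",
                                      target_id = "target") {
  if (length(universe) == 0) {
    abort("`universe` must be non-empty.", class = "cardiotrio_input_error")
  }
  universe <- unique(universe)
  clip <- function(x, nm) {
    out <- setdiff(x, universe)
    if (length(out) > 0) {
      inform(sprintf("hypergeometric_enrichment: clipping %d %s genes outside the universe.",
                     length(out), nm))
    }
    unique(intersect(x, universe))
  }
  mod <- clip(module_genes, "module")
  tgt <- clip(target_set, "target")
  N <- length(universe); K <- length(tgt); n <- length(mod)
  k <- length(intersect(mod, tgt))
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  res <- tibble(
    module = module_id, target_set = target_id,
    N = N, K = K, n = n, k = k,
    expected = expected,
    fold = ifelse(expected > 0, k / expected, NA_real_),
    p_value = p
  )
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment (a thin wrapper over
#' [stats::p.adjust()] with input validation); output order matches
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values, each >= its p-value.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].", class = "cardiotrio_input_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Enrichment of several target sets across all modules
#'
#' Applies [hypergeometric_enrichment()] to every (module, target set)
#' pair and adds BH q-values within each target set.
#'
#' @param module_membership Tibble with columns `gene_id`, `module`.
#' @param target_sets Named list of character vectors.
#' @param universe Background gene universe.
#' @return `enrichment_result` tibble with a `q_value` column.
#' @export
module_enrichment_table <- function(module_membership, target_sets, universe) {
  mods <- split(module_membership$gene_id, module_membership$module)
  res <- purrr::imap_dfr(target_sets, function(tgt, tname) {
    purrr::imap_dfr(mods, function(genes, mname) {
      hypergeometric_enrichment(genes, tgt, universe,
                                module_id = mname, target_id = tname)
    })
  })
  res <- res |>
    group_by(target_set) |>
    mutate(q_value = bh_fdr(p_value)) |>
    ungroup()
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(unclass(x))

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_tests = nrow(x), min_p = min(x$p_value),
         n_significant_q10 = if ("q_value" %in% names(x))
           sum(x$q_value < 0.1) else NA_integer_)
}

#' Aggregate coexpression-module scores per differentiation stage
#'
#' Library-size normalizes each cell (to 10,000 counts), log1p
#' transforms, z-scores each gene across cells, then averages over the
#' module's genes and over each stage's cells, giving one aggregate
#' score per module per stage.
#'
#' @param expression Numeric matrix, cells in rows and genes in
#'   columns (column names are gene ids).
#' @param module_membership Tibble with `gene_id`, `module`; genes
#'   absent from the matrix are logged and dropped.
#' @param stage_labels Character/factor vector, one stage per cell (row).
#' @return Tibble: `module`, `stage`, `score`, `n_genes`.
#' @export
aggregate_module_scores <- function(expression, module_membership,
                                    stage_labels) {
  if (length(stage_labels) != nrow(expression)) {
    abort("`stage_labels` must have one label per cell (matrix row).",
          class = "cardiotrio_input_error")
  }
  stages <- unique(as.character(stage_labels))
  counts <- table(factor(stage_labels, levels = stages))
  if (any(counts == 0)) {
    abort("every stage must have at least one cell.",
          class = "cardiotrio_input_error")
  }
  missing_genes <- setdiff(unique(module_membership$gene_id),
                           colnames(expression))
  if (length(missing_genes) > 0) {
    inform(sprintf("aggregate_module_scores: dropping %d module genes absent from the matrix.",
                   length(missing_genes)))
    module_membership <- module_membership |>
      filter(!gene_id %in% missing_genes)
  }
  lib <- rowSums(expression)
  lib[lib == 0] <- 1
  norm <- log1p(expression / lib * 1e4)
  mu <- colMeans(norm)
  sd_ <- apply(norm, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(norm, 2, mu, "-"), 2, sd_, "/")

  purrr::map_dfr(split(module_membership$gene_id, module_membership$module),
                 .id = "module", function(genes) {
    gz <- z[, genes, drop = FALSE]
    cell_score <- rowMeans(gz)
    tibble(stage = stages,
           score = vapply(stages, function(s)
             mean(cell_score[as.character(stage_labels) == s]), numeric(1),
             USE.NAMES = FALSE),
           n_genes = length(genes))
  })
}
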