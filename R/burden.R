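#' Poisson burden test for de novo mutations
#'
#' Compares the observed number of de novo mutations of a variant class
#' against the expectation under the per-gene mutational model: with
#' `n_trios` trios, the expected count for a gene set S is
#' `E = 2 * n_trios * sum over S of p_class(g)` (the factor 2 converts a
#' per-chromosome per-generation probability to a diploid genome), and
#' the one-sided enrichment p-value is the upper Poisson tail
#' `P(X >= O)` with mean E.
#'
#' Class aggregates: `"lof"` pools nonsense, essential splice, and
#' frameshift; `"damaging"` pools LoF and damaging missense;
#' `"protein_altering"` pools everything except synonymous. In-frame and
#' stop-gain-adjacent indel classes with no rate-model mass (e.g.
#' `inframe`) still count toward the observed protein-altering total, so
#' those aggregates are slightly anti-conservative by construction and
#' reported as such.
#'
#' @param dnms Classified de novo variant tibble (needs `gene_id`,
#'   `consequence`, `damaging_missense`).
#' @param expectation Per-gene expectation tibble from
#'   [gene_expectation_table()].
#' @param n_trios Number of trios observed.
#' @param variant_class One of the single classes or an aggregate
#'   (`"lof"`, `"damaging"`, `"protein_altering"`, `"all"`).
#' @param gene_set Optional character vector restricting the test to a
#'   gene set; `NULL` tests all genes in the expectation table.
#' @return One-row `burden_result` tibble: `variant_class`, `gene_set`,
#'   `n_genes`, `observed`, `expected`, `fold`, `p_value`, `n_trios`.
#' @export
poisson_burden <- function(dnms, expectation, n_trios,
                           variant_class = "protein_altering",
                           gene_set = NULL) {
  if (!is.numeric(n_trios) || n_trios <= 0) {
    abort("`n_trios` must be a positive count.", class = "cardiotrio_input_error")
  }
  set_label <- if (is.null(gene_set)) "all" else
    attr(gene_set, "label") %||% "gene_set"
  genes <- if (is.null(gene_set)) expectation$gene_id else
    intersect(gene_set, expectation$gene_id)

  unknown <- setdiff(unique(dnms$gene_id), expectation$gene_id)
  if (length(unknown) > 0) {
    inform(sprintf("poisson_burden: dropping %d DNMs in genes absent from the expectation table.",
                   sum(dnms$gene_id %in% unknown)))
    dnms <- dnms |> filter(!gene_id %in% unknown)
  }

  obs_classes <- observed_class_set(variant_class)
  in_set <- dnms |> filter(gene_id %in% genes)
  observed <- sum(
    in_set$consequence %in% obs_classes$classes |
      (obs_classes$include_damaging_missense &
         in_set$consequence == "missense" &
         tidyr::replace_na(in_set$damaging_missense, FALSE))
  )
  expected <- 2 * n_trios * expectation_mass(expectation, genes, variant_class)

  p <- if (observed == 0) 1 else ppois(observed - 1, expected, lower.tail = FALSE)
  res <- tibble(
    variant_class = variant_class, gene_set = set_label,
    n_genes = length(genes), observed = as.integer(observed),
    expected = expected,
    fold = ifelse(expected > 0, observed / expected, NA_real_),
    p_value = p, n_trios = n_trios
  )
  class(res) <- c("burden_result", class(res))
  res
}

# observed consequence labels counted for a class request
observed_class_set <- function(variant_class) {
  syn_map <- list(
    nonsense = c("nonsense", "stopgain"),
    essential_splice = c("essential_splice", "splicing"),
    frameshift = "frameshift",
    missense = "missense",
    synonymous = "synonymous",
    start_loss = "start_loss",
    stop_loss = "stop_loss",
    inframe = "inframe"
  )
  agg <- switch(variant_class,
    lof = c("nonsense", "essential_splice", "frameshift"),
    damaging = c("nonsense", "essential_splice", "frameshift"),
    protein_altering = c("nonsense", "essential_splice", "frameshift",
                         "missense", "start_loss", "stop_loss", "inframe"),
    all = names(syn_map),
    damaging_missense = character(),
    variant_class
  )
  if (!all(agg %in% names(syn_map))) {
    abort(sprintf("unknown variant class '%s'.", variant_class),
          class = "cardiotrio_input_error")
  }
  list(
    classes = unlist(syn_map[agg], use.names = FALSE),
    include_damaging_missense =
      variant_class %in% c("damaging", "damaging_missense")
  )
}

expectation_mass <- function(expectation, genes, variant_class) {
  e <- expectation |> filter(gene_id %in% genes)
  col_sum <- function(cols) sum(unlist(e[intersect(cols, names(e))]))
  switch(variant_class,
    lof = col_sum("lof"),
    damaging = col_sum(c("lof", "damaging_missense")),
    protein_altering = col_sum("protein_altering"),
    all = col_sum(c("protein_altering", "synonymous")),
    inframe = 0,
    col_sum(variant_class)
  )
}

#' Burden of de novo mutations within a target gene list
#'
#' Identical machinery to [poisson_burden()] restricted to a target list
#' (for example a known disease-gene panel or a differential-expression
#' hit list), additionally reporting the list's share of genome-wide
#' expectation as a diagnostic.
#'
#' @inheritParams poisson_burden
#' @param target_gene_list Non-empty character vector; genes outside the
#'   expectation universe are logged and ignored.
#' @return One-row `burden_result` tibble with an extra
#'   `expectation_share` column.
#' @export
geneset_overlap_burden <- function(dnms, target_gene_list, expectation,
                                   n_trios, variant_class = "lof") {
  if (length(target_gene_list) == 0) {
    abort("`target_gene_list` must be non-empty.",
          class = "cardiotrio_input_error")
  }
  outside <- setdiff(target_gene_list, expectation$gene_id)
  if (length(outside) > 0) {
    inform(sprintf("geneset_overlap_burden: %d target genes outside the expectation universe.",
                   length(outside)))
  }
  res <- poisson_burden(dnms, expectation, n_trios, variant_class,
                        gene_set = target_gene_list)
  total <- expectation_mass(expectation, expectation$gene_id, variant_class)
  res$expectation_share <- if (total > 0) res$expected / (2 * n_trios * total)
    else NA_real_
  res
}

#' @export
print.burden_result <- function(x, ...) {
  y <- x
  class(y) <- setdiff(class(y), "burden_result")
  cat(sprintf("De novo burden: %s in %s\n", x$variant_class[1], x$gene_set[1]))
  print(y, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy burden_result
#' @export
tidy.burden_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance burden_result
#' @export
glance.burden_result <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected, fold = x$fold,
         p_value = x$p_value, n_trios = x$n_trios)
}
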