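#' Simulate stage-structured coexpression modules
#'
#' Generates a cells x genes count matrix in which each module's genes
#' share a stage-specific mean profile (baseline expression with one
#' elevated peak stage, cycling over stages), observed through Poisson
#' sampling with a lognormal gene-level noise term. At `noise = 0` the
#' matrix equals the mean profiles exactly, so all genes of a module
#' have identical columns.
#'
#' @param config A [cohort_config()] (supplies the default seed).
#' @param seed Optional seed override.
#' @param n_stages Number of differentiation stages (>= 2).
#' @param n_modules Number of coexpression modules (>= 2).
#' @param genes_per_module Genes per module.
#' @param cells_per_stage Cells per stage.
#' @param baseline,peak Mean expression off-peak and at the module's
#'   peak stage.
#' @param noise Lognormal noise SD; 0 disables sampling entirely.
#' @param gene_ids Optional gene-id vector to draw module genes from
#'   (defaults to synthetic ids).
#' @return List of class `expression_sim`: `expression` (cells x genes
#'   matrix), `stage_labels`, `module_membership` (tibble `gene_id`,
#'   `module`), `peak_stage` (named vector module -> stage).
#' @export
simulate_expression_modules <- function(config, seed = NULL,
                                        n_stages = 4, n_modules = 6,
                                        genes_per_module = 15,
                                        cells_per_stage = 40,
                                        baseline = 2, peak = 16,
                                        noise = 0.3, gene_ids = NULL) {
  if (n_stages < 2 || n_modules < 2) {
    abort("need at least 2 stages and 2 modules.",
          class = "cardiotrio_config_error")
  }
  seed <- seed %||% config$seed
  with_seed(seed, {
    n_genes <- n_modules * genes_per_module
    gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(n_genes))
    if (length(gene_ids) < n_genes) {
      abort("not enough gene ids for the requested modules.",
            class = "cardiotrio_config_error")
    }
    gene_ids <- gene_ids[seq_len(n_genes)]
    modules <- paste0("M", seq_len(n_modules))
    membership <- tibble(
      gene_id = gene_ids,
      module = rep(modules, each = genes_per_module)
    )
    stages <- paste0("stage", seq_len(n_stages))
    stage_labels <- rep(stages, each = cells_per_stage)
    n_cells <- length(stage_labels)
    peak_stage <- setNames(stages[((seq_len(n_modules) - 1L) %% n_stages) + 1L],
                           modules)

    mean_mat <- matrix(baseline, nrow = n_cells, ncol = n_genes,
                       dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                       gene_ids))
    for (m in modules) {
      g <- membership$gene_id[membership$module == m]
      mean_mat[stage_labels == peak_stage[[m]], g] <- peak
    }
    expression <- if (noise == 0) {
      mean_mat
    } else {
      lam <- mean_mat * exp(matrix(rnorm(n_cells * n_genes, 0, noise),
                                   n_cells, n_genes))
      matrix(rpois(n_cells * n_genes, lam), n_cells, n_genes,
             dimnames = dimnames(mean_mat))
    }
    structure(
      list(expression = expression, stage_labels = stage_labels,
           module_membership = membership, peak_stage = peak_stage),
      class = "expression_sim"
    )
  })
}
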