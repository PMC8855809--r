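#' Simulate CNV call sets with planted truth
#'
#' Emits a deterministic constructed scenario on one synthetic contig
#' exercising every branch of the CNV region logic:
#'
#' * a cluster of three de novo cohort deletions at one locus, with a
#'   reference catalogue in which exactly one deletion (the shortest)
#'   has >50% reciprocal overlap with all of them (the planted
#'   copy-number variable region), one reference deletion too long to
#'   qualify and one too short;
#' * an isolated de novo deletion with no parental or population match;
#' * an inherited deletion (~95% reciprocal overlap with a parental
#'   call, emulating breakpoint jitter);
#' * a deletion highly overlapping a gold-standard population CNV;
#' * a mosaic deletion with depth ratio 0.75 and shifted heterozygous
#'   SNP allelic ratios (a ~50% cell fraction), while constitutive
#'   deletions carry depth ratio ~0.5 and loss-of-heterozygosity
#'   ratios;
#' * a de novo duplication plus a reference duplication whose
#'   intersection is a minimal critical region.
#'
#' @param config A [cohort_config()] (supplies the seed; interval
#'   layout is fixed by construction).
#' @param seed Optional seed override.
#' @return List of class `cnv_callset`: `case`, `parents`, `reference`,
#'   `gold`, and `truth` (tibble of planted case CNVs with
#'   `is_de_novo`, `is_mosaic`).
#' @export
simulate_cnv_callset <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  with_seed(seed, {
    ctg <- "chrC1"
    loh <- function() {
      k <- sample(3:6, 1)
      ifelse(rbinom(k, 1, 0.5) == 1, runif(k, 0.95, 0.99), runif(k, 0.01, 0.05))
    }
    mosaic_ratios <- runif(4, 0.32, 0.38)

    case <- tibble(
      cnv_id = paste0("case", 1:7),
      contig = ctg,
      start = c(10000L, 10500L, 9500L, 30000L, 40000L, 50000L, 60000L),
      end   = c(18000L, 18500L, 17500L, 30800L, 42000L, 51000L, 70000L),
      type = "deletion",
      trio_id = sprintf("trio%05d", c(1, 2, 3, 1, 2, 3, 4)),
      depth_ratio = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.75),
      het_allelic_ratios = c(replicate(6, loh(), simplify = FALSE),
                             list(mosaic_ratios))
    ) |>
      bind_rows(tibble(
        cnv_id = "case8", contig = ctg, start = 80000L, end = 90000L,
        type = "duplication", trio_id = "trio00005",
        depth_ratio = 1.5, het_allelic_ratios = list(numeric())
      )) |>
      mutate(sample_id = paste0(trio_id, "_child"), cohort = "case-child")

    parents <- tibble(
      cnv_id = "par1", contig = ctg, start = 40100L, end = 42100L,
      type = "deletion", trio_id = "trio00002",
      sample_id = "trio00002_father", cohort = "case-parent",
      depth_ratio = 0.5
    )

    gold <- tibble(
      cnv_id = "gold1", contig = ctg, start = 50050L, end = 51050L,
      type = "deletion"
    )

    reference <- tibble(
      cnv_id = c("refA", "refB", "refC", "refDup"),
      contig = ctg,
      start = c(2000L, 9800L, 11000L, 84000L),
      end   = c(19000L, 17800L, 14000L, 95000L),
      type = c("deletion", "deletion", "deletion", "duplication")
    )

    truth <- case |>
      select(cnv_id, sample_id, trio_id, contig, start, end, type) |>
      mutate(
        is_de_novo = !cnv_id %in% c("case5", "case6"),
        is_mosaic = cnv_id == "case7"
      )

    structure(
      list(case = case, parents = parents, reference = reference,
           gold = gold, truth = truth, cvr_reference_id = "refB"),
      class = "cnv_callset"
    )
  })
}
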