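#' Synthetic trinucleotide baseline mutation-rate table
#'
#' Generates a complete per-chromosome per-generation substitution rate
#' table keyed by trinucleotide context (5' base, reference base, 3' base)
#' and alternate base, with methylation-level entries for CpG contexts.
#' Rates are drawn lognormally around `mean_rate`, with transitions
#' elevated ~4x and methylated CpG C>T transitions elevated a further
#' ~12x, mirroring the qualitative shape of human germline rate tables.
#'
#' The default `mean_rate` of 1e-6 per site per generation is deliberately
#' higher than the human genome-wide average: the companion toy genome is
#' several thousand times smaller than the exome, and this scaling keeps
#' the per-trio number of coding de novo mutations in a realistic range
#' (on the order of 0.1--1 per trio).
#'
#' @param seed Integer seed.
#' @param mean_rate Geometric-mean substitution rate per site.
#' @return Tibble with columns `context`, `alt`, `methyl_level`
#'   (`"none"` for non-CpG rows; `"low"`/`"high"` for CpG rows), `rate`.
#'   Contexts are given with reference base A or C; the loader
#'   strand-symmetrizes so G/T-reference contexts resolve via reverse
#'   complement.
#' @export
make_rate_table <- function(seed = 1, mean_rate = 1e-6) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    grid <- expand.grid(p5 = bases, ref = c("A", "C"), p3 = bases,
                        alt = bases, stringsAsFactors = FALSE) |>
      as_tibble() |>
      filter(alt != ref) |>
      mutate(context = paste0(p5, ref, p3))
    is_transition <- with(grid, (ref == "A" & alt == "G") |
                                 (ref == "C" & alt == "T"))
    is_cpg <- with(grid, ref == "C" & p3 == "G")
    base_rate <- mean_rate * exp(rnorm(nrow(grid), 0, 0.5)) *
      ifelse(is_transition, 4, 1)
    non_cpg <- grid |>
      filter(!is_cpg) |>
      mutate(methyl_level = "none", rate = base_rate[!is_cpg])
    cpg <- bind_rows(
      grid |> filter(is_cpg) |>
        mutate(methyl_level = "low",
               rate = base_rate[is_cpg] *
                 ifelse(is_transition[is_cpg], 2, 1)),
      grid |> filter(is_cpg) |>
        mutate(methyl_level = "high",
               rate = base_rate[is_cpg] *
                 ifelse(is_transition[is_cpg], 12, 1))
    )
    out <- bind_rows(non_cpg, cpg) |>
      mutate(rate = pmin(rate, 9e-5)) |>
      select(context, alt, methyl_level, rate) |>
      arrange(context, alt, methyl_level)
    attr(out, "out.attrs") <- NULL
    out
  })
}

#' Validate and strand-symmetrize a rate table
#'
#' Checks that, after merging reverse-complement contexts, every one of the
#' 64 x 3 context-substitution pairs carries a non-negative rate below the
#' 1e-4 sanity bound, and returns a fast lookup closure.
#'
#' @param rates Tibble as produced by [make_rate_table()] or
#'   [read_rate_table()].
#' @return A function `(context, alt, methyl_level = "high")` vectorized
#'   over its arguments, returning rates; unknown contexts raise an input
#'   error naming the offending context.
#' @export
rate_lookup <- function(rates) {
  req <- c("context", "alt", "methyl_level", "rate")
  if (!all(req %in% names(rates))) {
    abort("rate table must have columns context, alt, methyl_level, rate.",
          class = "cardiotrio_input_error")
  }
  if (any(rates$rate < 0) || any(rates$rate >= 1e-4)) {
    abort("rates must lie in [0, 1e-4).", class = "cardiotrio_input_error")
  }
  fwd <- rates
  rc <- rates |>
    mutate(context = vapply(context, revcomp_chr, character(1)),
           alt = unname(comp_base(alt)))
  both <- bind_rows(fwd, rc) |>
    group_by(context, alt, methyl_level) |>
    summarise(rate = mean(rate), .groups = "drop")
  # completeness over all 64 contexts x 3 substitutions
  bases <- c("A", "C", "G", "T")
  full <- expand.grid(p5 = bases, ref = bases, p3 = bases, alt = bases,
                      stringsAsFactors = FALSE)
  full <- full[full$alt != full$ref, ]
  full_key <- paste0(full$p5, full$ref, full$p3, ">", full$alt)
  have_key <- paste0(both$context, ">", both$alt)
  missing_pairs <- setdiff(full_key, have_key)
  if (length(missing_pairs) > 0) {
    abort(sprintf("rate table is missing %d context-substitution pairs (e.g. %s).",
                  length(missing_pairs), missing_pairs[1]),
          class = "cardiotrio_input_error")
  }
  env <- new.env(parent = emptyenv())
  key <- paste(both$context, both$alt, both$methyl_level, sep = "|")
  for (i in seq_along(key)) assign(key[i], both$rate[i], envir = env)
  has_methyl <- unique(paste(both$context, both$alt, sep = "|")[
    both$methyl_level != "none"])

  function(context, alt, methyl_level = "high") {
    n <- max(length(context), length(alt))
    context <- rep_len(context, n)
    alt <- rep_len(alt, n)
    methyl_level <- rep_len(methyl_level, n)
    ck <- paste(context, alt, sep = "|")
    lvl <- ifelse(ck %in% has_methyl, methyl_level, "none")
    out <- vapply(paste(ck, lvl, sep = "|"), function(k) {
      if (!exists(k, envir = env, inherits = FALSE)) return(NA_real_)
      get(k, envir = env)
    }, numeric(1), USE.NAMES = FALSE)
    if (anyNA(out)) {
      bad <- context[which(is.na(out))[1]]
      abort(sprintf("no rate for context '%s' at the requested level.", bad),
            class = "cardiotrio_input_error")
    }
    out
  }
}

#' @rdname make_rate_table
#' @param path File path for the TSV form (columns context, alt,
#'   methyl_level, rate).
#' @param rates A rate-table tibble.
#' @export
write_rate_table <- function(rates, path) {
  readr::write_tsv(rates, path)
  invisible(rates)
}

#' @rdname make_rate_table
#' @export
read_rate_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    context = "c", alt = "c", methyl_level = "c", rate = "d"))
}
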