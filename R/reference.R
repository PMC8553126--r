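#' Published leaf-trait summary of a poplar F1 clonal trial
#'
#' Descriptive statistics (mean, SD, coefficient of variation, clone-level
#' heritability) of the seven classic leaf traits reported by a published
#' clonally replicated poplar F1 common-garden study, shipped for
#' internal-consistency checks (e.g. recomputing the CV from the mean and SD)
#' and as realistic anchors for synthetic-data settings.
#'
#' @return A tibble with columns `trait`, `unit`, `mean`, `sd`, `cv_pct`,
#'   `heritability_pct`.
#' @export
ref_leaf_trait_summary <- function() {
  tibble::tribble(
    ~trait, ~unit,   ~mean,   ~sd,     ~cv_pct, ~heritability_pct,
    "L",    "mm",    114.27,  23.76,   20.79,   41.56,
    "W",    "mm",    90.79,   21.90,   24.12,   46.46,
    "W13",  "mm",    89.95,   21.89,   24.34,   45.65,
    "W12",  "mm",    83.80,   19.83,   23.66,   46.67,
    "W23",  "mm",    64.97,   16.33,   25.14,   49.53,
    "A",    "mm2",   7317.88, 3091.52, 42.25,   49.52,
    "LW",   "ratio", 1.28,    0.13,    10.12,   64.74
  )
}

#' Published segregation-type SNP counts of a poplar F1 cross
#'
#' Per-type SNP counts of the same published F1 poplar pedigree (the
#' segregation funnel its QC produced), together with the printed total and
#' the post-pruning count of independent markers and LD blocks. Used for
#' internal-consistency checks and as the default segregation mix of
#' [cross_config()].
#'
#' @return A list with `counts` (tibble: `type`, `ratio`, `n`), `total`, and
#'   `n_independent`.
#' @export
ref_segregation_counts <- function() {
  list(
    counts = tibble::tribble(
      ~type,   ~ratio,  ~n,
      "aaxab", "1:1",   13385L,
      "aaxbc", "1:1",   76L,
      "abxaa", "1:1",   19295L,
      "abxcc", "1:1",   159L,
      "abxab", "1:2:1", 171L
    ),
    total = 33086L,
    n_independent = 10735L
  )
}
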