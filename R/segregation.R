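#' Classify the F1 segregation type of a SNP from its parents
#'
#' Determines the cross configuration and expected Mendelian offspring ratio
#' from the two parental genotypes. Homozygote x heterozygote crosses and the
#' two-observable-class het x hom configurations segregate 1:1; het x het with
#' identical alleles segregates 1:2:1; fully informative het x het crosses
#' (one or no shared allele) segregate 1:1:1:1. Monomorphic configurations
#' (both parents homozygous) and missing parental genotypes are
#' `unclassifiable`.
#'
#' @param parent1,parent2 Genotypes as allele pairs (`"A/T"`, `"a/b"`, ...);
#'   `NA` for missing.
#' @return A list with `type` (canonical label such as `"aaxab"`,
#'   `"abxac"`, `"abxcd"`, or `"unclassifiable"`), `ratio` (integer vector,
#'   `NULL` if unclassifiable), and `classes` (expected offspring genotypes as
#'   sorted allele pairs, aligned with `ratio`).
#' @export
classify_segregation <- function(parent1, parent2) {
  unclass_res <- list(type = "unclassifiable", ratio = NULL, classes = NULL)
  if (is.na(parent1) || is.na(parent2)) return(unclass_res)
  a1 <- split_geno(parent1)
  a2 <- split_geno(parent2)
  if (is.null(a1) || is.null(a2)) return(unclass_res)
  het1 <- a1[1] != a1[2]
  het2 <- a2[1] != a2[2]

  if (!het1 && !het2) return(unclass_res)  # aa x aa or aa x bb: no segregation

  classes <- offspring_classes(a1, a2)
  if (!het1 && het2) {
    type <- if (a1[1] %in% a2) "aaxab" else "aaxbc"
    return(list(type = type, ratio = c(1L, 1L), classes = classes))
  }
  if (het1 && !het2) {
    type <- if (a2[1] %in% a1) "abxaa" else "abxcc"
    return(list(type = type, ratio = c(1L, 1L), classes = classes))
  }
  shared <- length(intersect(a1, a2))
  if (shared == 2) {
    # classes are aa, ab, bb in sorted order; ratio 1:2:1 with ab in the middle
    het <- geno_string(a1[1], a1[2])
    classes <- c(setdiff(classes, het)[1], het, setdiff(classes, het)[2])
    return(list(type = "abxab", ratio = c(1L, 2L, 1L), classes = classes))
  }
  type <- if (shared == 1) "abxac" else "abxcd"
  list(type = type, ratio = rep(1L, 4L), classes = classes)
}

split_geno <- function(g) {
  al <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(al) != 2 || any(al == "" | al == ".")) return(NULL)
  sort(al)
}

#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Pearson chi-square of observed offspring class counts against the expected
#' segregation ratio, with `length(ratio) - 1` degrees of freedom.
#'
#' @param observed Non-negative counts per offspring class.
#' @param ratio Expected ratio (e.g. `c(1, 1)` or `c(1, 2, 1)`), aligned with
#'   `observed`.
#' @return A list with `chi2`, `df`, `p`.
#' @export
segregation_test <- function(observed, ratio) {
  if (length(observed) != length(ratio)) {
    stop("observed counts and ratio must align", call. = FALSE)
  }
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(observed)
  if (n == 0) stop("all counts are zero", call. = FALSE)
  expected <- n * ratio / sum(ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(ratio) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-SNP segregation QC records
#'
#' Classifies every SNP from its parental genotypes, tabulates offspring class
#' counts, tests them against the expected Mendelian ratio, and applies the F1
#' QC rule: a SNP passes when its segregation ratio is one of 1:1, 1:2:1,
#' 1:1:1:1, its chi-square p-value exceeds `min_p`, and its missing-genotype
#' fraction across clones is below `max_missing`.
#'
#' @param geno An `f1_geno` object ([simulate_cross()] or [read_vcf()]).
#' @param min_p Mendelian-deviation p-value cutoff (SNPs with `p <= min_p`
#'   fail).
#' @param max_missing Missingness cutoff (SNPs with a missing fraction
#'   `>= max_missing` fail).
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos`, `type`,
#'   `ratio`, `chi2`, `p`, `missing_fraction`, `pass`, plus a list-column
#'   `counts` of per-class observed counts.
#' @export
qc_segregation <- function(geno, min_p = 0.01, max_missing = 0.10) {
  stopifnot(inherits(geno, "f1_geno"))
  snps <- geno$snps
  m <- nrow(snps)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    cl <- classify_segregation(snps$p1[j], snps$p2[j])
    obs <- geno$geno[j, ]
    missing_fraction <- mean(is.na(obs))
    if (cl$type == "unclassifiable") {
      res[[j]] <- tibble::tibble(
        type = "unclassifiable", ratio = NA_character_, chi2 = NA_real_,
        p = NA_real_, missing_fraction = missing_fraction, pass = FALSE,
        counts = list(NULL)
      )
      next
    }
    counts <- vapply(cl$classes, function(k) sum(obs == k, na.rm = TRUE),
                     numeric(1))
    tst <- if (sum(counts) > 0) segregation_test(counts, cl$ratio) else
      list(chi2 = NA_real_, p = NA_real_)
    pass <- isTRUE(tst$p > min_p) && missing_fraction < max_missing &&
      ratio_string(cl$ratio) %in% c("1:1", "1:2:1", "1:1:1:1")
    res[[j]] <- tibble::tibble(
      type = cl$type, ratio = ratio_string(cl$ratio), chi2 = tst$chi2,
      p = tst$p, missing_fraction = missing_fraction, pass = pass,
      counts = list(counts)
    )
  }
  dplyr::bind_cols(snps[, c("snp_id", "chrom", "pos")],
                   dplyr::bind_rows(res))
}

#' Filter SNPs on the segregation QC records
#'
#' Keeps SNPs whose QC record passes and reports the per-type summary of the
#' kept set (the segregation-type funnel).
#'
#' @param records Output of [qc_segregation()].
#' @param geno The matching `f1_geno` object.
#' @return The `f1_geno` restricted to passing SNPs, with the per-type summary
#'   attached as attribute `"summary"`.
#' @export
filter_snps <- function(records, geno) {
  stopifnot(inherits(geno, "f1_geno"))
  keep <- records$snp_id[records$pass]
  idx <- match(keep, geno$snps$snp_id)
  out <- geno
  out$snps <- geno$snps[idx, ]
  out$geno <- geno$geno[idx, , drop = FALSE]
  out$geno_true <- geno$geno_true[idx, , drop = FALSE]
  if (!is.null(geno$hap1)) {
    out$hap1 <- geno$hap1[idx, , drop = FALSE]
    out$hap2 <- geno$hap2[idx, , drop = FALSE]
  }
  attr(out, "summary") <- segregation_summary(records)
  out
}

#' Per-type summary of segregation QC records
#'
#' @param records Output of [qc_segregation()].
#' @return A tibble with one row per segregation type: `type`, `ratio`,
#'   `n_total`, `n_pass`.
#' @export
segregation_summary <- function(records) {
  records |>
    dplyr::group_by(.data$type, .data$ratio) |>
    dplyr::summarise(n_total = dplyr::n(), n_pass = sum(.data$pass),
                     .groups = "drop")
}
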