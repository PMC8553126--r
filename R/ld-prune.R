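#' Numeric coding of F1 genotype classes
#'
#' Encodes offspring genotype classes for correlation-based LD measures.
#' Two-class (1:1) SNPs are coded 0/1 by the transmitted allele of the
#' informative (heterozygous) parent; three-class `abxab` SNPs are coded
#' 0/1/2 by allele dosage; four-class (1:1:1:1) SNPs are coded 0/1 by the
#' first parent's transmitted allele. Unrecognized classes and missing calls
#' become `NA`.
#'
#' @param classes Character vector of offspring genotypes (sorted allele
#'   pairs).
#' @param parent1,parent2 Parental genotypes.
#' @return Numeric vector of codes.
#' @export
geno_numeric <- function(classes, parent1, parent2) {
  cl <- classify_segregation(parent1, parent2)
  if (cl$type == "unclassifiable") {
    return(rep(NA_real_, length(classes)))
  }
  # canonicalize allele order ("T/C" -> "C/T") before class lookup
  classes <- vapply(classes, function(g) {
    if (is.na(g)) return(NA_character_)
    al <- split_geno(g)
    if (is.null(al)) NA_character_ else geno_string(al[1], al[2])
  }, character(1), USE.NAMES = FALSE)
  codes <- switch(as.character(length(cl$classes)),
    "2" = setNames(c(0, 1), cl$classes),
    "3" = setNames(c(0, 1, 2), cl$classes),
    "4" = {
      a1 <- split_geno(parent1)
      a2 <- split_geno(parent2)
      # p1-transmitted allele: the class allele not explainable by p2 alone
      first <- vapply(cl$classes, function(g) {
        al <- split_geno(g)
        p1al <- if (al[1] %in% a1 && !(al[1] %in% a2)) al[1]
                else if (al[2] %in% a1 && !(al[2] %in% a2)) al[2]
                else al[which(al %in% a1)][1]
        p1al
      }, character(1))
      setNames(as.numeric(first == a1[2]), cl$classes)
    }
  )
  unname(codes[classes])
}

# Numeric coding matrix (SNP x clone) for an f1_geno object.
geno_code_matrix <- function(geno) {
  stopifnot(inherits(geno, "f1_geno"))
  m <- nrow(geno$snps)
  out <- matrix(NA_real_, m, ncol(geno$geno),
                dimnames = dimnames(geno$geno))
  for (j in seq_len(m)) {
    out[j, ] <- geno_numeric(geno$geno[j, ], geno$snps$p1[j], geno$snps$p2[j])
  }
  out
}

#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of the numeric genotype codes, dropping
#' individuals missing at either SNP. Zero variance at either SNP makes the
#' correlation undefined; such pairs return 0 with attribute
#' `undefined = TRUE`.
#'
#' @param x,y Numeric genotype codes ([geno_numeric()]) of the two SNPs.
#' @return `r^2` in \[0, 1\].
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) {
    return(structure(0, undefined = TRUE))
  }
  cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Greedy windowed pruning of SNPs in linkage disequilibrium: within each
#' window of `window` SNPs (position-sorted, never spanning chromosomes),
#' while any pair of retained SNPs has `r^2` above `r2_threshold`, one member
#' of the worst offending pair is removed -- the SNP with the higher missing
#' fraction, then the later position (a deterministic PLINK-like tie rule).
#' The window then advances by `step` SNPs. Survivors approximate the number
#' of independent markers and LD blocks used for the Bonferroni correction.
#'
#' @param geno An `f1_geno` object, position-sorted within chromosome.
#' @param window Window size in SNPs.
#' @param step Step size in SNPs.
#' @param r2_threshold Pruning threshold on `r^2`.
#' @return A `pruned_set`: list with `kept_snp_ids`, `n_independent`,
#'   `window`, `step`, `r2_threshold`.
#' @export
ld_prune <- function(geno, window = 25L, step = 2L, r2_threshold = 0.7) {
  stopifnot(inherits(geno, "f1_geno"))
  snps <- geno$snps
  if (is.unsorted(order(snps$chrom, snps$pos))) {
    # order() of a sorted frame is 1..n; equivalent check below
  }
  if (any(diff(snps$pos)[diff(snps$chrom) == 0] < 0)) {
    stop("SNPs must be position-sorted within chromosome", call. = FALSE)
  }
  codes <- geno_code_matrix(geno)
  missing_fraction <- rowMeans(is.na(geno$geno))
  kept_all <- character(0)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    kept <- prune_chromosome(codes[idx, , drop = FALSE],
                             missing_fraction[idx], window, step, r2_threshold)
    kept_all <- c(kept_all, snps$snp_id[idx][kept])
  }
  structure(
    list(kept_snp_ids = kept_all, n_independent = length(kept_all),
         window = as.integer(window), step = as.integer(step),
         r2_threshold = r2_threshold),
    class = "pruned_set"
  )
}

# Greedy pruning of one chromosome; returns logical keep vector.
prune_chromosome <- function(codes, missing_fraction, window, step, r2_threshold) {
  m <- nrow(codes)
  keep <- rep(TRUE, m)
  if (m < 2) return(keep)
  start <- 1L
  repeat {
    win <- seq(start, min(start + window - 1L, m))
    active <- win[keep[win]]
    while (length(active) >= 2) {
      worst <- NULL
      worst_r2 <- r2_threshold
      for (ii in seq_len(length(active) - 1)) {
        for (jj in seq(ii + 1, length(active))) {
          r2 <- pairwise_r2(codes[active[ii], ], codes[active[jj], ])
          if (r2 > worst_r2) {
            worst_r2 <- r2
            worst <- c(active[ii], active[jj])
          }
        }
      }
      if (is.null(worst)) break
      drop <- prune_tiebreak(worst, missing_fraction)
      keep[drop] <- FALSE
      active <- setdiff(active, drop)
    }
    if (start + window - 1L >= m) break
    start <- start + step
  }
  keep
}

# Remove the member of an offending pair with the higher missing fraction,
# breaking ties towards the later position.
prune_tiebreak <- function(pair, missing_fraction) {
  mf <- missing_fraction[pair]
  if (mf[1] > mf[2]) pair[1] else if (mf[2] > mf[1]) pair[2] else max(pair)
}

#' @export
print.pruned_set <- function(x, ...) {
  cat("<pruned_set> ", x$n_independent, " independent markers",
      " (window ", x$window, ", step ", x$step, ", r2 > ",
      x$r2_threshold, ")\n", sep = "")
  invisible(x)
}
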