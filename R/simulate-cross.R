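# Segregation machinery shared by the simulator and the QC module.
#
# Genotypes are written as sorted allele pairs "a/b". In an outbred F1 cross a
# biallelic-or-multiallelic SNP falls into one of five observable segregation
# types (plus the fully informative het x het configurations that segregate
# 1:1:1:1). Types whose four gametic combinations collapse to two observable
# offspring classes (aa x bc, ab x cc) are handled as two-class 1:1 markers.

SEG_TYPES <- c("aaxab", "aaxbc", "abxaa", "abxcc", "abxab")

seg_type_info <- function(type) {
  switch(type,
    "aaxab" = list(p1 = c("a", "a"), p2 = c("a", "b"), ratio = c(1, 1)),
    "aaxbc" = list(p1 = c("a", "a"), p2 = c("b", "c"), ratio = c(1, 1)),
    "abxaa" = list(p1 = c("a", "b"), p2 = c("a", "a"), ratio = c(1, 1)),
    "abxcc" = list(p1 = c("a", "b"), p2 = c("c", "c"), ratio = c(1, 1)),
    "abxab" = list(p1 = c("a", "b"), p2 = c("a", "b"), ratio = c(1, 2, 1)),
    stop("unknown segregation type: ", type, call. = FALSE)
  )
}

geno_string <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

# Expected offspring classes (sorted allele pairs) for given parental gametes.
offspring_classes <- function(p1_alleles, p2_alleles) {
  cls <- unique(geno_string(rep(p1_alleles, each = 2), rep(p2_alleles, 2)))
  sort(cls)
}

ratio_string <- function(ratio) paste(ratio, collapse = ":")

#' Configure a synthetic F1 cross
#'
#' Study-condition defaults mirror a clonally replicated poplar F1 pedigree:
#' 163 clones, 19 chromosomes, and a segregation-type mix matching the
#' published SNP summary of such a cross (test-cross 1:1 types dominate).
#'
#' @param n_clones Number of F1 clones.
#' @param n_chromosomes Number of chromosomes.
#' @param snps_per_chromosome SNPs per chromosome.
#' @param chromosome_length Genetic map length per chromosome, in Morgans.
#' @param segregation_mix Named proportions over the five segregation types
#'   `aaxab`, `aaxbc`, `abxaa`, `abxcc`, `abxab`; must sum to 1.
#' @param missing_rate Fraction of genotype calls masked at random, in \[0, 1).
#' @param seed Integer seed.
#' @return A `cross_config` list.
#' @export
cross_config <- function(n_clones = 163L, n_chromosomes = 19L,
                         snps_per_chromosome = 110L, chromosome_length = 2,
                         segregation_mix = c(aaxab = 13385, aaxbc = 76,
                                             abxaa = 19295, abxcc = 159,
                                             abxab = 171) / 33086,
                         missing_rate = 0.03, seed = 1L) {
  if (!is_count(n_clones) || !is_count(n_chromosomes) ||
      !is_count(snps_per_chromosome)) {
    stop("clone, chromosome and SNP counts must be positive integers",
         call. = FALSE)
  }
  if (chromosome_length <= 0) stop("chromosome_length must be positive", call. = FALSE)
  if (!setequal(names(segregation_mix), SEG_TYPES)) {
    stop("segregation_mix must be named with the five segregation types",
         call. = FALSE)
  }
  segregation_mix <- segregation_mix[SEG_TYPES]
  if (any(segregation_mix < 0) || abs(sum(segregation_mix) - 1) > 1e-8) {
    stop("segregation_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_clones = as.integer(n_clones),
         n_chromosomes = as.integer(n_chromosomes),
         snps_per_chromosome = as.integer(snps_per_chromosome),
         chromosome_length = chromosome_length,
         segregation_mix = segregation_mix,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cross_config"
  )
}

# 1 cM ~ 250 kb, a Populus-like genome-to-map ratio used to place synthetic
# SNPs on a physical coordinate system for VCF output.
BP_PER_MORGAN <- 25e6

#' Simulate genotypes of an outbred F1 cross
#'
#' Draws phased parental haplotypes for each SNP according to its segregation
#' type, then transmits gametes by Mendelian segregation with recombination
#' along each chromosome under the Haldane map function
#' (recombination fraction \eqn{r = (1 - e^{-2d})/2} for map distance `d`
#' Morgans). Linkage disequilibrium between nearby SNPs therefore arises from
#' physical linkage, as in a real cross; distant SNPs are transmitted
#' independently. Genotype calls are masked completely at random at
#' `missing_rate`.
#'
#' @param config A [cross_config()].
#' @return An `f1_geno` object: list with `snps` (tibble: snp_id, chrom,
#'   pos, cm, type, ratio, p1, p2), `geno` (character matrix SNP x clone of
#'   sorted allele pairs with `NA` for missing), `geno_true` (pre-masking
#'   genotypes), `hap1`/`hap2` (integer matrices of the parental haplotype --
#'   1 or 2 -- transmitted by each parent at each SNP, for linkage oracles),
#'   and `config`.
#' @export
simulate_cross <- function(config = cross_config()) {
  stopifnot(inherits(config, "cross_config"))
  with_seed(config$seed, {
    n_chr <- config$n_chromosomes
    m_chr <- config$snps_per_chromosome
    n <- config$n_clones
    m <- n_chr * m_chr

    chrom <- rep(seq_len(n_chr), each = m_chr)
    cm <- as.vector(vapply(seq_len(n_chr), function(i) {
      sort(runif(m_chr, 0, config$chromosome_length)) * 100
    }, numeric(m_chr)))
    pos <- as.integer(round(cm / 100 * BP_PER_MORGAN)) + 1L

    type <- sample(SEG_TYPES, m, replace = TRUE,
                   prob = config$segregation_mix)
    info <- lapply(type, seg_type_info)

    # phase: random assignment of each parent's two alleles to haplotypes
    ph1 <- sample(c(TRUE, FALSE), m, replace = TRUE)
    ph2 <- sample(c(TRUE, FALSE), m, replace = TRUE)
    p1_hap <- t(vapply(seq_len(m), function(j) {
      al <- info[[j]]$p1
      if (ph1[j]) al else rev(al)
    }, character(2)))
    p2_hap <- t(vapply(seq_len(m), function(j) {
      al <- info[[j]]$p2
      if (ph2[j]) al else rev(al)
    }, character(2)))

    hap1 <- gamete_origins(chrom, cm, n)
    hap2 <- gamete_origins(chrom, cm, n)

    a1 <- matrix(p1_hap[cbind(rep(seq_len(m), n), as.vector(hap1))], m, n)
    a2 <- matrix(p2_hap[cbind(rep(seq_len(m), n), as.vector(hap2))], m, n)
    geno_true <- matrix(geno_string(a1, a2), m, n)

    clone_ids <- sprintf("C%03d", seq_len(n))
    colnames(geno_true) <- clone_ids
    colnames(hap1) <- colnames(hap2) <- clone_ids

    geno <- geno_true
    if (config$missing_rate > 0) {
      geno[runif(length(geno)) < config$missing_rate] <- NA_character_
    }

    snps <- tibble::tibble(
      snp_id = sprintf("snp_%02d_%05d", chrom, seq_len(m) - (chrom - 1L) * m_chr),
      chrom = chrom,
      pos = pos,
      cm = cm,
      type = type,
      ratio = vapply(info, function(x) ratio_string(x$ratio), character(1)),
      p1 = vapply(info, function(x) geno_string(x$p1[1], x$p1[2]), character(1)),
      p2 = vapply(info, function(x) geno_string(x$p2[1], x$p2[2]), character(1))
    )
    rownames(geno) <- rownames(geno_true) <- snps$snp_id

    structure(
      list(snps = snps, geno = geno, geno_true = geno_true,
           hap1 = hap1, hap2 = hap2, config = config),
      class = "f1_geno"
    )
  })
}

# Parental haplotype origin (1/2) transmitted to each of n gametes at each SNP,
# simulated as a Markov chain along each chromosome with Haldane switch
# probabilities between adjacent SNPs.
gamete_origins <- function(chrom, cm, n) {
  m <- length(chrom)
  H <- matrix(0L, m, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    k <- length(idx)
    r <- 0.5 * (1 - exp(-2 * diff(cm[idx]) / 100))
    start <- sample(c(0L, 1L), n, replace = TRUE)
    switches <- matrix(0L, k, n)
    switches[1, ] <- start
    if (k > 1) {
      switches[-1, ] <- matrix(rbinom((k - 1) * n, 1, rep(r, n)), k - 1, n)
    }
    H[idx, ] <- (apply(switches, 2, cumsum) %% 2L) + 1L
  }
  H
}

#' @export
print.f1_geno <- function(x, ...) {
  cat("<f1_geno> ", nrow(x$snps), " SNPs x ", ncol(x$geno), " clones (",
      length(unique(x$snps$chrom)), " chromosomes)\n", sep = "")
  print(dplyr::count(x$snps, .data$type, .data$ratio))
  invisible(x)
}
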