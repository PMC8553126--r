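#' Read F1 genotypes from a VCF file
#'
#' Parses GT fields with vcfR and assembles an `f1_geno` object: the two
#' declared parent samples provide the parental genotypes used for
#' segregation classification, all remaining samples are offspring clones.
#' Genotypes are stored as sorted allele pairs (actual alleles, e.g. `"A/T"`);
#' missing calls (`./.`) become `NA`. Positions stay 1-based.
#'
#' @param path VCF file.
#' @param parent_ids Character vector of the two parent sample names.
#' @return An `f1_geno` object.
#' @export
read_vcf <- function(path, parent_ids) {
  if (length(parent_ids) != 2) stop("exactly two parent ids required", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(parent_ids %in% samples)) {
    stop("parent sample(s) absent from VCF: ",
         paste(setdiff(parent_ids, samples), collapse = ", "), call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  m <- nrow(gt)

  decode <- function(g, ref, alt) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_character_)
    ix <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    if (length(ix) != 2 || anyNA(ix)) return(NA_character_)
    al <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])[ix + 1]
    if (anyNA(al)) return(NA_character_)
    geno_string(al[1], al[2])
  }

  geno_all <- matrix(NA_character_, m, length(samples),
                     dimnames = list(rownames(gt), samples))
  for (j in seq_len(m)) {
    geno_all[j, ] <- vapply(gt[j, ], decode, character(1),
                            ref = alleles[j, 1], alt = alleles[j, 2])
  }

  offspring <- setdiff(samples, parent_ids)
  p1 <- geno_all[, parent_ids[1]]
  p2 <- geno_all[, parent_ids[2]]
  type <- character(m); ratio <- character(m)
  for (j in seq_len(m)) {
    cl <- classify_segregation(p1[j], p2[j])
    type[j] <- cl$type
    ratio[j] <- if (is.null(cl$ratio)) NA_character_ else ratio_string(cl$ratio)
  }
  snps <- tibble::tibble(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    cm = NA_real_,
    type = type, ratio = ratio, p1 = unname(p1), p2 = unname(p2)
  )
  geno <- geno_all[, offspring, drop = FALSE]
  rownames(geno) <- snps$snp_id
  structure(list(snps = snps, geno = geno, geno_true = geno,
                 hap1 = NULL, hap2 = NULL, config = NULL),
            class = "f1_geno")
}

#' Write F1 genotypes as a minimal VCF
#'
#' Emits a GT-only VCF 4.2 file with the two parents as the first two samples
#' followed by the offspring clones. Allele tokens of each SNP are mapped to
#' nucleotide-like REF/ALT strings in order of appearance (first token = REF).
#'
#' @param geno An `f1_geno` object.
#' @param path Output path.
#' @param parent_ids Sample names to give the parents.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, parent_ids = c("P1", "P2"), seed = NULL) {
  stopifnot(inherits(geno, "f1_geno"))
  snps <- geno$snps
  m <- nrow(snps)
  clones <- colnames(geno$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=leafgwas", if (!is.null(seed)) paste0(" seed=", seed)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", parent_ids, clones), collapse = "\t")
  )
  body <- character(m)
  for (j in seq_len(m)) {
    gts <- c(snps$p1[j], snps$p2[j], geno$geno[j, ])
    toks <- unique(unlist(lapply(gts[!is.na(gts)], split_geno)))
    code <- setNames(seq_along(toks) - 1L, toks)
    enc <- vapply(gts, function(g) {
      if (is.na(g)) return("./.")
      al <- split_geno(g)
      paste(sort(code[al]), collapse = "/")
    }, character(1))
    body[j] <- paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j],
                       toks[1],
                       if (length(toks) > 1) paste(toks[-1], collapse = ",") else ".",
                       ".", "PASS", ".", "GT", enc), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a stage output table with a provenance header
#'
#' CSV with `#`-prefixed header lines naming the producing stage, the config
#' hash, and the seed, so the QC funnel stays reconstructible from outputs.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param stage Stage name.
#' @param seed Seed used by the stage.
#' @param config_hash Configuration hash ([config_hash()]).
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(df, path, stage, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# stage: ", stage),
    paste0("# config_hash: ", config_hash),
    paste0("# seed: ", seed)
  ), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage output table
#'
#' @param path File written by [write_stage_table()].
#' @return A tibble; provenance lines are attached as attribute `"header"`.
#' @export
read_stage_table <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con); on.exit()
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(out, "header") <- hdr
  out
}

#' Pipeline run configuration
#'
#' Collects the stage parameters of the full `simulate -> phenotype -> qc ->
#' gwas` pipeline into one serializable object. All randomness derives from
#' `seed`.
#'
#' @param seed Master integer seed.
#' @param cross A [cross_config()].
#' @param trial A [trial_config()].
#' @param qc List of QC cutoffs: `min_p`, `max_missing`.
#' @param prune List of pruning parameters: `window`, `step`, `r2_threshold`.
#' @param alpha Family-wise significance level for the scan.
#' @param traits Trait subset for the scan (`NULL` = all).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cross = cross_config(seed = seed),
                       trial = trial_config(seed = seed + 1L),
                       qc = list(min_p = 0.01, max_missing = 0.10),
                       prune = list(window = 25L, step = 2L, r2_threshold = 0.7),
                       alpha = 0.05, traits = NULL) {
  structure(
    list(seed = as.integer(seed), cross = cross, trial = trial, qc = qc,
         prune = prune, alpha = alpha, traits = traits,
         version = as.character(utils::packageVersion("leafgwas"))),
    class = "run_config"
  )
}

#' Serialize / restore a run configuration
#'
#' JSON round-trip: `read_config(write_config(cfg, path))` reproduces an
#' identical configuration.
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` / the restored `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.matrix(x)) {
    apply(x, 1, identity, simplify = FALSE)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # keep names through JSON (jsonlite drops names of vectors)
  } else x
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cr <- raw$cross
  cross <- cross_config(
    n_clones = cr$n_clones, n_chromosomes = cr$n_chromosomes,
    snps_per_chromosome = cr$snps_per_chromosome,
    chromosome_length = cr$chromosome_length,
    segregation_mix = unlist(cr$segregation_mix),
    missing_rate = cr$missing_rate, seed = cr$seed
  )
  tr <- raw$trial
  # jsonlite may simplify a list of equal-length rows back into a matrix
  rows_to_matrix <- function(x, nrow) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nrow, byrow = TRUE)
  }
  trial <- trial_config(
    n_blocks = tr$n_blocks, cuttings_per_plot = tr$cuttings_per_plot,
    n_traits = tr$n_traits,
    block_effects = rows_to_matrix(tr$block_effects, tr$n_blocks),
    qtl_spec = tr$qtl_spec %||% list(),
    V_G = rows_to_matrix(tr$V_G, tr$n_traits),
    V_E = rows_to_matrix(tr$V_E, tr$n_traits),
    mu = tr$mu, survival_rate = tr$survival_rate, seed = tr$seed
  )
  run_config(seed = raw$seed, cross = cross, trial = trial, qc = raw$qc,
             prune = raw$prune, alpha = raw$alpha, traits = raw$traits)
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical JSON serialization.
#'
#' @param config A [run_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Executes `simulate -> qc -> prune -> scan` end to end from one
#' configuration and returns all stage outputs plus a provenance manifest
#' (config hash, seeds, stage record counts). When `out_dir` is given, stage
#' tables (genotype VCF, phenotype CSV, QC records, scan results, summary
#' JSON) are written with provenance headers.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list: `cross`, `phenotypes`, `qc_records`, `filtered`, `pruned`,
#'   `scan`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)

  cross <- simulate_cross(config$cross)
  phenotypes <- simulate_rcbd_phenotypes(cross, config$trial)
  qc_records <- qc_segregation(cross, min_p = config$qc$min_p,
                               max_missing = config$qc$max_missing)
  filtered <- filter_snps(qc_records, cross)
  pruned <- ld_prune(filtered, window = config$prune$window,
                     step = config$prune$step,
                     r2_threshold = config$prune$r2_threshold)
  scan <- run_scan(phenotypes, filtered, traits = config$traits,
                   m_independent = pruned$n_independent, alpha = config$alpha)

  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    version = config$version,
    n_snps_total = nrow(cross$snps),
    n_snps_pass = nrow(filtered$snps),
    n_independent = pruned$n_independent,
    n_trees = nrow(phenotypes),
    n_clones = length(unique(phenotypes$clone)),
    n_traits = length(attr(scan, "traits")),
    lambda_gc = attr(scan, "lambda_gc"),
    p_threshold = attr(scan, "threshold"),
    n_significant = sum(scan$significant)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.json"))
    write_vcf(cross, file.path(out_dir, "genotypes.vcf"),
              seed = config$cross$seed)
    write_stage_table(phenotypes, file.path(out_dir, "phenotypes.csv"),
                      "simulate_rcbd_phenotypes", config$trial$seed, hash)
    write_stage_table(dplyr::select(qc_records, -"counts"),
                      file.path(out_dir, "qc_records.csv"),
                      "qc_segregation", config$cross$seed, hash)
    writeLines(pruned$kept_snp_ids, file.path(out_dir, "pruned_snps.txt"))
    write_stage_table(tibble::as_tibble(scan),
                      file.path(out_dir, "scan.csv"),
                      "run_scan", config$seed, hash)
    jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cross = cross, phenotypes = phenotypes, qc_records = qc_records,
       filtered = filtered, pruned = pruned, scan = scan, manifest = manifest)
}
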