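# Readers and writers for the standard formats (VCF, dosage TSV, CSV,
# JSON), the QC filters, and run configuration.

#' Write phased genotypes as a VCF
#'
#' Minimal VCFv4.2 with phased GT fields (`0|1` separators); REF/ALT are
#' written as A/B placeholder alleles since the simulator works on 0/1
#' alleles. Positions are 1-based.
#'
#' @param phased a `phased_genotypes`.
#' @param path output path.
#' @export
write_vcf <- function(phased, path) {
  map <- phased$marker_map
  ids <- rownames(phased$h1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gshap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(nrow(map))) {
    gt <- paste0(phased$h1[, j], "|", phased$h2[, j])
    writeLines(paste(c(map$chromosome[j], map$position_bp[j], map$marker_id[j],
                       "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into a dosage matrix (count of ALT alleles) and a
#' marker map. Uses the vcfR parser.
#'
#' @param path VCF path.
#' @return list: `genotypes` (individuals x markers dosage, `NA` for
#'   missing), `marker_map`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_gshap("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  map <- data.frame(marker_id = rownames(gt),
                    chromosome = as.integer(v@fix[, "CHROM"]),
                    position_bp = as.integer(v@fix[, "POS"]),
                    stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  list(genotypes = t(dose), marker_map = validate_marker_map(map))
}

#' Write / read a dosage TSV
#'
#' Individuals in rows (first column `individual_id`), markers in columns
#' named by marker id; missing as empty cells.
#' @param genotypes dosage matrix with row and column names.
#' @param path file path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df[[1]]
  g
}

#' Write a pedigree CSV (unknown parents as UNKNOWN)
#' @param pedigree a `pedigree`.
#' @param path file path.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  out <- pedigree
  out$sire_id[is.na(out$sire_id)] <- UNKNOWN_PARENT
  out$dam_id[is.na(out$dam_id)] <- UNKNOWN_PARENT
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sire_id", "dam_id"))
    ped[[col]][ped[[col]] == UNKNOWN_PARENT] <- NA_character_
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
}

#' Write simulation truth as JSON
#' @param truth the `truth` element of a `gs_dataset`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Quality-control filters for the genotype matrix
#'
#' Applies the standard filters in order: first markers with call rate
#' below `call_rate_min` are removed, then markers with minor allele
#' frequency below `maf_min` (monomorphic markers fall in this step).
#'
#' @param genotypes individuals x markers dosage matrix.
#' @param marker_map aligned `marker_map`.
#' @param call_rate_min minimum marker call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list: filtered `genotypes` and `marker_map`, plus `log`
#'   (`data.frame` of step, markers removed, markers kept).
#' @export
qc_genotypes <- function(genotypes, marker_map, call_rate_min = 0.90,
                         maf_min = 0.05) {
  validate_marker_map(marker_map)
  stopifnot(ncol(genotypes) == nrow(marker_map))
  cr <- colMeans(!is.na(genotypes))
  keep1 <- cr >= call_rate_min
  g1 <- genotypes[, keep1, drop = FALSE]
  p <- colMeans(g1, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- !is.na(maf) & maf >= maf_min
  log <- data.frame(
    step = c("call_rate", "maf"),
    removed = c(sum(!keep1), sum(!keep2)),
    kept = c(sum(keep1), sum(keep2))
  )
  map1 <- marker_map[keep1, , drop = FALSE]
  out_map <- map1[keep2, , drop = FALSE]
  class(out_map) <- c("marker_map", "data.frame")
  list(genotypes = g1[, keep2, drop = FALSE], marker_map = out_map, log = log)
}

#' Run configuration
#'
#' Bundles paths, QC thresholds, block parameters, model list, marker
#' modes, MCMC and CV settings, and the master seed. Round-trips through
#' YAML with [save_config()] / [load_config()].
#'
#' @param paths named list (`genotypes`, `map`, `pedigree`, `phenotypes`,
#'   `output_dir`); may be empty for in-memory runs.
#' @param call_rate_min,maf_min QC thresholds.
#' @param block_params a [gabriel_params()] list.
#' @param models character subset of BRR/BA/BB/BC/BL.
#' @param marker_modes character subset of SNP/HAP/HAP_SNP.
#' @param mcmc a [mcmc_settings()] list.
#' @param cv_cycles,cv_holdout cross-validation settings.
#' @param seed master seed.
#' @export
run_config <- function(paths = list(), call_rate_min = 0.90, maf_min = 0.05,
                       block_params = gabriel_params(),
                       models = c("BRR", "BA", "BB", "BC", "BL"),
                       marker_modes = c("SNP", "HAP", "HAP_SNP"),
                       mcmc = mcmc_settings(), cv_cycles = 20,
                       cv_holdout = 0.10, seed = 1L) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, cv_holdout > 0, cv_holdout < 1)
  if (length(models) == 0) stop_gshap("config must name at least one model")
  models <- match.arg(models, c("BRR", "BA", "BB", "BC", "BL"),
                      several.ok = TRUE)
  marker_modes <- match.arg(marker_modes, c("SNP", "HAP", "HAP_SNP"),
                            several.ok = TRUE)
  structure(list(paths = paths, call_rate_min = call_rate_min,
                 maf_min = maf_min, block_params = block_params,
                 models = models, marker_modes = marker_modes, mcmc = mcmc,
                 cv_cycles = cv_cycles, cv_holdout = cv_holdout,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "paths")])
  cfg$paths <- raw$paths %||% list()
  cfg
}

#' Load and QC a dataset from files
#'
#' Reads genotypes (VCF or dosage TSV by extension), pedigree and
#' phenotype CSVs, applies QC (call rate, then MAF), and joins tables by
#' individual id with an explicit report of unmatched ids.
#'
#' @param config a [run_config()] with `paths` set.
#' @return list: `genotypes`, `marker_map`, `pedigree`, `phenotypes`,
#'   `qc_log`, `unmatched_ids`.
#' @export
load_dataset <- function(config) {
  p <- config$paths
  for (need in c("genotypes", "pedigree", "phenotypes"))
    if (is.null(p[[need]])) stop_gshap("config paths must include '%s'", need)
  if (grepl("\\.vcf$", p$genotypes)) {
    gv <- read_vcf(p$genotypes)
    geno <- gv$genotypes; map <- gv$marker_map
  } else {
    geno <- read_dosage_tsv(p$genotypes)
    if (is.null(p$map)) stop_gshap("dosage TSV input needs a 'map' path")
    map <- utils::read.csv(p$map, stringsAsFactors = FALSE)
    class(map) <- c("marker_map", "data.frame")
    validate_marker_map(map)
    geno <- geno[, map$marker_id, drop = FALSE]
  }
  ped <- read_pedigree_csv(p$pedigree)
  phen <- utils::read.csv(p$phenotypes, stringsAsFactors = FALSE)
  qc <- qc_genotypes(geno, map, config$call_rate_min, config$maf_min)
  unmatched <- setdiff(phen$individual_id, rownames(qc$genotypes))
  phen <- phen[phen$individual_id %in% rownames(qc$genotypes), , drop = FALSE]
  list(genotypes = qc$genotypes, marker_map = qc$marker_map, pedigree = ped,
       phenotypes = phen, qc_log = qc$log, unmatched_ids = unmatched)
}
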