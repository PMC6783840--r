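# End-to-end orchestration: QC -> haplotype blocks -> marker encodings ->
# pedigree fit -> genomic fits -> cross-validation -> comparison reports.

#' Run the full analysis pipeline
#'
#' Executes the whole chain on an in-memory dataset (a `gs_dataset` from
#' [simulate_population()] or the result of [load_dataset()] merged with a
#' pedigree): QC, Gabriel blocks, SNP/HAP/HAP-SNP encodings, animal-model
#' fit per trait, genomic fits for every model x marker mode, genomic
#' parameters (heritability, genetic gain), cross-validated predictive
#' ability, Tukey-Kramer letters, and credible-set flags versus the
#' pedigree estimates. All stages derive their seeds from the config
#' master seed, so a re-run with the same config reproduces every number.
#'
#' @param dataset list with `genotypes`, `marker_map`, `pedigree`,
#'   `phenotypes` (and optionally `truth`).
#' @param config a [run_config()].
#' @param traits trait columns to analyse (default: all numeric phenotype
#'   columns except the design block).
#' @param selection_fraction truncation-selection fraction for genetic
#'   gain (default 0.1006).
#' @param output_dir optional directory for TSV/JSON reports.
#' @param run_cv run the cross-validation stage (default TRUE).
#' @return list of class `gs_report`: `qc_log`, `blocks`, `block_summary`,
#'   `designs`, `pedigree_fits`, `genomic_fits`, `parameter_table`,
#'   `pa_table`, `cv`, `letters`, `config`.
#' @export
run_pipeline <- function(dataset, config = run_config(), traits = NULL,
                         selection_fraction = 0.1006, output_dir = NULL,
                         run_cv = TRUE) {
  geno <- dataset$genotypes
  map <- dataset$marker_map
  phen <- dataset$phenotypes
  ped <- dataset$pedigree
  if (is.null(traits)) {
    traits <- setdiff(names(phen)[vapply(phen, is.numeric, logical(1))],
                      c("design_block"))
  }
  if (length(config$models) == 0) stop_gshap("config must name at least one model")

  qc <- qc_genotypes(geno, map, config$call_rate_min, config$maf_min)
  geno <- qc$genotypes; map <- qc$marker_map
  geno <- geno[intersect(phen$individual_id, rownames(geno)), , drop = FALSE]
  phen <- phen[match(rownames(geno), phen$individual_id), , drop = FALSE]

  blocks <- gabriel_blocks(geno, map, config$block_params)
  designs <- lapply(setNames(config$marker_modes, config$marker_modes),
                    function(mode) build_design(geno, blocks, mode = mode))
  X <- block_indicators(phen$design_block)

  a_inv <- build_a_inverse(ped)
  pedigree_fits <- list(); genomic_fits <- list()
  param_rows <- list(); cv_results <- list(); letters <- list()
  for (tr in traits) {
    y <- as.numeric(phen[[tr]])
    ok <- !is.na(y)
    pfit <- fit_animal_model(phen[ok, , drop = FALSE], tr, ped,
                             a_inverse = a_inv, mcmc = config$mcmc,
                             seed = derive_seed(config$seed, paste0("ped_", tr)))
    pedigree_fits[[tr]] <- pfit
    gg_ped <- genetic_gain(pfit$ebv[phen$individual_id[ok]],
                           selection_fraction, mean(y[ok]))
    param_rows[[length(param_rows) + 1]] <- data.frame(
      trait = tr, model = "PBP", mode = "pedigree",
      h2 = pfit$h2$mean, h2_lo = pfit$h2$ci90[1], h2_hi = pfit$h2$ci90[2],
      gg = gg_ped$gg_percent, h2_vs_pedigree = FALSE)
    for (mode in config$marker_modes) {
      dm <- designs[[mode]]
      for (mod in config$models) {
        spec <- model_spec(mod, mcmc = config$mcmc)
        fit <- fit_whole_regression(
          y[ok], X[ok, , drop = FALSE],
          structure(list(M = dm$M[ok, , drop = FALSE], freq = dm$freq,
                         source = dm$source, mode = dm$mode),
                    class = "design_matrix"),
          spec, seed = derive_seed(config$seed, paste(tr, mode, mod)))
        genomic_fits[[paste(tr, mode, mod, sep = ".")]] <- fit
        star <- credible_set_compare(fit$h2, pfit$h2)
        gg <- genetic_gain(fit$gebv, selection_fraction, mean(y[ok]))
        param_rows[[length(param_rows) + 1]] <- data.frame(
          trait = tr, model = mod, mode = mode,
          h2 = fit$h2$mean, h2_lo = fit$h2$ci90[1], h2_hi = fit$h2$ci90[2],
          gg = gg$gg_percent, h2_vs_pedigree = star$significant)
        if (run_cv) {
          cv <- cross_validate(
            y[ok], X[ok, , drop = FALSE], dm$M[ok, , drop = FALSE], spec,
            holdout_fraction = config$cv_holdout,
            n_cycles = config$cv_cycles,
            seed = derive_seed(config$seed, paste("cv", tr, mode, mod)),
            whole_fit = fit)
          cv_results[[paste(tr, mode, mod, sep = ".")]] <- cv
        }
      }
    }
    if (run_cv && length(config$models) >= 2) {
      for (mode in config$marker_modes) {
        pa <- sapply(config$models, function(mod)
          cv_results[[paste(tr, mode, mod, sep = ".")]]$pa_cycles)
        letters[[paste(tr, mode, sep = ".")]] <-
          compare_tukey_kramer(pa, alpha = 0.01)
      }
    }
  }
  parameter_table <- do.call(rbind, param_rows)
  pa_table <- if (run_cv) {
    do.call(rbind, lapply(names(cv_results), function(nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      data.frame(trait = parts[1], mode = parts[2], model = parts[3],
                 mean_pa = cv_results[[nm]]$mean_pa,
                 n_skipped = cv_results[[nm]]$n_skipped)
    }))
  } else NULL

  report <- structure(list(
    qc_log = qc$log, blocks = blocks,
    block_summary = block_summary(blocks, map),
    designs = designs, pedigree_fits = pedigree_fits,
    genomic_fits = genomic_fits, parameter_table = parameter_table,
    pa_table = pa_table, cv = cv_results, letters = letters,
    config = config
  ), class = "gs_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write pipeline reports to disk
#'
#' Emits the block table and per-chromosome summary, the genomic-parameter
#' table (heritability, genetic gain, credible-set flags), and the
#' predictive-ability table as TSV, plus a JSON sidecar with the config
#' and master seed.
#'
#' @param report a `gs_report`.
#' @param output_dir directory (created if missing).
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.table(df, file.path(output_dir, name),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  w(as.data.frame(report$blocks), "blocks.tsv")
  w(report$block_summary, "block_summary.tsv")
  w(report$parameter_table, "genomic_parameters.tsv")
  if (!is.null(report$pa_table)) w(report$pa_table, "predictive_ability.tsv")
  jsonlite::write_json(
    list(seed = report$config$seed,
         models = report$config$models,
         marker_modes = report$config$marker_modes,
         qc_log = report$qc_log),
    file.path(output_dir, "run_info.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
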