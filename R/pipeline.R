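#' barseqfit: fitness inference for pooled barcoded knockout assays
#'
#' Implements the full path from BarSeq barcode count tables to per-gene
#' invasion fitness effects and downstream comparative analyses. The stages
#' are exposed individually (see [process_counts()], [kappa_matrix()],
#' [decompose_noise()], [estimate_mean_fitness()], [infer_fitness()],
#' [resistant_diagnostic()], [cofitness_network()],
#' [environment_correlation()], [establishment_logit()]) and composed by
#' [barseq_pipeline()]. [build_experiment()] generates synthetic data under
#' the model's own generative assumptions for validation.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full inference pipeline on one experiment
#'
#' Composes the stages in the order they are meant to run: barcode error
#' merging and gene assignment, error-parameter estimation from intergenic
#' barcodes, mean-fitness estimation from super-barcodes, optional
#' outlier-barcode rejection, and per-gene maximum-likelihood fitness
#' inference with FDR-corrected neutrality calls.
#'
#' @param tab a [count_table()].
#' @param pool insertion pool data.frame.
#' @param merge_errors run the edit-distance barcode merge.
#' @param drop_outliers run the resistant diagnostic and drop flagged
#'   barcodes before the gene-level fit.
#' @param alpha FDR level for neutrality calls.
#' @param seed RNG seed for the stochastic stages (super-barcode grouping,
#'   kappa bootstrap, outlier resampling).
#' @param s_grid fitness grid for the likelihood.
#' @param rd_s_grid narrower grid used for per-barcode outlier likelihoods.
#' @param n_boot kappa bootstrap replicates.
#' @param ... further arguments to [process_counts()].
#' @return list with `fitness` (per-gene table), `noise` (the fitted
#'   [noise_model()]), `xbar` (mean-fitness series), `gene_sets`,
#'   `outlier_reports` (NULL unless `drop_outliers`).
#' @export
barseq_pipeline <- function(tab, pool, merge_errors = FALSE,
                            drop_outliers = FALSE, alpha = 0.05, seed = 1,
                            s_grid = default_s_grid(),
                            rd_s_grid = seq(-0.12, 0.12, by = 5e-4),
                            n_boot = 200, ...) {
  proc <- process_counts(tab, pool, merge_errors = merge_errors, ...)
  kap <- kappa_matrix(proc$intergenic, n_boot = n_boot,
                      seed = derive_seed(seed, "kappa"))
  noise <- decompose_noise(kap, tab$metadata$total_reads,
                           tab$metadata$transfer_index)
  xbar <- estimate_mean_fitness(
    build_superbarcodes(proc$intergenic, seed = derive_seed(seed, "super")))
  sets <- proc$gene_sets
  reports <- NULL
  if (drop_outliers) {
    reports <- lapply(sets, function(gs) {
      resistant_diagnostic(gs$counts, tab$metadata, noise, xbar,
                           seed = seed, gene = gs$gene, s_grid = rd_s_grid,
                           mask = gs$mask)
    })
    sets <- Filter(Negate(is.null), Map(function(gs, rep) {
      flag_outliers(gs, rep)
    }, sets, reports))
  }
  fitness <- infer_fitness(sets, tab$metadata, noise, xbar, s_grid,
                           alpha = alpha)
  list(fitness = fitness, noise = noise, xbar = xbar, gene_sets = sets,
       outlier_reports = reports)
}
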