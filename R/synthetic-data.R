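#' Configuration for a synthetic BarSeq experiment
#'
#' Collects the generative parameters of the assumed data-generating process:
#' exponential selection of rare lineages, genetic drift per transfer with
#' effective population size `Ne`, technical (measurement) noise of variance
#' `zeta` on the sqrt-frequency scale, and read sampling at depth `R_t`.
#'
#' @param n_genes number of genes.
#' @param barcodes_per_gene barcodes (independent insertions) per gene.
#' @param n_intergenic number of intergenic (neutral) barcodes.
#' @param s_values per-gene fitness (1/generation), recycled to `n_genes`.
#' @param outlier_spec optional data.frame with columns `gene` (index),
#'   `n_outliers`, `s_outlier`: within those genes, `n_outliers` barcodes
#'   carry the secondary fitness `s_outlier` instead of the gene's fitness.
#' @param Ne effective population size per transfer; drift adds variance
#'   `f/Ne` to a lineage frequency at each transfer.
#' @param zeta per-timepoint technical variance on the sqrt-frequency scale
#'   (recycled across timepoints). Interpreted as a variance, not an SD, so
#'   that variances add as in the error model. Includes the read-sampling
#'   floor `1/(4 R_t)`.
#' @param timepoints metadata data.frame as from [make_timepoints()].
#' @param f0_scale typical initial lineage frequency; initial frequencies are
#'   drawn log-uniformly on `[f0_scale/3, 3 f0_scale]`.
#' @param n_replicates number of replicate cultures sharing initial
#'   frequencies but with independent drift and noise after time 0.
#' @param seed RNG seed for the experiment.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, barcodes_per_gene = 20,
                       n_intergenic = 5000, s_values = 0,
                       outlier_spec = NULL,
                       Ne = 1e8, zeta = 2e-8,
                       timepoints = make_timepoints(4),
                       f0_scale = 2e-5, n_replicates = 1, seed = 1) {
  stopifnot(Ne > 0, all(zeta >= 0), all(timepoints$total_reads > 0))
  if (is.unsorted(timepoints$generations, strictly = TRUE)) {
    stop("generations must be strictly increasing")
  }
  n_lineages <- n_genes * barcodes_per_gene + n_intergenic
  if (3 * f0_scale * n_lineages > 1) {
    stop("total initial library frequency would exceed 1; reduce f0_scale")
  }
  structure(list(
    n_genes = n_genes, barcodes_per_gene = barcodes_per_gene,
    n_intergenic = n_intergenic,
    s_values = rep_len(s_values, n_genes),
    outlier_spec = outlier_spec,
    Ne = Ne, zeta = rep_len(zeta, nrow(timepoints)),
    timepoints = timepoints, f0_scale = f0_scale,
    n_replicates = n_replicates, seed = seed
  ), class = "sim_config")
}

#' Simulate lineage frequency trajectories
#'
#' Rare-lineage dynamics under the diffusion approximation
#' `df = s f dt + sqrt(f/Ne) dW`: deterministic exponential growth
#' `exp((s - xbar_t) t)` within each transfer, with a Gaussian drift kick of
#' variance `f/Ne` applied once per transfer (matching the error model, in
#' which drift variance accumulates per transfer). Frequencies are absorbing
#' at 0. Vectorized over lineages.
#'
#' @param s fitness per generation (scalar or per-lineage vector).
#' @param f0 initial frequency (scalar or per-lineage vector), in (0, 1).
#' @param Ne effective population size per transfer; `Inf` disables drift.
#' @param timepoints metadata data.frame (first row is time 0).
#' @param xbar per-timepoint mean fitness (1/generation, time-averaged from 0
#'   to t); the expected trajectory is `f0 * exp((s - xbar_t) t)`. Default 0.
#' @param seed optional RNG seed.
#' @return matrix of frequencies, lineages x timepoints (a vector if a single
#'   lineage is given).
#' @export
simulate_lineage_frequencies <- function(s, f0, Ne, timepoints, xbar = NULL,
                                         seed = NULL) {
  if (any(f0 >= 1) || any(f0 <= 0)) stop("f0 must be in (0, 1)")
  if (any(Ne <= 0)) stop("Ne must be positive")
  n <- max(length(s), length(f0))
  s <- rep_len(s, n); f0 <- rep_len(f0, n)
  tp <- timepoints
  nt <- nrow(tp)
  if (is.null(xbar)) xbar <- numeric(nt)
  sim <- function() {
    f <- matrix(0, n, nt)
    f[, 1] <- f0
    cur <- f0
    for (k in 2:nt) {
      dtr <- tp$transfer_index[k] - tp$transfer_index[k - 1]
      # cumulative discount over this interval from the mean-fitness series
      disc <- xbar[k] * tp$generations[k] - xbar[k - 1] * tp$generations[k - 1]
      gtot <- exp(s * (tp$generations[k] - tp$generations[k - 1]) - disc)
      if (dtr < 1) {
        cur <- cur * gtot
      } else {
        gstep <- gtot^(1 / dtr)
        for (j in seq_len(dtr)) {
          cur <- cur * gstep
          if (is.finite(Ne)) {
            cur <- pmax(0, cur + stats::rnorm(n, 0, sqrt(cur / Ne)))
          }
        }
      }
      f[, k] <- cur
    }
    f
  }
  f <- if (is.null(seed)) sim() else with_seed(seed, sim)
  rownames(f) <- names(s)
  if (n == 1) drop(f) else f
}

#' Add sqrt-scale measurement noise
#'
#' Observation model for technical noise: the observed sqrt-frequency is
#' Gaussian around the true sqrt-frequency with variance `zeta`
#' (`phi_obs ~ N(sqrt(f), zeta)`, `zeta` a variance), truncated at 0.
#'
#' @param f true frequencies.
#' @param zeta technical variance on the sqrt-frequency scale.
#' @param seed optional RNG seed.
#' @return observed sqrt-frequencies (same shape as `f`).
#' @export
add_measurement_noise <- function(f, zeta, seed = NULL) {
  stopifnot(zeta >= 0)
  draw <- function() pmax(0, sqrt(f) + stats::rnorm(length(f), 0, sqrt(zeta)))
  phi <- if (is.null(seed)) draw() else with_seed(seed, draw)
  if (is.matrix(f)) phi <- matrix(phi, nrow(f), ncol(f),
                                  dimnames = dimnames(f))
  phi
}

#' Sample read counts at a given depth
#'
#' Draws integer read counts with mean `R * f` and variance `c * R * f`:
#' Poisson when `c = 1`, negative binomial for `c > 1` (the linear
#' mean-variance family assumed by the likelihood).
#'
#' @param freqs per-lineage frequencies.
#' @param R sequencing depth (total reads).
#' @param c variance parameter, `var(r) = c * E[r]`; must be >= 1.
#' @param seed optional RNG seed.
#' @return integer counts, same shape as `freqs`.
#' @export
sample_read_counts <- function(freqs, R, c = 1, seed = NULL) {
  if (c < 1) stop("variance parameter c must be >= 1")
  stopifnot(R > 0)
  mu <- R * freqs
  draw <- function() {
    r <- numeric(length(mu))
    pos <- mu > 0
    if (c <= 1 + 1e-9) {
      r[pos] <- stats::rpois(sum(pos), mu[pos])
    } else {
      r[pos] <- stats::rnbinom(sum(pos), size = mu[pos] / (c - 1),
                               prob = 1 / c)
    }
    r
  }
  r <- if (is.null(seed)) draw() else with_seed(seed, draw)
  if (is.matrix(freqs)) r <- matrix(r, nrow(freqs), ncol(freqs),
                                    dimnames = dimnames(freqs))
  r
}

#' Generate a full synthetic BarSeq experiment
#'
#' Composes the generative steps into the data layout the pipeline consumes:
#' per-replicate [count_table]s sharing lineage identities and initial
#' frequencies (independent drift/noise after time 0), a pool table mapping
#' barcodes to genes or intergenic status, and a ground-truth table.
#'
#' The population mean-fitness trajectory is computed deterministically from
#' the configured fitness values and initial frequencies (treating the
#' library as the population), and every lineage's expected trajectory is
#' discounted by it. Since the configured technical variance `zeta_t`
#' includes the read-sampling floor, sqrt-scale Gaussian noise with variance
#' `max(0, zeta_t - 1/(4 R_t))` is added before Poisson read sampling at
#' depth `R_t`, so the realized total technical variance equals `zeta_t`.
#'
#' @param config a [sim_config()].
#' @return list with elements `replicates` (list of `count_table`), `pool`,
#'   `truth` (lineage, gene, s_true, outlier, f0), `xbar_true` (per-timepoint
#'   mean fitness used in generation), and `config`.
#' @export
build_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tp <- cf$timepoints
  nt <- nrow(tp)
  n_gene_bc <- cf$n_genes * cf$barcodes_per_gene

  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  bc_gene <- paste0(rep(gene_ids, each = cf$barcodes_per_gene), "_bc",
                    sprintf("%02d", rep(seq_len(cf$barcodes_per_gene),
                                        cf$n_genes)))
  bc_int <- sprintf("int%06d", seq_len(cf$n_intergenic))
  lineage <- c(bc_gene, bc_int)
  gene_of <- c(rep(gene_ids, each = cf$barcodes_per_gene),
               rep(NA_character_, cf$n_intergenic))

  s_true <- c(rep(cf$s_values, each = cf$barcodes_per_gene),
              numeric(cf$n_intergenic))
  outlier <- logical(length(lineage))
  if (!is.null(cf$outlier_spec)) {
    for (i in seq_len(nrow(cf$outlier_spec))) {
      g <- cf$outlier_spec$gene[i]
      k <- cf$outlier_spec$n_outliers[i]
      idx <- (g - 1) * cf$barcodes_per_gene + seq_len(k)
      s_true[idx] <- cf$outlier_spec$s_outlier[i]
      outlier[idx] <- TRUE
    }
  }

  out <- with_seed(cf$seed, function() {
    f0 <- cf$f0_scale * exp(stats::runif(length(lineage), log(1 / 3), log(3)))
    if (sum(f0) > 1) stop("total initial frequency exceeds 1")
    # deterministic mean fitness of the library: xbar_t * t = log W(t)/W(0)
    W <- vapply(tp$generations,
                function(t) sum(f0 * exp(s_true * t)) / sum(f0), 0)
    xbar <- ifelse(tp$generations > 0, log(W) / tp$generations, 0)
    reps <- lapply(seq_len(cf$n_replicates), function(rep_i) {
      f <- simulate_lineage_frequencies(s_true, f0, cf$Ne, tp, xbar = xbar)
      counts <- matrix(0, length(lineage), nt, dimnames = list(lineage, NULL))
      for (k in seq_len(nt)) {
        zt <- max(0, cf$zeta[k] - 1 / (4 * tp$total_reads[k]))
        phi <- add_measurement_noise(f[, k], zt)
        counts[, k] <- sample_read_counts(phi^2, tp$total_reads[k], c = 1)
      }
      count_table(counts, tp)
    })
    list(reps = reps, f0 = f0, xbar = xbar)
  })

  n_total <- length(lineage)
  frac <- rep(NA_real_, n_total)
  frac[seq_len(n_gene_bc)] <- with_seed(derive_seed(cf$seed, "pool"),
    function() stats::runif(n_gene_bc, 0.06, 0.94))
  pool <- data.frame(
    barcode = lineage,
    position = seq_len(n_total) * 1000L,
    gene = gene_of,
    frac_within_gene = frac,
    intergenic = is.na(gene_of)
  )
  truth <- data.frame(lineage = lineage, gene = gene_of, s_true = s_true,
                      outlier = outlier, f0 = out$f0)
  list(replicates = out$reps, pool = pool, truth = truth,
       xbar_true = out$xbar, config = cf)
}

#' Benchmark simulation for the outlier detector
#'
#' Simulates the generative process used to calibrate the resistant
#' diagnostic: genes of `n_lineages` lineages containing `n_outliers` planted
#' lineages of fitness `s_outlier` (same sign within a gene) among neutrals,
#' observed at the end of each of `days` daily transfers of
#' `log2(100) ~ 6.64` generations, with drift at `Ne` per day and sqrt-scale
#' Gaussian measurement noise of variance `zeta`. Observed sqrt-frequencies
#' are converted to integer read counts at depth `R` by rounding
#' (`round(R * phi_obs^2)`), whose extra variance is negligible at the
#' working point of several hundred reads; the matching count-variance
#' parameter is `c = (4 zeta + 1/Ne) R`.
#'
#' @param n_genes number of simulated genes; the planted configurations
#'   (`n_outliers` in 1:3, `s_outlier` = +/-0.02) are cycled across genes.
#' @param seed RNG seed.
#' @param n_lineages lineages per gene.
#' @param s_outlier absolute secondary fitness of planted lineages.
#' @param Ne,zeta drift and technical-noise parameters.
#' @param days number of daily observations after time 0.
#' @param R read depth per timepoint.
#' @param f0_scale typical initial lineage frequency.
#' @return list with `genes` (list of count matrices, lineages x timepoints),
#'   `truth` (gene, lineage, s_true, outlier), `metadata` (timepoints) and
#'   `noise` (a [noise_model()]).
#' @export
build_outlier_benchmark <- function(n_genes = 60, seed = 1, n_lineages = 20,
                                    s_outlier = 0.02, Ne = 1e8, zeta = 2e-8,
                                    days = 4, R = 2e7, f0_scale = 2e-5) {
  tp <- make_timepoints(days, dilution = 100, total_reads = R)
  spec <- expand.grid(n_out = 1:3, sgn = c(1, -1))
  spec <- spec[rep(seq_len(nrow(spec)), length.out = n_genes), ]
  genes <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("sim%04d", g)
    s <- numeric(n_lineages)
    s[seq_len(spec$n_out[g])] <- spec$sgn[g] * s_outlier
    counts <- with_seed(derive_seed(seed, gid), function() {
      f0 <- f0_scale * exp(stats::runif(n_lineages, log(1 / 3), log(3)))
      f <- simulate_lineage_frequencies(s, f0, Ne, tp)
      phi <- add_measurement_noise(f, zeta)
      round(R * phi^2)
    })
    rownames(counts) <- paste0(gid, "_bc", sprintf("%02d", seq_len(n_lineages)))
    genes[[g]] <- counts
    truth[[g]] <- data.frame(gene = gid, lineage = rownames(counts),
                             s_true = s, outlier = s != 0)
  }
  noise <- noise_model(zeta_t = rep(zeta, days + 1), Ne = Ne,
                       R_t = tp$total_reads)
  list(genes = genes, truth = do.call(rbind, truth), metadata = tp,
       noise = noise)
}
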