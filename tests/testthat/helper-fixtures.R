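# Shared fixtures: a standard 4-cycle serial-dilution design with the
# benchmark noise parameters, and a generator for single-gene count
# matrices under the full generative model.

tp_default <- function(n_cycles = 4, R = 2e7) {
  make_timepoints(n_cycles, dilution = 100, total_reads = R)
}

nm_default <- function(tp = tp_default(), zeta = 2e-8, Ne = 1e8) {
  noise_model(rep(zeta, nrow(tp)), Ne, tp$total_reads)
}

# Counts for one gene of n_bc barcodes with fitness s_true: diffusion with
# drift, sqrt-scale Gaussian noise, rounded to integer counts at depth R.
sim_gene_counts <- function(s_true, n_bc = 4, seed = 1, tp = tp_default(),
                            Ne = 1e8, zeta = 2e-8, f0_scale = 2e-5) {
  R <- tp$total_reads[1]
  with_seed_local(seed, {
    f0 <- f0_scale * exp(stats::runif(n_bc, log(1 / 3), log(3)))
    f <- simulate_lineage_frequencies(rep(s_true, n_bc), f0, Ne, tp)
    if (n_bc == 1) f <- matrix(f, 1)
    phi <- add_measurement_noise(f, zeta)
    m <- round(R * phi^2)
    rownames(m) <- sprintf("bc%02d", seq_len(n_bc))
    m
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Small count_table around fixed frequencies (deterministic counts).
det_count_table <- function(freqs, tp = tp_default()) {
  m <- round(outer(freqs, rep(1, nrow(tp))) * rep(tp$total_reads,
                                                  each = length(freqs)))
  rownames(m) <- sprintf("bc%04d", seq_along(freqs))
  count_table(m, tp)
}
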