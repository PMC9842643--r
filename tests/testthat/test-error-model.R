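# Neutral count table in which the sqrt-frequency noise at each timepoint is
# Gaussian with known variance, so kappa has a known target.
noisy_neutral_table <- function(n = 5000, v = 2e-8, f0 = 2e-4, R = 1e6,
                                nt = 2, seed = 1) {
  tp <- tp_default(nt - 1, R = R)
  cm <- with_seed_local(seed, {
    sapply(seq_len(nt), function(k) {
      phi <- sqrt(f0) + rnorm(n, 0, sqrt(v))
      round(R * phi^2)
    })
  })
  rownames(cm) <- sprintf("i%05d", seq_len(n))
  count_table(cm, tp)
}

test_that("vst is the square root and rejects negatives", {
  expect_equal(vst(c(0, 0.04, 1)), c(0, 0.2, 1))
  expect_error(vst(-1), "nonnegative")
})

test_that("kappa recovers the variance of Gaussian sqrt-scale differences", {
  v <- 2e-8
  tab <- noisy_neutral_table(v = v, seed = 2)
  est <- estimate_kappa(tab, 1, 2, n_boot = 100, seed = 1)
  # psi = phi1 - phi2 has variance ~ 2v (plus small rounding noise)
  expect_equal(est$kappa, 2 * v, tolerance = 0.1)
  expect_true(est$var_kappa > 0)
  expect_gt(est$n, 1000)
})

test_that("kappa is zero for identical timepoints and robust to outliers", {
  tp <- tp_default(1, R = 1e6)
  cm <- matrix(rep(200, 400), 200, 2)
  rownames(cm) <- sprintf("i%03d", 1:200)
  same <- count_table(cm, tp)
  expect_equal(estimate_kappa(same, 1, 2, n_boot = 10)$kappa, 0)

  tab <- noisy_neutral_table(v = 2e-8, seed = 3)
  clean <- estimate_kappa(tab, 1, 2, n_boot = 10, seed = 1)$kappa
  # contaminate 10% of barcodes at timepoint 2 with gross frequency shifts
  cm <- tab$counts
  idx <- seq_len(nrow(cm) %/% 10)
  cm[idx, 2] <- round(cm[idx, 2] * 2.2)  # stays within the 50-500 filter
  dirty <- count_table(cm, tab$metadata)
  kap_dirty <- estimate_kappa(dirty, 1, 2, n_boot = 10, seed = 1)$kappa
  expect_equal(kap_dirty, clean, tolerance = 0.15)
  # a plain variance blows up by much more
  psi_all <- vst(cm[, 1] / 1e6) - vst(cm[, 2] / 1e6)
  keep <- cm[, 1] > 50 & cm[, 1] < 500 & cm[, 2] > 50 & cm[, 2] < 500
  expect_gt(var(psi_all[keep]) / clean, 2)
})

test_that("kappa estimation refuses tiny samples and the matrix is symmetric", {
  tab <- noisy_neutral_table(n = 50, seed = 4)
  expect_error(estimate_kappa(tab, 1, 2), "pass the count filter")
  tab <- noisy_neutral_table(n = 800, nt = 3, seed = 5)
  kap <- kappa_matrix(tab, n_boot = 50, seed = 1)
  expect_equal(kap, t(kap))
  expect_equal(diag(kap), rep(0, 3))
})

test_that("noise decomposition solves the noiseless inverse problem exactly", {
  zeta <- c(1e-8, 2e-8, 1.5e-8, 1e-8)
  inv4ne <- 5e-9                       # |j-k|/(4 Ne) coefficient
  kap <- outer(zeta, zeta, "+") + abs(outer(0:3, 0:3, "-")) * inv4ne
  diag(kap) <- 0
  nm <- decompose_noise(kap, R_t = rep(1e9, 4))
  expect_equal(nm$zeta_t, zeta, tolerance = 1e-3)
  expect_equal(1 / (4 * nm$Ne), inv4ne, tolerance = 1e-3)
  expect_lt(attr(nm, "objective"), 1e-21)
  expect_equal(nm$c_t, (4 * nm$zeta_t + 1 / nm$Ne) * 1e9, tolerance = 1e-12)
})

test_that("pairwise-equal kappa drives drift to zero", {
  kap <- matrix(4e-8, 4, 4); diag(kap) <- 0
  nm <- decompose_noise(kap, R_t = rep(1e9, 4))
  expect_lt(1 / nm$Ne, 1e-12)
  expect_equal(nm$zeta_t, rep(2e-8, 4), tolerance = 1e-3)
  expect_true(all(nm$c_t >= 1 - 1e-9) || all(nm$c_t >= 0))
})

test_that("noise parameters are recovered from a synthetic neutral class", {
  cfg <- sim_config(n_genes = 1, barcodes_per_gene = 4, n_intergenic = 6000,
                    Ne = 1e8, zeta = 2e-8, seed = 7)
  ex <- build_experiment(cfg)
  tab <- ex$replicates[[1]]
  neutral <- count_table(
    tab$counts[ex$pool$barcode[ex$pool$intergenic], ], tab$metadata)
  kap <- kappa_matrix(neutral, n_boot = 100, seed = 2)
  nm <- decompose_noise(kap, tab$metadata$total_reads,
                        tab$metadata$transfer_index)
  expect_equal(nm$zeta_t, rep(2e-8, 5), tolerance = 0.2)
  expect_equal(1 / nm$Ne, 1e-8, tolerance = 0.3)
  expect_true(all(nm$c_t >= 1))
})

test_that("stratified kappa flags a planted noisy stratum", {
  tab <- noisy_neutral_table(n = 3000, v = 2e-8, seed = 8)
  groups <- rep(c("low_gc", "high_gc"), length.out = 3000)
  # single stratum reduces to the plain estimator
  one <- stratified_kappa(tab, rep("all", 3000), n_boot = 20, seed = 1)
  plain <- estimate_kappa(tab, 1, 2, n_boot = 20,
                          seed = barseqfit:::derive_seed(1, "all"))
  expect_equal(one$kappa, plain$kappa)
  # no bias: strata agree within bootstrap error
  res <- stratified_kappa(tab, groups, n_boot = 100, seed = 1)
  expect_lt(abs(diff(res$kappa)) / sqrt(sum(res$var_kappa)), 4)
  # plant 2x extra variance in one stratum at one timepoint
  cm <- tab$counts
  hi <- which(groups == "high_gc")
  cm[hi, 2] <- with_seed_local(9, {
    phi <- sqrt(cm[hi, 2] / 1e6) + rnorm(length(hi), 0, sqrt(2e-8))
    round(1e6 * pmax(phi, 0)^2)
  })
  res2 <- stratified_kappa(count_table(cm, tab$metadata), groups,
                           n_boot = 100, seed = 1)
  expect_gt(res2$kappa[res2$stratum == "high_gc"],
            1.4 * res2$kappa[res2$stratum == "low_gc"])
  # undersized strata are reported missing, not estimated
  small <- stratified_kappa(tab, c(rep("tiny", 40), rep("rest", 2960)),
                            n_boot = 10, seed = 1)
  expect_true(is.na(small$kappa[small$stratum == "tiny"]))
})
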