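test_that("lineage frequencies follow the deterministic dynamics when drift is off", {
  tp <- tp_default(2)
  # s = 0, no drift: constant trajectory
  f <- simulate_lineage_frequencies(0, 1e-5, Inf, tp)
  expect_equal(unname(f), rep(1e-5, 3))
  # closed form of the mean dynamics over one cycle
  f <- simulate_lineage_frequencies(0.02, 1e-5, Inf, tp)
  expect_equal(unname(f[2]), 1e-5 * exp(0.02 * log2(100)), tolerance = 1e-12)
  # mean-fitness discount shifts the exponent
  xb <- c(0, 0.01, 0.01)
  f <- simulate_lineage_frequencies(0.02, 1e-5, Inf, tp, xbar = xb)
  expect_equal(unname(f[3]),
               1e-5 * exp((0.02 - 0.01) * tp$generations[3]),
               tolerance = 1e-12)
  expect_error(simulate_lineage_frequencies(0, 1.5, Inf, tp), "f0")
  expect_error(simulate_lineage_frequencies(0, 1e-5, -1, tp), "Ne")
})

test_that("drift variance after one transfer matches the diffusion scale f0/Ne", {
  tp <- tp_default(1)
  f0 <- 1e-4; Ne <- 1e6
  f <- simulate_lineage_frequencies(numeric(20000), rep(f0, 20000), Ne, tp,
                                    seed = 42)
  v <- var(f[, 2])
  expect_equal(v, f0 / Ne, tolerance = 0.1)
  expect_true(all(f >= 0))
})

test_that("measurement noise has the configured sqrt-scale variance", {
  expect_equal(add_measurement_noise(c(0.04, 0.25), 0), c(0.2, 0.5))
  phi <- add_measurement_noise(rep(0, 1000), 1e-8, seed = 1)
  expect_true(mean(phi) < 1e-4)  # mean 0 up to truncation
  phi <- add_measurement_noise(rep(1e-4, 1e5), 2e-8, seed = 2)
  expect_equal(var(phi), 2e-8, tolerance = 0.05)
  expect_equal(mean(phi), 1e-2, tolerance = 1e-3)
})

test_that("read counts have the requested mean-variance relationship", {
  expect_identical(sample_read_counts(0, 1e7, c = 2), 0)
  r <- sample_read_counts(rep(2e-7, 1e5), 1e7, c = 1, seed = 3)  # mu = 2
  expect_equal(mean(r == 0), exp(-2), tolerance = 0.02)
  r <- sample_read_counts(rep(5e-7, 1e5), 1e7, c = 2, seed = 4)  # mu = 5
  expect_equal(mean(r), 5, tolerance = 0.01)
  expect_equal(var(r), 10, tolerance = 0.05)
  expect_error(sample_read_counts(1e-5, 1e7, c = 0.5), "c must be")
})

test_that("build_experiment composes the generative stages coherently", {
  cfg <- sim_config(n_genes = 3, barcodes_per_gene = 5, n_intergenic = 50,
                    s_values = c(0.05, 0, 0), Ne = Inf, zeta = 0,
                    f0_scale = 2e-5, n_replicates = 2, seed = 11)
  ex <- build_experiment(cfg)
  expect_length(ex$replicates, 2)
  expect_equal(nrow(ex$truth), 3 * 5 + 50)
  # every emitted lineage appears exactly once in the truth table
  expect_setequal(rownames(ex$replicates[[1]]$counts), ex$truth$lineage)
  expect_false(any(duplicated(ex$truth$lineage)))
  # intergenic lineages are neutral and the library stays rare
  expect_true(all(ex$truth$s_true[is.na(ex$truth$gene)] == 0))
  expect_lt(sum(ex$truth$f0), 0.1)
  # zeta = 0, Ne = Inf: counts are Poisson around the deterministic
  # trajectory; neutral lineages stay near f0 * R
  tab <- ex$replicates[[1]]
  neut <- ex$truth$lineage[ex$truth$s_true == 0]
  expected <- ex$truth$f0[match(neut, ex$truth$lineage)] *
    tab$metadata$total_reads[1]
  dev <- (tab$counts[neut, 1] - expected) / sqrt(expected)
  expect_lt(abs(mean(dev)), 0.2)
  expect_equal(sd(dev), 1, tolerance = 0.25)
  # selected gene: summed-barcode log-frequency slope tracks s - xbar
  sel <- ex$truth$lineage[!is.na(ex$truth$gene) & ex$truth$gene == "g0001"]
  traj <- colSums(tab$counts[sel, ]) / tab$metadata$total_reads
  slope <- coef(lm(log(traj) ~ tab$metadata$generations))[2]
  expect_equal(unname(slope) + mean(diff(ex$xbar_true *
                                           tab$metadata$generations) /
                                      diff(tab$metadata$generations)),
               0.05, tolerance = 0.01)
})

test_that("build_experiment is deterministic for a fixed seed", {
  cfg <- sim_config(n_genes = 2, barcodes_per_gene = 4, n_intergenic = 30,
                    seed = 9)
  a <- build_experiment(cfg)
  b <- build_experiment(cfg)
  expect_identical(a$replicates[[1]]$counts, b$replicates[[1]]$counts)
  expect_identical(a$truth, b$truth)
  expect_error(sim_config(n_genes = 10, barcodes_per_gene = 100,
                          n_intergenic = 1e6, f0_scale = 1e-4),
               "exceed 1")
})

test_that("the outlier benchmark has the stated planted structure", {
  bench <- build_outlier_benchmark(n_genes = 12, seed = 3)
  expect_length(bench$genes, 12)
  per_gene <- tapply(bench$truth$outlier, bench$truth$gene, sum)
  expect_setequal(unique(per_gene), 1:3)
  expect_true(all(tapply(bench$truth$outlier, bench$truth$gene, length) == 20))
  # planted lineages drift by ~ s * t over the four days
  t_final <- bench$metadata$generations[5]
  chg <- unlist(lapply(seq_along(bench$genes), function(g) {
    cm <- bench$genes[[g]]
    out <- bench$truth$outlier[bench$truth$gene ==
                                 sprintf("sim%04d", g)]
    s <- bench$truth$s_true[bench$truth$gene == sprintf("sim%04d", g)]
    log(cm[out, 5] / cm[out, 1]) / sign(s[out])
  }))
  expect_equal(mean(chg), 0.02 * t_final, tolerance = 0.25)
  # derived count-variance parameter matches (4 zeta + 1/Ne) R
  expect_equal(bench$noise$c_t, rep((4 * 2e-8 + 1e-8) * 2e7, 5))
})
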