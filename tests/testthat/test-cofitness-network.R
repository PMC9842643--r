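# Independent scalar implementation of the weighted correlation, written
# directly from the defining sums.
wp_oracle <- function(x, y, w) {
  mu <- function(v) sum(w * v) / sum(w)
  wc <- function(a, b) sum(w * (a - mu(a)) * (b - mu(b))) / sum(w)
  wc(x, y) / sqrt(wc(x, x) * wc(y, y))
}

test_that("weighted Pearson matches limits and the direct-sum oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(weighted_pearson(x, 2 * x), 1)
  expect_equal(weighted_pearson(x, -x), -1)
  expect_equal(weighted_pearson(c(1, 2, 3), c(1, 3, 2), w = c(1, 1, 10)),
               wp_oracle(c(1, 2, 3), c(1, 3, 2), c(1, 1, 10)),
               tolerance = 1e-14)
  # equal weights reduce to the unweighted correlation
  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(weighted_pearson(a, b), cor(a, b), tolerance = 1e-12)
  }
  # random weighted cases against the oracle
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10); w <- rexp(10)
    expect_equal(weighted_pearson(a, b, w = w), wp_oracle(a, b, w),
                 tolerance = 1e-12)
  }
  expect_true(is.na(weighted_pearson(c(1, 1, 1), c(1, 2, 3))))  # zero variance
  expect_true(is.na(weighted_pearson(c(1, 2), c(1, 2))))        # < 3 pairs
})

fm_fixture <- function(s, se, q = NULL) {
  envs <- paste0("e", seq_len(ncol(s)))
  tabs <- lapply(seq_along(envs), function(k) {
    data.frame(gene = rownames(s), s_hat = s[, k], se = se[, k],
               p = if (is.null(q)) 0.5 else q[, k],
               q = if (is.null(q)) 0.5 else q[, k], n_barcodes = 5)
  })
  names(tabs) <- envs
  fitness_matrix(tabs)
}

test_that("cofitness matrix applies inclusion filters and symmetry", {
  set.seed(7)
  s <- matrix(rnorm(6 * 6, sd = 0.02), 6, 6,
              dimnames = list(paste0("g", 1:6), NULL))
  s[6, ] <- s[5, ]                     # duplicate of gene 5
  se <- matrix(0.002, 6, 6, dimnames = dimnames(s))
  q <- matrix(0.01, 6, 6)
  q[2, ] <- 0.9                        # gene 2 significant nowhere
  s[3, 3:6] <- NA                      # gene 3 measured in < 4 environments
  fm <- fm_fixture(s, se, q)
  rho <- cofitness_matrix(fm)
  expect_false("g2" %in% rownames(rho))
  expect_false("g3" %in% rownames(rho))
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), setNames(rep(1, nrow(rho)), rownames(rho)))
  expect_equal(rho["g5", "g6"], 1, tolerance = 1e-9)
})

test_that("edge null p-values hit the plus-one floor for identical profiles", {
  x <- c(-0.05, -0.02, 0.01, 0.03, 0.06, 0.09, -0.08, 0.04, 0.02, -0.03)
  ep <- edge_null_pvalue(x, x, rep(1e-4, 10), rep(1e-4, 10),
                         n_resample = 300, seed = 1)
  expect_equal(ep$rho, 1, tolerance = 1e-6)
  expect_equal(ep$p, 1 / 301)
})

test_that("edge null p-values are calibrated and lose power with noise", {
  set.seed(9)
  ps <- replicate(150, {
    x <- rnorm(8, sd = 0.02); y <- rnorm(8, sd = 0.02)
    edge_null_pvalue(x, y, rep(1e-3, 8), rep(1e-3, 8), n_resample = 100,
                     seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.13)
  # a noisier measurement of the same underlying profile loses power
  set.seed(10)
  p_pair <- replicate(25, {
    x <- rnorm(10, sd = 0.03)
    y_lo <- x + rnorm(10, sd = 0.003)
    y_hi <- x + rnorm(10, sd = 0.03)
    c(lo = edge_null_pvalue(x, y_lo, rep(0.002, 10), rep(0.003, 10),
                            n_resample = 200, seed = sample.int(1e6, 1))$p,
      hi = edge_null_pvalue(x, y_hi, rep(0.002, 10), rep(0.03, 10),
                            n_resample = 200, seed = sample.int(1e6, 1))$p)
  })
  expect_gt(mean(p_pair["hi", ]), mean(p_pair["lo", ]))
})

test_that("fluid communities recover planted cliques and score sensibly", {
  cl_a <- t(combn(paste0("a", 1:8), 2))
  cl_b <- t(combn(paste0("b", 1:8), 2))
  edges <- data.frame(gene_a = c(cl_a[, 1], cl_b[, 1], "a1"),
                      gene_b = c(cl_a[, 2], cl_b[, 2], "b1"))
  cm <- detect_communities(edges, k_range = 2, reps_per_k = 20, seed = 4)
  m <- cm$membership
  expect_length(unique(m[paste0("a", 1:8)]), 1)
  expect_length(unique(m[paste0("b", 1:8)]), 1)
  expect_false(m["a1"] == m["b1"])
  expect_gt(cm$modularity, 0.4)
  # complete graph: no structure, modularity near zero for any partition
  full <- t(combn(paste0("x", 1:12), 2))
  cmf <- detect_communities(data.frame(gene_a = full[, 1],
                                       gene_b = full[, 2]),
                            k_range = 2:4, reps_per_k = 10, seed = 4)
  expect_lt(abs(cmf$modularity), 0.1)
  # fixed seed reproduces the partition
  cm2 <- detect_communities(edges, k_range = 2, reps_per_k = 20, seed = 4)
  expect_identical(cm$membership, cm2$membership)
})

test_that("cluster overlap behaves like a conditional collision probability", {
  pa <- setNames(rep(1:4, each = 50), paste0("g", 1:200))
  expect_equal(cluster_overlap(pa, pa), 1)
  # uniform random relabeling into 4 groups: expected sum of squared fractions
  pb <- setNames(with_seed_local(2, sample(1:4, 200, replace = TRUE)),
                 names(pa))
  expect_equal(cluster_overlap(pa, pb), 0.25, tolerance = 0.3)
  singles <- setNames(seq_len(200), names(pa))
  expect_true(is.na(cluster_overlap(singles, pa)))
})

test_that("planted correlated blocks are recovered from a fitness matrix", {
  skip_if_not_installed("mclust")
  set.seed(21)
  n_block <- 4; per_block <- 12; n_env <- 12
  latent <- matrix(rnorm(n_block * n_env, sd = 0.04), n_block, n_env)
  s <- latent[rep(1:n_block, each = per_block), ] +
    rnorm(n_block * per_block * n_env, sd = 0.003)
  rownames(s) <- sprintf("g%02d", seq_len(n_block * per_block))
  se <- matrix(0.002, nrow(s), n_env, dimnames = dimnames(s))
  fm <- fm_fixture(s, se, q = matrix(0.01, nrow(s), n_env))
  net <- cofitness_network(fm, n_resample = 300, seed = 3)
  cm <- detect_communities(net, k_range = 2:6, reps_per_k = 100, seed = 3)
  truth <- rep(1:n_block, each = per_block)
  ari <- mclust::adjustedRandIndex(cm$membership[rownames(s)], truth)
  expect_gt(ari, 0.8)
  expect_gt(cm$modularity, 0)
})
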