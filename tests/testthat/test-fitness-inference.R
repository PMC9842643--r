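# Direct Gamma-form evaluation of the overdispersed-count pmf, written out
# independently of the package implementation.
nb_pmf_direct <- function(r, mu, c) {
  k <- mu / (c - 1)
  exp(lgamma(r + k) - lgamma(k) - lgamma(r + 1)) * (c - 1)^r / c^(r + k)
}

test_that("the count likelihood is a normalized pmf with the right limits", {
  expect_lt(abs(sum(exp(nb_loglik(0:500, mu = 3, c = 2))) - 1), 1e-10)
  # Poisson limit at c -> 1
  expect_equal(nb_loglik(0, mu = 2, c = 1), -2)
  expect_equal(nb_loglik(0:20, 2, 1 + 1e-9), dpois(0:20, 2, log = TRUE))
  expect_equal(nb_loglik(0:20, 2, 1 + 1e-5),
               dpois(0:20, 2, log = TRUE), tolerance = 1e-3)
  # brute-force oracle for the Gamma form
  expect_equal(nb_loglik(5, mu = 5, c = 2), log(nb_pmf_direct(5, 5, 2)),
               tolerance = 1e-12)
  expect_equal(nb_loglik(17, mu = 6.5, c = 3.2),
               log(nb_pmf_direct(17, 6.5, 3.2)), tolerance = 1e-12)
  expect_error(nb_loglik(-1, 2, 2), "nonnegative")
  expect_error(nb_loglik(1, 2, 0.5), ">= 1")
})

test_that("a single timepoint leaves fitness unidentifiable (flat curve)", {
  ll <- integrated_loglik(400, seq(-0.1, 0.1, 0.01), generations = 0,
                          R_t = 2e7, c_t = 1.8)
  expect_equal(max(ll) - min(ll), 0)
})

test_that("the MLE recovers fitness from a noiseless trajectory", {
  tp <- tp_default()
  nm <- nm_default(tp)
  r <- round(2e7 * 2e-5 * exp(0.05 * tp$generations))
  fit <- mle_fitness(matrix(r, 1, dimnames = list("b", NULL)), tp, nm,
                     s_grid = seq(-0.15, 0.15, 5e-4))
  expect_equal(fit$estimate$s_hat, 0.05, tolerance = 0.01)
  expect_false(fit$estimate$boundary)
  expect_lt(fit$estimate$p, 1e-10)

  # all barcodes constant, xbar = 0: estimate is 0 within grid resolution
  cm <- matrix(rep(400, 4 * 5), 4, 5,
               dimnames = list(paste0("b", 1:4), NULL))
  fit0 <- mle_fitness(cm, tp, nm, s_grid = seq(-0.05, 0.05, 5e-4))
  expect_equal(fit0$estimate$s_hat, 0, tolerance = 2e-3)
})

test_that("information scales with depth: maximizer fixed, curvature grows", {
  tp <- tp_default()
  nm <- nm_default(tp)
  r <- round(2e7 * 2e-5 * exp(0.03 * tp$generations))
  g <- seq(-0.1, 0.1, 5e-4)
  f1 <- mle_fitness(matrix(r, 1, dimnames = list("b", NULL)), tp, nm,
                    s_grid = g)
  tp2 <- tp; tp2$total_reads <- tp$total_reads * 2
  nm2 <- noise_model(nm$zeta_t / 2, 1e16, tp2$total_reads)  # same c_t scale
  nm2$c_t <- nm$c_t
  f2 <- mle_fitness(matrix(2 * r, 1, dimnames = list("b", NULL)), tp2, nm2,
                    s_grid = g)
  expect_lt(abs(f2$estimate$s_hat - f1$estimate$s_hat), 2e-3)
  expect_lt(f2$estimate$se, f1$estimate$se)
})

test_that("likelihood curves are invariant to additive constants", {
  g <- seq(-0.1, 0.1, 5e-4)
  ll <- -((g - 0.02) / 0.005)^2 / 2
  a <- barseqfit:::mle_from_curve(g, ll)
  b <- barseqfit:::mle_from_curve(g, ll + 123.4)
  expect_equal(a$s_hat, b$s_hat)
  expect_equal(a$se, b$se)
  # p is invariant up to rounding of the boundary grid cell where the
  # log-likelihood ratio crosses zero
  ll2 <- -((g - 0.005) / 0.004)^2 / 2
  p1 <- neutrality_pvalue(likelihood_curve(g, ll2))
  p2 <- neutrality_pvalue(likelihood_curve(g, ll2 + 123.4))
  expect_lt(abs(p1 - p2), 0.01)
  expect_gt(p1, 0.05)  # a mildly non-zero peak is not overwhelming evidence
})

test_that("replicate combination multiplies likelihoods", {
  g <- seq(-0.1, 0.1, 5e-4)
  gauss <- function(mu, sd) likelihood_curve(g, -((g - mu) / sd)^2 / 2)
  cv <- gauss(0.02, 0.005)
  # combining a curve with itself: same maximizer, doubled curvature
  both <- combine_replicates(list(cv, cv))
  a <- barseqfit:::mle_from_curve(g, cv$loglik)
  b <- barseqfit:::mle_from_curve(g, both$loglik)
  expect_equal(b$s_hat, a$s_hat, tolerance = 1e-6)
  expect_equal(b$se, a$se / sqrt(2), tolerance = 1e-6)
  # combining with a flat curve is the identity
  flat <- likelihood_curve(g, rep(1.5, length(g)))
  expect_equal(combine_replicates(list(cv, flat))$loglik - 1.5, cv$loglik)
  # equal curvatures peaked at 0.01 and 0.03 combine to 0.02
  mid <- combine_replicates(list(gauss(0.01, 0.005), gauss(0.03, 0.005)))
  expect_equal(barseqfit:::mle_from_curve(g, mid$loglik)$s_hat, 0.02,
               tolerance = 1e-6)
  expect_error(combine_replicates(list()), "no curves")
  # replicate combination shrinks the SE of a real fit
  tp <- tp_default()
  nm <- nm_default(tp)
  c1 <- sim_gene_counts(0.02, n_bc = 4, seed = 31)
  c2 <- sim_gene_counts(0.02, n_bc = 4, seed = 32)
  g2 <- seq(-0.12, 0.12, 5e-4)
  f1 <- mle_fitness(c1, tp, nm, s_grid = g2)
  f2 <- mle_fitness(c2, tp, nm, s_grid = g2)
  comb <- combine_replicates(list(f1$curve, f2$curve))
  ec <- barseqfit:::mle_from_curve(comb$s, comb$loglik)
  expect_lt(ec$se, min(f1$estimate$se, f2$estimate$se))
})

test_that("the neutrality p-value follows the posterior-LLR definition", {
  g <- seq(-0.1, 0.1, 5e-4)
  # flat curve: no grid point strictly beats s = 0, so p = 0
  expect_equal(neutrality_pvalue(likelihood_curve(g, rep(2, length(g)))), 0)
  # brute-force evaluation of the discretized definition as the oracle
  ll <- -((g - 0.011) / 0.004)^2 / 2 + 7
  post <- exp(ll - max(ll)); post <- post / sum(post)
  ll0 <- ll[g == 0]
  p_oracle <- sum(post[ll0 - ll > 0])
  expect_equal(neutrality_pvalue(likelihood_curve(g, ll)), p_oracle)
  # maximizer 10 SE from zero: overwhelming evidence
  ll10 <- -((g - 0.05) / 0.005)^2 / 2
  expect_lt(neutrality_pvalue(likelihood_curve(g, ll10)), 1e-6)
  # grid not containing zero gets extended
  gpos <- seq(0.01, 0.1, 5e-4)
  expect_lt(neutrality_pvalue(likelihood_curve(gpos,
                                               -((gpos - 0.05) / 0.005)^2 / 2)),
            1e-6)
})

test_that("BH correction matches the hand-computed step-up rule", {
  fc <- fdr_correct(c(0.01, 0.02, 0.03, 0.2), alpha = 0.05)
  # thresholds i * 0.05 / 4: 0.0125, 0.025, 0.0375, 0.05 -> 3 rejections
  expect_equal(sum(fc$significant), 3)
  expect_equal(fc$q, p.adjust(c(0.01, 0.02, 0.03, 0.2), "BH"))
  expect_equal(sum(fdr_correct(rep(1, 10))$significant), 0)
  expect_true(fdr_correct(0.001)$significant)
})

test_that("one serial-dilution cycle is log2(dilution) generations", {
  tp <- make_timepoints(4, dilution = 100)
  expect_identical(tp$generations, 0:4 * log2(100))
  expect_equal(diff(tp$generations), rep(log2(100), 4))
  expect_equal(log2(100), 6.64, tolerance = 1e-3)
  tp10 <- make_timepoints(2, dilution = 10)
  expect_identical(tp10$generations[2], log2(10))
})
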