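#' Variance-stabilizing transform for count frequencies
#'
#' For count processes the frequency variance is proportional to the mean;
#' the square-root transform `phi = sqrt(f)` makes the noise variance
#' approximately frequency-independent, which is the scale on which all
#' error parameters are defined.
#'
#' @param f nonnegative frequencies.
#' @return sqrt-frequencies.
#' @export
vst <- function(f) {
  if (any(f < 0)) stop("frequencies must be nonnegative")
  sqrt(f)
}

#' Noise model for a BarSeq experiment
#'
#' Per-timepoint technical variance `zeta_t` (sqrt-frequency scale),
#' effective population size `Ne` (per transfer), and the derived
#' count-variance parameters `c_t = (4 zeta_t + 1/Ne) R_t` used by the
#' negative-binomial likelihood.
#'
#' @param zeta_t per-timepoint technical variance; must satisfy
#'   `zeta_t >= 1/(4 R_t)` (read sampling alone contributes that much).
#' @param Ne effective population size per transfer.
#' @param R_t per-timepoint total reads.
#' @param kappa optional fitted kappa matrix (with bootstrap variances as the
#'   `"var"` attribute) the parameters were estimated from.
#' @param boundary_active logical, per-timepoint: the `zeta_t >= 1/(4 R_t)`
#'   constraint was active in the fit.
#' @return object of class `noise_model` with derived `c_t`.
#' @export
noise_model <- function(zeta_t, Ne, R_t, kappa = NULL,
                        boundary_active = NULL) {
  stopifnot(Ne > 0, length(zeta_t) == length(R_t))
  if (any(zeta_t < 1 / (4 * R_t) - 1e-12)) {
    stop("zeta_t must be at least 1/(4 R_t)")
  }
  c_t <- (4 * zeta_t + 1 / Ne) * R_t
  structure(list(zeta_t = zeta_t, Ne = Ne, R_t = R_t, c_t = c_t,
                 kappa = kappa,
                 boundary_active = boundary_active %||% rep(FALSE,
                                                            length(zeta_t))),
            class = "noise_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: Ne = %.3g/transfer; zeta_t = %s; c_t = %s\n",
              x$Ne, paste(signif(x$zeta_t, 3), collapse = ", "),
              paste(signif(x$c_t, 3), collapse = ", ")))
  invisible(x)
}

# Robust variance of a sample via the median absolute deviation:
# (MAD / 0.67449)^2, the square of the Gaussian-consistent MAD.
mad_variance <- function(x) {
  (stats::mad(x, constant = 1) / 0.67449)^2
}

#' Robust pairwise variance of neutral sqrt-frequency differences
#'
#' For a pair of timepoints (j, k), computes
#' `kappa_jk = var(phi_ij - phi_ik)` over putatively neutral barcodes using
#' the Gaussian-consistent squared MAD, `(MAD/0.67449)^2`, which resists
#' contamination by barcodes carrying secondary fitness effects. Only
#' barcodes with `rmin < r < rmax` at both timepoints enter (enough counts
#' for the CLT; high-count barcodes are more likely selected). A
#' nonparametric bootstrap over barcodes supplies the estimator variance.
#'
#' @param neutral a `count_table` restricted to neutral (intergenic)
#'   barcodes.
#' @param j,k timepoint column indices (1-based).
#' @param rmin,rmax open count-filter interval applied at both timepoints.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param min_barcodes minimum surviving barcodes below which the estimate is
#'   refused.
#' @return list with `kappa`, `var_kappa`, `n` (barcodes used).
#' @export
estimate_kappa <- function(neutral, j, k, rmin = 50, rmax = 500,
                           n_boot = 500, seed = 1, min_barcodes = 100) {
  cm <- neutral$counts
  R <- neutral$metadata$total_reads
  keep <- cm[, j] > rmin & cm[, j] < rmax & cm[, k] > rmin & cm[, k] < rmax
  n <- sum(keep)
  if (n < min_barcodes) {
    stop(sprintf("only %d neutral barcodes pass the count filter (need >= %d)",
                 n, min_barcodes))
  }
  psi <- vst(cm[keep, j] / R[j]) - vst(cm[keep, k] / R[k])
  kap <- mad_variance(psi)
  vk <- with_seed(seed, function() {
    stats::var(vapply(seq_len(n_boot), function(b) {
      mad_variance(psi[sample.int(n, n, replace = TRUE)])
    }, 0))
  })
  list(kappa = kap, var_kappa = vk, n = n)
}

#' All-pairs kappa matrix
#'
#' Applies [estimate_kappa()] to every timepoint pair. The matrix is
#' symmetric with a zero diagonal; bootstrap variances are attached as the
#' `"var"` attribute (NA on the diagonal).
#'
#' @inheritParams estimate_kappa
#' @return symmetric matrix of kappa estimates with attribute `"var"`.
#' @export
kappa_matrix <- function(neutral, rmin = 50, rmax = 500, n_boot = 500,
                         seed = 1, min_barcodes = 100) {
  nt <- ncol(neutral$counts)
  kap <- matrix(0, nt, nt)
  vk <- matrix(NA_real_, nt, nt)
  for (j in seq_len(nt - 1)) {
    for (k in (j + 1):nt) {
      est <- estimate_kappa(neutral, j, k, rmin, rmax, n_boot,
                            seed = derive_seed(seed, paste0(j, "_", k)),
                            min_barcodes = min_barcodes)
      kap[j, k] <- kap[k, j] <- est$kappa
      vk[j, k] <- vk[k, j] <- est$var_kappa
    }
  }
  attr(kap, "var") <- vk
  kap
}

#' Decompose pairwise variances into technical noise and drift
#'
#' Fits the additive error model
#' `kappa_jk = zeta_j + zeta_k + |j - k| / (4 Ne)` (|j - k| in transfers) to
#' a measured kappa matrix by inverse-variance-weighted least squares, under
#' the box constraints `zeta_t >= 1/(4 R_t)` (technical noise is at least
#' read-sampling noise) and `1/Ne >= 0`. Optimized with L-BFGS-B;
#' initialization uses half the mean kappa involving each timepoint for
#' `zeta_t` and the regression slope of kappa on transfer separation for
#' `1/Ne`.
#'
#' @param kappa symmetric kappa matrix (attribute `"var"` holding bootstrap
#'   variances; equal weights if absent).
#' @param R_t per-timepoint total reads.
#' @param transfer_index per-timepoint transfer index.
#' @return a [noise_model()] with the fitted parameters; attributes
#'   `objective` (weighted residual sum) and `convergence` from the
#'   optimizer. A warning is raised (not an error) if every `zeta_t` sits on
#'   its lower bound.
#' @export
decompose_noise <- function(kappa, R_t, transfer_index = NULL) {
  nt <- nrow(kappa)
  stopifnot(length(R_t) == nt)
  transfer_index <- transfer_index %||% (seq_len(nt) - 1)
  vk <- attr(kappa, "var")
  pairs <- which(upper.tri(kappa), arr.ind = TRUE)
  y <- kappa[pairs]
  w <- if (is.null(vk)) rep(1, nrow(pairs)) else 1 / vk[pairs]
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  d <- abs(transfer_index[pairs[, 1]] - transfer_index[pairs[, 2]])

  lower <- c(1 / (4 * R_t), 0)
  # rescale so the objective is O(1): the optimizer's stopping rule is
  # relative to max(|f|, 1), which a raw sum of ~1e-16 residuals never meets
  scale <- max(mean(y), 1e-12)
  wn <- w / (mean(w) * scale^2)
  obj <- function(theta) {
    zeta <- theta[seq_len(nt)]
    inv_ne <- theta[nt + 1]
    pred <- zeta[pairs[, 1]] + zeta[pairs[, 2]] + d * inv_ne / 4
    sum(wn * (pred - y)^2)
  }
  zeta0 <- pmax(vapply(seq_len(nt), function(t) {
    mean(c(kappa[t, -t])) / 2
  }, 0), lower[seq_len(nt)])
  slope <- stats::cov(d, y) / max(stats::var(d), 1e-300)
  inv_ne0 <- max(4 * slope, 0)
  fit <- stats::optim(c(zeta0, inv_ne0), obj, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = 1000, factr = 1e4,
                                     parscale = rep(scale, nt + 1)))
  zeta <- fit$par[seq_len(nt)]
  inv_ne <- fit$par[nt + 1]
  at_bound <- zeta <= lower[seq_len(nt)] * (1 + 1e-9)
  if (all(at_bound)) {
    warning("all zeta_t estimates are at the read-sampling lower bound")
  }
  nm <- noise_model(zeta_t = pmax(zeta, lower[seq_len(nt)]),
                    Ne = if (inv_ne > 0) 1 / inv_ne else Inf,
                    R_t = R_t, kappa = kappa, boundary_active = at_bound)
  if (!is.finite(nm$Ne)) {
    # keep c_t finite and well-defined when drift fits to zero
    nm$Ne <- 1e300
    nm$c_t <- 4 * nm$zeta_t * R_t
  }
  attr(nm, "objective") <- fit$value * mean(w) * scale^2  # raw weighted SSR
  attr(nm, "convergence") <- fit$convergence
  nm
}

#' Stratified kappa diagnostic
#'
#' Re-estimates kappa within strata of a barcode attribute (GC content bins,
#' genomic-position bins, ...) to diagnose frequency biases: amplification or
#' copy-number biases would inflate the apparent noise of the affected
#' stratum. Strata with fewer than `min_barcodes` eligible barcodes are
#' reported as missing rather than estimated.
#'
#' @param neutral a `count_table` of neutral barcodes.
#' @param grouping factor (or vector coercible to one) over the rows of
#'   `neutral$counts`.
#' @param j,k timepoint pair.
#' @inheritParams estimate_kappa
#' @return data.frame with one row per stratum: `stratum`, `kappa`,
#'   `var_kappa`, `n` (NA where the stratum is too small).
#' @export
stratified_kappa <- function(neutral, grouping, j = 1, k = 2, rmin = 50,
                             rmax = 500, n_boot = 500, seed = 1,
                             min_barcodes = 100) {
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == nrow(neutral$counts))
  res <- lapply(levels(grouping), function(g) {
    sub <- count_table(neutral$counts[grouping == g, , drop = FALSE],
                       neutral$metadata)
    est <- tryCatch(
      estimate_kappa(sub, j, k, rmin, rmax, n_boot,
                     seed = derive_seed(seed, g),
                     min_barcodes = min_barcodes),
      error = function(e) list(kappa = NA_real_, var_kappa = NA_real_,
                               n = NA_integer_))
    data.frame(stratum = g, kappa = est$kappa, var_kappa = est$var_kappa,
               n = est$n)
  })
  do.call(rbind, res)
}
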