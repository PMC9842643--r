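#' Negative-binomial log-likelihood with linear mean-variance
#'
#' Log pmf of the NB distribution parameterized by its mean `mu` and
#' variance `c * mu` (equivalently size `mu/(c-1)`, success probability
#' `1/c`). As `c` approaches 1 from above the distribution degenerates to
#' Poisson; values of `c` within `1e-6` of 1 are routed to the Poisson pmf,
#' where the NB parameterization is singular.
#'
#' @param r observed counts (nonnegative).
#' @param mu mean (> 0).
#' @param c variance parameter (>= 1); `var(r) = c * mu`.
#' @return log-probabilities, recycled to common length.
#' @export
nb_loglik <- function(r, mu, c) {
  if (any(r < 0)) stop("counts must be nonnegative")
  if (any(c < 1)) stop("variance parameter c must be >= 1")
  n <- max(length(r), length(mu), length(c))
  r <- rep_len(r, n); mu <- rep_len(mu, n); c <- rep_len(c, n)
  out <- numeric(n)
  pois <- c <= 1 + 1e-6
  if (any(pois)) out[pois] <- stats::dpois(r[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(r[!pois], size = mu[!pois] / (c[!pois] - 1),
                                 prob = 1 / c[!pois], log = TRUE)
  }
  out
}

# Default fitness grid: covers the empirically observed |s| range with
# resolution well below typical standard errors.
default_s_grid <- function(s_min = -0.35, s_max = 0.35, s_step = 5e-4) {
  seq(s_min, s_max, by = s_step)
}

as_xbar_vec <- function(xbar, nt) {
  if (is.null(xbar)) return(numeric(nt))
  if (inherits(xbar, "mean_fitness_series") || is.data.frame(xbar)) {
    xbar <- xbar$xbar
  }
  stopifnot(length(xbar) == nt)
  xbar
}

#' Integrated log-likelihood of fitness for one barcode
#'
#' The expected count trajectory is `mu_t = R_t f0 exp((s - xbar_t) t)` with
#' the initial frequency `f0` a nuisance parameter. The likelihood of `s` is
#' the product over timepoints of NB pmfs, numerically integrated over `f0`
#' with a flat prior on the frequency scale ("integrated likelihood"),
#' reducing the problem to one dimension. The integral uses a log-spaced
#' grid of `n_f0` points spanning `span_sd` sampling standard deviations
#' around the naive estimate `r_0/R_0` on the sqrt-frequency scale
#' (the f0 posterior is sharply peaked there), with the trapezoidal rule.
#'
#' @param r count vector over retained timepoints (first entry is time 0).
#' @param s_grid fitness values (1/generation) at which to evaluate.
#' @param generations per-timepoint generations (first entry 0).
#' @param R_t per-timepoint total reads.
#' @param c_t per-timepoint count-variance parameters.
#' @param xbar per-timepoint mean fitness (defaults to 0).
#' @param n_f0 number of integration nodes.
#' @param span_sd half-width of the f0 grid in sampling SDs.
#' @return vector of log-likelihood values along `s_grid` (an additive
#'   constant from the prior normalization is irrelevant downstream).
#' @export
integrated_loglik <- function(r, s_grid, generations, R_t, c_t, xbar = NULL,
                              n_f0 = 61, span_sd = 6) {
  stopifnot(length(r) == length(generations), length(r) == length(R_t))
  xbar <- as_xbar_vec(xbar, length(r))
  ll <- barcode_curve_one(r, s_grid, generations, R_t, c_t, xbar,
                          n_f0, span_sd)
  if (any(!is.finite(ll))) warning("non-finite integrated likelihood values")
  ll
}

# Core kernel: integrated log-likelihood curve for one barcode.
barcode_curve_one <- function(r, s_grid, gens, R_t, c_t, xbar,
                              n_f0 = 61, span_sd = 6) {
  n_s <- length(s_grid)
  r0 <- r[1]
  phi0 <- sqrt(max(r0, 0.25) / R_t[1])
  sdp <- sqrt(c_t[1] / (4 * R_t[1]))
  lo <- max(phi0 - span_sd * sdp, 0.1 * sdp)
  hi <- phi0 + span_sd * sdp
  f0 <- exp(seq(log(lo^2), log(hi^2), length.out = n_f0))
  df <- diff(f0)
  lw <- log(c(df / 2, 0) + c(0, df / 2))  # trapezoid weights, flat f0 prior

  lp0 <- nb_loglik(r0, R_t[1] * f0, c_t[1])
  if (length(r) == 1) {
    # single timepoint: s unidentifiable, flat curve
    m <- max(lp0 + lw)
    return(rep(m + log(sum(exp(lp0 + lw - m))), n_s))
  }
  tt <- gens[-1]; Rt <- R_t[-1]; ct <- c_t[-1]
  xb <- xbar[-1]; rt <- r[-1]
  nt <- length(tt)
  # growth[t, s] = exp((s - xbar_t) * t)
  G <- exp(outer(tt, s_grid) - xb * tt)
  A <- Rt * G                               # (nt x n_s)
  mu <- outer(A, f0)                        # (nt x n_s x n_f0)
  lp <- nb_loglik(rep(rt, times = n_s * n_f0), as.vector(mu), rep(ct, n_s * n_f0))
  M <- matrix(colSums(matrix(lp, nt)), n_s, n_f0)  # summed over t > 0
  M <- sweep(M, 2, lp0 + lw, "+")
  mx <- do.call(pmax, as.data.frame(M))
  mx + log(rowSums(exp(M - mx)))
}

#' Per-barcode likelihood curves for a set of barcodes
#'
#' Evaluates [integrated_loglik()] for every barcode of a gene on a common
#' fitness grid, honoring per-barcode retained-timepoint masks.
#'
#' @param counts matrix (barcodes x timepoints).
#' @param metadata timepoint metadata (as in [count_table()]).
#' @param noise a [noise_model()].
#' @param xbar mean-fitness series (or per-timepoint vector), default 0.
#' @param s_grid fitness grid.
#' @param mask optional logical matrix of retained timepoints per barcode.
#' @inheritParams integrated_loglik
#' @return matrix of log-likelihoods, `length(s_grid)` x `nrow(counts)`.
#' @export
barcode_loglik_curves <- function(counts, metadata, noise, xbar = NULL,
                                  s_grid = default_s_grid(), mask = NULL,
                                  n_f0 = 61, span_sd = 6) {
  nt <- ncol(counts)
  xbar <- as_xbar_vec(xbar, nt)
  out <- matrix(NA_real_, length(s_grid), nrow(counts),
                dimnames = list(NULL, rownames(counts)))
  for (i in seq_len(nrow(counts))) {
    keep <- if (is.null(mask)) rep(TRUE, nt) else mask[i, ]
    out[, i] <- barcode_curve_one(counts[i, keep], s_grid,
                                  metadata$generations[keep],
                                  metadata$total_reads[keep],
                                  noise$c_t[keep], xbar[keep],
                                  n_f0, span_sd)
  }
  out
}

#' Likelihood curve for a gene
#'
#' Barcodes within a gene are independent given the fitness, so the gene
#' log-likelihood is the sum of the per-barcode integrated log-likelihoods.
#'
#' @inheritParams barcode_loglik_curves
#' @return object of class `likelihood_curve`: list with `s`, `loglik`,
#'   `n_barcodes`.
#' @export
gene_loglik_curve <- function(counts, metadata, noise, xbar = NULL,
                              s_grid = default_s_grid(), mask = NULL,
                              n_f0 = 61, span_sd = 6) {
  bc <- barcode_loglik_curves(counts, metadata, noise, xbar, s_grid, mask,
                              n_f0, span_sd)
  likelihood_curve(s_grid, rowSums(bc), n_barcodes = ncol(bc))
}

#' @rdname gene_loglik_curve
#' @param s fitness grid of an already-computed curve.
#' @param loglik log-likelihood values along `s`.
#' @param n_barcodes number of barcodes combined in the curve.
#' @export
likelihood_curve <- function(s, loglik, n_barcodes = NA_integer_) {
  stopifnot(length(s) == length(loglik))
  structure(list(s = s, loglik = loglik, n_barcodes = n_barcodes),
            class = "likelihood_curve")
}

# Quadratic-refined argmax and curvature-based SE from a discretized curve.
mle_from_curve <- function(s, ll) {
  i <- which.max(ll)
  step <- s[2] - s[1]
  boundary <- i <= 1 || i >= length(ll)
  if (boundary) {
    return(list(s_hat = s[i], se = NA_real_, boundary = TRUE,
                poor_curvature = FALSE, loglik_max = ll[i]))
  }
  y1 <- ll[i - 1]; y2 <- ll[i]; y3 <- ll[i + 1]
  curv <- (y1 - 2 * y2 + y3) / step^2
  poor <- FALSE
  if (curv < 0) {
    delta <- 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
    s_hat <- s[i] + delta * step
    se <- 1 / sqrt(-curv)
    llm <- y2 - 0.25 * (y1 - y3) * delta
  } else {
    # flat or convex at the grid max: quadratic fit over a window
    win <- max(1, i - 5):min(length(ll), i + 5)
    fit <- stats::lm(ll[win] ~ stats::poly(s[win], 2, raw = TRUE))
    a <- stats::coef(fit)[3]
    poor <- TRUE
    s_hat <- s[i]
    se <- if (is.finite(a) && a < 0) 1 / sqrt(-2 * a) else NA_real_
    llm <- y2
  }
  list(s_hat = s_hat, se = se, boundary = FALSE, poor_curvature = poor,
       loglik_max = llm)
}

#' Maximum-likelihood fitness of a gene
#'
#' Grid maximum of the combined gene likelihood, refined by a local
#' quadratic fit; the standard error comes from the observed information
#' (central finite differences of the log-likelihood at the maximum). When
#' the maximizer lands on a grid boundary, the grid is extended (doubling
#' the range on that side) up to `s_cap`, after which the estimate is
#' boundary-flagged.
#'
#' @inheritParams barcode_loglik_curves
#' @param s_cap maximum half-width to which the grid may auto-extend.
#' @return list with `estimate` (data.frame row: `s_hat`, `se`, `p`,
#'   `n_barcodes`, `boundary`, `poor_curvature`) and `curve` (the
#'   `likelihood_curve`).
#' @export
mle_fitness <- function(counts, metadata, noise, xbar = NULL,
                        s_grid = default_s_grid(), mask = NULL, n_f0 = 61,
                        span_sd = 6, s_cap = 1.4) {
  repeat {
    curve <- gene_loglik_curve(counts, metadata, noise, xbar, s_grid, mask,
                               n_f0, span_sd)
    est <- mle_from_curve(curve$s, curve$loglik)
    rng <- range(s_grid)
    if (!est$boundary || diff(rng) >= 2 * s_cap) break
    step <- s_grid[2] - s_grid[1]
    ext <- diff(rng)
    if (est$s_hat <= rng[1] + step) {
      s_grid <- seq(rng[1] - ext, rng[2], by = step)
    } else {
      s_grid <- seq(rng[1], rng[2] + ext, by = step)
    }
  }
  p <- neutrality_pvalue(curve)
  list(estimate = data.frame(s_hat = est$s_hat, se = est$se, p = p,
                             n_barcodes = curve$n_barcodes,
                             boundary = est$boundary,
                             poor_curvature = est$poor_curvature),
       curve = curve)
}

#' Combine likelihood curves across replicates
#'
#' Replicate experiments are independent, so their likelihoods multiply:
#' log-likelihood curves are summed pointwise on a common grid (curves on
#' different grids are linearly interpolated onto the grid of the first;
#' fitness estimates, errors and p-values are then recomputed from the
#' combined curve).
#'
#' @param curves list of `likelihood_curve` objects.
#' @return a `likelihood_curve`.
#' @export
combine_replicates <- function(curves) {
  if (length(curves) == 0) stop("no curves to combine")
  s <- curves[[1]]$s
  tot <- numeric(length(s))
  for (cv in curves) {
    ll <- if (identical(cv$s, s)) cv$loglik else {
      stats::approx(cv$s, cv$loglik, xout = s, rule = 2)$y
    }
    tot <- tot + ll
  }
  likelihood_curve(s, tot,
                   n_barcodes = sum(vapply(curves,
                                           function(cv) cv$n_barcodes, 1L)))
}

#' Posterior-likelihood-ratio neutrality p-value
#'
#' The discretized likelihood curve is normalized into a posterior over the
#' fitness grid (flat prior); the p-value is the posterior mass where the
#' data support the null `s = 0` more strongly than the alternative, i.e.
#' where `log L(0) - log L(s_j) > 0` (strict inequality, so a perfectly flat
#' curve gives p = 0). The grid is extended to include 0 if necessary.
#'
#' @param curve a `likelihood_curve`.
#' @return p-value in [0, 1].
#' @export
neutrality_pvalue <- function(curve) {
  s <- curve$s; ll <- curve$loglik
  if (min(s) > 0 || max(s) < 0) {
    step <- s[2] - s[1]
    s_new <- if (min(s) > 0) seq(0, max(s), by = step) else
      seq(min(s), 0, by = step)
    ll <- stats::approx(s, ll, xout = s_new, rule = 2)$y
    s <- s_new
  }
  ll0 <- if (any(s == 0)) ll[s == 0][1] else
    stats::approx(s, ll, xout = 0)$y
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  llr <- ll0 - ll
  sum(post[llr > 0])
}

#' Benjamini-Hochberg FDR correction and significance calls
#'
#' Step-up BH adjustment of neutrality p-values; a gene is called
#' significantly non-neutral when its q-value is at most `alpha`.
#'
#' @param p vector of p-values.
#' @param alpha FDR level.
#' @return data.frame with `p`, `q`, `significant`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = !is.na(q) & q <= alpha)
}

#' Fitness inference for a whole experiment
#'
#' Runs the per-gene maximum-likelihood fit over a list of gene barcode sets
#' and applies the FDR correction across genes (the experiment is the unit
#' of correction).
#'
#' @param gene_sets named list of gene barcode sets from
#'   [assemble_gene_sets()].
#' @inheritParams mle_fitness
#' @param alpha FDR level.
#' @param keep_curves set `TRUE` to also return per-gene likelihood curves.
#' @return data.frame with one row per gene: `gene`, `s_hat`, `se`, `p`,
#'   `q`, `significant`, `n_barcodes`, `boundary`, `poor_curvature`. With
#'   `keep_curves`, the curves are attached as the `"curves"` attribute.
#' @export
infer_fitness <- function(gene_sets, metadata, noise, xbar = NULL,
                          s_grid = default_s_grid(), alpha = 0.05,
                          n_f0 = 61, span_sd = 6, keep_curves = FALSE) {
  fits <- lapply(gene_sets, function(gs) {
    mle_fitness(gs$counts, metadata, noise, xbar, s_grid, mask = gs$mask,
                n_f0 = n_f0, span_sd = span_sd)
  })
  tab <- do.call(rbind, lapply(fits, `[[`, "estimate"))
  tab <- cbind(gene = names(gene_sets), tab)
  rownames(tab) <- NULL
  fc <- fdr_correct(tab$p, alpha)
  tab$q <- fc$q
  tab$significant <- fc$significant
  tab <- tab[, c("gene", "s_hat", "se", "p", "q", "significant",
                 "n_barcodes", "boundary", "poor_curvature")]
  if (keep_curves) attr(tab, "curves") <- lapply(fits, `[[`, "curve")
  tab
}
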