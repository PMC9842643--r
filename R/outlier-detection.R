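#' Weighted median
#'
#' The smallest value whose cumulative normalized weight reaches 1/2
#' (values sorted ascending).
#'
#' @param x values.
#' @param w positive weights.
#' @return the weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w > 0), all(is.finite(w)))
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Weighted trimmed mean
#'
#' Removes `trim` of the total weight from each tail (with fractional
#' inclusion of boundary observations) and returns the weighted mean of the
#' rest.
#'
#' @param x values.
#' @param w positive weights.
#' @param trim fraction of total weight removed from each tail.
#' @return the weighted trimmed mean.
#' @export
weighted_trimmed_mean <- function(x, w = rep(1, length(x)), trim = 0.3) {
  stopifnot(length(x) == length(w), all(w > 0), trim >= 0, trim < 0.5)
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  hi <- cumsum(w)
  lo <- c(0, hi[-length(hi)])
  eff <- pmax(0, pmin(hi, 1 - trim) - pmax(lo, trim))
  sum(eff * x) / sum(eff)
}

#' Typical fitness of a barcode sample
#'
#' Robust location estimate of a resampled set of per-barcode fitness
#' values, inverse-variance weighted: the weighted median for small samples
#' (`n_r < 10`), the 30%-per-tail weighted trimmed mean for larger ones
#' (lower sampling variance once enough observations survive trimming).
#'
#' @param s per-barcode fitness estimates in the sample.
#' @param var_s per-barcode fitness variances (weights are `1/var_s`).
#' @param trim tail fraction for the trimmed mean.
#' @return the typical fitness.
#' @export
typical_fitness <- function(s, var_s = rep(1, length(s)), trim = 0.3) {
  w <- 1 / var_s
  stopifnot(all(is.finite(w) & w > 0))
  if (length(s) < 10) weighted_median(s, w) else
    weighted_trimmed_mean(s, w, trim)
}

# Interpolate per-barcode log-likelihood curves (columns of `curves`) at a
# scalar fitness value.
interp_curves_at <- function(s_grid, curves, s0) {
  s0 <- min(max(s0, s_grid[1]), s_grid[length(s_grid)])
  i <- findInterval(s0, s_grid, all.inside = TRUE)
  a <- (s0 - s_grid[i]) / (s_grid[i + 1] - s_grid[i])
  (1 - a) * curves[i, ] + a * curves[i + 1, ]
}

#' Resistant diagnostic for outlier barcodes within a gene
#'
#' Barcodes carrying secondary mutations produce trajectories inconsistent
#' with their gene's typical fitness. For each barcode the per-barcode MLE
#' and likelihood curve are computed; `n_resample` random combinations J of
#' `ceiling(n_bc/2)` barcodes give typical-fitness estimates
#' (see [typical_fitness()]), and the evidence against the typical fitness is
#' the likelihood ratio `LR_Ji = log L_i(s_hat_i) - log L_i(s_typ_J)`. The
#' diagnostic standardizes twice by medians:
#' `u_i = max_J LR_Ji / med_i LR_Ji` and `RD_i = u_i / med_i u_i`, making it
#' scale-free and resistant to up to half the barcodes being contaminated.
#' Resamples where the median LR is nonpositive (all barcodes fit the
#' typical value) use a floored denominator so the ratio stays finite and
#' conservative.
#'
#' @param counts matrix (barcodes x timepoints) for one gene (>= 4 barcodes).
#' @param metadata timepoint metadata.
#' @param noise a [noise_model()].
#' @param xbar mean-fitness series or vector (default 0).
#' @param n_resample number of barcode resamples.
#' @param seed RNG seed; resampling is keyed to the gene id so results do not
#'   depend on gene processing order.
#' @param gene gene identifier used for seed derivation.
#' @param s_grid fitness grid for the per-barcode curves (auto-extended per
#'   barcode when an MLE lands on the boundary).
#' @param mask optional retained-timepoint mask.
#' @param cutoff RD threshold used for the `flagged` column.
#' @inheritParams integrated_loglik
#' @return data.frame of class `outlier_report` with one row per barcode:
#'   `gene`, `barcode`, `s_hat`, `var_s`, `u`, `RD`, `flagged`.
#' @export
resistant_diagnostic <- function(counts, metadata, noise, xbar = NULL,
                                 n_resample = 200, seed = 1, gene = "gene",
                                 s_grid = seq(-0.12, 0.12, by = 5e-4),
                                 mask = NULL, cutoff = 6,
                                 n_f0 = 61, span_sd = 6) {
  n_bc <- nrow(counts)
  if (n_bc < 4) stop("resistant diagnostic requires >= 4 barcodes")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("bc%03d", seq_len(n_bc))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("barcode rownames must be unique within a gene")
  }
  # process in barcode-name order so results do not depend on row order
  ord <- order(rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  if (!is.null(mask)) mask <- mask[ord, , drop = FALSE]
  curves <- barcode_loglik_curves(counts, metadata, noise, xbar, s_grid,
                                  mask, n_f0, span_sd)
  ests <- lapply(seq_len(n_bc), function(i) {
    est <- mle_from_curve(s_grid, curves[, i])
    if (est$boundary) {
      # widen the grid for this barcode only
      wide <- seq(min(s_grid) * 3, max(s_grid) * 3, by = s_grid[2] - s_grid[1])
      msk <- if (is.null(mask)) NULL else mask[i, , drop = FALSE]
      cv <- barcode_loglik_curves(counts[i, , drop = FALSE], metadata, noise,
                                  xbar, wide, msk, n_f0, span_sd)
      est <- mle_from_curve(wide, cv[, 1])
    }
    est
  })
  s_hat <- vapply(ests, `[[`, 0, "s_hat")
  se <- vapply(ests, `[[`, 0, "se")
  llmax <- vapply(ests, `[[`, 0, "loglik_max")
  var_s <- se^2
  var_s[!is.finite(var_s) | var_s <= 0] <- max(var_s[is.finite(var_s)], 1)

  n_r <- ceiling(n_bc / 2)
  lr <- with_seed(derive_seed(seed, gene), function() {
    t(vapply(seq_len(n_resample), function(j) {
      J <- sample.int(n_bc, n_r)
      s_typ <- typical_fitness(s_hat[J], var_s[J])
      pmax(llmax - interp_curves_at(s_grid, curves, s_typ), 0)
    }, numeric(n_bc)))
  })
  med_lr <- apply(lr, 1, stats::median)
  med_lr <- pmax(med_lr, .Machine$double.eps)
  u <- apply(lr / med_lr, 2, max)
  med_u <- stats::median(u)
  rd <- if (med_u > 0) u / med_u else rep(1, n_bc)
  structure(data.frame(gene = gene, barcode = rownames(counts),
                       s_hat = s_hat, var_s = var_s, u = u, RD = rd,
                       flagged = rd > cutoff, row.names = NULL),
            class = c("outlier_report", "data.frame"),
            n_resample = n_resample)
}

#' Remove flagged outlier barcodes from a gene set
#'
#' Drops barcodes with `RD` strictly greater than `cutoff` (a barcode at
#' exactly the cutoff is retained) and re-applies the minimum-barcode gene
#' filter.
#'
#' @param gset a `gene_barcode_set`.
#' @param report the matching `outlier_report`.
#' @param cutoff RD threshold.
#' @param min_barcodes minimum barcodes for the gene to survive.
#' @return the filtered `gene_barcode_set`, or `NULL` if the gene no longer
#'   passes the barcode-count filter.
#' @export
flag_outliers <- function(gset, report, cutoff = 6, min_barcodes = 4) {
  keep <- report$RD[match(rownames(gset$counts), report$barcode)] <= cutoff
  if (sum(keep) < min_barcodes) return(NULL)
  gset$counts <- gset$counts[keep, , drop = FALSE]
  gset$mask <- gset$mask[keep, , drop = FALSE]
  gset
}

#' Operating characteristics of the outlier detector on a benchmark
#'
#' Runs [resistant_diagnostic()] over every simulated gene of a
#' [build_outlier_benchmark()] result and tabulates, at the given cutoff,
#' the false-positive rate (truly neutral lineages flagged) and the
#' true-positive rate (planted non-neutral lineages flagged).
#'
#' @param bench result of [build_outlier_benchmark()].
#' @param cutoff RD threshold.
#' @param n_resample resamples per gene.
#' @param seed RNG seed (per-gene streams derived from it).
#' @param s_grid fitness grid for per-barcode likelihoods.
#' @return list with `fp_rate`, `tp_rate`, `reports` (combined data.frame
#'   joined with the truth), and per-`n_outliers` true-positive rates
#'   `tp_by_n`.
#' @export
benchmark_outlier_detection <- function(bench, cutoff = 6, n_resample = 200,
                                        seed = 1,
                                        s_grid = seq(-0.12, 0.12, by = 5e-4)) {
  reports <- lapply(seq_along(bench$genes), function(g) {
    gid <- bench$truth$gene[match(rownames(bench$genes[[g]])[1],
                                  bench$truth$lineage)]
    resistant_diagnostic(bench$genes[[g]], bench$metadata, bench$noise,
                         n_resample = n_resample, seed = seed, gene = gid,
                         s_grid = s_grid, cutoff = cutoff)
  })
  rep_all <- do.call(rbind, reports)
  rep_all$outlier <- bench$truth$outlier[match(rep_all$barcode,
                                               bench$truth$lineage)]
  rep_all$n_outliers <- stats::ave(as.numeric(rep_all$outlier),
                                   rep_all$gene, FUN = sum)
  fp <- mean(rep_all$flagged[!rep_all$outlier])
  tp <- mean(rep_all$flagged[rep_all$outlier])
  tp_by_n <- tapply(rep_all$flagged[rep_all$outlier],
                    rep_all$n_outliers[rep_all$outlier], mean)
  list(fp_rate = fp, tp_rate = tp, tp_by_n = tp_by_n, reports = rep_all)
}
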