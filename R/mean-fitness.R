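#' Group neutral barcodes into super-barcodes
#'
#' Randomly partitions eligible intergenic barcodes (read count below `rmax`
#' at every timepoint) into disjoint groups of about `size` and sums their
#' counts per timepoint. Summing averages away single-barcode drift and
#' sampling noise, giving low-noise probes of the neutral frequency decay.
#' Leftover barcodes after the full groups form one final smaller group.
#'
#' @param neutral a `count_table` of intergenic barcodes.
#' @param size target barcodes per super-barcode.
#' @param rmax exclude barcodes reaching this count at any timepoint.
#' @param seed RNG seed for the random grouping.
#' @return a `count_table` of super-barcodes.
#' @export
build_superbarcodes <- function(neutral, size = 100, rmax = 500, seed = 1) {
  cm <- neutral$counts
  eligible <- which(apply(cm, 1, max) < rmax)
  if (length(eligible) < 2 * size) {
    stop("need at least 2*size eligible barcodes to form super-barcodes")
  }
  perm <- with_seed(seed, function() sample(eligible))
  grp <- ceiling(seq_along(perm) / size)
  counts <- rowsum(cm[perm, , drop = FALSE], grp)
  rownames(counts) <- sprintf("super%03d", sort(unique(grp)))
  count_table(counts, neutral$metadata)
}

#' Estimate the population mean-fitness trajectory
#'
#' Each super-barcode is neutral in aggregate, so its frequency decays as
#' `exp(-xbar_t t)`; the per-super-barcode estimate at time t is the negative
#' log-slope `-(1/t) [log(r_t/R_t) - log(r_0/R_0)]`. The final estimate is
#' the median over super-barcodes, with a standard error from the
#' Gaussian-consistent MAD divided by `sqrt(n)` (a standard error of the
#' median across groups). `xbar` is 0 at time 0 by construction.
#'
#' @param superbarcodes a `count_table` from [build_superbarcodes()].
#' @return object of class `mean_fitness_series`: data.frame with columns
#'   `timepoint`, `generations`, `xbar`, `se`, `n`.
#' @export
estimate_mean_fitness <- function(superbarcodes) {
  cm <- superbarcodes$counts
  md <- superbarcodes$metadata
  nt <- ncol(cm)
  xbar <- numeric(nt)
  se <- numeric(nt)
  nn <- integer(nt)
  nn[1] <- nrow(cm)
  f0 <- cm[, 1] / md$total_reads[1]
  if (any(f0 <= 0)) stop("super-barcodes must have positive counts at t = 0")
  for (k in seq_len(nt)[-1]) {
    alive <- cm[, k] > 0
    if (!all(alive)) {
      warning(sprintf("%d super-barcode(s) extinct at timepoint %d excluded",
                      sum(!alive), md$timepoint[k]))
    }
    ft <- cm[alive, k] / md$total_reads[k]
    xi <- -(log(ft) - log(f0[alive])) / md$generations[k]
    xbar[k] <- stats::median(xi)
    se[k] <- stats::mad(xi) / sqrt(length(xi))
    nn[k] <- length(xi)
  }
  structure(data.frame(timepoint = md$timepoint,
                       generations = md$generations,
                       xbar = xbar, se = se, n = nn),
            class = c("mean_fitness_series", "data.frame"))
}

#' Mean fitness from intergenic barcodes in one call
#'
#' Convenience wrapper: restrict a count table to intergenic barcodes (per
#' the pool), build super-barcodes and estimate the mean-fitness series.
#'
#' @param tab a `count_table`.
#' @param pool pool data.frame with `barcode` and `intergenic` columns.
#' @inheritParams build_superbarcodes
#' @return a `mean_fitness_series`.
#' @export
mean_fitness_from_table <- function(tab, pool, size = 100, rmax = 500,
                                    seed = 1) {
  neutral_bc <- pool$barcode[pool$intergenic]
  keep <- rownames(tab$counts) %in% neutral_bc
  neutral <- count_table(tab$counts[keep, , drop = FALSE], tab$metadata)
  estimate_mean_fitness(build_superbarcodes(neutral, size, rmax, seed))
}
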