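#' Environment-by-environment fitness correlation
#'
#' Correlates fitness effects between pairs of environments across genes,
#' weighting by measurement error (`w_k = 1/(var s_ik + var s_jk)`). Genes
#' with noisy fitness in either member of a pair (`se > se_cutoff`) are
#' dropped from that pair; with `per_pair = FALSE` a gene noisy in any
#' environment is dropped globally.
#'
#' @param fm a [fitness_matrix()].
#' @param se_cutoff maximum standard error (1/generation); default 0.01
#'   (i.e. 1%).
#' @param min_genes minimum shared genes per pair; pairs below it are NA.
#' @param per_pair apply the noise filter per pair (default) or globally.
#' @return symmetric environment correlation matrix with unit diagonal.
#' @export
environment_correlation <- function(fm, se_cutoff = 0.01, min_genes = 3,
                                    per_pair = TRUE) {
  s <- fm$s; v <- fm$se^2
  ok <- !is.na(s) & !is.na(fm$se) & fm$se <= se_cutoff
  if (!per_pair) {
    keep <- rowSums(!ok & !is.na(s)) == 0
    s <- s[keep, , drop = FALSE]; v <- v[keep, , drop = FALSE]
    ok <- ok[keep, , drop = FALSE]
  }
  ne <- ncol(s)
  rho <- diag(1, ne)
  dimnames(rho) <- list(colnames(s), colnames(s))
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {
      use <- ok[, i] & ok[, j]
      rho[i, j] <- rho[j, i] <- if (sum(use) < min_genes) NA_real_ else
        weighted_pearson(s[use, i], s[use, j], v[use, i], v[use, j])
    }
  }
  rho
}

#' Hierarchical clustering of environments
#'
#' Ward linkage on the dissimilarity `1 - max(rho, 0)`: negative
#' correlations are clipped to zero before conversion to distances (they
#' are rare and small in this setting, and a negative correlation is no
#' more similar than none). Ties in merge heights resolve deterministically
#' by label order.
#'
#' @param rho environment correlation matrix (NAs treated as 0 correlation).
#' @return an `hclust` tree over environments.
#' @export
cluster_environments <- function(rho) {
  rho[is.na(rho)] <- 0
  d <- stats::as.dist(1 - pmax(rho, 0))
  stats::hclust(d, method = "ward.D2")
}

# Clades (leaf-name sets) of an hclust tree, as sorted name strings.
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    mem <- c()
    for (j in 1:2) {
      v <- hc$merge[i, j]
      mem <- c(mem, if (v < 0) hc$labels[-v] else members[[v]])
    }
    members[[i]] <- mem
  }
  vapply(members, function(m) paste(sort(m), collapse = "|"), "")
}

#' Bootstrap support for environment clades
#'
#' Resamples genes with replacement (using only genes that pass the noise
#' filter in all environments, so each bootstrap replicate correlates the
#' same gene set everywhere), recomputes the correlation matrix and tree,
#' and scores each clade of the original tree by the fraction of bootstrap
#' trees containing a clade with the identical leaf set.
#'
#' @inheritParams environment_correlation
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `tree` (original `hclust`), `support` (named vector per
#'   clade, in `hclust` merge order; the root clade always has support 1),
#'   `n_genes` (intersection size).
#' @export
bootstrap_support <- function(fm, se_cutoff = 0.01, n_boot = 5000, seed = 1) {
  ok <- !is.na(fm$s) & !is.na(fm$se) & fm$se <= se_cutoff
  keep <- rowSums(ok) == ncol(fm$s)
  if (!any(keep)) stop("no gene passes the filter in every environment")
  s <- fm$s[keep, , drop = FALSE]
  v <- fm$se[keep, , drop = FALSE]^2
  ng <- nrow(s)
  corr_of <- function(idx) {
    ne <- ncol(s)
    rho <- diag(1, ne); dimnames(rho) <- list(colnames(s), colnames(s))
    for (i in seq_len(ne - 1)) {
      for (j in (i + 1):ne) {
        rho[i, j] <- rho[j, i] <- weighted_pearson(s[idx, i], s[idx, j],
                                                   v[idx, i], v[idx, j])
      }
    }
    rho
  }
  tree <- cluster_environments(corr_of(seq_len(ng)))
  clades <- hclust_clades(tree)
  hits <- numeric(length(clades))
  with_seed(seed, function() {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ng, ng, replace = TRUE)
      bt <- cluster_environments(corr_of(idx))
      bclades <- hclust_clades(bt)
      hits <<- hits + as.numeric(clades %in% bclades)
    }
  })
  support <- hits / n_boot
  names(support) <- clades
  list(tree = tree, support = support, n_genes = ng)
}

#' Export an environment tree to Newick
#'
#' @param tree an `hclust` from [cluster_environments()].
#' @param file optional file path; when omitted the Newick string is
#'   returned.
#' @export
environment_tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file)
}

# Empirical quantile transform to a standard Gaussian, per column.
quantile_gaussianize <- function(x) {
  apply(x, 2, function(col) {
    stats::qnorm((rank(col, ties.method = "average") - 0.5) / length(col))
  })
}

#' PCA of normalized fitness profiles
#'
#' Restricts to genes measured in every environment, maps each
#' environment's fitness effects through an empirical quantile transform to
#' a standard Gaussian (making scales comparable across conditions), centers
#' and scales, and runs a principal components analysis with environments as
#' observations and genes as features.
#'
#' @param fm a [fitness_matrix()].
#' @return list with `scores` (environments x components),
#'   `explained_variance` (fractions summing to 1 over all components),
#'   `transformed` (the gene x environment matrix after normalization).
#' @export
pca_environments <- function(fm) {
  keep <- rowSums(is.na(fm$s)) == 0
  if (sum(keep) < 3) stop("need >= 3 genes measured in every environment")
  z <- quantile_gaussianize(fm$s[keep, , drop = FALSE])
  z <- scale(z)
  rownames(z) <- rownames(fm$s)[keep]
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained_variance = ev, transformed = z)
}
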