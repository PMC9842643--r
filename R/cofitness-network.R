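#' Fitness matrix across environments
#'
#' Gene-by-environment container for fitness estimates and their
#' uncertainties: matrices `s` (estimates), `se`, `p`, `q` and `n_barcodes`,
#' with genes in rows and environments in columns. Missing cells (gene
#' failed filters in that environment) are NA.
#'
#' @param tables named list (by environment) of per-experiment fitness
#'   tables as returned by [infer_fitness()].
#' @return object of class `fitness_matrix`.
#' @export
fitness_matrix <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  envs <- names(tables)
  mk <- function(col) {
    m <- matrix(NA_real_, length(genes), length(envs),
                dimnames = list(genes, envs))
    for (e in envs) {
      tb <- tables[[e]]
      m[match(tb$gene, genes), e] <- tb[[col]]
    }
    m
  }
  structure(list(s = mk("s_hat"), se = mk("se"), p = mk("p"), q = mk("q"),
                 n_barcodes = mk("n_barcodes")),
            class = "fitness_matrix")
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat(sprintf("fitness_matrix: %d genes x %d environments (%.0f%% measured)\n",
              nrow(x$s), ncol(x$s), 100 * mean(!is.na(x$s))))
  invisible(x)
}

#' Measurement-error-weighted Pearson correlation
#'
#' Pearson correlation of two vectors with per-observation weights
#' `w_k = 1/(varx_k + vary_k)`: weighted means, covariance and variances
#' replace their unweighted counterparts. Pairs with a missing value in
#' either vector are dropped.
#'
#' @param x,y paired observations.
#' @param varx,vary per-observation variances (defaults give equal weights).
#' @param w optional explicit weights overriding the variances.
#' @return weighted correlation in [-1, 1], or NA if fewer than 3 complete
#'   pairs remain or a weighted variance is 0.
#' @export
weighted_pearson <- function(x, y, varx = NULL, vary = NULL, w = NULL) {
  if (is.null(w)) {
    if (is.null(varx) && is.null(vary)) {
      w <- rep(1, length(x))
    } else {
      tot <- (varx %||% 0) + (vary %||% 0)
      w <- rep_len(1 / tot, length(x))
      w[!is.finite(w)] <- NA
    }
  }
  ok <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  cxy <- sum(w * (x - mx) * (y - my)) / sum(w)
  cxx <- sum(w * (x - mx)^2) / sum(w)
  cyy <- sum(w * (y - my)^2) / sum(w)
  if (cxx <= 0 || cyy <= 0) return(NA_real_)
  cxy / sqrt(cxx * cyy)
}

# Inclusion filter for the cofitness analysis: significant somewhere,
# measured in enough environments.
cofitness_gene_filter <- function(fm, alpha = 0.05, min_envs = 4) {
  sig <- rowSums(fm$q <= alpha, na.rm = TRUE) >= 1
  enough <- rowSums(!is.na(fm$s)) >= min_envs
  sig & enough
}

#' Gene-by-gene cofitness matrix
#'
#' Pairwise weighted Pearson correlation of fitness effects across shared
#' environments ("cofitness"), with weights `1/(var s_i + var s_j)` per
#' environment. Genes never called significantly non-neutral in any
#' environment, or measured in fewer than `min_envs` environments, are
#' excluded first.
#'
#' @param fm a [fitness_matrix()].
#' @param alpha significance level for the inclusion filter.
#' @param min_envs minimum environments with a successful measurement.
#' @return symmetric correlation matrix over included genes (unit diagonal).
#' @export
cofitness_matrix <- function(fm, alpha = 0.05, min_envs = 4) {
  keep <- cofitness_gene_filter(fm, alpha, min_envs)
  s <- fm$s[keep, , drop = FALSE]
  v <- fm$se[keep, , drop = FALSE]^2
  n <- nrow(s)
  rho <- diag(1, n)
  dimnames(rho) <- list(rownames(s), rownames(s))
  if (n < 2) return(rho)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rho[i, j] <- rho[j, i] <- weighted_pearson(s[i, ], s[j, ],
                                                 v[i, ], v[j, ])
    }
  }
  rho
}

#' Null p-value for one cofitness edge
#'
#' Compares an observed cofitness against a resampled null in which (1) the
#' environment labels of both genes are independently permuted, (2) each
#' fitness value is redrawn from `N(s_hat, se)` (parametric bootstrap), and
#' (3) the cofitness is recomputed. The one-sided p-value (large positive
#' cofitness) uses the plus-one estimator `(b + 1)/(n + 1)`, which cannot be
#' zero under finite resampling.
#'
#' @param x,y fitness vectors over environments.
#' @param sex,sey standard errors.
#' @param n_resample null draws.
#' @param seed RNG seed.
#' @param two_sided compare |null| to |observed| instead.
#' @return list with `rho` (observed) and `p`.
#' @export
edge_null_pvalue <- function(x, y, sex, sey, n_resample = 300, seed = 1,
                             two_sided = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; sex <- sex[ok]; sey <- sey[ok]
  obs <- weighted_pearson(x, y, sex^2, sey^2)
  if (!is.finite(obs)) return(list(rho = NA_real_, p = NA_real_))
  m <- length(x)
  null <- with_seed(seed, function() {
    vapply(seq_len(n_resample), function(b) {
      xi <- sample.int(m); yi <- sample.int(m)
      xb <- stats::rnorm(m, x[xi], sex[xi])
      yb <- stats::rnorm(m, y[yi], sey[yi])
      weighted_pearson(xb, yb, sex[xi]^2, sey[yi]^2)
    }, 0)
  })
  null <- null[is.finite(null)]
  b <- if (two_sided) sum(abs(null) >= abs(obs)) else sum(null >= obs)
  list(rho = obs, p = (b + 1) / (length(null) + 1))
}

#' Build the cofitness network
#'
#' Computes all pairwise cofitness values over filtered genes, their
#' resampled-null p-values, applies a BH-FDR correction across pairs, and
#' returns the significant edges (the network treats all significant edges
#' alike; weights are kept for reporting).
#'
#' @inheritParams cofitness_matrix
#' @inheritParams edge_null_pvalue
#' @param alpha_edge FDR level for edge calls.
#' @return object of class `cofitness_network`: list with `edges`
#'   (data.frame: gene_a, gene_b, rho, p, q, significant), `genes`, `rho`
#'   (the correlation matrix).
#' @export
cofitness_network <- function(fm, alpha = 0.05, min_envs = 4,
                              n_resample = 300, seed = 1, alpha_edge = 0.05,
                              two_sided = FALSE) {
  keep <- cofitness_gene_filter(fm, alpha, min_envs)
  genes <- rownames(fm$s)[keep]
  s <- fm$s[keep, , drop = FALSE]
  se <- fm$se[keep, , drop = FALSE]
  n <- length(genes)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(0L, 2, 0)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ep <- edge_null_pvalue(s[i, ], s[j, ], se[i, ], se[j, ], n_resample,
                           seed = derive_seed(seed,
                                              paste(genes[i], genes[j])),
                           two_sided = two_sided)
    data.frame(gene_a = genes[i], gene_b = genes[j], rho = ep$rho, p = ep$p)
  })
  edges <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_a = character(), gene_b = character(),
               rho = numeric(), p = numeric())
  fc <- fdr_correct(edges$p, alpha_edge)
  edges$q <- fc$q
  edges$significant <- fc$significant
  rho <- diag(1, n); dimnames(rho) <- list(genes, genes)
  for (k in seq_len(nrow(edges))) {
    rho[edges$gene_a[k], edges$gene_b[k]] <-
      rho[edges$gene_b[k], edges$gene_a[k]] <- edges$rho[k]
  }
  structure(list(edges = edges, genes = genes, rho = rho),
            class = "cofitness_network")
}

#' Community detection on a cofitness network
#'
#' Partitions the unweighted graph of significant edges with the fluid
#' communities algorithm, run over a range of community counts `k` with many
#' stochastic replicates each, keeping the partition of highest
#' Newman-Girvan modularity. Connected components are partitioned
#' independently (modularity is additive over communities, so per-component
#' optimization is globally optimal); isolated nodes get their own labels.
#'
#' @param net a `cofitness_network`, an igraph graph, or an edge data.frame
#'   with columns `gene_a`, `gene_b`.
#' @param k_range candidate community counts (clipped per component).
#' @param reps_per_k stochastic restarts per k.
#' @param seed RNG seed.
#' @return list with `membership` (named vector), `modularity`, `k`.
#' @export
detect_communities <- function(net, k_range = 4:20, reps_per_k = 200,
                               seed = 1) {
  g <- if (inherits(net, "igraph")) net else {
    edges <- if (inherits(net, "cofitness_network")) {
      net$edges[net$edges$significant, c("gene_a", "gene_b")]
    } else net[, c("gene_a", "gene_b")]
    verts <- if (inherits(net, "cofitness_network")) net$genes else
      unique(c(edges$gene_a, edges$gene_b))
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = verts)
  }
  if (igraph::ecount(g) < 1) stop("network has no edges")
  comp <- igraph::components(g)
  membership <- integer(igraph::vcount(g))
  names(membership) <- igraph::V(g)$name
  next_label <- 0L
  with_seed(seed, function() {
    for (ci in seq_len(comp$no)) {
      vids <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(g, vids)
      nv <- length(vids)
      if (nv == 1 || igraph::ecount(sub) == 0) {
        membership[vids] <<- next_label + 1L
        next_label <<- next_label + 1L
        next
      }
      # candidate counts: the requested range clipped to the component,
      # plus the undivided option (a whole component can be one community)
      ks <- unique(c(1L, pmin(pmax(k_range, 1L), nv)))
      best <- rep(1L, nv); best_q <- igraph::modularity(sub, rep(1L, nv))
      for (k in ks[ks > 1]) {
        for (rep_i in seq_len(reps_per_k)) {
          cl <- tryCatch(
            igraph::cluster_fluid_communities(sub, no.of.communities = k),
            error = function(e) NULL)
          if (is.null(cl)) next
          q <- igraph::modularity(sub, igraph::membership(cl))
          if (q > best_q) { best_q <- q; best <- igraph::membership(cl) }
        }
      }
      membership[vids] <<- next_label + as.integer(best)
      next_label <<- next_label + max(as.integer(best))
    }
  })
  q_total <- igraph::modularity(g, membership)
  list(membership = membership, modularity = q_total,
       k = length(unique(membership)))
}

#' Same-community agreement between two partitions
#'
#' Probability that two genes share a community in partition B given that
#' they share one in partition A, over gene pairs present in both
#' partitions. Quantifies how well community structure is preserved (e.g.
#' across genetic backgrounds).
#'
#' @param partition_a,partition_b named membership vectors.
#' @return the conditional probability, or NA if no pair is together in A.
#' @export
cluster_overlap <- function(partition_a, partition_b) {
  common <- intersect(names(partition_a), names(partition_b))
  if (length(common) < 2) return(NA_real_)
  a <- partition_a[common]; b <- partition_b[common]
  pairs <- utils::combn(length(common), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  if (!any(same_a)) return(NA_real_)
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_b[same_a])
}
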