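#' Merge sequencing-error barcodes into their parents
#'
#' PCR and sequencing errors spawn low-count derived barcodes near true
#' (majority) barcodes in edit distance. Two passes are applied, processing
#' minority barcodes in ascending order of total summed count (ties broken by
#' lexicographic barcode order): first, off-by-one pairs (edit distance 1)
#' are merged when the minority barcode maps unambiguously to a single
#' majority barcode; then, barcodes within `max_edit` are merged when a
#' unique majority barcode exists at the minimum edit distance. A majority
#' barcode is any barcode with a strictly larger total count. Ambiguous
#' minorities (two or more majority barcodes tied at the minimum distance)
#' are left unmerged. Total read counts are conserved.
#'
#' @param tab a `count_table` whose rownames are barcode sequences.
#' @param max_edit maximum Levenshtein distance to merge in the second pass.
#' @return a `count_table` with merged rows removed.
#' @export
merge_barcode_errors <- function(tab, max_edit = 4) {
  cm <- tab$counts
  cm <- cm[order(rownames(cm)), , drop = FALSE]  # order-independence
  for (pass_limit in c(1, max_edit)) {
    cm <- merge_pass(cm, pass_limit)
  }
  count_table(cm, tab$metadata)
}

merge_pass <- function(cm, max_edit) {
  repeat {
    tot <- rowSums(cm)
    ord <- order(tot, rownames(cm))  # ascending count, lexicographic ties
    merged_any <- FALSE
    for (i in ord) {
      others <- which(tot > tot[i])
      if (length(others) == 0) next
      dd <- utils::adist(rownames(cm)[i], rownames(cm)[others])[1, ]
      dmin <- min(dd)
      if (dmin > max_edit) next
      hits <- others[dd == dmin]
      if (length(hits) != 1) next  # ambiguous: leave unmerged
      cm[hits, ] <- cm[hits, ] + cm[i, ]
      cm <- cm[-i, , drop = FALSE]
      merged_any <- TRUE
      break
    }
    if (!merged_any) return(cm)
  }
}

#' Assign barcodes to genes and trim edge insertions
#'
#' Joins a count table against the insertion pool: barcodes inserted within a
#' gene keep their gene assignment only when the fractional position lies in
#' the closed interval `[edge_frac, 1 - edge_frac]` (default: the first and
#' last 5% of the gene are excluded, since such insertions may not disrupt
#' the product); intergenic barcodes are routed to the neutral set; barcodes
#' absent from the pool are dropped, with the dropped read count recorded.
#' A warning is raised when more than 10% of reads are unmapped.
#'
#' @param tab a `count_table`.
#' @param pool pool data.frame (`barcode`, `gene`, `frac_within_gene`,
#'   `intergenic`).
#' @param edge_frac excluded fraction at each end of the gene.
#' @return list with `genes` (a `count_table` of gene-assigned barcodes, with
#'   a `gene` attribute giving each row's gene), `intergenic` (a
#'   `count_table`), `n_unmapped_reads`, `n_edge_excluded`.
#' @export
map_and_trim <- function(tab, pool, edge_frac = 0.05) {
  cm <- tab$counts
  idx <- match(rownames(cm), pool$barcode)
  unmapped <- is.na(idx)
  n_unmapped_reads <- sum(cm[unmapped, , drop = FALSE])
  if (n_unmapped_reads > 0.1 * sum(cm)) {
    warning(sprintf("%.1f%% of reads are unmapped",
                    100 * n_unmapped_reads / sum(cm)))
  }
  cm <- cm[!unmapped, , drop = FALSE]
  info <- pool[idx[!unmapped], ]
  is_int <- info$intergenic
  in_gene <- !is_int & !is.na(info$gene)
  keep_gene <- in_gene & info$frac_within_gene >= edge_frac &
    info$frac_within_gene <= 1 - edge_frac
  genes <- count_table(cm[keep_gene, , drop = FALSE], tab$metadata)
  attr(genes, "gene") <- info$gene[keep_gene]
  list(genes = genes,
       intergenic = count_table(cm[is_int, , drop = FALSE], tab$metadata),
       n_unmapped_reads = n_unmapped_reads,
       n_edge_excluded = sum(in_gene & !keep_gene))
}

#' Enforce a minimum initial read count within a gene
#'
#' Low initial counts make single-barcode trajectories uninformative, so the
#' lowest-initial-count barcode is summed (across all timepoints) into the
#' next-lowest until every remaining barcode starts with at least `r0_min`
#' reads, or a single barcode remains. Ties on the initial count are broken
#' by lexicographic barcode order. Total counts are conserved.
#'
#' @param counts matrix of counts (barcodes x timepoints) for one gene.
#' @param r0_min minimum initial count.
#' @return count matrix with merged rows removed.
#' @export
enforce_min_initial <- function(counts, r0_min = 80) {
  while (nrow(counts) > 1 && min(counts[, 1]) < r0_min) {
    ord <- order(counts[, 1], rownames(counts))
    lo <- ord[1]; nxt <- ord[2]
    counts[nxt, ] <- counts[nxt, ] + counts[lo, ]
    counts <- counts[-lo, , drop = FALSE]
  }
  counts
}

#' Trim extinct tails of a barcode trajectory
#'
#' A barcode with zero counts from some timepoint to the end is extinct;
#' timepoints after (but not including) the first extinct timepoint carry no
#' information and are masked. Barcodes extinct from the second timepoint
#' onward are dropped entirely.
#'
#' @param counts count vector over timepoints.
#' @return logical mask of retained timepoints, or `NULL` if the barcode
#'   should be dropped.
#' @export
trim_extinct <- function(counts) {
  nt <- length(counts)
  if (counts[nt] != 0) return(rep(TRUE, nt))
  t_ext <- nt
  while (t_ext > 1 && counts[t_ext - 1] == 0) t_ext <- t_ext - 1
  if (t_ext <= 2) return(NULL)  # extinct after just one timepoint
  c(rep(TRUE, t_ext), rep(FALSE, nt - t_ext))
}

#' Assemble per-gene barcode sets
#'
#' Applies the initial-count floor and extinction trimming per gene, then
#' keeps genes with at least `min_barcodes` surviving barcodes; multiple
#' independent insertions guard the gene estimate against rare fluctuations
#' and secondary mutations.
#'
#' @param genes gene-assigned `count_table` from [map_and_trim()] (with its
#'   `gene` attribute), or a `count_table` plus explicit `gene` vector.
#' @param gene optional per-row gene assignment overriding the attribute.
#' @param r0_min minimum initial count per barcode.
#' @param min_barcodes minimum barcodes per retained gene.
#' @return named list (by gene) of objects of class `gene_barcode_set`, each
#'   a list with `gene`, `counts` (matrix), `mask` (logical matrix of
#'   retained timepoints). Excluded genes are recorded in the
#'   `"excluded_genes"` attribute.
#' @export
assemble_gene_sets <- function(genes, gene = NULL, r0_min = 80,
                               min_barcodes = 4) {
  gene <- gene %||% attr(genes, "gene")
  stopifnot(length(gene) == nrow(genes$counts))
  out <- list()
  excluded <- character()
  for (g in unique(gene)) {
    cm <- genes$counts[gene == g, , drop = FALSE]
    cm <- enforce_min_initial(cm, r0_min)
    masks <- lapply(seq_len(nrow(cm)), function(i) trim_extinct(cm[i, ]))
    keep <- !vapply(masks, is.null, TRUE)
    cm <- cm[keep, , drop = FALSE]
    if (nrow(cm) < min_barcodes) {
      excluded <- c(excluded, g)
      next
    }
    mask <- do.call(rbind, masks[keep])
    rownames(mask) <- rownames(cm)
    out[[g]] <- structure(list(gene = g, counts = cm, mask = mask),
                          class = "gene_barcode_set")
  }
  attr(out, "excluded_genes") <- excluded
  out
}

#' Full barcode-processing stage
#'
#' Error-merges barcodes, maps them to genes, trims gene-edge insertions,
#' and assembles filtered per-gene barcode sets plus the intergenic neutral
#' table.
#'
#' @inheritParams merge_barcode_errors
#' @inheritParams map_and_trim
#' @inheritParams assemble_gene_sets
#' @param merge_errors set `FALSE` to skip the edit-distance merge (useful
#'   when barcodes are known exact, e.g. synthetic data).
#' @return list with `gene_sets`, `intergenic`, `mapping` (the
#'   [map_and_trim()] bookkeeping).
#' @export
process_counts <- function(tab, pool, max_edit = 4, edge_frac = 0.05,
                           r0_min = 80, min_barcodes = 4,
                           merge_errors = TRUE) {
  if (merge_errors) tab <- merge_barcode_errors(tab, max_edit)
  mp <- map_and_trim(tab, pool, edge_frac)
  sets <- assemble_gene_sets(mp$genes, r0_min = r0_min,
                             min_barcodes = min_barcodes)
  list(gene_sets = sets, intergenic = mp$intergenic, mapping = mp)
}
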