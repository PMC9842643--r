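#' Barcode count table
#'
#' Container for a BarSeq experiment: an integer matrix of read counts
#' (barcodes in rows, timepoints in columns) together with per-timepoint
#' metadata (generations elapsed, transfer index, total library reads).
#'
#' `total_reads` is the sequencing depth of the whole library at each
#' timepoint, including reads from barcodes not present in the matrix, so
#' `total_reads >= colSums(counts)` is not enforced.
#'
#' @param counts numeric matrix of nonnegative read counts with barcode
#'   rownames; one column per timepoint.
#' @param metadata data.frame with columns `timepoint`, `generations`,
#'   `transfer_index`, `total_reads`; one row per column of `counts`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have barcode rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  req <- c("timepoint", "generations", "transfer_index", "total_reads")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(metadata) != ncol(counts)) {
    stop("metadata rows must match count columns")
  }
  if (any(metadata$total_reads <= 0)) stop("total_reads must be positive")
  o <- order(metadata$transfer_index)
  if (is.unsorted(metadata$generations[o], strictly = TRUE)) {
    stop("generations must be strictly increasing with transfer_index")
  }
  structure(list(counts = counts, metadata = as.data.frame(metadata)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d barcodes x %d timepoints (%.2f-%.2f generations)\n",
              nrow(x$counts), ncol(x$counts),
              min(x$metadata$generations), max(x$metadata$generations)))
  invisible(x)
}

#' Timepoint metadata for a serial-dilution design
#'
#' Builds the per-timepoint metadata table for a serial-transfer experiment.
#' The number of generations per cycle depends only on the fold-dilution:
#' a 1:100 daily dilution corresponds to `log2(100)` (about 6.64) generations
#' per cycle, the conversion factor between per-generation and per-cycle
#' fitness.
#'
#' @param n_cycles number of transfers after the initial timepoint.
#' @param dilution fold-dilution per cycle (default 100 for 1:100).
#' @param total_reads sequencing depth per timepoint, recycled to
#'   `n_cycles + 1` values.
#' @param gens_per_cycle generations per cycle; defaults to `log2(dilution)`.
#' @return data.frame with columns `timepoint`, `generations`,
#'   `transfer_index`, `total_reads`.
#' @export
make_timepoints <- function(n_cycles, dilution = 100, total_reads = 2e7,
                            gens_per_cycle = log2(dilution)) {
  stopifnot(n_cycles >= 1, dilution > 1)
  idx <- 0:n_cycles
  data.frame(timepoint = idx,
             generations = idx * gens_per_cycle,
             transfer_index = idx,
             total_reads = rep_len(total_reads, n_cycles + 1))
}

#' Read / write count tables
#'
#' Tab-separated layout: a `barcode` column followed by one column per
#' timepoint (named `t<index>`), with a sidecar metadata table
#' (`timepoint`, `generations`, `transfer_index`, `total_reads`).
#'
#' @param x a `count_table`.
#' @param counts_file,metadata_file file paths.
#' @return `write_count_table` returns `x` invisibly; `read_count_table`
#'   returns a `count_table`.
#' @export
write_count_table <- function(x, counts_file, metadata_file) {
  df <- data.frame(barcode = rownames(x$counts), x$counts,
                   check.names = FALSE)
  names(df)[-1] <- paste0("t", x$metadata$timepoint)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_file, metadata_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE)
  meta <- utils::read.delim(metadata_file)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  count_table(m, meta)
}

#' Read / write barcode pool tables
#'
#' The pool table maps each barcode to its transposon insertion: columns
#' `barcode`, `position` (1-based genomic coordinate), `gene` (empty/NA for
#' intergenic insertions), `frac_within_gene` (fractional position in the
#' gene, 0 at start), `intergenic` (0/1 flag), and optionally `gc`.
#'
#' @param pool data.frame as described.
#' @param file file path.
#' @export
write_pool <- function(pool, file) {
  utils::write.table(pool, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pool)
}

#' @rdname write_pool
#' @export
read_pool <- function(file) {
  pool <- utils::read.delim(file)
  pool$intergenic <- as.logical(pool$intergenic)
  pool
}

# Evaluate fn() with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

# Deterministic 31-bit sub-seed from a base seed and a string key, so
# per-gene/per-replicate streams do not depend on processing order.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
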