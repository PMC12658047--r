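#' Construct a count matrix container
#'
#' Bundles an integer genes-by-samples UMI count matrix with a per-gene
#' spike-in flag and a per-sample library label. All pipeline stages consume
#' and return this container so that spike-in rows and library assignments
#' travel with the counts.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Counts must be non-negative and
#'   integral.
#' @param is_spikein logical vector, one entry per gene.
#' @param library per-sample library label (coerced to factor).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `is_spikein`, `library`.
#' @export
count_matrix <- function(counts, is_spikein, library) {
  ps_assert(is.matrix(counts), "counts must be a matrix")
  ps_assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
            "counts must have gene ids as rownames and sample ids as colnames")
  ps_assert(!anyDuplicated(rownames(counts)), "duplicate gene ids")
  ps_assert(!anyDuplicated(colnames(counts)), "duplicate sample ids")
  ps_assert(all(is.finite(counts)) && all(counts >= 0),
            "counts must be finite and non-negative")
  ps_assert(max(abs(counts - round(counts))) < 1e-8,
            "counts must be integral")
  ps_assert(length(is_spikein) == nrow(counts),
            "is_spikein length must equal the number of genes")
  ps_assert(length(library) == ncol(counts),
            "library length must equal the number of samples")
  structure(
    list(counts = counts,
         is_spikein = as.logical(is_spikein),
         library = factor(library)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d spike-ins) x %d samples, %d libraries\n",
              nrow(x$counts), sum(x$is_spikein), ncol(x$counts),
              nlevels(x$library)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset helper preserving flags/labels.
cm_subset <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  count_matrix(x$counts[gi, si, drop = FALSE],
               x$is_spikein[if (is.logical(gi)) which(gi) else gi],
               droplevels(x$library[if (is.logical(si)) which(si) else si]))
}

#' Read a genes-by-samples count matrix from TSV
#'
#' The file must have a header of sample ids and the gene id in the first
#' column. Rows whose id starts with `spikein_prefix` are flagged as
#' spike-ins. Column order is preserved. Malformed (non-integer) cells are an
#' error, never silently coerced.
#'
#' @param path TSV file path.
#' @param metadata a `sample_metadata` data frame (see [read_metadata()]); its
#'   `library` column supplies per-sample library labels. Sample ids in the
#'   metadata must be a superset of the count columns.
#' @param spikein_prefix gene-id prefix marking spike-in rows (default the
#'   ERCC convention `"ERCC-"`).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, metadata = NULL, spikein_prefix = "ERCC-") {
  ps_assert(file.exists(path), "counts file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  ps_assert(ncol(df) >= 2, "counts file needs a gene-id column plus samples")
  gene_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) | abs(num - round(num)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ps_stop(sprintf("non-integer count at row %d (gene %s), column '%s'",
                    bad[1, 1], gene_ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  rownames(num) <- gene_ids
  lib <- rep(NA_character_, ncol(num))
  if (!is.null(metadata)) {
    ps_assert(all(colnames(num) %in% metadata$sample_id),
              "metadata sample ids must cover all count columns")
    lib <- as.character(metadata$library[match(colnames(num),
                                               metadata$sample_id)])
  }
  is_spike <- startsWith(gene_ids, spikein_prefix)
  ps_log(sprintf("read_counts: %d genes (%d spike-ins flagged by prefix '%s') x %d samples",
                 nrow(num), sum(is_spike), spikein_prefix, ncol(num)))
  count_matrix(num, is_spike, lib)
}

#' Write a count matrix as TSV
#'
#' First column `gene_id`, then one column per sample. Deterministic for
#' identical input.
#' @param x a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from CSV
#'
#' Requires at minimum `sample_id`, `condition` (PE/NP) and `library`
#' columns; further clinical covariates are carried through untouched.
#'
#' @param path CSV file path.
#' @return data frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  ps_assert(file.exists(path), "metadata file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("sample_id", "condition", "library")) {
    ps_assert(col %in% names(df), "metadata missing required column: ", col)
  }
  ps_assert(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata as CSV
#' @param meta metadata data frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Binary condition as 0/1 (PE = 1, NP = 0); errors on anything else.
condition_indicator <- function(condition) {
  x <- as.character(condition)
  ps_assert(all(x %in% c("PE", "NP")), "condition must be coded PE/NP")
  as.integer(x == "PE")
}
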