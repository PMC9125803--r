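#' Count table construction
#'
#' Wraps a samples x taxa matrix of sequencing counts, the raw input to the
#' compositional pipeline. Rows are samples, columns are taxa (OTUs at any
#' rank). Entries must be nonnegative integers.
#'
#' @param values numeric matrix, n samples x S taxa, nonnegative integers.
#' @param sample_ids character vector of n unique sample labels; defaults to
#'   rownames of `values`.
#' @param taxon_ids character vector of S unique taxon labels; defaults to
#'   colnames of `values`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(values, sample_ids = rownames(values),
                        taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  .assert(.is_count_matrix(values), "counts must be finite nonnegative integers")
  .assert(nrow(values) >= 1L, "need at least one sample")
  .assert(ncol(values) >= 2L, "need at least two taxa (S >= 2)")
  sample_ids <- as.character(sample_ids %||% paste0("sample", seq_len(nrow(values))))
  taxon_ids <- as.character(taxon_ids %||% paste0("taxon", seq_len(ncol(values))))
  .assert(length(sample_ids) == nrow(values), "sample_ids length mismatch")
  .assert(length(taxon_ids) == ncol(values), "taxon_ids length mismatch")
  .unique_labels(sample_ids, "sample")
  .unique_labels(taxon_ids, "taxon")
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, total count %s\n",
              nrow(x$values), ncol(x$values),
              format(sum(x$values), big.mark = ",")))
  invisible(x)
}

#' Convert counts to proportions
#'
#' Estimates per-sample taxon proportions from counts. A pseudocount is added
#' to every cell (not only zero cells, so all taxa are treated exchangeably)
#' before row-normalisation; it is required whenever a zero count is present,
#' because the downstream log-ratio transform needs strictly positive
#' proportions.
#'
#' @param counts a [count_table].
#' @param pseudocount nonnegative scalar added to every count; default 0.5.
#' @return an object of class `composition_table` with fields `values`
#'   (rows summing to 1), `sample_ids`, `taxon_ids`, `pseudocount`.
#' @export
counts_to_proportions <- function(counts, pseudocount = 0.5) {
  .assert(inherits(counts, "count_table"), "counts must be a count_table")
  .assert(is.numeric(pseudocount) && length(pseudocount) == 1L &&
            is.finite(pseudocount) && pseudocount >= 0,
          "pseudocount must be a nonnegative scalar")
  z <- counts$values
  if (pseudocount == 0 && any(z == 0)) {
    idx <- which(z == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "zero count for sample '%s', taxon '%s': a pseudocount > 0 is required",
      counts$sample_ids[idx[1L]], counts$taxon_ids[idx[2L]]), call. = FALSE)
  }
  zp <- z + pseudocount
  rho <- zp / rowSums(zp)
  composition_table(rho, counts$sample_ids, counts$taxon_ids, pseudocount)
}

#' @rdname counts_to_proportions
#' @param values n x S matrix of strictly positive proportions with unit row
#'   sums.
#' @param sample_ids,taxon_ids labels, as in [count_table].
#' @export
composition_table <- function(values, sample_ids = rownames(values),
                              taxon_ids = colnames(values), pseudocount = 0) {
  values <- as.matrix(values)
  .assert(all(is.finite(values)) && all(values > 0),
          "proportions must be strictly positive")
  .assert(max(abs(rowSums(values) - 1)) < 1e-10, "rows must sum to 1")
  sample_ids <- as.character(sample_ids %||% paste0("sample", seq_len(nrow(values))))
  taxon_ids <- as.character(taxon_ids %||% paste0("taxon", seq_len(ncol(values))))
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids, pseudocount = pseudocount),
            class = "composition_table")
}

#' Log-ratio transform
#'
#' Maps proportions to unconstrained coordinates y[i, s] =
#' log(rho[i, s] / rho[i, ref]) for the S - 1 non-reference taxa, preserving
#' the input taxon order. The reference taxon defaults to the last column; the
#' choice only shifts the coordinates (see the inverse transform) and model
#' results are insensitive to it.
#'
#' @param comp a `composition_table`.
#' @param reference_taxon label of the reference taxon; default last column.
#' @return an object of class `log_ratio_table` with fields `values`
#'   (n x (S-1)), `sample_ids`, `taxon_ids` (non-reference taxa in order) and
#'   `reference_taxon`.
#' @export
log_ratio_transform <- function(comp, reference_taxon = NULL) {
  .assert(inherits(comp, "composition_table"), "comp must be a composition_table")
  taxa <- comp$taxon_ids
  reference_taxon <- reference_taxon %||% taxa[length(taxa)]
  .assert(reference_taxon %in% taxa, "unknown reference taxon '%s'",
          reference_taxon)
  ref <- match(reference_taxon, taxa)
  y <- log(comp$values[, -ref, drop = FALSE]) - log(comp$values[, ref])
  log_ratio_table(y, comp$sample_ids, taxa[-ref], reference_taxon)
}

#' @rdname log_ratio_transform
#' @param values n x (S-1) real matrix of log-ratios.
#' @param sample_ids sample labels.
#' @param taxon_ids the S-1 non-reference taxon labels, in order.
#' @export
log_ratio_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values), reference_taxon) {
  values <- as.matrix(values)
  .assert(all(is.finite(values)), "log-ratios must be finite")
  sample_ids <- as.character(sample_ids %||% paste0("sample", seq_len(nrow(values))))
  taxon_ids <- as.character(taxon_ids %||% paste0("taxon", seq_len(ncol(values))))
  .assert(length(taxon_ids) == ncol(values), "taxon_ids length mismatch")
  .assert(!(reference_taxon %in% taxon_ids),
          "reference taxon cannot appear among the non-reference taxa")
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids, reference_taxon = reference_taxon),
            class = "log_ratio_table")
}

#' Inverse log-ratio transform
#'
#' Reconstructs proportions from log-ratio coordinates. The reference
#' proportion is rho[i, ref] = 1 / (1 + sum_s exp(y[i, s])) and
#' rho[i, s] = rho[i, ref] * exp(y[i, s]); this is the unique assignment for
#' which the proportions both satisfy the exp relation and sum to one. The
#' computation goes through a shifted log-sum-exp so large finite y never
#' produce NaN.
#'
#' @param y a `log_ratio_table`.
#' @return a `composition_table` with the reference taxon restored as the
#'   last column.
#' @export
inverse_log_ratio <- function(y) {
  .assert(inherits(y, "log_ratio_table"), "y must be a log_ratio_table")
  v <- y$values
  lse <- .lse_rows_with_zero(v)            # log(1 + sum exp(y)) per row
  rho <- exp(cbind(v, 0) - lse)            # last column is the reference
  rho <- pmax(rho, .Machine$double.xmin)   # extreme y underflow to 0 otherwise
  rho <- rho / rowSums(rho)                # mop up last-ulp rounding
  composition_table(rho, y$sample_ids, c(y$taxon_ids, y$reference_taxon))
}

#' Read / write count tables
#'
#' Count tables are plain TSV/CSV: samples as rows, taxa as columns, a header
#' row of taxon labels and the first column holding sample labels. The
#' delimiter is inferred from the file extension (`.csv` uses comma,
#' everything else tab).
#'
#' @param path file path.
#' @return for `read_count_table`, a [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          row.names = 1L, check.names = FALSE)
  count_table(as.matrix(df))
}

#' @rdname read_count_table
#' @param x a [count_table] or data-frame-like object to write.
#' @export
write_count_table <- function(x, path) {
  .write_labeled_matrix(x$values, path, "taxon")
}

#' @rdname read_count_table
#' @param y a `log_ratio_table`; the reference taxon is recorded in a JSON
#'   sidecar `<path>.meta.json`.
#' @export
write_log_ratio_table <- function(y, path) {
  .write_labeled_matrix(y$values, path, "taxon")
  jsonlite::write_json(list(reference_taxon = y$reference_taxon),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
}

#' @rdname read_count_table
#' @export
read_log_ratio_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          row.names = 1L, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  log_ratio_table(as.matrix(df), rownames(df), colnames(df),
                  meta$reference_taxon)
}

.sep_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

.write_labeled_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
}
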