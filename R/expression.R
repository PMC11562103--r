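#' Construct a gene-by-sample expression matrix
#'
#' The basic data container of the package: a numeric matrix with genes in
#' rows and samples in columns, unique dimnames, and a unit tag. All
#' downstream functions accept the plain matrix; this constructor only
#' validates and stamps the unit.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids,sample_ids Optional character vectors overriding dimnames.
#' @param unit One of `"tpm"`, `"log2_fpkm_plus1"`, `"arbitrary"`.
#' @return The validated matrix with a `"unit"` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              unit = c("arbitrary", "tpm", "log2_fpkm_plus1")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("ID lengths inconsistent with matrix shape")
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (any(!is.finite(values))) stop("non-finite values in expression matrix")
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "unit") <- unit
  values
}

#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample IDs and gene IDs in the first column.
#' Plain or gzip-compressed tab-separated text is accepted. Duplicate gene
#' IDs are collapsed by the per-cell maximum (with a warning), the common
#' convention when several annotation rows map to one symbol.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @param unit Unit tag recorded on the matrix.
#' @param sep Field separator, default tab.
#' @return Expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, unit = c("arbitrary", "tpm", "log2_fpkm_plus1"),
                            sep = "\t") {
  unit <- match.arg(unit)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.table(con, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", colClasses = NA)
  if (ncol(df) < 2) stop("expected a gene-ID column plus at least one sample column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric values in sample column '", colnames(df)[-1][bad], "'")
  }
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicated gene ID(s) collapsed by max")
    m <- do.call(rbind, lapply(split(seq_along(ids), ids), function(i) {
      apply(m[i, , drop = FALSE], 2, max)
    }))
    ids <- rownames(m)
    # restore first-occurrence order
    ord <- order(match(ids, as.character(df[[1]])))
    m <- m[ord, , drop = FALSE]
    ids <- ids[ord]
  }
  rownames(m) <- ids
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header row of sample IDs, first column
#' `gene_id`. Values are written at full precision so a read round-trips.
#'
#' @param x Expression matrix.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert log2(1+FPKM) values to TPM
#'
#' Applies the inverse log transform `FPKM = 2^v - 1` (clipped at zero) and
#' renormalizes each sample column to sum to one million, the standard
#' FPKM-to-TPM conversion.
#'
#' @param x Expression matrix with unit `log2_fpkm_plus1`.
#' @return Expression matrix in TPM.
#' @export
convert_log2fpkm_to_tpm <- function(x) {
  if (!identical(attr(x, "unit"), "log2_fpkm_plus1"))
    stop("input unit must be 'log2_fpkm_plus1'")
  fpkm <- pmax(2^x - 1, 0)
  totals <- colSums(fpkm)
  if (any(totals <= 0))
    stop("sample column(s) with zero total FPKM cannot be renormalized: ",
         paste(colnames(x)[totals <= 0], collapse = ", "))
  tpm <- sweep(fpkm, 2, totals, "/") * 1e6
  expression_matrix(tpm, unit = "tpm")
}

#' Restrict an expression matrix to a transcription-factor list
#'
#' @param x Expression matrix.
#' @param tf_list Character vector of gene IDs, or path to a plain-text file
#'   with one ID per line.
#' @return Submatrix with rows in the order of the list; IDs absent from the
#'   matrix are dropped with a warning reporting the count.
#' @export
restrict_to_tf_list <- function(x, tf_list) {
  if (length(tf_list) == 1 && file.exists(tf_list))
    tf_list <- readLines(tf_list)
  tf_list <- trimws(tf_list)
  tf_list <- tf_list[nzchar(tf_list)]
  if (length(tf_list) == 0) stop("empty TF list")
  hit <- tf_list[tf_list %in% rownames(x)]
  if (length(hit) == 0) stop("no TF list IDs found in the expression matrix")
  miss <- length(tf_list) - length(hit)
  if (miss > 0) warning(miss, " TF list ID(s) not present in the matrix")
  out <- x[hit, , drop = FALSE]
  attr(out, "unit") <- attr(x, "unit")
  out
}
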