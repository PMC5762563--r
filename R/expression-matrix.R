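#' Construct an expression matrix for one condition
#'
#' The package's central container for one condition's expression data:
#' a dense numeric matrix stored samples x genes (rows are the `n_t` samples,
#' columns are the `p` genes), with a condition name, a value kind and an
#' optional tumor/normal class per sample. All downstream linear algebra
#' assumes this orientation, so files in either orientation are transposed
#' on read, never later.
#'
#' @param values Numeric matrix, samples in rows and genes in columns.
#'   Row and column names are used as sample/gene IDs when `gene_ids` /
#'   `sample_ids` are not given.
#' @param condition Condition (e.g. cancer type) name.
#' @param value_kind `"raw_count"` (non-negative integers, for differential
#'   expression) or `"log2_fpkm"` (finite reals, for network construction).
#' @param sample_class Optional character vector, one of `"tumor"`/`"normal"`
#'   per sample.
#' @param gene_ids,sample_ids Optional explicit IDs overriding dimnames.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, condition, value_kind = c("log2_fpkm", "raw_count"),
                              sample_class = NULL, gene_ids = NULL, sample_ids = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_comod("expression values must be numeric", "comod_parse_error")
  }
  if (!is.null(gene_ids)) colnames(values) <- gene_ids
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (is.null(colnames(values))) colnames(values) <- paste0("g", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop_comod(paste0("duplicate gene IDs: ", paste(head(dup, 5), collapse = ", ")),
               "comod_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_comod(paste0("duplicate sample IDs: ", paste(head(dup, 5), collapse = ", ")),
               "comod_validation_error")
  }
  if (nrow(values) < 2L) stop_comod("need at least 2 samples", "comod_validation_error")
  if (ncol(values) < 1L) stop_comod("need at least 1 gene", "comod_validation_error")
  if (anyNA(values)) {
    stop_comod("missing expression values are not supported; impute or filter upstream",
               "comod_validation_error")
  }
  if (value_kind == "raw_count") {
    if (any(values < 0)) stop_comod("raw counts must be non-negative", "comod_validation_error")
    if (any(values != round(values))) {
      stop_comod("raw counts must be integers", "comod_validation_error")
    }
    if (max(values) <= .Machine$integer.max) storage.mode(values) <- "integer"
  } else if (any(!is.finite(values))) {
    stop_comod("log2-FPKM values must be finite", "comod_validation_error")
  }
  if (!is.null(sample_class)) {
    sample_class <- as.character(sample_class)
    if (length(sample_class) != nrow(values)) {
      stop_comod("sample_class length must equal the number of samples", "comod_validation_error")
    }
    if (!all(sample_class %in% c("tumor", "normal"))) {
      stop_comod("sample_class entries must be 'tumor' or 'normal'", "comod_validation_error")
    }
    names(sample_class) <- rownames(values)
  }
  structure(
    list(values = values, condition = as.character(condition),
         value_kind = value_kind, sample_class = sample_class),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> condition '%s': %d samples x %d genes (%s)\n",
              x$condition, nrow(x$values), ncol(x$values), x$value_kind))
  if (!is.null(x$sample_class)) {
    tb <- table(x$sample_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample IDs of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) colnames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) rownames(x$values)

#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "sample_id")
  out <- tidyr::pivot_longer(out, -"sample_id", names_to = "gene", values_to = "value")
  out$condition <- x$condition
  if (!is.null(x$sample_class)) out$sample_class <- x$sample_class[out$sample_id]
  out
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV matrix with one header row and a leading ID column;
#' gzip-compressed files are read transparently. The file may store genes in
#' rows or samples in rows; the result is always samples x genes.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (IDs in the first column are genes) or
#'   `"samples_in_rows"`.
#' @param value_kind,condition,sample_class See [expression_matrix()].
#' @param delim Field delimiter; default tab.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                                   value_kind = c("log2_fpkm", "raw_count"),
                                   condition = basename(path), sample_class = NULL,
                                   delim = "\t") {
  orientation <- match.arg(orientation)
  value_kind <- match.arg(value_kind)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2L) stop_comod("expected an ID column plus at least one data column",
                                 "comod_parse_error")
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body), dimnames = dimnames(body)))
  if (anyNA(num) && !anyNA(body)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1, ]
    stop_comod(sprintf("non-numeric cell at row '%s', column '%s'",
                       ids[bad[1]], colnames(body)[bad[2]]), "comod_parse_error")
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_comod(sprintf("missing cell at row '%s', column '%s'",
                       ids[bad[1]], colnames(body)[bad[2]]), "comod_parse_error")
  }
  rownames(num) <- ids
  if (orientation == "genes_in_rows") num <- t(num)
  expression_matrix(num, condition = condition, value_kind = value_kind,
                    sample_class = sample_class)
}

#' Write an expression matrix to delimited text
#'
#' Round-trips exactly with [read_expression_matrix()]: counts are written as
#' integers and reals at full precision.
#'
#' @param x An `expr_matrix`.
#' @param path Output path (`.gz` suffix compresses).
#' @param orientation Orientation to write; default genes in rows.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes_in_rows") t(x$values) else x$values
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Align several expression matrices to one gene panel
#'
#' Restricts and reorders every matrix to the same ordered gene set, as
#' required before a joint decomposition (one shared right basis implies one
#' shared gene order). Sample dimensions are untouched. Idempotent.
#'
#' @param matrices List of `expr_matrix` objects.
#' @param gene_set Ordered character vector of gene IDs; every gene must be
#'   present in every matrix.
#' @return List of aligned `expr_matrix` objects.
#' @export
align_gene_panels <- function(matrices, gene_set) {
  stopifnot(length(matrices) >= 1L)
  gene_set <- as.character(gene_set)
  missing <- purrr::map_dfr(matrices, function(m) {
    absent <- setdiff(gene_set, gene_ids(m))
    if (length(absent)) tibble(gene = absent, condition = m$condition) else NULL
  })
  if (nrow(missing)) {
    stop_comod(paste0("genes missing from matrices: ",
                      paste(sprintf("%s (%s)", missing$gene, missing$condition)[
                        seq_len(min(5, nrow(missing)))], collapse = ", ")),
               "comod_validation_error")
  }
  lapply(matrices, function(m) {
    m$values <- m$values[, gene_set, drop = FALSE]
    m
  })
}

#' log2 transform of linear FPKM values
#'
#' `log2(FPKM + 1)`; the +1 offset keeps zero-FPKM genes finite.
#'
#' @param fpkm Non-negative numeric matrix or vector of linear FPKM values.
#' @return Same shape, log2 scale.
#' @export
log2_fpkm <- function(fpkm) {
  if (any(fpkm < 0)) stop_comod("FPKM values must be non-negative", "comod_validation_error")
  log2(fpkm + 1)
}
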