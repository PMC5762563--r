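#' Built-in nonparametric differential-expression backend
#'
#' A deterministic two-sided Wilcoxon rank-sum test per gene between tumor
#' and normal samples, with Benjamini-Hochberg adjustment. Two variants are
#' provided as distinct "methods": the test is applied either to
#' library-size-normalized log2 counts per million (`ranksum_logcounts`,
#' the default) or to the raw counts (`ranksum_counts`). External tools
#' (limma, edgeR, DESeq, SAMseq) are consumed through [import_de_table()],
#' never re-implemented.
#'
#' @param x An `expr_matrix` with `value_kind = "raw_count"` and both tumor
#'   and normal samples (at least 2 per class).
#' @param method `"ranksum_logcounts"` or `"ranksum_counts"`.
#' @return A `de_result` tibble with columns `gene`, `p_value`, `adj_p`;
#'   condition and method names stored as attributes. Genes with identical
#'   values in all samples get `p_value = 1`.
#' @export
run_builtin_de <- function(x, method = c("ranksum_logcounts", "ranksum_counts")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$value_kind != "raw_count") {
    stop_comod("built-in DE requires raw counts", "comod_validation_error")
  }
  if (is.null(x$sample_class)) {
    stop_comod("sample_class (tumor/normal) required for DE", "comod_validation_error")
  }
  cls <- x$sample_class
  if (sum(cls == "tumor") < 2L || sum(cls == "normal") < 2L) {
    stop_comod("need at least 2 tumor and 2 normal samples", "comod_validation_error")
  }
  vals <- x$values
  constant <- apply(vals, 2, function(v) max(v) == min(v))
  if (method == "ranksum_logcounts") {
    libsize <- rowSums(vals)
    libsize[libsize == 0] <- 1
    vals <- log2(sweep(vals, 1, libsize, "/") * 1e6 + 1)
  }
  tum <- cls == "tumor"
  pv <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    if (constant[j] || max(v) == min(v)) return(1)
    suppressWarnings(wilcox.test(v[tum], v[!tum], exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  pv[is.na(pv)] <- 1
  de_result(tibble(gene = colnames(vals), p_value = pv, adj_p = p.adjust(pv, "BH")),
            condition = x$condition, method = method)
}

de_result <- function(tbl, condition, method, metadata = NULL) {
  attr(tbl, "condition") <- condition
  attr(tbl, "method") <- method
  attr(tbl, "metadata") <- metadata
  class(tbl) <- unique(c("de_result", class(tbl)))
  tbl
}

#' Import a differential-expression result table from an external tool
#'
#' Adapter for limma/edgeR/DESeq/SAMseq exports: a delimited file with a gene
#' column and a multiple-test-corrected p-value column (names configurable,
#' e.g. edgeR's `FDR`). Tool-specific settings (SAMseq permutation and
#' resample counts, limma's TMM+voom preprocessing) belong to the external
#' run and can be recorded via `metadata`.
#'
#' @param path File path.
#' @param condition,method Names recorded on the result.
#' @param col_gene,col_adj_p Column names in the file.
#' @param col_p Optional raw p-value column.
#' @param metadata Optional named list of external-tool settings.
#' @return A `de_result` tibble.
#' @export
import_de_table <- function(path, condition, method, col_gene = "gene",
                            col_adj_p = "adj_p", col_p = NULL, metadata = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c(col_gene, col_adj_p, col_p)
  if (!all(need %in% names(raw))) {
    stop_comod(paste0("expected columns: ", paste(setdiff(need, names(raw)), collapse = ", ")),
               "comod_parse_error")
  }
  adj <- suppressWarnings(as.numeric(raw[[col_adj_p]]))
  if (nrow(raw) > 0 && (anyNA(adj) || any(adj < 0) || any(adj > 1))) {
    stop_comod("adjusted p-values must lie in [0, 1]", "comod_validation_error")
  }
  if (anyDuplicated(raw[[col_gene]])) {
    stop_comod("duplicate genes in DE table", "comod_validation_error")
  }
  out <- tibble(gene = raw[[col_gene]],
                p_value = if (!is.null(col_p)) suppressWarnings(as.numeric(raw[[col_p]])) else NA_real_,
                adj_p = adj)
  de_result(out, condition = condition, method = method, metadata = metadata)
}

#' Genes shared across conditions for one method
#'
#' Step 1 of the three-step consensus: genes significantly differentially
#' expressed (adjusted p strictly below `alpha`) in at least `min_conditions`
#' conditions under a single method.
#'
#' @param results List of `de_result` tibbles, one per condition, all from
#'   the same method.
#' @param alpha Significance cutoff on adjusted p (default 0.05).
#' @param min_conditions Minimum number of conditions (default 4; use 2 for
#'   the 4-condition variant of the workflow).
#' @return Sorted character vector of genes.
#' @export
per_method_shared_genes <- function(results, alpha = 0.05, min_conditions = 4L) {
  stopifnot(length(results) >= 1L, alpha > 0, alpha < 1)
  methods <- unique(vapply(results, function(r) attr(r, "method") %||% NA_character_,
                           character(1)))
  if (length(methods) > 1L) {
    stop_comod("all results must come from the same method", "comod_validation_error")
  }
  if (min_conditions < 1L || min_conditions > length(results)) {
    stop_comod("min_conditions must be between 1 and the number of conditions",
               "comod_validation_error")
  }
  sig <- unlist(lapply(results, function(r) r$gene[r$adj_p < alpha]))
  counts <- table(sig)
  sort(names(counts)[counts >= min_conditions])
}

#' Intersection of per-method gene sets
#'
#' Step 2 of the consensus: genes present in every method's shared set.
#'
#' @param method_sets List of character vectors (one per method).
#' @return Sorted character vector.
#' @export
intersect_methods <- function(method_sets) {
  if (length(method_sets) < 1L) stop_comod("need at least one gene set", "comod_validation_error")
  sort(Reduce(intersect, method_sets))
}

#' Map gene IDs and drop redundant ones
#'
#' Step 3 of the consensus: source IDs without a mapping are removed; when
#' several source IDs share one canonical ID, the lexicographically smallest
#' source ID is kept as the representative (a deterministic stand-in for
#' "remove the redundant one"). The result is reported in canonical IDs.
#'
#' @param genes Character vector of source gene IDs.
#' @param id_map Tibble with columns `source_id`, `canonical_id`
#'   (see [read_id_map()]).
#' @return Sorted character vector of canonical IDs.
#' @export
map_and_dedupe <- function(genes, id_map) {
  hit <- id_map[id_map$source_id %in% genes, , drop = FALSE]
  if (nrow(hit) == 0L) return(character(0))
  hit <- hit[order(hit$source_id), , drop = FALSE]
  keep <- !duplicated(hit$canonical_id)
  sort(unique(hit$canonical_id[keep]))
}

#' Consensus differentially expressed genes across conditions and methods
#'
#' The full three-step procedure: per-method sharing across conditions,
#' intersection across methods, then optional ID mapping and de-redundancy.
#'
#' @param results_by_method Named list; each element is a list of
#'   `de_result` tibbles (one per condition) for one method.
#' @param alpha,min_conditions See [per_method_shared_genes()].
#' @param id_map Optional ID map applied via [map_and_dedupe()].
#' @return Sorted character vector of consensus genes.
#' @export
consensus_genes <- function(results_by_method, alpha = 0.05, min_conditions = 4L,
                            id_map = NULL) {
  sets <- lapply(results_by_method, per_method_shared_genes,
                 alpha = alpha, min_conditions = min_conditions)
  out <- intersect_methods(sets)
  if (!is.null(id_map)) out <- map_and_dedupe(out, id_map)
  out
}
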