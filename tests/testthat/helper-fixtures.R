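# Shared fixtures and independent oracles, all built in code.

tiny_expr <- function(condition = "c1", value_kind = "log2_fpkm",
                      n = 4L, p = 3L, seed = 1L, sample_class = NULL) {
  set.seed(seed)
  vals <- matrix(round(rnorm(n * p, 5, 1), 4), n, p,
                 dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(p))))
  if (value_kind == "raw_count") vals <- matrix(rpois(n * p, 50), n, p, dimnames = dimnames(vals))
  expression_matrix(vals, condition = condition, value_kind = value_kind,
                    sample_class = sample_class)
}

random_spd <- function(p, seed = 1L) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) + diag(0.5, p)
}

# Naive triple-loop oracle for the pairwise S matrix.
build_s_oracle <- function(Es) {
  Tn <- length(Es)
  p <- ncol(Es[[1]])
  S <- matrix(0, p, p)
  for (t in seq_len(Tn)) {
    for (r in seq_len(Tn)) {
      if (r > t) {
        S <- S + Es[[t]] %*% solve(Es[[r]]) + Es[[r]] %*% solve(Es[[t]])
      }
    }
  }
  S / (Tn * (Tn - 1))
}

# Exhaustive consensus oracle: loop over genes x conditions x methods.
consensus_oracle <- function(results_by_method, alpha, min_conditions) {
  genes <- unique(unlist(lapply(results_by_method, function(rs) {
    unlist(lapply(rs, function(r) r$gene))
  })))
  keep <- vapply(genes, function(g) {
    all(vapply(results_by_method, function(rs) {
      n_sig <- sum(vapply(rs, function(r) {
        i <- match(g, r$gene)
        !is.na(i) && r$adj_p[i] < alpha
      }, logical(1)))
      n_sig >= min_conditions
    }, logical(1)))
  }, logical(1))
  sort(genes[keep])
}

# Random DE result for oracle comparisons.
random_de_result <- function(genes, condition, method, seed) {
  set.seed(seed)
  tbl <- tibble::tibble(gene = genes, p_value = NA_real_, adj_p = runif(length(genes)))
  attr(tbl, "condition") <- condition
  attr(tbl, "method") <- method
  class(tbl) <- c("de_result", class(tbl))
  tbl
}

# Best modularity over every bipartition of a small graph (exhaustive oracle).
best_bipartition_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 12)
  best <- -Inf
  best_m <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    membership <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    m <- igraph::modularity(g, membership)
    if (m > best) {
      best <- m
      best_m <- membership
    }
  }
  list(modularity = best, membership = best_m)
}

expect_same_partition <- function(labels_a, labels_b) {
  # equal up to label renaming
  expect_equal(length(labels_a), length(labels_b))
  ta <- as.integer(factor(labels_a, levels = unique(labels_a)))
  tb <- as.integer(factor(labels_b, levels = unique(labels_b)))
  expect_equal(ta, tb)
}
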