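make_counts <- function(vals, classes, condition = "c1") {
  expression_matrix(vals, condition = condition, value_kind = "raw_count",
                    sample_class = classes)
}

test_that("built-in DE ranks a perfectly separated gene first and is deterministic", {
  set.seed(42)
  n <- 6L
  vals <- matrix(rpois(n * 10, 50), n, 10,
                 dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
  vals[, "g1"] <- c(100, 120, 110, 10, 12, 11)
  x <- make_counts(vals, c(rep("tumor", 3), rep("normal", 3)))
  de <- run_builtin_de(x)
  expect_equal(de$gene[which.min(de$adj_p)], "g1")
  expect_identical(de, run_builtin_de(x))
})

test_that("a constant gene gets p = 1 and single-class input errors", {
  set.seed(1)
  vals <- matrix(rpois(40, 30), 4, 10,
                 dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  vals[, "g5"] <- 7L
  x <- make_counts(vals, c("tumor", "tumor", "normal", "normal"))
  de <- run_builtin_de(x)
  expect_equal(de$p_value[de$gene == "g5"], 1)

  y <- make_counts(vals, rep("tumor", 4))
  expect_error(run_builtin_de(y), "tumor and")
})

test_that("under a global NB null, almost no gene is called at adjusted p < 0.05", {
  cfg <- de_sim_config(seed = 7, n_conditions = 1L)
  cfg$de$lfc <- 0
  panel <- simulate_count_panel(cfg)
  de <- run_builtin_de(panel$matrices[[1]])
  expect_lte(sum(de$adj_p < 0.05), 5L)
})

test_that("import_de_table maps columns and validates p-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlogFC\tFDR", "g1\t2.3\t0.01", "g2\t-1\t0.8"), path)
  de <- import_de_table(path, "BRCA", "edgeR", col_adj_p = "FDR")
  expect_equal(de$adj_p, c(0.01, 0.8))
  expect_equal(attr(de, "method"), "edgeR")

  writeLines(c("gene\tpadj", "g1\t1.7"), path)
  expect_error(import_de_table(path, "c", "m", col_adj_p = "padj"), "\\[0, 1\\]")
  writeLines(c("gene\tpadj", "g1\t0.1", "g1\t0.2"), path)
  expect_error(import_de_table(path, "c", "m", col_adj_p = "padj"), "duplicate")
  writeLines(c("gene\tother", "g1\t0.1"), path)
  expect_error(import_de_table(path, "c", "m"), "adj_p")
  writeLines("gene\tadj_p", path)
  expect_equal(nrow(import_de_table(path, "c", "m")), 0L)
})

test_that("per-method sharing respects the threshold boundary exactly", {
  genes <- paste0("g", 1:3)
  mk <- function(p_g1, cond) {
    r <- tibble::tibble(gene = genes, p_value = NA_real_, adj_p = c(p_g1, 0.5, 0.01))
    attr(r, "condition") <- cond
    attr(r, "method") <- "m1"
    r
  }
  # g1 significant in 4 of 8 conditions -> in; g3 in all 8; g2 never
  results <- lapply(1:8, function(i) mk(if (i <= 4) 0.01 else 0.9, paste0("c", i)))
  out <- per_method_shared_genes(results, alpha = 0.05, min_conditions = 4)
  expect_setequal(out, c("g1", "g3"))
  # 3 of 8 at m = 4 -> out
  results3 <- lapply(1:8, function(i) mk(if (i <= 3) 0.01 else 0.9, paste0("c", i)))
  expect_setequal(per_method_shared_genes(results3, 0.05, 4), "g3")
  # mixed methods refuse
  attr(results[[1]], "method") <- "m2"
  expect_error(per_method_shared_genes(results, 0.05, 4), "same method")
})

test_that("strictness at the cutoff: adjusted p exactly alpha is not significant", {
  r <- tibble::tibble(gene = c("g1", "g2"), p_value = NA_real_, adj_p = c(0.05, 0.049))
  attr(r, "method") <- "m"
  expect_equal(per_method_shared_genes(list(r), alpha = 0.05, min_conditions = 1), "g2")
})

test_that("method intersection and ID dedup follow the documented rules", {
  expect_equal(intersect_methods(list(c("A", "B", "C"), c("B", "C", "D"), c("B", "C"))),
               c("B", "C"))
  expect_equal(intersect_methods(list(c("B", "A"))), c("A", "B"))
  expect_equal(intersect_methods(list("A", "B")), character(0))
  expect_error(intersect_methods(list()), "at least one")

  im <- tibble::tibble(source_id = c("g1", "g2", "g3"),
                       canonical_id = c("G", "G", "H"))
  expect_equal(map_and_dedupe(c("g1", "g2", "g3", "g4"), im), c("G", "H"))
  ident <- tibble::tibble(source_id = c("a", "b"), canonical_id = c("a", "b"))
  expect_equal(map_and_dedupe(c("a", "b"), ident), c("a", "b"))
  expect_equal(map_and_dedupe("zz", im), character(0))
})

test_that("consensus equals the exhaustive brute-force oracle on random instances", {
  case <- 0L
  for (n_genes in c(3L, 7L, 10L)) {
    for (n_cond in c(2L, 4L)) {
      for (n_meth in c(1L, 3L)) {
        case <- case + 1L
        genes <- paste0("g", seq_len(n_genes))
        rbm <- lapply(seq_len(n_meth), function(m) {
          lapply(seq_len(n_cond), function(cidx) {
            random_de_result(genes, paste0("c", cidx), paste0("m", m),
                             seed = case * 100 + m * 10 + cidx)
          })
        })
        names(rbm) <- paste0("m", seq_len(n_meth))
        for (m_min in seq_len(n_cond)) {
          expect_identical(
            consensus_genes(rbm, alpha = 0.4, min_conditions = m_min),
            consensus_oracle(rbm, alpha = 0.4, min_conditions = m_min))
        }
      }
    }
  }
})

test_that("the shared-gene set shrinks monotonically in alpha and min_conditions", {
  genes <- paste0("g", 1:20)
  results <- lapply(1:6, function(cidx) random_de_result(genes, paste0("c", cidx), "m", cidx))
  sets_alpha <- lapply(c(0.5, 0.3, 0.1), function(a) {
    per_method_shared_genes(results, alpha = a, min_conditions = 2)
  })
  expect_true(all(sets_alpha[[2]] %in% sets_alpha[[1]]))
  expect_true(all(sets_alpha[[3]] %in% sets_alpha[[2]]))
  sets_m <- lapply(2:5, function(m) per_method_shared_genes(results, 0.4, m))
  for (i in 2:length(sets_m)) expect_true(all(sets_m[[i]] %in% sets_m[[i - 1]]))
  # intersection is contained in every input
  s <- intersect_methods(sets_alpha)
  for (x in sets_alpha) expect_true(all(s %in% x))
})

test_that("planted shared-DE genes are recovered from the NB simulation", {
  cfg <- de_sim_config(seed = 11)
  panel <- simulate_count_panel(cfg)
  rbm <- lapply(c(ranksum_logcounts = "ranksum_logcounts",
                  ranksum_counts = "ranksum_counts"),
                function(m) lapply(panel$matrices, run_builtin_de, method = m))
  got <- consensus_genes(rbm, alpha = 0.05, min_conditions = 4)
  expect_gte(length(intersect(got, panel$truth$de_genes)) /
               length(union(got, panel$truth$de_genes)), 0.8)
})
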