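test_that("all three generators are fully deterministic from the seed", {
  cfg <- de_sim_config(seed = 5, n_conditions = 2L, n_genes = 50L)
  a <- simulate_count_panel(cfg)
  b <- simulate_count_panel(cfg)
  expect_identical(a$matrices[[1]]$values, b$matrices[[1]]$values)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  mcfg <- module_sim_config(seed = 5, n_conditions = 2L, n_genes = 100L, n_tumor = 20L,
                            modules = list(list(size = 10L, loading_range = c(0.6, 1),
                                                factor_sd = 1)))
  f1 <- simulate_fpkm_panel(mcfg)
  f2 <- simulate_fpkm_panel(mcfg)
  expect_identical(f1$matrices[[2]]$values, f2$matrices[[2]]$values)
  s1 <- simulate_survival(mcfg, f1)
  s2 <- simulate_survival(mcfg, f2)
  expect_identical(s1[[1]]$time, s2[[1]]$time)
  e1 <- simulate_edge_list(mcfg, f1$truth)
  e2 <- simulate_edge_list(mcfg, f1$truth)
  expect_identical(e1, e2)
})

test_that("a zero fold-change panel is null for the built-in DE backend", {
  cfg <- de_sim_config(seed = 13, n_conditions = 1L)
  cfg$de$lfc <- 0
  panel <- simulate_count_panel(cfg)
  de <- run_builtin_de(panel$matrices[[1]])
  expect_lte(sum(de$adj_p < 0.05), 0.05 * nrow(de))
})

test_that("a strong fold-change separates planted from background genes", {
  cfg <- de_sim_config(seed = 17, n_conditions = 1L)
  cfg$de$lfc <- 2
  cfg$de$min_conditions <- 1L
  panel <- simulate_count_panel(cfg)
  de <- run_builtin_de(panel$matrices[[1]])
  affected <- names(panel$truth$de_conditions)[
    vapply(panel$truth$de_conditions, function(a) 1L %in% a, logical(1))]
  planted_p <- de$adj_p[de$gene %in% affected]
  background_p <- de$adj_p[!de$gene %in% panel$truth$de_genes]
  expect_lt(median(planted_p), quantile(background_p, 0.05))
})

test_that("planted modules are strongly internally correlated, background is not", {
  cfg <- module_sim_config(seed = 19, modules = list(
    list(size = 40L, loading_range = c(0.6, 1), factor_sd = 1)))
  panel <- simulate_fpkm_panel(cfg)
  mod <- panel$truth$module_genes[[1]]
  bg <- setdiff(sprintf("gene_%04d", 1:200), mod)
  for (m in panel$matrices) {
    cm <- abs(cor(m$values[, mod]))
    expect_gte(mean(cm[upper.tri(cm)]), 0.5)
    cb <- abs(cor(m$values[, bg]))
    expect_lte(median(cb[upper.tri(cb)]), 0.1)
  }
})

test_that("a zero loading range collapses the module into the background", {
  cfg <- module_sim_config(seed = 23, modules = list(
    list(size = 40L, loading_range = c(0, 0), factor_sd = 1)))
  panel <- simulate_fpkm_panel(cfg)
  mod <- panel$truth$module_genes[[1]]
  cm <- abs(cor(panel$matrices[[1]]$values[, mod]))
  expect_lte(median(cm[upper.tri(cm)]), 0.1)
})

test_that("survival generation honors the censoring knob, including both edges", {
  cfg <- module_sim_config(seed = 29, n_conditions = 2L, n_genes = 100L, n_tumor = 60L,
                           modules = list(list(size = 10L, loading_range = c(0.6, 1),
                                               factor_sd = 1)))
  panel <- simulate_fpkm_panel(cfg)
  survs <- simulate_survival(cfg, panel)
  cens <- 1 - mean(unlist(lapply(survs, function(s) s$event)))
  expect_equal(cens, cfg$survival$censoring_rate, tolerance = 0.15)

  cfg_all <- cfg
  cfg_all$survival$censoring_rate <- 1
  s_all <- simulate_survival(cfg_all, panel)
  expect_true(all(s_all[[1]]$event == 0))
  grp <- tibble::tibble(patient_id = s_all[[1]]$patient_id,
                        group = rep(1:2, length.out = nrow(s_all[[1]])))
  expect_error(logrank_p(grp, s_all[[1]]), "no events")

  cfg_none <- cfg
  cfg_none$survival$censoring_rate <- 0
  s_none <- simulate_survival(cfg_none, panel)
  expect_true(all(s_none[[1]]$event == 1))

  cfg_bad <- cfg
  cfg_bad$survival$module <- 5L
  expect_error(simulate_survival(cfg_bad, panel), "not planted")
})

test_that("a hazard-driving module stratifies survival while a random set does not", {
  sig <- 0L
  null_sig <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    cfg <- module_sim_config(seed = 100 + s, n_conditions = 2L, n_genes = 300L,
                             n_tumor = 80L,
                             modules = list(list(size = 20L, loading_range = c(0.6, 1),
                                                 factor_sd = 1)))
    panel <- simulate_fpkm_panel(cfg)
    survs <- simulate_survival(cfg, panel)
    mod <- panel$truth$module_genes[[1]]
    set.seed(s)
    rand <- sample(setdiff(sprintf("gene_%04d", 1:300), mod), 20)
    e <- panel$matrices[[1]]
    grp_mod <- group_patients(e, genes = mod, k = 2, seed = s)
    grp_rand <- group_patients(e, genes = rand, k = 2, seed = s)
    if (as.numeric(logrank_p(grp_mod, survs[[1]])) < 0.01) sig <- sig + 1L
    if (as.numeric(logrank_p(grp_rand, survs[[1]])) < 0.05) null_sig <- null_sig + 1L
  }
  expect_gte(sig / n_seeds, 0.8)
  expect_lte(null_sig, 2L)
})

test_that("module sizes beyond the panel and missing seeds are refused", {
  expect_error(sim_config(n_genes = 30L, modules = list(list(size = 40L))),
               "exceed")
  expect_error(sim_config(seed = NULL), "seed")
})

test_that("synthetic edge lists wire planted modules as dense cliques", {
  cfg <- module_sim_config(seed = 37, n_genes = 200L, n_conditions = 2L,
                           modules = list(list(size = 20L, loading_range = c(0.6, 1),
                                               factor_sd = 1)))
  panel <- simulate_fpkm_panel(cfg)
  edges <- simulate_edge_list(cfg, panel$truth, within_prob = 0.8,
                              background_prob = 0.002)
  expect_false(any(edges$from == edges$to))
  mod <- panel$truth$module_genes[[1]]
  n_within <- sum(edges$from %in% mod & edges$to %in% mod)
  expect_equal(n_within / choose(20, 2), 0.8, tolerance = 0.15)
  n_bg <- sum(!(edges$from %in% mod) | !(edges$to %in% mod))
  expect_lt(n_bg, 0.01 * choose(200, 2))
})
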