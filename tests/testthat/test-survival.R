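block_expr <- function(seed = 3, n_per_block = 40L, n_genes = 10L, gap = 3) {
  set.seed(seed)
  n <- 2L * n_per_block
  vals <- matrix(rnorm(n * n_genes, 5, 1), n, n_genes)
  vals[seq_len(n_per_block), ] <- vals[seq_len(n_per_block), ] + gap
  dimnames(vals) <- list(paste0("p", seq_len(n)), paste0("g", seq_len(n_genes)))
  expression_matrix(vals, condition = "c1", value_kind = "log2_fpkm",
                    sample_class = rep("tumor", n))
}

sim_surv <- function(rates, seed = 5, cens_frac = 0.2, ids = paste0("p", seq_along(rates))) {
  set.seed(seed)
  t_event <- rexp(length(rates), rates)
  cens <- rbinom(length(rates), 1, cens_frac) == 1
  time <- ifelse(cens, t_event * runif(length(rates)), t_event)
  survival_table(patient_id = ids, time = time, event = as.numeric(!cens),
                 condition = "c1")
}

test_that("NMF grouping recovers planted patient blocks in nearly every seed", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    x <- block_expr(seed = s)
    grp <- group_patients(x, k = 2, seed = s)
    truth <- rep(1:2, each = 40)
    agree <- max(mean(grp$group == truth), mean(grp$group == 3 - truth))
    if (agree == 1) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("the NMF objective is non-increasing across iterations", {
  x <- block_expr(seed = 1)
  grp <- group_patients(x, k = 2, seed = 1)
  expect_equal(attr(grp, "method"), "nmf")
  traj <- attr(grp, "objective_trajectory")
  expect_true(all(diff(traj) <= 1e-8 * max(traj)))
})

test_that("a single-gene module takes the k-means path; bad inputs error", {
  x <- block_expr(seed = 2)
  grp <- group_patients(x, genes = "g1", k = 2, seed = 1)
  expect_equal(attr(grp, "method"), "kmeans")
  expect_equal(sort(unique(grp$group)), 1:2)

  expect_error(group_patients(x, k = 50, seed = 1), "half the number")
  const <- expression_matrix(matrix(1.5, 10, 3,
                                    dimnames = list(paste0("p", 1:10), paste0("g", 1:3))),
                             "c", "log2_fpkm")
  expect_error(group_patients(const, k = 2), "constant")
  expect_error(group_patients(x, genes = "not_here", k = 2), "absent")
})

test_that("identical survival in both groups gives statistic 0 and p = 1", {
  set.seed(8)
  times <- rexp(30, 0.1)
  events <- rbinom(30, 1, 0.8)
  st <- survival_table(patient_id = c(paste0("a", 1:30), paste0("b", 1:30)),
                       time = c(times, times), event = c(events, events))
  grp <- tibble::tibble(patient_id = st$patient_id,
                        group = rep(1:2, each = 30))
  p <- logrank_p(grp, st)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "statistic"), 0, tolerance = 1e-10)
})

test_that("a strong hazard contrast is detected; degenerate inputs refuse", {
  rates <- c(rep(1.0, 100), rep(0.2, 100))
  st <- sim_surv(rates, seed = 5)
  grp <- tibble::tibble(patient_id = st$patient_id,
                        group = rep(1:2, each = 100)[match(st$patient_id,
                                                           paste0("p", 1:200))])
  p <- logrank_p(grp, st)
  expect_lt(as.numeric(p), 0.001)

  # single group errors
  expect_error(logrank_p(dplyr::mutate(grp, group = 1L), st), "two non-empty groups")
  # zero events errors
  st0 <- survival_table(paste0("p", 1:20), rexp(20, 1), rep(0, 20))
  expect_error(logrank_p(tibble::tibble(patient_id = st0$patient_id,
                                        group = rep(1:2, 10)), st0),
               "no events")
})

test_that("log-rank p is invariant to group relabeling and time rescaling", {
  rates <- rep(c(0.5, 0.1), each = 50)
  st <- sim_surv(rates, seed = 11, ids = paste0("q", 1:100))
  grp <- tibble::tibble(patient_id = st$patient_id, group = rep(1:2, each = 50)[
    match(st$patient_id, paste0("q", 1:100))])
  p0 <- as.numeric(logrank_p(grp, st))
  p_swap <- as.numeric(logrank_p(dplyr::mutate(grp, group = 3L - group), st))
  expect_equal(p_swap, p0)
  st_scaled <- st
  st_scaled$time <- st_scaled$time * 365.25
  expect_equal(as.numeric(logrank_p(grp, st_scaled)), p0)
})

test_that("the Cox scan recovers a unit log-hazard coefficient", {
  set.seed(21)
  n <- 300L
  x <- rnorm(n)
  rate <- 0.05 * exp(1 * x)
  vals <- matrix(x, n, 1, dimnames = list(paste0("p", 1:n), "g1"))
  # second, null gene
  vals <- cbind(vals, g0 = rnorm(n))
  em <- expression_matrix(vals, "c1", "log2_fpkm", sample_class = rep("tumor", n))
  st <- survival_table(paste0("p", 1:n), rexp(n, rate), rep(1, n))
  scan <- cox_prognostic_scan(em, st)
  expect_equal(scan$coef[scan$gene == "g1"], 1, tolerance = 0.2)
  expect_true(scan$prognostic[scan$gene == "g1"])
})

test_that("Cox coefficients flip sign with the covariate; constant genes flag NA", {
  set.seed(22)
  n <- 120L
  x <- rnorm(n)
  vals <- cbind(gpos = x, gneg = -x, gconst = rep(2, n))
  rownames(vals) <- paste0("p", 1:n)
  em <- expression_matrix(vals, "c1", "log2_fpkm")
  st <- survival_table(paste0("p", 1:n), rexp(n, 0.05 * exp(0.8 * x)), rep(1, n))
  scan <- cox_prognostic_scan(em, st)
  expect_equal(scan$coef[scan$gene == "gpos"], -scan$coef[scan$gene == "gneg"],
               tolerance = 1e-6)
  expect_equal(scan$wald_p[scan$gene == "gpos"], scan$wald_p[scan$gene == "gneg"],
               tolerance = 1e-6)
  expect_true(is.na(scan$coef[scan$gene == "gconst"]))
  expect_true(is.na(scan$wald_p[scan$gene == "gconst"]))
})

test_that("module_prognosis isolates failing pairs and reports the rest", {
  cfg <- module_sim_config(seed = 3, n_conditions = 2L, n_genes = 150L,
                           modules = list(list(size = 15L, loading_range = c(0.6, 1),
                                               factor_sd = 1)))
  panel <- simulate_fpkm_panel(cfg)
  survs <- simulate_survival(cfg, panel)
  # make the second condition eventless: not evaluable, but isolated
  survs[[2]]$event <- 0
  exprs <- setNames(panel$matrices, c("c1", "c2"))
  names(survs) <- names(exprs)
  mods <- list(planted = panel$truth$module_genes[[1]])
  rep_out <- suppressWarnings(module_prognosis(mods, exprs, survs, k = 2, seed = 1))
  expect_equal(nrow(rep_out), 2L)
  row1 <- rep_out[rep_out$condition == "c1", ]
  expect_true(row1$evaluable)
  expect_equal(row1$neglog2_p, -log2(row1$logrank_p))
  row2 <- rep_out[rep_out$condition == "c2", ]
  expect_false(row2$evaluable)
  expect_match(row2$note, "events")
})

test_that("km_curves exports one survival curve per group", {
  rates <- rep(c(0.5, 0.1), each = 30)
  st <- sim_surv(rates, seed = 31, ids = paste0("r", 1:60))
  grp <- tibble::tibble(patient_id = st$patient_id,
                        group = rep(1:2, each = 30)[match(st$patient_id, paste0("r", 1:60))])
  km <- km_curves(grp, st)
  expect_setequal(unique(km$group), 1:2)
  for (g in 1:2) {
    sg <- km$surv[km$group == g]
    expect_true(all(diff(sg) <= 1e-12))
  }
})
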