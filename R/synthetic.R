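#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. The defaults of the two presets ([de_sim_config()],
#' [module_sim_config()]) are the package's reference study conditions; see
#' the methods vignette for the rationale behind each value.
#'
#' @param n_conditions Number of conditions T.
#' @param n_tumor,n_normal Samples per condition and class.
#' @param n_genes Panel size p.
#' @param de List: `n_genes` planted DE genes, `lfc` (log2 fold-change in
#'   tumor samples of affected conditions), `min_conditions` (every planted
#'   gene is affected in at least this many conditions).
#' @param nb Negative-binomial count model: `meanlog`/`sdlog` of the
#'   log-normal gene-mean distribution and the fixed `dispersion`.
#' @param modules List of planted co-expression modules, each a list with
#'   `size`, `loading_range` and `factor_sd`.
#' @param noise_sd Background Gaussian sd on the log2-FPKM scale.
#' @param baseline_range Range of per-gene baseline log2-FPKM means.
#' @param survival List: `baseline_hazard` (events/day), `effect`
#'   (log-hazard per unit of centered module metagene), `censoring_rate`
#'   (approximate fraction censored), `module` (index of the hazard-driving
#'   module).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_conditions = 4L, n_tumor = 80L, n_normal = 0L,
                       n_genes = 1000L,
                       de = list(n_genes = 40L, lfc = 2, min_conditions = 4L),
                       nb = list(meanlog = log(100), sdlog = 1, dispersion = 0.1),
                       modules = list(list(size = 40L, loading_range = c(0.6, 1), factor_sd = 1),
                                      list(size = 30L, loading_range = c(0.6, 1), factor_sd = 1)),
                       noise_sd = 0.3, baseline_range = c(2, 8),
                       survival = list(baseline_hazard = 0.01, effect = 1,
                                       censoring_rate = 0.3, module = 1L),
                       seed = 1L) {
  if (is.null(seed)) stop_comod("a seed is mandatory", "comod_validation_error")
  stopifnot(n_conditions >= 1L, n_tumor >= 1L, n_normal >= 0L, n_genes >= 1L)
  if (sum(vapply(modules, function(m) m$size, numeric(1))) > n_genes) {
    stop_comod("module sizes exceed the gene panel", "comod_validation_error")
  }
  structure(list(n_conditions = as.integer(n_conditions), n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), n_genes = as.integer(n_genes),
                 de = de, nb = nb, modules = modules, noise_sd = noise_sd,
                 baseline_range = baseline_range, survival = survival,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @describeIn sim_config Reference conditions for the DE-consensus
#'   benchmark: 8 conditions, 20 tumor vs 20 normal samples, 200 genes, 40
#'   planted DE genes at log2 fold-change 2 each affecting at least 4
#'   conditions, NB dispersion 0.1.
#' @export
de_sim_config <- function(seed = 1L, ...) {
  preset_config(list(n_conditions = 8L, n_tumor = 20L, n_normal = 20L,
                     n_genes = 200L, modules = list(), seed = seed), list(...))
}

#' @describeIn sim_config Reference conditions for the module-recovery
#'   benchmark: 4 conditions of 80 tumor samples, 1000 genes, two planted
#'   modules of 40 and 30 genes with loadings Uniform(0.6, 1), unit factor
#'   sd, background noise sd 0.3.
#' @export
module_sim_config <- function(seed = 1L, ...) {
  preset_config(list(seed = seed), list(...))
}

# flat (non-recursive) preset merge: overrides win wholesale
preset_config <- function(defaults, overrides) {
  args <- c(overrides, defaults[setdiff(names(defaults), names(overrides))])
  do.call(sim_config, args)
}

#' Simulate negative-binomial count panels with planted DE genes
#'
#' Gene-level means are drawn log-normally and shared across conditions;
#' counts are NB with fixed dispersion. Each planted DE gene is assigned a
#' random subset of conditions (size uniform between `de$min_conditions` and
#' T) in which its tumor-sample mean is multiplied by `2^lfc`. Fully
#' deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `matrices` (list of raw-count `expr_matrix`) and
#'   `truth` (a `synthetic_truth` list with the planted gene IDs and their
#'   affected conditions).
#' @export
simulate_count_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- config$n_genes
    Tn <- config$n_conditions
    genes <- sprintf("gene_%04d", seq_len(p))
    mu <- rlnorm(p, config$nb$meanlog, config$nb$sdlog)
    n_de <- config$de$n_genes
    de_idx <- sort(sample.int(p, n_de))
    m_min <- min(config$de$min_conditions, Tn)
    affected <- lapply(seq_len(n_de), function(i) {
      n_aff <- if (m_min == Tn) Tn else sample(seq(m_min, Tn), 1L)
      sort(sample.int(Tn, n_aff))
    })
    size <- 1 / config$nb$dispersion
    fold <- 2^config$de$lfc
    matrices <- lapply(seq_len(Tn), function(t) {
      cond <- sprintf("cond_%02d", t)
      n_t <- config$n_tumor
      n_n <- config$n_normal
      mu_t <- mu
      hit <- de_idx[vapply(affected, function(a) t %in% a, logical(1))]
      mu_t[hit] <- mu_t[hit] * fold
      tum <- matrix(rnbinom(n_t * p, mu = rep(mu_t, each = n_t), size = size), n_t, p)
      nor <- matrix(rnbinom(n_n * p, mu = rep(mu, each = n_n), size = size), n_n, p)
      vals <- rbind(tum, nor)
      rownames(vals) <- c(sprintf("%s_T%03d", cond, seq_len(n_t)),
                          sprintf("%s_N%03d", cond, seq_len(n_n)))
      colnames(vals) <- genes
      expression_matrix(vals, condition = cond, value_kind = "raw_count",
                        sample_class = c(rep("tumor", n_t), rep("normal", n_n)))
    })
    truth <- structure(list(de_genes = genes[de_idx],
                            de_conditions = setNames(affected, genes[de_idx]),
                            seed = config$seed),
                       class = "synthetic_truth")
    list(matrices = matrices, truth = truth)
  })
}

#' Simulate log2-FPKM panels with planted co-expression modules
#'
#' Background values are independent Gaussians around per-gene baseline
#' means (shared across conditions, drawn from `baseline_range`). Each
#' planted module has fixed gene loadings `a ~ Uniform(loading_range)` and,
#' per condition, an independent per-sample latent factor
#' `f ~ N(0, factor_sd^2)`; member gene g receives `a_g * f`. The shared
#' object across conditions is the loading pattern, not the sample-level
#' factor values, matching the shared-right-basis / distinct-left-basis
#' structure the decomposition targets.
#'
#' @param config A [sim_config()].
#' @return List with `matrices` (list of log2-FPKM `expr_matrix`, tumor
#'   samples) and `truth` (planted module memberships and loadings).
#' @export
simulate_fpkm_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- config$n_genes
    Tn <- config$n_conditions
    genes <- sprintf("gene_%04d", seq_len(p))
    baseline <- runif(p, config$baseline_range[1], config$baseline_range[2])
    sizes <- vapply(config$modules, function(m) as.integer(m$size), integer(1))
    placement <- if (sum(sizes) > 0) sample.int(p, sum(sizes)) else integer(0)
    offs <- 0L
    mod_idx <- list()
    loadings <- list()
    for (i in seq_along(config$modules)) {
      mod_idx[[i]] <- sort(placement[seq(offs + 1L, offs + sizes[i])])
      offs <- offs + sizes[i]
      rng <- config$modules[[i]]$loading_range
      loadings[[i]] <- setNames(runif(sizes[i], rng[1], rng[2]), genes[mod_idx[[i]]])
    }
    matrices <- lapply(seq_len(Tn), function(t) {
      cond <- sprintf("cond_%02d", t)
      n <- config$n_tumor
      vals <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)
      vals <- sweep(vals, 2, baseline, "+")
      for (i in seq_along(mod_idx)) {
        f <- rnorm(n, 0, config$modules[[i]]$factor_sd)
        vals[, mod_idx[[i]]] <- vals[, mod_idx[[i]]] + outer(f, unname(loadings[[i]]))
      }
      rownames(vals) <- sprintf("%s_T%03d", cond, seq_len(n))
      colnames(vals) <- genes
      expression_matrix(vals, condition = cond, value_kind = "log2_fpkm",
                        sample_class = rep("tumor", n))
    })
    truth <- structure(list(module_genes = lapply(mod_idx, function(i) genes[i]),
                            module_loadings = loadings,
                            seed = config$seed),
                       class = "synthetic_truth")
    list(matrices = matrices, truth = truth)
  })
}

#' Simulate right-censored survival driven by a module metagene
#'
#' Per tumor sample, the hazard is
#' `baseline_hazard * exp(effect * metagene)` where the metagene is the mean
#' expression of the planted module's genes, centered across the condition's
#' samples (so `baseline_hazard` is the hazard of an average patient). Event
#' times are exponential; censoring times are Uniform(0, u) with u solved
#' numerically so the expected censored fraction matches
#' `survival$censoring_rate`.
#'
#' @param config A [sim_config()].
#' @param panel Result of [simulate_fpkm_panel()] under the same config.
#' @return List of `survival_table`, one per condition.
#' @export
simulate_survival <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  sv <- config$survival
  mod_i <- sv$module
  if (mod_i > length(panel$truth$module_genes)) {
    stop_comod("survival effect refers to a module that was not planted",
               "comod_validation_error")
  }
  mg <- panel$truth$module_genes[[mod_i]]
  with_seed(derive_seed(config$seed, 77L), {
    lapply(panel$matrices, function(m) {
      vals <- m$values
      meta <- rowMeans(vals[, mg, drop = FALSE])
      meta <- meta - mean(meta)
      rate <- sv$baseline_hazard * exp(sv$effect * meta)
      n <- length(rate)
      t_event <- rexp(n, rate)
      cr <- sv$censoring_rate
      if (cr <= 0) {
        time <- t_event; event <- rep(1, n)
      } else if (cr >= 1) {
        time <- rep(0, n); event <- rep(0, n)
      } else {
        cens_frac <- function(u) mean((1 - exp(-rate * u)) / (rate * u)) - cr
        u <- uniroot(cens_frac, lower = 1e-6 / max(rate), upper = 1e6 / min(rate))$root
        t_cens <- runif(n, 0, u)
        event <- as.numeric(t_event <= t_cens)
        time <- pmin(t_event, t_cens)
      }
      survival_table(patient_id = rownames(vals), time = time, event = event,
                     condition = m$condition)
    })
  })
}

#' Simulate a functional-interaction edge list wired to planted modules
#'
#' Each planted module is wired as a noisy clique (every within-module pair
#' kept with probability `within_prob`); background gene pairs receive edges
#' independently with probability `background_prob`.
#'
#' @param config A [sim_config()].
#' @param truth The `synthetic_truth` from [simulate_fpkm_panel()].
#' @param within_prob Within-module edge retention (default 0.8).
#' @param background_prob Background edge probability (default 0.002).
#' @return An edge-list tibble.
#' @export
simulate_edge_list <- function(config, truth, within_prob = 0.8,
                               background_prob = 0.002) {
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  with_seed(derive_seed(config$seed, 131L), {
    edges <- list()
    mod_sets <- lapply(truth$module_genes, function(g) sort(match(g, genes)))
    for (mi in seq_along(mod_sets)) {
      idx <- mod_sets[[mi]]
      if (length(idx) < 2L) next
      pairs <- utils::combn(idx, 2)
      keep <- runif(ncol(pairs)) < within_prob
      edges[[length(edges) + 1L]] <- tibble(from = genes[pairs[1, keep]],
                                            to = genes[pairs[2, keep]])
    }
    p <- config$n_genes
    all_pairs <- utils::combn(seq_len(p), 2)
    in_mod <- rep(FALSE, ncol(all_pairs))
    for (idx in mod_sets) {
      in_mod <- in_mod | (all_pairs[1, ] %in% idx & all_pairs[2, ] %in% idx)
    }
    bg <- all_pairs[, !in_mod, drop = FALSE]
    keep <- runif(ncol(bg)) < background_prob
    edges[[length(edges) + 1L]] <- tibble(from = genes[bg[1, keep]],
                                          to = genes[bg[2, keep]])
    edge_list(dplyr::bind_rows(edges))
  })
}
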