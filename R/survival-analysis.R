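#' Group tumor patients by module-gene expression
#'
#' Rank-k NMF of the (min-subtracted, hence non-negative) module-gene x
#' patient expression matrix, 20 restarts of multiplicative updates with the
#' best Frobenius objective kept. Patients are then clustered by k-means on
#' their metagene coefficient vectors (columns of H, scaled by the norms of
#' the corresponding W columns to resolve the factorization's scale
#' ambiguity); a raw arg-max over metagene coefficients is not
#' scale-identifiable and fails when one metagene captures the shared
#' expression profile. When the module has exactly one gene, NMF is
#' meaningless and k-means on that gene's values is used instead.
#'
#' @param x An `expr_matrix` (log2-FPKM). Only tumor samples are used when a
#'   `sample_class` is present.
#' @param genes Module gene IDs to restrict to (default: all genes of `x`).
#' @param k Number of patient groups (default 2).
#' @param seed RNG seed for restarts.
#' @param method `"auto"` (NMF, or k-means for a single gene), `"nmf"` or
#'   `"kmeans"`.
#' @return A `patient_grouping` tibble with columns `patient_id`, `group`,
#'   and attributes `method`, `k`, `seed`, `objective`, `objective_trajectory`
#'   (non-increasing), `condition`.
#' @export
group_patients <- function(x, genes = NULL, k = 2L, seed = 1L,
                           method = c("auto", "nmf", "kmeans")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  vals <- x$values
  if (!is.null(x$sample_class)) vals <- vals[x$sample_class == "tumor", , drop = FALSE]
  if (!is.null(genes)) {
    genes <- module_genes(genes)
    missing <- setdiff(genes, colnames(vals))
    if (length(missing)) {
      stop_comod(paste0("module genes absent from expression matrix: ",
                        paste(head(missing, 5), collapse = ", ")),
                 "comod_validation_error")
    }
    vals <- vals[, genes, drop = FALSE]
  }
  n_pat <- nrow(vals)
  if (k > n_pat / 2) stop_comod("k exceeds half the number of patients", "comod_validation_error")
  if (max(vals) == min(vals)) stop_comod("expression is constant; cannot group", "comod_numeric_error")
  use_kmeans <- method == "kmeans" || (method == "auto" && ncol(vals) == 1L)
  if (use_kmeans) {
    km <- with_seed(seed, kmeans(vals, centers = k, nstart = 20L))
    groups <- km$cluster
    objective <- km$tot.withinss
    trajectory <- objective
    method_used <- "kmeans"
  } else {
    X <- t(vals) - min(vals) # genes x patients, shifted non-negative
    fit <- nmf_fit(X, k = k, seed = seed)
    scores <- t(fit$H * sqrt(colSums(fit$W^2))) # patients x metagenes
    km <- with_seed(derive_seed(seed, 7L), kmeans(scores, centers = k, nstart = 20L))
    groups <- km$cluster
    objective <- fit$objective
    trajectory <- fit$trajectory
    method_used <- "nmf"
  }
  if (length(unique(groups)) < k) {
    warn(sprintf("only %d of %d groups are non-empty", length(unique(groups)), k))
  }
  out <- tibble(patient_id = rownames(vals), group = as.integer(groups))
  attr(out, "method") <- method_used
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- seed
  attr(out, "objective") <- objective
  attr(out, "objective_trajectory") <- trajectory
  attr(out, "condition") <- x$condition
  class(out) <- unique(c("patient_grouping", class(out)))
  out
}

#' Log-rank test between patient groups
#'
#' Standard k-group log-rank chi-square comparison of Kaplan-Meier curves.
#' Patients missing from either the grouping or the survival table are
#' dropped (counted in the attributes).
#'
#' @param grouping A `patient_grouping`.
#' @param survival A `survival_table`.
#' @return The log-rank p-value (scalar), with attributes `statistic`, `df`,
#'   `group_sizes` and `n_dropped`.
#' @export
logrank_p <- function(grouping, survival) {
  merged <- dplyr::inner_join(as_tibble(grouping), as_tibble(survival), by = "patient_id")
  n_dropped <- (nrow(grouping) - nrow(merged)) + (nrow(survival) - nrow(merged))
  if (length(unique(merged$group)) < 2L) {
    stop_comod("need at least two non-empty groups after matching patients",
               "comod_validation_error")
  }
  if (sum(merged$event) == 0) {
    stop_comod("no events observed; log-rank p is undefined", "comod_validation_error")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = merged)
  df <- length(sd$n) - 1L
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(p, statistic = unname(sd$chisq), df = df,
            group_sizes = as.integer(table(merged$group)), n_dropped = n_dropped)
}

#' Per-gene univariate Cox proportional-hazards scan
#'
#' Fits one Cox PH model per gene with its expression as the only covariate
#' (Efron tie handling) and reports the raw (uncorrected) Wald p-value.
#' Genes whose fit fails or does not converge are flagged `NA`, never dropped
#' silently.
#'
#' @param x An `expr_matrix`; tumor samples are used when classes are known.
#' @param survival A `survival_table`; patients matched by sample ID.
#' @param alpha Prognostic-flag cutoff on the raw Wald p (default 0.05).
#' @param genes Optional gene subset.
#' @return Tibble with columns `gene`, `coef`, `wald_p`, `prognostic`.
#' @export
cox_prognostic_scan <- function(x, survival, alpha = 0.05, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- x$values
  if (!is.null(x$sample_class)) vals <- vals[x$sample_class == "tumor", , drop = FALSE]
  if (!is.null(genes)) vals <- vals[, module_genes(genes), drop = FALSE]
  common <- intersect(rownames(vals), survival$patient_id)
  if (length(common) < 3L) stop_comod("too few patients shared between expression and survival",
                                      "comod_validation_error")
  vals <- vals[common, , drop = FALSE]
  st <- as_tibble(survival)
  st <- st[match(common, st$patient_id), , drop = FALSE]
  n_events <- sum(st$event)
  if (n_events == 0) stop_comod("no events observed; Cox model is undefined", "comod_validation_error")
  if (n_events < 10) warn(sprintf("only %d events; Cox estimates will be unstable", n_events))
  surv_obj <- survival::Surv(st$time, st$event)
  res <- purrr::map_dfr(colnames(vals), function(g) {
    v <- vals[, g]
    if (max(v) == min(v)) return(tibble(gene = g, coef = NA_real_, wald_p = NA_real_))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv_obj ~ v, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[1])) {
      return(tibble(gene = g, coef = NA_real_, wald_p = NA_real_))
    }
    z <- fit$coefficients[1] / sqrt(fit$var[1, 1])
    tibble(gene = g, coef = unname(fit$coefficients[1]),
           wald_p = 2 * pnorm(-abs(z)))
  })
  res$prognostic <- !is.na(res$wald_p) & res$wald_p < alpha
  res
}

#' Prognostic assessment of modules across conditions
#'
#' For every (condition, module) pair: group tumor patients by module-gene
#' expression ([group_patients()]), compare groups by the log-rank test, and
#' scan module genes with univariate Cox models. Failures in one pair (e.g.
#' zero events in a condition) are isolated and reported as not evaluable.
#'
#' @param modules Named list of modules (`gene_module` objects or character
#'   vectors of gene IDs).
#' @param exprs Named list of `expr_matrix` (log2-FPKM), one per condition.
#' @param survs Named list of `survival_table`, aligned with `exprs`.
#' @param k Number of patient groups (default 2).
#' @param alpha Prognostic cutoff (default 0.05).
#' @param seed RNG seed.
#' @return A `prognosis_report` tibble: one row per (condition, module) with
#'   `logrank_p`, `neglog2_p`, group sizes, the number and fraction of
#'   prognostic genes, and `evaluable`/`note` for failed pairs.
#' @export
module_prognosis <- function(modules, exprs, survs, k = 2L, alpha = 0.05, seed = 1L) {
  stopifnot(length(exprs) == length(survs))
  conds <- names(exprs) %||% vapply(exprs, function(e) e$condition, character(1))
  mod_names <- names(modules) %||% paste0("module_", seq_along(modules))
  grid <- tidyr::expand_grid(condition = conds, module = mod_names)
  out <- purrr::pmap_dfr(grid, function(condition, module) {
    e <- exprs[[match(condition, conds)]]
    s <- survs[[match(condition, conds)]]
    genes <- module_genes(modules[[module]])
    row <- tibble(condition = condition, module = module,
                  n_genes = length(genes), n_patients = NA_integer_,
                  group_sizes = NA_character_, logrank_p = NA_real_,
                  neglog2_p = NA_real_, n_prognostic = NA_integer_,
                  prognostic_fraction = NA_real_,
                  evaluable = FALSE, note = NA_character_)
    tryCatch({
      grp <- group_patients(e, genes = genes, k = k, seed = seed)
      p <- logrank_p(grp, s)
      scan <- cox_prognostic_scan(e, s, alpha = alpha, genes = genes)
      row$n_patients <- sum(attr(p, "group_sizes"))
      row$group_sizes <- paste(attr(p, "group_sizes"), collapse = "/")
      row$logrank_p <- as.numeric(p)
      row$neglog2_p <- -log2(as.numeric(p))
      row$n_prognostic <- sum(scan$prognostic, na.rm = TRUE)
      row$prognostic_fraction <- mean(scan$prognostic, na.rm = TRUE)
      row$evaluable <- TRUE
      row
    }, comod_error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
  })
  class(out) <- unique(c("prognosis_report", class(out)))
  out
}

#' Significance plot of a prognosis report
#'
#' One point per (condition, module) at `-log2(p)`; the horizontal line marks
#' `-log2(alpha)`.
#'
#' @param object A `prognosis_report`.
#' @param alpha Significance threshold drawn as a line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prognosis_report
#' @export
autoplot.prognosis_report <- function(object, alpha = 0.05, ...) {
  td <- dplyr::filter(as_tibble(object), .data$evaluable)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$module, y = .data$neglog2_p,
                                   color = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log2(alpha), linetype = "solid") +
    ggplot2::labs(x = NULL, y = expression(-log[2](p)),
                  title = "Module survival stratification (log-rank)")
}

#' Kaplan-Meier curve data for one grouping
#'
#' Exports per-group survival-curve coordinates for external plotting.
#'
#' @param grouping A `patient_grouping`.
#' @param survival A `survival_table`.
#' @return Tibble with columns `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(grouping, survival) {
  merged <- dplyr::inner_join(as_tibble(grouping), as_tibble(survival), by = "patient_id")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = merged)
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep(1L, length(sm$time)) else {
    as.integer(sub("group=", "", as.character(sm$strata)))
  }
  tibble(group = strata, time = sm$time, surv = sm$surv,
         n_risk = sm$n.risk, n_event = sm$n.event)
}
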