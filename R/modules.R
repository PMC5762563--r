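#' Select the top right-basis eigenvectors
#'
#' The k columns of V with the largest eigenvalues, in eigenvalue rank order.
#'
#' @param fit A `hogsvd` object.
#' @param k Number of eigenvectors (default 10).
#' @return List with `indices`, `lambda` and `vectors` (p x k matrix).
#' @export
select_top_eigenvectors <- function(fit, k = 10L) {
  stopifnot(inherits(fit, "hogsvd"))
  p <- length(fit$lambda)
  if (k < 1L || k > p) stop_comod("k must be between 1 and p", "comod_validation_error")
  idx <- seq_len(k)
  list(indices = idx, lambda = fit$lambda[idx], vectors = fit$V[, idx, drop = FALSE])
}

#' Two-component Gaussian mixture fit to eigenvector loadings
#'
#' Loadings are standardized to zero median and unit MAD (eigenvector scale
#' is arbitrary), then decomposed into two Gaussian components by EM on the
#' signed values: a large-weight empirical-null component capturing the bulk
#' and a small-weight component capturing the minority of highly similar
#' (co-expressed) genes. EM runs from 10 initializations (5 quantile-spread,
#' 5 random under the given seed); the best log-likelihood fit is kept.
#' Restarts whose components collapse (vanishing sd or weight) are discarded;
#' if all collapse, the fit errors.
#'
#' @param loadings Numeric vector of length p >= 10.
#' @param seed RNG seed for the random restarts.
#' @param tol,max_iter EM convergence tolerance on the log-likelihood
#'   (default 1e-8) and iteration cap (default 500).
#' @return A `mixture_fit`: means, sds, weights (component 1 = null by
#'   weight), `null_index`, `loglik`, `converged`, `n_iter`, and the
#'   standardization used (`center`, `scale`).
#' @export
fit_bimodal <- function(loadings, seed = 1L, tol = 1e-8, max_iter = 500L) {
  p <- length(loadings)
  if (p < 10L) stop_comod("need at least 10 loadings to fit a mixture", "comod_validation_error")
  ctr <- median(loadings)
  scl <- mad(loadings)
  if (scl == 0) {
    scl <- sd(loadings)
    if (is.na(scl) || scl == 0) {
      stop_comod("degenerate loadings: no variation to decompose", "comod_numeric_error")
    }
  }
  x <- (loadings - ctr) / scl
  with_seed(seed, {
    qs <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9)))
    inits <- list(c(qs[3], qs[5]), c(qs[3], qs[1]), c(qs[2], qs[4]),
                  c(qs[1], qs[5]), c(qs[3], max(x)))
    best <- NULL
    for (r in seq_len(10L)) {
      mu <- if (r <= length(inits)) inits[[r]] else sort(sample(x, 2L))
      sds <- c(sd(x), sd(x) / 2)
      w <- c(0.9, 0.1)
      ll_old <- -Inf
      iter <- 0L
      converged <- FALSE
      degenerate <- FALSE
      while (iter < max_iter) {
        iter <- iter + 1L
        d1 <- w[1] * dnorm(x, mu[1], sds[1])
        d2 <- w[2] * dnorm(x, mu[2], sds[2])
        tot <- d1 + d2
        tot[tot < 1e-300] <- 1e-300
        g <- d2 / tot
        w <- c(1 - mean(g), mean(g))
        if (min(w) < 1e-6) { degenerate <- TRUE; break }
        mu <- c(sum((1 - g) * x) / sum(1 - g), sum(g * x) / sum(g))
        sds <- sqrt(c(sum((1 - g) * (x - mu[1])^2) / sum(1 - g),
                      sum(g * (x - mu[2])^2) / sum(g)))
        if (any(sds < 1e-4)) { degenerate <- TRUE; break }
        ll <- sum(log(tot))
        if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
        ll_old <- ll
      }
      if (degenerate) next
      if (is.null(best) || ll_old > best$loglik) {
        best <- list(mu = mu, sds = sds, w = w, loglik = ll_old,
                     converged = converged, n_iter = iter)
      }
    }
    if (is.null(best)) {
      stop_comod("all EM restarts collapsed; loadings are degenerate", "comod_numeric_error")
    }
    ni <- which.max(best$w)
    ord <- c(ni, setdiff(1:2, ni))
    structure(list(means = best$mu[ord], sds = best$sds[ord], weights = best$w[ord],
                   null_index = 1L, loglik = best$loglik, converged = best$converged,
                   n_iter = best$n_iter, center = ctr, scale = scl),
              class = "mixture_fit")
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> null: N(%.3f, %.3f^2) w=%.3f | alt: N(%.3f, %.3f^2) w=%.3f\n",
              x$means[1], x$sds[1], x$weights[1], x$means[2], x$sds[2], x$weights[2]))
  cat(sprintf("  loglik %.2f, %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# Distance of each standardized loading from the fitted null, in null sds.
loading_scores <- function(loadings, fit) {
  x <- (loadings - fit$center) / fit$scale
  abs(x - fit$means[1]) / fit$sds[1]
}

#' Tail-area false discovery rate per gene
#'
#' For each gene with null-standardized score `s = |x - mu0| / sd0`, the
#' q-value is the estimated fraction of null genes among all genes at least
#' as extreme: `q = w0 * 2*(1 - Phi(s)) / max(tail_fraction(s), 1/p)`,
#' clipped to \[0, 1\] and monotonized so q never increases with s.
#'
#' @param loadings Numeric vector of eigenvector loadings.
#' @param fit The [fit_bimodal()] result for these loadings.
#' @return Numeric vector of q-values in \[0, 1\], non-increasing in the
#'   standardized score.
#' @export
tail_fdr_qvalues <- function(loadings, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) warn("mixture fit did not converge; q-values may be unstable")
  p <- length(loadings)
  s <- loading_scores(loadings, fit)
  ord <- order(s, decreasing = TRUE)
  # empirical two-sided tail fraction: share of genes at least as extreme
  emp <- rank(-s, ties.method = "max") / p
  q <- fit$weights[1] * 2 * pnorm(-s) / pmax(emp, 1 / p)
  q <- pmin(q, 1)
  q[ord] <- cummax(q[ord])
  q
}

#' Call a gene module from one eigenvector
#'
#' @param eigenvector_index 1-based eigenvalue rank of the eigenvector.
#' @param genes Character vector of gene IDs (analysis panel order).
#' @param loadings Loadings of those genes on the eigenvector.
#' @param q Q-values from [tail_fdr_qvalues()].
#' @param q_cutoff Module inclusion cutoff (default 0.001).
#' @param fit The mixture fit (stored on the module).
#' @param members Optional explicit member gene IDs (used by the
#'   coherence-refinement step); defaults to all genes with `q <= q_cutoff`.
#' @return A `gene_module`: tibble of member genes with `loading` and `q`,
#'   with the eigenvector index, cutoff and mixture fit as attributes.
#' @export
extract_module <- function(eigenvector_index, genes, loadings, q, q_cutoff = 0.001,
                           fit = NULL, members = NULL) {
  sel <- if (is.null(members)) genes[q <= q_cutoff] else members
  keep <- match(sel, genes)
  out <- tibble(gene = genes[keep], loading = loadings[keep], q = q[keep])
  attr(out, "eigenvector_index") <- as.integer(eigenvector_index)
  attr(out, "q_cutoff") <- q_cutoff
  attr(out, "mixture_fit") <- fit
  class(out) <- unique(c("gene_module", class(out)))
  out
}

#' Genes of a module
#' @param module A `gene_module` (or character vector, returned as-is).
#' @return Character vector of member gene IDs.
#' @export
module_genes <- function(module) {
  if (is.character(module)) module else module$gene
}

#' Call co-expression modules from the top eigenvectors
#'
#' For each of the `k` top right-basis eigenvectors: standardize loadings,
#' fit the two-component Gaussian mixture, compute tail-area q-values and
#' call genes with `q <= q_cutoff`. Because the top eigenvalues of the
#' non-normal S matrix often form near-degenerate clusters, eigenvectors can
#' mix several underlying modules; with `refine = TRUE` (default) the called
#' genes are therefore partitioned into coherent co-expression groups
#' (average-linkage clustering on mean cross-condition absolute correlation,
#' cut at `1 - coherence_cut`) and groups are matched one-to-one to the
#' calling eigenvectors by mean standardized loading score (greedy; an
#' eigenvector left without a free group takes its best already-used group).
#' `refine = FALSE` returns the bare per-eigenvector calls, which may
#' overlap. Overlap statistics between the raw calls are always reported.
#'
#' @param fit A `hogsvd` object.
#' @param matrices The gene-aligned expression matrices the decomposition was
#'   built from (needed for coherence refinement; may be `NULL` when
#'   `refine = FALSE`).
#' @param k Number of top eigenvectors (default 10).
#' @param q_cutoff Tail-FDR cutoff (default 0.001).
#' @param seed Seed for the mixture-fit restarts.
#' @param refine Apply coherence refinement (default `TRUE`).
#' @param coherence_cut Minimum mean cross-condition |correlation| for two
#'   called genes to stay in one coherent group (default 0.5).
#' @return A `module_set`: list of `gene_module` objects (one per
#'   eigenvector, possibly empty), with raw calls and overlap statistics as
#'   attributes.
#' @export
call_all_modules <- function(fit, matrices = NULL, k = 10L, q_cutoff = 0.001,
                             seed = 1L, refine = TRUE, coherence_cut = 0.5) {
  top <- select_top_eigenvectors(fit, k)
  genes <- fit$gene_ids
  p <- length(genes)
  calls <- vector("list", k)
  qlist <- vector("list", k)
  fits <- vector("list", k)
  smat <- matrix(NA_real_, p, k)
  for (j in seq_len(k)) {
    v <- top$vectors[, j]
    mf <- fit_bimodal(v, seed = seed)
    q <- tail_fdr_qvalues(v, mf)
    calls[[j]] <- which(q <= q_cutoff)
    qlist[[j]] <- q
    fits[[j]] <- mf
    smat[, j] <- loading_scores(v, mf)
  }
  raw_modules <- lapply(seq_len(k), function(j) {
    extract_module(j, genes, top$vectors[, j], qlist[[j]], q_cutoff, fits[[j]])
  })
  modules <- raw_modules
  if (refine) {
    if (is.null(matrices)) {
      stop_comod("matrices are required for coherence refinement (or set refine = FALSE)",
                 "comod_validation_error")
    }
    members <- refine_module_calls(calls, smat, matrices, coherence_cut)
    modules <- lapply(seq_len(k), function(j) {
      extract_module(j, genes, top$vectors[, j], qlist[[j]], q_cutoff, fits[[j]],
                     members = genes[members[[j]]])
    })
  }
  overlap <- module_overlap(raw_modules)
  structure(modules, class = "module_set",
            raw_calls = raw_modules, overlap = overlap, lambda = top$lambda,
            refined = refine)
}

# Partition the union of per-eigenvector calls into coherent co-expression
# groups and match groups back to eigenvectors. Returns a list of member
# index vectors, one per eigenvector.
refine_module_calls <- function(calls, smat, matrices, coherence_cut) {
  k <- length(calls)
  members <- rep(list(integer(0)), k)
  cand <- sort(unique(unlist(calls)))
  if (length(cand) == 0L) return(members)
  if (length(cand) == 1L) {
    groups <- list(cand)
  } else {
    cors <- lapply(matrices, function(m) {
      D <- if (inherits(m, "expr_matrix")) m$values else as.matrix(m)
      abs(cor(D[, cand, drop = FALSE]))
    })
    cmean <- Reduce(`+`, cors) / length(cors)
    hc <- hclust(as.dist(1 - cmean), method = "average")
    groups <- unname(split(cand, cutree(hc, h = 1 - coherence_cut)))
  }
  act <- which(lengths(calls) > 0L)
  score <- matrix(-Inf, length(act), length(groups))
  for (ai in seq_along(act)) {
    for (gi in seq_along(groups)) {
      if (length(intersect(groups[[gi]], calls[[act[ai]]])) > 0L) {
        score[ai, gi] <- mean(smat[groups[[gi]], act[ai]])
      }
    }
  }
  assigned <- rep(NA_integer_, length(act))
  used <- logical(length(groups))
  work <- score
  repeat {
    open <- is.na(assigned)
    if (!any(open) || all(used)) break
    sub <- work
    sub[!open, ] <- -Inf
    sub[, used] <- -Inf
    if (max(sub) == -Inf) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    assigned[hit[1]] <- hit[2]
    used[hit[2]] <- TRUE
  }
  for (ai in seq_along(act)) {
    if (is.na(assigned[ai])) {
      g <- which.max(score[ai, ])
      if (score[ai, g] > -Inf) assigned[ai] <- g
    }
    if (!is.na(assigned[ai])) members[[act[ai]]] <- groups[[assigned[ai]]]
  }
  members
}

# Pairwise overlap (shared genes and Jaccard) between non-empty modules.
module_overlap <- function(modules) {
  nonempty <- which(vapply(modules, nrow, integer(1)) > 0L)
  if (length(nonempty) < 2L) {
    return(tibble(module_a = integer(0), module_b = integer(0),
                  shared = integer(0), jaccard = numeric(0)))
  }
  pairs <- utils::combn(nonempty, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ga <- modules[[a]]$gene; gb <- modules[[b]]$gene
    tibble(module_a = a, module_b = b,
           shared = length(intersect(ga, gb)),
           jaccard = jaccard(ga, gb))
  })
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat(sprintf("<module_set> %d eigenvectors, %d non-empty modules\n",
              length(x), sum(sizes > 0)))
  for (j in which(sizes > 0)) {
    cat(sprintf("  eigenvector %d: %d genes\n", j, sizes[j]))
  }
  invisible(x)
}

#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(j) {
    m <- x[[j]]
    if (nrow(m) == 0L) return(NULL)
    tibble(eigenvector = j, gene = m$gene, loading = m$loading, q = m$q)
  })
}

#' Loading/q plot of called modules
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot object (one facet per non-empty module).
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  td <- tidy(object)
  if (nrow(td) == 0L) stop_comod("no non-empty modules to plot", "comod_validation_error")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$loading, y = -log10(pmax(.data$q, 1e-300)))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~eigenvector, scales = "free") +
    ggplot2::labs(x = "eigenvector loading", y = expression(-log[10](q)),
                  title = "Co-expression module calls")
}
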