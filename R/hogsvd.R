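#' Co-expression matrix of one condition
#'
#' The gene x gene cross-product `E = D' D` of one condition's expression
#' matrix (optionally gene-centered first, giving the covariance reading).
#' With more genes than samples E is singular, so a relative ridge
#' `ridge * (trace(E)/p) * I` keeps the downstream eigensystem well-posed;
#' the absolute amount added is recorded.
#'
#' @param x An `expr_matrix` (continuous values; raw counts are refused) or
#'   a plain samples x genes numeric matrix.
#' @param ridge Relative ridge epsilon (0 for none; default 0).
#' @param center `"gene"` (default) subtracts each gene's mean across samples
#'   before the cross-product; `"none"` uses the matrix as-is.
#' @return A `coexpr_matrix` object: list with `E`, `condition`,
#'   `ridge_epsilon` (absolute), `n_samples`.
#' @export
coexpression_matrix <- function(x, ridge = 0, center = c("gene", "none")) {
  center <- match.arg(center)
  if (inherits(x, "expr_matrix")) {
    if (x$value_kind == "raw_count") {
      stop_comod("co-expression matrices are built from continuous (log2-FPKM) values",
                 "comod_validation_error")
    }
    D <- x$values
    condition <- x$condition
  } else {
    D <- as.matrix(x)
    condition <- "condition"
  }
  p <- ncol(D)
  if (p < 1L) stop_comod("need at least one gene", "comod_validation_error")
  if (center == "gene") D <- scale(D, center = TRUE, scale = FALSE)
  E <- crossprod(D)
  eps_abs <- 0
  if (ridge > 0) {
    eps_abs <- ridge * (sum(diag(E)) / p)
    E <- E + diag(eps_abs, p)
  }
  structure(list(E = E, condition = condition, ridge_epsilon = eps_abs,
                 n_samples = nrow(D)),
            class = "coexpr_matrix")
}

#' The pairwise-averaged S matrix of the HO-GSVD eigensystem
#'
#' For T co-expression matrices,
#' `S = 1/(T(T-1)) * sum_{t<r} (E_t E_r^{-1} + E_r E_t^{-1})`.
#' Inverses are realized through Cholesky factorization of each E (a stable
#' solve, never cofactor inversion); a singular E without ridge is an error.
#' When all E coincide S is the identity.
#'
#' @param ematrices List of `coexpr_matrix` objects (or plain symmetric
#'   positive-definite matrices), all of the same dimension, T >= 2.
#' @return The p x p S matrix.
#' @export
build_s <- function(ematrices) {
  Es <- lapply(ematrices, function(e) if (inherits(e, "coexpr_matrix")) e$E else as.matrix(e))
  Tn <- length(Es)
  if (Tn < 2L) stop_comod("need at least two conditions", "comod_validation_error")
  p <- ncol(Es[[1]])
  if (!all(vapply(Es, function(E) all(dim(E) == p), logical(1)))) {
    stop_comod("co-expression matrices have mismatched dimensions", "comod_validation_error")
  }
  Einv <- lapply(seq_along(Es), function(i) {
    ch <- tryCatch(chol(Es[[i]]), error = function(e) NULL)
    if (is.null(ch)) {
      stop_comod(sprintf(
        "co-expression matrix %d is singular or not positive definite; rebuild with a ridge (e.g. ridge = 1e-6)", i),
        "comod_numeric_error")
    }
    chol2inv(ch)
  })
  S <- matrix(0, p, p)
  for (t in seq_len(Tn - 1L)) {
    for (r in seq((t + 1L), Tn)) {
      S <- S + Es[[t]] %*% Einv[[r]] + Es[[r]] %*% Einv[[t]]
    }
  }
  S / (Tn * (Tn - 1L))
}

#' Right basis of the HO-GSVD: eigensystem of S
#'
#' Eigenvalues are sorted descending (ties broken by original index) and each
#' eigenvector is unit-norm with its largest-magnitude entry oriented
#' positive, so module membership is invariant to solver sign conventions.
#' For symmetric-positive-definite inputs the eigenvalues are real and at
#' least 1; imaginary leakage beyond tolerance signals non-SPD inputs and is
#' an error.
#'
#' @param S The S matrix from [build_s()].
#' @param tol_imag Relative tolerance on imaginary parts (default 1e-8).
#' @return List with `lambda` (descending) and `V` (columns are unit-norm
#'   right basis vectors).
#' @export
right_basis <- function(S, tol_imag = 1e-8) {
  # exactly diagonal S (e.g. identical E_t give S = I): coordinate basis,
  # ordered by the diagonal, is the documented degenerate-case convention
  off <- S
  diag(off) <- 0
  if (all(off == 0)) {
    lam <- diag(S)
    ord <- order(-lam, seq_along(lam))
    V <- diag(nrow(S))[, ord, drop = FALSE]
    return(list(lambda = lam[ord], V = V, imag_leakage = 0))
  }
  es <- eigen(S)
  lam <- es$values
  V <- es$vectors
  scale_ref <- max(abs(Re(lam)), 1)
  leak <- if (is.complex(lam)) max(abs(Im(lam))) / scale_ref else 0
  if (leak > tol_imag) {
    stop_comod(sprintf("complex eigenvalues (relative imaginary leakage %.3g); inputs are not SPD", leak),
               "comod_numeric_error")
  }
  lam <- Re(lam)
  V <- Re(V)
  ord <- order(-lam, seq_along(lam))
  lam <- lam[ord]
  V <- V[, ord, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, j] <- v
  }
  list(lambda = lam, V = V, imag_leakage = leak)
}

#' Higher-order generalized SVD of matched expression matrices
#'
#' Joint factorization `D_t = U_t Sigma_t V'` of T gene-aligned matrices
#' sharing one right basis V, computed from the eigensystem of the pairwise
#' S matrix. Per condition, `B_t = D_t V^{-T}` is obtained by a stable
#' linear solve; `Sigma_t` holds the column norms of `B_t` (the higher-order
#' generalized singular values) and `U_t` its normalized columns. All-zero
#' columns get a zero singular value, a zero U column and a flag.
#'
#' @param matrices List of gene-aligned `expr_matrix` objects (or plain
#'   samples x genes matrices with identical column order), T >= 2.
#' @param ridge Relative ridge passed to [coexpression_matrix()]
#'   (default 1e-6).
#' @param center Centering mode, see [coexpression_matrix()].
#' @param tol_imag Imaginary-leakage tolerance for [right_basis()].
#' @param compute_u Compute the left bases and singular values (default
#'   `TRUE`). Requires a well-conditioned V, which exists when the panels
#'   are full rank (n_t > p); in the many-more-genes-than-samples regime
#'   the near-degenerate lambda = 1 eigenspace makes V numerically singular
#'   and only the right basis (all that module calling needs) is meaningful,
#'   so set `compute_u = FALSE` there.
#' @return An object of class `hogsvd` with elements `lambda`, `V`, `U`
#'   (list), `sigma` (list), `S`, `T`, `gene_ids`, `conditions` and
#'   `diagnostics` (max relative reconstruction residual, imaginary leakage,
#'   absolute ridge added, flagged zero columns).
#' @export
hogsvd <- function(matrices, ridge = 1e-6, center = c("gene", "none"), tol_imag = 1e-8,
                   compute_u = TRUE) {
  center <- match.arg(center)
  stopifnot(length(matrices) >= 2L)
  Ds <- lapply(matrices, function(m) if (inherits(m, "expr_matrix")) m$values else as.matrix(m))
  conds <- vapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (inherits(m, "expr_matrix")) m$condition else paste0("condition_", i)
  }, character(1))
  genes <- colnames(Ds[[1]]) %||% paste0("g", seq_len(ncol(Ds[[1]])))
  for (i in seq_along(Ds)) {
    gi <- colnames(Ds[[i]]) %||% genes
    if (ncol(Ds[[i]]) != length(genes) || !identical(gi, genes)) {
      stop_comod("matrices are not gene-aligned; run align_gene_panels() first",
                 "comod_validation_error")
    }
  }
  Es <- lapply(matrices, coexpression_matrix, ridge = ridge, center = center)
  S <- build_s(Es)
  rb <- right_basis(S, tol_imag = tol_imag)
  V <- rb$V
  kap <- kappa(V, exact = FALSE)
  U <- NULL
  sigma <- NULL
  zero_cols <- list()
  max_resid <- NA_real_
  if (compute_u) {
    if (!is.finite(kap) || kap > 1e12) {
      stop_comod(sprintf(
        "right basis V is ill-conditioned (kappa ~ %.3g); increase the ridge, or set compute_u = FALSE if only the right basis is needed", kap),
        "comod_numeric_error")
    }
    # D = B V'  =>  B' = V^{-1} D'
    U <- vector("list", length(Ds))
    sigma <- vector("list", length(Ds))
    max_resid <- 0
    for (t in seq_along(Ds)) {
      D <- Ds[[t]]
      B <- t(solve(V, t(D)))
      sig <- sqrt(colSums(B^2))
      sig[sig <= 1e-12 * max(sig, 1)] <- 0
      Ut <- B
      nz <- sig > 0
      Ut[, nz] <- sweep(B[, nz, drop = FALSE], 2, sig[nz], "/")
      Ut[, !nz] <- 0
      if (any(!nz)) zero_cols[[conds[t]]] <- which(!nz)
      recon <- Ut %*% (sig * t(V))
      denom <- sqrt(sum(D^2))
      if (denom > 0) max_resid <- max(max_resid, sqrt(sum((D - recon)^2)) / denom)
      U[[t]] <- Ut
      sigma[[t]] <- sig
    }
    names(U) <- conds
    names(sigma) <- conds
  }
  structure(
    list(lambda = rb$lambda, V = V, U = U, sigma = sigma, S = S,
         T = length(Ds), gene_ids = genes, conditions = conds,
         center = center, ridge = ridge,
         diagnostics = list(max_reconstruction_residual = max_resid,
                            imag_leakage = rb$imag_leakage,
                            ridge_epsilon_abs = vapply(Es, function(e) e$ridge_epsilon, numeric(1)),
                            kappa_V = kap,
                            zero_sigma_columns = zero_cols)),
    class = "hogsvd")
}

#' @export
print.hogsvd <- function(x, ...) {
  cat(sprintf("<hogsvd> T=%d conditions, p=%d genes\n", x$T, length(x$gene_ids)))
  cat("  lambda (top 5):", paste(signif(head(x$lambda, 5), 4), collapse = ", "), "\n")
  cat(sprintf("  max reconstruction residual: %.3g\n",
              x$diagnostics$max_reconstruction_residual))
  invisible(x)
}

#' @describeIn hogsvd Eigenvalues as a tibble (one row per right basis
#'   vector, eigenvalue rank order).
#' @param x A `hogsvd` object.
#' @param ... Unused.
#' @method tidy hogsvd
#' @export
tidy.hogsvd <- function(x, ...) {
  tibble(eigenvector = seq_along(x$lambda), lambda = x$lambda)
}

#' @describeIn hogsvd One-row summary of the decomposition.
#' @method glance hogsvd
#' @export
glance.hogsvd <- function(x, ...) {
  tibble(n_conditions = x$T, n_genes = length(x$gene_ids),
         max_reconstruction_residual = x$diagnostics$max_reconstruction_residual,
         imag_leakage = x$diagnostics$imag_leakage,
         kappa_V = x$diagnostics$kappa_V,
         lambda_min = min(x$lambda), lambda_max = max(x$lambda))
}

#' Scree plot of S eigenvalues
#'
#' @param object A `hogsvd` object.
#' @param k Number of leading eigenvalues to show (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hogsvd
#' @export
autoplot.hogsvd <- function(object, k = 50, ...) {
  td <- head(tidy(object), k)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$eigenvector, y = .data$lambda)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "right basis vector (eigenvalue rank)",
                  y = expression(lambda), title = "HO-GSVD eigenvalue spectrum")
}
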