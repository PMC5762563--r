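# Non-negative matrix factorization by Lee-Seung multiplicative updates
# (Frobenius objective). Small dense problems only: module genes x patients.

nmf_fit <- function(X, k, n_restarts = 20L, max_iter = 1000L, tol = 1e-10, seed = 1L) {
  stopifnot(all(X >= 0), k >= 1L)
  n <- nrow(X); m <- ncol(X)
  eps <- .Machine$double.eps
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      W <- matrix(runif(n * k, 1e-3, 1), n, k)
      H <- matrix(runif(k * m, 1e-3, 1), k, m)
      obj <- rep(NA_real_, max_iter)
      prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
        W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
        o <- sum((X - W %*% H)^2)
        obj[it] <- o
        if (prev - o < tol * max(o, 1)) { obj <- obj[seq_len(it)]; break }
        prev <- o
      }
      o_final <- obj[length(obj)]
      if (is.null(best) || o_final < best$objective) {
        best <- list(W = W, H = H, objective = o_final, trajectory = obj)
      }
    }
    best
  })
}
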