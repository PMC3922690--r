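#' Hoyer sparsity of a vector
#'
#' Quantifies how concentrated a non-negative (or arbitrary) vector is:
#' 0 for a vector with all elements equal, 1 for a vector with a single
#' non-zero component. Defined as (sqrt(n) - ||v||_1/||v||_2) / (sqrt(n) - 1).
#'
#' @param v Numeric vector with at least two elements.
#' @return A scalar in [0, 1]. An all-zero vector returns 0 with a warning
#'   (the measure is undefined there).
#' @export
hoyer_sparsity <- function(v) {
  if (!is.numeric(v)) stop("'v' must be numeric")
  n <- length(v)
  if (n < 2L) stop("Hoyer sparsity requires a vector of length >= 2")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) {
    warning("all-zero vector: Hoyer sparsity undefined, returning 0")
    return(0)
  }
  (sqrt(n) - sum(abs(v)) / l2) / (sqrt(n) - 1)
}

#' Mean Hoyer sparsity over matrix rows
#'
#' @param M Numeric matrix.
#' @return Arithmetic mean of `hoyer_sparsity` over rows; all-zero rows are
#'   skipped with a warning.
#' @export
matrix_sparsity <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 1L) stop("empty matrix")
  zero <- rowSums(abs(M)) == 0
  if (all(zero)) stop("all rows are zero: matrix sparsity undefined")
  if (any(zero)) warning(sum(zero), " all-zero row(s) skipped in matrix_sparsity")
  mean(apply(M[!zero, , drop = FALSE], 1L, hoyer_sparsity))
}

#' NNDSVD initialization for non-negative matrix factorization
#'
#' Non-negative double singular value decomposition: the leading singular
#' triplet is taken with absolute values; every subsequent singular vector
#' pair is split into its positive and negative parts, the part pair with the
#' larger product of norms is kept and rescaled by the singular value. The
#' plain variant is fully deterministic. The `ar` variant replaces the exact
#' zeros of the plain construction by small uniform values in
#' (0, mean(V)/100], which avoids locked zero entries in some optimizers.
#'
#' @param V Non-negative numeric matrix (loci x marks).
#' @param c Factorization rank, 1 <= c <= min(dim(V)).
#' @param variant "plain" (deterministic) or "ar" (randomized zeros).
#' @param seed Integer seed used by the "ar" variant only.
#' @return List with non-negative matrices `W0` (nrow(V) x c) and
#'   `H0` (c x ncol(V)).
#' @export
nndsvd_init <- function(V, c, variant = c("plain", "ar"), seed = NULL) {
  variant <- match.arg(variant)
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  n <- nrow(V); m <- ncol(V)
  if (c < 1L || c > min(n, m)) stop("rank c must satisfy 1 <= c <= min(dim(V))")
  s <- svd(V, nu = c, nv = c)
  W0 <- matrix(0, n, c)
  H0 <- matrix(0, c, m)
  W0[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  H0[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  if (c >= 2L) {
    for (j in 2:c) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      mp <- nup * nvp; mn <- nun * nvn
      # tie (mp == mn) resolves to the positive part: deterministic
      if (mp >= mn) {
        uu <- if (nup > 0) up / nup else up
        vv <- if (nvp > 0) vp / nvp else vp
        sig <- mp
      } else {
        uu <- un / nun
        vv <- vn / nvn
        sig <- mn
      }
      W0[, j] <- sqrt(s$d[j] * sig) * uu
      H0[j, ] <- sqrt(s$d[j] * sig) * vv
    }
  }
  if (variant == "ar") {
    if (!is.null(seed)) set.seed(seed)
    eps <- mean(V) / 100
    zw <- W0 == 0; zh <- H0 == 0
    W0[zw] <- stats::runif(sum(zw), 0, eps)
    H0[zh] <- stats::runif(sum(zh), 0, eps)
  }
  list(W0 = W0, H0 = H0)
}

# One HALS sweep over the columns of W; exact per-block minimization of
# ||V - WH||_F^2 keeps the objective monotone.
.hals_update_W <- function(V, W, H) {
  HHt <- tcrossprod(H)          # c x c
  VHt <- tcrossprod(V, H)       # n x c
  for (k in seq_len(nrow(H))) {
    denom <- HHt[k, k]
    if (denom <= .Machine$double.eps) next
    wk <- W[, k] + (VHt[, k] - W %*% HHt[, k]) / denom
    W[, k] <- pmax(wk, 0)
  }
  W
}

# HALS sweep over the rows of H with an L1 penalty (weight l1) on H.
.hals_update_H <- function(V, W, H, l1) {
  WtW <- crossprod(W)           # c x c
  WtV <- crossprod(W, V)        # c x m
  for (k in seq_len(nrow(H))) {
    denom <- WtW[k, k]
    if (denom <= .Machine$double.eps) next
    hk <- H[k, ] + (WtV[k, ] - WtW[k, ] %*% H) / denom - l1 / (2 * denom)
    H[k, ] <- pmax(hk, 0)
  }
  H
}

#' Sparsity-penalized non-negative matrix factorization
#'
#' Minimizes ||V - WH||_F^2 + l1_H * sum(H) subject to W, H >= 0 by block
#' coordinate descent (HALS updates: each column of W and row of H is
#' minimized exactly in turn, so the penalized objective is non-increasing).
#' The L1 penalty is applied to H only, favouring basis patterns ("codes")
#' that load on few marks.
#'
#' @param V Non-negative matrix, typically sigmoid-scaled (see
#'   [scale_matrix()]); rows are loci, columns marks.
#' @param c Factorization rank (number of codes).
#' @param init Initialization: "nndsvd" (deterministic), "nndsvdar", or
#'   "random" (uniform (0,1) entries).
#' @param l1_H L1 penalty weight on H (default 0.1, tuned for data scaled
#'   to [0,1)).
#' @param max_iter Maximum number of outer iterations.
#' @param tol Relative change of the penalized objective below which
#'   iteration stops.
#' @param seed Integer seed (used by "random" and "nndsvdar" inits).
#' @return An object of class `chromcode_nmf`: list with `W` (n x c),
#'   `H` (c x m), `rank`, `reconstruction_error` (Frobenius norm of V - WH,
#'   unpenalized), `objective_trace`, `n_iter`, `init_method`, `l1_H`,
#'   `mode` tag, and row/column labels.
#' @export
nmf <- function(V, c, init = c("nndsvd", "nndsvdar", "random"),
                l1_H = 0.1, max_iter = 500L, tol = 1e-4, seed = NULL) {
  init <- match.arg(init)
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("V contains non-finite entries")
  if (any(V < 0)) stop("V must be non-negative")
  if (sum(V) == 0) stop("V is all zero: nothing to factorize")
  n <- nrow(V); m <- ncol(V)
  if (c < 1L || c > min(n, m)) stop("rank c must satisfy 1 <= c <= min(dim(V))")

  if (init == "random") {
    if (!is.null(seed)) set.seed(seed)
    W <- matrix(stats::runif(n * c), n, c)
    H <- matrix(stats::runif(c * m), c, m)
  } else {
    ini <- nndsvd_init(V, c, variant = if (init == "nndsvdar") "ar" else "plain",
                       seed = seed)
    W <- ini$W0; H <- ini$H0
  }

  obj <- function(W, H) sum((V - W %*% H)^2) + l1_H * sum(H)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj(W, H)
  it <- 0L
  for (it in seq_len(max_iter)) {
    W <- .hals_update_W(V, W, H)
    H <- .hals_update_H(V, W, H, l1_H)
    trace[it + 1L] <- obj(W, H)
    prev <- trace[it]
    if (prev > 0 && abs(prev - trace[it + 1L]) / prev < tol) break
  }
  trace <- trace[seq_len(it + 1L)]

  dimnames(W) <- list(rownames(V), paste0("code_", seq_len(c)))
  dimnames(H) <- list(paste0("code_", seq_len(c)), colnames(V))
  structure(list(
    W = W, H = H, rank = c,
    reconstruction_error = sqrt(sum((V - W %*% H)^2)),
    objective_trace = trace, n_iter = it,
    init_method = init, l1_H = l1_H, tol = tol, max_iter = max_iter,
    mode = "matrix"
  ), class = "chromcode_nmf")
}

#' @export
print.chromcode_nmf <- function(x, ...) {
  cat("chromcode NMF factorization (", x$mode, " mode)\n", sep = "")
  cat("  rank c: ", x$rank, ", loci: ", nrow(x$W), ", columns: ", ncol(x$H), "\n", sep = "")
  cat("  init: ", x$init_method, ", l1_H: ", x$l1_H,
      ", iterations: ", x$n_iter, "\n", sep = "")
  cat("  reconstruction error (Frobenius): ",
      format(x$reconstruction_error, digits = 6), "\n", sep = "")
  cat("  mean Hoyer sparsity H rows: ",
      format(matrix_sparsity(x$H), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Scan factorization ranks
#'
#' Runs [nmf()] once per requested rank with identical settings and records
#' the mean Hoyer sparsity of the rows of H and of W and the reconstruction
#' error, so the user can locate a knee in the sparsity curve. No automatic
#' rank selection is attempted.
#'
#' @param V Non-negative input matrix.
#' @param c_values Integer vector of ranks to scan.
#' @inheritParams nmf
#' @return A data.frame with one row per rank: `c`, `sparsity_H`,
#'   `sparsity_W`, `reconstruction_error`, `n_iter`.
#' @export
rank_scan <- function(V, c_values, init = "nndsvd", l1_H = 0.1,
                      max_iter = 500L, tol = 1e-4, seed = NULL) {
  if (length(c_values) < 1L) stop("no ranks requested")
  rows <- lapply(c_values, function(cc) {
    fit <- nmf(V, cc, init = init, l1_H = l1_H, max_iter = max_iter,
               tol = tol, seed = seed)
    data.frame(c = cc,
               sparsity_H = suppressWarnings(matrix_sparsity(fit$H)),
               # Hoyer sparsity is undefined for the length-1 rows of W at c = 1
               sparsity_W = if (cc < 2L) NA_real_ else
                 suppressWarnings(matrix_sparsity(fit$W)),
               reconstruction_error = fit$reconstruction_error,
               n_iter = fit$n_iter)
  })
  do.call(rbind, rows)
}
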