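#' Sigmoid percentile scaling of a signal column
#'
#' Maps a non-negative vector into [0, 1) with
#' `2 / (1 + exp(-2 * x / u)) - 1`, where `u` is the 95th percentile of `x`
#' (linear-interpolation percentile). The mapping is approximately linear up
#' to `u` and saturates above it, so extreme loci do not dominate the
#' factorization; it is invariant to rescaling the input by any positive
#' constant.
#'
#' @param x Non-negative numeric vector.
#' @return Scaled vector: 0 maps to 0, `u` maps to 2/(1+e^-2)-1 ~ 0.7616,
#'   values are strictly below 1 and monotone in the input.
#' @export
sigmoid_scale <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) stop("'x' must be a non-empty numeric vector")
  if (any(x < 0)) stop("'x' must be non-negative")
  if (all(x == 0)) {
    warning("all-zero column: 95th percentile undefined, returning zeros")
    return(x)
  }
  u <- stats::quantile(x, 0.95, names = FALSE, type = 7)
  if (u == 0) {
    u <- min(x[x > 0])
    warning("95th percentile is zero; using smallest positive value as scale")
  }
  2 / (1 + exp(-2 * x / u)) - 1
}

#' Sigmoid-scale every column of a signal matrix
#'
#' @param M Non-negative matrix (loci x marks), unscaled.
#' @return Matrix of the same shape with [sigmoid_scale()] applied to each
#'   column independently; attribute `scaled` set to TRUE.
#' @export
scale_matrix <- function(M) {
  M <- as.matrix(M)
  if (isTRUE(attr(M, "scaled"))) stop("matrix is already scaled")
  out <- apply(M, 2L, sigmoid_scale)
  dimnames(out) <- dimnames(M)
  attr(out, "scaled") <- TRUE
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed with the DESeq
#' median-of-ratios estimator: the factor of sample j is the median over rows
#' of K_ij divided by the row geometric mean, rows containing a zero being
#' excluded.
#'
#' @param K Count matrix (windows or loci x samples), >= 2 samples.
#' @return Named positive numeric vector of length ncol(K).
#' @export
size_factors <- function(K) {
  K <- as.matrix(K)
  if (ncol(K) < 2L) stop("size factors need at least two samples")
  if (!any(apply(K, 1L, function(r) all(r > 0))))
    stop("no row with all-positive counts; use coarser windows")
  sf <- DESeq2::estimateSizeFactorsForMatrix(K)
  names(sf) <- colnames(K)
  sf
}

#' Per-locus gain and loss of windowed differential coverage
#'
#' Subtracts depth-corrected condition-A window counts from condition-B
#' counts and integrates the signed parts: gain is the sum of positive window
#' differences, loss the sum of the magnitudes of negative ones. A broadened
#' peak therefore shows losses at its summit and gains at its slopes within
#' the same locus.
#'
#' @param counts_a,counts_b Windowed counts for the two conditions: named
#'   lists (one element per locus) of per-window count vectors on the same
#'   window grid, as returned by [windowed_counts()].
#' @param factors Length-2 numeric vector of size factors `c(a = ..., b = ...)`
#'   from [size_factors()] on the pooled window-count matrix.
#' @return List with `summary`, a data.frame (`locus`, `gain`, `loss`), and
#'   `diffs`, the per-locus vectors of depth-corrected B - A differences.
#' @export
gain_loss <- function(counts_a, counts_b, factors) {
  if (length(counts_a) != length(counts_b) ||
      !identical(lengths(counts_a), lengths(counts_b)))
    stop("window grids of the two conditions do not match")
  if (length(factors) != 2L || any(factors <= 0))
    stop("'factors' must be two positive size factors")
  # depth-corrected differences; magnitudes below float resolution of the
  # corrected counts are snapped to zero so that identical libraries yield
  # exact zero gain/loss (the later sigmoid scaling would otherwise blow
  # rounding residue up to full scale)
  scale_ab <- max(1, max(unlist(counts_a)) / factors[1L],
                  max(unlist(counts_b)) / factors[2L])
  tol <- 1e-8 * scale_ab
  diffs <- Map(function(a, b) {
    d <- b / factors[2L] - a / factors[1L]
    d[abs(d) < tol] <- 0
    d
  }, counts_a, counts_b)
  summary <- data.frame(
    locus = names(counts_a),
    gain = vapply(diffs, function(d) sum(pmax(d, 0)), numeric(1)),
    loss = vapply(diffs, function(d) sum(pmax(-d, 0)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(summary = summary, diffs = diffs)
}

#' Assemble and scale the differential gain/loss signal matrix
#'
#' Builds the loci x 2m matrix whose columns are the per-mark gain and loss
#' scores (interleaved `<mark>.gain`, `<mark>.loss`), then sigmoid-scales
#' every column. This is the input of the differential factorization mode.
#'
#' @param profiles Named list (one element per mark) of [gain_loss()] results
#'   over the same region set.
#' @param scale If FALSE the raw unscaled matrix is returned.
#' @return Scaled matrix with 2 * length(profiles) columns.
#' @export
build_differential_matrix <- function(profiles, scale = TRUE) {
  if (length(profiles) < 1L || is.null(names(profiles)))
    stop("'profiles' must be a named list with one entry per mark")
  loci <- profiles[[1L]]$summary$locus
  cols <- list()
  for (mark in names(profiles)) {
    s <- profiles[[mark]]$summary
    if (!identical(s$locus, loci))
      stop("mark '", mark, "' has profiles for a different region set")
    cols[[paste0(mark, ".gain")]] <- s$gain
    cols[[paste0(mark, ".loss")]] <- s$loss
  }
  M <- do.call(cbind, cols)
  rownames(M) <- loci
  if (scale) M <- scale_matrix(M)
  M
}
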