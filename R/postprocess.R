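# Hungarian (Kuhn-Munkres) minimum-cost assignment with dual potentials and
# explicit predecessor bookkeeping (Jonker-Volgenant style shortest
# augmenting paths). cost: n x m matrix with n <= m; returns, for each row,
# its assigned column. Used for matching basis patterns between
# factorizations.
.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("internal: .hungarian requires nrow <= ncol")
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Hard code assignment of loci
#'
#' Labels every locus with the code (column of W) carrying its maximal
#' weight, analogous to hard cluster assignment in K-means. Ties are broken
#' towards the lowest code index; an all-zero row is reported as unassigned
#' (NA).
#'
#' @param W Non-negative weight matrix (loci x codes) or a `chromcode_nmf`
#'   object.
#' @return data.frame with columns `locus`, `code` (integer index, NA if
#'   unassigned), `code_label`, `weight` (the maximal weight) and `margin`
#'   (distance to the runner-up weight).
#' @export
assign_codes <- function(W) {
  if (inherits(W, "chromcode_nmf")) W <- W$W
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be non-negative")
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("code_", seq_len(ncol(W)))
  res <- lapply(seq_len(nrow(W)), function(i) {
    w <- W[i, ]
    if (all(w == 0))
      return(data.frame(code = NA_integer_, weight = 0, margin = 0))
    k <- which.max(w)  # which.max takes the first maximum: low-index tie rule
    runner <- if (length(w) > 1L) max(w[-k]) else 0
    data.frame(code = as.integer(k), weight = unname(w[k]),
               margin = unname(w[k] - runner))
  })
  out <- do.call(rbind, res)
  out <- cbind(
    data.frame(locus = if (is.null(rownames(W))) as.character(seq_len(nrow(W)))
               else rownames(W), stringsAsFactors = FALSE),
    out)
  out$code_label <- ifelse(is.na(out$code), NA_character_, labels[out$code])
  out[, c("locus", "code", "code_label", "weight", "margin")]
}

#' Match codes between two factorizations
#'
#' Finds the minimum-total-cost pairing of the basis patterns (rows of H) of
#' two factorizations, where the cost of a pair is the Euclidean distance
#' between the rows, using the Hungarian algorithm. For unequal ranks a
#' rectangular assignment is solved on the smaller side and unmatched codes
#' are reported as singletons.
#'
#' @param H_a,H_b Basis matrices (codes x marks) with identical column
#'   labels (a permuted column order is aligned internally), or
#'   `chromcode_nmf` objects.
#' @param normalize "none" (plain Euclidean distance, the default) or "l2"
#'   (rows scaled to unit L2 norm before matching, for cross-dataset
#'   comparisons where overall scale differs).
#' @return List of class `chromcode_matching`: `pairs`, a data.frame
#'   (`code_a`, `code_b`, `cost`), `total_cost`, and `unmatched` (indices on
#'   the larger side left without a partner).
#' @export
match_codes <- function(H_a, H_b, normalize = c("none", "l2")) {
  normalize <- match.arg(normalize)
  if (inherits(H_a, "chromcode_nmf")) H_a <- H_a$H
  if (inherits(H_b, "chromcode_nmf")) H_b <- H_b$H
  H_a <- as.matrix(H_a); H_b <- as.matrix(H_b)
  if (!is.null(colnames(H_a)) && !is.null(colnames(H_b))) {
    if (!setequal(colnames(H_a), colnames(H_b)) ||
        anyDuplicated(colnames(H_a)) || anyDuplicated(colnames(H_b)))
      stop("column labels of the two basis matrices do not match")
    H_b <- H_b[, colnames(H_a), drop = FALSE]
  } else if (ncol(H_a) != ncol(H_b)) {
    stop("basis matrices have different numbers of columns")
  }
  if (normalize == "l2") {
    unit <- function(M) {
      nrm <- sqrt(rowSums(M^2)); nrm[nrm == 0] <- 1
      M / nrm
    }
    H_a <- unit(H_a); H_b <- unit(H_b)
  }
  ca <- nrow(H_a); cb <- nrow(H_b)
  cost <- matrix(0, ca, cb)
  for (i in seq_len(ca))
    for (j in seq_len(cb))
      cost[i, j] <- sqrt(sum((H_a[i, ] - H_b[j, ])^2))
  swap <- ca > cb
  cm <- if (swap) t(cost) else cost
  assign <- .hungarian(cm)
  if (swap) {
    pairs <- data.frame(code_a = assign, code_b = seq_len(cb))
  } else {
    pairs <- data.frame(code_a = seq_len(ca), code_b = assign)
  }
  pairs$cost <- cost[cbind(pairs$code_a, pairs$code_b)]
  pairs <- pairs[order(pairs$code_a), , drop = FALSE]
  rownames(pairs) <- NULL
  unmatched <- if (swap) setdiff(seq_len(ca), pairs$code_a)
               else setdiff(seq_len(cb), pairs$code_b)
  structure(list(pairs = pairs, total_cost = sum(pairs$cost),
                 unmatched = unmatched, side = if (swap) "a" else "b"),
            class = "chromcode_matching")
}

#' @export
print.chromcode_matching <- function(x, ...) {
  cat("code matching (", nrow(x$pairs), " pairs, total cost ",
      format(x$total_cost, digits = 6), ")\n", sep = "")
  print(x$pairs)
  if (length(x$unmatched))
    cat("unmatched on side '", x$side, "': ",
        paste(x$unmatched, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Spearman correlation matrix of signal or weight columns
#'
#' Pairwise Spearman rank correlations between the columns of a matrix
#' (marks of V, or code weights W). Pairs with |rho| above `flag_threshold`
#' are reported in the `flagged` attribute: such variables should not enter
#' a multivariate regression together.
#'
#' @param M Numeric matrix with >= 3 rows.
#' @param flag_threshold Absolute correlation above which a pair is flagged
#'   (default 0.8).
#' @return Symmetric correlation matrix; constant columns yield 0 (not NA)
#'   and are listed in the `constant_columns` attribute. Attribute `flagged`
#'   is a data.frame of high-correlation pairs.
#' @export
correlation_matrix <- function(M, flag_threshold = 0.8) {
  M <- as.matrix(M)
  if (nrow(M) < 3L) stop("need at least 3 rows for a rank correlation")
  const <- apply(M, 2L, function(x) length(unique(x)) == 1L)
  suppressWarnings(R <- stats::cor(M, method = "spearman"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  labels <- colnames(M)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(M)))
  dimnames(R) <- list(labels, labels)
  idx <- which(upper.tri(R) & abs(R) > flag_threshold, arr.ind = TRUE)
  attr(R, "flagged") <- data.frame(
    var1 = labels[idx[, 1L]], var2 = labels[idx[, 2L]],
    rho = R[idx], stringsAsFactors = FALSE)
  attr(R, "constant_columns") <- labels[const]
  R
}
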