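#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (one set per line: id, description,
#'   tab-separated member genes).
#' @return Named list of character vectors of gene ids. Errors on an empty
#'   collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("empty GMT collection: ", path)
  sets
}

#' Random-set enrichment test of a gene score vector
#'
#' Compares the mean score of the genes in a set against its exact mean and
#' variance under random sets of the same size drawn without replacement
#' from all scored genes: with N genes, set size m, population mean mu and
#' population variance sigma^2, the mean score Xbar of a random set has
#' E[Xbar] = mu and Var[Xbar] = (sigma^2 / m) * (N - m) / (N - 1). The test
#' statistic z = (Xbar - mu) / sd is referred to the standard normal;
#' by default the upper tail (positive association) is reported.
#'
#' @param scores Named numeric vector of per-gene scores (N >= 2, unique
#'   names).
#' @param gene_set Character vector of gene ids; only genes present among
#'   the scores count towards the set size m.
#' @param alternative "greater" (default, positive association) or
#'   "two.sided".
#' @return List with `m`, `xbar`, `z` and `p`. If no set member is scored
#'   (m = 0) all values are NA; if the scores have zero variance, z is NA
#'   and p = 1.
#' @export
random_set_test <- function(scores, gene_set,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("'scores' must have unique gene names")
  N <- length(scores)
  if (N < 2L) stop("need at least two scored genes")
  members <- intersect(gene_set, names(scores))
  m <- length(members)
  if (m == 0L)
    return(list(m = 0L, xbar = NA_real_, z = NA_real_, p = NA_real_))
  if (m == N) stop("gene set covers every scored gene (m = N): no contrast")
  mu <- mean(scores)
  sigma2 <- mean((scores - mu)^2)      # population variance
  xbar <- mean(scores[members])
  sd_xbar <- sqrt(sigma2 / m * (N - m) / (N - 1))
  if (sd_xbar == 0)
    return(list(m = m, xbar = xbar, z = NA_real_, p = 1))
  z <- (xbar - mu) / sd_xbar
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(m = m, xbar = xbar, z = z, p = p)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up q-values: q_(i) = min over j >= i of p_(j) * M / j,
#' capped at 1 and mapped back to input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set enrichment of every code's locus weights
#'
#' Runs the random-set test for every (code, gene set) pair, scoring genes
#' by the code's column of W, and corrects all p-values jointly by
#' Benjamini-Hochberg (the stricter family; per-collection reporting can be
#' done by filtering the output).
#'
#' @param fit A `chromcode_nmf` object (or a weight matrix W with locus row
#'   names).
#' @param gene_sets Named list of gene-id vectors, e.g. from [read_gmt()].
#' @param gene_map Optional named character vector mapping locus names to
#'   gene ids; loci mapping to the same gene have their weights averaged.
#'   By default locus names are used as gene ids directly.
#' @param alternative Passed to [random_set_test()].
#' @return data.frame with one row per tested (code, set) pair: `code`,
#'   `set`, `m`, `z`, `p`, `q`, sorted by q then p. Sets with no scored
#'   member are skipped (attribute `skipped_sets`).
#' @export
enrich_all <- function(fit, gene_sets, gene_map = NULL,
                       alternative = "greater") {
  W <- if (inherits(fit, "chromcode_nmf")) fit$W else as.matrix(fit)
  if (length(gene_sets) == 0L) stop("empty gene-set collection")
  if (is.null(rownames(W))) stop("W must carry locus row names")
  genes <- rownames(W)
  if (!is.null(gene_map)) {
    mapped <- unname(gene_map[genes])
    keep <- !is.na(mapped)
    if (!any(keep)) stop("no locus maps to a gene id")
    W <- W[keep, , drop = FALSE]
    genes <- mapped[keep]
  }
  if (anyDuplicated(genes)) {
    W <- apply(W, 2L, function(col) tapply(col, genes, mean))
    genes <- rownames(W)
  }
  codes <- colnames(W)
  if (is.null(codes)) codes <- paste0("code_", seq_len(ncol(W)))
  rows <- list(); skipped <- character(0)
  for (k in seq_len(ncol(W))) {
    scores <- stats::setNames(W[, k], genes)
    for (s in names(gene_sets)) {
      res <- random_set_test(scores, gene_sets[[s]],
                             alternative = alternative)
      if (res$m == 0L) {
        skipped <- union(skipped, s)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        code = codes[k], set = s, m = res$m, z = res$z, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no gene set overlaps the scored genes")
  out <- do.call(rbind, rows)
  out$p[is.na(out$p)] <- 1       # zero-variance degenerate case
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_sets") <- skipped
  out
}
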