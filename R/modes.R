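#' Non-negative least-squares weights for a fixed basis
#'
#' Solves, for every row v of the scaled signal matrix, min ||v - wH||_2
#' subject to w >= 0. Used to recombine class-specific codes in the
#' discriminatory mode and to project new data onto an existing basis.
#'
#' @param V Non-negative matrix (loci x columns).
#' @param H Basis matrix (codes x columns) with matching column dimension.
#' @return Non-negative weight matrix W (loci x codes). All-zero rows of H
#'   are dropped from the solve and restored as zero weights, with a
#'   warning; an all-zero row of V yields an all-zero row of W.
#' @export
nnls_weights <- function(V, H) {
  V <- as.matrix(V); H <- as.matrix(H)
  if (ncol(V) != ncol(H)) stop("column dimensions of V and H disagree")
  zero_codes <- rowSums(abs(H)) == 0
  if (all(zero_codes)) stop("all rows of H are zero")
  if (any(zero_codes))
    warning(sum(zero_codes), " all-zero row(s) of H dropped from NNLS solve")
  Hc <- H[!zero_codes, , drop = FALSE]
  Ct <- t(Hc)                        # columns x active codes
  W <- matrix(0, nrow(V), nrow(H))
  for (i in seq_len(nrow(V))) {
    v <- V[i, ]
    if (all(v == 0)) next
    W[i, !zero_codes] <- pracma::lsqnonneg(Ct, v)$x
  }
  dimnames(W) <- list(rownames(V), rownames(H))
  W
}

# shared finishing: attach labels and mode tag to a fit
.tag_fit <- function(fit, mode) {
  fit$mode <- mode
  fit
}

#' Absolute-mode code discovery from BAM and BED files
#'
#' The basic pipeline: count reads per locus and mark, sigmoid-scale each
#' mark column, and factorize the scaled matrix into c sparse basis patterns
#' ("codes") and per-locus weights.
#'
#' @param bams Character vector of BAM paths, one per mark.
#' @param bed Path to the BED6+ file defining the loci (rows of V).
#' @param c Factorization rank.
#' @param labels Optional mark labels (default: BAM file names).
#' @inheritParams nmf
#' @inheritParams count_reads
#' @return A `chromcode_nmf` object tagged mode "absolute", with `regions`
#'   and `counts` attached.
#' @export
absolute_mode <- function(bams, bed, c, labels = NULL,
                          init = "nndsvd", l1_H = 0.1, max_iter = 500L,
                          tol = 1e-4, seed = NULL,
                          filter_dup = FALSE, min_mapq = 0L) {
  regions <- read_regions(bed)
  counts <- build_count_matrix(bams, regions, labels = labels,
                               filter_dup = filter_dup, min_mapq = min_mapq)
  V <- scale_matrix(counts)
  fit <- nmf(V, c, init = init, l1_H = l1_H, max_iter = max_iter,
             tol = tol, seed = seed)
  fit$regions <- regions
  fit$counts <- counts
  .tag_fit(fit, "absolute")
}

#' Discriminatory code discovery from per-class scaled matrices
#'
#' Core of the discriminatory mode, operating on matrices: each class's
#' scaled signal matrix is factorized independently (class-specific codes),
#' the per-class basis matrices are row-concatenated, and a single weight
#' matrix over all loci of all classes is re-derived by non-negative least
#' squares against the combined basis. Codes specific to one class should
#' receive weight mostly at loci of that class; if the classes share their
#' latent structure the codes are interchangeable instead.
#'
#' @param V_list Named list of scaled non-negative matrices (same columns,
#'   one element per class).
#' @param c_per_class Rank per class: a single value applied to every class
#'   or one value per class.
#' @inheritParams nmf
#' @return A `chromcode_nmf` object tagged "discriminatory". `H` has
#'   sum(c_per_class) rows labeled `<class>:code_<j>`; `W` stacks all
#'   classes in input order; `class_partition` records each row's class and
#'   the per-class fits are kept in `class_fits`.
#' @export
discriminatory_nmf <- function(V_list, c_per_class, init = "nndsvd",
                               l1_H = 0.1, max_iter = 500L, tol = 1e-4,
                               seed = NULL) {
  k <- length(V_list)
  if (k < 1L) stop("no classes given")
  if (is.null(names(V_list)) || any(!nzchar(names(V_list))))
    names(V_list) <- paste0("class", seq_len(k))
  c_per_class <- rep_len(c_per_class, k)
  cols <- colnames(V_list[[1L]])
  for (i in seq_len(k)) {
    if (!identical(colnames(V_list[[i]]), cols))
      stop("all classes must share the same mark columns")
    if (nrow(V_list[[i]]) < c_per_class[i])
      stop("class '", names(V_list)[i], "' has fewer loci (",
           nrow(V_list[[i]]), ") than its rank ", c_per_class[i])
  }
  fits <- Map(function(V, cc) nmf(V, cc, init = init, l1_H = l1_H,
                                  max_iter = max_iter, tol = tol, seed = seed),
              V_list, c_per_class)
  H <- do.call(rbind, lapply(names(fits), function(cl) {
    Hk <- fits[[cl]]$H
    rownames(Hk) <- paste0(cl, ":", rownames(Hk))
    Hk
  }))
  W <- do.call(rbind, lapply(V_list, function(V) nnls_weights(V, H)))
  rownames(W) <- unlist(lapply(V_list, rownames), use.names = FALSE)
  Vall <- do.call(rbind, V_list)
  partition <- rep(names(V_list), vapply(V_list, nrow, integer(1)))
  structure(list(
    W = W, H = H, rank = nrow(H),
    reconstruction_error = sqrt(sum((Vall - W %*% H)^2)),
    objective_trace = NULL,
    n_iter = sum(vapply(fits, `[[`, integer(1), "n_iter")),
    init_method = init, l1_H = l1_H, tol = tol, max_iter = max_iter,
    mode = "discriminatory",
    class_partition = partition, class_fits = fits
  ), class = "chromcode_nmf")
}

#' Discriminatory-mode code discovery from BAM and BED files
#'
#' Counts and sigmoid-scales the same set of marks at k classes of loci
#' (one BED file per class, class-specific scaling), then runs
#' [discriminatory_nmf()].
#'
#' @param bams BAM paths, one per mark (shared across classes).
#' @param beds Character vector of >= 2 BED paths; names (or file names)
#'   become class labels.
#' @param c_per_class Rank per class (recycled if a single value).
#' @inheritParams absolute_mode
#' @return A `chromcode_nmf` object tagged "discriminatory".
#' @export
discriminatory_mode <- function(bams, beds, c_per_class, labels = NULL,
                                init = "nndsvd", l1_H = 0.1, max_iter = 500L,
                                tol = 1e-4, seed = NULL,
                                filter_dup = FALSE, min_mapq = 0L) {
  if (length(beds) < 2L) stop("discriminatory mode needs >= 2 region classes")
  class_names <- names(beds)
  if (is.null(class_names))
    class_names <- sub("\\.bed$", "", basename(beds))
  V_list <- lapply(beds, function(b) {
    regions <- read_regions(b)
    scale_matrix(build_count_matrix(bams, regions, labels = labels,
                                    filter_dup = filter_dup,
                                    min_mapq = min_mapq))
  })
  names(V_list) <- class_names
  discriminatory_nmf(V_list, c_per_class, init = init, l1_H = l1_H,
                     max_iter = max_iter, tol = tol, seed = seed)
}

#' Differential-mode code discovery from paired BAM files
#'
#' For each mark, windowed counts are computed in both conditions, the two
#' libraries are depth-corrected with median-of-ratios size factors from the
#' pooled window-count matrix, the per-window differences are integrated
#' into per-locus gain and loss scores, and the resulting loci x 2m
#' gain/loss matrix is sigmoid-scaled and factorized. The basis rows are
#' patterns of coordinated mark changes rather than absolute levels.
#'
#' @param bams_a,bams_b BAM paths for conditions A and B; same marks, same
#'   order (replicates should be merged beforehand).
#' @param bed BED path defining the loci.
#' @param c Factorization rank.
#' @param window Window width in bp for the differential integration
#'   (default 100).
#' @param labels Optional mark labels (must coincide between conditions).
#' @inheritParams absolute_mode
#' @return A `chromcode_nmf` object tagged "differential"; `H` has 2m
#'   columns labeled `<mark>.gain` / `<mark>.loss`; per-mark size factors
#'   and gain/loss profiles are attached.
#' @export
differential_mode <- function(bams_a, bams_b, bed, c, window = 100L,
                              labels = NULL, init = "nndsvd", l1_H = 0.1,
                              max_iter = 500L, tol = 1e-4, seed = NULL,
                              filter_dup = FALSE, min_mapq = 0L) {
  if (length(bams_a) != length(bams_b))
    stop("conditions A and B must provide the same marks")
  if (is.null(labels)) {
    la <- sub("\\.bam$", "", basename(bams_a))
    lb <- sub("\\.bam$", "", basename(bams_b))
    if (!identical(la, lb))
      warning("condition file names differ; using condition-A names as mark labels")
    labels <- la
  }
  if (anyDuplicated(labels)) stop("duplicate mark labels")
  regions <- read_regions(bed)
  profiles <- list(); sf_all <- list()
  for (j in seq_along(labels)) {
    wa <- windowed_counts(bams_a[j], regions, window = window,
                          filter_dup = filter_dup, min_mapq = min_mapq)
    wb <- windowed_counts(bams_b[j], regions, window = window,
                          filter_dup = filter_dup, min_mapq = min_mapq)
    K <- cbind(a = unlist(wa, use.names = FALSE),
               b = unlist(wb, use.names = FALSE))
    sf <- size_factors(K)
    profiles[[labels[j]]] <- gain_loss(wa, wb, sf)
    sf_all[[labels[j]]] <- sf
  }
  M <- build_differential_matrix(profiles)
  fit <- nmf(M, c, init = init, l1_H = l1_H, max_iter = max_iter,
             tol = tol, seed = seed)
  fit$regions <- regions
  fit$size_factors <- sf_all
  fit$profiles <- profiles
  .tag_fit(fit, "differential")
}
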