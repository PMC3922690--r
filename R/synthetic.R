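#' Planted sparse-factor benchmark matrix
#'
#' Generates a non-negative loci x marks matrix V = W* H* + noise with known
#' sparse ground truth, emulating the structure the factorization is meant
#' to recover: each planted code loads on at most 3 dominant marks, and each
#' locus superimposes one or two codes. The matrix is clipped at zero and
#' sigmoid-scaled per column (see [scale_matrix()]) so it enters [nmf()]
#' directly. Because the factorization operates in scaled space, the truth
#' record carries, besides the raw factors, `H_scaled`: the planted basis
#' expressed in scaled units (columns divided by their sigmoid scale u),
#' which is the representation recovered codes should be compared against.
#'
#' @param n Number of loci (> c).
#' @param m Number of marks (>= c).
#' @param c Number of planted codes.
#' @param sparsity Probability that a non-dominant basis entry is exactly
#'   zero (the rest receive a moderate background loading, so marks
#'   participate in several codes as they do in real chromatin data); in
#'   [0, 1].
#' @param noise_sd Standard deviation of additive Gaussian noise on W* H*.
#' @param seed Integer seed; the construction is fully reproducible.
#' @return List with `V` (scaled matrix) and `model`, a list holding
#'   `H_true`, `W_true`, `H_scaled`, `u` (per-column sigmoid scales),
#'   `noise_sd` and `seed`.
#' @export
make_planted_matrix <- function(n = 200L, m = 8L, c = 3L, sparsity = 0.65,
                                noise_sd = 0.05, seed = 1L) {
  if (n <= c || m < c) stop("need n > c and m >= c")
  if (sparsity < 0 || sparsity > 1) stop("'sparsity' must be in [0, 1]")
  set.seed(seed)
  H_true <- matrix(0, c, m)
  for (k in seq_len(c)) {
    ndom <- 3L
    # rotate dominant supports so codes are distinguishable
    dom <- ((k - 1L) * 3L + seq_len(ndom) - 1L) %% m + 1L
    H_true[k, dom] <- stats::runif(ndom, 0.6, 1)
    bg <- setdiff(seq_len(m), dom)
    on <- stats::runif(length(bg)) > sparsity
    H_true[k, bg[on]] <- stats::runif(sum(on), 0.05, 0.3)
  }
  # codes activate independently across loci (one primary code plus
  # occasional extras), with heavy-tailed weights so that most entries stay
  # in the near-linear range of the sigmoid
  W_true <- matrix(0, n, c)
  primary <- sample(seq_len(c), n, replace = TRUE)
  W_true[cbind(seq_len(n), primary)] <- stats::rexp(n, rate = 2) + 0.2
  for (k in seq_len(c)) {
    extra <- stats::runif(n) < 0.3 & primary != k
    W_true[extra, k] <- W_true[extra, k] + stats::rexp(sum(extra), rate = 4)
  }
  V0 <- W_true %*% H_true
  if (noise_sd > 0)
    V0 <- V0 + matrix(stats::rnorm(n * m, 0, noise_sd), n, m)
  V0 <- pmax(V0, 0)
  rownames(V0) <- paste0("locus_", seq_len(n))
  colnames(V0) <- paste0("mark_", seq_len(m))
  u <- apply(V0, 2L, stats::quantile, 0.95, names = FALSE)
  u[u == 0] <- 1
  V <- scale_matrix(V0)
  H_scaled <- H_true %*% diag(1 / u, m)
  dimnames(H_scaled) <- list(paste0("code_", seq_len(c)), colnames(V0))
  dimnames(H_true) <- dimnames(H_scaled)
  dimnames(W_true) <- list(rownames(V0), paste0("code_", seq_len(c)))
  list(V = V,
       model = list(H_true = H_true, W_true = W_true, H_scaled = H_scaled,
                    u = u, noise_sd = noise_sd, seed = seed))
}

#' Cosine similarity of matched code pairs
#'
#' Pairs the rows of an estimated basis matrix with a reference basis by
#' minimum-total-Euclidean-cost matching on unit-normalized rows
#' (see [match_codes()]) and returns the cosine similarity of each matched
#' pair, in reference-row order.
#'
#' @param H Estimated basis matrix (or `chromcode_nmf` object).
#' @param H_ref Reference (e.g. planted) basis matrix.
#' @return Numeric vector of cosine similarities, one per matched pair.
#' @export
matched_cosines <- function(H, H_ref) {
  if (inherits(H, "chromcode_nmf")) H <- H$H
  H <- as.matrix(H); H_ref <- as.matrix(H_ref)
  mc <- match_codes(H_ref, H, normalize = "l2")
  vapply(seq_len(nrow(mc$pairs)), function(i) {
    a <- H_ref[mc$pairs$code_a[i], ]
    b <- H[mc$pairs$code_b[i], ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }, numeric(1))
}

#' Two-class benchmark with disjoint planted codes
#'
#' Builds one planted matrix per class such that the dominant mark supports
#' of the two classes' codes are disjoint (class 1 codes load dominantly on
#' the first half of the marks, class 2 codes on the second half), while
#' every code also carries small background loadings on the other half —
#' as real marks carry background signal everywhere, which matters because
#' the per-class sigmoid scaling normalizes each mark column to its own
#' dynamic range. The fixture exercises the discriminatory factorization:
#' the dominant code of a locus should originate from its own class.
#'
#' @param n_per_class Loci per class.
#' @param m Number of marks (must accommodate disjoint supports:
#'   floor(m/2) >= 2 * c_per_class).
#' @param c_per_class Codes per class.
#' @param noise_sd Gaussian noise level.
#' @param seed Integer seed.
#' @param shared If TRUE both classes use the same planted basis (a control
#'   in which class-specific codes are interchangeable and class purity
#'   drops to chance).
#' @return List of two elements (`class1`, `class2`), each with `V` and
#'   `model` as in [make_planted_matrix()].
#' @export
make_two_class_fixture <- function(n_per_class = 150L, m = 8L,
                                   c_per_class = 2L, noise_sd = 0.02,
                                   seed = 1L, shared = FALSE) {
  half <- floor(m / 2)
  ndom <- max(2L, floor(half / c_per_class))
  if (half < 2L * c_per_class)
    stop("m too small for disjoint dominant supports")
  build_class <- function(offset, class_seed) {
    set.seed(class_seed)
    H <- matrix(0, c_per_class, m)
    own <- offset + seq_len(half)
    other <- setdiff(seq_len(m), own)
    for (k in seq_len(c_per_class)) {
      dom <- own[(k - 1L) * ndom + seq_len(ndom)]
      H[k, dom] <- stats::runif(ndom, 0.6, 1)
      bg <- other[stats::runif(length(other)) < 0.5]
      H[k, bg] <- stats::runif(length(bg), 0.05, 0.2)
    }
    W <- matrix(0, n_per_class, c_per_class)
    primary <- rep_len(seq_len(c_per_class), n_per_class)
    W[cbind(seq_len(n_per_class), primary)] <-
      stats::rexp(n_per_class, rate = 2) + 0.2
    V0 <- W %*% H
    if (noise_sd > 0)
      V0 <- V0 + matrix(stats::rnorm(length(V0), 0, noise_sd),
                        n_per_class, m)
    V0 <- pmax(V0, 0)
    colnames(V0) <- paste0("mark_", seq_len(m))
    list(H = H, W = W, V0 = V0)
  }
  s1 <- seed * 2L + 1L
  s2 <- if (shared) s1 else seed * 2L + 2L
  cl1 <- build_class(0L, s1)
  cl2 <- build_class(if (shared) 0L else half, s2)
  wrap <- function(cl, label) {
    rownames(cl$V0) <- paste0(label, "_locus_", seq_len(nrow(cl$V0)))
    u <- apply(cl$V0, 2L, stats::quantile, 0.95, names = FALSE)
    u[u == 0] <- 1
    Vs <- suppressWarnings(scale_matrix(cl$V0))
    Hs <- cl$H %*% diag(1 / u, m)
    colnames(Hs) <- colnames(cl$V0)
    list(V = Vs, model = list(H_true = cl$H, W_true = cl$W, H_scaled = Hs,
                              u = u, noise_sd = noise_sd, seed = seed))
  }
  list(class1 = wrap(cl1, "c1"), class2 = wrap(cl2, "c2"))
}

# Writes 36 bp single-end perfect alignments as a coordinate-sorted,
# indexed BAM. `starts0` are 0-based alignment start positions on chrS.
.write_toy_bam <- function(starts0, out_prefix, contig = "chrS",
                           contig_len = 100000L, read_len = 36L) {
  starts0 <- sort(as.integer(starts0))
  sam <- file.path(paste0(out_prefix, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  recs <- sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  seq_along(starts0), contig, starts0 + 1L, read_len,
                  strrep("A", read_len), strrep("I", read_len))
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Deterministic in-locus read placement: `count` reads fully inside
# [start0, start0 + width), stride chosen so reads never leave the interval.
.place_reads <- function(start0, width, count, read_len = 36L) {
  if (count == 0L) return(integer(0))
  span <- width - read_len
  start0 + ((seq_len(count) - 1L) * 19L) %% (span + 1L)
}

#' Miniature BAM + BED fixtures with hand-constructed coverage
#'
#' Writes sorted, indexed BAM files on a synthetic 100 kb contig ("chrS")
#' with 36 bp single-end reads placed deterministically to realize known
#' per-locus or per-window coverage, plus the matching BED file and a
#' machine-readable truth table. Three scenarios are provided:
#' \describe{
#'   \item{absolute}{24 loci x 3 marks; two planted mark-co-occurrence
#'     patterns (marks 1+2 vs mark 3) with per-locus intensities, so the
#'     absolute pipeline should recover both patterns. Truth: the expected
#'     count of every locus/mark pair.}
#'   \item{differential}{6 loci, one mark; condition B contains every
#'     condition-A read twice, so the size-factor ratio is exactly 2 and
#'     every depth-corrected gain and loss is 0.}
#'   \item{broadened_peak}{a focal locus whose narrow summit peak in A
#'     becomes lower and broader in B (losses at the summit, gains at the
#'     slopes: both scores positive at that locus), next to a stable locus
#'     with identical coverage in both conditions.}
#' }
#'
#' @param scenario One of "absolute", "differential", "broadened_peak".
#' @param out_dir Writable output directory (created if needed).
#' @param seed Unused by the deterministic constructions; kept so all
#'   generators share a seeded interface.
#' @return List with `bams` (named paths; for the paired scenarios nested
#'   lists `a` and `b`), `bed`, `truth` (data.frame), `truth_path`, and
#'   `window` (the window width the truth assumes, where relevant).
#' @export
make_toy_alignments <- function(scenario = c("absolute", "differential",
                                             "broadened_peak"),
                                out_dir, seed = 1L) {
  scenario <- match.arg(scenario)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  bed <- file.path(out_dir, paste0(scenario, ".bed"))

  if (scenario == "absolute") {
    n_loci <- 24L; width <- 1000L
    starts <- 2000L + (seq_len(n_loci) - 1L) * 4000L
    names <- sprintf("L%02d", seq_len(n_loci))
    writeLines(sprintf("chrS\t%d\t%d\t%s\t0\t+", starts, starts + width, names),
               bed)
    intensity <- rep(seq(0.6, 1.5, length.out = n_loci / 2L), 2L)
    patternA <- c(mark1 = 30, mark2 = 24, mark3 = 3)
    patternB <- c(mark1 = 4, mark2 = 3, mark3 = 30)
    pattern_of <- rep(c("A", "B"), each = n_loci / 2L)
    counts <- t(vapply(seq_len(n_loci), function(i) {
      p <- if (pattern_of[i] == "A") patternA else patternB
      as.integer(round(intensity[i] * p))
    }, integer(3)))
    colnames(counts) <- names(patternA)
    bams <- vapply(colnames(counts), function(mk) {
      starts0 <- unlist(lapply(seq_len(n_loci), function(i)
        .place_reads(starts[i], width, counts[i, mk])))
      .write_toy_bam(starts0, file.path(out_dir, mk))
    }, character(1))
    truth <- data.frame(locus = names, pattern = pattern_of, counts,
                        stringsAsFactors = FALSE)
    truth_path <- file.path(out_dir, "absolute.truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(list(bams = bams, bed = bed, truth = truth,
                truth_path = truth_path, window = NA_integer_))
  }

  if (scenario == "differential") {
    n_loci <- 6L; width <- 1000L
    starts <- 10000L + (seq_len(n_loci) - 1L) * 5000L
    names <- sprintf("L%d", seq_len(n_loci))
    writeLines(sprintf("chrS\t%d\t%d\t%s\t0\t+", starts, starts + width, names),
               bed)
    per_locus <- c(10L, 15L, 20L, 25L, 30L, 35L)
    reads_a <- unlist(lapply(seq_len(n_loci), function(i)
      .place_reads(starts[i], width, per_locus[i])))
    bam_a <- .write_toy_bam(reads_a, file.path(out_dir, "mark1.A"))
    bam_b <- .write_toy_bam(rep(reads_a, each = 2L),
                            file.path(out_dir, "mark1.B"))
    truth <- data.frame(locus = names, count_a = per_locus,
                        count_b = 2L * per_locus, sf_ratio = 2,
                        gain = 0, loss = 0, stringsAsFactors = FALSE)
    truth_path <- file.path(out_dir, "differential.truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(list(bams = list(a = c(mark1 = bam_a), b = c(mark1 = bam_b)),
                bed = bed, truth = truth, truth_path = truth_path,
                window = 100L))
  }

  # broadened_peak: window grid of 100 bp over two 1000 bp loci
  width <- 1000L; window <- 100L
  starts <- c(focal = 10000L, stable = 20000L)
  writeLines(sprintf("chrS\t%d\t%d\t%s\t0\t+", starts, starts + width,
                     names(starts)), bed)
  win_counts <- function(spec, locus_start) {
    unlist(lapply(seq_along(spec), function(w) {
      if (spec[w] == 0L) return(integer(0))
      wstart <- locus_start + (w - 1L) * window
      wstart + (seq_len(spec[w]) - 1L) * 2L      # 36 bp reads stay in-window
    }))
  }
  a_focal  <- c(0L, 0L, 0L, 0L, 30L, 30L, 0L, 0L, 0L, 0L)
  b_focal  <- c(0L, 0L, 12L, 12L, 8L, 8L, 12L, 12L, 0L, 0L)
  stable10 <- rep(10L, 10L)
  bam_a <- .write_toy_bam(c(win_counts(a_focal, starts["focal"]),
                            win_counts(stable10, starts["stable"])),
                          file.path(out_dir, "mark1.A"))
  bam_b <- .write_toy_bam(c(win_counts(b_focal, starts["focal"]),
                            win_counts(stable10, starts["stable"])),
                          file.path(out_dir, "mark1.B"))
  truth <- data.frame(
    locus = c("focal", "stable"),
    windows_a = c(paste(a_focal, collapse = ","),
                  paste(stable10, collapse = ",")),
    windows_b = c(paste(b_focal, collapse = ","),
                  paste(stable10, collapse = ",")),
    gain_positive = c(TRUE, FALSE), loss_positive = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "broadened_peak.truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bams = list(a = c(mark1 = bam_a), b = c(mark1 = bam_b)),
       bed = bed, truth = truth, truth_path = truth_path, window = window)
}
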