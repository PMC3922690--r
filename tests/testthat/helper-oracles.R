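# Shared fixtures and independent oracles used across test files.

write_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# Brute-force read counting: scan every BAM record, compute its reference
# span from the CIGAR by hand, and test 0-based half-open interval overlap
# against every locus. Independent of the countOverlaps path.
brute_force_counts <- function(bam, starts0, ends0) {
  b <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("pos", "cigar", "flag")))[[1]]
  keep <- !bitwAnd(b$flag, 4L) & !bitwAnd(b$flag, 256L) &
    !bitwAnd(b$flag, 2048L) & !bitwAnd(b$flag, 512L)
  ref_width <- vapply(b$cigar[keep], function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(o) {
      len <- as.integer(sub("[A-Z=]$", "", o))
      if (grepl("[MDN=X]$", o)) len else 0L
    }, integer(1)))
  }, integer(1))
  rstart0 <- b$pos[keep] - 1L
  rend0 <- rstart0 + ref_width
  vapply(seq_along(starts0), function(i)
    sum(rstart0 < ends0[i] & rend0 > starts0[i]), integer(1))
}

# Exhaustive minimum-cost perfect matching over all permutations (c <= 6).
brute_force_matching <- function(H_a, H_b) {
  cc <- nrow(H_a)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  costs <- vapply(perms(seq_len(cc)), function(p)
    sum(vapply(seq_len(cc), function(i)
      sqrt(sum((H_a[i, ] - H_b[p[i], ])^2)), numeric(1))), numeric(1))
  min(costs)
}

median_abs_spearman <- function(M) {
  R <- abs(stats::cor(M, method = "spearman"))
  stats::median(R[upper.tri(R)])
}

# One shared noisy planted benchmark, reused where only a fixture is needed.
bench <- make_planted_matrix(n = 200L, m = 8L, c = 3L, noise_sd = 0.05,
                             seed = 1L)
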