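test_that("non-negative least squares recovers exact weights and edge cases", {
  H <- diag(3)
  dimnames(H) <- NULL
  V <- matrix(runif(12), 4, 3)
  expect_equal(unname(nnls_weights(V, H)), unname(V), tolerance = 1e-10)

  set.seed(3)
  Ws <- matrix(rexp(20), 10, 2)
  Hs <- rbind(c(1, 0.2, 0), c(0, 0.3, 1))      # full row rank
  expect_equal(unname(nnls_weights(Ws %*% Hs, Hs)), unname(Ws),
               tolerance = 1e-6)

  V0 <- rbind(c(0, 0, 0), c(1, 2, 3))
  expect_equal(nnls_weights(V0, Hs)[1, ], c(0, 0), ignore_attr = TRUE)

  Hz <- rbind(Hs, 0)
  expect_warning(Wz <- nnls_weights(Ws %*% Hs, Hz), "all-zero row")
  expect_true(all(Wz[, 3] == 0))
})

test_that("discriminatory mode with a single class reduces to the absolute fit", {
  fit_abs <- nmf(bench$V, 3, seed = 1)
  fit_dis <- discriminatory_nmf(list(all = bench$V), 3, seed = 1)
  expect_equal(unname(fit_dis$H), unname(fit_abs$H), tolerance = 1e-12)
  expect_equal(rownames(fit_dis$H), paste0("all:code_", 1:3))
  # W re-derived by NNLS agrees with the optimizer's W within its resolution
  expect_lt(max(abs(fit_dis$W - fit_abs$W)), 0.01)
})

test_that("class-specific codes capture their own loci in the two-class benchmark", {
  tc <- make_two_class_fixture(seed = 1)
  fit <- discriminatory_nmf(list(c1 = tc$class1$V, c2 = tc$class2$V), 2,
                            seed = 1)
  expect_equal(nrow(fit$H), 4L)
  asg <- assign_codes(fit)
  own <- ifelse(grepl("^c1_", asg$locus), "c1", "c2")
  origin <- sub(":.*", "", asg$code_label)
  purity <- mean(origin == own, na.rm = TRUE)
  expect_gte(purity, 0.9)
})

test_that("interchangeable codes emerge when both classes share one model", {
  tc <- make_two_class_fixture(seed = 1, shared = TRUE)
  V1 <- tc$class1$V; V2 <- tc$class2$V
  f1 <- nmf(V1, 2, seed = 1)
  f2 <- nmf(V2, 2, seed = 1)
  # cross-class NNLS residuals comparable to within-class residuals
  resid <- function(V, H) {
    W <- suppressWarnings(nnls_weights(V, H))
    sqrt(sum((V - W %*% H)^2))
  }
  ratio <- resid(V1, f2$H) / resid(V1, f1$H)
  expect_lt(ratio, 1.5)

  fit <- discriminatory_nmf(list(c1 = V1, c2 = V2), 2, seed = 1)
  asg <- assign_codes(fit)
  purity <- mean(sub(":.*", "", asg$code_label) ==
                   ifelse(grepl("^c1_", asg$locus), "c1", "c2"),
                 na.rm = TRUE)
  expect_lt(abs(purity - 0.5), 0.15)
})

test_that("a class smaller than its rank is rejected", {
  expect_error(discriminatory_nmf(list(a = bench$V, b = bench$V[1:2, ]), 3),
               "fewer loci")
})

test_that("coordinated gain/loss patterns are recovered in differential space", {
  set.seed(21)
  n <- 100L
  intensity <- rexp(n, 2) + 0.2
  grp1 <- seq_len(n) <= 50L
  # pattern 1: mark1 gains exactly where mark2 loses; pattern 2: the reverse
  prof <- function(gain, loss, loci)
    list(summary = data.frame(locus = loci, gain = gain, loss = loss))
  loci <- paste0("L", seq_len(n))
  profiles <- list(
    mark1 = prof(ifelse(grp1, intensity, 0), ifelse(grp1, 0, intensity), loci),
    mark2 = prof(ifelse(grp1, 0, intensity), ifelse(grp1, intensity, 0), loci))
  M <- suppressWarnings(build_differential_matrix(profiles))
  expect_equal(ncol(M), 4L)
  fit <- nmf(M, 2, seed = 1)
  planted <- rbind(c(1, 0, 0, 1),    # mark1.gain + mark2.loss
                   c(0, 1, 1, 0))
  expect_gte(min(matched_cosines(fit, planted)), 0.9)
})

test_that("single-signed loci put all weight on one of gain or loss", {
  gl <- gain_loss(list(L = c(1, 1, 2)), list(L = c(5, 3, 2.5)),
                  c(a = 1, b = 1))
  expect_gt(gl$summary$gain, 0)
  expect_equal(gl$summary$loss, 0)
})

test_that("the differential pipeline runs end-to-end on the broadened peak", {
  td <- file.path(tempdir(), "modes_bp")
  fx <- make_toy_alignments("broadened_peak", td)
  fit <- suppressWarnings(differential_mode(
    fx$bams$a, fx$bams$b, fx$bed, c = 1, window = fx$window,
    labels = "mark1", seed = 1))
  expect_equal(fit$mode, "differential")
  expect_equal(colnames(fit$H), c("mark1.gain", "mark1.loss"))
  s <- fit$profiles$mark1$summary
  expect_gt(s$gain[s$locus == "focal"], 0)
  expect_gt(s$loss[s$locus == "focal"], 0)
  expect_equal(s$gain[s$locus == "stable"], 0, tolerance = 1e-10)
})

test_that("identical conditions collapse to a degenerate all-zero matrix", {
  td <- file.path(tempdir(), "modes_ident")
  fx <- make_toy_alignments("differential", td)
  expect_error(
    suppressWarnings(differential_mode(fx$bams$a, fx$bams$b, fx$bed,
                                       c = 1, window = fx$window,
                                       labels = "mark1")),
    "all zero")
})

test_that("mismatched mark sets between conditions are refused", {
  expect_error(differential_mode(c("a.bam", "b.bam"), "a.bam", "x.bed", 2),
               "same marks")
})
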