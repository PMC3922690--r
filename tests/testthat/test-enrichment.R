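test_that("the random-set z-statistic uses the exact finite-population moments", {
  set.seed(5)
  scores <- setNames(rnorm(20), paste0("g", 1:20))
  members <- paste0("g", c(2, 5, 9, 11, 17))
  res <- random_set_test(scores, members)
  N <- 20; m <- 5
  mu <- mean(scores)
  sigma2 <- mean((scores - mu)^2)
  z_hand <- (mean(scores[members]) - mu) /
    sqrt(sigma2 / m * (N - m) / (N - 1))
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, pnorm(z_hand, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$m, 5L)

  # genes absent from the score vector do not count towards m
  expect_equal(random_set_test(scores, c(members, "absent"))$m, 5L)
})

test_that("degenerate random-set inputs are handled as specified", {
  flat <- setNames(rep(2, 10), paste0("g", 1:10))
  res <- random_set_test(flat, paste0("g", 1:3))
  expect_true(is.na(res$z))
  expect_equal(res$p, 1)

  scores <- setNames(rnorm(10), paste0("g", 1:10))
  expect_equal(random_set_test(scores, "nope")$m, 0L)
  expect_error(random_set_test(scores, paste0("g", 1:10)), "m = N")

  # m = N - 1: tiny variance, z keeps the sign of the mean shift
  res2 <- random_set_test(scores, paste0("g", 1:9))
  expect_equal(sign(res2$z), sign(res2$xbar - mean(scores)))
})

test_that("the analytic p agrees with a permutation oracle", {
  # symmetric score population: zero skewness, so the normal reference for
  # the sampled mean is accurate well within Monte-Carlo resolution
  set.seed(17)
  v <- rnorm(25)
  scores <- setNames(c(v, -v), paste0("g", 1:50))
  ord <- names(sort(scores, decreasing = TRUE))
  members <- ord[round(seq(2, 48, length.out = 20))]
  res <- random_set_test(scores, members)
  draws <- 5e4
  emp <- mean(replicate(draws, mean(sample(scores, 20))) >= res$xbar)
  se <- sqrt(emp * (1 - emp) / draws)
  expect_lt(abs(res$p - emp), 3 * se + 1e-12)
})

test_that("BH correction reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_false(is.unsorted(q[order(p)]))   # step-up monotonicity
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment ranks a planted top-score set first", {
  set.seed(23)
  n <- 100L
  genes <- paste0("g", seq_len(n))
  scores <- sort(rexp(n), decreasing = TRUE)
  W <- matrix(scores, ncol = 1, dimnames = list(genes, "code_1"))
  sets <- c(list(top = genes[1:10]),
            lapply(1:20, function(i) sample(genes, 10)))
  names(sets)[-1] <- paste0("rand", 1:20)
  tab <- enrich_all(W, sets)
  expect_equal(tab$set[1], "top")
  expect_lt(tab$q[1], 0.05)
  expect_equal(nrow(tab), 21L)

  single <- enrich_all(W, sets["top"])
  expect_equal(nrow(single), 1L)
})

test_that("loci mapping to one gene are averaged and unmapped sets skipped", {
  W <- matrix(c(1, 3, 10, 6), ncol = 1,
              dimnames = list(c("pk1", "pk2", "pk3", "pk4"), "code_1"))
  gmap <- c(pk1 = "geneA", pk2 = "geneA", pk3 = "geneB", pk4 = "geneC")
  sets <- list(s1 = c("geneB"), s2 = c("unknown1", "unknown2"))
  tab <- enrich_all(W, sets, gene_map = gmap)
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "skipped_sets"), "s2")
  # geneA's score is the average of pk1 and pk2: population of (2, 10, 6)
  mu <- mean(c(2, 10, 6)); s2 <- mean((c(2, 10, 6) - mu)^2)
  z_hand <- (10 - mu) / sqrt(s2 / 1 * (3 - 1) / (3 - 1))
  expect_equal(tab$z, z_hand, tolerance = 1e-12)
})

test_that("GMT collections round-trip through the reader", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg9"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g2", "g9"))
  empty <- tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_error(read_gmt(empty), "empty")
})
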