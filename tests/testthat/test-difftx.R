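test_that("median-of-ratios size factors behave canonically", {
  m <- matrix(rpois(200, 50) + 1, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # permuting sample order permutes the factors
  expect_equal(size_factors(m2[, c("b", "a")]),
               size_factors(m2)[c("b", "a")])
  # scaling one sample by c multiplies its factor accordingly (up to the
  # change of the geometric-mean reference)
  m3 <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  sf3 <- size_factors(cbind(m3[, 1:2], c = 3 * m3[, 3]))
  expect_equal(unname(sf3[3] / sf3[1]), 3)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- matrix(rnbinom(3000, mu = 80, size = 10) + 1, ncol = 6)
  colnames(m) <- paste0("s", 1:6)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("identical groups give a null Wald result", {
  m <- matrix(rep(c(10, 20, 30, 40), each = 4), ncol = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  design <- c(s1 = "ctl", s2 = "ctl", s3 = "trt", s4 = "trt")
  res <- nb_wald_test(m, design, "trt", "ctl")
  expect_equal(res$log2FC, rep(0, 4))
  expect_true(all(res$p >= 0.999))
})

test_that("all-zero genes are flagged with p = 1", {
  m <- rbind(g1 = c(0, 0, 0, 0), g2 = c(50, 60, 100, 120),
             g3 = c(30, 35, 30, 28))
  colnames(m) <- paste0("s", 1:4)
  design <- stats::setNames(c("c", "c", "t", "t"), colnames(m))
  res <- nb_wald_test(m, design, "t", "c")
  expect_true(res$allzero[1])
  expect_equal(res$p[1], 1)
  expect_equal(res$log2FC[1], 0)
})

test_that("the null type-I error is calibrated near the nominal level", {
  set.seed(7)
  n <- 3000
  mu <- stats::rlnorm(n, log(300), 1)
  m <- vapply(1:4, function(i) stats::rnbinom(n, mu = mu, size = 20),
              numeric(n))
  dimnames(m) <- list(paste0("g", 1:n), paste0("s", 1:4))
  design <- stats::setNames(c("c", "c", "t", "t"), colnames(m))
  res <- nb_wald_test(m, design, "t", "c")
  expect_gt(mean(res$p < 0.05), 0.025)
  expect_lt(mean(res$p < 0.05), 0.075)
})

test_that("moderate fold-changes are detected against a null background", {
  # 2-vs-2, NB dispersion 0.05, mean 500, true FC 1.6 on a tenth of genes:
  # close to half of the effect genes clear nominal p < 0.05 (the Wald z
  # for this effect is ~2), and BH at 0.05 retains a conservative subset.
  set.seed(13)
  n <- 4000
  eff <- seq_len(n) <= n / 10
  mu0 <- rep(500, n)
  muT <- mu0 * ifelse(eff, 1.6, 1)
  m <- cbind(c1 = stats::rnbinom(n, mu = mu0, size = 20),
             c2 = stats::rnbinom(n, mu = mu0, size = 20),
             t1 = stats::rnbinom(n, mu = muT, size = 20),
             t2 = stats::rnbinom(n, mu = muT, size = 20))
  rownames(m) <- paste0("g", 1:n)
  design <- stats::setNames(c("c", "c", "t", "t"), colnames(m))
  res <- nb_wald_test(m, design, "t", "c")
  expect_gt(mean(res$p[eff] < 0.05), 0.35)
  expect_gt(mean(res$log2FC[eff]), 0.4)
  # the null background stays calibrated in the same run
  expect_lt(mean(res$p[!eff] < 0.05), 0.09)
})

test_that("BH adjustment matches analytic and brute-force oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:25) {
    p <- round(stats::runif(sample(1:40, 1)), 3)  # rounding forces ties
    expect_equal(bh_adjust(p), bh_bruteforce(p))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("DTG and DEG classification is boundary-inclusive as printed", {
  expect_equal(classify_dtg(log2(1.30), 0.01), "UP")
  expect_equal(classify_dtg(log2(1.25), 0.05), "UP")
  expect_equal(classify_dtg(log2(0.79), 0.04), "DOWN")
  expect_equal(classify_dtg(log2(0.8), 0.05), "DOWN")
  expect_equal(classify_dtg(log2(2.0), 0.2), "NS")
  expect_equal(classify_dtg(log2(1.24), 0.001), "NS")
  expect_equal(classify_deg(1.2, 1e-4), "UP")
  expect_equal(classify_deg(-1.0, 1e-4), "DOWN")
  expect_equal(classify_deg(0.9, 1e-9), "NS")
  expect_equal(classify_deg(1.5, 0.002), "NS")
  # pure threshold functions: permutation invariant
  l2 <- c(1.3, -2, 0.1); pa <- c(1e-4, 1e-5, 0.5)
  perm <- c(3, 1, 2)
  expect_equal(classify_deg(l2, pa)[perm], classify_deg(l2[perm], pa[perm]))
})

test_that("MA tables report log2 base mean against log2 fold-change", {
  res <- data.frame(gene_id = c("a", "b"), baseMean = c(256, 4),
                    log2FC = c(1, -2), class = c("UP", "NS"))
  ma <- ma_table(res)
  expect_equal(ma$a, c(8, 2))
  expect_equal(ma$m, c(1, -2))
  expect_equal(ma$class, c("UP", "NS"))
  expect_equal(nrow(ma_table(res[0, ])), 0L)
})

test_that("length summaries reproduce type-7 boxplot statistics", {
  s <- length_summary(c(1, 2, 3, 4, 5), rep("UP", 5))
  expect_equal(s$q1, 2); expect_equal(s$median, 3); expect_equal(s$q3, 4)
  expect_equal(s$whisker_low, 1); expect_equal(s$whisker_high, 5)
  expect_length(s$outliers[[1]], 0L)
  sc <- length_summary(rep(7, 4), rep("DOWN", 4))
  expect_equal(sc$q1, sc$q3)
  expect_length(sc$outliers[[1]], 0L)
  # hand oracle: Q3 + 1.5 IQR = 4 + 3 = 7 < 100
  so <- length_summary(c(1, 2, 3, 4, 100), rep("UP", 5))
  expect_equal(so$outliers[[1]], 100)
  expect_equal(so$whisker_high, 4)
  two <- length_summary(c(1, 2, 3, 10, 20, 30), rep(c("UP", "DOWN"), each = 3))
  expect_equal(two$class, c("UP", "DOWN"))
  expect_equal(two$n, c(3L, 3L))
})
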