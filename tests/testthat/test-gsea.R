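test_that("ranked lists order by descending score with id tie-break", {
  rl <- ranked_list(c(b = 1, a = 1, c = 5))
  expect_equal(rl$gene, c("c", "a", "b"))
  expect_error(ranked_list(c(a = 1, a = 2)), "duplicate")
})

test_that("a single top hit gives the maximal unweighted ES", {
  rl <- ranked_list(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  expect_equal(enrichment_score(rl, "g1", weight_p = 0), 1)
  expect_error(enrichment_score(rl, "absent"), "intersect")
  expect_error(enrichment_score(rl, c("g1", "g2", "g3", "g4")), "whole")
})

test_that("ES is antisymmetric under score negation", {
  set.seed(5)
  for (i in 1:20) {
    sc <- stats::setNames(stats::rnorm(30), sprintf("g%02d", 1:30))
    set <- sample(names(sc), 6)
    es1 <- enrichment_score(ranked_list(sc), set)
    es2 <- enrichment_score(ranked_list(-sc), set)
    expect_equal(es2, -es1, tolerance = 1e-12)
  }
})

test_that("ES equals the brute-force running-sum oracle", {
  sc <- c(4, 3, 2, 1, -1, -2, -3, -4)
  names(sc) <- paste0("g", 1:8)
  rl <- ranked_list(sc)
  set <- c("g1", "g2")
  expect_equal(enrichment_score(rl, set, weight_p = 1),
               es_bruteforce(rl$score, rl$gene, set, 1))
  set.seed(23)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    sc <- stats::setNames(round(stats::rnorm(n), 2), sprintf("r%03d", 1:n))
    set <- sample(names(sc), sample(2:(n - 2), 1))
    p_w <- sample(c(0, 1, 1.5), 1)
    rl <- ranked_list(sc)
    expect_equal(enrichment_score(rl, set, weight_p = p_w),
                 es_bruteforce(rl$score, rl$gene, set, p_w),
                 tolerance = 1e-12)
  }
  # ES always bounded in [-1, 1]
  set.seed(29)
  for (i in 1:50) {
    sc <- stats::setNames(stats::rcauchy(25), sprintf("c%02d", 1:25))
    set <- sample(names(sc), 5)
    es <- enrichment_score(ranked_list(sc), set)
    expect_gte(es, -1); expect_lte(es, 1)
  }
})

test_that("ES matches the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(37)
  for (i in 1:10) {
    sc <- stats::setNames(stats::rnorm(40), sprintf("f%02d", 1:40))
    rl <- ranked_list(sc)
    set <- sample(names(sc), 8)
    stats_vec <- stats::setNames(rl$score, rl$gene)
    expect_equal(enrichment_score(rl, set),
                 fgsea::calcGseaStat(stats_vec,
                                     which(rl$gene %in% set)),
                 tolerance = 1e-9)
  }
})

test_that("nominal p equals exhaustive enumeration on tiny universes", {
  sc <- c(4, 3, 2, 1, -1, -2, -3, -4)
  names(sc) <- paste0("g", 1:8)
  rl <- ranked_list(sc)
  res <- gsea_preranked(rl, list(top = c("g1", "g2"), mid = c("g4", "g5")),
                        nperm = 100, seed = 1)
  expect_true(all(res$exhaustive))
  # oracle: enumerate all C(8,2) = 28 same-size sets independently
  combs <- combn(names(sc), 2)
  null_es <- apply(combs, 2, function(s) es_bruteforce(rl$score, rl$gene, s, 1))
  for (i in seq_len(nrow(res))) {
    es <- res$es[i]
    expected_p <- if (es >= 0) mean(null_es[null_es >= 0] >= es)
                  else mean(null_es[null_es < 0] <= es)
    expect_equal(res$p[i], expected_p)
  }
})

test_that("permutation results are reproducible and sign-consistent", {
  set.seed(41)
  sc <- stats::setNames(stats::rnorm(100), sprintf("g%03d", 1:100))
  rl <- ranked_list(sc)
  coll <- list(s1 = sample(names(sc), 12), s2 = sample(names(sc), 20))
  r1 <- gsea_preranked(rl, coll, nperm = 300, seed = 9)
  r2 <- gsea_preranked(rl, coll, nperm = 300, seed = 9)
  expect_equal(r1, r2)
  expect_equal(sign(r1$nes), sign(r1$es))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
  # sets outside the universe are skipped with a message
  expect_message(r3 <- gsea_preranked(rl, c(coll, list(bad = "zzz")),
                                      nperm = 300, seed = 9),
                 "skipping")
  expect_equal(nrow(r3), 2L)
})

test_that("a planted top set reaches low q while a random set does not", {
  set.seed(2)
  scores <- stats::rnorm(200)
  names(scores) <- sprintf("x%03d", 1:200)
  scores[1:15] <- scores[1:15] + 3
  rl <- ranked_list(scores)
  coll <- list(planted = sprintf("x%03d", 1:15),
               rand = sprintf("x%03d", 100:114))
  res <- gsea_preranked(rl, coll, nperm = 1000, seed = 7)
  expect_lte(res$q[res$set == "planted"], 0.05)
  expect_gt(res$q[res$set == "rand"], 0.2)
  expect_gt(res$nes[res$set == "planted"], 1.5)
})

test_that("score-free rankings give near-uniform nominal p", {
  # all scores of equal magnitude, unweighted statistic: every set is its
  # own null, so nominal p over many random sets is ~uniform and q ~ 1
  set.seed(3)
  sc <- stats::setNames(rep(c(1, -1), each = 30), sprintf("u%02d", 1:60))
  rl <- ranked_list(sc)
  coll <- lapply(1:40, function(i) sample(names(sc), 8))
  names(coll) <- paste0("s", 1:40)
  res <- gsea_preranked(rl, coll, weight_p = 0, nperm = 400, seed = 11)
  expect_gt(mean(res$p), 0.25)
  expect_gt(stats::median(res$q, na.rm = TRUE), 0.5)
})
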