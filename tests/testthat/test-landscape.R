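# Landscape summaries, association testing, BH correction, network
# learning, gene clustering.

test_that("additional-mutation distribution matches a brute-force tally", {
  set.seed(5)
  v <- make_variant(sample(sprintf("P%02d", 1:10), 18, TRUE),
                    sample(c("TET2", "ASXL1", "DNMT3A"), 18, TRUE),
                    vaf = runif(18, 2, 50))
  pats <- sprintf("P%02d", 1:10)
  mm <- build_mutation_matrix(v, pats)
  s <- summarize_landscape(mm, v)
  counts <- table(factor(v$patient_id, levels = pats))
  d <- s$n_additional_distribution
  expect_equal(d$count[d$n_additional == "0"], sum(counts == 0))
  expect_equal(d$count[d$n_additional == "1"], sum(counts == 1))
  expect_equal(d$count[d$n_additional == ">=1"], sum(counts >= 1))
  expect_equal(d$count[d$n_additional == ">=2"], sum(counts >= 2))
})

test_that("summaries of an empty cohort are all zero", {
  mm <- build_mutation_matrix(make_variant(character(0), character(0)),
                              character(0))
  s <- summarize_landscape(mm)
  expect_equal(s$n_patients, 0)
  expect_true(all(s$n_additional_distribution$count == 0))
})

test_that("isolated-mutation fractions split-gene categories by gene", {
  # P1 has TET2 truncating + TET2 missense only: isolated for TET2
  v <- rbind(make_variant("P1", "TET2", effect = "nonsense"),
             make_variant("P1", "TET2", effect = "missense"),
             make_variant("P2", "ASXL1", effect = "nonsense"),
             make_variant("P2", "TET2", effect = "missense"))
  mm <- build_mutation_matrix(v, c("P1", "P2", "P3"))
  s <- summarize_landscape(mm, v)
  iso <- s$isolated
  expect_equal(iso$n_isolated[iso$gene == "TET2"], 1L)
  expect_equal(iso$n_isolated[iso$gene == "ASXL1"], 0L)
  expect_equal(s$multi_variant$n_patients_multi[s$multi_variant$gene == "TET2"], 1L)
})

test_that("exact association p-values equal hypergeometric enumeration", {
  # the canonical diagonal table
  b <- data.frame(a = rep(c(1, 0), each = 5), b = rep(c(1, 0), each = 5))
  res <- pairwise_association(binary = b)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(res$direction, "positive")

  # random 2x2 tables up to n = 30
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- pairwise_association(binary = data.frame(x = x, y = y))
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    expect_equal(res$p_value, oracle_fisher_p(tab), tolerance = 1e-9)
  }
})

test_that("degenerate association inputs are flagged, not fatal", {
  b <- data.frame(const = rep(0, 8), var = rep(c(0, 1), 4))
  cont <- data.frame(z = rnorm(8))
  res <- pairwise_association(binary = b, continuous = cont)
  degen <- res[res$feature_a == "const" & res$feature_b == "var", ]
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_true(is.na(degen$estimate))

  # identical continuous values in the two groups -> p = 1
  b2 <- data.frame(g = rep(c(0, 1), each = 4))
  c2 <- data.frame(v = rep(2.5, 8))
  res2 <- pairwise_association(binary = b2, continuous = c2)
  expect_equal(res2$p_value, 1)
})

test_that("binary-continuous tests report the direction of the median shift", {
  b <- data.frame(g = rep(c(0, 1), each = 10))
  cont <- data.frame(v = c(rnorm(10, 0), rnorm(10, 5)))
  res <- pairwise_association(binary = b, continuous = cont)
  expect_equal(res$direction, "positive")
  expect_lt(res$p_value, 0.05)
  expect_true(res$reported)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")

  set.seed(8)
  for (rep in 1:10) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # sorted-order monotone
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # BH rejections are a superset of Bonferroni rejections
    alpha <- 0.1
    expect_true(all(which(p.adjust(p, "bonferroni") <= alpha) %in%
                      which(q <= alpha)))
  }
})

test_that("network learning recovers simple dependence structure", {
  set.seed(2)
  n <- 2000
  A <- rbinom(n, 1, 0.3)
  B <- ifelse(A == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.05))
  C <- rbinom(n, 1, 0.3)
  net <- learn_network(cbind(A = A, B = B, C = C), min_patients = 1,
                       n_boot = 10, seed = 5)
  skel <- net$adjacency + t(net$adjacency)
  expect_equal(skel["A", "B"], 1L)
  expect_equal(skel["A", "C"] + skel["B", "C"], 0L)

  # three independent coins: empty structure
  m2 <- cbind(A = rbinom(n, 1, 0.3), B = rbinom(n, 1, 0.3),
              C = rbinom(n, 1, 0.3))
  net2 <- learn_network(m2, min_patients = 1, n_boot = 5, seed = 5)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(net2$score, oracle_best_dag_score(m2), tolerance = 1e-8)
})

test_that("hill-climbing attains the exhaustive-search BIC on 3 nodes", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 300
    A <- rbinom(n, 1, runif(1, 0.2, 0.8))
    B <- ifelse(A == 1, rbinom(n, 1, runif(1)), rbinom(n, 1, runif(1)))
    C <- ifelse(B == 1, rbinom(n, 1, runif(1)), rbinom(n, 1, runif(1)))
    m <- cbind(A = A, B = B, C = C)
    if (any(colSums(m) == 0) || any(colSums(m) == n)) next
    net <- learn_network(m, min_patients = 0, n_boot = 1, seed = rep)
    expect_equal(net$score, oracle_best_dag_score(m), tolerance = 1e-8)
    # never below the empty graph
    empty <- oracle_bic_score(m, matrix(0L, 3, 3))
    expect_gte(net$score, empty - 1e-8)
  }
})

test_that("network learning is reproducible and warns on tiny inputs", {
  set.seed(3)
  m <- matrix(rbinom(600, 1, 0.4), ncol = 4,
              dimnames = list(NULL, c("W", "X", "Y", "Z")))
  a <- learn_network(m, min_patients = 1, n_boot = 25, seed = 99)
  b <- learn_network(m, min_patients = 1, n_boot = 25, seed = 99)
  expect_identical(a$edges, b$edges)
  expect_identical(a$skeleton_confidence, b$skeleton_confidence)
  expect_true(all(a$skeleton_confidence >= 0 & a$skeleton_confidence <= 1))

  expect_warning(one <- learn_network(m[, 1, drop = FALSE], min_patients = 1,
                                      n_boot = 5, seed = 1),
                 "fewer than 2")
  expect_equal(nrow(one$edges), 0)
})

test_that("gene clustering merges duplicates first and cuts blocks apart", {
  set.seed(12)
  base1 <- runif(30, 0, 50); base2 <- runif(30, 0, 50)
  m <- cbind(A = base1, B = base1 + rnorm(30, 0, 0.5),
             C = base2, D = base2 + rnorm(30, 0, 0.5))
  cl <- cluster_genes(m, k = 2)
  expect_equal(cl$clusters[["A"]], cl$clusters[["B"]])
  expect_equal(cl$clusters[["C"]], cl$clusters[["D"]])
  expect_false(cl$clusters[["A"]] == cl$clusters[["C"]])

  # exact duplicates merge at distance 0
  m2 <- cbind(A = base1, B = base1, C = base2)
  cl2 <- cluster_genes(m2)
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)

  # two categories: a single merge
  cl3 <- cluster_genes(m[, 1:2])
  expect_equal(length(cl3$hclust$height), 1)

  # constant column flagged at distance 1
  m4 <- cbind(A = base1, B = base1, K = rep(3, 30))
  cl4 <- cluster_genes(m4)
  expect_equal(cl4$degenerate, "K")
  expect_equal(max(cl4$hclust$height), 1)
})

test_that("CNV summary computes per-region and non-9p fractions", {
  cnv <- data.frame(patient_id = c("P1", "P2", "P3", "P3"),
                    region = c("9p", "9p", "20q", "9p"),
                    kind = c("UPD", "UPD", "loss", "UPD"))
  s <- summarize_cnv(cnv, sprintf("P%d", 1:10))
  expect_equal(s$count[s$region == "9p"], 3)
  expect_equal(s$count[s$region == "any_non9"], 1)
  expect_equal(s$pct[s$region == "any_non9"], 10)
})
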