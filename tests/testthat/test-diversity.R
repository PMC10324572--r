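test_that("Shannon index and richness match closed forms and bounds", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(observed_richness(c(10, 10, 10, 10)), 4)
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(observed_richness(c(7, 0, 0)), 1)
  q <- c(5, 3, 2) / 10
  expect_equal(shannon(c(5, 3, 2)), -sum(q * log(q)))  # approx 1.0297
  expect_equal(shannon(c(5, 3, 2), base = 2), -sum(q * log2(q)))
  expect_error(shannon(c(0, 0)), "all-zero")
  # 0 <= H <= log(richness), maximised by uniform composition
  for (s in 1:20) {
    x <- withr::with_seed(s, rpois(15, 3))
    if (sum(x) == 0) next
    expect_gte(shannon(x), 0)
    expect_lte(shannon(x), log(observed_richness(x)) + 1e-12)
  }
  tab <- alpha_diversity(toy_cm())
  expect_equal(tab$richness, c(2L, 3L))
})

test_that("Bray-Curtis matches the hand formula and its bounds", {
  a <- c(6, 4, 0); b <- c(0, 4, 6)
  cm <- community_matrix(matrix(c(a, b), 3, 2,
                                dimnames = list(paste0("t", 1:3), c("A", "B"))))
  d <- as.matrix(bray_curtis(cm))
  expect_equal(d["A", "B"], sum(abs(a - b)) / sum(a + b))  # 12/20
  expect_equal(d["A", "B"], 0.6)
  same <- community_matrix(matrix(c(3L, 1L, 3L, 1L), 2, 2,
                                  dimnames = list(c("x", "y"), c("A", "B"))))
  expect_equal(as.matrix(bray_curtis(same))["A", "B"], 0)
  disj <- community_matrix(matrix(c(5L, 0L, 0L, 7L), 2, 2,
                                  dimnames = list(c("x", "y"), c("A", "B"))))
  expect_equal(as.matrix(bray_curtis(disj))["A", "B"], 1)
  dm <- as.matrix(bray_curtis(random_cm(12, 6, seed = 2)))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("UPGMA reproduces hand-computed merge heights and keeps the leaf set", {
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  tr2 <- upgma(d2)
  expect_setequal(tr2$tip.label, c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(1.5, 1.5))  # single node at height d/2

  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(stats::as.dist(m))
  expect_equal(sort(unname(ape::branching.times(tr3))), c(1, 4))
  expect_true(ape::is.ultrametric(tr3))
  expect_true(grepl("\\(", upgma_newick(stats::as.dist(m))))
  expect_setequal(ape::read.tree(text = upgma_newick(stats::as.dist(m)))$tip.label,
                  c("A", "B", "C"))
})

test_that("ANOSIM matches its exhaustive permutation distribution and vegan", {
  # 6 samples, two tight clusters
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.3), ncol = 1)
  rownames(x) <- paste0("s", 1:6)
  dm <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(dm, g, n_permutations = 2000, seed = 1)
  expect_equal(res$r, 1)  # all between > all within

  # exhaustive oracle over all C(6,3) = 20 label assignments
  rk <- rank(as.numeric(dm))
  M <- length(rk)
  pairs <- t(combn(6, 2))
  r_of <- function(lab) {
    w <- lab[pairs[, 1]] == lab[pairs[, 2]]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  combos <- combn(6, 3)
  r_all <- apply(combos, 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"; r_of(lab)
  })
  p_exact <- mean(r_all >= res$r)
  expect_lt(abs(res$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1e-3)

  # agreement with vegan on a richer data set
  cm <- random_cm(15, 10, seed = 8)
  dmr <- bray_curtis(cm)
  grp <- rep(c("u", "v"), each = 5)
  ours <- anosim_test(dmr, grp, n_permutations = 999, seed = 3)
  ref <- vegan::anosim(dmr, grp, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)

  expect_error(anosim_test(dmr, rep("one", 10)), "2 groups")
})

test_that("ANOSIM is calibrated on structureless data", {
  hits <- 0
  for (s in 1:20) {
    cm <- random_cm(10, 12, seed = 100 + s)
    dm <- bray_curtis(cm)
    g <- withr::with_seed(200 + s, sample(rep(c("a", "b"), 6)))
    res <- anosim_test(dm, g, n_permutations = 499, seed = 300 + s)
    hits <- hits + (res$p_value > 0.05)
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("PCA matches an SVD oracle and orders explained variance", {
  ram <- matrix(c(0.5, 0.3, 0.2,
                  0.1, 0.6, 0.3,
                  0.4, 0.4, 0.2,
                  0.2, 0.2, 0.6), nrow = 3,
                dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  res <- pca_scores(ram, n_components = 2)
  X <- scale(t(ram), center = TRUE, scale = FALSE)
  sv <- svd(X)
  oracle <- sv$u %*% diag(sv$d)
  expect_equal(abs(res$scores$PC1), abs(oracle[, 1]), tolerance = 1e-10)
  expect_equal(abs(res$scores$PC2), abs(oracle[, 2]), tolerance = 1e-10)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)

  dup <- community_matrix(matrix(c(4L, 6L, 4L, 6L, 1L, 9L), 2, 3,
                                 dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
  sc <- expect_warning(pca_scores(dup, 2), "clipped")$scores
  expect_equal(sc$PC1[1], sc$PC1[2], tolerance = 1e-12)
  expect_warning(pca_scores(ram, 10), "clipped")
})

test_that("environmental heterogeneity is a standardized mean pairwise distance", {
  md0 <- tibble::tibble(sample_id = paste0("s", 1:4),
                        x = c(1, 1, 5, 9), group = c("a", "a", "b", "b"))
  h0 <- environmental_heterogeneity(md0, variables = "x")
  expect_equal(h0$heterogeneity[h0$group == "a"], 0)
  # two samples one overall-sd apart give heterogeneity exactly 1
  md1 <- tibble::tibble(sample_id = paste0("s", 1:3),
                        x = c(0, 1, 2), group = c("a", "a", "b"))
  h1 <- environmental_heterogeneity(md1, variables = "x")  # sd(x) = 1
  expect_equal(h1$heterogeneity[h1$group == "a"], 1)
  # constant variables dropped with a warning
  md1$flat <- 3
  expect_warning(environmental_heterogeneity(md1, variables = c("x", "flat")), "constant")
  # wide low-salinity ranges vs narrow high-salinity ranges
  md <- generate_group_metadata(15, habitats = "water", seed = 9)
  h <- environmental_heterogeneity(md)
  expect_gt(h$heterogeneity[h$group == "low-salinity-water"],
            h$heterogeneity[h$group == "high-salinity-water"])
})

test_that("rarefaction curves match the hypergeometric expectation", {
  x <- withr::with_seed(4, rpois(25, 8))
  total <- sum(x)
  rc <- rarefaction_curve(x, depths = c(1, 20, 80, total), reps = 300, seed = 2)
  expect_equal(rc$richness[rc$depth == total], sum(x > 0))
  expect_lt(abs(rc$richness[rc$depth == 1] - 1), 1e-12)
  for (d in c(20, 80)) {
    exact <- expected_richness_hyper(x, d)
    expect_lt(abs(rc$richness[rc$depth == d] - exact), 0.35)
    # vegan's closed form agrees with our oracle
    expect_equal(exact, as.numeric(suppressWarnings(vegan::rarefy(x, d))),
                 tolerance = 1e-8)
  }
  expect_true(all(diff(rc$richness) >= -0.5))  # non-decreasing in expectation
  expect_error(rarefaction_curve(x, total + 1), "depths")
})
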