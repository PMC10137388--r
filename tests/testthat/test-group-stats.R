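test_that("log preprocessing substitutes half-minimum for zeros and drops dead rows", {
  mat <- rbind(a = c(100, 1000, 10), b = c(0, 4, 8), c = c(0, 0, 0))
  expect_warning(out <- preprocess_log(mat), "all-zero")
  expect_equal(rownames(out), c("a", "b"))
  expect_equal(out["a", ], log10(c(100, 1000, 10)), ignore_attr = TRUE)
  expect_equal(unname(out["b", 1]), log10(2)) # half the smallest positive (4)
  # strictly positive rows keep their rank order
  expect_equal(order(out["a", ]), order(mat["a", ]))
})

test_that("the assumption gate picks branches as specified", {
  # constant group: Shapiro-Wilk undefined -> nonparametric
  expect_equal(choose_test_branch(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
               "nonparametric")
  # fewer than 3 per group -> nonparametric with a warning
  expect_warning(
    br <- choose_test_branch(c(1, 2, 3, 4), rep(c("a", "b"), each = 2)),
    "fewer than 3")
  expect_equal(br, "nonparametric")
})

test_that("the gate routes normal data mostly parametric, heavy tails nonparametric", {
  set.seed(202)
  grp <- rep(letters[1:4], each = 5)
  branches <- replicate(400, choose_test_branch(stats::rnorm(20), grp))
  frac_par <- mean(branches == "parametric")
  # every group must pass Shapiro-Wilk and the groups must pass Levene, so
  # the null parametric rate is near 0.95^4 * 0.95 ~ 0.77 (Shapiro is
  # slightly conservative at n = 5)
  expect_gt(frac_par, 0.65)
  expect_lt(frac_par, 0.95)
  grp2 <- rep(c("a", "b"), each = 20)
  branches2 <- replicate(200, choose_test_branch(stats::rlnorm(40, sdlog = 2), grp2))
  expect_gt(mean(branches2 == "nonparametric"), 0.5)
})

test_that("omnibus tests behave on degenerate and textbook inputs", {
  mat <- rbind(flat = rep(1:3, 3), sep = c(1, 2, 3, 11, 12, 13, 21, 22, 23))
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  out <- compare_features(mat, grp)$results
  expect_gte(out$p[out$feature == "flat"], 0.99) # identical group patterns
  sep <- out[out$feature == "sep", ]
  expect_equal(sep$branch, "parametric")
  expect_lt(sep$p, 0.001)
  expect_error(compare_features(mat, rep("g1", 9)), "two groups")
  expect_error(compare_features(mat, c("a", "b", "b", rep("c", 6))), "at least two samples")
})

test_that("pairwise post-hoc tables cover all group pairs on both branches", {
  set.seed(31)
  mat <- rbind(norm = stats::rnorm(20, rep(c(0, 0, 0, 3), each = 5)),
               lumpy = stats::rlnorm(20, rep(c(0, 0, 0, 3), each = 5), sdlog = 2))
  grp <- rep(c("a", "b", "c", "d"), each = 5)
  cmp <- compare_features(mat, grp)
  pw <- cmp$pairwise
  expect_equal(sum(pw$feature == "norm"), choose(4, 2))
  expect_equal(sum(pw$feature == "lumpy"), choose(4, 2))
  expect_true(all(pw$q >= pw$p - 1e-12))
  # the shifted group d should drive the smallest pairwise p for 'norm'
  norm_pw <- pw[pw$feature == "norm", ]
  best <- norm_pw[which.min(norm_pw$p), ]
  expect_true("d" %in% c(best$group1, best$group2))
})

test_that("Dunn z statistics agree with a direct rank computation", {
  v <- c(1, 5, 2, 8, 9, 11, 4, 3, 12, 10)
  g <- rep(c("a", "b"), each = 5)
  d <- dunn_test(v, g)
  # two groups, no ties: z^2 equals the Kruskal-Wallis statistic
  kw <- stats::kruskal.test(v, factor(g))$statistic
  expect_equal(unname(d$z^2), unname(kw), tolerance = 1e-12)
  expect_equal(d$p, 2 * stats::pnorm(-abs(d$z)))
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
  # order invariance and q >= p
  set.seed(5)
  p <- stats::runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_true(all(adjust_bh(p) >= p))
})

test_that("top-discriminant selection caps at k with deterministic ties", {
  res <- tibble::tibble(feature = sprintf("f%02d", 1:60),
                        branch = "parametric",
                        p = rep(0.001, 60), q = rep(0.01, 60))
  expect_length(top_discriminant(res, k = 50), 50)
  expect_equal(top_discriminant(res, k = 50), sort(res$feature)[1:50])
  res$q <- seq(0.001, 0.06, length.out = 60)
  few <- top_discriminant(res, k = 50, q_max = 0.01)
  expect_equal(few, res$feature[res$q < 0.01])
  expect_length(top_discriminant(dplyr::mutate(res, q = 0.9)), 0)
})

test_that("PCA explains all variance with one varying feature and reconstructs", {
  mat <- rbind(varies = c(1, 2, 3, 4), flat = rep(5, 4))
  pca <- pca_ordination(mat)
  expect_equal(pca$explained_variance[1], 1)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  # duplicated samples get identical scores
  mat2 <- rbind(a = c(1, 1, 4, 9), b = c(2, 2, 0, 3), c = c(5, 5, 1, 1))
  sc <- pca_ordination(mat2)$scores
  expect_equal(unlist(sc[1, -1]), unlist(sc[2, -1]))
  # full reconstruction of the centered matrix
  set.seed(8)
  m <- matrix(stats::rnorm(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  pc <- pca_ordination(m)
  centered <- t(scale(t(m), center = rowMeans(m), scale = FALSE))
  recon <- pc$loadings %*% t(as.matrix(pc$scores[, -1]))
  expect_equal(unname(recon), unname(centered), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
})

test_that("Ward/Euclidean agglomeration matches the brute-force oracle", {
  set.seed(17)
  for (i in 1:5) {
    pts <- matrix(stats::rnorm(8 * 3), 8, 3)
    hc <- stats::hclust(stats::dist(pts), method = "ward.D")
    expect_equal(hc$height, ward_bruteforce_heights(pts), tolerance = 1e-10)
  }
  # three points on a line: the near pair merges first
  hc3 <- stats::hclust(stats::dist(c(0, 1, 10)), method = "ward.D")
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))
  expect_equal(hc3$height[1], 1)
})

test_that("heatmap cells are log2 fold from the feature mean; twins merge at zero", {
  mat <- matrix(c(2, 2, 4, 8, 8, 16), nrow = 2, byrow = TRUE,
                dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  hh <- hclust_heatmap(mat)
  expect_equal(hh$heatmap["f1", ], log2(c(2, 2, 4) / mean(c(2, 2, 4))),
               ignore_attr = TRUE)
  # identical samples s1/s2 merge first at height zero
  expect_equal(sort(hh$sample_hclust$merge[1, ]), c(-2, -1))
  expect_equal(hh$sample_hclust$height[1], 0)
  expect_error(hclust_heatmap(mat, features = "nope"), "not in matrix")
  # Newick export mirrors the tree tips
  nwk <- dendrogram_newick(hh$sample_hclust)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(colnames(mat), grepl, logical(1), x = nwk, fixed = TRUE)))
})
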