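test_that("pg-to-Mb conversion uses 1 pg = 978 Mb", {
  expect_equal(pg_to_mb(1), 978)
  expect_equal(pg_to_mb(0), 0)
  expect_equal(pg_to_mb(3.68), 3599.04)
  expect_error(pg_to_mb(-1), ">= 0")
})

test_that("genome coverage reproduces the species-table values", {
  # C = L * N / G with N both mates, G = (2C/2) * 978 Mb
  expect_equal(genome_coverage(12060743, 7.36, digits = 2), 0.67)
  expect_equal(genome_coverage(6752840, 9.41, digits = 2), 0.29)
  # linearity in read pairs
  c1 <- genome_coverage(1e6, 10)
  expect_equal(genome_coverage(2e6, 10), 2 * c1)
  expect_error(genome_coverage(0, 10), "> 0")
  # at L = 100 the computed coverages track the printed column closely;
  # most printed rows reflect a slightly shorter post-trim read length
  tab <- load_species_table()
  cv <- genome_coverage(tab$read_pairs, tab$c2_pg, digits = 2)
  expect_true(all(abs(cv - tab$coverage) <= 0.021))
})

test_that("pearson correlation matches printed and hand-computed values", {
  tab <- load_species_table()
  ct <- pearson_correlation(tab$c2_pg, tab$repetitive_fraction_pct)
  expect_equal(round(ct$r, 4), 0.9121)
  expect_equal(ct$p, 0.0006, tolerance = 0.05)
  expect_equal(ct$n, 9)

  x <- 1:5
  expect_equal(pearson_correlation(x, x * 2 + 1)$r, 1)
  # closed-form oracle on a 3-point set
  x3 <- c(1, 2, 3); y3 <- c(2, 4, 5)
  r_hand <- sum((x3 - 2) * (y3 - mean(y3))) /
    sqrt(sum((x3 - 2)^2) * sum((y3 - mean(y3))^2))
  expect_equal(pearson_correlation(x3, y3)$r, r_hand)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("tip dropping preserves surviving root-to-tip path lengths", {
  tree <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:1):2);")
  depths_before <- ape::node.depth.edgelength(tree)[1:4]
  names(depths_before) <- tree$tip.label
  pruned <- drop_tips(tree, "b")
  expect_equal(sort(pruned$tip.label), c("a", "c", "d"))
  depths_after <- ape::node.depth.edgelength(pruned)[1:3]
  names(depths_after) <- pruned$tip.label
  expect_equal(depths_after[c("a", "c", "d")],
               depths_before[c("a", "c", "d")])
  # no-op and error paths
  expect_identical(drop_tips(tree, character(0)), tree)
  expect_error(drop_tips(tree, "zz"), "zz")
})

test_that("the bundled study tree prunes from nine species to eight", {
  tree <- load_study_tree()
  expect_equal(length(tree$tip.label), 8) # topology ships without ANO
  tab <- load_species_table()
  expect_true(all(tree$tip.label %in% tab$abbreviation))
  # removing a named tip leaves 7
  expect_equal(length(drop_tips(tree, "AGR")$tip.label), 7)
})

test_that("contrasts follow the two-tip closed form and basic identities", {
  tree <- ape::read.tree(text = "(a:2,b:3);")
  x <- c(a = 5, b = 1)
  expect_equal(unname(pic_contrasts(tree, x)), (5 - 1) / sqrt(2 + 3))
  # equal trait values: all contrasts zero
  tree4 <- ape::rtree(6, rooted = TRUE)
  expect_true(all(abs(pic_contrasts(
    tree4, setNames(rep(2, 6), tree4$tip.label))) < 1e-12))
  # contrast count is tips - 1
  expect_equal(length(pic_contrasts(
    tree4, setNames(rnorm(6), tree4$tip.label))), 5)
  # polytomies rejected unless resolved
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(pic_contrasts(poly, c(a = 1, b = 2, c = 3)), "polytom")
})

# GLS oracle: under Brownian motion the contrast correlation equals the
# correlation of GLS residuals with covariance V[i, j] = shared path length
gls_correlation <- function(tree, x, y) {
  V <- ape::vcv(tree)
  x <- x[rownames(V)]; y <- y[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  ax <- sum(Vi %*% x) / sum(Vi)
  ay <- sum(Vi %*% y) / sum(Vi)
  rx <- x - ax; ry <- y - ay
  sxy <- as.numeric(t(rx) %*% Vi %*% ry)
  sxx <- as.numeric(t(rx) %*% Vi %*% rx)
  syy <- as.numeric(t(ry) %*% Vi %*% ry)
  sxy / sqrt(sxx * syy)
}

test_that("pic correlation equals the GLS brute-force oracle", {
  for (seed in 1:5) {
    tree <- ltrtracer:::with_seed(seed, ape::rtree(4, rooted = TRUE))
    x <- setNames(rnorm(4), tree$tip.label)
    y <- setNames(rnorm(4), tree$tip.label)
    expect_equal(pic_correlation(tree, x, y)$r,
                 gls_correlation(tree, x, y), tolerance = 1e-10)
  }
})

test_that("pic correlation behaves under simple transformations", {
  tree <- ltrtracer:::with_seed(99, ape::rtree(8, rooted = TRUE))
  x <- setNames(rnorm(8), tree$tip.label)
  # proportional traits: r = 1
  expect_equal(pic_correlation(tree, x, 2 * x)$r, 1, tolerance = 1e-12)
  # sign flip negates r exactly
  y <- setNames(rnorm(8), tree$tip.label)
  expect_equal(pic_correlation(tree, x, -y)$r,
               -pic_correlation(tree, x, y)$r, tolerance = 1e-12)
  # permutation of tip order leaves r unchanged
  perm <- sample(8)
  expect_equal(pic_correlation(tree, x[perm], y[perm])$r,
               pic_correlation(tree, x, y)$r, tolerance = 1e-12)
})

test_that("star-tree contrasts reduce to centred tip differences", {
  # on a star tree (resolved with zero-length internal branches) the
  # through-origin contrast correlation equals the ordinary correlation
  # computed through the origin on scaled pairwise differences
  tree <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  x <- c(a = 1, b = 4, c = 2, d = 7)
  y <- c(a = 2, b = 5, c = 1, d = 9)
  r <- pic_correlation(tree, x, y, resolve_polytomies = TRUE)$r
  expect_equal(r, gls_correlation(ape::multi2di(tree, random = FALSE),
                                  x, y), tolerance = 1e-10)
})
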