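test_that("centroids are cluster means with sigma and chi2 behaving at the degenerate points", {
  b <- c(a1 = 2, a2 = 2, a3 = 2, b1 = 1, b2 = 3, c1 = 5)
  cl <- suppressWarnings(fit_centroids(b, c("A", "A", "A", "B", "B", "C")))
  expect_equal(cl$centroid, c(2, 2, 5))
  expect_equal(cl$sigma[1], 0)
  expect_equal(cl$chi2[1], 0)
  expect_equal(cl$sigma[2], sd(c(1, 3)))
  w <- capture_warnings(fit_centroids(c(1, 2, 3), c("A", "B", "C")))
  expect_match(w, "singleton", all = TRUE)
  expect_length(w, 3)
  expect_error(fit_centroids(c(1, 2), c("A", "B")), "min\\|A\\|")
})

test_that("the centroid minimizes the within-cluster sum of squares (golden-section oracle)", {
  set.seed(42)
  for (rep in 1:20) {
    b <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    opt <- golden_section(function(c) sum((b - c)^2), min(b) - 1, max(b) + 1)
    expect_equal(mean(b), opt, tolerance = 1e-6)
  }
})

test_that("chi-squared matches hand values, shifts for non-positive centroids, and is monotone in outlier distance", {
  expect_equal(as.numeric(chi_squared(c(1, 3), 2)), 1)
  expect_equal(attr(chi_squared(c(1, 3), 2), "shift"), 0)
  expect_equal(as.numeric(chi_squared(c(4, 4, 4), 4)), 0)
  # negative values trigger the positivity shift c = 1 + |min|
  x <- chi_squared(c(-2, 0, 2), 0)
  expect_equal(attr(x, "shift"), 3)
  expect_equal(as.numeric(x), (4 + 0 + 4) / 3)
  expect_gte(as.numeric(x), 0)
  expect_equal(as.numeric(chi_squared(c(-1, -1), -1)), 0) # zero point survives the shift
  # pulling an outlier toward the centroid never increases chi2
  base <- c(1, 1.2, 0.8, 1.1)
  chis <- sapply(seq(5, 1, length.out = 9), function(out) {
    as.numeric(chi_squared(c(base, out), mean(c(base, out))))
  })
  expect_true(all(diff(chis) <= 1e-12))
})

test_that("outlier flagging applies |beta - centroid| >= sigma as computed directly", {
  expect_equal(flag_outliers(c(2, 2, 2), 2, 0), character(0))
  # direct computation for (0, 0, 10): centroid 10/3, sample sd 5.7735;
  # only the member at 10 is at or beyond one sd
  b <- c(s1 = 0, s2 = 0, s3 = 10)
  expect_equal(abs(10 - 10 / 3) >= sd(b), TRUE)
  expect_equal(abs(0 - 10 / 3) >= sd(b), FALSE)
  expect_equal(flag_outliers(b, mean(b), sd(b)), "s3")
  # planted-outlier fixture: exactly the planted sequence is flagged
  fx <- make_worked_fixture("planted-outlier")
  f <- featurize(fx$scores)
  beta <- beta_values(f)
  names(beta) <- fx$scores$sequence_ids
  cl <- fit_centroids(beta, fx$labels)
  expect_equal(attr(cl, "outliers")[[fx$expected$outlier_cluster]], fx$expected$flagged)
})

test_that("k-means concordance recovers labelled structure and degrades predictably", {
  expect_equal(as.numeric(unsupervised_check(c(-10, 0, 10), c("A", "B", "C"), k = 3)), 1)
  # all identical betas: purity equals the majority class frequency
  p <- suppressWarnings(
    unsupervised_check(rep(1, 6), c("A", "A", "A", "B", "C", "C"), k = 3)
  )
  expect_equal(as.numeric(p), 0.5)
  expect_error(unsupervised_check(c(1, 2), c("A", "B"), k = 3), "exceeds")
  # three 6-sigma-separated gaussian clusters, 30 members each
  set.seed(1234)
  beta <- c(rnorm(30, 0), rnorm(30, 6), rnorm(30, 12))
  labs <- rep(c("A", "B", "C"), each = 30)
  expect_gte(as.numeric(unsupervised_check(beta, labs, k = 3, seed = 1234)), 0.95)
})

test_that("cluster report round-trips through TSV", {
  b <- c(x1 = 1, x2 = 1.2, y1 = 5, y2 = 5.1, z1 = 9)
  cl <- suppressWarnings(fit_centroids(b, c("X", "X", "Y", "Y", "Z")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(cl, path)
  back <- read.delim(path)
  expect_equal(back$label, cl$label)
  expect_equal(back$centroid, cl$centroid, tolerance = 1e-12)
})
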