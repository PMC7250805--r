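mk_model <- function(label, centroid, sigma, size) {
  list(label = label, centroid = centroid, sigma = sigma, size = size)
}

test_that("interval half-widths use t below 30 members and z from 30, degenerating at sigma 0", {
  iv0 <- build_interval(mk_model("A", 1.5, 0, 10))
  expect_equal(c(iv0$low, iv0$high), c(1.5, 1.5))
  expect_equal(iv0$kind, "degenerate")
  # |G| = 30: normal quantile 1.959964 from standard tables
  iv30 <- build_interval(mk_model("A", 0, 2, 30), alpha = 0.05)
  expect_equal(iv30$kind, "z")
  expect_equal(iv30$high, 1.959964 * 2 / sqrt(30), tolerance = 1e-6)
  # |G| = 4: t coefficient 3.182446 (3 df) from t tables
  iv4 <- build_interval(mk_model("A", 0, 1, 4), alpha = 0.05)
  expect_equal(iv4$kind, "t")
  expect_equal(iv4$coefficient, 3.182446, tolerance = 1e-6)
  expect_warning(build_interval(mk_model("A", 1, 0, 1)), "degenerate")
  expect_error(build_interval(mk_model("A", 0, 1, 10), alpha = 1.2), "alpha")
})

test_that("t-based intervals strictly contain z-based ones and converge as |G| grows", {
  for (alpha in c(0.05, 0.01)) {
    for (g in c(3, 5, 10, 29)) {
      t_half <- build_interval(mk_model("A", 0, 1, g), alpha)$high
      z_half <- abs(qnorm(alpha / 2)) * 1 / sqrt(g)
      expect_gt(t_half, z_half)
    }
  }
  half <- function(g) {
    c(
      t = abs(qt(0.975, g - 1)) / sqrt(g),
      z = abs(qnorm(0.975)) / sqrt(g)
    )
  }
  h3 <- half(1e3)
  expect_lt(abs(h3["t"] - h3["z"]), 1e-3)
  h6 <- half(1e6)
  expect_lt(abs(h6["t"] - h6["z"]), 1e-6)
})

test_that("partition assembly sorts, detects overlap, and measures |b - a|", {
  ivs <- lapply(
    list(
      mk_model("mid", 0, 0.1, 10),
      mk_model("low", -3, 0.1, 10),
      mk_model("high", 3, 0.1, 10)
    ),
    build_interval
  )
  p <- build_partition(ivs)
  expect_true(p$disjoint)
  expect_equal(vapply(p$intervals, `[[`, character(1), "label"), c("low", "mid", "high"))
  expect_equal(p$tau, 1 / 3)
  expect_equal(p$a, -3.1) # min centroid - its sigma
  expect_equal(p$b, 3.1)
  expect_equal(p$measure, 6.2)
  overlapping <- lapply(
    list(
      mk_model("A", 0, 1, 5), mk_model("B", 0.5, 1, 5), mk_model("C", 9, 1, 5)
    ),
    build_interval
  )
  expect_warning(po <- build_partition(overlapping), "overlap")
  expect_false(po$disjoint)
  expect_error(build_partition(ivs[1:2]), "3 function")
})

test_that("mapping assigns by strict open-interval containment with explicit degradation", {
  p <- build_partition(lapply(
    list(
      mk_model("A", -3, 0.2, 10), mk_model("B", 0, 0.2, 10),
      mk_model("C", 3, 0.2, 10)
    ),
    build_interval
  ))
  expect_equal(map_prediction(0, p)$label, "B")
  expect_equal(map_prediction(0, p)$status, "assigned")
  far <- map_prediction(50, p)
  expect_equal(far$status, "unassigned")
  expect_equal(far$nearest, "C")
  # boundary value of an open interval is unassigned, with a warning
  hi <- p$intervals[[2]]$high
  expect_warning(onb <- map_prediction(hi, p), "boundary")
  expect_equal(onb$status, "unassigned")
  expect_error(map_prediction(NaN, p), "finite")
  # overlapping fixture: ambiguous with both labels; nearest centroid by distance
  po <- suppressWarnings(build_partition(lapply(
    list(
      mk_model("A", 0, 1, 5), mk_model("B", 0.6, 1, 5), mk_model("C", 9, 1, 5)
    ),
    build_interval
  )))
  amb <- map_prediction(0.35, po)
  expect_equal(amb$status, "ambiguous")
  expect_setequal(amb$candidates, c("A", "B"))
  expect_equal(amb$nearest, c("A", "B")[which.min(abs(0.35 - c(0, 0.6)))])
  # epsilon = "sigma" widens each interval by its cluster sigma
  wide <- map_prediction(-3 - 0.3, p, epsilon = "sigma")
  expect_equal(wide$status, "assigned")
  expect_equal(wide$label, "A")
})

test_that("tau is 1/n and truncates to the quoted bounds of the feasible range", {
  mk_part <- function(k) {
    build_partition(lapply(seq_len(k), function(i) {
      build_interval(mk_model(paste0("F", i), 10 * i, 0.1, 10))
    }))
  }
  expect_equal(truncate_decimal(mapping_probability(mk_part(3)), 2), 0.33)
  expect_equal(truncate_decimal(mapping_probability(mk_part(6)), 3), 0.166)
  expect_equal(mapping_probability(mk_part(4)), 0.25)
})

test_that("training betas inside their own interval are mapped back to their function", {
  sim <- tiny_sim(separation = 6, per = 12, seed = 5)
  f <- featurize(sim$scores)
  beta <- beta_values(f)
  names(beta) <- sim$scores$sequence_ids
  cl <- fit_centroids(beta, sim$labels)
  p <- build_partition(cl)
  expect_true(p$disjoint)
  for (i in seq_along(beta)) {
    own <- Filter(function(iv) iv$label == sim$labels[i], p$intervals)[[1]]
    if (beta[i] > own$low && beta[i] < own$high) {
      expect_equal(map_prediction(beta[i], p)$label, unname(sim$labels[i]))
    }
  }
})

test_that("partitions serialize to JSON with their geometry intact", {
  p <- build_partition(lapply(
    list(
      mk_model("A", -2, 0.1, 8), mk_model("B", 0, 0.1, 8), mk_model("C", 2, 0.1, 8)
    ),
    build_interval
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(p, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$tau, p$tau)
  expect_equal(back$measure, p$measure)
  expect_equal(back$intervals$label, c("A", "B", "C"))
})
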