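test_that("pair and POP counts match brute-force enumeration for n = 3..12", {
  for (n in 3:12) {
    expect_identical(pair_count(n), as.integer(choose(n, 2)))
    expect_identical(nrow(enumerate_pairs(n)), as.integer(pair_count(n)))
    expect_identical(pop_count(n), as.integer(brute_force_pop_count(n)))
    expect_identical(nrow(enumerate_pops(n)), as.integer(pop_count(n)))
  }
})

test_that("the quartic closed form equals the exact POP count for n = 3..50", {
  for (n in 3:50) {
    quartic <- 0.125 * n^4 - 0.25 * n^3 - 0.125 * n^2 + 0.25 * n
    expect_lt(abs(quartic - pop_count(n)), 1e-6)
    # the published fit differs from the quartic only by its -2e-08 constant
    expect_lt(abs(fitted_cardinality(n, "D_poly") - pop_count(n)), 1e-6)
  }
})

test_that("superset sizes below 3 are rejected with the axiom named", {
  expect_error(pair_count(2), "min")
  expect_error(pop_count(2), "axiom|min")
  expect_error(enumerate_pairs(1), "min")
  expect_error(enumerate_pops(2), "min")
  expect_error(hidden_nodes(2), "minimum|>= 3")
})

test_that("pair enumeration is lexicographic and exhaustive", {
  p3 <- enumerate_pairs(3)
  expect_equal(p3$i, c(1, 1, 2))
  expect_equal(p3$j, c(2, 3, 3))
  p4 <- enumerate_pairs(4)
  expect_equal(nrow(p4), 6)
  expect_equal(unlist(p4[1, ]), c(i = 1, j = 2))
  expect_equal(unlist(p4[6, ]), c(i = 3, j = 4))
  for (n in 3:8) {
    p <- enumerate_pairs(n)
    expect_true(all(p$i < p$j))
    keys <- paste(p$i, p$j)
    expect_identical(anyDuplicated(keys), 0L)
    expect_setequal(keys, apply(utils::combn(n, 2), 2, paste, collapse = " "))
  }
})

test_that("POP enumeration lists all unordered pairs of distinct pairs in stable order", {
  d3 <- enumerate_pops(3)
  expect_equal(d3$ordinal, 1:3)
  # the three POPs over pairs (1,2), (1,3), (2,3)
  expect_equal(d3$i1, c(1, 1, 1))
  expect_equal(d3$j1, c(2, 2, 3))
  expect_equal(d3$i2, c(1, 2, 2))
  expect_equal(d3$j2, c(3, 3, 3))
  expect_identical(enumerate_pops(5), enumerate_pops(5)) # deterministic
  # the two pairs of a POP are always distinct
  d5 <- enumerate_pops(5)
  expect_false(any(d5$i1 == d5$i2 & d5$j1 == d5$j2))
})

test_that("chained POP variant keeps only single-shared-index couples", {
  d4c <- enumerate_pops(4, chained = TRUE)
  expect_equal(nrow(d4c), 12) # inconsistent with the architecture table's 15
  shared <- mapply(
    function(a, b, c, d) length(intersect(c(a, b), c(c, d))),
    d4c$i1, d4c$j1, d4c$i2, d4c$j2
  )
  expect_true(all(shared == 1))
})

test_that("published fitted curves evaluate to their frozen values", {
  expect_equal(fitted_cardinality(4, "D_poly"), 15, tolerance = 1e-6)
  expect_equal(fitted_cardinality(4, "B_power"), 6.038475, tolerance = 1e-6)
  # the printed |B| polynomial does NOT reproduce the exact count
  expect_equal(fitted_cardinality(3, "B_poly"), 3.75, tolerance = 1e-10)
  expect_error(fitted_cardinality(4, "nope"))
})

test_that("hidden-node heuristics reproduce reference rows under half-away-from-zero rounding", {
  expect_equal(hidden_nodes(3), c(h1 = 4L, h2 = 4L, h3 = 3L))
  expect_equal(hidden_nodes(990), c(h1 = 527L, h2 = 63L, h3 = 661L))
  expect_equal(hidden_nodes(11628), c(h1 = 5922L, h2 = 216L, h3 = 7753L))
  # rounding rule: ties go away from zero, not to even
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, 781.5, -2.5)), c(1, 2, 3, 782, -3))
})

test_that("architecture table rows satisfy d = C(b, 2) and match the frozen reference", {
  tab <- architecture_table(18)
  expect_equal(nrow(tab), 16)
  expect_true(all(tab$d == choose(tab$b, 2)))
  expect_equal(unname(as.matrix(tab)), unname(reference_architecture))
  expect_equal(unlist(architecture_table(3)), c(n = 3, b = 3, d = 3, h1 = 4, h2 = 4, h3 = 3))
})

test_that("feasible superset sizes honour the node cap and slack", {
  expect_equal(feasible_superset_sizes(18), 3:6)
  expect_equal(feasible_superset_sizes(18, slack = 0), 3:5)
  expect_equal(feasible_superset_sizes(4, rule = "H2", slack = 0), 3L)
  expect_error(feasible_superset_sizes(2))
})
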