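# Independent oracles used across tests.

# Brute-force count of 2-subsets of the 2-subsets of 1..n, via the generic
# combinations routine only.
brute_force_pop_count <- function(n) {
  pairs <- utils::combn(n, 2, simplify = FALSE)
  ncol(utils::combn(length(pairs), 2))
}

# Golden-section minimizer of f over [lo, hi]; independent of any package
# code.
golden_section <- function(f, lo, hi, tol = 1e-9) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      hi <- x2
      x2 <- x1
      f2 <- f1
      x1 <- hi - phi * (hi - lo)
      f1 <- f(x1)
    } else {
      lo <- x1
      x1 <- x2
      f1 <- f2
      x2 <- lo + phi * (hi - lo)
      f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

# The architecture table as printed in the reference, frozen by hand:
# columns n, |B|, |D|, H1, H2, H3 for n = 3..18.
reference_architecture <- matrix(
  c(
    3, 3, 3, 4, 4, 3,
    4, 6, 15, 12, 8, 11,
    5, 10, 45, 30, 14, 31,
    6, 15, 105, 63, 21, 71,
    7, 21, 210, 120, 29, 141,
    8, 28, 378, 209, 39, 253,
    9, 36, 630, 341, 50, 421,
    10, 45, 990, 527, 63, 661,
    11, 55, 1485, 782, 77, 991,
    12, 66, 2145, 1119, 93, 1431,
    13, 78, 3003, 1557, 110, 2003,
    14, 91, 4095, 2112, 128, 2731,
    15, 105, 5460, 2804, 148, 3641,
    16, 120, 7140, 3655, 169, 4761,
    17, 136, 9180, 4686, 192, 6121,
    18, 153, 11628, 5922, 216, 7753
  ),
  ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("n", "b", "d", "h1", "h2", "h3"))
)

# Small labelled simulation used by several files.
tiny_sim <- function(separation = 6, per = 10, seed = 1, n_functions = 3) {
  simulate_scores(simulation_spec(
    n_functions = n_functions, seqs_per_function = per,
    separation = separation, seed = seed
  ))
}
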