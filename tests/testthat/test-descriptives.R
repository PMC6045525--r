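test_that("Wilson interval matches its closed form and stays in bounds", {
  wilson_oracle <- function(x, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(center - half, center + half)
  }
  ci <- prevalence_with_ci(50, 100)
  expect_equal(unname(ci), c(0.5, wilson_oracle(50, 100)), tolerance = 1e-10)
  expect_equal(round(unname(ci[2:3]), 3), c(0.404, 0.596))
  # boundary: zero successes pin the lower limit at 0
  ci0 <- prevalence_with_ci(0, 40)
  expect_equal(unname(ci0[["lower"]]), 0)
  # the interval contains the estimate and lies in [0, 1]
  for (x in c(1, 17, 399)) {
    ci <- prevalence_with_ci(x, 400)
    expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
    expect_true(ci[["lower"]] <= ci[["estimate"]] &&
                  ci[["estimate"]] <= ci[["upper"]])
  }
  expect_error(prevalence_with_ci(5, 4), "successes")
  expect_error(prevalence_with_ci(1, 10, level = 1), "level")
})

test_that("published neck-pain interval reproduces under the item denominator", {
  ci <- prevalence_with_ci(437, 1565)
  expect_equal(round(unname(ci[2:3]), 3), c(0.258, 0.302))
})

test_that("homogeneity test gives the Pearson statistic and seeded MC p", {
  gc <- group_counts(c("a", "b"), c(30, 70), c(100, 100))
  ht <- homogeneity_test(gc, "asymptotic")
  # hand Pearson: all four cells (obs-exp)^2/exp = 8 each
  expect_equal(ht$statistic, 32, tolerance = 1e-12)
  expect_equal(ht$df, 1L)
  # identical proportions: statistic 0, p 1
  same <- group_counts(c("a", "b", "c"), c(20, 40, 60), c(50, 100, 150))
  ht0 <- homogeneity_test(same, "asymptotic")
  expect_equal(ht0$statistic, 0, tolerance = 1e-12)
  expect_equal(ht0$p, 1)
  # Monte Carlo: bit-for-bit reproducible and close to asymptotic at large n
  m1 <- homogeneity_test(gc, "monte_carlo", seed = 99, n_rep = 1e5)
  m2 <- homogeneity_test(gc, "monte_carlo", seed = 99, n_rep = 1e5)
  expect_identical(m1$p, m2$p)
  big <- group_counts(c("a", "b"), c(300, 360), c(1000, 1000))
  pa <- homogeneity_test(big, "asymptotic")$p
  pm <- homogeneity_test(big, "monte_carlo", seed = 3, n_rep = 1e5)$p
  expect_lt(abs(pa - pm), 0.01)
  expect_error(homogeneity_test(gc, "monte_carlo"), "seed")
})

test_that("letter display separates exactly the significantly different groups", {
  # all proportions equal: a single shared letter
  same <- group_counts(letters[1:4], rep(30, 4), rep(100, 4))
  expect_equal(unname(pairwise_letter_display(same)$letters), rep("a", 4))
  # two well-separated proportions get distinct letters
  far <- group_counts(c("lo", "hi"), c(10, 90), c(100, 100))
  expect_equal(unname(pairwise_letter_display(far)$letters), c("a", "b"))
  # four strata where only the low group stands apart (shoulder-row pattern)
  four <- group_counts(c("g13", "g14", "b13", "b14"),
                       round(c(0.23, 0.21, 0.24, 0.14) * 470), rep(470, 4))
  ld <- pairwise_letter_display(four)
  shared <- strsplit(ld$letters, "")
  expect_length(intersect(shared[["b14"]],
                          unlist(shared[c("g13", "g14", "b13")])), 0)
  expect_length(unique(unlist(shared[c("g13", "g14", "b13")])), 1L)
})

test_that("letter partition is invariant to group reordering", {
  gc <- group_counts(c("a", "b", "c", "d"), c(50, 58, 90, 130),
                     c(300, 300, 300, 300))
  base <- pairwise_letter_display(gc)
  perm <- c(3, 1, 4, 2)
  gc2 <- group_counts(gc$group_names[perm], gc$successes[perm],
                      gc$totals[perm])
  re <- pairwise_letter_display(gc2)
  # same-letter relation must be identical after renaming
  share <- function(ld, i, j) {
    a <- strsplit(ld$letters, "")
    length(intersect(a[[i]], a[[j]])) > 0
  }
  for (i in c("a", "b", "c")) for (j in c("b", "c", "d")) {
    if (i != j) expect_equal(share(base, i, j), share(re, i, j))
  }
})

test_that("union probabilities and the joint distribution are inverse maps", {
  # J = 1: union of the single item is its marginal
  expect_equal(joint_from_subset_unions(0.3), c(0.7, 0.3))
  # independent items: reconstruction returns the product joint
  p <- c(0.25, 0.6)
  joint_ind <- as.numeric(outer(c(1 - p[1], p[1]), c(1 - p[2], p[2])))
  # bitmask order: (00, 10, 01, 11) with bit1 = item1
  joint_ind <- joint_ind[c(1, 2, 3, 4)]
  u <- union_probabilities(joint_ind)
  expect_equal(joint_from_subset_unions(u), joint_ind, tolerance = 1e-12)
  # random J = 4 joints round-trip to 1e-12
  for (s in 1:6) {
    set.seed(s)
    joint <- rexp(16)
    joint <- joint / sum(joint)
    expect_equal(joint_from_subset_unions(union_probabilities(joint)), joint,
                 tolerance = 1e-12)
  }
  expect_error(joint_from_subset_unions(c(0.5, NA, 0.6)), "missing")
  # infeasible union system: implied P(1,1) = 1 - 0.3 - 0.3 + ... < 0
  expect_error(joint_from_subset_unions(c(0.3, 0.3, 0.9)), "inconsistent")
})
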