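test_that("free-parameter accounting covers single- and multigroup models", {
  expect_equal(count_free_parameters(3, 4), 14L)
  expect_equal(count_free_parameters(1, 7), 7L)
  expect_equal(count_free_parameters(3, 4, G = 4, rho_invariant = FALSE), 56L)
  expect_equal(count_free_parameters(3, 4, G = 4, rho_invariant = TRUE), 20L)
  # the free-minus-invariant difference is the invariance test df
  expect_equal(count_free_parameters(3, 4, 4, FALSE) -
                 count_free_parameters(3, 4, 4, TRUE), 36L)
  expect_error(count_free_parameters(0, 4), "positive")
})

test_that("information criteria follow the G-squared convention", {
  ic <- information_criteria(0, 0, 10)
  expect_equal(unname(ic), c(0, 0))
  ic1 <- information_criteria(5, 3, 100)
  ic2 <- information_criteria(5, 6, 100)
  expect_equal(ic2[["aic"]] - ic1[["aic"]], 2 * 3)
  expect_equal(ic2[["bic"]] - ic1[["bic"]], log(100) * 3)
  expect_error(information_criteria(1, 1, 0), "n_used")
})

test_that("chi-square tail matches closed forms and is monotone", {
  expect_equal(chi_square_tail(0, 5), 1)
  # df = 2 closed form: exp(-x/2)
  for (x in c(0.5, 2 * log(2), 5, 10)) {
    expect_equal(chi_square_tail(x, 2), exp(-x / 2), tolerance = 1e-10)
  }
  xs <- seq(0.1, 30, length.out = 50)
  expect_true(all(diff(chi_square_tail(xs, 7)) < 0))
  expect_error(chi_square_tail(-1, 2), "non-negative")
  expect_error(chi_square_tail(1, 0), "df")
})

test_that("goodness of fit reproduces hand-computed G2 and X2", {
  # J = 1 table: observed (30, 70) against a fair-coin model
  d <- response_matrix(matrix(c(rep(0L, 30), rep(1L, 70)), ncol = 1))
  tab <- pattern_table(d)
  expect_equal(tab$counts, c(30L, 70L))
  fair <- lca_params(1, matrix(0.5, 1, 1))
  gof <- goodness_of_fit(fair, tab, n_params = 0L)
  expect_equal(gof$gsq, 2 * (30 * log(30 / 50) + 70 * log(70 / 50)),
               tolerance = 1e-12)
  expect_equal(gof$xsq, 16)
  # a model matching the empirical frequencies exactly fits perfectly
  emp <- lca_params(1, matrix(0.7, 1, 1))
  gof0 <- goodness_of_fit(emp, tab, n_params = 0L)
  expect_equal(gof0$gsq, 0, tolerance = 1e-12)
  expect_equal(gof0$xsq, 0, tolerance = 1e-12)
})

test_that("pattern-table statistics are invariant to record order", {
  set.seed(8)
  d <- random_data(80, 3, seed = 8, miss = 0.1)
  p <- random_params(2, 3, seed = 9)
  tab1 <- pattern_table(d)
  shuf <- subset_records(d, sample(nrow(d$items)))
  tab2 <- pattern_table(shuf)
  expect_equal(tab1$counts, tab2$counts)
  g1 <- goodness_of_fit(p, tab1)
  g2 <- goodness_of_fit(p, tab2)
  expect_equal(g1$gsq, g2$gsq)
  expect_equal(g1$xsq, g2$xsq)
})

test_that("residual df for the three-class four-item model is 1", {
  d <- simulate_lca(load_fixture("table2"), n_total = 300, seed = 5)
  f <- fit_em(d, 3, em_config(seed = 2, n_starts = 3, mad_tol = 1e-6,
                              max_iter = 1500))
  expect_equal(f$df, 1L)
  expect_equal(f$n_params, 14L)
  # FitResult invariant: criteria recompute from the stored pieces
  expect_equal(f$aic, f$gsq + 2 * f$n_params)
  expect_equal(f$bic, f$gsq + log(f$n_used) * f$n_params)
})

test_that("degenerate sweeps behave: single candidate, single-class data", {
  one <- lca_params(1, matrix(c(0.3, 0.6, 0.2), 1, 3))
  fx <- make_fixture(multigroup_params("all", matrix(1, 1, 1), one$rho,
                                       rho_invariant = TRUE),
                     default_n = 800, name = "one_class")
  d <- simulate_lca(fx, seed = 404, missing_rates = 0)
  cfg <- em_config(seed = 6, n_starts = 4, mad_tol = 1e-6, max_iter = 1500)
  # c_min == c_max: that C comes back with no advancement
  s1 <- select_classes(d, 2, 2, cfg)
  expect_equal(s1$selected_C, 2L)
  expect_false(any(s1$rule_trace$advanced))
  # data with no class structure: the sweep stays at c_min
  s2 <- select_classes(d, 2, 3, cfg)
  expect_equal(s2$selected_C, 2L)
})
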