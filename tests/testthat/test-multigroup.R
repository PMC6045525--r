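test_that("invariance df counts the constrained parameters", {
  expect_equal(invariance_df(3, 4, 2), 12L)
  expect_equal(invariance_df(3, 4, 4), 36L)
  expect_equal(invariance_df(3, 4, 1), 0L)
  expect_error(invariance_df(3, 4, 0), "G")
})

test_that("a single-group free fit reduces to the plain EM fit", {
  d <- simulate_lca(load_fixture("table2"), n_total = 400, seed = 12)
  cfg <- em_config(seed = 9, n_starts = 3, mad_tol = 1e-6, max_iter = 1500)
  single <- fit_em(d, 2, cfg)
  grouped <- fit_multigroup(
    response_matrix(d$items, item_names = d$item_names,
                    group = rep("all", nrow(d$items))),
    2, rho_invariant = FALSE, config = cfg)
  expect_equal(grouped$loglik, single$loglik, tolerance = 1e-8)
  expect_equal(unname(group_params(grouped$params, 1)$rho),
               unname(single$params$rho), tolerance = 1e-8)
})

test_that("the free model equals independent per-group fits and nests the constrained", {
  fx <- load_fixture("table3_gender")
  cfg <- em_config(seed = 5, n_starts = 3, mad_tol = 1e-6, max_iter = 1500)
  for (s in 1:3) {
    d <- simulate_lca(fx, n_total = 700, seed = 900 + s)
    free <- fit_multigroup(d, 2, rho_invariant = FALSE, config = cfg)
    cons <- fit_multigroup(d, 2, rho_invariant = TRUE, config = cfg)
    # nesting inequality
    expect_gte(free$loglik, cons$loglik - 1e-6)
    # concatenation of single-group fits with the same derived seeds
    ll_parts <- 0
    for (g in 1:2) {
      sub <- subset_records(drop_missing_group(d, quiet = TRUE),
                            d$group == levels(d$group)[g])
      cfg_g <- cfg
      cfg_g$seed <- cfg$seed + 1000L * (g - 1L)
      ll_parts <- ll_parts + fit_em(sub, 2, cfg_g)$loglik
    }
    expect_equal(free$loglik, ll_parts, tolerance = 1e-8)
  }
})

test_that("parameter accounting and stacked fit fields are coherent", {
  d <- simulate_lca(load_fixture("table3_gender"), n_total = 500, seed = 77)
  cfg <- em_config(seed = 2, n_starts = 2, mad_tol = 1e-5, max_iter = 800)
  cons <- fit_multigroup(d, 3, rho_invariant = TRUE, config = cfg)
  free <- fit_multigroup(d, 3, rho_invariant = FALSE, config = cfg)
  expect_equal(cons$n_params, count_free_parameters(3, 4, 2, TRUE))
  expect_equal(free$n_params, count_free_parameters(3, 4, 2, FALSE))
  expect_equal(free$n_params - cons$n_params, invariance_df(3, 4, 2))
  expect_equal(cons$df, 2L * 15L - cons$n_params)
  expect_equal(cons$aic, cons$gsq + 2 * cons$n_params)
  expect_equal(cons$bic, cons$gsq + log(cons$n_used) * cons$n_params)
})

test_that("the invariance statistic is the floored G2 difference with the right df", {
  d <- simulate_lca(load_fixture("table3_gender"), n_total = 800, seed = 31)
  inv <- suppressWarnings(
    invariance_test(d, 3, em_config(seed = 4, n_starts = 3,
                                    mad_tol = 1e-6, max_iter = 2000)))
  expect_gte(inv$chisq_diff, 0)
  expect_equal(inv$df_diff, 12L)
  expect_equal(inv$chisq_diff,
               max(0, 2 * (inv$free_fit$loglik - inv$constrained_fit$loglik)),
               tolerance = 1e-10)
  expect_equal(inv$p_value, chi_square_tail(inv$chisq_diff, 12))
})

test_that("groups must be labeled and non-empty", {
  d <- simulate_lca(load_fixture("table2"), n_total = 50, seed = 1)
  cfg <- em_config(seed = 1, n_starts = 1, max_iter = 100, mad_tol = 1e-4)
  ungrouped <- response_matrix(d$items, item_names = d$item_names)
  expect_error(fit_multigroup(ungrouped, 2, TRUE, cfg), "no group labels")
  grp <- factor(rep("girl", 50), levels = c("girl", "boy"))
  d2 <- response_matrix(d$items, item_names = d$item_names, group = grp)
  expect_error(fit_multigroup(d2, 2, TRUE, cfg), "empty group")
})

test_that("the invariance test detects a non-invariant group", {
  # one group's rho shifted by 0.25 (up on two items, down on two — a shift
  # no re-weighting of shared classes can absorb), n = 1611
  base_rho <- rbind(c(0.10, 0.15, 0.10, 0.20),
                    c(0.45, 0.40, 0.50, 0.45),
                    c(0.85, 0.80, 0.75, 0.90))
  shifted <- pmin(pmax(base_rho +
    0.25 * matrix(c(1, 1, -1, -1), 3, 4, byrow = TRUE), 0.05), 0.95)
  fx <- make_fixture(
    multigroup_params(c("girl", "boy"),
                      rbind(c(0.35, 0.5, 0.15), c(0.45, 0.4, 0.15)),
                      list(base_rho, shifted), rho_invariant = FALSE,
                      item_names = c("neck", "shoulder", "upper_back",
                                     "low_back")),
    c(0.529, 0.471), name = "power_shift")
  rejections <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    d <- simulate_lca(fx, n_total = 1611, seed = 7500 + r, missing_rates = 0)
    p <- suppressWarnings(invariance_test(d, 3,
      em_config(seed = r, n_starts = 3, mad_tol = 1e-6,
                max_iter = 1500))$p_value)
    rejections <- rejections + (p < 0.05)
  }
  expect_gte(rejections, 0.9 * n_rep)
})

test_that("gender fixture refits reproduce the published major-class split", {
  fx <- load_fixture("table3_gender")
  d <- simulate_lca(fx, seed = 42)
  free <- fit_multigroup(d, 3, rho_invariant = FALSE,
                         config = em_config(seed = 7, n_starts = 8,
                                            mad_tol = 1e-7),
                         align_to = group_params(fx$params, 1))
  # girls' major class ~= 11.4%, boys' ~= 4.0% (sampling tolerance)
  expect_lt(abs(free$params$gamma["girl", "major"] - 0.114), 0.05)
  expect_lt(abs(free$params$gamma["boy", "major"] - 0.040), 0.05)
})
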