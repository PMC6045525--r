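test_that("pattern log probability matches hand-evaluated mixtures", {
  # uniform independent items: every complete pattern has probability 1/16
  unif <- lca_params(1, matrix(0.5, 1, 4))
  expect_equal(pattern_log_probability(unif, c(1, 0, 1, 0)), log(1 / 16))
  # full MAR marginalization: an all-missing pattern has probability 1
  expect_equal(pattern_log_probability(unif, rep(NA, 4)), 0)
  # two-class worked example: P(1,1) = 0.4*0.9*0.1 + 0.6*0.2*0.8 = 0.132
  expect_equal(pattern_log_probability(example_c2(), c(1, 1)), log(0.132))
  expect_error(pattern_log_probability(unif, c(1, 0)), "does not match J")
})

test_that("log-likelihood is additive and handles empty/missing records", {
  p <- example_c2()
  d2 <- response_matrix(rbind(c(1L, 1L), c(1L, 1L)))
  expect_equal(log_likelihood(p, d2), 2 * log(0.132))
  expect_warning(ll0 <- log_likelihood(p, response_matrix(matrix(0L, 0, 2))),
                 "empty")
  expect_equal(ll0, 0)
  # an all-missing record contributes exactly nothing
  d3 <- response_matrix(rbind(c(1L, 1L), c(NA, NA)))
  expect_equal(log_likelihood(p, d3), log(0.132))
})

test_that("likelihood and posterior agree with brute-force enumeration", {
  for (case in list(c(C = 2, J = 2, n = 20), c(C = 3, J = 4, n = 50),
                    c(C = 2, J = 3, n = 35), c(C = 3, J = 3, n = 50))) {
    p <- random_params(case["C"], case["J"], seed = 100 + sum(case))
    d <- random_data(case["n"], case["J"], seed = 200 + sum(case), miss = 0.15)
    expect_equal(log_likelihood(p, d),
                 brute_loglik(p$gamma, p$rho, d$items), tolerance = 1e-10)
    post <- posterior_probabilities(p, d)
    for (i in c(1L, nrow(d$items))) {
      expect_equal(unname(post$probs[i, ]),
                   brute_posterior(p$gamma, p$rho, d$items[i, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("complete-pattern probabilities always sum to one", {
  for (s in 1:5) {
    p <- random_params(C = 1 + s %% 3 + 1, J = 4, seed = s)
    pats <- all_patterns(4)
    total <- sum(exp(vapply(seq_len(nrow(pats)), function(i)
      pattern_log_probability(p, pats[i, ]), numeric(1))))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("posterior follows Bayes' theorem with deterministic tie-breaking", {
  p <- example_c2()
  d <- response_matrix(rbind(c(1L, 1L)))
  post <- posterior_probabilities(p, d)
  expect_equal(unname(post$probs[1, ]), c(0.036, 0.096) / 0.132,
               tolerance = 1e-12)
  expect_equal(post$assigned, 2L)
  # identical rho rows: the likelihood cancels, posterior equals gamma
  flat <- lca_params(c(0.3, 0.7), rbind(c(0.4, 0.6), c(0.4, 0.6)))
  post2 <- posterior_probabilities(flat, d)
  expect_equal(unname(post2$probs[1, ]), c(0.3, 0.7), tolerance = 1e-12)
  # degenerate prior: gamma mass on one class wins regardless of pattern
  deg <- lca_params(c(1, 0), rbind(c(0.2, 0.2), c(0.9, 0.9)))
  post3 <- posterior_probabilities(deg, d)
  expect_equal(unname(post3$probs[1, ]), c(1, 0))
  expect_equal(post3$assigned, 1L)
  # exact tie: equal gamma, identical rho rows -> lowest class index
  tie <- lca_params(c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(posterior_probabilities(tie, d)$assigned, 1L)
  # a record impossible under every class is an error naming the record
  imp <- lca_params(c(1, 0), rbind(c(1, 1), c(1, 1)))
  expect_error(posterior_probabilities(imp, response_matrix(rbind(c(0L, 0L)))),
               "record 1")
})
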