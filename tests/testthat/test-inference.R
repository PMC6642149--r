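test_that("Pearson chi-squared matches the hand-computed statistic", {
  # equal proportions: no signal
  eq <- chisq_proportions(matrix(c(15, 15, 30, 30), 2))
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1, tolerance = 1e-12)

  # [[10,20],[20,10]]: chi2 = 20/3 by the textbook formula
  out <- chisq_proportions(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(out$chi2, 20 / 3, tolerance = 1e-10)
  expect_equal(out$df, 1)

  # 2 x 4 table: df = 3
  out4 <- chisq_proportions(matrix(c(5, 10, 15, 20, 20, 15, 10, 5), 2,
                                   byrow = TRUE))
  expect_equal(out4$df, 3)

  expect_error(chisq_proportions(matrix(c(0, 0, 5, 5), 2)), "expected")
})

test_that("significance stars follow the printed thresholds strictly", {
  expect_identical(significance_stars(0.0005), "***")
  expect_identical(significance_stars(0.001), "**")   # not < 0.001
  expect_identical(significance_stars(0.009), "**")
  expect_identical(significance_stars(0.03), "*")
  expect_identical(significance_stars(0.05), "NS")    # not < 0.05
  expect_identical(significance_stars(0.2), "NS")
  expect_identical(significance_stars(c(1e-6, 0.04, 0.5)),
                   c("***", "*", "NS"))
})

test_that("exact multinomial test agrees with brute-force enumeration (k = 3)", {
  # independent oracle: direct double loop over all compositions
  brute <- function(obs, probs) {
    n <- sum(obs)
    p_obs <- dmultinom(obs, prob = probs)
    d_obs <- sqrt(sum((obs / n - probs)^2))
    pp <- dd <- 0
    for (i in 0:n) for (j in 0:(n - i)) {
      x <- c(i, j, n - i - j)
      px <- dmultinom(x, prob = probs)
      if (px <= p_obs * (1 + 1e-12)) pp <- pp + px
      if (sqrt(sum((x / n - probs)^2)) >= d_obs - 1e-12) dd <- dd + px
    }
    c(pp, dd)
  }
  cases <- list(list(obs = c(3, 1, 1), probs = rep(1, 3) / 3),
                list(obs = c(0, 2, 3), probs = c(0.5, 0.3, 0.2)),
                list(obs = c(10, 5, 5), probs = c(0.6, 0.2, 0.2)),
                list(obs = c(7, 7, 6), probs = rep(1, 3) / 3))
  for (cs in cases) {
    got <- exact_multinomial_test(cs$obs, cs$probs)
    want <- brute(cs$obs, cs$probs)
    expect_identical(got$method, "exact")
    expect_equal(got$p_prob, want[1], tolerance = 1e-12)
    expect_equal(got$p_distance, want[2], tolerance = 1e-12)
    expect_true(got$p_prob >= 0 && got$p_prob <= 1)
    expect_true(got$p_distance >= 0 && got$p_distance <= 1)
  }
})

test_that("exact multinomial test boundary properties hold", {
  # observed exactly at expectation: every outcome is at least as distant
  out <- exact_multinomial_test(c(10, 6, 4), c(0.5, 0.3, 0.2))
  expect_equal(out$p_distance, 1, tolerance = 1e-12)
  # k = 2 probability-ordering p equals the exact binomial test
  for (k in c(0, 3, 7, 10)) {
    got <- exact_multinomial_test(c(k, 10 - k), c(0.4, 0.6))
    want <- binom.test(k, 10, p = 0.4)$p.value
    expect_equal(got$p_prob, want, tolerance = 1e-10)
  }
  expect_error(exact_multinomial_test(c(1, 2), c(0.5, 0.4)), "sum to 1")
})

test_that("Monte-Carlo fallback is seeded and close to enumeration", {
  obs <- c(130, 60, 30)
  a <- exact_multinomial_test(obs, c(0.6, 0.25, 0.15), enumeration_cap = 100,
                              mc_draws = 2e4, seed = 7)
  b <- exact_multinomial_test(obs, c(0.6, 0.25, 0.15), enumeration_cap = 100,
                              mc_draws = 2e4, seed = 7)
  expect_identical(a, b)
  expect_identical(a$method, "monte_carlo")
  exact <- exact_multinomial_test(obs, c(0.6, 0.25, 0.15),
                                  enumeration_cap = 250)
  expect_equal(a$p_prob, exact$p_prob, tolerance = 0.02)
  expect_equal(a$p_distance, exact$p_distance, tolerance = 0.02)
})

test_that("reference residuals are indicator minus fitted probability", {
  d <- data.frame(y = c("a", "b", "b"))
  fit <- multinom_ml(y ~ 1, d, reference = "a")
  # intercept-only: fitted P(a) = 1/3 for every record
  expect_equal(unname(reference_residuals(fit)),
               c(1 - 1/3, -1/3, -1/3), tolerance = 1e-8)
  # choosing another category re-bases the residual
  expect_equal(unname(reference_residuals(fit, reference = "b")),
               c(-2/3, 1/3, 1/3), tolerance = 1e-8)
})
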