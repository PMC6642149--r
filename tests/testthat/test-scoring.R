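test_that("darkness scores assemble from the printed increments", {
  expect_identical(darkness_score("yellow", 0, 0), 0)
  expect_identical(darkness_score("brown", 0, 0), 0.6)
  expect_identical(darkness_score("pink", 0, 0), 0.3)
  expect_equal(darkness_score("pink", 5, 2), 0.71, tolerance = 1e-12)
  expect_equal(darkness_score("yellow", 1, 0), 0.07, tolerance = 1e-12)
  expect_equal(darkness_score("brown", 5, 4), 0.6 + 5 * 0.07 + 4 * 0.03,
               tolerance = 1e-12)
  # vectorised
  expect_equal(darkness_score(c("yellow", "pink"), c(3, 0), c(1, 0)),
               c(3 * 0.07 + 0.03, 0.3), tolerance = 1e-12)
  expect_error(darkness_score("pink", 0, 1), "n_fusions")
  expect_error(darkness_score("pink", 6, 0), "n_bands")
  expect_error(darkness_score("green", 0, 0), "colour")
})

test_that("darkness score is monotone in bands, fusions and colour ordering", {
  params <- darkness_params()
  for (cl in c("yellow", "pink", "brown")) {
    s <- darkness_score(rep(cl, 6), 0:5, 0)
    expect_true(all(diff(s) > 0))
  }
  s_fus <- darkness_score("pink", 5, 0:4)
  expect_true(all(diff(s_fus) > 0))
  for (b in 0:5) {
    expect_lte(darkness_score("yellow", b, 0), darkness_score("pink", b, 0))
    expect_lte(darkness_score("pink", b, 0), darkness_score("brown", b, 0))
  }
})

test_that("thermal binning uses half-open 0.25-degree bins with a 0.75 tail", {
  ts <- c(9.30, 9.50, 9.74, 9.75, 10.10, 10.40, 10.60, 10.90, 9.10)
  dk <- seq_along(ts) / 10
  bn <- bin_mean_darkness(ts, dk, start = 9.25, width = 0.25)
  bins <- bn$bins
  expect_equal(bins$lower[1], 9.25)
  expect_equal(bins$upper[1], 9.50)
  expect_equal(bins$centre[1], 9.375)
  # record at 9.30 is alone in bin 1; 9.50 opens bin 2 (half-open edges)
  expect_equal(bins$n[1], 1)
  expect_equal(bins$mean_darkness[1], 0.1)
  expect_equal(bins$n[2], 2)  # 9.50 and 9.74
  # tail bin merges the last three unit bins
  last <- nrow(bins)
  expect_equal(bins$upper[last] - bins$lower[last], 0.75, tolerance = 1e-9)
  # below-start record goes to the underflow bucket, not a bin
  expect_identical(bn$underflow, 9L)
  expect_equal(sum(bins$n), length(ts) - 1)
  # bins are contiguous
  expect_equal(bins$lower[-1], bins$upper[-last])
})

test_that("constant darkness gives flat bin means and zero standard error", {
  ts <- rep(seq(9.3, 11.1, by = 0.1), each = 3)
  bn <- bin_mean_darkness(ts, rep(0.4, length(ts)))
  full <- bn$bins[bn$bins$n > 0, ]
  expect_true(all(abs(full$mean_darkness - 0.4) < 1e-12))
  expect_true(all(full$se < 1e-12))
  flat <- fit_log_darkness(bn)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("the log-curve fit recovers a noiseless logarithmic law exactly", {
  centres <- seq(9.375, 11.875, by = 0.25)
  bins <- data.frame(centre = centres,
                     mean_darkness = 1.136 - 0.334 * log(centres),
                     n = 50)
  fit <- fit_log_darkness(bins)
  expect_equal(fit$slope, -0.334, tolerance = 1e-9)
  expect_equal(fit$intercept, 1.136, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$p, 1e-10)
  # empty bins are excluded; fewer than three non-empty bins is an error
  bins$n[2] <- 0
  expect_equal(fit_log_darkness(bins)$slope, -0.334, tolerance = 1e-9)
  expect_error(fit_log_darkness(bins[1:2, ]), "three")
})

test_that("Wilson intervals match the closed form and stay inside [0, 1]", {
  ci <- wilson_interval(0, 10)
  expect_equal(unname(ci[1]), 0)
  expect_gt(ci[2], 0)

  ci5 <- wilson_interval(5, 10)
  expect_equal(unname(ci5[1] + ci5[2]), 1, tolerance = 1e-12)  # symmetric about 0.5

  # closed-form oracle with z = 1.959964
  z <- 1.959964
  p <- 0.8; n <- 10
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  got <- wilson_interval(8, 10, 0.95)
  expect_equal(unname(got), c(lo, hi), tolerance = 1e-6)

  # independent implementation: score interval from prop.test without correction
  pt <- prop.test(8, 10, correct = FALSE)$conf.int
  expect_equal(unname(got), as.numeric(pt), tolerance = 1e-9)
  expect_error(wilson_interval(5, 0), "n")
})

test_that("UHI proportion curves split at the median and sum to one per bin", {
  L <- tiny_landscape()
  obs <- generate_observations(6000, L, uhi_only_truth(), seed = 13)
  cv <- uhi_proportion_curves(obs)
  expect_equal(cv$temperature_split, stats::median(obs$temperature))
  for (half in c("cold", "hot")) {
    tab <- cv[[half]]
    sums <- tapply(tab$proportion, tab$centre, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(tab$ci_lower >= 0 & tab$ci_upper <= 1))
    expect_true(all(tab$ci_lower <= tab$proportion + 1e-12 &
                      tab$proportion <= tab$ci_upper + 1e-12))
  }
  # a pink odds ratio below 1 per degree UHI: pink declines with UHI in the
  # cold half (straight-line fit over bins with decent sample size)
  cold_pink <- cv$cold[cv$cold$colour == "pink" & cv$cold$n >= 50, ]
  slope <- coef(lm(proportion ~ centre, cold_pink))["centre"]
  expect_lt(slope, 0)
})

test_that("all-yellow input yields degenerate proportions", {
  rec <- data.frame(uhi = runif(50, 0, 2), temperature = runif(50, 9, 11),
                    colour = "yellow")
  cv <- uhi_proportion_curves(rec)
  y <- cv$cold[cv$cold$colour == "yellow", ]
  expect_true(all(y$proportion == 1))
  p <- cv$cold[cv$cold$colour != "yellow", ]
  expect_true(all(p$proportion == 0))
})
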