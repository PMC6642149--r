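test_that("haversine distances match the closed form on a 6378137 m sphere", {
  R_earth <- 6378137
  d <- haversine_matrix(c(52, 52), c(4, 4))
  expect_equal(d, matrix(0, 2, 2))

  anti <- haversine_matrix(c(0, 0), c(0, 180))
  expect_equal(anti[1, 2], pi * R_earth, tolerance = 1 / (pi * R_earth))

  # direct formula oracle
  hav <- function(lat1, lon1, lat2, lon2) {
    to <- pi / 180
    a <- sin((lat2 - lat1) * to / 2)^2 +
      cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
    2 * R_earth * asin(sqrt(a))
  }
  d2 <- haversine_matrix(c(52, 52), c(4, 5))
  expect_equal(d2[1, 2], hav(52, 4, 52, 5), tolerance = 1e-6)
  expect_error(haversine_matrix(c(91, 0), c(0, 0)), "invalid")
})

test_that("haversine matrix is symmetric and satisfies the triangle inequality", {
  set.seed(14)
  for (i in 1:20) {
    lat <- runif(3, -80, 80)
    lon <- runif(3, -180, 180)
    d <- haversine_matrix(lat, lon)
    expect_equal(d, t(d), tolerance = 1e-9)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-6)
  }
})

test_that("Moran's I equals a brute-force double loop on a hand-built case", {
  x <- c(1.2, -0.7, 0.4, 2.1)
  w <- matrix(c(0, 1, 0.5, 0,
                1, 0, 0.2, 0.3,
                0.5, 0.2, 0, 0.9,
                0, 0.3, 0.9, 0), 4, 4, byrow = TRUE)
  got <- morans_i(x, w)
  n <- 4; z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  I_brute <- (n / sum(w)) * num / sum(z^2)
  expect_equal(got$I, I_brute, tolerance = 1e-12)
  expect_equal(got$expected, -1 / 3, tolerance = 1e-15)
  expect_gt(got$variance, 0)
})

test_that("Moran's I moments and p agree with the ape implementation", {
  skip_if_not_installed("ape")
  set.seed(21)
  n <- 40
  x <- rnorm(n)
  d <- as.matrix(dist(cbind(runif(n), runif(n))))
  w <- 1 / d; diag(w) <- 0
  # ape row-standardises internally; feed it pre-standardised weights so both
  # implementations see the same matrix
  wr <- w / rowSums(w)
  got <- morans_i(x, wr, null = "randomisation")
  ref <- ape::Moran.I(x, wr, scaled = FALSE, alternative = "two.sided")
  expect_equal(got$I, ref$observed, tolerance = 1e-10)
  expect_equal(got$expected, ref$expected, tolerance = 1e-12)
  expect_equal(got$sd, ref$sd, tolerance = 1e-8)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
})

test_that("Moran's I is invariant to shifts, scaling and weight symmetrisation", {
  set.seed(33)
  x <- rnorm(25)
  d <- as.matrix(dist(cbind(runif(25), runif(25))))
  w <- 1 / d; diag(w) <- 0
  base <- morans_i(x, w)$I
  expect_equal(morans_i(x + 100, w)$I, base, tolerance = 1e-12)
  expect_equal(morans_i(3.7 * x, w)$I, base, tolerance = 1e-12)
  expect_equal(morans_i(x, (w + t(w)) / 2)$I, base, tolerance = 1e-12)
})

test_that("degenerate Moran inputs raise errors", {
  w <- matrix(1, 3, 3); diag(w) <- 0
  expect_error(morans_i(c(2, 2, 2), w), "zero variance")
  expect_error(morans_i(c(1, 2, 3), matrix(0, 3, 3)), "all weights are zero")
  expect_error(morans_i(c(1, 2), matrix(0, 2, 2)), "three")
  wneg <- w; wneg[1, 2] <- -1
  expect_error(morans_i(c(1, 2, 3), wneg), "non-negative")
  wd <- w; diag(wd) <- 1
  expect_error(morans_i(c(1, 2, 3), wd), "diagonal")
})

test_that("coincident points get zero or max inverse-distance weight by policy", {
  d <- matrix(c(0, 0, 1000,
                0, 0, 1000,
                1000, 1000, 0), 3, byrow = TRUE)
  w0 <- inverse_distance_weights(d, "zero")
  expect_equal(w0[1, 2], 0)
  expect_equal(w0[1, 3], 1e-3)
  wm <- inverse_distance_weights(d, "max")
  expect_equal(wm[1, 2], 1e-3)
})

test_that("a single correlogram class reproduces global binary-weight Moran's I", {
  set.seed(5)
  n <- 30
  lat <- 52 + runif(n, 0, 0.01)
  lon <- 4 + runif(n, 0, 0.01)
  x <- rnorm(n)
  cg <- correlogram(x, lat, lon, increment_m = 5e5, n_perm = 99)
  expect_equal(nrow(cg), 1)
  wb <- (haversine_matrix(lat, lon) > 0) * 1
  diag(wb) <- 0
  expect_equal(cg$I[1], morans_i(x, wb)$I, tolerance = 1e-10)
  expect_equal(cg$n_pairs[1], n * (n - 1) / 2)
})

test_that("short-range correlated fields light up only the first correlogram class", {
  first_sig <- later_sig <- logical(0)
  for (s in 1:8) {
    set.seed(400 + s)
    n <- 250
    # clustered points over a ~3 km square
    lat <- 52 + runif(n, 0, 0.03)
    lon <- 4 + runif(n, 0, 0.05)
    x <- as.vector(snailcline:::.correlated_fields(lat, lon, sd = 1,
                                                   range_m = 400, k = 1)) +
      rnorm(n, 0, 0.3)
    cg <- correlogram(x, lat, lon, increment_m = 500, n_perm = 199,
                      seed = s, max_distance_m = 2500)
    first_sig <- c(first_sig, cg$I[1] > -1 / (n - 1) && cg$p[1] < 0.05)
    # by 2-2.5 km the exponential correlation (range 400 m) is ~exp(-5.6);
    # far classes may drift significantly *negative* (centred residuals sum
    # to zero), so test for positive similarity only
    later_sig <- c(later_sig, isTRUE(cg$I[5] > -1 / (n - 1) && cg$p[5] < 0.05))
  }
  expect_gte(sum(first_sig), 7)      # the genuine 400 m signal
  expect_lte(sum(later_sig), 2)      # positive similarity gone by 2 km
})

test_that("spatial diagnostics bundle global I, correlogram and weight spec", {
  L <- tiny_landscape()
  obs <- generate_observations(250, L, clean_truth(), seed = 17)
  fit <- fit_multinomial(obs, reference = "yellow")
  di <- spatial_diagnostics(fit, obs, correlogram_classes = 3, seed = 2)
  expect_s3_class(di$global, "morans_i")
  expect_equal(di$global$expected, -1 / (nrow(obs) - 1))
  expect_equal(nrow(di$correlogram), 3)
  expect_identical(di$weight_spec$type, "inverse_distance")
  paths <- file.path(withr::local_tempdir(), c("g.csv", "c.csv"))
  write_spatial_diagnostics(di, paths[1], paths[2])
  expect_true(all(file.exists(paths)))
})
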