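test_that("identity misclassification reports the latent colour verbatim", {
  L <- tiny_landscape()
  obs <- generate_observations(400, L, clean_truth(), seed = 2)
  expect_identical(obs$colour, obs$latent_colour)
  expect_equal(nrow(obs), 400)
  expect_false(any(duplicated(obs$record_id)))
})

test_that("misclassification and GPS-failure artifacts appear when configured", {
  L <- tiny_landscape()
  tr <- truth_model(gps_failure_rate = 0.3, spatial_noise_sd = 0)
  obs <- generate_observations(600, L, tr, seed = 3)
  # default confusion keeps ~94% on the diagonal
  agree <- mean(obs$colour == obs$latent_colour)
  expect_gt(agree, 0.88)
  expect_lt(agree, 0.99)
  dup_coord <- obs$latitude[-1] == obs$latitude[-600] &
    obs$longitude[-1] == obs$longitude[-600]
  expect_gt(mean(dup_coord), 0.2)

  none <- generate_observations(600, L, clean_truth(), seed = 3)
  dup0 <- none$latitude[-1] == none$latitude[-600] &
    none$longitude[-1] == none$longitude[-600]
  expect_identical(sum(dup0), 0L)
})

test_that("observation sampling is deterministic and needs observer centres", {
  L <- tiny_landscape()
  a <- generate_observations(150, L, clean_truth(), seed = 9)
  b <- generate_observations(150, L, clean_truth(), seed = 9)
  expect_identical(a, b)
  expect_error(generate_observations(10, L, clean_truth(),
                                     observer_centres = data.frame(lon = numeric(0),
                                                                   lat = numeric(0))),
               "non-empty")
})

test_that("a pink UHI odds ratio below one depresses pink across UHI terciles", {
  L <- tiny_landscape()
  obs <- generate_observations(20000, L, uhi_only_truth(), seed = 4)
  terc <- cut(obs$uhi, stats::quantile(obs$uhi, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  p_pink <- tapply(obs$latent_colour == "pink", terc, mean)
  expect_true(all(diff(p_pink) < 0))
})

test_that("brown snails are almost always unbanded", {
  L <- tiny_landscape()
  obs <- generate_observations(4000, L, clean_truth(), seed = 6)
  brown <- obs[obs$latent_colour == "brown" & !is.na(obs$banding_code), ]
  unb <- mean(brown$banding_code == "00000")
  expect_gt(unb, 0.9)
})

test_that("spatial logit noise induces detectable residual autocorrelation", {
  # Dense neighbourhood sampling of the 500 m field: 30 tight observer
  # clusters (sd 250 m) over a 100 x 80 km region, a strong field (sd 1),
  # and a main-effects colour fit whose reference residuals are screened by
  # inverse-distance Moran's I.
  L <- tiny_landscape()
  set.seed(1)
  centres <- data.frame(lon = runif(30, 4.05, 4.95),
                        lat = runif(30, 51.65, 52.35), weight = 1)
  screen <- function(noise_sd, s) {
    truth <- clean_truth(spatial_noise_sd = noise_sd)
    obs <- generate_observations(2500, L, truth, observer_centres = centres,
                                 seed = 600 + s, cluster_sd_km = 0.25)
    fit <- suppressWarnings(
      multinom_ml(colour ~ day_number + uhi + temperature + dry_days, obs,
                  reference = "yellow"))
    w <- inverse_distance_weights(
      haversine_matrix(obs$latitude, obs$longitude))
    g <- morans_i(reference_residuals(fit), w)
    g$I > 0 && g$p < 0.05
  }
  with_noise <- vapply(1:10, function(s) screen(1.0, s), TRUE)
  expect_gte(sum(with_noise), 9)
  without <- vapply(1:10, function(s) screen(0, s), TRUE)
  expect_lte(sum(without), 1)
})

test_that("discovery-time generator honours hazard limits and censoring", {
  fast <- generate_detectability_experiment(c(yellow = 50), c(yellow = 1e6),
                                            seed = 1)
  expect_true(all(fast$found))
  expect_true(all(fast$time_s < 0.01))

  slow <- generate_detectability_experiment(c(yellow = 50), c(yellow = 1e-9),
                                            seed = 1)
  expect_true(all(!slow$found))
  expect_true(all(slow$time_s == 600))

  mixed <- generate_detectability_experiment(
    c(yellow = 30, pink = 20, brown = 10),
    c(yellow = 0.01, pink = 0.01, brown = 0.01), seed = 2)
  expect_equal(nrow(mixed), 60)
  expect_true(all(mixed$time_s > 0 & mixed$time_s <= 600))
  expect_error(generate_detectability_experiment(c(yellow = 5), c(yellow = 0)),
               "discovery_hazards")
})

test_that("equal hazards recover the true colour mix among found shells", {
  # Monte-Carlo: with one shared hazard the found-shell composition at the
  # search limit converges to the laid-out composition
  devs <- vapply(1:40, function(s) {
    ev <- generate_detectability_experiment(
      c(yellow = 21, pink = 15, brown = 6),
      c(yellow = 0.012, pink = 0.012, brown = 0.012), seed = s)
    pb <- proportions_by_time(ev, checkpoints = c(150, 600))
    last <- pb[pb$checkpoint_s == 600, ]
    max(abs(last$proportion - last$true_proportion))
  }, 1)
  expect_lt(mean(devs), 0.05)
})
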