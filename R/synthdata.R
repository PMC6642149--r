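# Run `code` under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# kilometre offsets of lon/lat from a reference point (local equirectangular)
.km_offsets <- function(lon, lat, lon0, lat0) {
  list(dx = (lon - lon0) * 111.320 * cos(lat0 * pi / 180),
       dy = (lat - lat0) * 110.574)
}

# smooth random surface: coarse iid normal grid, bilinearly upsampled
.smooth_noise <- function(nr, nc, sd, coarse = 12L) {
  if (sd <= 0) return(matrix(0, nr, nc))
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  yi <- seq(1, coarse, length.out = nr)
  xi <- seq(1, coarse, length.out = nc)
  tmp <- apply(g, 2, function(col) stats::approx(seq_len(coarse), col, yi)$y)
  sd * t(apply(tmp, 1, function(row) stats::approx(seq_len(coarse), row, xi)$y))
}

#' Configuration for the synthetic landscape
#'
#' Defaults emulate a Netherlands-like study region: a lon 3.3-7.2 / lat
#' 50.75-53.55 degree extent, eight city kernels with peak urban-heat-island
#' values up to 2 degrees C, a north-south mean-temperature gradient around a
#' 10 degree C median, and a west-east dry-day gradient (drier inland).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` degrees (x = lon, y = lat).
#' @param cell_size grid cell edge, degrees.
#' @param cities data.frame with columns `name, lon, lat, peak_uhi, radius_km,
#'   core_km, green_km`: Gaussian UHI kernel peak/scale and the radii of the
#'   urban-grey core and urban-green ring.
#' @param t_south,temp_gradient temperature at the southern edge (degC) and
#'   its decrease per degree latitude northward.
#' @param temp_noise_sd sd of the smooth temperature noise surface (degC).
#' @param dry_west,dry_gradient dry days at the western edge and increase per
#'   degree longitude eastward (days/year).
#' @param dry_noise_sd sd of the smooth dry-day noise surface.
#' @param uhi_texture_sd relative sd of street-scale (~2 km) multiplicative
#'   texture on the UHI surface, emulating the neighbourhood-level variation
#'   in soil sealing and vegetation that a fine-resolution UHI raster shows.
#'   The default 0 keeps the surface a pure sum of city kernels.
#' @param nature_prob probability that a non-urban coarse tile is `nature`
#'   rather than `agricultural`.
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(3.3, 7.2, 50.75, 53.55),
                             cell_size = 0.01,
                             cities = NULL,
                             t_south = 11.2, temp_gradient = 0.55,
                             temp_noise_sd = 0.15,
                             dry_west = 160, dry_gradient = 7,
                             dry_noise_sd = 1.5,
                             uhi_texture_sd = 0,
                             nature_prob = 0.45) {
  if (is.null(cities)) {
    cities <- data.frame(
      name = c("amsterdam", "rotterdam", "den_haag", "utrecht",
               "eindhoven", "groningen", "nijmegen", "maastricht"),
      lon  = c(4.90, 4.48, 4.30, 5.12, 5.47, 6.57, 5.85, 5.69),
      lat  = c(52.37, 51.92, 52.08, 52.09, 51.44, 53.22, 51.84, 50.85),
      peak_uhi  = c(2.0, 1.9, 1.7, 1.6, 1.4, 1.2, 1.2, 1.1),
      radius_km = c(6, 6, 5, 5, 5, 4, 4, 4),
      core_km   = c(4, 4, 3.5, 3, 3, 2.5, 2.5, 2.5),
      green_km  = c(6.5, 6.5, 5.5, 5, 5, 4, 4, 4),
      stringsAsFactors = FALSE)
  }
  structure(list(extent = extent, cell_size = cell_size, cities = cities,
                 t_south = t_south, temp_gradient = temp_gradient,
                 temp_noise_sd = temp_noise_sd, dry_west = dry_west,
                 dry_gradient = dry_gradient, dry_noise_sd = dry_noise_sd,
                 uhi_texture_sd = uhi_texture_sd, nature_prob = nature_prob),
            class = "landscape_config")
}

#' Generate a synthetic environmental landscape
#'
#' Builds the four gridded layers from a [landscape_config()]: UHI as a sum
#' of Gaussian kernels around the city centres, temperature linear in
#' latitude (colder north) plus smooth noise, dry days linear in longitude
#' plus smooth noise, and land use as urban-grey city cores, urban-green
#' rings, and a random coarse tiling of nature/agricultural elsewhere.
#' Deterministic given `seed`.
#'
#' @param config a [landscape_config()].
#' @param seed integer RNG seed.
#' @return an [env_layers()] object; the config (including city table) is
#'   attached as attribute `"config"`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  if (config$cell_size <= 0) stop("cell_size must be positive")
  .with_seed(seed, {
    e <- config$extent; cs <- config$cell_size
    nc <- as.integer(round((e[2] - e[1]) / cs))
    nr <- as.integer(round((e[4] - e[3]) / cs))
    lon_c <- e[1] + (seq_len(nc) - 0.5) * cs
    lat_c <- e[4] - (seq_len(nr) - 0.5) * cs  # row 1 = north
    lon_m <- matrix(lon_c, nr, nc, byrow = TRUE)
    lat_m <- matrix(lat_c, nr, nc)

    uhi <- matrix(0, nr, nc)
    dist_city <- matrix(Inf, nr, nc)   # km to nearest city centre
    core <- matrix(FALSE, nr, nc)
    green <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(config$cities))) {
      ci <- config$cities[i, ]
      o <- .km_offsets(lon_m, lat_m, ci$lon, ci$lat)
      d <- sqrt(o$dx^2 + o$dy^2)
      uhi <- uhi + ci$peak_uhi * exp(-d^2 / (2 * ci$radius_km^2))
      dist_city <- pmin(dist_city, d)
      core <- core | d < ci$core_km
      green <- green | d < ci$green_km
    }

    if (!is.null(config$uhi_texture_sd) && config$uhi_texture_sd > 0)
      uhi <- uhi * pmax(0, 1 + .smooth_noise(nr, nc, config$uhi_texture_sd,
                                             coarse = max(2L, nr %/% 2L)))

    temperature <- config$t_south - config$temp_gradient * (lat_m - e[3]) +
      .smooth_noise(nr, nc, config$temp_noise_sd)
    dry_days <- config$dry_west + config$dry_gradient * (lon_m - e[1]) +
      .smooth_noise(nr, nc, config$dry_noise_sd)

    # coarse (10-cell) tiles of nature vs agricultural outside the cities
    bi <- ceiling(row(uhi) / 10); bj <- ceiling(col(uhi) / 10)
    tiles <- matrix(stats::runif(max(bi) * max(bj)) < config$nature_prob,
                    max(bi), max(bj))
    landuse <- ifelse(tiles[cbind(as.vector(bi), as.vector(bj))],
                      2L, 1L)  # nature / agricultural
    landuse[green] <- 3L
    landuse[core] <- 4L
    out <- env_layers(uhi, temperature, dry_days,
                      matrix(landuse, nr, nc), extent = e, cell_size = cs)
    attr(out, "config") <- config
    out
  })
}

# design-matrix term names shared by the truth model and the fitted models
.cline_terms <- c("(Intercept)", "day_number", "uhi", "temperature",
                  "dry_days", "uhi:temperature", "uhi:dry_days",
                  "temperature:dry_days", "uhi:temperature:dry_days")

.coef_matrix <- function(odds, outcomes) {
  m <- log(matrix(odds, nrow = length(.cline_terms),
                  dimnames = list(.cline_terms, outcomes)))
  m
}

#' The multinomial truth model behind the synthetic observations
#'
#' Coefficients are stored on the log-odds scale for *centred* covariates;
#' `exp()` of each entry is the corresponding odds ratio. The default colour
#' coefficients encode field-realistic odds ratios for an urban-grey colour
#' model (yellow
#' reference): pink intercept 0.395, day 1.001, UHI 0.719, temperature 0.753,
#' dry days 1.029, UHI:temp 1.758, UHI:dry 1.039, temp:dry 1.030, three-way
#' 1.009; brown intercept 0.219, day 1.004, UHI 0.844, temperature 0.574,
#' dry days 0.962, UHI:temp 1.917, UHI:dry 1.008, temp:dry 1.017, three-way
#' 0.949. Banding coefficients (per colour, unbanded reference) default to
#' values with the same qualitative structure: UHI raises mid- and
#' three-banded but not five-banded odds, temperature lowers unbanded and
#' five-banded, dry days favour unbanded.
#'
#' @param colour_coefs 9 x 2 matrix (rows [.cline_terms], columns
#'   `pink`, `brown`) of log-odds vs the yellow reference.
#' @param banding_coefs list with elements `yellow` and `pink`, each a 9 x 3
#'   matrix (columns `midbanded`, `three_banded`, `five_banded`) of log-odds
#'   vs the unbanded reference.
#' @param misclassification 3 x 3 row-stochastic colour confusion matrix
#'   (rows = true colour, columns = reported colour). The default keeps 94%
#'   of records on the diagonal, matching photograph-vs-specimen agreement.
#' @param gps_failure_rate probability that a record inherits the previous
#'   record's coordinates (failed GPS fix), in \[0, 1\].
#' @param spatial_noise_sd sd of the short-range spatially correlated
#'   perturbation added to each non-reference colour logit.
#' @param spatial_range_m range (metres) of the exponential correlation of
#'   that perturbation.
#' @param brown_unbanded_prob probability that a brown snail is unbanded.
#' @param fusion_prob probability that a banded shell shows a band fusion.
#' @param apical_prob probability a photograph is taken from an apical angle.
#' @param dark_lip_prob probability the dark lip is visible on the photo.
#' @return a list of class `truth_model`.
#' @export
truth_model <- function(colour_coefs = NULL, banding_coefs = NULL,
                        misclassification = NULL,
                        gps_failure_rate = 0.04,
                        spatial_noise_sd = 0.5, spatial_range_m = 500,
                        brown_unbanded_prob = 0.96, fusion_prob = 0.15,
                        apical_prob = 0.12, dark_lip_prob = 0.985) {
  if (is.null(colour_coefs))
    colour_coefs <- .coef_matrix(
      c(0.395, 1.001, 0.719, 0.753, 1.029, 1.758, 1.039, 1.030, 1.009,   # pink
        0.219, 1.004, 0.844, 0.574, 0.962, 1.917, 1.008, 1.017, 0.949),  # brown
      c("pink", "brown"))
  if (is.null(banding_coefs))
    banding_coefs <- list(
      yellow = .coef_matrix(
        c(0.55, 1.001, 1.495, 1.35, 0.980, 1, 1, 1, 1,    # midbanded
          0.74, 1.001, 1.645, 1.42, 0.985, 1, 1, 1, 1,    # three_banded
          1.10, 1.000, 0.750, 0.64, 0.975, 1, 1, 1, 1),   # five_banded
        c("midbanded", "three_banded", "five_banded")),
      pink = .coef_matrix(
        c(0.37, 1.000, 1.05, 0.90, 0.970, 1, 1, 1, 1,
          0.82, 1.000, 1.40, 1.10, 0.970, 1, 1, 1, 1,
          1.35, 1.000, 0.95, 0.82, 0.970, 1, 1, 1, 1),
        c("midbanded", "three_banded", "five_banded")))
  if (is.null(misclassification)) {
    misclassification <- matrix(0.03, 3, 3,
                                dimnames = list(c("yellow", "pink", "brown"),
                                                c("yellow", "pink", "brown")))
    diag(misclassification) <- 0.94
  }
  stopifnot(nrow(colour_coefs) == length(.cline_terms),
            all(abs(rowSums(misclassification) - 1) < 1e-12),
            gps_failure_rate >= 0, gps_failure_rate <= 1)
  structure(list(colour_coefs = colour_coefs, banding_coefs = banding_coefs,
                 misclassification = misclassification,
                 gps_failure_rate = gps_failure_rate,
                 spatial_noise_sd = spatial_noise_sd,
                 spatial_range_m = spatial_range_m,
                 brown_unbanded_prob = brown_unbanded_prob,
                 fusion_prob = fusion_prob, apical_prob = apical_prob,
                 dark_lip_prob = dark_lip_prob),
            class = "truth_model")
}

# build the centred 9-column design used by both truth model and fits
.cline_design <- function(day_number, uhi, temperature, dry_days) {
  d <- scale(day_number, scale = FALSE)[, 1]
  u <- scale(uhi, scale = FALSE)[, 1]
  t <- scale(temperature, scale = FALSE)[, 1]
  y <- scale(dry_days, scale = FALSE)[, 1]
  cbind(`(Intercept)` = 1, day_number = d, uhi = u, temperature = t,
        dry_days = y, `uhi:temperature` = u * t, `uhi:dry_days` = u * y,
        `temperature:dry_days` = t * y, `uhi:temperature:dry_days` = u * t * y)
}

# n x k matrix of spatially correlated fields (exponential covariance) at the
# given locations; exact via Cholesky, so O(n^3) — intended for n up to a few
# thousand.
.correlated_fields <- function(latitude, longitude, sd, range_m, k) {
  n <- length(latitude)
  if (sd <= 0) return(matrix(0, n, k))
  d <- geosphere::distm(cbind(longitude, latitude),
                        fun = geosphere::distHaversine)
  cv <- sd^2 * exp(-d / range_m)
  diag(cv) <- diag(cv) + 1e-8
  L <- chol(cv)
  crossprod(L, matrix(stats::rnorm(n * k), n, k))
}

.rcat <- function(prob_matrix) {
  # one draw per row from the categorical distribution given by each row
  cum <- t(apply(prob_matrix, 1, cumsum))
  cum[, ncol(cum)] <- 1
  u <- stats::runif(nrow(prob_matrix))
  1L + rowSums(u > cum)
}

.banding_code_for <- function(main_type, fused) {
  switch(main_type,
         unbanded = "00000",
         midbanded = "00300",
         three_banded = if (fused) sample(c("00(34)5", "003(45)", "00(345)"), 1L)
                        else "00345",
         five_banded = if (fused) sample(c("(12)345", "12(34)5", "123(45)", "(12345)"), 1L)
                       else "12345")
}

#' Sample synthetic morph observations from the truth model
#'
#' Emulates the citizen-science observation process: record locations are
#' drawn from a mixture of Gaussian clusters around observer centres
#' (observers concentrate in towns), day numbers uniform over the season,
#' covariates extracted from the landscape at each point, the latent shell
#' colour from the truth model's multinomial logit at the centred covariates
#' (plus an optional short-range spatially correlated logit perturbation),
#' banding conditional on the latent colour, reported colour through the
#' misclassification matrix, and a fraction of records inherit the previous
#' record's coordinates (failed GPS fix).
#'
#' @param n number of records (>= 1).
#' @param layers an [env_layers()] landscape.
#' @param truth a [truth_model()].
#' @param observer_centres data.frame with columns `lon`, `lat` and optional
#'   `weight`; default = the landscape's city centres (weight 3) plus a
#'   regular lattice of rural centres (weight 1).
#' @param seed integer RNG seed.
#' @param season_length last day of the season (default 198 = 15 October).
#' @param cluster_sd_km sd of the Gaussian scatter around observer centres.
#' @return a `shell_records` data.frame with additional columns
#'   `latent_colour`, `uhi`, `temperature`, `dry_days`, `habitat` (sampled at
#'   the *reported* coordinates) and attribute `"truth"`.
#' @export
generate_observations <- function(n, layers, truth = truth_model(),
                                  observer_centres = NULL, seed = 1L,
                                  season_length = 198L, cluster_sd_km = 4) {
  stopifnot(n >= 1)
  e <- layers$extent
  if (is.null(observer_centres)) {
    cfg <- attr(layers, "config")
    cities <- if (!is.null(cfg)) cfg$cities[, c("lon", "lat")] else NULL
    rural <- expand.grid(lon = seq(e[1] + 0.3, e[2] - 0.3, length.out = 5),
                         lat = seq(e[3] + 0.3, e[4] - 0.3, length.out = 5))
    observer_centres <- rbind(
      if (!is.null(cities)) cbind(cities, weight = 3),
      cbind(rural, weight = 1))
  }
  if (nrow(observer_centres) == 0L) stop("observer_centres must be non-empty")
  w <- if ("weight" %in% names(observer_centres)) observer_centres$weight else
    rep(1, nrow(observer_centres))

  .with_seed(seed, {
    # rejection-sample cluster offsets until inside the extent
    lat <- lon <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      ci <- sample.int(nrow(observer_centres), length(todo), replace = TRUE,
                       prob = w)
      lo <- observer_centres$lon[ci] +
        stats::rnorm(length(todo), 0, cluster_sd_km / (111.32 * cos(mean(e[3:4]) * pi / 180)))
      la <- observer_centres$lat[ci] +
        stats::rnorm(length(todo), 0, cluster_sd_km / 110.574)
      ok <- lo >= e[1] & lo <= e[2] & la >= e[3] & la <= e[4]
      lon[todo[ok]] <- lo[ok]; lat[todo[ok]] <- la[ok]
      todo <- todo[!ok]
    }
    day_number <- sample.int(season_length, n, replace = TRUE)

    env <- sample_layers(layers, lat, lon)
    X <- .cline_design(day_number, env$uhi, env$temperature, env$dry_days)
    eta <- X %*% truth$colour_coefs +
      .correlated_fields(lat, lon, truth$spatial_noise_sd,
                         truth$spatial_range_m, ncol(truth$colour_coefs))
    pr <- cbind(1, exp(eta))
    pr <- pr / rowSums(pr)
    colours <- c("yellow", colnames(truth$colour_coefs))
    latent <- colours[.rcat(pr)]

    # banding conditional on latent colour
    main_type <- character(n)
    for (cl in c("yellow", "pink")) {
      i <- which(latent == cl)
      if (!length(i)) next
      B <- truth$banding_coefs[[cl]]
      pe <- cbind(1, exp(X[i, , drop = FALSE] %*% B))
      pe <- pe / rowSums(pe)
      main_type[i] <- c("unbanded", colnames(B))[.rcat(pe)]
    }
    i <- which(latent == "brown")
    if (length(i)) {
      ub <- stats::runif(length(i)) < truth$brown_unbanded_prob
      main_type[i] <- ifelse(ub, "unbanded",
                             sample(c("midbanded", "three_banded", "five_banded"),
                                    length(i), replace = TRUE))
    }
    fused <- stats::runif(n) < truth$fusion_prob
    banding_code <- vapply(seq_len(n),
                           function(j) .banding_code_for(main_type[j], fused[j]), "")

    reported <- vapply(latent, function(cl) {
      sample(colnames(truth$misclassification), 1L,
             prob = truth$misclassification[cl, ])
    }, "")

    view <- ifelse(stats::runif(n) < truth$apical_prob, "apical", "lateral")
    banding_code[view == "apical"] <- NA_character_
    dark_lip <- stats::runif(n) < truth$dark_lip_prob

    # failed GPS fixes: inherit the previous record's coordinates
    fail <- which(stats::runif(n) < truth$gps_failure_rate)
    fail <- fail[fail > 1L]
    lat[fail] <- lat[fail - 1L]; lon[fail] <- lon[fail - 1L]

    env <- sample_layers(layers, lat, lon)  # covariates at reported coords
    out <- data.frame(record_id = sprintf("S%06d", seq_len(n)),
                      latitude = lat, longitude = lon,
                      day_number = day_number, colour = unname(reported),
                      banding_code = banding_code, view = view,
                      dark_lip = dark_lip, latent_colour = latent,
                      uhi = env$uhi, temperature = env$temperature,
                      dry_days = env$dry_days, habitat = env$habitat,
                      stringsAsFactors = FALSE)
    out <- shell_records(out)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a shell-discovery (detectability) experiment
#'
#' Marked empty shells are scattered and volunteers search for them; the time
#' to discovery of each shell is recorded, censored at the search limit.
#' Discovery times are exponential with a per-colour hazard (constant-hazard
#' search).
#'
#' @param true_counts named integer vector: shells laid out per colour.
#' @param discovery_hazards named numeric vector (per second), same names,
#'   all > 0.
#' @param censor_time search limit in seconds (default 600 = ten minutes).
#' @param seed integer RNG seed.
#' @param volunteer label stored in the `volunteer` column.
#' @return data.frame `shell_id`, `colour`, `volunteer`, `time_s`, `found`.
#' @export
generate_detectability_experiment <- function(true_counts, discovery_hazards,
                                              censor_time = 600, seed = 1L,
                                              volunteer = "V1") {
  stopifnot(all(discovery_hazards > 0),
            all(names(true_counts) %in% names(discovery_hazards)))
  .with_seed(seed, {
    colour <- rep(names(true_counts), times = true_counts)
    t <- stats::rexp(length(colour), rate = discovery_hazards[colour])
    found <- t < censor_time
    data.frame(shell_id = sprintf("E%03d", seq_along(colour)),
               colour = colour, volunteer = volunteer,
               time_s = pmin(t, censor_time), found = found,
               stringsAsFactors = FALSE)
  })
}
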