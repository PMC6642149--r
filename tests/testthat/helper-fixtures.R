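# Shared fixtures, all built in code.

# A small fast landscape: one city on a known cell centre, 0.02-degree cells.
tiny_landscape <- function(seed = 11L, peak = 2, cities = NULL) {
  if (is.null(cities))
    cities <- data.frame(name = "city", lon = 4.51, lat = 52.01,
                         peak_uhi = peak, radius_km = 6,
                         core_km = 4, green_km = 6.5)
  cfg <- landscape_config(extent = c(4.0, 5.0, 51.6, 52.4),
                          cell_size = 0.02, cities = cities)
  generate_landscape(cfg, seed = seed)
}

# Truth model with a clean observation process (no reporting noise), used
# wherever a test targets the sampling model itself.
clean_truth <- function(...) {
  args <- list(misclassification = identity_confusion(),
               gps_failure_rate = 0, spatial_noise_sd = 0,
               apical_prob = 0, dark_lip_prob = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(truth_model, args)
}

identity_confusion <- function() {
  m <- diag(3)
  dimnames(m) <- list(c("yellow", "pink", "brown"),
                      c("yellow", "pink", "brown"))
  m
}

# Truth whose only non-zero colour slope is the UHI effect on pink
# (odds ratio 0.719 per degree C), for monotonicity-style checks.
uhi_only_truth <- function(...) {
  cc <- matrix(0, 9, 2, dimnames = list(
    c("(Intercept)", "day_number", "uhi", "temperature", "dry_days",
      "uhi:temperature", "uhi:dry_days", "temperature:dry_days",
      "uhi:temperature:dry_days"),
    c("pink", "brown")))
  cc["(Intercept)", ] <- log(c(0.395, 0.219))
  cc["uhi", "pink"] <- log(0.719)
  clean_truth(colour_coefs = cc, ...)
}

# Observer centres for the spatial-correction experiment: the city centre
# plus four neighbourhood centres 3 km out, per city (weight 2 each).
neighbourhood_centres <- function(cities, off_km = 3, weight = 2) {
  do.call(rbind, lapply(seq_len(nrow(cities)), function(i) {
    dlat <- off_km / 110.574
    dlon <- off_km / (111.32 * cos(cities$lat[i] * pi / 180))
    data.frame(lon = cities$lon[i] + c(0, dlon, -dlon, 0, 0),
               lat = cities$lat[i] + c(0, 0, 0, dlat, -dlat),
               weight = weight)
  }))
}

# Minimal record table builder
make_records <- function(n = 4, latitude = 52, longitude = 5,
                         day_number = 10, colour = "yellow",
                         banding_code = "00000", view = "lateral",
                         dark_lip = TRUE, record_id = NULL) {
  if (is.null(record_id)) record_id <- sprintf("R%03d", seq_len(n))
  shell_records(data.frame(record_id = record_id, latitude = latitude,
                           longitude = longitude, day_number = day_number,
                           colour = colour, banding_code = banding_code,
                           view = view, dark_lip = dark_lip,
                           stringsAsFactors = FALSE))
}
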