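#' Default run configuration
#'
#' Configuration for a full synthetic run: simulation seed and size, season
#' cut-off, binning and smoothing settings, and the size cap for the
#' O(n^2)-memory spatial diagnostics (a seeded subsample of records is used
#' beyond it).
#'
#' @param seed integer master seed; all randomness in a run flows from it.
#' @param n_records number of synthetic records to generate.
#' @param season_end_day last retained day number (198 = 15 October).
#' @param truth named list of scalar [truth_model()] overrides
#'   (e.g. `spatial_noise_sd`, `gps_failure_rate`).
#' @param binning list with `start` and `width` for [bin_mean_darkness()].
#' @param uhi_bin_width UHI bin width for [uhi_proportion_curves()].
#' @param smooth_edf effective df for [fit_smoothed_multinomial()].
#' @param rsa_max_n largest number of records used for Moran's I (seeded
#'   subsample beyond this).
#' @param correlogram_classes number of 500 m correlogram classes.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_records = 8000L, season_end_day = 198L,
                       truth = list(), binning = list(start = 9.25, width = 0.25),
                       uhi_bin_width = 0.2,
                       smooth_edf = c(latitude = 4, longitude = 4,
                                      day_number = 4, tensor = 9),
                       rsa_max_n = 2000L, correlogram_classes = 10L) {
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 season_end_day = as.integer(season_end_day), truth = truth,
                 binning = binning, uhi_bin_width = uhi_bin_width,
                 smooth_edf = smooth_edf, rsa_max_n = as.integer(rsa_max_n),
                 correlogram_classes = as.integer(correlogram_classes)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (is.list(base$smooth_edf)) base$smooth_edf <- unlist(base$smooth_edf)
  base
}

#' @param config a [run_config()].
#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$smooth_edf <- as.list(cfg$smooth_edf)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
}

.stage <- function(name, log_con, expr) {
  tryCatch({
    .log_line(log_con, "stage ", name, " start")
    r <- expr
    .log_line(log_con, "stage ", name, " done")
    r
  }, error = function(e) {
    .log_line(log_con, "stage ", name, " FAILED: ", conditionMessage(e))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Simulate a full synthetic input set
#'
#' Generates the landscape and observation table under the configured seed
#' and writes everything a later [cmd_analyse()] run consumes: the
#' observation CSV, the four ASCII grid layers, and the configuration used.
#' Byte-identical across runs with the same config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `records`, `layers`, `truth`, `paths`.
#' @export
cmd_simulate <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- do.call(truth_model, config$truth)
  layers <- generate_landscape(seed = config$seed)
  records <- generate_observations(config$n_records, layers, truth,
                                   seed = config$seed + 1L)
  write_layers(layers, file.path(out_dir, "layers"))
  write_observations(records, file.path(out_dir, "observations.csv"))
  write_run_config(config, file.path(out_dir, "config_used.yaml"))
  invisible(list(records = records, layers = layers, truth = truth,
                 paths = list(observations = file.path(out_dir, "observations.csv"),
                              layers = file.path(out_dir, "layers"))))
}

# Fig-4-analogue habitat contingency tests on the four-type banding set
.habitat_tests <- function(banding) {
  urban <- banding$habitat %in% c("urban_green", "urban_grey")
  tests <- list()
  for (cl in c("yellow", "pink")) {
    tab <- table(banding$colour == cl, urban)
    tests[[paste0(cl, "_urban_vs_nonurban")]] <- chisq_proportions(tab)
  }
  tests$brown_across_habitats <-
    chisq_proportions(table(banding$colour == "brown", banding$habitat))
  gg <- banding[banding$habitat %in% c("urban_green", "urban_grey"), ]
  tests$yellow_grey_vs_green <-
    chisq_proportions(table(gg$colour == "yellow", gg$habitat == "urban_grey"))
  data.frame(test = names(tests),
             chi2 = vapply(tests, `[[`, 1, "chi2"),
             df = vapply(tests, `[[`, 1, "df"),
             p = vapply(tests, `[[`, 1, "p"),
             row.names = NULL)
}

#' Run the end-to-end morph-cline analysis
#'
#' Sequences the full analysis on an observation table plus layer set:
#' filtering with a rejection log, habitat assignment and chi-squared
#' habitat comparisons, the colour and per-colour banding multinomial fits,
#' darkness binning with the log-curve fit, the UHI proportion curves, and
#' residual-spatial-autocorrelation diagnostics before and after the
#' penalized-spline refit. All tables are written as CSV into `out_dir`
#' together with a timestamped run log recording seeds and attrition.
#'
#' @param config a [run_config()].
#' @param records a `shell_records` table, or a path to an observation CSV.
#' @param layers an [env_layers()] object, or a path to a layer directory.
#' @param out_dir report directory (created).
#' @return invisibly, a list with every fitted object and table.
#' @export
cmd_analyse <- function(config = run_config(), records, layers, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "snailcline ",
            as.character(utils::packageVersion("snailcline")),
            " | R ", R.version.string, " | seed ", config$seed)

  if (is.character(records)) records <- read_observations(records)
  if (is.character(layers)) layers <- read_layers(layers)
  n0 <- nrow(records)

  filt <- .stage("filter", log_con, {
    f <- filter_records(records, config$season_end_day)
    write_rejection_log(f$rejections, file.path(out_dir, "rejections.csv"))
    f
  })
  .log_line(log_con, "records in ", n0, "; colour set ", nrow(filt$colour),
            "; banding set ", nrow(filt$banding),
            "; rejections ", nrow(filt$rejections))

  covar <- .stage("covariates", log_con, {
    add <- function(df) {
      env <- sample_layers(layers, df$latitude, df$longitude)
      for (nm in names(env)) df[[nm]] <- env[[nm]]
      df
    }
    list(colour = add(filt$colour), banding = add(filt$banding))
  })

  habitat <- .stage("habitat_tests", log_con, {
    counts <- as.data.frame(table(colour = covar$banding$colour,
                                  habitat = covar$banding$habitat))
    type_counts <- as.data.frame(table(main_type = covar$banding$main_type,
                                       habitat = covar$banding$habitat))
    tests <- .habitat_tests(covar$banding)
    utils::write.csv(counts, file.path(out_dir, "habitat_colour_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(type_counts, file.path(out_dir, "habitat_type_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(out_dir, "habitat_tests.csv"),
                     row.names = FALSE)
    list(counts = counts, type_counts = type_counts, tests = tests)
  })

  colour_fit <- .stage("colour_model", log_con, {
    fit <- fit_multinomial(covar$colour, reference = "yellow")
    write_fit_summary(fit, file.path(out_dir, "colour_model.csv"))
    fit
  })

  banding_fits <- .stage("banding_models", log_con, {
    fits <- list()
    for (cl in c("yellow", "pink")) {
      sub <- covar$banding[covar$banding$colour == cl, ]
      fits[[cl]] <- fit_multinomial(sub, outcome = "main_type",
                                    reference = "unbanded")
      write_fit_summary(fits[[cl]],
                        file.path(out_dir, paste0("banding_model_", cl, ".csv")))
    }
    fits
  })

  darkness <- .stage("darkness", log_con, {
    d <- covar$banding
    score <- darkness_score(d$colour, d$n_bands, d$n_fusions)
    binning <- bin_mean_darkness(d$temperature + d$uhi, score,
                                 start = config$binning$start,
                                 width = config$binning$width)
    logfit <- fit_log_darkness(binning)
    write_binning(binning, file.path(out_dir, "darkness_bins.csv"))
    utils::write.csv(as.data.frame(logfit[c("intercept", "slope", "F", "p",
                                            "r_squared")]),
                     file.path(out_dir, "darkness_logfit.csv"),
                     row.names = FALSE)
    list(binning = binning, logfit = logfit)
  })

  curves <- .stage("uhi_curves", log_con, {
    cv <- uhi_proportion_curves(covar$colour,
                                uhi_bin_width = config$uhi_bin_width)
    utils::write.csv(cv$cold, file.path(out_dir, "uhi_curves_cold.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$hot, file.path(out_dir, "uhi_curves_hot.csv"),
                     row.names = FALSE)
    cv
  })

  rsa <- .stage("spatial", log_con, {
    dat <- covar$colour
    idx <- seq_len(nrow(dat))
    if (nrow(dat) > config$rsa_max_n)
      idx <- .with_seed(config$seed + 2L,
                        sort(sample.int(nrow(dat), config$rsa_max_n)))
    sub <- dat[idx, ]
    d <- haversine_matrix(sub$latitude, sub$longitude)
    w <- inverse_distance_weights(d)
    before <- morans_i(reference_residuals(colour_fit)[idx], w)
    smooth_fit <- fit_smoothed_multinomial(dat, reference = "yellow",
                                           smooth_edf = config$smooth_edf)
    after <- morans_i(reference_residuals(smooth_fit)[idx], w)
    cg <- correlogram(reference_residuals(colour_fit)[idx],
                      sub$latitude, sub$longitude,
                      max_distance_m = config$correlogram_classes * 500,
                      seed = config$seed + 3L)
    utils::write.csv(
      data.frame(model = c("parametric", "smoothed"),
                 I = c(before$I, after$I),
                 expected = c(before$expected, after$expected),
                 variance = c(before$variance, after$variance),
                 p = c(before$p, after$p)),
      file.path(out_dir, "rsa_global.csv"), row.names = FALSE)
    utils::write.csv(cg, file.path(out_dir, "correlogram_colour.csv"),
                     row.names = FALSE)
    list(before = before, after = after, smooth_fit = smooth_fit,
         correlogram = cg, subsample = idx)
  })

  .log_line(log_con, "analysis complete")
  invisible(list(filtered = filt, covariates = covar, habitat = habitat,
                 colour_fit = colour_fit, banding_fits = banding_fits,
                 darkness = darkness, curves = curves, rsa = rsa))
}
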