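#' Darkness-score increments
#'
#' Expected internal-temperature increase of each morph feature relative to a
#' yellow unbanded shell, from published thermal measurements of shell
#' morphs: 0.3 degC for a pink and 0.6 degC for a brown ground colour,
#' 0.07 degC per dark band and 0.03 degC per band fusion.
#'
#' @param pink_increment,brown_increment,band_increment,fusion_increment
#'   increments in degrees C, all >= 0.
#' @return list of class `darkness_params`.
#' @export
darkness_params <- function(pink_increment = 0.3, brown_increment = 0.6,
                            band_increment = 0.07, fusion_increment = 0.03) {
  stopifnot(pink_increment >= 0, brown_increment >= 0,
            band_increment >= 0, fusion_increment >= 0)
  structure(list(pink_increment = pink_increment,
                 brown_increment = brown_increment,
                 band_increment = band_increment,
                 fusion_increment = fusion_increment),
            class = "darkness_params")
}

#' Darkness score of a morph
#'
#' Using a yellow unbanded shell as baseline (score 0), the score is the
#' colour increment plus `n_bands` band increments plus `n_fusions` fusion
#' increments. Vectorised over all three arguments.
#'
#' @param colour `"yellow"`, `"pink"` or `"brown"`.
#' @param n_bands number of dark bands, 0..5.
#' @param n_fusions number of band fusions, at most `max(0, n_bands - 1)`.
#' @param params a [darkness_params()].
#' @return numeric score in degC-equivalents.
#' @examples
#' darkness_score("brown", 0, 0)  # 0.6
#' darkness_score("pink", 5, 2)   # 0.3 + 5*0.07 + 2*0.03 = 0.71
#' @export
darkness_score <- function(colour, n_bands = 0L, n_fusions = 0L,
                           params = darkness_params()) {
  m <- max(length(colour), length(n_bands), length(n_fusions))
  colour <- rep_len(colour, m)
  n_bands <- rep_len(n_bands, m)
  n_fusions <- rep_len(n_fusions, m)
  if (any(!colour %in% c("yellow", "pink", "brown")))
    stop("colour must be yellow, pink or brown")
  if (any(n_bands < 0 | n_bands > 5))
    stop("n_bands must be in 0..5")
  if (any(n_fusions < 0 | n_fusions > pmax(0, n_bands - 1)))
    stop("n_fusions must be at most max(0, n_bands - 1)")
  col_inc <- c(yellow = 0, pink = params$pink_increment,
               brown = params$brown_increment)[colour]
  unname(col_inc + n_bands * params$band_increment +
           n_fusions * params$fusion_increment)
}

#' Bin records by thermal sum and average their darkness scores
#'
#' `thermal_sum` (temperature + UHI, degC) is cut into contiguous half-open
#' bins `[lower, upper)` of width `width` starting at `start`; the final
#' three width-`width` bins are merged into a single tail bin of width
#' `3 * width` (so each bin retains a comparable sample size). Per-bin mean
#' darkness and its standard error are reported at the bin centre. Records
#' below `start` go to an explicit underflow bucket and are excluded from
#' the bins.
#'
#' @param thermal_sum numeric vector, temperature + UHI per record.
#' @param darkness numeric vector of darkness scores, same length.
#' @param start lower edge of the first bin (default 9.25 degC).
#' @param width bin width (default 0.25 degC).
#' @return list of class `thermal_binning`: `bins` (data.frame `lower`,
#'   `upper`, `centre`, `n`, `mean_darkness`, `se`), `underflow` (indices of
#'   records below `start`), `start`, `width`.
#' @export
bin_mean_darkness <- function(thermal_sum, darkness,
                              start = 9.25, width = 0.25) {
  stopifnot(length(thermal_sum) == length(darkness), width > 0)
  under <- which(thermal_sum < start)
  keep <- setdiff(seq_along(thermal_sum), under)
  ts <- thermal_sum[keep]; dk <- darkness[keep]
  n_units <- max(1L, floor((max(ts) - start) / width) + 1L)
  if (n_units < 4L)
    stop("need at least four unit bins before merging the tail")
  lower <- start + (seq_len(n_units - 2L) - 1L) * width
  upper <- lower + width
  upper[length(upper)] <- start + n_units * width  # merged 3-unit tail
  idx <- findInterval(ts, c(lower, upper[length(upper)]),
                      rightmost.closed = FALSE)
  bins <- data.frame(lower = lower, upper = upper,
                     centre = (lower + upper) / 2)
  bins$n <- vapply(seq_len(nrow(bins)), function(b) sum(idx == b), 1L)
  bins$mean_darkness <- vapply(seq_len(nrow(bins)), function(b)
    if (bins$n[b] > 0L) mean(dk[idx == b]) else NA_real_, 1)
  bins$se <- vapply(seq_len(nrow(bins)), function(b)
    if (bins$n[b] > 1L) stats::sd(dk[idx == b]) / sqrt(bins$n[b]) else NA_real_, 1)
  structure(list(bins = bins, underflow = under, start = start, width = width),
            class = "thermal_binning")
}

#' Logarithmic fit of mean darkness against thermal sum
#'
#' Unweighted ordinary least squares of per-bin mean darkness on the natural
#' log of the bin centre, `darkness = a + b * ln(thermal_sum)`, with the
#' regression F test on 1 and k - 2 df. Bins with no records are excluded;
#' at least three non-empty bins are required.
#'
#' @param binning a [bin_mean_darkness()] result (or its `bins` data.frame).
#' @return list `intercept`, `slope`, `F`, `p`, `r_squared`, `df`.
#' @export
fit_log_darkness <- function(binning) {
  bins <- if (inherits(binning, "thermal_binning")) binning$bins else binning
  bins <- bins[!is.na(bins$mean_darkness) & bins$n > 0, , drop = FALSE]
  if (nrow(bins) < 3L) stop("need at least three non-empty bins")
  if (stats::sd(bins$mean_darkness) == 0)
    return(list(intercept = bins$mean_darkness[1], slope = 0, F = 0, p = 1,
                r_squared = 0, df = c(1, nrow(bins) - 2)))
  fit <- stats::lm(mean_darkness ~ log(centre), data = bins)
  sm <- summary(fit)
  Fv <- unname(sm$fstatistic)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       F = Fv[1],
       p = unname(stats::pf(Fv[1], Fv[2], Fv[3], lower.tail = FALSE)),
       r_squared = sm$r.squared,
       df = c(Fv[2], Fv[3]))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The interval obtained by inverting the score test,
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n},}
#' always inside \[0, 1\].
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, >= 1.
#' @param confidence confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Colour proportions against UHI, split at the median temperature
#'
#' Splits the records into a "cold" half (temperature <= the median) and a
#' "hot" half (temperature > the median), bins UHI into half-open categories
#' of `uhi_bin_width` degC starting at 0, and tabulates the proportion of
#' each shell colour per bin with 95% Wilson score intervals, reported at
#' bin centres.
#'
#' @param records data.frame with columns `uhi`, `temperature`, `colour`.
#' @param uhi_bin_width bin width in degC (default 0.2).
#' @param temperature_split split value; default the median temperature of
#'   `records`.
#' @param confidence confidence level for the Wilson intervals.
#' @return list with elements `cold` and `hot`, each a data.frame with one
#'   row per bin x colour (`bin_lower`, `bin_upper`, `centre`, `n`, `colour`,
#'   `proportion`, `ci_lower`, `ci_upper`), plus `temperature_split`.
#' @export
uhi_proportion_curves <- function(records, uhi_bin_width = 0.2,
                                  temperature_split = NULL,
                                  confidence = 0.95) {
  if (is.null(temperature_split))
    temperature_split <- stats::median(records$temperature)
  halves <- list(cold = records[records$temperature <= temperature_split, ],
                 hot = records[records$temperature > temperature_split, ])
  out <- lapply(halves, function(df) {
    if (!nrow(df)) return(data.frame())
    bin <- floor(df$uhi / uhi_bin_width)
    rows <- lapply(sort(unique(bin)), function(b) {
      sel <- df[bin == b, ]
      n <- nrow(sel)
      do.call(rbind, lapply(c("yellow", "pink", "brown"), function(cl) {
        k <- sum(sel$colour == cl)
        ci <- wilson_interval(k, n, confidence)
        data.frame(bin_lower = b * uhi_bin_width,
                   bin_upper = (b + 1) * uhi_bin_width,
                   centre = (b + 0.5) * uhi_bin_width,
                   n = n, colour = cl, proportion = k / n,
                   ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  out$temperature_split <- temperature_split
  out
}

#' Write binned output tables as CSV
#'
#' @param binning a [bin_mean_darkness()] result.
#' @param path output CSV path.
#' @export
write_binning <- function(binning, path) {
  b <- binning$bins
  utils::write.csv(data.frame(bin_lower = b$lower, bin_upper = b$upper,
                              centre = b$centre, n = b$n,
                              value = b$mean_darkness, se = b$se),
                   path, row.names = FALSE)
  invisible(path)
}
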