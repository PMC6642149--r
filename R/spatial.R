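#' Pairwise haversine great-circle distance matrix
#'
#' Distances in metres on a sphere of radius 6,378,137 m (the geodesy
#' convention of the geosphere tool family, which performs the evaluation).
#'
#' @param latitude,longitude numeric vectors, decimal degrees.
#' @return symmetric n x n matrix of metres, zero diagonal.
#' @export
haversine_matrix <- function(latitude, longitude) {
  if (any(abs(latitude) > 90) || any(abs(longitude) > 180))
    stop("invalid coordinates")
  d <- geosphere::distm(cbind(longitude, latitude),
                        fun = geosphere::distHaversine)
  dimnames(d) <- NULL
  d
}

#' Inverse-distance spatial weights
#'
#' `w_ij = 1 / d_ij` with a zero diagonal. Pairs at exactly zero distance
#' (coincident points, e.g. repeated GPS fixes) would have infinite weight;
#' the default policy gives them weight zero, alternatively the largest
#' finite off-diagonal weight.
#'
#' @param dist_m distance matrix in metres (e.g. [haversine_matrix()]).
#' @param coincident how to weight coincident pairs: `"zero"` or `"max"`.
#' @return weight matrix, zero diagonal, non-negative.
#' @export
inverse_distance_weights <- function(dist_m, coincident = c("zero", "max")) {
  coincident <- match.arg(coincident)
  w <- 1 / dist_m
  diag(w) <- 0
  bad <- !is.finite(w)
  if (any(bad)) {
    w[bad] <- if (coincident == "zero") 0 else max(w[!bad & w > 0])
  }
  w
}

#' Global Moran's I with analytical null moments
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z_i = x_i - \bar x}. Expectation is \eqn{-1/(n-1)}; the
#' variance is computed under the normality null (default) or under the
#' randomisation null (kurtosis-corrected, the moments the permutation
#' distribution has exactly); the p-value is two-sided from the normal
#' approximation.
#'
#' @param values numeric vector (not all equal), length n >= 3.
#' @param weights n x n non-negative weight matrix with zero diagonal
#'   (need not be symmetric).
#' @param null `"normal"` or `"randomisation"` variance formula.
#' @return list of class `morans_i`: `I`, `expected` (= -1/(n-1)),
#'   `variance`, `sd`, `p`, `n`, `S0`.
#' @export
morans_i <- function(values, weights, null = c("normal", "randomisation")) {
  null <- match.arg(null)
  n <- length(values)
  if (n < 3L) stop("need at least three values")
  if (!all(dim(weights) == c(n, n))) stop("weight matrix dimension mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("values have zero variance")
  S0 <- sum(weights)
  if (S0 == 0) stop("all weights are zero")
  I <- (n / S0) * sum(z * (weights %*% z)) / m2
  EI <- -1 / (n - 1)
  wsym <- weights + t(weights)
  S1 <- 0.5 * sum(wsym^2)
  S2 <- sum((rowSums(weights) + colSums(weights))^2)
  b2 <- n * sum(z^4) / m2^2  # sample kurtosis of the values
  varI <- if (null == "normal") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  } else {
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
       b2 * (n * (n - 1) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  p <- 2 * stats::pnorm(-abs(I - EI) / sqrt(varI))
  structure(list(I = I, expected = EI, variance = varI, sd = sqrt(varI),
                 p = p, n = n, S0 = S0, kurtosis = b2),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (expected %.4f, sd %.4f), p = %.4g, n = %d\n",
              x$I, x$expected, x$sd, x$p, x$n))
  invisible(x)
}

#' Distance-class Moran's I correlogram with permutation tests
#'
#' Pairs of points are binned by haversine distance into contiguous classes
#' of width `increment_m`; within each class Moran's I is computed with
#' binary weights (1 for pairs in the class) and tested by a seeded
#' permutation test (two-sided, against the permutation-null expectation
#' -1/(n-1)). Classes with fewer than two pairs are reported empty and not
#' tested.
#'
#' @param values numeric vector, one value per point.
#' @param latitude,longitude point coordinates, decimal degrees.
#' @param increment_m class width in metres (default 500, the scale at which
#'   residual similarity decays in these data).
#' @param max_distance_m ignore pairs beyond this distance (default: none).
#' @param n_perm number of permutations per class.
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per class: `class_centre_m`, `I`, `p`,
#'   `n_pairs` (`I` and `p` are `NA` for empty classes).
#' @export
correlogram <- function(values, latitude, longitude, increment_m = 500,
                        max_distance_m = NULL, n_perm = 500L, seed = 1L) {
  if (increment_m <= 0) stop("increment_m must be positive")
  n <- length(values)
  d <- haversine_matrix(latitude, longitude)
  iu <- which(upper.tri(d))
  dd <- d[iu]
  if (!is.null(max_distance_m)) {
    keep <- dd < max_distance_m
    iu <- iu[keep]; dd <- dd[keep]
  }
  cls <- floor(dd / increment_m) + 1L
  n_classes <- if (length(cls)) max(cls) else 0L
  z <- values - mean(values)
  m2 <- sum(z^2)
  EI <- -1 / (n - 1)
  .with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    zp <- matrix(z[perms], n, n_perm)
    rows <- lapply(seq_len(n_classes), function(b) {
      sel <- iu[cls == b]
      np <- length(sel)
      if (np < 2L)
        return(data.frame(class_centre_m = (b - 0.5) * increment_m,
                          I = NA_real_, p = NA_real_, n_pairs = np))
      i <- (sel - 1L) %% n + 1L
      j <- (sel - 1L) %/% n + 1L
      S0 <- 2 * np
      Iobs <- (n / S0) * 2 * sum(z[i] * z[j]) / m2
      Iperm <- (n / S0) * 2 * colSums(zp[i, , drop = FALSE] *
                                        zp[j, , drop = FALSE]) / m2
      p <- (1 + sum(abs(Iperm - EI) >= abs(Iobs - EI))) / (n_perm + 1)
      data.frame(class_centre_m = (b - 0.5) * increment_m,
                 I = Iobs, p = p, n_pairs = np)
    })
    do.call(rbind, rows)
  })
}

#' Residual spatial autocorrelation diagnostics for a fit
#'
#' Computes global Moran's I of the reference-category residuals under raw
#' inverse-distance weights, plus (optionally) the distance-class
#' correlogram.
#'
#' @param fit a `multinom_ml` or `smooth_multinom_ml` fit.
#' @param records the data the model was fitted to (provides coordinates).
#' @param correlogram_classes number of correlogram classes (0 = skip).
#' @param increment_m correlogram class width, metres.
#' @param coincident coincident-pair policy, see [inverse_distance_weights()].
#' @param seed RNG seed for the correlogram permutations.
#' @return list of class `spatial_diagnostics`: `global` (a [morans_i()]
#'   result), `correlogram` (data.frame or `NULL`), `weight_spec`.
#' @export
spatial_diagnostics <- function(fit, records, correlogram_classes = 10L,
                                increment_m = 500, coincident = "zero",
                                seed = 1L) {
  res <- reference_residuals(fit)
  if (length(res) != nrow(records))
    stop("fit and records disagree on the number of rows")
  d <- haversine_matrix(records$latitude, records$longitude)
  w <- inverse_distance_weights(d, coincident = coincident)
  global <- morans_i(res, w)
  cg <- NULL
  if (correlogram_classes > 0L)
    cg <- correlogram(res, records$latitude, records$longitude,
                      increment_m = increment_m,
                      max_distance_m = correlogram_classes * increment_m,
                      seed = seed)
  structure(list(global = global, correlogram = cg,
                 weight_spec = list(type = "inverse_distance",
                                    zero_diagonal = TRUE,
                                    coincident_policy = coincident)),
            class = "spatial_diagnostics")
}

#' @export
print.spatial_diagnostics <- function(x, ...) {
  print(x$global)
  if (!is.null(x$correlogram)) {
    cat("Correlogram:\n")
    print(x$correlogram, row.names = FALSE)
  }
  invisible(x)
}

#' Write spatial diagnostics as CSV
#'
#' @param diag a [spatial_diagnostics()] result.
#' @param global_path CSV for the global statistic
#'   (`statistic, value, expected, variance, p`).
#' @param correlogram_path optional CSV for the correlogram
#'   (`class_centre_m, I, p, n_pairs`).
#' @export
write_spatial_diagnostics <- function(diag, global_path,
                                      correlogram_path = NULL) {
  g <- diag$global
  utils::write.csv(data.frame(statistic = "global_morans_i", value = g$I,
                              expected = g$expected, variance = g$variance,
                              p = g$p),
                   global_path, row.names = FALSE)
  if (!is.null(correlogram_path) && !is.null(diag$correlogram))
    utils::write.csv(diag$correlogram, correlogram_path, row.names = FALSE)
  invisible(global_path)
}
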