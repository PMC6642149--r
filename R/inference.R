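#' Pearson chi-squared test on a contingency table of morph counts
#'
#' Compares morph proportions between habitat types: Pearson chi-squared
#' without continuity correction, df = (rows - 1)(cols - 1), upper-tail
#' p-value. Errors if any expected cell count is zero.
#'
#' @param contingency matrix of counts (e.g. 2 x k: morph yes/no by habitat).
#' @return list `chi2`, `df`, `p`.
#' @export
chisq_proportions <- function(contingency) {
  contingency <- as.matrix(contingency)
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected <= 0)) stop("zero expected cell count")
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else `NS`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "NS")))
}

# all compositions of n into k non-negative cells, as a (choose(n+k-1, k-1)) x k
# matrix; recursive enumeration, intended for small n and k
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  do.call(rbind, lapply(0:n, function(i)
    cbind(i, .compositions(n - i, k - 1L))))
}

#' Exact multinomial goodness-of-fit test
#'
#' Tests observed category counts against expected probabilities by full
#' enumeration of all outcomes of `n` draws into `k` cells. Two p-values are
#' returned, matching the two orderings in common use: `p_prob` sums the
#' probability of every outcome whose multinomial probability is at most
#' that of the observed outcome (the classical exact multinomial test), and
#' `p_distance` sums the probability of every outcome whose Euclidean
#' distance between outcome proportions and `expected_probs` is at least the
#' observed distance. Above `enumeration_cap` total counts the enumeration
#' is replaced by seeded Monte Carlo sampling.
#'
#' @param observed integer vector of k category counts.
#' @param expected_probs numeric vector of k probabilities summing to 1.
#' @param enumeration_cap largest `sum(observed)` enumerated exactly.
#' @param mc_draws Monte Carlo sample size beyond the cap.
#' @param seed RNG seed for the Monte Carlo fallback.
#' @return list `p_prob`, `p_distance`, `method` (`"exact"` or
#'   `"monte_carlo"`), `n_outcomes` (number of enumerated outcomes, exact
#'   method only).
#' @export
exact_multinomial_test <- function(observed, expected_probs,
                                   enumeration_cap = 200L,
                                   mc_draws = 1e5, seed = 1L) {
  observed <- as.integer(observed)
  k <- length(observed)
  n <- sum(observed)
  if (length(expected_probs) != k) stop("length mismatch")
  if (abs(sum(expected_probs) - 1) > 1e-12)
    stop("expected_probs must sum to 1")
  obs_prob <- stats::dmultinom(observed, prob = expected_probs)
  obs_dist <- sqrt(sum((observed / n - expected_probs)^2))
  tol <- 1e-12

  if (n <= enumeration_cap) {
    outcomes <- .compositions(n, k)
    probs <- apply(outcomes, 1, stats::dmultinom, prob = expected_probs)
    dists <- sqrt(colSums((t(outcomes) / n - expected_probs)^2))
    p_prob <- sum(probs[probs <= obs_prob * (1 + tol)])
    p_distance <- sum(probs[dists >= obs_dist - tol])
    list(p_prob = p_prob, p_distance = p_distance, method = "exact",
         n_outcomes = nrow(outcomes))
  } else {
    .with_seed(seed, {
      draws <- stats::rmultinom(mc_draws, n, expected_probs)
      probs <- apply(draws, 2, stats::dmultinom, prob = expected_probs)
      dists <- sqrt(colSums((draws / n - expected_probs)^2))
      list(p_prob = mean(probs <= obs_prob * (1 + tol)),
           p_distance = mean(dists >= obs_dist - tol),
           method = "monte_carlo", n_outcomes = NA_integer_)
    })
  }
}
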