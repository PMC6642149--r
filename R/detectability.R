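#' Kaplan-Meier shell-discovery curves
#'
#' Product-limit estimate of the proportion of shells not yet discovered as
#' a function of search time, per stratum (colour, and volunteer when more
#' than one is present). Shells not found by the search limit are censored.
#' Ties are handled by the simultaneous-death convention of the
#' product-limit estimator (computed by `survival::survfit`).
#'
#' @param events data.frame with columns `colour`, `time_s`, `found` and
#'   optionally `volunteer` (see [generate_detectability_experiment()]).
#' @return data.frame `time`, `survival`, `n_risk`, `n_event`, `stratum`,
#'   one row per event time per stratum (plus the time-0 point).
#' @export
kaplan_meier <- function(events) {
  stopifnot(all(c("colour", "time_s", "found") %in% names(events)))
  strat <- events$colour
  if ("volunteer" %in% names(events) &&
      length(unique(events$volunteer)) > 1L)
    strat <- paste(events$colour, events$volunteer, sep = "/")
  df <- data.frame(time_s = events$time_s, found = events$found,
                   stratum = strat)
  out <- lapply(split(df, df$stratum), function(d) {
    sf <- survival::survfit(survival::Surv(time_s, found) ~ 1, data = d)
    data.frame(time = c(0, sf$time), survival = c(1, sf$surv),
               n_risk = c(nrow(d), sf$n.risk), n_event = c(0, sf$n.event),
               stratum = d$stratum[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Colour composition of discovered shells at time checkpoints
#'
#' At each checkpoint, the colour proportions among shells found by that
#' time, next to the true proportions among all shells laid out. A
#' checkpoint with no shells found yet gets `NA` proportions.
#'
#' @param events discovery-event data.frame (`colour`, `time_s`, `found`).
#' @param checkpoints increasing times in seconds
#'   (default `c(150, 300, 450, 600)`).
#' @param true_counts named vector of shells laid out per colour; default:
#'   tabulated from `events`.
#' @return data.frame `checkpoint_s`, `colour`, `found_n`, `proportion`,
#'   `true_proportion`.
#' @export
proportions_by_time <- function(events, checkpoints = c(150, 300, 450, 600),
                                true_counts = NULL) {
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("checkpoints must be strictly increasing")
  if (is.null(true_counts))
    true_counts <- table(events$colour)
  cols <- names(true_counts)
  truep <- as.numeric(true_counts) / sum(true_counts)
  rows <- lapply(checkpoints, function(cp) {
    sel <- events$found & events$time_s <= cp
    ntot <- sum(sel)
    data.frame(checkpoint_s = cp, colour = cols,
               found_n = vapply(cols, function(cl)
                 sum(sel & events$colour == cl), 1L),
               proportion = if (ntot == 0L) NA_real_ else
                 vapply(cols, function(cl)
                   sum(sel & events$colour == cl) / ntot, 1),
               true_proportion = truep,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Agreement between two colour classifications
#'
#' Percentage of exact matches (rounded to an integer, as agreement is
#' conventionally reported) and the full confusion table between two
#' classifications of the same shells — e.g. photographs against a
#' background vs the shell specimens in hand.
#'
#' @param labels_a,labels_b equal-length character vectors over
#'   `{yellow, pink, brown}`.
#' @return list `percent_match` (integer), `exact_match` (unrounded
#'   fraction), `confusion` (3 x 3 table, rows = `labels_a`).
#' @export
classification_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  lev <- c("yellow", "pink", "brown")
  bad <- setdiff(unique(c(labels_a, labels_b)), lev)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  frac <- mean(a == b)
  list(percent_match = as.integer(round(100 * frac)),
       exact_match = frac,
       confusion = table(a, b, dnn = c("labels_a", "labels_b")))
}
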