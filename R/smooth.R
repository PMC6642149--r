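# Equally-spaced cubic B-spline basis (P-spline) with `nbasis` columns.
.pspline_basis <- function(x, nbasis) {
  stopifnot(nbasis >= 4L)
  rng <- range(x)
  nseg <- nbasis - 3L
  h <- diff(rng) / nseg
  knots <- rng[1] + (-3:(nseg + 3)) * h
  splines::splineDesign(knots, x, ord = 4L, outer.ok = TRUE)
}

# sum-to-zero constraint: project out the constant coefficient direction
.constraint_null <- function(m) {
  qr.Q(qr(matrix(1, m, 1L)), complete = TRUE)[, -1L, drop = FALSE]
}

# difference roughness penalty D'D of the given order
.diff_penalty <- function(m, order = 1L) {
  D <- diff(diag(m), differences = order)
  crossprod(D)
}

# smoothing parameter such that the Gaussian-analogue effective degrees of
# freedom tr((B'B + lambda S)^-1 B'B) equal `edf`
.calibrate_lambda <- function(B, S, edf) {
  BtB <- crossprod(B)
  edf_at <- function(loglam) {
    sum(diag(solve(BtB + 10^loglam * S + diag(1e-10, ncol(B)), BtB)))
  }
  if (edf >= ncol(B) - 1e-6) return(1e-10)
  lo <- -10; hi <- 15
  if (edf_at(lo) < edf) return(10^lo)
  10^stats::uniroot(function(l) edf_at(l) - edf, c(lo, hi), tol = 1e-4)$root
}

# build one constrained, penalized smooth block
.smooth_block <- function(B, penalty_order, edf, lambda = NULL) {
  Z <- .constraint_null(ncol(B))
  Bc <- B %*% Z
  S <- t(Z) %*% .diff_penalty(ncol(B), penalty_order) %*% Z
  if (is.null(lambda)) lambda <- .calibrate_lambda(Bc, S, edf)
  list(B = Bc, S = lambda * S, lambda = lambda, edf = edf)
}

.tensor_block <- function(B1, B2, penalty_order, edf, lambda = NULL) {
  m1 <- ncol(B1); m2 <- ncol(B2)
  # row-wise Kronecker product
  BT <- B1[, rep(seq_len(m1), each = m2), drop = FALSE] *
    B2[, rep(seq_len(m2), times = m1), drop = FALSE]
  P1 <- .diff_penalty(m1, penalty_order)
  P2 <- .diff_penalty(m2, penalty_order)
  S <- kronecker(P1, diag(m2)) + kronecker(diag(m1), P2)
  Z <- .constraint_null(m1 * m2)
  Bc <- BT %*% Z
  Sc <- t(Z) %*% S %*% Z
  if (is.null(lambda)) lambda <- .calibrate_lambda(Bc, Sc, edf)
  list(B = Bc, S = lambda * Sc, lambda = lambda, edf = edf)
}

#' Multinomial logit with penalized spline smooths of location and season
#'
#' Fits the same baseline-category multinomial logit as [multinom_ml()] but
#' adds penalized B-spline smooth terms to each linear predictor: marginal
#' smooths of latitude, longitude and day number, and a tensor-product
#' smooth of latitude x longitude. This is the spatial-correction model used
#' to absorb residual spatial autocorrelation: broad geographic trends move
#' into the smooths, while the parametric climate/UHI terms keep their
#' odds-ratio/Wald interpretation.
#'
#' Each smooth carries a difference roughness penalty (default first order,
#' so an infinitely penalized smooth degenerates to a constant absorbed by
#' the intercept and the model nests the plain parametric fit). The
#' smoothing parameter of each term is calibrated so its Gaussian-analogue
#' effective degrees of freedom match `smooth_edf`; sum-to-zero constraints
#' keep the smooths identifiable next to the intercept.
#'
#' @param records data.frame with outcome, covariates, `latitude`,
#'   `longitude`, `day_number`.
#' @param formula parametric part (default
#'   `colour ~ uhi * temperature * dry_days`; day number enters through its
#'   smooth).
#' @param reference reference outcome category.
#' @param smooth_edf named effective degrees of freedom:
#'   `latitude`, `longitude`, `day_number` (default 4 each) and
#'   `tensor` (default 9).
#' @param nbasis_marginal,nbasis_tensor_margin B-spline basis sizes.
#' @param penalty_order difference order of the roughness penalty.
#' @param lambda optional named numeric vector (same names as `smooth_edf`)
#'   of fixed smoothing parameters, bypassing the EDF calibration.
#' @param centre centre numeric parametric predictors (as in
#'   [multinom_ml()]).
#' @param control a [multinom_control()].
#' @return object of class `smooth_multinom_ml`: parametric coefficient
#'   table (`parametric`: estimate, odds ratio, se, z, p per outcome), the
#'   full coefficient matrix, fitted probabilities, smooth-term metadata
#'   (`smooths`), log-likelihood (unpenalized, at the penalized optimum).
#'   `reference_residuals()` and [spatial_diagnostics()] work on it
#'   directly.
#' @export
fit_smoothed_multinomial <- function(records,
                                     formula = NULL,
                                     reference = NULL,
                                     smooth_edf = c(latitude = 4, longitude = 4,
                                                    day_number = 4, tensor = 9),
                                     nbasis_marginal = 8L,
                                     nbasis_tensor_margin = 5L,
                                     penalty_order = 1L,
                                     lambda = NULL,
                                     centre = TRUE,
                                     control = multinom_control()) {
  if (is.null(formula))
    formula <- stats::as.formula("colour ~ uhi * temperature * dry_days")
  mf <- stats::model.frame(formula, records, na.action = stats::na.pass)
  if (anyNA(mf)) stop("missing values in model variables")
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  lev <- levels(y)
  if (is.null(reference)) reference <- lev[1L]
  lev <- c(reference, setdiff(lev, reference))
  y <- factor(y, levels = lev)

  centres <- numeric(0)
  if (centre) {
    for (v in attr(mt, "term.labels")) {
      if (v %in% names(mf) && is.numeric(mf[[v]])) {
        centres[v] <- mean(mf[[v]])
        mf[[v]] <- mf[[v]] - centres[v]
      }
    }
  }
  Xp <- stats::model.matrix(mt, mf)
  p_par <- ncol(Xp)

  lam <- function(nm) if (!is.null(lambda) && nm %in% names(lambda))
    lambda[[nm]] else NULL
  blocks <- list(
    latitude = .smooth_block(.pspline_basis(records$latitude, nbasis_marginal),
                             penalty_order, smooth_edf[["latitude"]],
                             lam("latitude")),
    longitude = .smooth_block(.pspline_basis(records$longitude, nbasis_marginal),
                              penalty_order, smooth_edf[["longitude"]],
                              lam("longitude")),
    day_number = .smooth_block(.pspline_basis(records$day_number, nbasis_marginal),
                               penalty_order, smooth_edf[["day_number"]],
                               lam("day_number")),
    tensor = .tensor_block(.pspline_basis(records$latitude, nbasis_tensor_margin),
                           .pspline_basis(records$longitude, nbasis_tensor_margin),
                           penalty_order, smooth_edf[["tensor"]],
                           lam("tensor")))

  X <- cbind(Xp, do.call(cbind, lapply(blocks, `[[`, "B")))
  colnames(X) <- c(colnames(Xp), unlist(lapply(names(blocks), function(nm)
    paste0("s(", nm, ").", seq_len(ncol(blocks[[nm]]$B))))))
  p <- ncol(X)
  S <- matrix(0, p, p)
  off <- p_par
  for (b in blocks) {
    idx <- off + seq_len(ncol(b$B))
    S[idx, idx] <- b$S
    off <- off + ncol(b$B)
  }
  K1 <- length(lev) - 1L
  S_full <- kronecker(diag(K1), S)

  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- lev
  fit <- .multinom_engine(X, Y, penalty = S_full, control = control)
  if (!fit$converged)
    warning("smoothed multinomial fit did not converge in ",
            fit$iterations, " iterations")

  B <- fit$B
  dimnames(B) <- list(colnames(X), lev[-1L])
  vc <- fit$vcov
  se_all <- matrix(sqrt(pmax(diag(vc), 0)), p, K1, dimnames = dimnames(B))
  P <- .multinom_probs(X %*% B)
  colnames(P) <- lev

  par_idx <- seq_len(p_par)
  parametric <- data.frame(
    outcome = rep(lev[-1L], each = p_par),
    term = rep(colnames(Xp), K1),
    estimate = as.vector(B[par_idx, , drop = FALSE]),
    odds_ratio = as.vector(exp(B[par_idx, , drop = FALSE])),
    se = as.vector(se_all[par_idx, , drop = FALSE]),
    stringsAsFactors = FALSE)
  parametric$z <- parametric$estimate / parametric$se
  parametric$p <- 2 * stats::pnorm(-abs(parametric$z))
  parametric$stars <- significance_stars(parametric$p)

  structure(list(coefficients = B, parametric = parametric, vcov = vc,
                 fitted = P, y = y, levels = lev, reference = reference,
                 smooths = lapply(blocks, function(b)
                   list(lambda = b$lambda, edf = b$edf, ncol = ncol(b$B))),
                 log_likelihood = fit$loglik,
                 penalized_objective = fit$objective,
                 converged = fit$converged, iterations = fit$iterations,
                 centres = centres, n = length(y)),
            class = "smooth_multinom_ml")
}

#' @export
print.smooth_multinom_ml <- function(x, ...) {
  cat("Penalized-spline multinomial logit (reference: ", x$reference,
      "), n = ", x$n, "\n", sep = "")
  cat("Smooths:",
      paste(sprintf("%s (edf %.3g, lambda %.3g)", names(x$smooths),
                    vapply(x$smooths, `[[`, 1, "edf"),
                    vapply(x$smooths, `[[`, 1, "lambda")),
            collapse = ", "), "\n\n")
  cat("Parametric terms:\n")
  tab <- x$parametric
  tab$odds_ratio <- round(tab$odds_ratio, 3)
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.smooth_multinom_ml <- function(object, ...) object$fitted

#' @export
residuals.smooth_multinom_ml <- function(object,
                                         type = c("reference", "raw"), ...) {
  residuals.multinom_ml(object, type = match.arg(type))
}

#' @export
coef.smooth_multinom_ml <- function(object, ...) object$coefficients
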