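#' Control parameters for the multinomial Newton fitter
#'
#' @param grad_tol convergence when the max absolute (penalized) score entry
#'   drops below this.
#' @param rel_tol convergence when the relative objective change drops below
#'   this.
#' @param max_iter Newton iteration cap.
#' @param max_halvings step-halvings allowed per iteration.
#' @param ridge jitter added to a numerically singular information matrix.
#' @return list of class `multinom_control`.
#' @export
multinom_control <- function(grad_tol = 1e-8, rel_tol = 1e-12,
                             max_iter = 200L, max_halvings = 30L,
                             ridge = 1e-8) {
  structure(list(grad_tol = grad_tol, rel_tol = rel_tol,
                 max_iter = max_iter, max_halvings = max_halvings,
                 ridge = ridge), class = "multinom_control")
}

# Fitted class probabilities for linear predictors eta (n x K-1, reference
# class has eta = 0). Returns n x K matrix, reference first.
.multinom_probs <- function(eta) {
  m <- pmax(0, apply(eta, 1, max))
  ex <- exp(eta - m)
  denom <- exp(-m) + rowSums(ex)
  cbind(exp(-m) / denom, ex / denom)
}

# Newton maximisation of the baseline-category multinomial log-likelihood,
# optionally penalized by a quadratic form 0.5 * b' S b on the stacked
# coefficient vector b = vec(B) (column-major over non-reference outcomes).
# Step-halving guarantees a monotone objective; a ridge is added only when
# the information matrix is numerically singular.
.multinom_engine <- function(X, Y, penalty = NULL,
                             control = multinom_control(), start = NULL) {
  n <- nrow(X); p <- ncol(X); K <- ncol(Y); K1 <- K - 1L
  npar <- p * K1
  S <- if (is.null(penalty)) matrix(0, npar, npar) else penalty
  B <- if (is.null(start)) matrix(0, p, K1) else start
  Y1 <- Y[, -1L, drop = FALSE]
  yidx <- max.col(Y, ties.method = "first")

  objective <- function(B) {
    P <- .multinom_probs(X %*% B)
    b <- as.vector(B)
    sum(log(pmax(P[cbind(seq_len(n), yidx)], 1e-300))) -
      0.5 * sum(b * (S %*% b))
  }

  obj <- objective(B)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- .multinom_probs(X %*% B)
    P1 <- P[, -1L, drop = FALSE]
    grad <- as.vector(crossprod(X, Y1 - P1)) - S %*% as.vector(B)
    info <- matrix(0, npar, npar)
    for (k in seq_len(K1)) {
      rk <- ((k - 1L) * p + 1L):(k * p)
      for (l in k:K1) {
        w <- if (k == l) P1[, k] * (1 - P1[, k]) else -P1[, k] * P1[, l]
        blk <- crossprod(X, X * w)
        rl <- ((l - 1L) * p + 1L):(l * p)
        info[rk, rl] <- blk
        if (l > k) info[rl, rk] <- t(blk)
      }
    }
    info <- info + S
    step_dir <- tryCatch(solve(info, grad), error = function(e) {
      solve(info + diag(control$ridge, npar), grad)
    })
    # step-halving: never accept a decrease of the objective
    step <- 1
    repeat {
      Bnew <- B + matrix(step * step_dir, p, K1)
      objnew <- objective(Bnew)
      if (objnew >= obj - 1e-12 || step < 2^(-control$max_halvings)) break
      step <- step / 2
    }
    rel_change <- abs(objnew - obj) / (abs(obj) + 1e-10)
    B <- Bnew
    obj <- objnew
    trace <- c(trace, obj)
    if (max(abs(grad)) < control$grad_tol ||
        rel_change < control$rel_tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  vcov <- tryCatch(solve(info), error = function(e)
    solve(info + diag(control$ridge, npar)))
  list(B = B, vcov = vcov, loglik = objective(B) +
         0.5 * sum(as.vector(B) * (S %*% as.vector(B))),
       objective = obj, converged = converged, iterations = iter,
       trace = trace, info = info)
}

#' Baseline-category multinomial logistic regression by maximum likelihood
#'
#' Fits the multinomial logit in which each non-reference outcome category is
#' contrasted against a declared reference (e.g. pink and brown shells vs the
#' yellow reference), by Newton iteration on the full log-likelihood with
#' step-halving. Inference is Wald: standard errors from the inverse observed
#' information at the optimum, two-sided p-values against the normal
#' reference, odds ratios as `exp(coefficient)`.
#'
#' Numeric predictor variables are centred around the mean of the fitted
#' subset before the design matrix (including any interactions) is built, so
#' interaction columns are products of centred variables; the centres are
#' stored and re-applied by `predict()`.
#'
#' @param formula model formula, e.g.
#'   `colour ~ day_number + uhi * temperature * dry_days`.
#' @param data data.frame containing the variables.
#' @param reference reference outcome level (default: first factor level).
#' @param centre centre numeric predictors around the fitted-subset mean?
#' @param control a [multinom_control()].
#' @return object of class `multinom_ml` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `logLik`, `simulate`.
#'   Coefficients are a term x outcome matrix.
#' @examples
#' d <- data.frame(y = rep(c("a", "b"), c(30, 70)), x = rnorm(100))
#' fit <- multinom_ml(y ~ x, d, reference = "a")
#' summary(fit)
#' @export
multinom_ml <- function(formula, data, reference = NULL, centre = TRUE,
                        control = multinom_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  lev <- levels(y)
  if (length(lev) < 2L) stop("need at least two outcome categories")
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop("reference level '", reference, "' not found")
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
  X <- stats::model.matrix(mt, mf)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- lev

  fit <- .multinom_engine(X, Y, control = control)
  if (!fit$converged || max(abs(fit$B)) > 15) {
    big <- which.max(abs(fit$B))
    msg <- if (max(abs(fit$B)) > 15)
      paste0("possible perfect separation (term '",
             colnames(X)[(big - 1L) %% ncol(X) + 1L], "' diverging)")
    else paste0("did not converge in ", fit$iterations, " iterations")
    warning(msg)
  }
  B <- fit$B
  dimnames(B) <- list(colnames(X), lev[-1L])
  parnames <- as.vector(outer(colnames(X), lev[-1L],
                              function(a, b) paste(b, a, sep = ":")))
  vc <- fit$vcov
  dimnames(vc) <- list(parnames, parnames)
  se <- matrix(sqrt(pmax(diag(vc), 0)), nrow(B), ncol(B), dimnames = dimnames(B))
  z <- B / se
  P <- .multinom_probs(X %*% B)
  colnames(P) <- lev
  if (max(abs(rowSums(P) - 1)) > 1e-10)
    stop("internal error: fitted probabilities do not sum to 1")

  structure(list(call = cl, coefficients = B, vcov = vc, se = se, z = z,
                 p_values = 2 * stats::pnorm(-abs(z)),
                 odds_ratios = exp(B), fitted = P, y = y, levels = lev,
                 reference = reference, terms = mt, centres = centres,
                 log_likelihood = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, loglik_trace = fit$trace,
                 n = length(y),
                 xlevels = stats::.getXlevels(mt, mf)),
            class = "multinom_ml")
}

#' Fit a multinomial morph model on observation records
#'
#' Thin wrapper around [multinom_ml()] keeping the record-table interface.
#'
#' @param records data.frame of records (e.g. a filtered `shell_records`).
#' @param formula model formula (default: the standard morph-cline design
#'   `outcome ~ day_number + uhi * temperature * dry_days`).
#' @param outcome name of the outcome column used in the default formula.
#' @param reference reference category.
#' @param ... passed to [multinom_ml()].
#' @return a `multinom_ml` fit.
#' @export
fit_multinomial <- function(records, formula = NULL, outcome = "colour",
                            reference = NULL, ...) {
  if (is.null(formula))
    formula <- stats::as.formula(
      paste(outcome, "~ day_number + uhi * temperature * dry_days"))
  multinom_ml(formula, records, reference = reference, ...)
}

#' @export
print.multinom_ml <- function(x, ...) {
  cat("Baseline-category multinomial logit (reference: ", x$reference, ")\n",
      sep = "")
  cat("n =", x$n, " log-likelihood =", format(x$log_likelihood), "\n\n")
  cat("Coefficients (log-odds vs reference):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.multinom_ml <- function(object, ...) object$coefficients

#' @export
vcov.multinom_ml <- function(object, ...) object$vcov

#' @export
logLik.multinom_ml <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), class = "logLik")
}

#' @export
fitted.multinom_ml <- function(object, ...) object$fitted

#' @rdname multinom_ml
#' @param object,x a `multinom_ml` fit.
#' @param ... unused.
#' @export
summary.multinom_ml <- function(object, ...) {
  B <- object$coefficients
  out <- data.frame(
    outcome = rep(colnames(B), each = nrow(B)),
    term = rep(rownames(B), ncol(B)),
    estimate = as.vector(B),
    odds_ratio = as.vector(object$odds_ratios),
    se = as.vector(object$se),
    z = as.vector(object$z),
    p = as.vector(object$p_values),
    stringsAsFactors = FALSE)
  out$stars <- significance_stars(out$p)
  structure(list(table = out, reference = object$reference, n = object$n,
                 log_likelihood = object$log_likelihood,
                 converged = object$converged),
            class = "summary.multinom_ml")
}

#' @export
print.summary.multinom_ml <- function(x, ...) {
  cat("Multinomial logit (reference: ", x$reference, "), n = ", x$n,
      ", logLik = ", format(x$log_likelihood), "\n\n", sep = "")
  tab <- x$table
  tab$odds_ratio <- round(tab$odds_ratio, 3)
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
predict.multinom_ml <- function(object, newdata = NULL,
                                type = c("probs", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    P <- object$fitted
  } else {
    tt <- stats::delete.response(object$terms)
    for (v in names(object$centres))
      if (v %in% names(newdata))
        newdata[[v]] <- newdata[[v]] - object$centres[v]
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    P <- .multinom_probs(X %*% object$coefficients)
    colnames(P) <- object$levels
  }
  switch(type,
         probs = P,
         class = factor(object$levels[max.col(P)], levels = object$levels),
         link = log(P[, -1L, drop = FALSE] / P[, 1L]))
}

#' Residuals of a multinomial fit
#'
#' `type = "reference"` returns the reference-category residual used for the
#' spatial diagnostics: `1(outcome == reference) - fitted_prob(reference)`.
#' `type = "raw"` returns the full indicator-minus-probability matrix.
#'
#' @param object a `multinom_ml` fit.
#' @param type `"reference"` or `"raw"`.
#' @param ... unused.
#' @export
residuals.multinom_ml <- function(object, type = c("reference", "raw"), ...) {
  type <- match.arg(type)
  Y <- stats::model.matrix(~ object$y - 1)
  colnames(Y) <- object$levels
  if (type == "reference")
    Y[, 1L] - object$fitted[, 1L]
  else
    Y - object$fitted
}

#' Reference-category residuals
#'
#' Standalone form of `residuals(fit, type = "reference")`: the indicator of
#' the reference outcome minus its fitted probability, per record.
#'
#' @param fit a `multinom_ml` (or smoothed) fit.
#' @param reference optional alternative category to treat as reference.
#' @return numeric vector, one residual per record.
#' @export
reference_residuals <- function(fit, reference = NULL) {
  if (is.null(reference) || identical(reference, fit$reference))
    return(residuals.multinom_ml(fit, type = "reference"))
  if (!reference %in% fit$levels) stop("unknown category '", reference, "'")
  (fit$y == reference) - fit$fitted[, reference]
}

#' @export
simulate.multinom_ml <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    P <- object$fitted
    out <- replicate(nsim, factor(object$levels[.rcat(P)],
                                  levels = object$levels),
                     simplify = FALSE)
    names(out) <- paste0("sim_", seq_len(nsim))
    as.data.frame(out)
  })
}

#' Write a fit summary as CSV (regression-table layout)
#'
#' Columns `outcome, term, odds_ratio, z, p, stars`, mirroring the layout of
#' a published multinomial regression table.
#'
#' @param fit a `multinom_ml` fit.
#' @param path output CSV path.
#' @export
write_fit_summary <- function(fit, path) {
  tab <- summary(fit)$table[, c("outcome", "term", "odds_ratio", "z", "p", "stars")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
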