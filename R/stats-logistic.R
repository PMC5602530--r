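## Maximum-likelihood logistic regression by iteratively reweighted least
## squares, with Wald inference on the odds scale.

#' Fit a logistic regression by IRLS
#'
#' Binomial log-likelihood maximized by iteratively reweighted least squares
#' with a convergence tolerance of `tol` on the log-likelihood and at most
#' `maxit` iterations. Wald 95% confidence intervals are reported on the
#' exponential (odds-ratio) scale. Apparent separation (diverging
#' coefficients or failure to converge) is flagged with `converged = FALSE`
#' and a warning; coefficients are still reported.
#'
#' @param design numeric matrix or data.frame of covariates (no intercept
#'   column; one is added). May have zero columns for an intercept-only fit.
#' @param outcome binary vector (0/1 or logical) with both classes present.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100).
#' @return A [LogisticFit-class].
#' @examples
#' fit <- fitLogistic(data.frame(x = c(1, 1, 0, 0, 1, 0)),
#'                    c(1, 1, 0, 1, 0, 0))
#' fit@oddsRatios
#' @export
fitLogistic <- function(design, outcome, tol = 1e-8, maxit = 100L) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  X <- if (is.null(design) || NCOL(design) == 0L)
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  else {
    d <- as.matrix(as.data.frame(design))
    storage.mode(d) <- "double"
    cbind("(Intercept)" = 1, d)
  }
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("design and outcome lengths differ")
  if (n <= p) stop("need more observations than coefficients")
  if (anyNA(X)) stop("design contains missing values")

  beta <- rep(0, p)
  llOld <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (is.finite(ll) && abs(ll - llOld) < tol) { converged <- TRUE; break }
    llOld <- ll
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  ## a log-likelihood at (numerically) zero means every observation is
  ## fitted to its class exactly - the signature of perfect separation
  if (max(abs(beta)) > 30 || ll > -1e-6 * length(y)) converged <- FALSE
  if (!converged)
    warning("logistic fit did not converge (possible perfect separation); ",
            "coefficients reported with converged = FALSE")

  w <- mu * (1 - mu)
  vcov <- tryCatch(solve(crossprod(X, X * w)),
                   error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  zcrit <- qnorm(0.975)
  ci <- cbind(lower = exp(beta - zcrit * se), upper = exp(beta + zcrit * se))
  rownames(ci) <- colnames(X)
  pv <- 2 * pnorm(-abs(beta / se))
  names(beta) <- names(se) <- names(pv) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  new("LogisticFit", coefficients = beta, oddsRatios = exp(beta), ci = ci,
      pValues = pv, se = se, vcov = vcov, converged = converged,
      nIterations = iter, logLik = ll)
}
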