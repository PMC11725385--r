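# Maximum-likelihood beta regression with a logit mean link and common
# precision, plus Wald pairwise group contrasts.

# Negative log-likelihood and analytic gradient in theta = (beta, log phi).
.betaNll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.betaGrad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  ystar <- log(y / (1 - y))
  mustar <- digamma(a) - digamma(b)
  # score wrt eta_i, then chain through the logistic link
  deta <- phi * (ystar - mustar) * mu * (1 - mu)
  gbeta <- -colSums(X * deta)
  dphi <- sum(mu * (ystar - mustar) + log(1 - y) - digamma(b) +
                digamma(phi))
  c(gbeta, -dphi * phi)
}

#' Fit a beta regression of a unit-interval response on group labels
#'
#' Maximises the beta log-likelihood with mean
#' \eqn{\mu_i = logistic(x_i^T\beta)} and shapes
#' \eqn{(\mu_i\phi, (1-\mu_i)\phi)} by BFGS with an analytic gradient.
#' Initialisation: ordinary least squares of `qlogis(y)` on the design
#' for \eqn{\beta}; a method-of-moments value for \eqn{\phi} from the
#' OLS residual variance mapped through the link (clamped to
#' `[1, 1e4]`).  Standard errors come from the inverse observed
#' information at the optimum; non-convergence is flagged on the fit and
#' warned about, never silent.
#'
#' @param y responses strictly inside (0, 1) (see
#'   [squeezeToUnitInterval()]).
#' @param groups factor (or coercible) of group labels; the design is
#'   `model.matrix(~ groups)` (treatment coding).  `n` must exceed the
#'   number of groups.
#' @return A [BetaRegressionFit-class].
#' @export
fitBetaRegression <- function(y, groups) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    .stopf("y must lie strictly inside (0, 1); squeeze first")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != length(y)) .stopf("y and groups lengths differ")
  if (length(y) <= nlevels(groups))
    .stopf("need more observations than groups")
  X <- if (nlevels(groups) == 1L) {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~groups)
  }
  colnames(X) <- sub("^groups", "", colnames(X))
  p <- ncol(X)

  # documented initialisation
  z <- stats::qlogis(y)
  fit0 <- stats::lm.fit(X, z)
  beta0 <- fit0$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  sigma2 <- sum(fit0$residuals^2) / max(1, length(y) - p)
  vary <- sigma2 * (mu0 * (1 - mu0))^2   # delta method back to response scale
  phi0 <- mean(mu0 * (1 - mu0) / pmax(vary, 1e-10)) - 1
  phi0 <- min(max(phi0, 1), 1e4)
  theta0 <- c(beta0, log(phi0))

  opt <- stats::optim(theta0, .betaNll, gr = .betaGrad, X = X, y = y,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- stats::optimHess(opt$par, .betaNll, gr = .betaGrad, X = X, y = y)
  V <- tryCatch(solve(H), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(V) &&
    all(diag(V)[seq_len(p)] > 0)
  if (!converged)
    warning("beta regression did not converge cleanly; inspect the fit")
  if (is.null(V)) V <- matrix(NA_real_, p + 1L, p + 1L)
  dimnames(V) <- list(c(colnames(X), "log(phi)"),
                      c(colnames(X), "log(phi)"))
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
  names(se) <- colnames(X)
  new("BetaRegressionFit", coefficients = beta,
      phi = unname(exp(opt$par[p + 1L])), se = se, vcov = V,
      logLik = -opt$value, converged = converged, groups = groups, y = y)
}

#' Wald pairwise group contrasts with Holm adjustment
#'
#' Tests every pairwise difference of group means on the logit scale
#' using Wald z statistics built from the fit's variance-covariance
#' matrix; p-values are Holm-adjusted for the number of contrasts.
#' (Holm replaces Tukey's HSD: the studentised-range distribution is
#' not defined for beta-regression contrasts.)
#'
#' @param fit a [BetaRegressionFit-class] from [fitBetaRegression()].
#' @return data.frame with columns `contrast`, `estimate`, `se`, `z`,
#'   `p`, `p_adj`.
#' @export
pairwiseGroupTests <- function(fit) {
  lev <- levels(fit@groups)
  if (length(lev) < 2L) .stopf("need at least 2 groups")
  p <- length(fit@coefficients)
  # row of the design giving each group's linear predictor
  L <- matrix(0, length(lev), p, dimnames = list(lev, names(fit@coefficients)))
  L[, 1L] <- 1
  for (k in seq_along(lev)[-1L]) L[k, lev[k]] <- 1
  Vb <- fit@vcov[seq_len(p), seq_len(p), drop = FALSE]
  pairs <- utils::combn(lev, 2L)
  out <- data.frame(contrast = character(0), estimate = numeric(0),
                    se = numeric(0), z = numeric(0), p = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    v <- L[a, ] - L[b, ]
    est <- sum(v * fit@coefficients)
    se2 <- drop(t(v) %*% Vb %*% v)
    if (!is.finite(se2) || se2 <= 0)
      .stopf("singular contrast %s - %s", a, b)
    se <- sqrt(se2)
    z <- est / se
    out <- rbind(out, data.frame(contrast = paste(a, b, sep = " - "),
                                 estimate = est, se = se, z = z,
                                 p = 2 * stats::pnorm(-abs(z))))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
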