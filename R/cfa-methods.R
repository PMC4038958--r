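#' @export
print.cfa_fit <- function(x, ...) {
  cat("Confirmatory factor analysis fit (maximum likelihood)\n")
  cat("  factors:", length(x$model$factors),
      " indicators:", length(x$model$indicators),
      " groups:", length(x$group_levels), "\n")
  cat("  n =", x$n, " free parameters =", x$k,
      " df =", model_df(x$model, length(x$group_levels), x$group_equal,
                        x$meanstructure, x$identification), "\n")
  cat("  log-likelihood =", format(x$loglik, nsmall = 2), "\n")
  invisible(x)
}

#' @export
coef.cfa_fit <- function(object, ...) object$coefficients

#' @export
logLik.cfa_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.cfa_fit <- function(object, ...) object$n

#' Asymptotic covariance matrix of the estimates
#'
#' Inverse of \eqn{n} times the per-observation information matrix
#' (observed by default).
#' @param object a \code{cfa_fit}.
#' @param kind information matrix used; see \code{\link{info_matrix}}.
#' @param ... unused.
#' @export
vcov.cfa_fit <- function(object, kind = "observed", ...) {
  I <- info_matrix(object, kind)
  V <- solve(object$n * I)
  dimnames(V) <- list(names(object$coefficients),
                      names(object$coefficients))
  V
}

#' @export
summary.cfa_fit <- function(object, kind = "observed", ...) {
  se <- sqrt(diag(vcov(object, kind)))
  est <- object$coefficients
  tab <- data.frame(estimate = est, se = se, z = est / se,
                    row.names = names(est))
  out <- list(fit = object, table = tab,
              aic = -2 * object$loglik + 2 * object$k,
              bic = -2 * object$loglik + object$k * log(object$n))
  class(out) <- "summary.cfa_fit"
  out
}

#' @export
print.summary.cfa_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$n_dropped > 0)
    cat("  (", x$fit$n_dropped, "incomplete rows dropped )\n")
  cat("  AIC =", format(x$aic, nsmall = 1),
      "  BIC =", format(x$bic, nsmall = 1), "\n\n")
  printCoefmat(as.matrix(x$table), digits = 4)
  invisible(x)
}

#' Model-implied moments
#' @param object a \code{cfa_fit}.
#' @param ... unused.
#' @return named list per group with elements \code{mu} and \code{Sigma}.
#' @export
fitted.cfa_fit <- function(object, ...) {
  out <- lapply(seq_along(object$group_levels), function(g) {
    implied_moments(pt_matrices(object$ptable, object$coefficients, g))
  })
  names(out) <- object$group_levels
  out
}

#' @export
residuals.cfa_fit <- function(object, ...) {
  mom <- fitted(object)
  R <- object$X
  for (g in seq_along(object$group_levels)) {
    idx <- object$group_index == g
    R[idx, ] <- sweep(R[idx, , drop = FALSE], 2, mom[[g]]$mu)
  }
  R
}

#' Simulate data from a fitted CFA model
#'
#' Draws multivariate-normal observations from the model-implied moments,
#' preserving the group sizes of the original data.
#' @param object a \code{cfa_fit}.
#' @param nsim number of simulated data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of data frames (length \code{nsim}).
#' @export
simulate.cfa_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mom <- fitted(object)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    X <- object$X
    for (g in seq_along(object$group_levels)) {
      idx <- which(object$group_index == g)
      X[idx, ] <- rmvnorm_chol(length(idx), mom[[g]]$mu, mom[[g]]$Sigma)
    }
    d <- as.data.frame(X)
    if (!is.null(object$group))
      d[[object$group]] <- object$group_levels[object$group_index]
    out[[s]] <- d
  }
  if (nsim == 1) out[[1L]] else out
}

rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% chol(Sigma), 2, mu, `+`)
}

#' Casewise log-likelihoods of a fitted model
#' @param fit a \code{cfa_fit}.
#' @return numeric vector of length \code{n}, in input row order.
#' @export
casewise_loglik <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  fit$casewise
}

#' Casewise score matrix
#'
#' Row \eqn{i} holds the gradient of \eqn{\ell(\theta; x_i)} with respect to
#' the free parameters, evaluated at the ML estimate; equality-constrained
#' parameters accumulate their chain-rule contributions. Column sums are zero
#' up to the first-order condition. Gradients are analytic; set
#' \code{method = "numeric"} for a central finite-difference fallback.
#'
#' @param fit a converged \code{cfa_fit}.
#' @param method \code{"analytic"} (default) or \code{"numeric"}.
#' @return an \code{n x k} matrix with parameter labels as column names.
#' @export
scores <- function(fit, method = c("analytic", "numeric")) {
  stopifnot(inherits(fit, "cfa_fit"))
  method <- match.arg(method)
  S <- if (method == "analytic") {
    score_matrix_internal(fit$coefficients, fit$ptable, fit$X,
                          fit$group_index)
  } else {
    score_matrix_fd(fit$coefficients, fit$ptable, fit$X, fit$group_index)
  }
  colnames(S) <- names(fit$coefficients)
  S
}

score_matrix_fd <- function(theta, ptable, X, group_index, h = 1e-5) {
  k <- length(theta)
  S <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    hp <- h * (1 + abs(theta[j]))
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + hp; tm[j] <- tm[j] - hp
    S[, j] <- (casewise_loglik_all(tp, ptable, X, group_index) -
                 casewise_loglik_all(tm, ptable, X, group_index)) / (2 * hp)
  }
  S
}

#' @exportS3Method sandwich::estfun
estfun.cfa_fit <- function(x, ...) scores(x)

#' Information matrix of a fitted model
#'
#' Per-observation information: \code{"observed"} is minus the Hessian of
#' the total log-likelihood at the estimate divided by \eqn{n} (computed by
#' central differences of the analytic gradient); \code{"opg"} is the outer
#' product of the casewise scores divided by \eqn{n}; \code{"expected"} is
#' the analytic Fisher information at the estimate, group-weighted.
#'
#' @param fit a converged \code{cfa_fit}.
#' @param kind one of \code{"observed"}, \code{"opg"}, \code{"expected"}.
#' @return a symmetric \code{k x k} matrix.
#' @export
info_matrix <- function(fit, kind = c("observed", "opg", "expected")) {
  stopifnot(inherits(fit, "cfa_fit"))
  kind <- match.arg(kind)
  I <- switch(kind,
    observed = observed_info_internal(fit$coefficients, fit$ptable,
                                      fit$suffstats, fit$n),
    opg = crossprod(scores(fit)) / fit$n,
    expected = expected_info_internal(
      fit$coefficients, fit$ptable,
      vapply(fit$suffstats, `[[`, 0, "n") / fit$n))
  if (kind == "observed") {
    ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      warning("observed information is numerically indefinite; ",
              "consider kind = 'expected' or 'opg'")
  }
  dimnames(I) <- list(names(fit$coefficients), names(fit$coefficients))
  I
}

#' Likelihood ratio test of nested CFA fits
#'
#' @param full fit with more free parameters.
#' @param restricted nested fit on the same data.
#' @return data frame with the statistic, degrees of freedom and p-value.
#' @examples
#' # chi-square upper tail used on (38.1, 20) gives p = 0.0087
#' @export
lr_test <- function(full, restricted) {
  stopifnot(inherits(full, "cfa_fit"), inherits(restricted, "cfa_fit"))
  if (full$k < restricted$k)
    stop("'full' must have at least as many free parameters as 'restricted'",
         call. = FALSE)
  if (full$n != restricted$n)
    stop("fits use different numbers of observations", call. = FALSE)
  stat <- 2 * (full$loglik - restricted$loglik)
  if (stat < -1e-6)
    stop("negative likelihood-ratio statistic: models are not nested or a ",
         "fit did not reach its optimum", call. = FALSE)
  stat <- max(stat, 0)
  df <- full$k - restricted$k
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p.value = p)
}

#' @export
anova.cfa_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- fits[vapply(fits, inherits, TRUE, "cfa_fit")]
  if (length(fits) != 2L)
    stop("anova() for cfa_fit compares exactly two nested fits",
         call. = FALSE)
  ord <- order(vapply(fits, `[[`, 0L, "k"), decreasing = TRUE)
  full <- fits[[ord[1L]]]; restr <- fits[[ord[2L]]]
  lrt <- lr_test(full, restr)
  mdf <- function(f) model_df(f$model, length(f$group_levels), f$group_equal,
                              f$meanstructure, f$identification)
  tab <- data.frame(
    Df = c(mdf(full), mdf(restr)),
    AIC = c(-2 * full$loglik + 2 * full$k,
            -2 * restr$loglik + 2 * restr$k),
    BIC = c(-2 * full$loglik + full$k * log(full$n),
            -2 * restr$loglik + restr$k * log(restr$n)),
    `Chisq diff` = c(NA, lrt$statistic),
    `Df diff` = c(NA, lrt$df),
    `Pr(>Chisq)` = c(NA, lrt$p.value),
    row.names = c("full", "restricted"), check.names = FALSE)
  structure(tab, heading = "Chi Square Difference Test",
            class = c("anova", "data.frame"))
}
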